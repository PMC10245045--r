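#' Assign reads to isoforms of their gene of origin
#'
#' Aligns each read against every isoform transcript of its (truth-known)
#' gene with a banded fitting alignment (read global, transcript ends free,
#' so 5'-truncated reads still fit). The read is assigned to the isoform
#' with the smallest edit distance when the per-base edit rate is at most
#' `assign_threshold` and the margin to the runner-up exceeds `margin_min`;
#' otherwise it stays unassigned. Reverse-strand reads are oriented first.
#' Deterministic throughout.
#'
#' @param reads read tibble (raw or corrected; ids must appear in `truth`).
#' @param genes gene models from [simulate_genes()].
#' @param truth truth tibble from [simulate_reads()].
#' @param assign_threshold maximum edit rate (edit distance / read length)
#'   for an assignment; use a looser value for raw reads (default 0.30)
#'   than for corrected reads (0.10).
#' @param margin_min minimum edit-distance margin to the second-best
#'   isoform.
#' @param band half-band width for the fitting alignment; must exceed the
#'   largest skipped-exon length plus indel drift.
#' @return tibble: `read_id`, `gene_id`, `isoform_id` (`NA` when
#'   unassigned), `best_dist`, `best_rate`, `margin`.
#' @export
assign_isoforms <- function(reads, genes, truth, assign_threshold = 0.30,
                            margin_min = 20, band = 200L) {
  tx <- gene_transcripts(genes)
  tr <- truth[match(reads$read_id, truth$read_id), ]
  if (anyNA(tr$read_id))
    stop("missing truth record for read(s): ",
         paste(utils::head(reads$read_id[is.na(tr$read_id)], 3), collapse = ", "))
  tx_by_gene <- split(tx, tx$gene_id)
  n <- nrow(reads)
  iso <- character(n); bd <- integer(n); mg <- numeric(n)
  for (j in seq_len(n)) {
    s <- reads$sequence[j]
    if (tr$strand[j] == "-") s <- cpp_revcomp(s)
    gt <- tx_by_gene[[tr$gene_id[j]]]
    d <- vapply(gt$sequence, function(t)
      cpp_fit_distance(s, t, as.integer(band)), integer(1), USE.NAMES = FALSE)
    o <- order(d, gt$isoform_id)
    best <- o[1]
    margin <- if (nrow(gt) > 1) d[o[2]] - d[o[1]] else Inf
    rate <- d[best] / nchar(s)
    iso[j] <- if (rate <= assign_threshold && margin > margin_min)
      gt$isoform_id[best] else NA_character_
    bd[j] <- d[best]; mg[j] <- margin
  }
  tibble::tibble(read_id = reads$read_id, gene_id = tr$gene_id,
                 isoform_id = iso, best_dist = bd,
                 best_rate = bd / nchar(reads$sequence), margin = mg)
}

#' Relative coverage of each isoform among a gene's raw reads
#'
#' The relative coverage of an isoform is the fraction of the gene's raw
#' reads assigned to it: `isoform reads / all reads of the gene`. Low
#' values mark weakly expressed (minor) isoforms, the ones most at risk of
#' being erased by error correction.
#'
#' @param assignments assignment tibble from [assign_isoforms()] on the raw
#'   reads.
#' @return tibble: `gene_id`, `isoform_id`, `n_assigned`, `n_gene_reads`,
#'   `rel_cov`.
#' @export
relative_coverage <- function(assignments) {
  totals <- dplyr::count(assignments, .data$gene_id, name = "n_gene_reads")
  asg <- dplyr::filter(assignments, !is.na(.data$isoform_id))
  out <- dplyr::count(asg, .data$gene_id, .data$isoform_id, name = "n_assigned")
  out <- dplyr::left_join(out, totals, by = "gene_id")
  out$rel_cov <- out$n_assigned / out$n_gene_reads
  out
}

#' Rebuild a minimal gene-model table from transcripts and truth
#'
#' For evaluation runs that start from files rather than in-memory
#' simulator output: groups transcript sequences (ids matching the truth's
#' `isoform_id`) by gene. Abundances are unknown and left `NA`; nothing in
#' the evaluators uses them.
#'
#' @param transcripts read tibble of transcript sequences (`read_id` =
#'   isoform id).
#' @param truth truth tibble linking `isoform_id` to `gene_id`.
#' @return gene-model tibble compatible with [gene_transcripts()].
#' @export
transcripts_to_genes <- function(transcripts, truth) {
  map <- dplyr::distinct(truth[, c("gene_id", "isoform_id")])
  miss <- setdiff(map$isoform_id, transcripts$read_id)
  if (length(miss) > 0)
    stop("transcript sequence missing for: ", paste(utils::head(miss, 3), collapse = ", "))
  map$sequence <- transcripts$sequence[match(map$isoform_id, transcripts$read_id)]
  map$abundance <- NA_real_
  nested <- tidyr::nest(map, isoforms = c("isoform_id", "abundance", "sequence"))
  tibble::tibble(gene_id = nested$gene_id,
                 n_exons = NA_integer_,
                 exons = vector("list", nrow(nested)),
                 isoforms = nested$isoforms)
}

#' Basic read properties of a corrected set
#'
#' Throughput (read/base counts and fractions of the raw set), length
#' statistics, and error rates measured by aligning every corrected read to
#' its true transcript: the error rate is the number of non-matching bases
#' (mismatch + insertion + deletion) over the number of corrected bases,
#' split by type. Reads whose best alignment exceeds `map_threshold` count
#' as unmapped and are excluded from the rate denominators.
#'
#' @param raw_reads,corrected_reads read tibbles; corrected ids must be a
#'   subset of raw ids.
#' @param genes,truth simulator output.
#' @param map_threshold edit-rate above which a read is unmapped.
#' @param band fitting-alignment half-band.
#' @return one-row tibble of metrics (`n_read`, `pct_read`, `n_base`,
#'   `pct_base`, `min_size`, `mean_size`, `max_size`, `n_umr`, `pct_umr`,
#'   `error_rate`, `mismatch_rate`, `insert_rate`, `delete_rate`; rates as
#'   fractions).
#' @export
compute_read_metrics <- function(raw_reads, corrected_reads, genes, truth,
                                 map_threshold = 0.35, band = 200L) {
  stopifnot(all(corrected_reads$read_id %in% raw_reads$read_id))
  n_raw <- nrow(raw_reads)
  raw_bases <- sum(nchar(raw_reads$sequence))
  n <- nrow(corrected_reads)
  if (n == 0) {
    return(tibble::tibble(n_read = 0L, pct_read = 0, n_base = 0, pct_base = 0,
                          min_size = NA_integer_, mean_size = NA_real_,
                          max_size = NA_integer_, n_umr = 0L, pct_umr = NA_real_,
                          error_rate = NA_real_, mismatch_rate = NA_real_,
                          insert_rate = NA_real_, delete_rate = NA_real_))
  }
  tx <- gene_transcripts(genes)
  tr <- truth[match(corrected_reads$read_id, truth$read_id), ]
  if (anyNA(tr$read_id)) stop("missing truth record for corrected read(s)")
  lens <- nchar(corrected_reads$sequence)
  nmis <- nins <- ndel <- integer(n)
  unmapped <- logical(n)
  for (j in seq_len(n)) {
    s <- corrected_reads$sequence[j]
    if (tr$strand[j] == "-") s <- cpp_revcomp(s)
    t <- tx$sequence[match(tr$isoform_id[j], tx$isoform_id)]
    al <- cpp_fit_align_counts(s, t, as.integer(band))
    if (is.na(al$dist) ||
        (al$nmis + al$nins + al$ndel) / nchar(s) > map_threshold) {
      unmapped[j] <- TRUE
    } else {
      nmis[j] <- al$nmis; nins[j] <- al$nins; ndel[j] <- al$ndel
    }
  }
  mapped_bases <- sum(lens[!unmapped])
  tibble::tibble(
    n_read = n, pct_read = 100 * n / n_raw,
    n_base = sum(lens), pct_base = 100 * sum(lens) / raw_bases,
    min_size = min(lens), mean_size = mean(lens), max_size = max(lens),
    n_umr = sum(unmapped), pct_umr = 100 * sum(unmapped) / n,
    error_rate = sum(nmis + nins + ndel) / mapped_bases,
    mismatch_rate = sum(nmis) / mapped_bases,
    insert_rate = sum(nins) / mapped_bases,
    delete_rate = sum(ndel) / mapped_bases)
}

#' Isoform retention after correction
#'
#' For each gene, the isoform set *before* correction is the set of
#' isoforms with at least one assigned raw read, and *after* is the same
#' over the corrected reads. The per-gene change in isoform count feeds a
#' delta histogram (clipped at +/-3); every isoform present before gets a
#' relative-coverage bin (`(0,0.1], (0.1,0.2], ..., (0.9,1]` of the gene's
#' raw reads) and is *lost* when absent after correction. Minor isoforms
#' live in the low bins, so a correction method that erases them shows its
#' losses concentrated there.
#'
#' @param raw_reads,corrected_reads read tibbles.
#' @param genes,truth simulator output.
#' @param raw_threshold,corrected_threshold assignment edit-rate thresholds
#'   for the raw and corrected sets.
#' @param margin_min,band see [assign_isoforms()].
#' @param raw_assignments optional precomputed [assign_isoforms()] result
#'   for the raw reads (reused across paired evaluations).
#' @return an `isocorr_retention` object: list with `per_gene` (before/
#'   after/delta per gene), `delta_histogram`, `isoforms` (per-isoform
#'   coverage and loss flags), `by_coverage` (per-bin totals, losses and
#'   loss fraction) and the assignment tibbles. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
isoform_retention <- function(raw_reads, corrected_reads, genes, truth,
                              raw_threshold = 0.30, corrected_threshold = 0.10,
                              margin_min = 20, band = 200L,
                              raw_assignments = NULL) {
  raw_asg <- raw_assignments %||%
    assign_isoforms(raw_reads, genes, truth, raw_threshold, margin_min, band)
  cor_asg <- assign_isoforms(corrected_reads, genes, truth,
                             corrected_threshold, margin_min, band)
  before <- dplyr::distinct(dplyr::filter(raw_asg, !is.na(.data$isoform_id)),
                            .data$gene_id, .data$isoform_id)
  after <- dplyr::distinct(dplyr::filter(cor_asg, !is.na(.data$isoform_id)),
                           .data$gene_id, .data$isoform_id)
  nb <- dplyr::count(before, .data$gene_id, name = "n_before")
  na_ <- dplyr::count(after, .data$gene_id, name = "n_after")
  per_gene <- dplyr::left_join(nb, na_, by = "gene_id")
  per_gene$n_after[is.na(per_gene$n_after)] <- 0L
  per_gene$delta <- per_gene$n_after - per_gene$n_before
  clipped <- pmax(-3L, pmin(3L, per_gene$delta))
  delta_histogram <- tibble::tibble(delta = -3:3)
  delta_histogram$n_genes <- vapply(delta_histogram$delta,
                                    function(d) sum(clipped == d), integer(1))
  rc <- relative_coverage(raw_asg)
  lost_tbl <- dplyr::anti_join(before, after, by = c("gene_id", "isoform_id"))
  isoforms <- dplyr::semi_join(rc, before, by = c("gene_id", "isoform_id"))
  isoforms$lost <- paste(isoforms$gene_id, isoforms$isoform_id) %in%
    paste(lost_tbl$gene_id, lost_tbl$isoform_id)
  edges <- seq(0, 1, by = 0.1)
  isoforms$bin <- cut(isoforms$rel_cov, breaks = edges, include.lowest = FALSE,
                      labels = sprintf("%.1f", edges[-1]))
  by_coverage <- dplyr::summarise(
    dplyr::group_by(isoforms, .data$bin, .drop = FALSE),
    n_isoforms = dplyr::n(), n_lost = sum(.data$lost), .groups = "drop")
  by_coverage$loss_frac <- ifelse(by_coverage$n_isoforms > 0,
                                  by_coverage$n_lost / by_coverage$n_isoforms, 0)
  structure(list(per_gene = per_gene, delta_histogram = delta_histogram,
                 isoforms = isoforms, by_coverage = by_coverage,
                 raw_assignments = raw_asg, corrected_assignments = cor_asg),
            class = "isocorr_retention")
}

#' @export
print.isocorr_retention <- function(x, ...) {
  cat(sprintf("<isocorr_retention> %d genes, %d isoforms before, %d lost\n",
              nrow(x$per_gene), nrow(x$isoforms), sum(x$isoforms$lost)))
  invisible(x)
}

#' @describeIn isoform_retention per-bin loss table.
#' @param x an `isocorr_retention` object.
#' @param ... unused.
#' @export
tidy.isocorr_retention <- function(x, ...) x$by_coverage

#' @describeIn isoform_retention one-row summary: genes evaluated, genes
#'   with reduced/unchanged/increased isoform counts, total isoforms lost.
#' @export
glance.isocorr_retention <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$per_gene),
                 reduced = sum(x$per_gene$delta < 0),
                 unchanged = sum(x$per_gene$delta == 0),
                 increased = sum(x$per_gene$delta > 0),
                 n_isoforms = nrow(x$isoforms),
                 n_lost = sum(x$isoforms$lost))
}

#' @describeIn isoform_retention bar chart of the loss fraction per
#'   relative-coverage bin.
#' @param object an `isocorr_retention` object.
#' @export
autoplot.isocorr_retention <- function(object, ...) {
  ggplot2::ggplot(object$by_coverage,
                  ggplot2::aes(x = .data$bin, y = .data$loss_frac)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relative coverage bin (upper edge)",
                  y = "fraction of isoforms lost",
                  title = "Isoform loss by relative coverage") +
    ggplot2::theme_minimal()
}
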