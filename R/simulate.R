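BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# sample() treats a length-1 numeric x as 1:x; this version never does
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

seq_kmers <- function(s, k = 13L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Simulate gene models with alternative isoforms
#'
#' Generates multi-exon genes whose isoforms differ by exon skipping: the
#' major isoform uses every exon, each minor isoform drops one distinct
#' internal exon. Exon sequences are drawn uniformly over `A/C/G/T` with a
#' uniqueness guard (no 13-mer shared between two exons of the same gene),
#' so isoform assignment is never trivially ambiguous. Per-gene isoform
#' abundances give each minor isoform `minor_abundance`, the remainder to
#' the major isoform. Defaults target transcripts of roughly 1.5 kb, the
#' typical full-length mRNA scale.
#'
#' @param n_genes number of genes.
#' @param isoform_range integer `c(min, max)` isoforms per gene.
#' @param exon_count_range integer `c(min, max)` exons per gene.
#' @param exon_length_range integer `c(min, max)` exon length (bases).
#' @param minor_abundance abundance of each minor isoform, in `(0, 0.5]`.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return tibble of gene models: `gene_id`, `n_exons`, list-column `exons`
#'   (exon sequences in order) and list-column `isoforms` (tibble with
#'   `isoform_id`, `exon_chain`, `abundance`, `sequence`).
#' @examples
#' genes <- simulate_genes(n_genes = 2, isoform_range = c(2, 2), seed = 1)
#' gene_transcripts(genes)
#' @export
simulate_genes <- function(n_genes, isoform_range = c(1L, 2L),
                           exon_count_range = c(5L, 7L),
                           exon_length_range = c(150L, 300L),
                           minor_abundance = 0.2, seed = 1L) {
  stopifnot(n_genes >= 1, length(isoform_range) == 2,
            isoform_range[1] >= 1, isoform_range[1] <= isoform_range[2],
            exon_count_range[1] >= 1, exon_count_range[1] <= exon_count_range[2],
            exon_length_range[1] >= 20, exon_length_range[1] <= exon_length_range[2],
            minor_abundance > 0, minor_abundance <= 0.5)
  if (isoform_range[2] > 1 && exon_count_range[1] - 2L < isoform_range[2] - 1L)
    stop("infeasible ranges: need at least ", isoform_range[2] + 1L,
         " exons for ", isoform_range[2], " skip isoforms")
  if ((isoform_range[2] - 1L) * minor_abundance >= 1)
    stop("infeasible minor_abundance: abundances must sum below 1")
  withr::with_seed(seed, {
    genes <- lapply(seq_len(n_genes), function(g) {
      gene_id <- sprintf("g%04d", g)
      n_ex <- resample(exon_count_range[1]:exon_count_range[2])
      exons <- character(n_ex)
      seen <- character(0)
      for (e in seq_len(n_ex)) {
        for (try in 1:50) {
          len <- resample(exon_length_range[1]:exon_length_range[2])
          s <- random_seq(len)
          km <- seq_kmers(s)
          if (!any(km %in% seen)) break
        }
        exons[e] <- s
        seen <- c(seen, km)
      }
      n_iso <- resample(isoform_range[1]:isoform_range[2])
      chains <- list(seq_len(n_ex))
      if (n_iso > 1) {
        skip <- resample(2:(n_ex - 1L), n_iso - 1L)
        for (sk in skip) chains[[length(chains) + 1L]] <- setdiff(seq_len(n_ex), sk)
      }
      ab <- c(1 - (n_iso - 1L) * minor_abundance,
              rep(minor_abundance, n_iso - 1L))
      isoforms <- tibble::tibble(
        isoform_id = sprintf("%s.i%d", gene_id, seq_len(n_iso)),
        exon_chain = chains,
        abundance = ab,
        sequence = vapply(chains, function(ch) paste(exons[ch], collapse = ""),
                          character(1)))
      tibble::tibble(gene_id = gene_id, n_exons = n_ex,
                     exons = list(exons), isoforms = list(isoforms))
    })
    dplyr::bind_rows(genes)
  })
}

#' Flatten gene models to one row per transcript
#'
#' @param genes output of [simulate_genes()].
#' @return tibble: `gene_id`, `isoform_id`, `abundance`, `length`,
#'   `sequence`.
#' @export
gene_transcripts <- function(genes) {
  out <- tidyr::unnest(genes[, c("gene_id", "isoforms")], "isoforms")
  out$length <- nchar(out$sequence)
  out[, c("gene_id", "isoform_id", "abundance", "length", "sequence")]
}

# apply recorded edits (0-based positions on the true sequence) to rebuild
# the read; inverse of the error injection, used to check conservation
apply_edits <- function(true_seq, edits) {
  chars <- strsplit(true_seq, "", fixed = TRUE)[[1]]
  out <- as.list(chars)
  for (r in seq_len(nrow(edits))) {
    p <- edits$pos[r] + 1L
    switch(edits$type[r],
           mismatch = { out[[p]][1] <- edits$new[r] },
           delete = { out[[p]] <- out[[p]][-1] },
           insert = { out[[p]] <- c(out[[p]], edits$new[r]) })
  }
  paste(unlist(out), collapse = "")
}

inject_errors <- function(true_seq, mismatch_rate, insert_rate, delete_rate,
                          keep_edits = FALSE) {
  chars <- strsplit(true_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  del <- stats::runif(n) < delete_rate
  mis <- !del & (stats::runif(n) < mismatch_rate)
  ins <- stats::runif(n) < insert_rate
  sub_off <- sample(1:3, n, replace = TRUE)
  code <- match(chars, BASES) - 1L
  sub_base <- BASES[(code + sub_off) %% 4L + 1L]
  ins_base <- sample(BASES, n, replace = TRUE)
  emitted <- ifelse(del, "", ifelse(mis, sub_base, chars))
  inserted <- ifelse(ins, ins_base, "")
  seq <- paste(paste0(emitted, inserted), collapse = "")
  edits <- NULL
  if (keep_edits) {
    rows <- list(
      tibble::tibble(pos = which(mis) - 1L, type = "mismatch",
                     orig = chars[mis], new = sub_base[mis]),
      tibble::tibble(pos = which(del) - 1L, type = "delete",
                     orig = chars[del], new = NA_character_),
      tibble::tibble(pos = which(ins) - 1L, type = "insert",
                     orig = NA_character_, new = ins_base[ins]))
    edits <- dplyr::arrange(dplyr::bind_rows(rows), .data$pos)
  }
  list(sequence = seq, n_mismatch = sum(mis), n_insert = sum(ins),
       n_delete = sum(del), edits = edits)
}

#' Simulate error-laden long reads with ground truth
#'
#' Draws `depth` reads per gene, choosing the isoform by abundance. Reads
#' are optionally truncated from the 5' end (full-length cDNA capture is
#' imperfect; the 3' end is always retained) and then corrupted with
#' i.i.d. per-base errors: deletions first, substitutions on the surviving
#' bases, and single-base insertions after any position. The defaults (4%
#' mismatch, 5% insertion, 4% deletion) give the indel-dominant ~13% total
#' error profile characteristic of raw PacBio/Nanopore transcriptome reads.
#' Every read gets one truth record with its isoform, covered transcript
#' interval and realised error counts.
#'
#' @param genes gene models from [simulate_genes()].
#' @param depth reads per gene.
#' @param mismatch_rate,insert_rate,delete_rate per-base error rates, each
#'   in `[0, 0.3]`.
#' @param full_length_fraction fraction of reads covering the whole
#'   transcript; the rest lose a uniform 0--40% prefix.
#' @param reverse_strand_fraction fraction of reads emitted as reverse
#'   complements (strand `-`).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param keep_edits record the individual edits per read (list-column
#'   `edits` in the truth; used to verify that the injection conserves the
#'   underlying transcript).
#' @return list with `reads` (read tibble) and `truth` (tibble: `read_id`,
#'   `gene_id`, `isoform_id`, `strand`, 0-based half-open
#'   `transcript_start`, `transcript_end`, `n_mismatch`, `n_insert`,
#'   `n_delete`).
#' @examples
#' genes <- simulate_genes(n_genes = 1, seed = 1)
#' sim <- simulate_reads(genes, depth = 5, seed = 2)
#' sim$truth
#' @export
simulate_reads <- function(genes, depth = 30L, mismatch_rate = 0.04,
                           insert_rate = 0.05, delete_rate = 0.04,
                           full_length_fraction = 0.85,
                           reverse_strand_fraction = 0, seed = 1L,
                           keep_edits = FALSE) {
  stopifnot(depth >= 1L)
  for (r in c(mismatch_rate, insert_rate, delete_rate))
    stopifnot(r >= 0, r <= 0.3)
  stopifnot(full_length_fraction >= 0, full_length_fraction <= 1,
            reverse_strand_fraction >= 0, reverse_strand_fraction <= 1)
  tx <- gene_transcripts(genes)
  withr::with_seed(seed, {
    recs <- list()
    rid <- 0L
    for (g in unique(tx$gene_id)) {
      gt <- tx[tx$gene_id == g, ]
      iso_idx <- sample.int(nrow(gt), depth, replace = TRUE, prob = gt$abundance)
      for (j in seq_len(depth)) {
        rid <- rid + 1L
        iso <- gt[iso_idx[j], ]
        len <- iso$length
        s0 <- 0L
        if (stats::runif(1) > full_length_fraction)
          s0 <- sample.int(max(1L, floor(0.4 * len)), 1L)
        true_sub <- substr(iso$sequence, s0 + 1L, len)
        err <- inject_errors(true_sub, mismatch_rate, insert_rate,
                             delete_rate, keep_edits)
        strand <- if (stats::runif(1) < reverse_strand_fraction) "-" else "+"
        seq <- if (strand == "-") cpp_revcomp(err$sequence) else err$sequence
        recs[[rid]] <- list(read_id = sprintf("r%06d", rid), sequence = seq,
                            gene_id = g, isoform_id = iso$isoform_id,
                            strand = strand, transcript_start = s0,
                            transcript_end = len,
                            n_mismatch = err$n_mismatch,
                            n_insert = err$n_insert,
                            n_delete = err$n_delete,
                            edits = err$edits)
      }
    }
    truth <- dplyr::bind_rows(lapply(recs, function(r)
      tibble::as_tibble(r[c("read_id", "gene_id", "isoform_id", "strand",
                            "transcript_start", "transcript_end",
                            "n_mismatch", "n_insert", "n_delete")])))
    if (keep_edits) truth$edits <- lapply(recs, `[[`, "edits")
    reads <- tibble::tibble(
      read_id = vapply(recs, `[[`, character(1), "read_id"),
      sequence = vapply(recs, `[[`, character(1), "sequence"),
      quality = NA_character_)
    list(reads = reads, truth = truth)
  })
}

#' Write a minimal exon-level GTF for simulated genes
#'
#' Exon features on a pseudo-chromosome per gene (transcript coordinates),
#' enough for annotation-driven tooling to group isoforms by gene.
#'
#' @param genes gene models from [simulate_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in seq_len(nrow(genes))) {
    exons <- genes$exons[[g]]
    starts <- cumsum(c(1L, nchar(exons)))[seq_along(exons)]
    ends <- starts + nchar(exons) - 1L
    iso <- genes$isoforms[[g]]
    for (i in seq_len(nrow(iso))) {
      for (e in iso$exon_chain[[i]]) {
        lines <- c(lines, sprintf(
          "%s\tisocorr_sim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          genes$gene_id[g], starts[e], ends[e], genes$gene_id[g],
          iso$isoform_id[i]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
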