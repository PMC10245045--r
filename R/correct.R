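# Internal fast path for one template: same kernels as the exported
# module functions, minus per-candidate object overhead. `correct_multi`
# runs several parameter sets over one template, sharing the candidate
# search and alignments (which do not depend on the windowing settings).
correct_one <- function(ti, reads, index, params) {
  correct_multi(ti, reads, index, list(params))[[1]]
}

correct_multi <- function(ti, reads, index, params_list) {
  p <- params_list[[1]]
  res <- list(read_id = reads$read_id[ti], sequence = NA_character_,
              t_start = NA_integer_, t_end = NA_integer_,
              n_candidates = 0L, n_aligned = 0L, n_complex = 0L,
              complex_len = NA_real_, status = "discarded",
              reason = NA_character_)
  tmpl_seq <- reads$sequence[ti]
  cd <- cpp_find_candidates(tmpl_seq, ti, index$cpp, index$read_lens,
                            p$min_seed, p$max_candidates, p$max_diag_spread,
                            p$min_struct_ins)
  res$n_candidates <- nrow(cd)
  if (nrow(cd) == 0) {
    res$reason <- "no_candidates"
    return(rep(list(res), length(params_list)))
  }

  tstrs <- qstrs <- character(nrow(cd))
  t_starts <- integer(nrow(cd))
  keep <- logical(nrow(cd))
  for (j in seq_len(nrow(cd))) {
    a <- substr(tmpl_seq, cd$t_start[j] + 1L, cd$t_end[j])
    cseq <- index$sequences[cd$candidate[j]]
    if (cd$strand[j] == 1L) cseq <- cpp_revcomp(cseq)
    b <- substr(cseq, cd$c_start[j] + 1L, cd$c_end[j])
    na <- nchar(a); nb <- nchar(b)
    d_seed <- (cd$t_start[j] - cd$c_start[j]) - c(cd$diag_hi[j], cd$diag_lo[j])
    band <- max(p$band_pad, max(d_seed) - max(0L, nb - na) + p$band_pad,
                min(0L, nb - na) - min(d_seed) + p$band_pad)
    al <- cpp_align_banded(a, b, as.integer(band))
    if (!isTRUE(al$ok) || al$dist > p$max_align_error * nchar(al$tstr)) next
    nm <- cpp_normalize_alignment(al$tstr, al$qstr)
    tstrs[j] <- nm$tstr
    qstrs[j] <- nm$qstr
    t_starts[j] <- cd$t_start[j]
    keep[j] <- TRUE
  }
  if (!any(keep)) {
    res$reason <- "no_alignments"
    return(rep(list(res), length(params_list)))
  }
  tstrs <- tstrs[keep]; qstrs <- qstrs[keep]
  t_starts <- t_starts[keep]
  res$n_aligned <- sum(keep)
  # structural-insertion candidates: seed-diagonal jumps of kept alignments
  kj <- which(keep & cd$jump >= p$min_struct_ins)
  jumps <- list(
    t1 = cd$j_t1[kj], t2 = cd$j_t2[kj],
    seg = vapply(kj, function(j) {
      cseq <- index$sequences[cd$candidate[j]]
      if (cd$strand[j] == 1L) cseq <- cpp_revcomp(cseq)
      substr(cseq, cd$j_c1[j] + 1L, cd$j_c2[j])
    }, character(1)))
  spans <- list(t_start = cd$t_start[keep], t_end = cd$t_end[keep])
  lapply(params_list, function(pp)
    consensus_stage(res, tmpl_seq, tstrs, qstrs, t_starts, pp, jumps, spans))
}

consensus_stage <- function(res, tmpl_seq, tstrs, qstrs, t_starts, p,
                            jumps = NULL, spans = NULL) {
  newqs <- vapply(seq_along(qstrs), function(j)
    cpp_mask_low_identity(tstrs[j], qstrs[j], p$window_length,
                          p$identity_threshold), character(1))
  tlen <- nchar(tmpl_seq)
  normal <- cpp_build_table(tstrs, qstrs, t_starts, tlen)
  modify <- cpp_build_table(tstrs, newqs, t_starts, tlen)
  cov <- modify[, "match"] + modify[, "insert"] + modify[, "skip"]
  qual <- which(cov >= p$min_coverage)
  if (length(qual) == 0) { res$reason <- "low_coverage"; return(res) }
  left <- min(qual) - 1L; right <- max(qual)  # 0-based half-open

  sel <- (left + 1L):right
  covm <- cov[sel]
  structural <- modify[sel, "skip"] > covm * p$scov
  chosen <- function(col) ifelse(structural, modify[sel, col], normal[sel, col])
  m <- chosen("match"); i <- chosen("ins_reads"); d <- chosen("del")
  kind <- classify_kind(m, i, d, chosen("skip"))

  ref <- strsplit(substr(tmpl_seq, left + 1L, right), "", fixed = TRUE)[[1]]
  # per-position voted base (MAT emission), vectorised
  V <- cbind(chosen("A"), chosen("C"), chosen("G"), chosen("T"))
  mx <- pmax(V[, 1], V[, 2], V[, 3], V[, 4])
  refv <- V[cbind(seq_along(ref), match(ref, c("A", "C", "G", "T")))]
  voted <- ifelse(mx == 0 | refv == mx, ref,
                  c("A", "C", "G", "T")[max.col(V, ties.method = "first")])

  # majority-gated structural-insertion splice, suppressed when the
  # junction is flagged structurally divergent (skip-dominated evidence)
  splice <- NULL
  if (!is.null(jumps) && length(jumps$t1) >= 2) {
    splice <- pick_splice(jumps, spans, structural, left, right, p)
  }

  n_complex <- 0L; complex_lens <- integer(0)
  emit_region <- function(a, b) {
    if (b <= a) return("")
    rel <- (a - left + 1L):(b - left)
    runs <- partition_kind_runs(kind[rel])
    cstart <- a + runs$from[runs$complex] - 1L
    cend <- a + runs$to[runs$complex]
    careas <- NULL
    if (length(cstart) > 0)
      careas <- cpp_area_rows_multi(tstrs, newqs, t_starts,
                                    as.integer(cstart), as.integer(cend))
    pieces <- character(nrow(runs))
    ci <- 0L
    for (s in seq_len(nrow(runs))) {
      idx <- rel[runs$from[s]:runs$to[s]]
      if (!runs$complex[s]) {
        emit <- idx[kind[idx] == "MAT"]
        pieces[s] <- paste(voted[emit], collapse = "")
      } else {
        ci <- ci + 1L
        pieces[s] <- complex_consensus_fast(tmpl_seq, cstart[ci], cend[ci],
                                            careas[[ci]])
      }
    }
    n_complex <<- n_complex + length(cstart)
    complex_lens <<- c(complex_lens, cend - cstart)
    paste(pieces, collapse = "")
  }

  out <- if (is.null(splice)) {
    emit_region(left, right)
  } else {
    paste0(emit_region(left, splice$t1), splice$seq,
           emit_region(splice$t2, right))
  }
  res$n_complex <- n_complex
  res$complex_len <- if (length(complex_lens)) stats::median(complex_lens) else NA_real_
  if (nchar(out) < p$min_output_size) { res$reason <- "too_short"; return(res) }
  res$sequence <- out
  res$t_start <- left; res$t_end <- right
  res$status <- "corrected"
  res
}

complex_consensus_fast <- function(tmpl_seq, start, end, area) {
  chars <- c(substr(tmpl_seq, start + 1L, end), as.character(area$chars))
  keys <- c(list(as.integer(start:(end - 1L)) * 2048L), area$keys)
  full <- c(TRUE, as.logical(area$full))
  is_t <- c(TRUE, rep(FALSE, length(area$full)))
  nz <- nchar(chars) > 0
  area_consensus(tmpl_seq, start, end, keys[nz], chars[nz], full[nz], is_t[nz])
}

# Structural-insertion splice selection. Candidates whose seed chains show
# a consistent diagonal jump carry extra sequence (e.g. an exon the
# template skips). When a majority of the junction-spanning candidates
# agree -- and the junction is NOT flagged structurally divergent by the
# skip statistic (the windowed mode's protection) -- their segments are
# polished into one consensus insert that replaces the short template
# interval between the flanking seed blocks.
pick_splice <- function(jumps, spans, structural, left, right, p) {
  ord <- order(jumps$t1)
  t1 <- jumps$t1[ord]; t2 <- jumps$t2[ord]; seg <- jumps$seg[ord]
  grp <- cumsum(c(TRUE, diff(t1) > 50L))
  best <- NULL
  for (g in split(seq_along(t1), grp)) {
    if (is.null(best) || length(g) > length(best)) best <- g
  }
  lo <- min(t1[best]); hi <- max(t2[best])
  spanning <- sum(spans$t_start <= lo & spans$t_end >= hi)
  if (length(best) < max(2L, ceiling(spanning / 2))) return(NULL)
  # pick the median-length segment as representative
  lens <- nchar(seg[best])
  rep_i <- best[order(lens)[ceiling(length(best) / 2)]]
  st1 <- t1[rep_i]; st2 <- t2[rep_i]
  # coincidental junction-spanning seeds can push the blocks together by a
  # base or two; clamp to a pure insertion at st1 in that case
  st2 <- max(st2, st1)
  if (st1 < left || st2 > right) return(NULL)
  # suppression: skip-dominated (structurally divergent) junction evidence
  jsel <- (max(left, st1 - 2L) - left + 1L):(min(right, st2 + 2L) - left)
  if (any(structural[jsel])) return(NULL)
  polished <- polish_segment(seg[rep_i], as.list(seg[setdiff(best, rep_i)]))
  list(t1 = st1, t2 = st2, seq = polished)
}

# Majority vote per column of the representative segment; other segments
# contribute through a banded alignment to the representative.
polish_segment <- function(rep_seq, others) {
  rep_chars <- strsplit(rep_seq, "", fixed = TRUE)[[1]]
  L <- length(rep_chars)
  letters5 <- c("A", "C", "G", "T", "-")
  V <- matrix(0L, L, 5, dimnames = list(NULL, letters5))
  V[cbind(seq_len(L), match(rep_chars, letters5))] <- 1L
  for (o in others) {
    band <- as.integer(max(16L, ceiling(0.2 * L)) + abs(nchar(o) - L))
    al <- cpp_align_banded(rep_seq, o, band)
    if (!isTRUE(al$ok)) next
    t <- strsplit(al$tstr, "", fixed = TRUE)[[1]]
    q <- strsplit(al$qstr, "", fixed = TRUE)[[1]]
    rpos <- cumsum(t != "-")
    hit <- t != "-" & q %in% letters5
    ij <- cbind(rpos[hit], match(q[hit], letters5))
    V[ij] <- V[ij] + 1L
  }
  win <- colnames(V)[max.col(V, ties.method = "first")]
  # ties resolve to the representative's base
  mx <- V[cbind(seq_len(L), match(win, letters5))]
  rep_v <- V[cbind(seq_len(L), match(rep_chars, letters5))]
  win[rep_v == mx] <- rep_chars[rep_v == mx]
  paste(win[win != "-"], collapse = "")
}

# Consensus of one complex area: coverage-centred max-weight path through
# the alignment graph, falling back to the template substring.
area_consensus <- function(tmpl_seq, start, end, keys, chars, full, is_t) {
  fallback <- substr(tmpl_seq, start + 1L, end)
  if (length(chars) == 0) return(fallback)
  spanning <- sum(full & !grepl("N", chars, fixed = TRUE))
  has_n <- any(grepl("N", chars, fixed = TRUE))
  dag <- cpp_build_dag(keys, chars, full, is_t, has_n)
  if (dag$n_nodes == 0) return(fallback)
  pth <- cpp_max_weight_path(dag$n_nodes, dag$edges$from, dag$edges$to,
                             dag$edges$weight, dag$edges$template,
                             dag$nodes$base, spanning / 2)
  if (length(pth$path) == 0) return(fallback)
  paste(dag$nodes$base[pth$path], collapse = "")
}

#' Correct a single template read
#'
#' Runs the full per-template pipeline: candidate recruitment, banded
#' alignment, mismatch normalisation, sliding-window masking, consensus
#' tables, boundary determination, position typing, area partitioning and
#' per-area consensus, concatenated in template order. A read is discarded
#' when it has no candidates, no position reaches `min_coverage`, or the
#' corrected sequence is shorter than `min_output_size`.
#'
#' @param reads read tibble.
#' @param template_id id of the read to correct.
#' @param params an [correction_params()] object.
#' @param index optional [index_kmers()] object over `reads` (built on the
#'   fly otherwise).
#' @return one-row tibble: `read_id`, `sequence` (`NA` when discarded),
#'   half-open corrected template span `t_start`, `t_end`, `status` and
#'   `reason`.
#' @export
correct_read <- function(reads, template_id, params = correction_params(),
                         index = NULL) {
  stopifnot(inherits(params, "isocorr_params"))
  if (is.null(index)) index <- index_kmers(reads, params$k, params$max_kmer_occ)
  ti <- match(template_id, reads$read_id)
  if (is.na(ti)) stop("template read '", template_id, "' not found")
  tibble::as_tibble(correct_one(ti, reads, index, params)[
    c("read_id", "sequence", "t_start", "t_end", "n_candidates",
      "n_aligned", "n_complex", "status", "reason")])
}

#' Correct every read in a set
#'
#' Each read serves once as template; corrected reads are emitted
#' independently. With `params$baseline = TRUE` (equivalently
#' `identity_threshold = 0`) the run degenerates to a windowing-free,
#' skip-free pipeline -- the behaviour of a conventional DNA self-corrector.
#'
#' @param reads read tibble (`read_id`, `sequence`).
#' @param params an [correction_params()] object.
#' @param progress print a progress note every `progress` templates
#'   (0 = quiet).
#' @return an `isocorr_correction` object: list with `corrected` (tibble of
#'   surviving reads), `log` (per-read disposition) and `params`. Has
#'   [tidy()] and [glance()] methods.
#' @examples
#' \donttest{
#' genes <- simulate_genes(n_genes = 2, seed = 1)
#' sim <- simulate_reads(genes, depth = 12, seed = 2)
#' cr <- correct_reads(sim$reads, correction_params(min_output_size = 50))
#' glance(cr)
#' }
#' @export
correct_reads <- function(reads, params = correction_params(), progress = 0L) {
  stopifnot(inherits(params, "isocorr_params"))
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$read_id)) stop("duplicate read ids")
  index <- index_kmers(reads, params$k, params$max_kmer_occ)
  run <- function(ti) {
    if (progress > 0 && ti %% progress == 0)
      message("  template ", ti, "/", nrow(reads))
    correct_one(ti, reads, index, params)
  }
  results <- if (params$threads > 1L) {
    parallel::mclapply(seq_len(nrow(reads)), run, mc.cores = params$threads)
  } else {
    lapply(seq_len(nrow(reads)), run)
  }
  assemble_correction(results, params)
}

assemble_correction <- function(results, params) {
  log <- dplyr::bind_rows(lapply(results, function(r)
    tibble::as_tibble(r[c("read_id", "n_candidates", "n_aligned", "n_complex",
                          "complex_len", "status", "reason")])))
  ok <- vapply(results, function(r) r$status == "corrected", logical(1))
  corrected <- dplyr::bind_rows(lapply(results[ok], function(r)
    tibble::as_tibble(r[c("read_id", "sequence", "t_start", "t_end")])))
  if (nrow(corrected) == 0)
    corrected <- tibble::tibble(read_id = character(), sequence = character(),
                                t_start = integer(), t_end = integer())
  structure(list(corrected = corrected, log = log, params = params),
            class = "isocorr_correction")
}

# run several parameter sets over one read set, sharing the overlap and
# alignment stage (used by run_benchmark for the windowed/baseline pair)
correct_reads_multi <- function(reads, params_list, progress = 0L) {
  index <- index_kmers(reads, params_list[[1]]$k, params_list[[1]]$max_kmer_occ)
  results <- lapply(seq_len(nrow(reads)), function(ti) {
    if (progress > 0 && ti %% progress == 0)
      message("  template ", ti, "/", nrow(reads))
    correct_multi(ti, reads, index, params_list)
  })
  lapply(seq_along(params_list), function(k)
    assemble_correction(lapply(results, `[[`, k), params_list[[k]]))
}

#' @export
print.isocorr_correction <- function(x, ...) {
  cat(sprintf("<isocorr_correction> %d/%d reads corrected (%s mode)\n",
              nrow(x$corrected), nrow(x$log),
              if (x$params$identity_threshold <= 0) "baseline" else "windowed"))
  invisible(x)
}

#' @describeIn correct_reads per-read disposition table.
#' @param x an `isocorr_correction` object.
#' @param ... unused.
#' @export
tidy.isocorr_correction <- function(x, ...) x$log

#' @describeIn correct_reads one-row run summary (reads kept, throughput,
#'   median complex-area length).
#' @export
glance.isocorr_correction <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x$log),
    n_corrected = nrow(x$corrected),
    pct_corrected = 100 * nrow(x$corrected) / max(1L, nrow(x$log)),
    n_bases = sum(nchar(x$corrected$sequence)),
    mean_candidates = mean(x$log$n_candidates),
    median_complex_len = stats::median(x$log$complex_len, na.rm = TRUE),
    baseline = x$params$identity_threshold <= 0
  )
}
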