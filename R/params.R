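#' Correction parameters
#'
#' Bundles every tunable of the correction pipeline with its validated range.
#' Defaults follow the method's reference settings: a 5-column sliding window
#' with identity threshold 0.5, structural coefficient `scov` 0.1, minimum
#' position coverage 4 and minimum output size 100 bases.
#'
#' @param k k-mer size for the overlap index (8--21).
#' @param min_seed minimum number of shared k-mers (in a consistent diagonal
#'   band) for a read to become a candidate.
#' @param max_candidates at most this many candidates per template, best
#'   seed scores first.
#' @param max_kmer_occ k-mers occurring in more than this many reads are
#'   dropped from the index (repeat masking).
#' @param max_diag_spread maximum diagonal spread (bases) of the seed cluster
#'   accepted for one candidate; must exceed the largest expected skipped-exon
#'   length so cross-isoform overlaps still align end to end.
#' @param band_pad extra half-band (bases) added around the seed diagonals for
#'   the banded alignment.
#' @param max_align_error candidates whose alignment edit rate exceeds this
#'   fraction are dropped (alignment-failure rule).
#' @param window_length sliding-window length in alignment columns.
#' @param identity_threshold windows with identity at or below this value are
#'   masked; `0` disables masking entirely (the baseline mode).
#' @param scov structural coefficient: a position is structurally divergent
#'   when `skip > coverage * scov`.
#' @param min_coverage minimum `match + insert + skip` coverage for a template
#'   position to be correctable; positions failing it are trimmed at the read
#'   boundaries.
#' @param min_struct_ins minimum seed-diagonal jump (bases) treated as a
#'   structural insertion: candidates whose seed chains jump by at least
#'   this much carry extra sequence (e.g. an exon the template skips); a
#'   majority of junction-spanning candidates triggers a polished splice,
#'   unless the junction is flagged structurally divergent by the skip
#'   statistic.
#' @param min_output_size corrected reads shorter than this are discarded.
#' @param baseline logical; `TRUE` disables windowing (sets
#'   `identity_threshold` to 0), giving the skip-free behaviour of a
#'   conventional DNA self-correction pipeline.
#' @param threads number of worker processes for the per-template loop.
#'
#' @return a list of class `isocorr_params`.
#' @examples
#' correction_params(window_length = 7)
#' @export
correction_params <- function(k = 13L, min_seed = 4L, max_candidates = 50L,
                              max_kmer_occ = 200L, max_diag_spread = 400L,
                              band_pad = 64L, max_align_error = 0.5,
                              window_length = 5L, identity_threshold = 0.5,
                              scov = 0.1, min_coverage = 4L,
                              min_struct_ins = 20L,
                              min_output_size = 100L, baseline = FALSE,
                              threads = 1L) {
  stopifnot(k >= 8L, k <= 21L)
  stopifnot(min_seed >= 1L, max_candidates >= 1L, max_kmer_occ >= 1L)
  stopifnot(max_diag_spread >= 0L, band_pad >= 1L)
  stopifnot(max_align_error > 0, max_align_error <= 1)
  stopifnot(window_length >= 1L)
  stopifnot(identity_threshold >= 0, identity_threshold <= 1)
  stopifnot(scov >= 0, scov <= 1)
  stopifnot(min_coverage >= 1L, min_struct_ins >= 2L, min_output_size >= 0L,
            threads >= 1L)
  if (isTRUE(baseline)) identity_threshold <- 0
  structure(list(
    k = as.integer(k), min_seed = as.integer(min_seed),
    max_candidates = as.integer(max_candidates),
    max_kmer_occ = as.integer(max_kmer_occ),
    max_diag_spread = as.integer(max_diag_spread),
    band_pad = as.integer(band_pad), max_align_error = max_align_error,
    window_length = as.integer(window_length),
    identity_threshold = identity_threshold, scov = scov,
    min_coverage = as.integer(min_coverage),
    min_struct_ins = as.integer(min_struct_ins),
    min_output_size = as.integer(min_output_size),
    baseline = isTRUE(baseline), threads = as.integer(threads)
  ), class = "isocorr_params")
}

#' @export
print.isocorr_params <- function(x, ...) {
  cat("<isocorr_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

format_params_header <- function(params, seed = NULL) {
  kv <- vapply(names(params), function(nm) {
    sprintf("%s=%s", nm, format(params[[nm]]))
  }, character(1))
  if (!is.null(seed)) kv <- c(kv, sprintf("seed=%d", seed))
  paste0("# ", paste(kv, collapse = " "))
}
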