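#' Build a k-mer index over a read set
#'
#' Indexes every length-`k` substring of every read (forward strand).
#' k-mers occurring in more than `max_kmer_occ` distinct reads are dropped --
#' they are almost always repeats and would flood candidate finding.
#'
#' @param reads read tibble (`read_id`, `sequence`).
#' @param k k-mer length, 8--21.
#' @param max_kmer_occ occurrence cap per k-mer (distinct reads).
#' @return an `isocorr_kmer_index` object; the read table travels with it so
#'   downstream calls only need the index.
#' @examples
#' reads <- tibble::tibble(read_id = c("a", "b"), sequence = c("ACGTACGT", "ACGTACGT"))
#' idx <- index_kmers(reads, k = 8)
#' @export
index_kmers <- function(reads, k = 13L, max_kmer_occ = 200L) {
  if (k < 8L || k > 21L) stop("k must be in [8, 21]")
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  cpp <- cpp_build_kmer_index(reads$sequence, as.integer(k), as.integer(max_kmer_occ))
  structure(list(cpp = cpp, k = as.integer(k),
                 max_kmer_occ = as.integer(max_kmer_occ),
                 read_ids = reads$read_id,
                 read_lens = nchar(reads$sequence),
                 sequences = reads$sequence),
            class = "isocorr_kmer_index")
}

#' @export
print.isocorr_kmer_index <- function(x, ...) {
  cat(sprintf("<isocorr_kmer_index> %d reads, k=%d, %s indexed positions, %d k-mers dropped\n",
              length(x$read_ids), x$k, format(x$cpp$n_positions, big.mark = ","),
              x$cpp$n_dropped_kmers))
  invisible(x)
}

#' Find overlap candidates for a template read
#'
#' Recruits reads sharing at least `min_seed` k-mers with the template inside
#' a consistent diagonal band (both strands are tried via the reverse
#' complement). This is a deterministic, desk-scale stand-in for a
#' production overlapper: exact k-mer hits are binned onto alignment
#' diagonals and the densest diagonal window (spread at most
#' `max_diag_spread`, wide enough to span a skipped exon) defines one
#' candidate per read. Results are ordered by descending seed score, ties
#' broken by read id.
#'
#' @param template_id id of the template read (present in the index).
#' @param index an [index_kmers()] object.
#' @param min_seed,max_candidates,max_diag_spread see [correction_params()].
#' @param min_jump report a seed-diagonal jump of at least this many bases
#'   inside the chain (columns `jump`, `j_t1`, `j_c1`, `j_t2`, `j_c2`) --
#'   the signature of a structural indel such as a skipped exon between the
#'   two reads. 0 disables jump detection.
#' @return tibble of candidate matches: `template_id`, `candidate_id`,
#'   `strand` (`"forward"`/`"reverse"`), half-open 0-based spans `t_start`,
#'   `t_end` on the template and `c_start`, `c_end` on the (oriented)
#'   candidate, `seed_score`, the seed diagonal range `diag_lo`, `diag_hi`,
#'   and the jump fields (`jump > 0`: the candidate carries extra sequence
#'   between template positions `j_t1` and `j_t2`, spanning candidate
#'   interval `j_c1`--`j_c2`). For reverse-strand candidates the `c_*`
#'   coordinates refer to the reverse-complemented candidate sequence.
#' @export
find_candidates <- function(template_id, index, min_seed = 4L,
                            max_candidates = 50L, max_diag_spread = 400L,
                            min_jump = 20L) {
  stopifnot(inherits(index, "isocorr_kmer_index"))
  ti <- match(template_id, index$read_ids)
  if (is.na(ti)) stop("template read '", template_id, "' not in index")
  df <- cpp_find_candidates(index$sequences[ti], ti, index$cpp,
                            index$read_lens, as.integer(min_seed),
                            as.integer(max_candidates),
                            as.integer(max_diag_spread), as.integer(min_jump))
  tibble::tibble(template_id = rep(template_id, nrow(df)),
                 candidate_id = index$read_ids[df$candidate],
                 candidate = df$candidate,
                 strand = ifelse(df$strand == 0L, "forward", "reverse"),
                 t_start = df$t_start, t_end = df$t_end,
                 c_start = df$c_start, c_end = df$c_end,
                 seed_score = df$seed_score,
                 diag_lo = df$diag_lo, diag_hi = df$diag_hi,
                 jump = df$jump, j_t1 = df$j_t1, j_c1 = df$j_c1,
                 j_t2 = df$j_t2, j_c2 = df$j_c2)
}

# half-band needed so the banded DP covers the seed diagonals plus padding
band_for <- function(cand, na, nb, band_pad) {
  d_seed <- (cand$t_start - cand$c_start) - c(cand$diag_hi, cand$diag_lo)
  lo <- min(0L, nb - na)
  hi <- max(0L, nb - na)
  max(band_pad, max(d_seed) - hi + band_pad, lo - min(d_seed) + band_pad)
}

new_alignment <- function(cand, tstr, qstr, dist, normalized = FALSE) {
  structure(list(template_id = cand$template_id,
                 candidate_id = cand$candidate_id,
                 strand = cand$strand,
                 t_start = cand$t_start, t_end = cand$t_end,
                 c_start = cand$c_start, c_end = cand$c_end,
                 seed_score = cand$seed_score,
                 tstr = tstr, qstr = qstr, dist = dist,
                 normalized = normalized),
            class = "isocorr_alignment")
}

#' @export
print.isocorr_alignment <- function(x, ...) {
  cat(sprintf("<isocorr_alignment> %s vs %s (%s) t:[%d,%d) c:[%d,%d) dist=%s%s\n",
              x$template_id, x$candidate_id, x$strand, x$t_start, x$t_end,
              x$c_start, x$c_end, format(x$dist),
              if (isTRUE(x$normalized)) " normalized" else ""))
  invisible(x)
}

#' Banded global alignment of a candidate to its template span
#'
#' Aligns the candidate span against the template span (reverse-complementing
#' the candidate once for reverse-strand matches) with a banded
#' edit-distance dynamic programme. The band is derived from the seed
#' diagonals plus `band_pad`. Ties are resolved with a fixed operation
#' preference (match > deletion > insertion), so results are deterministic.
#' The raw alignment may contain mismatch columns; see
#' [normalize_alignment()].
#'
#' @param reads read tibble containing both template and candidate.
#' @param cand one row of [find_candidates()] output.
#' @param band optional explicit half-band width (columns); default derived
#'   from the seed diagonals.
#' @param band_pad padding added around the seed diagonal range.
#' @param max_align_error drop the candidate (return `NULL`) when the edit
#'   rate over alignment columns exceeds this fraction.
#' @return an `isocorr_alignment` (rows `tstr`, `qstr`), or `NULL` when the
#'   alignment fails the error cap.
#' @export
align_pair <- function(reads, cand, band = NULL, band_pad = 100L,
                       max_align_error = 0.5) {
  ti <- match(cand$template_id, reads$read_id)
  ci <- match(cand$candidate_id, reads$read_id)
  if (is.na(ti) || is.na(ci)) stop("template or candidate missing from reads")
  a <- substr(reads$sequence[ti], cand$t_start + 1L, cand$t_end)
  cseq <- reads$sequence[ci]
  if (cand$strand == "reverse") cseq <- cpp_revcomp(cseq)
  b <- substr(cseq, cand$c_start + 1L, cand$c_end)
  if (is.null(band)) band <- band_for(cand, nchar(a), nchar(b), band_pad)
  al <- cpp_align_banded(a, b, as.integer(band))
  if (!isTRUE(al$ok)) return(NULL)
  if (al$dist > max_align_error * nchar(al$tstr)) return(NULL)
  new_alignment(cand, al$tstr, al$qstr, al$dist)
}

#' Split mismatches into deletion + insertion columns
#'
#' Normalises a raw alignment so that no column holds two differing bases:
#' every mismatch column `(X, Y)` is replaced by a deletion column `(X, -)`
#' followed by an insertion column `(-, Y)` (template base leaves first).
#' Match and indel columns are untouched, so the gap-stripped rows are
#' preserved exactly.
#'
#' @param aln an `isocorr_alignment` from [align_pair()].
#' @return the normalised `isocorr_alignment`.
#' @export
normalize_alignment <- function(aln) {
  stopifnot(inherits(aln, "isocorr_alignment"))
  nm <- cpp_normalize_alignment(aln$tstr, aln$qstr)
  out <- aln
  out$tstr <- nm$tstr
  out$qstr <- nm$qstr
  out$normalized <- TRUE
  out
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)
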