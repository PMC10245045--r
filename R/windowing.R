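#' Sliding-window identity at one alignment column
#'
#' Identity of the window anchored at column `pos`:
#' `match_base_num / window_length`, where `match_base_num` counts columns
#' whose two rows hold the same base. Windows truncated at the right edge use
#' the truncated length as denominator.
#'
#' @param aln an `isocorr_alignment`.
#' @param pos 1-based anchor column.
#' @param window_length window length in alignment columns.
#' @return identity fraction in `[0, 1]`.
#' @export
window_identity <- function(aln, pos, window_length = 5L) {
  stopifnot(inherits(aln, "isocorr_alignment"), window_length >= 1L)
  L <- nchar(aln$tstr)
  if (pos < 1L || pos > L) stop("pos out of range [1, ", L, "]")
  wl <- min(window_length, L - pos + 1L)
  t <- substring(aln$tstr, pos:(pos + wl - 1L), pos:(pos + wl - 1L))
  q <- substring(aln$qstr, pos:(pos + wl - 1L), pos:(pos + wl - 1L))
  sum(t != "-" & t == q) / wl
}

#' Mask low-identity alignment windows with 'N'
#'
#' Copies the candidate row to `newqstr` and slides a window one column at a
#' time (anchored at its left edge, shrinking at the right margin). Whenever
#' a window's identity is at or below `identity_threshold`, the anchor
#' column's candidate character is replaced by `N`; gap characters are never
#' replaced. A low-identity stretch therefore masks every character whose
#' window reaches into it. In transcriptome data such stretches typically
#' mark evidence from a different exon structure. A threshold of 0 disables
#' masking (`newqstr` equals `qstr` -- the baseline mode), and windows with
#' identity 1 never fire.
#'
#' @param aln a normalised `isocorr_alignment`.
#' @param window_length window length in alignment columns.
#' @param identity_threshold masking threshold in `[0, 1]`.
#' @return the alignment with an additional `newqstr` row (class
#'   `isocorr_masked_alignment`).
#' @export
mask_low_identity <- function(aln, window_length = 5L, identity_threshold = 0.5) {
  stopifnot(inherits(aln, "isocorr_alignment"), window_length >= 1L,
            identity_threshold >= 0, identity_threshold <= 1)
  out <- aln
  out$newqstr <- cpp_mask_low_identity(aln$tstr, aln$qstr,
                                       as.integer(window_length),
                                       identity_threshold)
  out$window_length <- as.integer(window_length)
  out$identity_threshold <- identity_threshold
  class(out) <- unique(c("isocorr_masked_alignment", class(aln)))
  out
}
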