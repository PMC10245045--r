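#' Partition the boundary interval into simple and complex areas
#'
#' Maximal runs of `MAT`/`DEL` positions form *simple* areas (a `DEL`
#' between two `MAT`s stays simple). Any run containing an `INS` or
#' `UNDEFINE` position is *complex* and is extended to its flanking `MAT`
#' anchors (or to the boundary edge when no anchor exists). Segments tile
#' the interval without overlap; a complex area's anchors belong to it, not
#' to the neighbouring simple areas.
#'
#' @param types classification tibble from [classify_positions()] (contiguous
#'   `pos`, ordered).
#' @return tibble of segments: half-open `start`, `end`, `kind`
#'   (`"simple"`/`"complex"`) and `structural` (any structurally flagged
#'   position inside).
#' @export
partition_areas <- function(types) {
  stopifnot(nrow(types) > 0)
  pos <- types$pos
  stopifnot(all(diff(pos) == 1L))
  runs <- partition_kind_runs(types$kind)
  tibble::tibble(
    start = pos[runs$from], end = pos[runs$to] + 1L,
    kind = ifelse(runs$complex, "complex", "simple"),
    structural = vapply(seq_len(nrow(runs)), function(t)
      any(types$structural[runs$from[t]:runs$to[t]]), logical(1)))
}

# core run-scanning on the kind vector; returns 1-based inclusive index
# intervals [from, to] with a complex flag, tiling seq_along(kind)
partition_kind_runs <- function(kind) {
  n <- length(kind)
  bad <- kind %in% c("INS", "UNDEFINE")
  if (!any(bad))
    return(data.frame(from = 1L, to = n, complex = FALSE))
  is_mat <- kind == "MAT"
  prev_mat <- cummax(ifelse(is_mat, seq_len(n), 0L))
  next_mat <- rev(n + 1L - cummax(rev(ifelse(is_mat, n + 1L - seq_len(n), 0L))))
  r <- rle(bad)
  rends <- cumsum(r$lengths)
  rstarts <- rends - r$lengths + 1L
  runs <- which(r$values)
  lo <- hi <- integer(length(runs))
  for (t in seq_along(runs)) {
    a <- rstarts[runs[t]]; b <- rends[runs[t]]
    l <- if (a > 1L) prev_mat[a - 1L] else 0L
    u <- if (b < n) next_mat[b + 1L] else n + 1L
    lo[t] <- if (l >= 1L) l else 1L
    hi[t] <- if (u <= n) u else n
  }
  # merge overlapping / shared-anchor complex intervals
  ml <- mh <- integer(0)
  cl <- lo[1]; ch <- hi[1]
  for (t in seq_along(lo)[-1]) {
    if (lo[t] <= ch) ch <- max(ch, hi[t])
    else { ml <- c(ml, cl); mh <- c(mh, ch); cl <- lo[t]; ch <- hi[t] }
  }
  ml <- c(ml, cl); mh <- c(mh, ch)
  from <- to <- integer(0); complex <- logical(0); cur <- 1L
  for (t in seq_along(ml)) {
    if (ml[t] > cur) {
      from <- c(from, cur); to <- c(to, ml[t] - 1L); complex <- c(complex, FALSE)
    }
    from <- c(from, ml[t]); to <- c(to, mh[t]); complex <- c(complex, TRUE)
    cur <- mh[t] + 1L
  }
  if (cur <= n) { from <- c(from, cur); to <- c(to, n); complex <- c(complex, FALSE) }
  data.frame(from = from, to = to, complex = complex)
}

#' List-voting consensus for a simple area
#'
#' Fast per-position voting: each `MAT` position emits the base with the
#' most votes (ties involving the template base resolve to the template
#' base, other ties to the alphabetically first base; a `MAT` position with
#' no votes at all emits the template base). Each `DEL` position emits
#' nothing -- the template base is deleted.
#'
#' @param area one segment row from [partition_areas()] with
#'   `kind == "simple"`.
#' @param types classification tibble covering the area (columns `pos`,
#'   `ref`, `kind`, and votes `A`, `C`, `G`, `T` from the chosen table).
#' @return the corrected base string for the area.
#' @export
correct_simple <- function(area, types) {
  if (area$kind != "simple") stop("correct_simple() requires a simple area")
  sel <- types$pos >= area$start & types$pos < area$end
  tt <- types[sel, ]
  if (any(!tt$kind %in% c("MAT", "DEL")))
    stop("simple area contains non-MAT/DEL positions")
  tt <- tt[tt$kind == "MAT", ]
  if (nrow(tt) == 0) return("")
  V <- cbind(A = tt$A, C = tt$C, G = tt$G, T = tt$T)
  bases <- colnames(V)
  mx <- apply(V, 1L, max)
  ref_i <- match(tt$ref, bases)
  ref_v <- V[cbind(seq_len(nrow(V)), ref_i)]
  first_max <- bases[apply(V, 1L, which.max)]
  out <- ifelse(mx == 0L | ref_v == mx, tt$ref, first_max)
  n_empty <- sum(mx == 0L)
  if (n_empty > 0)
    rlang::warn(sprintf("%d MAT position(s) without votes; template base kept", n_empty),
                .frequency = "once", .frequency_id = "isocorr_empty_votes")
  paste(out, collapse = "")
}

#' Extract per-candidate aligned rows over a template area
#'
#' Pulls each candidate's (masked) characters over the half-open template
#' interval, keyed by `(template position, insertion rank)` so coincident
#' bases merge in the alignment graph. Inserted bases are attributed to
#' their left flanking position. The template's own row is included first.
#'
#' @param template one-row read tibble.
#' @param alignments list of masked alignments for this template.
#' @param start,end half-open 0-based template interval.
#' @return tibble of rows: `row_id`, `is_template`, `full` (row spans the
#'   whole area), `chars`, and list-column `keys`.
#' @export
extract_area_rows <- function(template, alignments, start, end) {
  tstrs <- vapply(alignments, `[[`, character(1), "tstr")
  rows <- vapply(alignments, function(a) a$newqstr %||% a$qstr, character(1))
  t_starts <- vapply(alignments, function(a) as.integer(a$t_start), integer(1))
  ex <- cpp_area_rows(tstrs, rows, t_starts, as.integer(start), as.integer(end))
  tmpl_chars <- substr(template$sequence, start + 1L, end)
  out <- tibble::tibble(
    row_id = c(template$read_id,
               vapply(alignments, `[[`, character(1), "candidate_id")),
    is_template = c(TRUE, rep(FALSE, length(alignments))),
    full = c(TRUE, vapply(ex, function(e) isTRUE(e$full), logical(1))),
    chars = c(tmpl_chars, vapply(ex, `[[`, character(1), "chars")),
    keys = c(list(as.integer(start:(end - 1L)) * 2048L),
             lapply(ex, function(e) as.integer(e$keys)))
  )
  out[nchar(out$chars) > 0, ]
}

#' Build the consensus DAG for a complex area
#'
#' Each row contributes a chain of `(position, insertion-rank, base)` nodes;
#' coincident nodes merge and parallel edges collapse with summed weights.
#' With `drop_n_edges`, rows are split around masked (`N`) characters so no
#' edge derives from masked evidence, and only fragments reaching their
#' row's own ends attach to the source/sink sentinels. Nodes not on any
#' source-to-sink path are pruned.
#'
#' @param rows row tibble from [extract_area_rows()] (template row first).
#' @param drop_n_edges remove edges touching masked characters. Required
#'   when any row contains `N`.
#' @return an `isocorr_dag`: list with `nodes` (tibble `node`, `pos`, `off`,
#'   `base`, `from_template`), `edges` (tibble `from`, `to`, `weight`,
#'   `template`; node 0 is the source, `n_nodes + 1` the sink) and
#'   `n_nodes`. Node ids are a topological order.
#' @export
build_dag <- function(rows, drop_n_edges = FALSE) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  res <- cpp_build_dag(rows$keys, rows$chars, rows$full, rows$is_template,
                       isTRUE(drop_n_edges))
  structure(list(nodes = tibble::as_tibble(res$nodes),
                 edges = tibble::as_tibble(res$edges),
                 n_nodes = res$n_nodes),
            class = "isocorr_dag")
}

#' @export
print.isocorr_dag <- function(x, ...) {
  cat(sprintf("<isocorr_dag> %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Maximum-weight path consensus over a DAG
#'
#' Dynamic programme in topological order returning the base labels along
#' the source-to-sink path of maximum total edge weight. Ties prefer
#' template-supporting edges, then the alphabetically smaller predecessor
#' base, then the smaller node id, so the result is deterministic.
#'
#' With `center > 0` every edge contributes `weight - center` instead of its
#' raw weight. Raw total weight favours longer paths -- a detour through an
#' extra node accumulates an extra edge -- so an insertion supported by only
#' half the reads would always win. Centring by half the number of spanning
#' rows (as the complex-area corrector does) makes minority edges score
#' negative, restoring majority behaviour while leaving equal-length
#' comparisons unchanged.
#'
#' @param dag an `isocorr_dag` (or any list with compatible `nodes`,
#'   `edges`, `n_nodes`; node ids must be topologically ordered).
#' @param center per-edge score offset; 0 gives the pure maximum-weight
#'   path.
#' @return the consensus base string; `""` when no source-to-sink path
#'   exists. The raw weight of the chosen path is available via
#'   `attr(, "weight")`.
#' @export
max_weight_consensus <- function(dag, center = 0) {
  if (dag$n_nodes == 0 || nrow(dag$edges) == 0) return("")
  res <- cpp_max_weight_path(dag$n_nodes, dag$edges$from, dag$edges$to,
                             dag$edges$weight, dag$edges$template,
                             dag$nodes$base, center)
  if (length(res$path) == 0) return("")
  out <- paste(dag$nodes$base[res$path], collapse = "")
  attr(out, "weight") <- res$weight
  out
}

#' Consensus for one complex area
#'
#' Judges whether the area shows a structural change -- i.e. whether any
#' masked `N` character appears in the candidate rows. If so the DAG is
#' built with `drop_n_edges = TRUE`, so the consensus uses only
#' same-structure evidence; otherwise the plain graph consensus is used
#' (with coverage-centred edge scores, see [max_weight_consensus()]).
#' Falls back to the template substring when the graph yields no path.
#'
#' @param template one-row read tibble.
#' @param area one `complex` segment row from [partition_areas()].
#' @param alignments list of masked alignments for this template.
#' @return corrected base string for the area.
#' @export
correct_complex <- function(template, area, alignments) {
  if (area$kind != "complex") stop("correct_complex() requires a complex area")
  rows <- extract_area_rows(template, alignments, area$start, area$end)
  area_consensus(template$sequence, area$start, area$end, rows$keys,
                 rows$chars, rows$full, rows$is_template)
}
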