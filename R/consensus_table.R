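#' Build the normal and modify consensus tables for a template
#'
#' Accumulates per-template-position statistics over all candidate
#' alignments: the *normal* table from the unmasked candidate rows (`qstr`)
#' and the *modify* table from the masked rows (`newqstr`). Per alignment
#' column: a matching base increments `match` and the base vote; a candidate
#' gap against a template base increments `del`; a masked character (`N`)
#' against a template base increments `skip` (modify table only -- this is
#' the statistic that flags structurally divergent evidence); a candidate
#' base against a template gap is an insertion, attributed to the left
#' flanking template position (`insert` counts inserted-base events, while
#' `ins_reads` counts distinct candidates inserting there). Masked characters
#' at template-gap columns record nothing.
#'
#' @param template one-row read tibble (or list with `read_id`, `sequence`).
#' @param alignments list of masked alignments sharing this template.
#' @param collect_inserts also record the inserted strings observed between
#'   consecutive template positions (list-column `inserted`).
#' @return list with elements `normal` and `modify`; each is a tibble with
#'   0-based `pos`, the template base `ref`, counts `match`, `mis`,
#'   `insert`, `ins_reads`, `del`, `skip` and base votes `A`, `C`, `G`, `T`.
#' @export
build_tables <- function(template, alignments, collect_inserts = FALSE) {
  stopifnot(length(alignments) > 0)
  bad <- vapply(alignments, function(a) !identical(a$template_id, template$read_id),
                logical(1))
  if (any(bad))
    stop("alignment ", which(bad)[1], " refers to template '",
         alignments[[which(bad)[1]]]$template_id, "', expected '",
         template$read_id, "'")
  tstrs <- vapply(alignments, `[[`, character(1), "tstr")
  qstrs <- vapply(alignments, `[[`, character(1), "qstr")
  newqs <- vapply(alignments, function(a) a$newqstr %||% a$qstr, character(1))
  t_starts <- vapply(alignments, function(a) as.integer(a$t_start), integer(1))
  tlen <- nchar(template$sequence)
  ref <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
  as_tbl <- function(M, flavor, rows) {
    tbl <- tibble::as_tibble(as.data.frame(M))
    tbl <- tibble::add_column(tbl, pos = 0:(tlen - 1L), ref = ref, .before = 1)
    if (collect_inserts)
      tbl$inserted <- cpp_collect_inserts(tstrs, rows, t_starts, tlen)
    attr(tbl, "flavor") <- flavor
    attr(tbl, "template_id") <- template$read_id
    tbl
  }
  list(normal = as_tbl(cpp_build_table(tstrs, qstrs, t_starts, tlen), "normal", qstrs),
       modify = as_tbl(cpp_build_table(tstrs, newqs, t_starts, tlen), "modify", newqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Left/right correction boundaries from position coverage
#'
#' A template position is correctable when its coverage
#' `match + insert + skip` reaches `min_coverage`; the boundaries are the
#' first and one-past-the-last such position. Evaluated on the modify table,
#' where masked evidence still counts as coverage through the skip statistic.
#'
#' @param table a consensus table (normally the `modify` flavor).
#' @param min_coverage minimum coverage (>= 1).
#' @return integer `c(left, right)`, a half-open 0-based interval; empty
#'   (`left == right`) when no position qualifies.
#' @export
determine_boundaries <- function(table, min_coverage = 4L) {
  stopifnot(min_coverage >= 1L)
  cov <- table$match + table$insert + table$skip
  idx <- which(cov >= min_coverage)
  if (length(idx) == 0) return(c(left = 0L, right = 0L))
  c(left = table$pos[min(idx)], right = table$pos[max(idx)] + 1L)
}

#' Classify template positions inside the boundaries
#'
#' For each position the structural test `skip > coverage * scov` (coverage
#' being the modify table's `match + insert + skip`) decides which table
#' supplies the counts: the modify table for structurally divergent positions
#' (evidence from other exon structures removed), the normal table otherwise.
#' The base-alignment kind is then assigned from the chosen counts
#' `m = match`, `d = del` and `i = ins_reads` (candidates inserting at least
#' one base immediately after the position). Because a candidate can match a
#' position *and* insert after it, insertion support does not compete with
#' the through-going support: `UNDEFINE` when there is no evidence at all;
#' `INS` when `i >= (m + d)/2` (an insertion event rivals the uncensored
#' covering support, so the area needs graph consensus); else `DEL` when
#' `d > (m + d + skip)/2` (strict majority of the full covering population
#' deletes the template base; ties keep it); else `MAT`.
#'
#' @param normal,modify the two tables from [build_tables()].
#' @param boundaries interval from [determine_boundaries()].
#' @param scov structural coefficient.
#' @return tibble with `pos`, `ref`, `structural`, `kind` and the chosen
#'   counts `m`, `i`, `d`, plus chosen base votes `A`, `C`, `G`, `T`.
#' @export
classify_positions <- function(normal, modify, boundaries, scov = 0.1) {
  left <- boundaries[[1]]; right <- boundaries[[2]]
  if (right <= left)
    return(tibble::tibble(pos = integer(), ref = character(),
                          structural = logical(), kind = character(),
                          m = integer(), i = integer(), d = integer(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer()))
  sel <- normal$pos >= left & normal$pos < right
  nm <- normal[sel, ]; md <- modify[sel, ]
  cov <- md$match + md$insert + md$skip
  structural <- md$skip > cov * scov
  pick <- function(col) ifelse(structural, md[[col]], nm[[col]])
  m <- pick("match"); i <- pick("ins_reads"); d <- pick("del")
  kind <- classify_kind(m, i, d, pick("skip"))
  tibble::tibble(pos = nm$pos, ref = nm$ref, structural = structural,
                 kind = kind, m = m, i = i, d = d,
                 A = as.integer(pick("A")), C = as.integer(pick("C")),
                 G = as.integer(pick("G")), T = as.integer(pick("T")))
}

# the base-alignment typing policy (vectorised); isolated so it can be
# swapped out. Denominators follow the observable populations: deletions
# are observed for every covering candidate (gaps are never masked), so the
# DEL test uses m + d + skip -- skipped candidates still cover the position
# and must not hand deletions a spurious majority. Insertion events are
# censored for masked candidates (their inserted characters are discarded),
# so the INS test compares i against the uncensored support m + d only.
# INS outranks DEL so del+ins pairs (split mismatches) reach the graph
# consensus instead of being half-applied.
classify_kind <- function(m, i, d, s = 0L) {
  kind <- rep("MAT", length(m))
  kind[d > 0.5 * (m + d + s)] <- "DEL"
  kind[i > 0 & i >= 0.5 * (m + d)] <- "INS"
  kind[m + d + s + i == 0] <- "UNDEFINE"
  kind
}
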