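# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no stored data files.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# a random raw alignment (mismatch columns allowed, no gap/gap columns),
# returned as the two row strings
rand_raw_alignment <- function(len = 40, p_match = 0.7, p_mis = 0.1,
                               p_ins = 0.1) {
  t <- q <- character(len)
  for (j in seq_len(len)) {
    u <- stats::runif(1)
    if (u < p_match) { b <- sample(BASES4, 1); t[j] <- b; q[j] <- b }
    else if (u < p_match + p_mis) {
      b <- sample(BASES4, 2); t[j] <- b[1]; q[j] <- b[2]
    } else if (u < p_match + p_mis + p_ins) {
      t[j] <- "-"; q[j] <- sample(BASES4, 1)
    } else { t[j] <- sample(BASES4, 1); q[j] <- "-" }
  }
  list(tstr = paste(t, collapse = ""), qstr = paste(q, collapse = ""))
}

# wrap two row strings into the package's alignment object
as_alignment <- function(tstr, qstr, template_id = "t", candidate_id = "c",
                         t_start = 0L, normalized = FALSE) {
  structure(list(template_id = template_id, candidate_id = candidate_id,
                 strand = "forward", t_start = t_start,
                 t_end = t_start + nchar(gsub("-", "", tstr)),
                 c_start = 0L, c_end = nchar(gsub("-", "", qstr)),
                 seed_score = NA_integer_, tstr = tstr, qstr = qstr,
                 dist = NA_integer_, normalized = normalized),
            class = "isocorr_alignment")
}

# brute-force reference: mark anchors of every window with
# identity <= threshold (and < 1), then mask non-gap candidate characters
brute_mask <- function(tstr, qstr, w, thr) {
  t <- strsplit(tstr, "")[[1]]; q <- strsplit(qstr, "")[[1]]
  L <- length(t)
  out <- q
  if (thr <= 0) return(paste(out, collapse = ""))
  for (i in seq_len(L)) {
    wl <- min(w, L - i + 1L)
    cols <- i:(i + wl - 1L)
    m <- sum(t[cols] != "-" & t[cols] == q[cols])
    if (m / wl <= thr && m < wl && out[i] != "-") out[i] <- "N"
  }
  paste(out, collapse = "")
}

# unbanded edit-distance dynamic programme (oracle for the banded aligner)
dp_edit_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  D <- matrix(0L, na + 1, nb + 1)
  D[, 1] <- 0:na; D[1, ] <- 0:nb
  for (i in seq_len(na))
    for (j in seq_len(nb))
      D[i + 1, j + 1] <- min(D[i, j] + (A[i] != B[j]), D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
  D[na + 1, nb + 1]
}

# random consensus-table tibble with plausible count columns
rand_table <- function(n = 50, max_count = 20) {
  tibble::tibble(
    pos = 0:(n - 1L),
    ref = sample(BASES4, n, replace = TRUE),
    match = sample(0:max_count, n, replace = TRUE),
    mis = 0L,
    insert = sample(0:5, n, replace = TRUE),
    ins_reads = sample(0:5, n, replace = TRUE),
    del = sample(0:5, n, replace = TRUE),
    skip = sample(0:5, n, replace = TRUE),
    A = sample(0:max_count, n, replace = TRUE),
    C = sample(0:max_count, n, replace = TRUE),
    G = sample(0:max_count, n, replace = TRUE),
    T = sample(0:max_count, n, replace = TRUE))
}

# random DAG in the package's node/edge layout: a ladder of `n` levels with
# 1-2 nodes each, random extra skip edges; node ids are topological
rand_dag <- function(max_nodes = 10) {
  repeat {
    n <- sample(2:max_nodes, 1)
    base <- sample(BASES4, n, replace = TRUE)
    nodes <- tibble::tibble(node = 1:n, pos = 1:n, off = 0L, base = base,
                            from_template = FALSE)
    from <- integer(0); to <- integer(0)
    # chain + random forward shortcuts, plus source/sink attachments
    for (v in 2:n) {
      u <- sample(seq_len(v - 1), 1)
      from <- c(from, u); to <- c(to, v)
    }
    n_extra <- sample(0:n, 1)
    for (k in seq_len(n_extra)) {
      u <- sample(0:(n - 1), 1)
      v <- sample((u + 1):(n + 1), 1)
      if (u == 0 && v == n + 1) next  # no base-less source->sink shortcut
      from <- c(from, u); to <- c(to, v)
    }
    from <- c(from, 0L, sample(1:n, 1))
    to <- c(to, sample(1:n, 1), n + 1L)
    ed <- dplyr::distinct(tibble::tibble(from = from, to = to))
    ed$weight <- sample(1:9, nrow(ed), replace = TRUE)
    ed$template <- FALSE
    dag <- structure(list(nodes = nodes, edges = ed, n_nodes = n),
                     class = "isocorr_dag")
    # need at least one source->sink path
    if (nrow(ed[ed$from == 0, ]) > 0) return(dag)
  }
}

# exhaustive enumeration of all source->sink paths; returns best total
# weight (oracle for the DP)
enumerate_best_path <- function(dag) {
  ed <- dag$edges
  sink <- dag$n_nodes + 1L
  best <- -Inf
  recurse <- function(u, w) {
    if (u == sink) { best <<- max(best, w); return(invisible()) }
    nxt <- ed[ed$from == u, ]
    for (k in seq_len(nrow(nxt))) recurse(nxt$to[k], w + nxt$weight[k])
  }
  recurse(0L, 0)
  best
}
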