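mk_types <- function(kinds, start = 0L) {
  n <- length(kinds)
  tibble::tibble(pos = start:(start + n - 1L),
                 ref = sample(BASES4, n, replace = TRUE),
                 structural = FALSE, kind = kinds,
                 m = 10L, i = 0L, d = 0L,
                 A = 0L, C = 0L, G = 0L, T = 0L)
}

test_that("area partitioning follows the MAT/DEL vs INS/UNDEFINE rules", {
  # all MAT -> one simple segment
  segs <- partition_areas(mk_types(rep("MAT", 6)))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$kind, "simple")
  expect_equal(c(segs$start, segs$end), c(0L, 6L))

  # DEL between MATs stays simple
  segs <- partition_areas(mk_types(c("MAT", "MAT", "DEL", "MAT")))
  expect_equal(segs$kind, "simple")

  # INS between MATs becomes complex, extended to the flanking MAT anchors
  segs <- partition_areas(mk_types(c("MAT", "MAT", "INS", "MAT", "MAT")))
  expect_equal(segs$kind, c("simple", "complex", "simple"))
  expect_equal(segs$start[2], 1L)
  expect_equal(segs$end[2], 4L)

  # complex run at the boundary edge without an anchor
  segs <- partition_areas(mk_types(c("UNDEFINE", "MAT", "MAT")))
  expect_equal(segs$kind, c("complex", "simple"))
  expect_equal(segs$start[1], 0L)
})

test_that("segments always tile the interval (random typing)", {
  withr::local_seed(17)
  for (rep in 1:200) {
    kinds <- sample(c("MAT", "DEL", "INS", "UNDEFINE"), sample(1:40, 1),
                    replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
    segs <- partition_areas(mk_types(kinds))
    expect_equal(segs$start[1], 0L)
    expect_equal(segs$end[nrow(segs)], length(kinds))
    if (nrow(segs) > 1)
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
    # simple segments contain only MAT and DEL
    for (s in which(segs$kind == "simple")) {
      inside <- kinds[(segs$start[s] + 1L):segs$end[s]]
      expect_true(all(inside %in% c("MAT", "DEL")))
    }
    # every INS/UNDEFINE position is inside a complex segment
    bad <- which(kinds %in% c("INS", "UNDEFINE")) - 1L
    for (p in bad)
      expect_true(any(segs$kind == "complex" & segs$start <= p & p < segs$end))
  }
})

test_that("simple-area consensus equals per-position argmax voting", {
  ty <- mk_types(c("MAT", "MAT", "DEL", "MAT"))
  ty$ref <- c("A", "C", "G", "T")
  ty$A <- c(7L, 1L, 0L, 0L); ty$G <- c(3L, 0L, 0L, 0L)
  ty$C <- c(0L, 5L, 9L, 0L); ty$T <- c(0L, 0L, 0L, 2L)
  area <- tibble::tibble(start = 0L, end = 4L, kind = "simple", structural = FALSE)
  # DEL position emits nothing; majority bases elsewhere
  expect_equal(correct_simple(area, ty), "ACT")

  # tie goes to the template base
  ty$A[1] <- 3L  # A:3 G:3, ref A
  expect_equal(correct_simple(area, ty), "ACT")

  # no votes at all -> template base, with a warning
  ty$A[1] <- 0L; ty$G[1] <- 0L
  expect_warning(out <- correct_simple(area, ty), "without votes")
  expect_equal(out, "ACT")

  # random vote tables vs an argmax oracle
  withr::local_seed(18)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    ty <- mk_types(rep("MAT", n))
    V <- matrix(sample(0:20, 4 * n, TRUE), n, 4)
    ty$A <- V[, 1]; ty$C <- V[, 2]; ty$G <- V[, 3]; ty$T <- V[, 4]
    area <- tibble::tibble(start = 0L, end = n, kind = "simple",
                           structural = FALSE)
    got <- strsplit(suppressWarnings(correct_simple(area, ty)), "")[[1]]
    for (p in seq_len(n)) {
      votes <- V[p, ]; names(votes) <- BASES4
      mx <- max(votes)
      exp <- if (mx == 0 || votes[ty$ref[p]] == mx) ty$ref[p]
             else BASES4[which.max(votes)]
      expect_equal(got[p], exp)
    }
  }
})

test_that("DAG construction merges coincident nodes and sums edge weights", {
  rows <- tibble::tibble(
    row_id = c("t", "c1", "c2"),
    is_template = c(TRUE, FALSE, FALSE),
    full = TRUE,
    chars = c("ACG", "ACG", "ACG"),
    keys = list(c(0L, 2048L, 4096L), c(0L, 2048L, 4096L), c(0L, 2048L, 4096L)))
  dag <- build_dag(rows)
  expect_equal(dag$n_nodes, 3L)
  expect_equal(nrow(dag$edges), 4L)  # source, A->C, C->G, sink
  expect_true(all(dag$edges$weight == 3L))
  expect_equal(as.character(max_weight_consensus(dag)), "ACG")

  # a variant middle base branches with split weights
  rows$chars[3] <- "ATG"
  dag2 <- build_dag(rows)
  mid <- dag2$edges[dag2$edges$from == 1, ]
  expect_setequal(mid$weight, c(2L, 1L))
  expect_equal(as.character(max_weight_consensus(dag2)), "ACG")
})

test_that("masked rows are split and only clean fragments attach to ends", {
  rows <- tibble::tibble(
    row_id = c("t", "c1"),
    is_template = c(TRUE, FALSE),
    full = TRUE,
    chars = c("ACGT", "ACNT"),
    keys = list(0:3 * 2048L, 0:3 * 2048L))
  expect_error(build_dag(rows, drop_n_edges = FALSE), "drop_n_edges")
  dag <- build_dag(rows, drop_n_edges = TRUE)
  # the masked G node contributes nothing; no edge touches an N-derived node
  expect_false(any(dag$nodes$base == "N"))
  expect_equal(as.character(max_weight_consensus(dag)), "ACGT")
})

test_that("max-weight path equals exhaustive enumeration on random DAGs", {
  withr::local_seed(19)
  for (rep in 1:60) {
    dag <- rand_dag(10)
    best <- enumerate_best_path(dag)
    got <- max_weight_consensus(dag)
    if (!is.finite(best)) {
      expect_equal(got, "")
    } else {
      expect_equal(attr(got, "weight"), best)
    }
  }
})

test_that("complex-area consensus equals composing build_dag + max path", {
  withr::local_seed(20)
  genes <- simulate_genes(1, isoform_range = c(1, 1),
                          exon_count_range = c(3, 3),
                          exon_length_range = c(60, 80), seed = 23)
  sim <- simulate_reads(genes, depth = 12, full_length_fraction = 1, seed = 24)
  reads <- sim$reads
  idx <- index_kmers(reads)
  tpl <- list(read_id = reads$read_id[1], sequence = reads$sequence[1])
  cd <- find_candidates(reads$read_id[1], idx)
  alns <- lapply(seq_len(nrow(cd)), function(j)
    mask_low_identity(normalize_alignment(align_pair(reads, cd[j, ]))))
  tt <- build_tables(tpl, alns)
  b <- determine_boundaries(tt$modify)
  ty <- classify_positions(tt$normal, tt$modify, b)
  segs <- partition_areas(ty)
  cx <- segs[segs$kind == "complex", ]
  expect_gt(nrow(cx), 0)
  for (s in seq_len(min(5, nrow(cx)))) {
    area <- cx[s, ]
    composed <- {
      rows <- extract_area_rows(tpl, alns, area$start, area$end)
      has_n <- any(grepl("N", rows$chars, fixed = TRUE))
      dag <- build_dag(rows, drop_n_edges = has_n)
      spanning <- sum(rows$full & !grepl("N", rows$chars, fixed = TRUE))
      out <- as.character(max_weight_consensus(dag, center = spanning / 2))
      if (!nzchar(out)) substr(tpl$sequence, area$start + 1, area$end) else out
    }
    expect_equal(correct_complex(tpl, area, alns), composed)
  }
})
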