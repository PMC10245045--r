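mk_template <- function(seq, id = "t") list(read_id = id, sequence = seq)

test_that("an error-free spanning candidate yields pure match counts", {
  s <- "ACGTACGTAC"
  aln <- mask_low_identity(normalize_alignment(as_alignment(s, s)), 5, 0.5)
  tt <- build_tables(mk_template(s), list(aln))
  for (tab in tt) {
    expect_equal(tab$match, rep(1L, 10))
    expect_equal(tab$del, rep(0L, 10))
    expect_equal(tab$insert, rep(0L, 10))
    expect_equal(tab$skip, rep(0L, 10))
  }
  expect_equal(tt$normal$A, as.integer(tt$normal$ref == "A"))
})

test_that("masked stretches count as skips in the modify table only", {
  s <- "ACGTACGTAC"
  aln <- as_alignment(s, s)
  aln$normalized <- TRUE
  aln$newqstr <- paste0("ACGT", "NNNN", "AC")  # positions 4-7 masked
  class(aln) <- c("isocorr_masked_alignment", class(aln))
  tt <- build_tables(mk_template(s), list(aln))
  expect_equal(tt$modify$skip, c(0L,0L,0L,0L,1L,1L,1L,1L,0L,0L))
  expect_equal(tt$modify$match, c(1L,1L,1L,1L,0L,0L,0L,0L,1L,1L))
  expect_equal(tt$normal$skip, rep(0L, 10))
  expect_equal(tt$normal$match, rep(1L, 10))
})

test_that("insertions attach to the left flanking position; masked inserts vanish", {
  #   template ACG T
  #   cand     ACGXT  (X inserted between pos 2 and 3)
  aln <- as_alignment("ACG-T", "ACGCT", normalized = TRUE)
  aln$newqstr <- "ACGNT"  # the inserted base got masked
  class(aln) <- c("isocorr_masked_alignment", class(aln))
  tt <- build_tables(mk_template("ACGT"), list(aln))
  expect_equal(tt$normal$insert, c(0L, 0L, 1L, 0L))
  expect_equal(tt$normal$ins_reads, c(0L, 0L, 1L, 0L))
  expect_equal(tt$modify$insert, c(0L, 0L, 0L, 0L))  # masked -> not recorded
  expect_equal(tt$modify$skip, rep(0L, 4))           # gap column, no skip
})

test_that("counts equal a brute-force column sweep on noisy candidates", {
  withr::local_seed(71)
  genes <- simulate_genes(1, isoform_range = c(1, 1),
                          exon_count_range = c(3, 3),
                          exon_length_range = c(60, 80), seed = 9)
  sim <- simulate_reads(genes, depth = 20, mismatch_rate = 0.05,
                        insert_rate = 0.05, delete_rate = 0.05,
                        full_length_fraction = 1, seed = 10)
  reads <- sim$reads
  idx <- index_kmers(reads)
  cd <- find_candidates(reads$read_id[1], idx)
  alns <- lapply(seq_len(nrow(cd)), function(j)
    mask_low_identity(normalize_alignment(align_pair(reads, cd[j, ]))))
  tpl <- mk_template(reads$sequence[1], reads$read_id[1])
  tt <- build_tables(tpl, alns)
  # brute force on both flavors
  for (flavor in c("normal", "modify")) {
    ref <- c(match = 0, insert = 0, del = 0, skip = 0)
    n <- nchar(tpl$sequence)
    M <- matrix(0L, n, 4, dimnames = list(NULL, names(ref)))
    for (a in alns) {
      t <- strsplit(a$tstr, "")[[1]]
      q <- strsplit(if (flavor == "normal") a$qstr else a$newqstr, "")[[1]]
      tpos <- a$t_start - 1L
      for (col in seq_along(t)) {
        if (t[col] != "-") {
          tpos <- tpos + 1L
          if (q[col] == "-") M[tpos + 1L, "del"] <- M[tpos + 1L, "del"] + 1L
          else if (q[col] == "N") M[tpos + 1L, "skip"] <- M[tpos + 1L, "skip"] + 1L
          else if (q[col] == t[col]) M[tpos + 1L, "match"] <- M[tpos + 1L, "match"] + 1L
        } else if (q[col] != "-" && q[col] != "N" && tpos >= 0L) {
          M[tpos + 1L, "insert"] <- M[tpos + 1L, "insert"] + 1L
        }
      }
    }
    tab <- tt[[flavor]]
    expect_equal(tab$match, unname(M[, "match"]))
    expect_equal(tab$insert, unname(M[, "insert"]))
    expect_equal(tab$del, unname(M[, "del"]))
    expect_equal(tab$skip, unname(M[, "skip"]))
  }
  # normal flavor never sees masked characters
  expect_equal(sum(tt$normal$skip), 0L)
  # per-candidate conservation: match+del+skip summed over positions equals
  # the candidate's template-consuming columns
  for (a in alns[1:3]) {
    one <- build_tables(tpl, list(a))
    t <- strsplit(a$tstr, "")[[1]]
    expect_equal(sum(one$modify$match + one$modify$del + one$modify$skip +
                       one$modify$mis),
                 sum(t != "-"))
  }
})

test_that("boundaries implement the coverage filter and are monotone", {
  tab <- rand_table(60)
  # uniform high coverage -> full interval
  tab2 <- tab
  tab2$match <- 10L; tab2$insert <- 0L; tab2$skip <- 0L
  expect_equal(unname(determine_boundaries(tab2, 4)), c(0L, 60L))
  # rising/falling profile clips the flanks
  prof <- c(1, 2, 3, 5, 6, 6, 5, 3, 2, 1)
  tab3 <- rand_table(10)
  tab3$match <- as.integer(prof); tab3$insert <- 0L; tab3$skip <- 0L
  expect_equal(unname(determine_boundaries(tab3, 4)), c(3L, 7L))
  # no qualifying position -> empty interval
  expect_equal(unname(determine_boundaries(tab3, 99)), c(0L, 0L))

  withr::local_seed(13)
  for (rep in 1:500) {
    tb <- rand_table(sample(5:40, 1))
    mc <- sample(1:30, 1)
    got <- determine_boundaries(tb, mc)
    cov <- tb$match + tb$insert + tb$skip
    ok <- which(cov >= mc)
    exp <- if (length(ok) == 0) c(0L, 0L) else c(min(ok) - 1L, max(ok))
    expect_equal(unname(got), exp)
  }
  # monotone: larger min_coverage never widens
  tb <- rand_table(40)
  prev <- determine_boundaries(tb, 1)
  for (mc in 2:10) {
    cur <- determine_boundaries(tb, mc)
    expect_gte(cur[1], prev[1])
    expect_lte(cur[2], prev[2])
    prev <- cur
  }
})

test_that("position typing follows the structural test and typing policy", {
  withr::local_seed(14)
  for (rep in 1:100) {
    n <- 30
    normal <- rand_table(n); modify <- rand_table(n)
    modify$ref <- normal$ref
    b <- c(0L, n)
    got <- classify_positions(normal, modify, b, scov = 0.1)
    cov <- modify$match + modify$insert + modify$skip
    structural <- modify$skip > cov * 0.1
    expect_equal(got$structural, structural)
    for (p in seq_len(n)) {
      src <- if (structural[p]) modify else normal
      m <- src$match[p]; i <- src$ins_reads[p]; d <- src$del[p]; s <- src$skip[p]
      kind <-
        if (m + d + s + i == 0) "UNDEFINE"
        else if (i > 0 && i >= 0.5 * (m + d)) "INS"
        else if (d > 0.5 * (m + d + s)) "DEL"
        else "MAT"
      expect_equal(got$kind[p], kind)
    }
  }
})

test_that("skip-free tables make every position non-structural", {
  normal <- rand_table(20)
  normal$skip <- 0L
  got <- classify_positions(normal, normal, c(0L, 20L), scov = 0.1)
  expect_false(any(got$structural))
})
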