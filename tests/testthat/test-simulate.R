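test_that("gene models respect the requested structure", {
  genes <- simulate_genes(1, isoform_range = c(1, 1), seed = 1)
  iso <- genes$isoforms[[1]]
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$abundance, 1.0)

  genes <- simulate_genes(5, isoform_range = c(2, 2), minor_abundance = 0.2,
                          seed = 2)
  for (g in seq_len(5)) {
    iso <- genes$isoforms[[g]]
    expect_equal(nrow(iso), 2L)
    expect_equal(iso$abundance, c(0.8, 0.2))
    # minor chain drops exactly one internal exon
    major <- iso$exon_chain[[1]]; minor <- iso$exon_chain[[2]]
    dropped <- setdiff(major, minor)
    expect_length(dropped, 1L)
    expect_true(dropped > 1 && dropped < genes$n_exons[g])
    # exon chains distinct, transcripts are exon concatenations
    exons <- genes$exons[[g]]
    expect_equal(iso$sequence[2], paste(exons[minor], collapse = ""))
  }
  expect_error(simulate_genes(1, isoform_range = c(4, 4),
                              exon_count_range = c(4, 4), seed = 1),
               "infeasible")
})

test_that("gene generation is deterministic given the seed", {
  g1 <- simulate_genes(20, isoform_range = c(1, 3), seed = 99)
  g2 <- simulate_genes(20, isoform_range = c(1, 3), seed = 99)
  expect_identical(g1, g2)
  g3 <- simulate_genes(20, isoform_range = c(1, 3), seed = 100)
  expect_false(identical(g1$exons[[1]], g3$exons[[1]]))
  s1 <- simulate_reads(g1, depth = 5, seed = 7)
  s2 <- simulate_reads(g1, depth = 5, seed = 7)
  expect_identical(s1, s2)
})

test_that("exons of one gene never share a 13-mer", {
  genes <- simulate_genes(10, isoform_range = c(2, 2), seed = 5)
  for (g in seq_len(10)) {
    km <- lapply(genes$exons[[g]], function(e)
      substring(e, 1:(nchar(e) - 12), 13:nchar(e)))
    for (a in seq_along(km)) for (b in seq_along(km))
      if (a < b) expect_length(intersect(km[[a]], km[[b]]), 0L)
  }
})

test_that("zero error rates give exact (sub)transcripts", {
  genes <- simulate_genes(2, isoform_range = c(1, 2), seed = 3)
  sim <- simulate_reads(genes, depth = 6, mismatch_rate = 0, insert_rate = 0,
                        delete_rate = 0, seed = 4)
  tx <- gene_transcripts(genes)
  for (j in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[j, ]
    full <- tx$sequence[match(tr$isoform_id, tx$isoform_id)]
    expect_equal(sim$reads$sequence[j],
                 substr(full, tr$transcript_start + 1, tr$transcript_end))
  }
  expect_true(all(sim$truth$n_mismatch == 0 & sim$truth$n_insert == 0 &
                    sim$truth$n_delete == 0))
})

test_that("realized error rates sit within binomial expectation", {
  genes <- simulate_genes(3, isoform_range = c(1, 1),
                          exon_count_range = c(5, 5), seed = 6)
  sim <- simulate_reads(genes, depth = 10, mismatch_rate = 0.04,
                        insert_rate = 0.05, delete_rate = 0.04,
                        full_length_fraction = 1, seed = 7)
  n_bases <- sum(sim$truth$transcript_end - sim$truth$transcript_start)
  expect_gt(n_bases, 10000)
  check <- function(observed, rate) {
    expected <- n_bases * rate
    sd3 <- 3 * sqrt(n_bases * rate * (1 - rate))
    expect_lt(abs(observed - expected), sd3)
  }
  check(sum(sim$truth$n_insert), 0.05)
  check(sum(sim$truth$n_delete), 0.04)
  # mismatches only hit non-deleted bases
  check(sum(sim$truth$n_mismatch), 0.04 * 0.96)
})

test_that("recorded edits reproduce the read from the true transcript", {
  genes <- simulate_genes(2, isoform_range = c(1, 2), seed = 8)
  sim <- simulate_reads(genes, depth = 4, seed = 9, keep_edits = TRUE)
  tx <- gene_transcripts(genes)
  for (j in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[j, ]
    true_sub <- substr(tx$sequence[match(tr$isoform_id, tx$isoform_id)],
                       tr$transcript_start + 1, tr$transcript_end)
    rebuilt <- isocorr:::apply_edits(true_sub, tr$edits[[1]])
    expect_equal(rebuilt, sim$reads$sequence[j])
    # and reverting: removing all edits reproduces the true sequence length
    ed <- tr$edits[[1]]
    expect_equal(nchar(sim$reads$sequence[j]),
                 nchar(true_sub) + sum(ed$type == "insert") -
                   sum(ed$type == "delete"))
  }
})

test_that("isoform sampling tracks the configured abundances", {
  genes <- simulate_genes(10, isoform_range = c(2, 2), minor_abundance = 0.2,
                          seed = 10)
  sim <- simulate_reads(genes, depth = 30, seed = 11)
  minor <- grepl("\\.i2$", sim$truth$isoform_id)
  n <- nrow(sim$truth)
  # 300 draws at p = 0.2: stay within 4 binomial sds
  expect_lt(abs(sum(minor) - 0.2 * n), 4 * sqrt(n * 0.2 * 0.8))
})
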