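fix_eval <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genes <- simulate_genes(6, isoform_range = c(2, 2), minor_abundance = 0.25,
                              exon_count_range = c(4, 5),
                              exon_length_range = c(100, 160), seed = 31)
      sim <- simulate_reads(genes, depth = 12, seed = 32)
      cache <<- list(genes = genes, sim = sim)
    }
    cache
  }
})

test_that("error-free reads are assigned to their true isoform with the skipped exon as margin", {
  genes <- simulate_genes(4, isoform_range = c(2, 2), seed = 33)
  sim <- simulate_reads(genes, depth = 6, mismatch_rate = 0, insert_rate = 0,
                        delete_rate = 0, full_length_fraction = 1, seed = 34)
  asg <- assign_isoforms(sim$reads, genes, sim$truth)
  expect_equal(asg$isoform_id, sim$truth$isoform_id)
  expect_true(all(asg$best_dist == 0))
  # the margin reflects the skipped exon: bounded by its length above and
  # by half of it below (the edit-distance optimum may thread part of the
  # exon through coincidental matches, so exact equality is not expected)
  tx <- gene_transcripts(genes)
  for (j in seq_len(nrow(asg))) {
    both <- tx[tx$gene_id == asg$gene_id[j], ]
    exon_len <- abs(diff(both$length))
    expect_lte(asg$margin[j], exon_len)
    expect_gte(asg$margin[j], 0.5 * exon_len)
  }
})

test_that("ambiguous reads stay unassigned under the margin rule", {
  # two isoforms identical except a tiny internal exon below the margin
  genes <- simulate_genes(1, isoform_range = c(1, 1),
                          exon_count_range = c(3, 3),
                          exon_length_range = c(100, 120), seed = 35)
  iso <- genes$isoforms[[1]]
  exons <- genes$exons[[1]]
  tiny <- "ACGTACGTAA"  # 10 bp < margin_min = 20
  iso2 <- tibble::tibble(isoform_id = c("g0001.i1", "g0001.i2"),
                         exon_chain = list(1:3, 1:3),
                         abundance = c(0.5, 0.5),
                         sequence = c(paste(c(exons[1], tiny, exons[2], exons[3]),
                                            collapse = ""),
                                      paste(exons, collapse = "")))
  genes$isoforms[[1]] <- iso2
  reads <- tibble::tibble(read_id = "q1", sequence = iso2$sequence[2])
  truth <- tibble::tibble(read_id = "q1", gene_id = "g0001",
                          isoform_id = "g0001.i2", strand = "+",
                          transcript_start = 0L,
                          transcript_end = nchar(iso2$sequence[2]))
  asg <- assign_isoforms(reads, genes, truth)
  expect_true(is.na(asg$isoform_id))
  expect_lte(asg$margin, 20)
})

test_that("raw-read assignment at full error rates is nearly always correct", {
  f <- fix_eval()
  asg <- assign_isoforms(f$sim$reads, f$genes, f$sim$truth,
                         assign_threshold = 0.30)
  ok <- !is.na(asg$isoform_id)
  expect_gt(mean(ok), 0.9)
  expect_gt(mean(asg$isoform_id[ok] == f$sim$truth$isoform_id[ok]), 0.99)
})

test_that("relative coverage is exact fraction counting", {
  asg <- tibble::tibble(
    read_id = sprintf("r%02d", 1:30), gene_id = "g1",
    isoform_id = c(rep("g1.i1", 24), rep("g1.i2", 6)),
    best_dist = 0L, best_rate = 0, margin = Inf)
  rc <- relative_coverage(asg)
  expect_equal(rc$rel_cov[rc$isoform_id == "g1.i2"], 0.2)
  expect_equal(rc$rel_cov[rc$isoform_id == "g1.i1"], 0.8)
  expect_equal(rc$n_gene_reads, c(30L, 30L))
  # unassigned reads count in the denominator only
  asg$isoform_id[1:3] <- NA
  rc2 <- relative_coverage(asg)
  expect_equal(rc2$n_assigned[rc2$isoform_id == "g1.i1"], 21L)
  expect_equal(rc2$n_gene_reads[1], 30L)
})

test_that("read metrics: exact transcripts give zero error, raw reads the injected rate", {
  f <- fix_eval()
  tx <- gene_transcripts(f$genes)
  # corrected == true transcripts
  perfect <- f$sim$reads
  perfect$sequence <- vapply(seq_len(nrow(perfect)), function(j) {
    tr <- f$sim$truth[j, ]
    substr(tx$sequence[match(tr$isoform_id, tx$isoform_id)],
           tr$transcript_start + 1, tr$transcript_end)
  }, character(1))
  m0 <- compute_read_metrics(f$sim$reads, perfect, f$genes, f$sim$truth)
  expect_equal(m0$error_rate, 0)
  expect_equal(m0$n_umr, 0L)
  expect_equal(m0$pct_read, 100)

  # corrected == raw: error rate ~ injected 13%
  m1 <- compute_read_metrics(f$sim$reads, f$sim$reads, f$genes, f$sim$truth)
  injected <- with(f$sim$truth,
                   sum(n_mismatch + n_insert + n_delete) /
                     sum(nchar(f$sim$reads$sequence)))
  expect_lt(abs(m1$error_rate - injected), 0.02)

  # empty corrected set -> zero throughput, vacuous rates
  m2 <- compute_read_metrics(f$sim$reads, f$sim$reads[0, ], f$genes, f$sim$truth)
  expect_equal(m2$n_read, 0L)
  expect_true(is.na(m2$error_rate))
})

test_that("isoform retention: identity run has zero loss, dropped minors concentrate low bins", {
  f <- fix_eval()
  ret <- isoform_retention(f$sim$reads, f$sim$reads, f$genes, f$sim$truth,
                           raw_threshold = 0.30, corrected_threshold = 0.30)
  expect_true(all(ret$per_gene$delta == 0))
  expect_equal(sum(ret$isoforms$lost), 0L)
  # conservation: histogram sums to genes evaluated
  expect_equal(sum(ret$delta_histogram$n_genes), nrow(ret$per_gene))

  # drop every minor-isoform read from the "corrected" set
  minor <- grepl("\\.i2$", f$sim$truth$isoform_id)
  cor2 <- f$sim$reads[!minor, ]
  ret2 <- isoform_retention(f$sim$reads, cor2, f$genes, f$sim$truth,
                            raw_threshold = 0.30, corrected_threshold = 0.30)
  g2 <- glance(ret2)
  expect_gt(g2$reduced, 0)
  expect_equal(g2$reduced + g2$unchanged + g2$increased, g2$n_genes)
  # all losses in bins at or below the minor abundance neighbourhood
  lost_bins <- as.numeric(as.character(ret2$isoforms$bin[ret2$isoforms$lost]))
  expect_true(all(lost_bins <= 0.5))
  # an isoform absent from raw assignments is never "lost"
  expect_true(all(paste(ret2$isoforms$gene_id, ret2$isoforms$isoform_id) %in%
                    paste(ret2$raw_assignments$gene_id,
                          ret2$raw_assignments$isoform_id)))
})

test_that("tidy/glance/autoplot methods return the documented shapes", {
  f <- fix_eval()
  ret <- isoform_retention(f$sim$reads, f$sim$reads, f$genes, f$sim$truth,
                           corrected_threshold = 0.30)
  expect_s3_class(tidy(ret), "tbl_df")
  expect_equal(nrow(tidy(ret)), 10L)  # ten relative-coverage bins
  expect_s3_class(autoplot(ret), "ggplot")
  expect_equal(nrow(glance(ret)), 1L)
})
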