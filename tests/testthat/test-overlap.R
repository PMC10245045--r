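test_that("k-mer indexing counts positions exactly", {
  reads <- tibble::tibble(read_id = "r1", sequence = "ACGTACGT")
  idx <- index_kmers(reads, k = 8)
  expect_equal(idx$cpp$n_positions, 1)
  # 5 indexed positions for k=4: ACGT (x2), CGTA, GTAC, TACG
  idx4 <- isocorr:::cpp_build_kmer_index("ACGTACGT", 4L, 200L)
  expect_equal(idx4$n_positions, 5)
  expect_error(index_kmers(reads, k = 5), "k must be")

  # brute-force total position count over random reads
  withr::local_seed(21)
  reads <- tibble::tibble(read_id = sprintf("r%02d", 1:20),
                          sequence = vapply(sample(50:150, 20, TRUE),
                                            rand_seq, character(1)))
  k <- 13
  idx <- index_kmers(reads, k = k, max_kmer_occ = 200)
  expected <- sum(pmax(0L, nchar(reads$sequence) - k + 1L))
  expect_equal(idx$cpp$n_positions, expected)  # no k-mer repeats 200+ reads
})

test_that("identical reads list each other as candidates symmetrically", {
  withr::local_seed(5)
  s <- rand_seq(300)
  reads <- tibble::tibble(read_id = c("a", "b", "zz"),
                          sequence = c(s, s, rand_seq(300)))
  idx <- index_kmers(reads)
  ca <- find_candidates("a", idx)
  cb <- find_candidates("b", idx)
  expect_equal(ca$candidate_id[1], "b")
  expect_equal(cb$candidate_id[1], "a")
  expect_equal(ca$seed_score[1], 300 - 13 + 1)
  # no shared k-mers -> empty result
  expect_true(!"zz" %in% ca$candidate_id || ca$seed_score[ca$candidate_id == "zz"] >= 4)
})

test_that("error-free copies of one transcript all recruit each other", {
  withr::local_seed(6)
  s <- rand_seq(500)
  reads <- tibble::tibble(read_id = sprintf("c%02d", 1:30),
                          sequence = rep(s, 30))
  idx <- index_kmers(reads)
  for (id in reads$read_id[c(1, 15, 30)]) {
    cd <- find_candidates(id, idx, min_seed = 5)
    expect_equal(nrow(cd), 29)
    expect_false(id %in% cd$candidate_id)
  }
})

test_that("reverse-strand candidates are found and align after orientation", {
  withr::local_seed(8)
  s <- rand_seq(400)
  reads <- tibble::tibble(read_id = c("f", "r"),
                          sequence = c(s, revcomp(s)))
  idx <- index_kmers(reads)
  cd <- find_candidates("f", idx)
  expect_equal(cd$strand, "reverse")
  aln <- align_pair(reads, cd[1, ])
  expect_equal(aln$dist, 0)
  expect_equal(gsub("-", "", aln$qstr), s)
})

test_that("banded alignment matches hand cases and an unbanded DP oracle", {
  al <- isocorr:::cpp_align_banded("ACGT", "ACGT", 10L)
  expect_equal(al$dist, 0)
  expect_equal(al$tstr, "ACGT")
  al2 <- isocorr:::cpp_align_banded("ACGT", "AGT", 10L)
  expect_equal(al2$dist, 1)
  expect_equal(sum(strsplit(al2$qstr, "")[[1]] == "-"), 1)

  withr::local_seed(33)
  for (rep in 1:20) {
    a <- rand_seq(sample(100:200, 1))
    # derive b from a with ~10% errors
    err <- isocorr:::inject_errors(a, 0.03, 0.04, 0.03)
    b <- err$sequence
    al <- isocorr:::cpp_align_banded(a, b, 60L)
    expect_equal(al$dist, dp_edit_distance(a, b))
    expect_equal(gsub("-", "", al$tstr), a)
    expect_equal(gsub("-", "", al$qstr), b)
  }
})

test_that("alignment edit distance agrees with Biostrings on small pairs", {
  withr::local_seed(54)
  for (rep in 1:5) {
    a <- rand_seq(150)
    b <- isocorr:::inject_errors(a, 0.04, 0.05, 0.04)$sequence
    al <- isocorr:::cpp_align_banded(a, b, 80L)
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix =
        Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1),
      gapOpening = 0, gapExtension = -1, type = "global", scoreOnly = TRUE)
    expect_equal(al$dist, -ref)
  }
})

test_that("mismatch splitting preserves sequences and removes mismatches", {
  nm <- isocorr:::cpp_normalize_alignment("ACT", "AGT")
  expect_equal(nm$tstr, "AC-T")
  expect_equal(nm$qstr, "A-GT")

  aln <- as_alignment("ACGT", "ACGT")
  out <- normalize_alignment(aln)
  expect_equal(out$tstr, "ACGT")

  withr::local_seed(44)
  for (rep in 1:200) {
    raw <- rand_raw_alignment(sample(10:60, 1))
    nm <- isocorr:::cpp_normalize_alignment(raw$tstr, raw$qstr)
    t2 <- strsplit(nm$tstr, "")[[1]]; q2 <- strsplit(nm$qstr, "")[[1]]
    expect_equal(gsub("-", "", nm$tstr), gsub("-", "", raw$tstr))
    expect_equal(gsub("-", "", nm$qstr), gsub("-", "", raw$qstr))
    expect_equal(sum(t2 != "-" & q2 != "-" & t2 != q2), 0L)
    n_mis <- {
      t1 <- strsplit(raw$tstr, "")[[1]]; q1 <- strsplit(raw$qstr, "")[[1]]
      sum(t1 != "-" & q1 != "-" & t1 != q1)
    }
    expect_equal(nchar(nm$tstr), nchar(raw$tstr) + n_mis)
  }
})

test_that("seed chains across a skipped exon report the diagonal jump", {
  withr::local_seed(55)
  a1 <- rand_seq(400); a2 <- rand_seq(400); exon <- rand_seq(150)
  reads <- tibble::tibble(
    read_id = c("skipper", "carrier"),
    sequence = c(paste0(a1, a2), paste0(a1, exon, a2)))
  idx <- index_kmers(reads)
  cd <- find_candidates("skipper", idx)
  expect_equal(cd$candidate_id, "carrier")
  expect_equal(cd$jump, 150L)   # candidate carries 150 extra bases
  expect_lt(abs(cd$j_t1 - 400L), 20)
  # the candidate interval between the seed blocks holds the exon (up to a
  # couple of bases of boundary wobble from junction-spanning seeds)
  seg <- substr(reads$sequence[2], cd$j_c1 + 1, cd$j_c2)
  expect_lt(abs(nchar(seg) - 150L), 10)
  expect_true(grepl(substr(exon, 5, 145), seg, fixed = TRUE))
  # seen from the carrier, the jump is a deletion (negative)
  cd2 <- find_candidates("carrier", idx)
  expect_equal(cd2$jump, -150L)
})
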