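test_that("exact substrings align at their true coordinates", {
  ref <- ref_fixture()
  q <- substr(ref$sequence, 101, 250)  # 0-based 100..249
  a <- semi_global_align(q, ref)
  expect_equal(a$ref_start, 100L)
  expect_equal(a$ref_end, 249L)
  expect_equal(a$identity, 1)
  expect_equal(a$orientation, "forward")
  expect_equal(a$score, 2L * 150L)
})

test_that("reverse-complement queries keep coordinates, flip orientation", {
  ref <- ref_fixture()
  q <- substr(ref$sequence, 101, 250)
  a <- semi_global_align(oracle_revcomp(q), ref)
  expect_equal(a$ref_start, 100L)
  expect_equal(a$ref_end, 249L)
  expect_equal(a$orientation, "reverse")
  expect_equal(a$identity, 1)
})

test_that("the full reference aligns to itself end to end", {
  ref <- ref_fixture()
  a <- semi_global_align(ref$sequence, ref)
  expect_equal(a$ref_start, 0L)
  expect_equal(a$ref_end, 1540L)
  expect_equal(a$identity, 1)
})

test_that("optimal scores equal the exhaustive DP oracle on random pairs", {
  set.seed(31)
  sc <- scoring(min_identity = 0, min_aligned_len = 1, min_score = -Inf)
  for (i in 1:60) {
    q <- random_dna(sample(3:50, 1))
    r <- random_dna(sample(3:50, 1))
    a <- semi_global_align(q, r, sc, banded = FALSE)
    expect_equal(a$score, oracle_semiglobal_best(q, r),
                 info = paste("q:", q, "r:", r))
  }
})

test_that("scores also match an independent aligner implementation", {
  set.seed(32)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  sc <- scoring(min_identity = 0, min_aligned_len = 1, min_score = -Inf)
  for (i in 1:25) {
    q <- random_dna(sample(10:80, 1))
    r <- random_dna(sample(40:200, 1))
    a <- semi_global_align(q, r, sc, banded = FALSE)
    pa <- Biostrings::pairwiseAlignment(q, r, type = "global-local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    ra <- Biostrings::pairwiseAlignment(oracle_revcomp(q), r,
                                        type = "global-local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    expect_equal(a$score,
                 max(Biostrings::score(pa), Biostrings::score(ra)))
  }
})

test_that("banded acceleration agrees with the full DP on realistic reads", {
  ref <- ref_fixture()
  set.seed(33)
  # substitution-error reads from assorted windows, both orientations
  seqs <- character(0)
  for (i in 1:40) {
    s <- sample(0:1200, 1)
    len <- sample(80:300, 1)
    frag <- strsplit(substr(ref$sequence, s + 1, s + len), "")[[1]]
    nerr <- rbinom(1, len, 0.02)
    if (nerr > 0) {
      at <- sample(len, nerr)
      frag[at] <- sample(c("A", "C", "G", "T"), nerr, TRUE)
    }
    q <- paste(frag, collapse = "")
    if (i %% 2 == 0) q <- oracle_revcomp(q)
    seqs <- c(seqs, q)
  }
  reads <- make_reads(seqs)
  fast <- align_sample(reads, ref, banded = TRUE)
  slow <- align_sample(reads, ref, banded = FALSE)
  expect_equal(fast$alignments, slow$alignments)
  expect_equal(fast$counts, slow$counts)
})

test_that("strand symmetry holds for error-bearing reads", {
  ref <- ref_fixture()
  set.seed(34)
  for (i in 1:10) {
    s <- sample(0:1300, 1)
    q <- substr(ref$sequence, s + 1, s + 120)
    a_f <- semi_global_align(q, ref)
    a_r <- semi_global_align(oracle_revcomp(q), ref)
    expect_equal(a_f[, c("ref_start", "ref_end", "score")],
                 a_r[, c("ref_start", "ref_end", "score")])
    expect_equal(a_f$orientation, "forward")
    expect_equal(a_r$orientation, "reverse")
  }
})

test_that("free reference context never shifts an exact substring", {
  set.seed(35)
  core <- random_dna(60)
  for (pad in c(0, 5, 40)) {
    r <- paste0(random_dna(pad), core, random_dna(pad))
    a <- semi_global_align(core, r, scoring(min_aligned_len = 10))
    expect_equal(a$ref_start, pad)
    expect_equal(a$ref_end, pad + 59)
  }
})

test_that("non-16S sequences fail the identity threshold", {
  ref <- ref_fixture()
  set.seed(36)
  junk <- make_reads(replicate(10, random_dna(150)))
  out <- align_sample(junk, ref)
  expect_equal(unname(out$counts["failed"]), 10L)
  expect_equal(nrow(out$alignments), 0L)
})

test_that("aligning an empty sample is a sample failure", {
  expect_error(align_sample(make_reads(character(0)), ref_fixture()),
               "no reads")
})
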