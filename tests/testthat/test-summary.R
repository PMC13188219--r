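aln_df <- function(starts, ends) {
  data.frame(read_id = paste0("r", seq_along(starts)),
             ref_start = starts, ref_end = ends,
             orientation = "forward", score = 1L,
             identity = 1, aligned_len = ends - starts + 1L,
             stringsAsFactors = FALSE)
}

test_that("position statistics use the median conventions", {
  st <- position_stats(aln_df(c(10, 20, 30), c(110, 120, 130)))
  expect_equal(st$median_start, 20)
  expect_equal(st$min_start, 10)
  expect_equal(st$max_end, 130)
  # even n: average of the two middle values
  st <- position_stats(aln_df(c(10, 20, 30, 40), c(50, 60, 70, 80)))
  expect_equal(st$median_start, 25.0)
  # the median resists the outliers that skew the mean
  st <- position_stats(aln_df(c(0, rep(532, 9)), rep(806, 10)))
  expect_equal(st$median_start, 532)
  expect_equal(st$mean_start, 478.8)
  expect_error(position_stats(aln_df(1, 2)[0, ]), "no alignments")
})

test_that("coverage equals the positionwise brute-force oracle", {
  map <- map_fixture()
  ref_len <- ref_fixture()$length
  # simple exact cases
  prof <- coverage_profile(aln_df(rep(500, 10), rep(700, 10)), map, ref_len)
  expect_equal(unname(prof$per_region["Cov_V4"]), 1.0)   # V4 = 575..681
  prof <- coverage_profile(aln_df(c(rep(500, 5), rep(1200, 5)),
                                  c(rep(700, 5), rep(1400, 5))),
                           map, ref_len)
  expect_equal(unname(prof$per_region["Cov_V4"]), 0.5)
  # staggered random alignment sets against the oracle
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    s <- sample(0:1400, n, replace = TRUE)
    e <- pmin(s + sample(30:400, n, replace = TRUE), ref_len - 1L)
    prof <- coverage_profile(aln_df(s, e), map, ref_len)
    expect_equal(unname(prof$per_region),
                 oracle_region_coverage(s, e, map, ref_len),
                 tolerance = 1e-12)
    expect_true(all(prof$per_position >= 0 & prof$per_position <= 1))
  }
})

test_that("region calling combines median positions and coverage", {
  map <- map_fixture()
  ref_len <- ref_fixture()$length
  # V4 amplicon: every read spans 532..785
  aln <- aln_df(rep(532, 9), rep(785, 9))
  st <- position_stats(aln)
  prof <- coverage_profile(aln, map, ref_len)
  calls <- call_regions(st, prof, map, 0.6)
  expect_equal(calls$predicted_start_region, "V4")
  expect_equal(calls$predicted_end_region, "V4")
  expect_equal(calls$covbased_start_region, "V4")
  expect_equal(calls$covbased_end_region, "V4")
  expect_equal(calls$cov_at_start_region, 1.0)
  expect_length(calls$warnings, 0L)
  # multi-region span V3..V4
  aln <- aln_df(rep(357, 5), rep(783, 5))
  calls <- call_regions(position_stats(aln),
                        coverage_profile(aln, map, ref_len), map, 0.6)
  expect_equal(calls$covbased_start_region, "V3")
  expect_equal(calls$covbased_end_region, "V4")
  # nothing reaches the threshold: NA plus warning
  aln <- aln_df(rep(100, 4), rep(120, 4))  # conserved stretch only
  calls <- call_regions(position_stats(aln),
                        coverage_profile(aln, map, ref_len), map, 0.6)
  expect_true(is.na(calls$covbased_start_region))
  expect_true("LOW_COVERAGE" %in% calls$warnings)
  # covbased start index never exceeds end index when both defined
  set.seed(42)
  for (i in 1:20) {
    s <- sample(0:1200, 8, TRUE); e <- pmin(s + sample(50:500, 8, TRUE), 1540)
    calls <- call_regions(position_stats(aln_df(s, e)),
                          coverage_profile(aln_df(s, e), map, ref_len),
                          map, 0.3)
    if (!is.na(calls$covbased_start_region)) {
      expect_lte(match(calls$covbased_start_region, map$name),
                 match(calls$covbased_end_region, map$name))
    }
  }
})

test_that("warning codes mirror the failure taxonomy", {
  # fewer than 500 reads: the sample is failed
  st <- collect_warnings(499)
  expect_equal(st$warnings, "LOW_READS")
  expect_true(st$failed)
  # exactly 500 reads, everything aligned: clean
  st <- collect_warnings(500, n_align_failed = 0)
  expect_length(st$warnings, 0L)
  expect_false(st$failed)
  # mostly unalignable reads
  st <- collect_warnings(1000, n_align_failed = 900)
  expect_equal(st$warnings, "HIGH_ALIGN_FAIL")
  expect_false(st$failed)
  # empty sample
  st <- collect_warnings(0)
  expect_equal(st$warnings, "NO_READS")
  expect_true(st$failed)
})
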