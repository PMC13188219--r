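test_that("feature extraction pools cycles 1-5 and 6-10 across reads", {
  reads <- make_reads(replicate(100, strrep("A", 20)),
                      replicate(100, rep(30L, 20), simplify = FALSE))
  f <- extract_features(reads)
  expect_length(f, 16L)
  expect_named(f, hvr_feature_names())
  expect_equal(unname(f["s1_count"]), 500)  # 5 cycles x 100 reads
  expect_equal(unname(f["s2_count"]), 500)
  for (stat in c("mean", "median", "min", "max", "q25", "q75")) {
    expect_equal(unname(f[paste0("s1_", stat)]), 30)
    expect_equal(unname(f[paste0("s2_", stat)]), 30)
  }
  expect_equal(unname(f["s1_sd"]), 0)
})

test_that("features match a naive reimplementation on mixed qualities", {
  set.seed(51)
  n <- 40
  quals <- lapply(sample(4:30, n, TRUE), function(l) sample(2:41, l, TRUE))
  reads <- make_reads(vapply(lengths(quals), function(l) strrep("A", l),
                             character(1)), quals)
  f <- extract_features(reads)
  seg_a <- unlist(lapply(quals, function(q) q[seq_len(min(5, length(q)))]))
  seg_b <- unlist(lapply(quals, function(q) {
    if (length(q) >= 6) q[6:min(10, length(q))] else integer(0)
  }))
  expect_equal(unname(f[1:8]), unname(oracle_segment_stats(seg_a)))
  expect_equal(unname(f[9:16]), unname(oracle_segment_stats(seg_b)))
  # quantile ordering invariant within each segment
  for (p in c("s1", "s2")) {
    v <- f[paste0(p, "_", c("min", "q25", "median", "q75", "max"))]
    expect_true(all(diff(v) >= 0))
  }
})

test_that("feature extraction ignores reads beyond the first 1000", {
  set.seed(52)
  quals <- replicate(1100, sample(2:41, 12, TRUE), simplify = FALSE)
  reads <- make_reads(replicate(1100, strrep("A", 12)), quals)
  f1 <- extract_features(reads)
  # permute only the tail beyond 1000
  idx <- c(1:1000, sample(1001:1100))
  f2 <- extract_features(hvrscan:::reads_slice(reads, idx))
  expect_identical(f1, f2)
  expect_silent(extract_features(make_reads("ACGT")))
  expect_error(extract_features(hvr_reads("a", "ACGT", NULL)),
               "unavailable")
})

test_that("training is reproducible and separable classes are learned", {
  corpus <- simulate_training_corpus(n_per_class = 25, seed = 9,
                                     n_reads_per_sample = 60)
  m1 <- train_primer_model(corpus[, hvr_feature_names()], corpus$label)
  m2 <- train_primer_model(corpus[, hvr_feature_names()], corpus$label)
  expect_equal(m1$n_trees, 100L)
  expect_equal(m1$forest$ntree, 100L)
  expect_equal(m1$metrics$n_test, 10L)  # 20% of 50
  for (cl in c("primer", "no-primer")) {
    expect_gte(m1$metrics$per_class[[cl]]$precision, 0.9)
    expect_gte(m1$metrics$per_class[[cl]]$recall, 0.9)
  }
  # same seed, same data: identical predictions
  p1 <- predict_primer(m1, as.numeric(corpus[1, hvr_feature_names()]))
  p2 <- predict_primer(m2, as.numeric(corpus[1, hvr_feature_names()]))
  expect_identical(p1, p2)
})

test_that("degenerate training inputs are rejected", {
  corpus <- simulate_training_corpus(n_per_class = 10, seed = 9,
                                     n_reads_per_sample = 30)
  feats <- corpus[, hvr_feature_names()]
  expect_error(train_primer_model(feats, rep("primer", nrow(corpus))),
               "both classes")
  expect_error(train_primer_model(feats[, 1:5], corpus$label), "16 columns")
})

test_that("prediction thresholds govern the presence call", {
  corpus <- simulate_training_corpus(n_per_class = 15, seed = 10,
                                     n_reads_per_sample = 40)
  model <- train_primer_model(corpus[, hvr_feature_names()], corpus$label)
  f_primer <- as.numeric(corpus[corpus$label == "primer", ][1,
                         hvr_feature_names()])
  p <- predict_primer(model, f_primer)
  expect_true(p$score >= 0 && p$score <= 1)
  # thresholds straddling the score flip the call; score itself is unchanged
  just_below <- max(p$score - 1e-9, 0)
  expect_true(predict_primer(model, f_primer, just_below)$presence)
  if (p$score < 1) {
    expect_false(predict_primer(model, f_primer, 1.0)$presence)
  }
  expect_error(predict_primer(model, f_primer[1:5]), "length 16")
})

test_that("models persist with their feature manifest", {
  corpus <- simulate_training_corpus(n_per_class = 10, seed = 11,
                                     n_reads_per_sample = 30)
  model <- train_primer_model(corpus[, hvr_feature_names()], corpus$label)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_primer_model(model, tf)
  back <- load_primer_model(tf)
  expect_identical(back$feature_names, hvr_feature_names())
  f <- as.numeric(corpus[1, hvr_feature_names()])
  expect_identical(predict_primer(back, f), predict_primer(model, f))
})
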