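test_that("primer catalog is consistent with the bundled reference", {
  cat_ <- load_primer_catalog()
  ref <- ref_fixture()
  map <- map_fixture()
  expect_gte(nrow(cat_), 6L)
  expect_true(all(c("515F-806R", "27F-338R", "341F-805R") %in% cat_$name))
  for (i in seq_len(nrow(cat_))) {
    # frozen windows equal the windows recomputed by primer matching
    w <- primer_window(cat_$fwd_primer[i], cat_$rev_primer[i], ref)
    expect_equal(unname(w), c(cat_$window_start[i], cat_$window_end[i]),
                 info = cat_$name[i])
    # and the recorded truth regions follow from the boundary map
    expect_equal(position_to_start_region(cat_$window_start[i], map),
                 cat_$start_region[i], info = cat_$name[i])
    expect_equal(position_to_end_region(cat_$window_end[i], map),
                 cat_$end_region[i], info = cat_$name[i])
  }
  # the archived V4 standard: trimmed amplicon starts at 532
  v4 <- cat_[cat_$name == "515F-806R", ]
  expect_equal(v4$window_start, 532L)
  expect_equal(v4$start_region, "V4")
})

test_that("simulation is deterministic and respects its config", {
  ref <- ref_fixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(primer_pair = "515F-806R", n_reads = 250, seed = 5)
  o1 <- simulate_sample(cfg, ref, dir = d1)
  o2 <- simulate_sample(cfg, ref, dir = d2)
  expect_identical(readLines(o1$files), readLines(o2$files))  # byte-identical
  reads <- quiet_read_fastq(o1$files)
  expect_equal(length(reads), 250L)
  expect_equal(o1$truth$true_start_region, "V4")
  # error-free simulation yields exact window substrings
  cfg0 <- sim_config(primer_pair = "515F-806R", n_reads = 20,
                     substitution_rate = 0, seed = 5)
  o0 <- simulate_sample(cfg0, ref, dir = d1)
  reads0 <- quiet_read_fastq(o0$files)
  window_seq <- substr(ref$sequence, 533, 786)  # 0-based 532..785
  expect_true(all(reads0$seq == window_seq))
})

test_that("paired simulation writes mates that merge back to the fragment", {
  ref <- ref_fixture()
  d <- withr::local_tempdir()
  cfg <- sim_config(primer_pair = "515F-806R", n_reads = 15,
                    layout = "paired", read_len = 150,
                    substitution_rate = 0, seed = 6)
  out <- simulate_sample(cfg, ref, dir = d)
  expect_length(out$files, 2L)
  pair <- suppressWarnings(read_sample(
    sample_input("s", out$files, "paired", "fastq")))
  expect_equal(nchar(pair$fwd$seq[1]), 150L)
  m <- merge_pair(list(seq = pair$fwd$seq[1], qual = pair$fwd$qual[[1]]),
                  list(seq = pair$rev$seq[1], qual = pair$rev$qual[[1]]))
  expect_equal(m$seq, substr(ref$sequence, 533, 786))
  # window shorter than the mate length is an error
  expect_error(simulate_sample(
    sim_config(window = c(100, 180), layout = "paired", read_len = 150,
               n_reads = 5), ref, dir = d), "read_len")
})

test_that("retained primers leave sequence and quality signatures", {
  ref <- ref_fixture()
  d <- withr::local_tempdir()
  cfg <- sim_config(primer_pair = "515F-806R", n_reads = 50,
                    with_primer = TRUE, substitution_rate = 0, seed = 8)
  out <- simulate_sample(cfg, ref, dir = d)
  reads <- quiet_read_fastq(out$files)
  # reads start with the (degeneracy-resolved) forward primer
  expect_true(all(startsWith(reads$seq, "GTG")))
  expect_equal(nchar(reads$seq[1]), 19 + 254)
  # first ten cycles: elevated mean, depressed spread
  early <- unlist(lapply(reads$qual, `[`, 1:10))
  late <- unlist(lapply(reads$qual, `[`, 30:60))
  expect_gt(mean(early), mean(late))
  expect_lt(sd(early), sd(late))
  expect_true(out$truth$with_primer)
})

test_that("training corpus generation is deterministic and labeled", {
  c1 <- simulate_training_corpus(n_per_class = 12, seed = 14,
                                 n_reads_per_sample = 40)
  c2 <- simulate_training_corpus(n_per_class = 12, seed = 14,
                                 n_reads_per_sample = 40)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 24L)
  expect_equal(sum(c1$label == "primer"), 12L)
  expect_equal(ncol(c1), 18L)  # id + 16 features + label
  expect_identical(names(c1)[2:17], hvr_feature_names())
})
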