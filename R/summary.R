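# ---- position statistics ----------------------------------------------------

#' Alignment position statistics for one sample
#'
#' Medians (middle value, or average of the two middle values for even n)
#' are the authoritative basis for region calls; means are reported because
#' low-quality reads skew them, which is informative to see but never drives
#' a call. Min/max columns report the observed minimum start and maximum end
#' across the sample's alignments (the theoretical bounds 0 and
#' reference-length minus 1 carry no per-sample information).
#'
#' @param alignments Alignment data.frame from [align_sample()].
#' @return Named list: `min_start`, `max_end`, `mean_start`, `mean_end`,
#'   `median_start`, `median_end`.
#' @export
position_stats <- function(alignments) {
  if (is.null(alignments) || nrow(alignments) == 0L) {
    stop("no alignments (sample failure)")
  }
  list(
    min_start = min(alignments$ref_start),
    max_end = max(alignments$ref_end),
    mean_start = mean(alignments$ref_start),
    mean_end = mean(alignments$ref_end),
    median_start = stats::median(alignments$ref_start),
    median_end = stats::median(alignments$ref_end)
  )
}

# ---- coverage ---------------------------------------------------------------

#' Per-position and per-region coverage profile
#'
#' Coverage at a position is the fraction of aligned reads whose span
#' `[ref_start, ref_end]` includes it (0 = no read covers it, 1 = all do);
#' region coverage is the mean of the per-position values over the region.
#'
#' @param alignments Alignment data.frame from [align_sample()].
#' @param region_map A `RegionMap`.
#' @param ref_length Reference length in bases (positions `0..ref_length-1`).
#' @return List with `per_position` (numeric vector indexed by position+1)
#'   and `per_region` (named numeric, `Cov_V1`..`Cov_V9`).
#' @export
coverage_profile <- function(alignments, region_map, ref_length) {
  if (is.null(alignments) || nrow(alignments) == 0L) {
    stop("no alignments (sample failure)")
  }
  n <- nrow(alignments)
  d <- numeric(ref_length + 1L)
  s <- alignments$ref_start + 1L
  e <- alignments$ref_end + 2L
  for (i in seq_len(n)) {
    d[s[i]] <- d[s[i]] + 1
    if (e[i] <= ref_length) d[e[i]] <- d[e[i]] - 1
  }
  per_position <- cumsum(d[seq_len(ref_length)]) / n
  per_region <- vapply(seq_len(nrow(region_map)), function(k) {
    mean(per_position[(region_map$start[k] + 1L):(region_map$end[k] + 1L)])
  }, numeric(1))
  names(per_region) <- paste0("Cov_", region_map$name)
  list(per_position = per_position, per_region = per_region)
}

# ---- region calls -----------------------------------------------------------

#' Call hypervariable regions from position statistics and coverage
#'
#' Predicted regions come from the median start/end positions through the
#' boundary map; coverage-based regions are the lowest- and highest-index
#' regions whose per-region coverage reaches the threshold (NA plus a
#' low-coverage warning when none does).
#'
#' @param stats Output of [position_stats()].
#' @param profile Output of [coverage_profile()].
#' @param region_map A `RegionMap`.
#' @param threshold Coverage threshold in (0, 1], default 0.6.
#' @return Named list: `predicted_start_region`, `predicted_end_region`,
#'   `covbased_start_region`, `covbased_end_region`, `cov_at_start_region`,
#'   `cov_at_end_region`, `warnings` (character vector).
#' @export
call_regions <- function(stats, profile, region_map, threshold = 0.6) {
  stopifnot(threshold > 0, threshold <= 1)
  warnings <- character(0)
  pred_start <- position_to_start_region(stats$median_start, region_map)
  pred_end <- position_to_end_region(stats$median_end, region_map)
  if (pred_start == "beyond-V9") warnings <- c(warnings, "BEYOND_V9")
  if (pred_end == "before-V1") warnings <- c(warnings, "BEFORE_V1")
  hit <- which(profile$per_region >= threshold)
  if (length(hit) == 0L) {
    warnings <- c(warnings, "LOW_COVERAGE")
    cov_start <- cov_end <- NA_character_
    cov_at_start <- cov_at_end <- NA_real_
  } else {
    cov_start <- region_map$name[hit[1]]
    cov_end <- region_map$name[hit[length(hit)]]
    cov_at_start <- unname(profile$per_region[hit[1]])
    cov_at_end <- unname(profile$per_region[hit[length(hit)]])
  }
  list(predicted_start_region = pred_start,
       predicted_end_region = pred_end,
       covbased_start_region = cov_start,
       covbased_end_region = cov_end,
       cov_at_start_region = cov_at_start,
       cov_at_end_region = cov_at_end,
       warnings = warnings)
}

# ---- warnings ---------------------------------------------------------------

#' Warning codes for a sample's processing state
#'
#' Mirrors the failure taxonomy of large-scale archive processing:
#' `LOW_READS` (fewer than `low_reads_min` reads retrieved; the sample is
#' failed and gets no region calls), `HIGH_ALIGN_FAIL` (more than
#' `align_fail_frac` of processed reads failed to merge or align), plus the
#' codes produced elsewhere (`LOW_COVERAGE`, `MISSING_FASTQ`, `NO_READS`,
#' `BEYOND_V9`, `BEFORE_V1`).
#'
#' @param n_reads_in Reads retrieved for the sample.
#' @param n_align_failed Reads lost to merge failure or alignment failure.
#' @param n_processed Reads that entered merging/alignment.
#' @param low_reads_min Failure boundary for read count (default 500).
#' @param align_fail_frac Failure fraction for `HIGH_ALIGN_FAIL`
#'   (default 0.5).
#' @return List with `warnings` (character vector) and `failed` (logical:
#'   sample gets no region calls).
#' @export
collect_warnings <- function(n_reads_in, n_align_failed = 0L,
                             n_processed = n_reads_in,
                             low_reads_min = 500L, align_fail_frac = 0.5) {
  warnings <- character(0)
  failed <- FALSE
  if (n_reads_in == 0L) {
    warnings <- c(warnings, "NO_READS")
    failed <- TRUE
  } else if (n_reads_in < low_reads_min) {
    warnings <- c(warnings, "LOW_READS")
    failed <- TRUE
  }
  if (n_processed > 0L && n_align_failed / n_processed > align_fail_frac) {
    warnings <- c(warnings, "HIGH_ALIGN_FAIL")
  }
  list(warnings = warnings, failed = failed)
}

# ---- full sample summary ----------------------------------------------------

#' Summarize a sample's alignments into the per-sample record
#'
#' @param alignments Alignment data.frame from [align_sample()].
#' @param region_map A `RegionMap`.
#' @param ref_length Reference length.
#' @param threshold Coverage threshold (default 0.6).
#' @return List combining [position_stats()], [coverage_profile()] and
#'   [call_regions()] output.
#' @export
summarize_alignments <- function(alignments, region_map, ref_length,
                                 threshold = 0.6) {
  st <- position_stats(alignments)
  prof <- coverage_profile(alignments, region_map, ref_length)
  calls <- call_regions(st, prof, region_map, threshold)
  c(st, list(coverage = prof), calls["warnings" != names(calls)],
    list(region_warnings = calls$warnings))
}
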