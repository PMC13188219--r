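# ---- run configuration ------------------------------------------------------

#' End-to-end run configuration
#'
#' @param coverage_threshold Region coverage threshold `t` (default 0.6).
#' @param n_reads Head-subsample size per sample (default 1000).
#' @param primer_threshold Primer-presence probability threshold
#'   (default 0.5).
#' @param low_reads_min Minimum reads for a sample to be processed
#'   (default 500).
#' @param trim A [trim_config()].
#' @param merge A [merge_config()].
#' @param sc A [scoring()].
#' @param seed Seed used where randomness exists (default-model training).
#' @return An `hvr_run_config` list.
#' @export
run_config <- function(coverage_threshold = 0.6, n_reads = 1000L,
                       primer_threshold = 0.5, low_reads_min = 500L,
                       trim = trim_config(), merge = merge_config(),
                       sc = scoring(), seed = 42L) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1,
            primer_threshold >= 0, primer_threshold <= 1)
  structure(list(coverage_threshold = coverage_threshold,
                 n_reads = as.integer(n_reads),
                 primer_threshold = primer_threshold,
                 low_reads_min = as.integer(low_reads_min),
                 trim = trim, merge = merge, sc = sc,
                 seed = as.integer(seed)),
            class = "hvr_run_config")
}

# ---- sample discovery -------------------------------------------------------

#' Discover samples from FASTQ/FASTA paths or a directory
#'
#' Files named `*_1.fastq`/`*_2.fastq` (or `_R1`/`_R2`, optionally `.gz`)
#' are paired by stem; everything else is a single-end sample. Truth
#' manifests (`*_truth.tsv`) are ignored.
#'
#' @param paths Files and/or directories.
#' @return List of [sample_input()] objects.
#' @export
discover_samples <- function(paths) {
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.(fastq|fq|fasta|fa)(\\.gz)?$",
                 full.names = TRUE)
    } else p
  }))
  files <- files[file.exists(files)]
  if (length(files) == 0L) stop("no input files found")
  files <- sort(unique(files))
  stem <- sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "", basename(files))
  fmt <- ifelse(grepl("\\.(fasta|fa)(\\.gz)?$", files), "fasta", "fastq")
  mate <- ifelse(grepl("(_R?1)$", stem), 1L,
                 ifelse(grepl("(_R?2)$", stem), 2L, 0L))
  base <- sub("(_R?[12])$", "", stem)
  inputs <- list()
  for (b in unique(base)) {
    idx <- which(base == b)
    m <- mate[idx]
    if (setequal(m, c(1L, 2L)) && length(idx) == 2L &&
        all(fmt[idx] == "fastq")) {
      inputs[[b]] <- sample_input(b, files[idx][order(m)], "paired", "fastq")
    } else {
      for (i in idx) {
        inputs[[stem[i]]] <- sample_input(stem[i], files[i], "single",
                                          fmt[i])
      }
    }
  }
  unname(inputs)
}

# ---- per-sample processing --------------------------------------------------

#' Process one sample into a report row
#'
#' Ingest, head-subsample, primer-predict on the raw reads, quality-trim,
#' merge mates (paired layout), align, and summarize. Failures (missing
#' files, no/low reads, no surviving alignments) produce a row with
#' warnings and NA fields rather than an error.
#'
#' @param input A [sample_input()].
#' @param reference A `ReferenceGene`.
#' @param region_map A `RegionMap`.
#' @param config An [run_config()].
#' @param primer_model An `hvr_primer_model`, or `NULL` to use
#'   [default_primer_model()], or `NA` to skip primer prediction.
#' @return A one-row tibble with the [hvr_report_columns()] schema.
#' @export
process_sample <- function(input, reference = load_reference(),
                           region_map = load_region_map(),
                           config = run_config(), primer_model = NULL) {
  sid <- input$sample_id
  if (any(!file.exists(input$files))) {
    return(empty_report_row(sid, "MISSING_FASTQ"))
  }
  sample_reads <- tryCatch(read_sample(input, n_max = config$n_reads),
                           error = function(e) e)
  if (inherits(sample_reads, "error")) {
    code <- if (grepl("missing FASTQ", conditionMessage(sample_reads)))
      "MISSING_FASTQ" else "READ_ERROR"
    return(empty_report_row(sid, code))
  }

  raw <- if (inherits(sample_reads, "hvr_reads")) sample_reads
         else sample_reads$fwd
  row <- empty_report_row(sid)

  # primer prediction works on the raw (untrimmed) head of the file
  primer <- list(presence = NA, score = NA_real_)
  if (!isTRUE(is.na(primer_model)) && !is.null(raw$qual) &&
      length(raw) > 0L) {
    model <- primer_model %||% default_primer_model(reference,
                                                    seed = config$seed)
    feats <- extract_features(raw, n_max = config$n_reads)
    primer <- predict_primer(model, feats, config$primer_threshold)
  }
  row$primer_presence <- primer$presence
  row$score_primer_presence <- primer$score

  prep <- preprocess_sample(sample_reads, n_reads = config$n_reads,
                            trim = config$trim, merge = config$merge)
  n_lost <- prep$n_trim_discarded + prep$n_merge_failed
  state <- collect_warnings(prep$n_in, n_align_failed = n_lost,
                            n_processed = prep$n_in,
                            low_reads_min = config$low_reads_min)
  warnings <- state$warnings
  if (state$failed || length(prep$reads) == 0L) {
    if (!state$failed) warnings <- c(warnings, "HIGH_ALIGN_FAIL")
    row$warnings <- paste(warnings, collapse = ";")
    return(row)
  }

  aln <- align_sample(prep$reads, reference, config$sc)
  n_failed_total <- n_lost + unname(aln$counts["failed"])
  state <- collect_warnings(prep$n_in, n_align_failed = n_failed_total,
                            n_processed = prep$n_in,
                            low_reads_min = config$low_reads_min)
  warnings <- state$warnings
  if (aln$counts["aligned"] == 0L) {
    row$warnings <- paste(unique(c(warnings, "NO_ALIGNED_READS")),
                          collapse = ";")
    return(row)
  }

  st <- position_stats(aln$alignments)
  prof <- coverage_profile(aln$alignments, region_map, reference$length)
  calls <- call_regions(st, prof, region_map, config$coverage_threshold)
  warnings <- c(warnings, calls$warnings)

  row$min_alignment_start <- st$min_start
  row$max_alignment_end <- st$max_end
  row$average_alignment_start <- st$mean_start
  row$average_alignment_end <- st$mean_end
  row$median_alignment_start <- st$median_start
  row$median_alignment_end <- st$median_end
  row$predicted_hv_region_start <- calls$predicted_start_region
  row$predicted_hv_region_end <- calls$predicted_end_region
  row$coverage_based_hv_region_start <- calls$covbased_start_region
  row$coverage_based_hv_region_end <- calls$covbased_end_region
  row$coverage_hv_region_start <- calls$cov_at_start_region
  row$coverage_hv_region_end <- calls$cov_at_end_region
  for (k in 1:9) row[[paste0("cov_v", k)]] <- unname(prof$per_region[k])
  row$warnings <- paste(warnings, collapse = ";")
  row
}

# ---- batch run --------------------------------------------------------------

#' Run the full pipeline over a batch of samples
#'
#' Samples are processed independently: one sample's failure never affects
#' another's row.
#'
#' @param inputs Paths (files/directories) or a list of [sample_input()]
#'   objects.
#' @param output Optional report TSV path; written with [write_report()]
#'   when given.
#' @param reference A `ReferenceGene`.
#' @param region_map A `RegionMap`.
#' @param config An [run_config()].
#' @param primer_model See [process_sample()].
#' @param quiet Suppress per-sample progress messages.
#' @return Tibble of report rows (one per sample).
#' @export
hvr_run <- function(inputs, output = NULL, reference = load_reference(),
                    region_map = load_region_map(), config = run_config(),
                    primer_model = NULL, quiet = TRUE) {
  if (is.character(inputs)) inputs <- discover_samples(inputs)
  stopifnot(length(inputs) > 0L)
  if (is.null(primer_model) && !isTRUE(is.na(primer_model))) {
    # train/cache once up front so rows are independent of each other
    primer_model <- default_primer_model(reference, seed = config$seed)
  }
  rows <- lapply(inputs, function(inp) {
    if (!quiet) message("processing ", inp$sample_id)
    tryCatch(
      process_sample(inp, reference, region_map, config, primer_model),
      error = function(e) empty_report_row(inp$sample_id, "READ_ERROR")
    )
  })
  report <- do.call(rbind, rows)
  if (!is.null(output)) write_report(report, output)
  report
}

#' Machine-readable effective configuration
#'
#' @param config An [run_config()].
#' @return Named list of every effective parameter (for logging a
#'   reproducibility record of a run).
#' @export
effective_config <- function(config = run_config()) {
  list(coverage_threshold = config$coverage_threshold,
       n_reads = config$n_reads,
       primer_threshold = config$primer_threshold,
       low_reads_min = config$low_reads_min,
       trim_window = config$trim$window,
       trim_mean_q_threshold = config$trim$mean_q_threshold,
       trim_min_len = config$trim$min_len_after_trim,
       merge_min_overlap = config$merge$min_overlap,
       merge_max_mismatch_frac = config$merge$max_mismatch_frac,
       align_match = config$sc$match,
       align_mismatch = config$sc$mismatch,
       align_gap_open = config$sc$gap_open,
       align_gap_extend = config$sc$gap_extend,
       align_min_identity = config$sc$min_identity,
       align_min_aligned_len = config$sc$min_aligned_len,
       seed = config$seed)
}
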