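#' @useDynLib hvrscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- read container ---------------------------------------------------------

#' Construct a read set
#'
#' Internal container flowing through trim/merge/align: parallel vectors of
#' ids and sequences plus a list of per-base integer Phred scores (`NULL` for
#' FASTA input, which has no qualities).
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of base strings (may contain N).
#' @param qual List of integer vectors (Phred scores, 0-93), or `NULL`.
#' @return An `hvr_reads` object.
#' @export
hvr_reads <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq))
    nq <- lengths(qual)
    if (any(nq != nchar(seq))) {
      stop("quality and sequence lengths differ for ",
           sum(nq != nchar(seq)), " read(s)")
    }
    rng <- suppressWarnings(range(unlist(qual, use.names = FALSE)))
    if (length(nq) && any(nq > 0) && (rng[1] < 0 || rng[2] > 93)) {
      stop("Phred scores must lie in [0, 93]")
    }
  }
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = qual),
            class = "hvr_reads")
}

#' @export
length.hvr_reads <- function(x) length(x$seq)

#' @export
print.hvr_reads <- function(x, ...) {
  cat("<hvr_reads> ", length(x), " read(s)",
      if (is.null(x$qual)) " (no qualities)" else "", "\n", sep = "")
  invisible(x)
}

# subset a read set
reads_slice <- function(x, i) {
  hvr_reads(x$id[i], x$seq[i], if (!is.null(x$qual)) x$qual[i])
}

# ---- FASTQ / FASTA ----------------------------------------------------------

#' Read a FASTQ file (plain or gzip) into a read set
#'
#' Assumes Phred+33 (Sanger) encoding, the encoding of all modern archived
#' data; apparent Phred+64 quality strings are rejected with an explicit
#' error rather than silently mis-decoded.
#'
#' @param path FASTQ path, optionally `.gz`.
#' @param n_max Read at most this many records (`Inf` for all).
#' @return An [hvr_reads()] object.
#' @export
read_fastq <- function(path, n_max = Inf) {
  if (!file.exists(path)) stop("missing FASTQ: ", path)
  nrec <- if (is.finite(n_max)) as.integer(n_max) else -1L
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, nrec = nrec),
    warning = function(w) {
      # metadata columns are intentionally dropped from the container
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  qual <- as.list(methods::as(Biostrings::quality(x), "IntegerList"))
  q <- unlist(qual, use.names = FALSE)
  if (length(q) && min(q) >= 31L && max(q) > 45L) {
    stop("quality strings look Phred+64-encoded; only Phred+33 is supported: ",
         path)
  }
  hvr_reads(names(x), as.character(x), qual)
}

#' Read a FASTA file (plain or gzip) into a read set (no qualities)
#'
#' @inheritParams read_fastq
#' @return An [hvr_reads()] object with `qual = NULL`.
#' @export
read_fasta <- function(path, n_max = Inf) {
  if (!file.exists(path)) stop("missing FASTA: ", path)
  nrec <- if (is.finite(n_max)) as.integer(n_max) else -1L
  x <- Biostrings::readDNAStringSet(path, nrec = nrec)
  hvr_reads(names(x), as.character(x), NULL)
}

#' Write a read set to FASTQ
#'
#' @param reads An [hvr_reads()] object with qualities.
#' @param path Output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(reads$qual)) stop("cannot write FASTQ without qualities")
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qstr <- vapply(reads$qual,
                 function(q) rawToChar(as.raw(as.integer(q) + 33L)),
                 character(1))
  quals <- Biostrings::PhredQuality(qstr)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# ---- sample descriptors -----------------------------------------------------

#' Describe one input sample
#'
#' @param sample_id Sample identifier (run accession or file stem).
#' @param files One path (single-end / FASTA) or two paths (paired mates).
#' @param layout `"single"` or `"paired"`.
#' @param format `"fastq"` or `"fasta"`.
#' @return A `sample_input` object.
#' @export
sample_input <- function(sample_id, files,
                         layout = c("single", "paired"),
                         format = c("fastq", "fasta")) {
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (layout == "paired" && length(files) != 2L) {
    stop("paired layout requires exactly 2 files")
  }
  if (layout == "single" && length(files) != 1L) {
    stop("single layout requires exactly 1 file")
  }
  if (format == "fasta" && layout != "single") {
    stop("FASTA input must be single-layout")
  }
  structure(list(sample_id = sample_id, files = files, layout = layout,
                 format = format),
            class = "hvr_sample_input")
}

#' Read the reads of a sample
#'
#' @param input A [sample_input()].
#' @param n_max Maximum records to read per file.
#' @return For single layout, one [hvr_reads()]; for paired layout a list
#'   `list(fwd = , rev = )` with mates matched by record order. A mate-count
#'   mismatch is an error.
#' @export
read_sample <- function(input, n_max = Inf) {
  stopifnot(inherits(input, "hvr_sample_input"))
  missing <- !file.exists(input$files)
  if (any(missing)) {
    stop("missing FASTQ: ", paste(input$files[missing], collapse = ", "))
  }
  reader <- if (input$format == "fastq") read_fastq else read_fasta
  if (input$layout == "single") return(reader(input$files[1], n_max))
  fwd <- reader(input$files[1], n_max)
  rev <- reader(input$files[2], n_max)
  if (length(fwd) != length(rev)) {
    stop("mate-count mismatch: ", length(fwd), " vs ", length(rev),
         " records")
  }
  list(fwd = fwd, rev = rev)
}

#' Parse a run-accession list file
#'
#' One accession per line; blank lines and `#` comments are ignored;
#' duplicates are dropped keeping first occurrence.
#'
#' @param path Text file path.
#' @return Character vector of accessions (at least one, else an error).
#' @export
parse_accession_list <- function(path) {
  if (!file.exists(path)) stop("accession list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- unique(lines[nzchar(lines)])
  if (length(ids) == 0L) stop("accession list contains no accessions: ", path)
  ids
}

# ---- report -----------------------------------------------------------------

#' Report column schema
#'
#' Column names and order of the per-sample TSV report, frozen: sample id,
#' primer call and score, observed min start / max end, mean and median
#' alignment start/end, region calls from the median positions, region calls
#' and coverages from the coverage profile, warnings, and per-region
#' coverages Cov_V1..Cov_V9.
#'
#' @return Character vector of 25 column names.
#' @export
hvr_report_columns <- function() {
  c("sample_id", "primer_presence", "score_primer_presence",
    "min_alignment_start", "max_alignment_end",
    "average_alignment_start", "average_alignment_end",
    "median_alignment_start", "median_alignment_end",
    "predicted_hv_region_start", "predicted_hv_region_end",
    "coverage_based_hv_region_start", "coverage_based_hv_region_end",
    "coverage_hv_region_start", "coverage_hv_region_end",
    "warnings", paste0("cov_v", 1:9))
}

# an all-NA report row for failed samples
empty_report_row <- function(sample_id, warnings = character()) {
  row <- tibble::as_tibble(
    stats::setNames(as.list(rep(NA, length(hvr_report_columns()))),
                    hvr_report_columns())
  )
  row$sample_id <- sample_id
  row$warnings <- paste(warnings, collapse = ";")
  row
}

#' Write the per-sample report TSV
#'
#' Deterministic, tab-separated, UTF-8/LF. Floats are printed with fixed
#' 4-decimal formatting, integers as integers, logicals as TRUE/FALSE,
#' missing values as NA, and warnings as a semicolon-joined code list.
#'
#' @param rows A data.frame/tibble whose columns are [hvr_report_columns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  cols <- hvr_report_columns()
  if (!identical(names(rows), cols)) {
    stop("report rows must have exactly the frozen column schema; see ",
         "hvr_report_columns()")
  }
  fmt1 <- function(v, col) {
    if (col %in% c("min_alignment_start", "max_alignment_end")) {
      ifelse(is.na(v), "NA", format(as.integer(v), scientific = FALSE))
    } else if (is.logical(v)) {
      ifelse(is.na(v), "NA", ifelse(v, "TRUE", "FALSE"))
    } else if (is.numeric(v)) {
      ifelse(is.na(v), "NA", sprintf("%.4f", v))
    } else {
      v <- as.character(v)
      ifelse(is.na(v), "NA", v)
    }
  }
  out <- if (nrow(rows) == 0L) {
    matrix(character(), ncol = length(cols))
  } else {
    m <- vapply(cols, function(cl) fmt1(rows[[cl]], cl),
                character(nrow(rows)))
    if (nrow(rows) == 1L) matrix(m, nrow = 1L) else m
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(rows) > 0L) {
    writeLines(apply(out, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a report TSV back into a tibble
#'
#' @param path Report path written by [write_report()].
#' @return Tibble with the frozen schema.
#' @export
read_report <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", check.names = FALSE)
  tibble::as_tibble(tab)
}
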