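#' Alignment scoring configuration
#'
#' Scores for the semi-global aligner and the acceptance thresholds that
#' define the alignment-error failure class. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match Match score (> 0), default +2.
#' @param mismatch Mismatch score (< 0), default -3.
#' @param gap_open Gap-opening penalty (<= 0), default -5.
#' @param gap_extend Per-base gap-extension penalty (<= 0), default -2.
#' @param min_identity Minimum identity (matching columns / aligned
#'   non-gap columns) for a read to count as aligned, default 0.70.
#' @param min_aligned_len Minimum number of aligned columns, default 50.
#' @param min_score Minimum alignment score for a read to count as aligned,
#'   default 0: a placement that scores no better than aligning nothing is
#'   an alignment failure (gap-riddled chance placements of non-16S
#'   sequences can reach 70% identity over their few aligned columns while
#'   scoring far below zero). Set to `-Inf` to report every optimum.
#' @return A `scoring` list.
#' @export
scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                    gap_extend = -2L, min_identity = 0.70,
                    min_aligned_len = 50L, min_score = 0) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_identity >= 0, min_identity <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity,
                 min_aligned_len = as.integer(min_aligned_len),
                 min_score = min_score),
            class = "hvr_scoring")
}

#' Semi-globally align one query to the reference
#'
#' Aligns the query end-to-end while gaps on the reference before the first
#' and after the last query base are free, locating the amplicon read within
#' the 16S gene. Both the query and its reverse complement are aligned and
#' the higher-scoring orientation is kept (ties keep forward). The result is
#' an alignment failure (`NULL`) if identity falls below
#' `scoring$min_identity` or fewer than `scoring$min_aligned_len` columns
#' align.
#'
#' @param query DNA string.
#' @param reference A `ReferenceGene` from [load_reference()] (or a plain
#'   DNA string).
#' @param sc A [scoring()] configuration.
#' @param banded Use the k-mer-seeded banded accelerator (default TRUE);
#'   reads that do not seed, or whose banded alignment falls under the
#'   identity bar, fall back to the full dynamic program automatically.
#'   `FALSE` forces the full DP everywhere.
#' @return A one-row data.frame with `ref_start`, `ref_end` (0-based
#'   inclusive), `orientation`, `score`, `identity`, `aligned_len`, or
#'   `NULL` on alignment failure.
#' @export
semi_global_align <- function(query, reference, sc = scoring(),
                              banded = TRUE) {
  res <- align_sample(hvr_reads("q", query, NULL), reference, sc, banded)
  if (res$counts["aligned"] == 0L) return(NULL)
  res$alignments[1, , drop = FALSE]
}

#' Align a sample's processed reads to the reference
#'
#' @param reads An [hvr_reads()] object (zero reads is a sample failure).
#' @param reference A `ReferenceGene` or DNA string.
#' @param sc A [scoring()] configuration.
#' @param banded See [semi_global_align()].
#' @return List with `alignments` (data.frame of passing reads: `read_id`,
#'   `ref_start`, `ref_end`, `orientation`, `score`, `identity`,
#'   `aligned_len`) and `counts` (named vector `aligned`, `failed`).
#' @export
align_sample <- function(reads, reference, sc = scoring(), banded = TRUE) {
  stopifnot(inherits(reads, "hvr_reads"))
  if (length(reads) == 0L) stop("no reads to align (sample failure)")
  refseq <- if (inherits(reference, "hvr_reference")) reference$sequence
            else toupper(as.character(reference))
  raw <- .cpp_align_batch(reads$seq, refseq, sc$match, sc$mismatch,
                          sc$gap_open, sc$gap_extend, TRUE,
                          isTRUE(banded), sc$min_identity)
  identity <- raw$matches / raw$aligned_len
  min_score <- if (is.null(sc$min_score)) 0 else sc$min_score
  pass <- !is.na(raw$score) & raw$score > min_score &
    identity >= sc$min_identity &
    raw$aligned_len >= sc$min_aligned_len
  pass[is.na(pass)] <- FALSE
  aln <- data.frame(
    read_id = reads$id[pass],
    ref_start = raw$ref_start[pass],
    ref_end = raw$ref_end[pass],
    orientation = raw$orientation[pass],
    score = raw$score[pass],
    identity = identity[pass],
    aligned_len = raw$aligned_len[pass],
    stringsAsFactors = FALSE
  )
  list(alignments = aln,
       counts = c(aligned = sum(pass), failed = sum(!pass)))
}
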