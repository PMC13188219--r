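# ---- configs ----------------------------------------------------------------

#' Quality-trimming configuration
#'
#' 3'-end sliding-window trimming in the spirit of common read QC tools:
#' window mean quality below the threshold trims the tail base by base.
#'
#' @param window Window width in bases (default 4).
#' @param mean_q_threshold Phred threshold for the window mean (default 15).
#' @param min_len_after_trim Reads shorter than this after trimming are
#'   discarded (default 50).
#' @return A `trim_config` list.
#' @export
trim_config <- function(window = 4L, mean_q_threshold = 15,
                        min_len_after_trim = 50L) {
  stopifnot(window >= 1L, mean_q_threshold >= 0, mean_q_threshold <= 93)
  structure(list(window = as.integer(window),
                 mean_q_threshold = mean_q_threshold,
                 min_len_after_trim = as.integer(min_len_after_trim)),
            class = "trim_config")
}

#' Pair-merging configuration
#'
#' @param min_overlap Minimum ungapped overlap between mates (default 10).
#' @param max_mismatch_frac Maximum fraction of mismatching positions in the
#'   accepted overlap (default 0.25).
#' @param require_merge If `TRUE`, unmergeable pairs are a failure counted
#'   toward alignment-failure statistics (they always are; the flag is kept
#'   for interface stability).
#' @return A `merge_config` list.
#' @export
merge_config <- function(min_overlap = 10L, max_mismatch_frac = 0.25,
                         require_merge = TRUE) {
  stopifnot(min_overlap >= 1L, max_mismatch_frac >= 0, max_mismatch_frac <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 require_merge = isTRUE(require_merge)),
            class = "merge_config")
}

# ---- subsample --------------------------------------------------------------

#' Subsample a read set
#'
#' Takes the first `n` reads in stream order (the semantics of retrieving the
#' head of an archived run); `seed` is accepted for a future random mode and
#' unused in head mode.
#'
#' @param reads An [hvr_reads()] object.
#' @param n Number of reads to keep (default 1000).
#' @param seed Unused in head mode.
#' @return The first `min(n, length(reads))` reads.
#' @export
subsample_reads <- function(reads, n = 1000L, seed = NULL) {
  stopifnot(n >= 1L)
  if (length(reads) <= n) return(reads)
  reads_slice(reads, seq_len(n))
}

# ---- quality trimming -------------------------------------------------------

# trimmed length under the 3' sliding-window rule; q integer vector
trim_length <- function(q, window, thr) {
  n <- length(q)
  if (n == 0L) return(0L)
  cs <- cumsum(as.numeric(q))
  lo <- pmax(seq_len(n) - window, 0L)
  wmean <- (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
  # a length L survives only if every longer length failed and L itself is ok;
  # "ok" = window mean >= threshold AND the terminal base itself >= threshold,
  # so a kept read never ends in a sub-threshold base
  fail <- (wmean < thr) | (q < thr)
  n - (match(FALSE, rev(fail), nomatch = n + 1L) - 1L)
}

#' Quality-trim the 3' ends of reads
#'
#' Slides a window over the 3' end and trims while the window mean quality is
#' below the threshold (or the terminal base itself is below it). Reads whose
#' trimmed length falls under `min_len_after_trim` are discarded; discarding
#' is a counted, normal outcome.
#'
#' @param reads An [hvr_reads()] object with qualities; FASTA read sets
#'   (no qualities) are returned unchanged.
#' @param cfg A [trim_config()].
#' @return List with `reads` (trimmed survivors) and `n_discarded`.
#' @export
quality_trim <- function(reads, cfg = trim_config()) {
  stopifnot(inherits(reads, "hvr_reads"))
  if (is.null(reads$qual) || length(reads) == 0L) {
    return(list(reads = reads, n_discarded = 0L))
  }
  len <- vapply(reads$qual, trim_length, integer(1),
                window = cfg$window, thr = cfg$mean_q_threshold)
  keep <- len >= cfg$min_len_after_trim
  trimmed <- hvr_reads(
    reads$id[keep],
    substr(reads$seq[keep], 1L, len[keep]),
    mapply(function(q, l) q[seq_len(l)], reads$qual[keep], len[keep],
           SIMPLIFY = FALSE)
  )
  list(reads = trimmed, n_discarded = sum(!keep))
}

# ---- pair merging -----------------------------------------------------------

#' Reverse-complement a base string
#' @param seq DNA string (IUPAC codes supported).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Merge a read pair at its ungapped overlap
#'
#' The reverse mate is reverse-complemented (qualities reversed), all ungapped
#' suffix-prefix overlaps of at least `min_overlap` bases are scanned, each is
#' scored matches - mismatches, and the best-scoring overlap is accepted if
#' its mismatch fraction is within `max_mismatch_frac` (score ties prefer the
#' longer overlap). In the overlap, the consensus base is the one with the
#' higher quality (tie goes to the forward base); consensus quality is the
#' maximum of the two where the bases agree and the minimum where they
#' disagree. The non-overlapping ends are copied verbatim.
#'
#' @param fwd,rev Single-read [hvr_reads()] fields as lists
#'   `list(seq =, qual =)` or 1-read `hvr_reads` objects.
#' @param cfg A [merge_config()].
#' @return A list `list(seq =, qual =)` for the merged fragment, or `NULL`
#'   for a merge failure (no admissible overlap).
#' @export
merge_pair <- function(fwd, rev, cfg = merge_config()) {
  f <- as_single_read(fwd)
  r <- as_single_read(rev)
  if (nchar(f$seq) == 0L || nchar(r$seq) == 0L) return(NULL)
  rseq <- revcomp(r$seq)
  rqual <- rev(r$qual)
  fb <- strsplit(f$seq, "")[[1]]
  rb <- strsplit(rseq, "")[[1]]
  nf <- length(fb); nr <- length(rb)
  best <- NULL
  for (o in seq(from = cfg$min_overlap, to = min(nf, nr))) {
    fi <- (nf - o + 1L):nf
    ri <- seq_len(o)
    mism <- sum(fb[fi] != rb[ri])
    score <- (o - mism) - mism
    if (mism / o <= cfg$max_mismatch_frac &&
        (is.null(best) || score > best$score ||
         (score == best$score && o > best$o))) {
      best <- list(o = o, mism = mism, score = score)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  fi <- (nf - o + 1L):nf
  ri <- seq_len(o)
  fq <- f$qual[fi]; rq <- rqual[ri]
  agree <- fb[fi] == rb[ri]
  take_rev <- !agree & (rq > fq)
  cons_b <- ifelse(take_rev, rb[ri], fb[fi])
  cons_q <- ifelse(agree, pmax(fq, rq), pmin(fq, rq))
  list(
    seq = paste(c(fb[seq_len(nf - o)], cons_b, rb[(o + 1L):nr][seq_len(nr - o)]),
                collapse = ""),
    qual = as.integer(c(f$qual[seq_len(nf - o)], cons_q,
                        rqual[(o + 1L):nr][seq_len(nr - o)]))
  )
}

as_single_read <- function(x) {
  if (inherits(x, "hvr_reads")) {
    stopifnot(length(x) == 1L)
    return(list(seq = x$seq[1], qual = x$qual[[1]]))
  }
  list(seq = x$seq, qual = as.integer(x$qual))
}

#' Merge all pairs of a paired sample
#'
#' @param fwd,rev [hvr_reads()] objects of equal length (mates by order).
#' @param cfg A [merge_config()].
#' @return List with `reads` (merged [hvr_reads()]) and `n_failed`.
#' @export
merge_sample <- function(fwd, rev, cfg = merge_config()) {
  stopifnot(length(fwd) == length(rev))
  out_seq <- character(0); out_qual <- list(); out_id <- character(0)
  n_failed <- 0L
  for (i in seq_len(length(fwd))) {
    m <- merge_pair(list(seq = fwd$seq[i], qual = fwd$qual[[i]]),
                    list(seq = rev$seq[i], qual = rev$qual[[i]]), cfg)
    if (is.null(m)) {
      n_failed <- n_failed + 1L
    } else {
      out_id <- c(out_id, fwd$id[i])
      out_seq <- c(out_seq, m$seq)
      out_qual <- c(out_qual, list(m$qual))
    }
  }
  list(reads = hvr_reads(out_id, out_seq, out_qual), n_failed = n_failed)
}

# ---- whole-sample preprocessing --------------------------------------------

#' Subsample, trim and (for pairs) merge a sample's reads
#'
#' @param sample_reads Output of [read_sample()].
#' @param n_reads Head-subsample size (default 1000).
#' @param trim A [trim_config()].
#' @param merge A [merge_config()].
#' @return List with `reads` (processed single stream), `n_in` (reads
#'   retrieved), `n_trim_discarded`, `n_merge_failed`.
#' @export
preprocess_sample <- function(sample_reads, n_reads = 1000L,
                              trim = trim_config(), merge = merge_config()) {
  paired <- is.list(sample_reads) && !inherits(sample_reads, "hvr_reads")
  if (paired) {
    fwd <- subsample_reads(sample_reads$fwd, n_reads)
    rev <- subsample_reads(sample_reads$rev, n_reads)
    n_in <- length(fwd)
    tf <- quality_trim(fwd, trim)
    tr <- quality_trim(rev, trim)
    # keep only pairs where both mates survived trimming
    keep <- intersect(tf$reads$id, tr$reads$id)
    fi <- match(keep, tf$reads$id)
    ri <- match(keep, tr$reads$id)
    n_trim_discarded <- n_in - length(keep)
    merged <- merge_sample(reads_slice(tf$reads, fi),
                           reads_slice(tr$reads, ri), merge)
    list(reads = merged$reads, n_in = n_in,
         n_trim_discarded = n_trim_discarded,
         n_merge_failed = merged$n_failed)
  } else {
    reads <- subsample_reads(sample_reads, n_reads)
    n_in <- length(reads)
    tt <- quality_trim(reads, trim)
    list(reads = tt$reads, n_in = n_in, n_trim_discarded = tt$n_discarded,
         n_merge_failed = 0L)
  }
}
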