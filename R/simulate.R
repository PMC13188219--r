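# ---- primer catalog ---------------------------------------------------------

#' Load the primer-pair catalog
#'
#' Named primer pairs with their primer-trimmed amplicon windows on the
#' bundled reference (0-based inclusive) and the true start/end regions
#' implied by the default boundary map. Windows were computed once by
#' matching the degenerate primers against the bundled reference and frozen
#' into the data file; [primer_window()] recomputes them for verification.
#'
#' @param path Catalog TSV (`NULL` for the packaged default).
#' @return data.frame with columns `name`, `fwd_primer`, `rev_primer`,
#'   `window_start`, `window_end`, `start_region`, `end_region`.
#' @export
load_primer_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "primer_catalog.tsv", package = "hvrscan",
                        mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Locate a primer pair's trimmed amplicon window on a reference
#'
#' Matches the degenerate forward primer and the reverse complement of the
#' degenerate reverse primer against the reference (each must match exactly
#' once) and returns the inner, primer-free window.
#'
#' @param fwd_primer,rev_primer IUPAC primer strings (reverse primer given
#'   5'->3' as ordered, i.e. it matches the reference as a reverse
#'   complement).
#' @param reference A `ReferenceGene`.
#' @return Integer vector `c(start, end)`, 0-based inclusive.
#' @export
primer_window <- function(fwd_primer, rev_primer, reference) {
  ref <- Biostrings::DNAString(reference$sequence)
  fm <- Biostrings::matchPattern(Biostrings::DNAString(fwd_primer), ref,
                                 fixed = FALSE)
  rm_ <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_primer)), ref,
    fixed = FALSE)
  if (length(fm) != 1L || length(rm_) != 1L) {
    stop("primer must match the reference exactly once (fwd: ", length(fm),
         ", rev: ", length(rm_), " matches)")
  }
  c(start = Biostrings::end(fm)[1],       # 0-based: end(fm) is 1-based end
    end = Biostrings::start(rm_)[1] - 2L) # position before the reverse site
}

# ---- configuration ----------------------------------------------------------

#' Simulation configuration
#'
#' Defines one synthetic amplicon sample: reads are drawn from a reference
#' window (a primer-trimmed amplicon), substitution errors and per-cycle
#' Gaussian Phred qualities are applied, and optionally the primer sequence
#' is retained at the read start together with the low-diversity quality
#' signature of the first ten sequencing cycles (elevated mean, depressed
#' variance) that untrimmed primers produce.
#'
#' @param primer_pair Catalog entry name (e.g. `"515F-806R"`); alternative
#'   to `window`.
#' @param window Integer `c(start, end)`, 0-based inclusive, if no catalog
#'   entry is used.
#' @param n_reads Reads per sample (default 1000).
#' @param layout `"single"` (fragment = whole window) or `"paired"`
#'   (`read_len` prefix and reverse-complemented `read_len` suffix).
#' @param read_len Mate length for paired layout (default 150).
#' @param substitution_rate Per-base i.i.d. substitution probability
#'   (default 0.01).
#' @param with_primer Retain the primer at the read start and apply the
#'   first-10-cycle quality signature (default FALSE).
#' @param q_mean,q_sd Baseline per-cycle Phred mean and sd (defaults 34, 3).
#' @param primer_q_mean,primer_q_sd Quality signature of cycles 1-10 when
#'   `with_primer` (defaults 38, 0.5).
#' @param seed RNG seed (default 1).
#' @param catalog Primer catalog (default packaged).
#' @return A `sim_config` list.
#' @export
sim_config <- function(primer_pair = NULL, window = NULL, n_reads = 1000L,
                       layout = c("single", "paired"), read_len = 150L,
                       substitution_rate = 0.01, with_primer = FALSE,
                       q_mean = 34, q_sd = 3,
                       primer_q_mean = 38, primer_q_sd = 0.5,
                       seed = 1L, catalog = load_primer_catalog()) {
  layout <- match.arg(layout)
  fwd_primer <- rev_primer <- NA_character_
  if (!is.null(primer_pair)) {
    row <- catalog[catalog$name == primer_pair, ]
    if (nrow(row) != 1L) stop("unknown primer pair: ", primer_pair)
    window <- c(row$window_start, row$window_end)
    fwd_primer <- row$fwd_primer
    rev_primer <- row$rev_primer
  }
  if (is.null(window) || length(window) != 2L || window[1] > window[2]) {
    stop("need a valid window (start <= end) or a primer_pair")
  }
  stopifnot(n_reads >= 1L, substitution_rate >= 0, substitution_rate <= 1)
  structure(list(primer_pair = primer_pair %||% NA_character_,
                 window = as.integer(window),
                 fwd_primer = fwd_primer, rev_primer = rev_primer,
                 n_reads = as.integer(n_reads), layout = layout,
                 read_len = as.integer(read_len),
                 substitution_rate = substitution_rate,
                 with_primer = isTRUE(with_primer),
                 q_mean = q_mean, q_sd = q_sd,
                 primer_q_mean = primer_q_mean, primer_q_sd = primer_q_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve IUPAC degeneracies deterministically (first base of the code set)
resolve_iupac <- function(p) {
  chartr("RYSWKMBDHVN", "ACCAGACAAAA", toupper(p))
}

# ---- read generation --------------------------------------------------------

# n_reads copies of template with iid substitutions + per-cycle qualities;
# first `sig_cycles` cycles optionally get the primer quality signature
simulate_read_set <- function(template, n_reads, substitution_rate,
                              q_mean, q_sd, sig_cycles = 0L,
                              sig_mean = NULL, sig_sd = NULL,
                              id_prefix = "read") {
  bases <- c("A", "C", "G", "T")
  tmpl <- strsplit(template, "")[[1]]
  L <- length(tmpl)
  mat <- matrix(rep(tmpl, n_reads), nrow = L)
  if (substitution_rate > 0) {
    hit <- which(stats::runif(L * n_reads) < substitution_rate)
    if (length(hit)) {
      orig <- mat[hit]
      # uniform choice among the three other bases
      shift <- sample.int(3L, length(hit), replace = TRUE)
      mat[hit] <- bases[(match(orig, bases) - 1L + shift) %% 4L + 1L]
    }
  }
  mu <- rep(q_mean, L)
  sd <- rep(q_sd, L)
  if (sig_cycles > 0L) {
    k <- seq_len(min(sig_cycles, L))
    mu[k] <- sig_mean
    sd[k] <- sig_sd
  }
  q <- round(stats::rnorm(L * n_reads, mean = mu, sd = sd))
  q <- pmin(pmax(q, 2L), 41L)
  qmat <- matrix(as.integer(q), nrow = L)
  hvr_reads(sprintf("%s_%d", id_prefix, seq_len(n_reads)),
            apply(mat, 2L, paste, collapse = ""),
            lapply(seq_len(n_reads), function(i) qmat[, i]))
}

#' Simulate one amplicon sample
#'
#' Draws reads from the configured reference window, writes FASTQ file(s)
#' and a ground-truth manifest TSV. Output is byte-identical for identical
#' configurations (including seed).
#'
#' @param cfg A [sim_config()].
#' @param reference A `ReferenceGene` (default: bundled).
#' @param dir Output directory (created if needed).
#' @param sample_id Sample name (default derived from config).
#' @param region_map Boundary map used to record the true regions.
#' @param gzip Write gzip-compressed FASTQ (default FALSE).
#' @return List with `files` (FASTQ paths), `manifest_file`, and `truth`
#'   (one-row data.frame: window, true regions, primer flag, seed).
#' @export
simulate_sample <- function(cfg, reference = load_reference(),
                            dir = tempdir(), sample_id = NULL,
                            region_map = load_region_map(), gzip = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  ws <- cfg$window[1]; we <- cfg$window[2]
  if (we > reference$length - 1L) stop("window extends beyond the reference")
  if (is.null(sample_id)) {
    sample_id <- sprintf("sim_%s_%d",
                         if (!is.na(cfg$primer_pair)) cfg$primer_pair
                         else paste0(ws, "-", we), cfg$seed)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fragment <- substr(reference$sequence, ws + 1L, we + 1L)
  sig <- if (cfg$with_primer) 10L else 0L
  fwd_p <- if (cfg$with_primer) {
    resolve_iupac(if (!is.na(cfg$fwd_primer)) cfg$fwd_primer
                  else "GTGCCAGCAGCCGCGGTAA")
  } else ""
  rev_p <- if (cfg$with_primer) {
    resolve_iupac(if (!is.na(cfg$rev_primer)) cfg$rev_primer
                  else "GGACTACAAGGGTATCTAAT")
  } else ""

  set.seed(cfg$seed)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  if (cfg$layout == "single") {
    template <- paste0(fwd_p, fragment)
    reads <- simulate_read_set(template, cfg$n_reads, cfg$substitution_rate,
                               cfg$q_mean, cfg$q_sd, sig,
                               cfg$primer_q_mean, cfg$primer_q_sd,
                               id_prefix = sample_id)
    files <- file.path(dir, paste0(sample_id, ext))
    write_fastq(reads, files)
  } else {
    template <- paste0(fwd_p, fragment, revcomp(rev_p))
    if (nchar(template) < cfg$read_len) {
      stop("window shorter than read_len in paired mode")
    }
    frags <- simulate_read_set(template, cfg$n_reads, cfg$substitution_rate,
                               # qualities re-drawn per mate below
                               q_mean = cfg$q_mean, q_sd = cfg$q_sd,
                               id_prefix = sample_id)
    r1_seq <- substr(frags$seq, 1L, cfg$read_len)
    r2_seq <- revcomp(substr(frags$seq,
                             nchar(template) - cfg$read_len + 1L,
                             nchar(template)))
    mate_quals <- function() {
      q <- simulate_read_set(strrep("A", cfg$read_len), cfg$n_reads, 0,
                             cfg$q_mean, cfg$q_sd, sig,
                             cfg$primer_q_mean, cfg$primer_q_sd)$qual
      q
    }
    r1 <- hvr_reads(frags$id, r1_seq, mate_quals())
    r2 <- hvr_reads(frags$id, r2_seq, mate_quals())
    files <- file.path(dir, paste0(sample_id, c("_1", "_2"), ext))
    write_fastq(r1, files[1])
    write_fastq(r2, files[2])
  }

  truth <- data.frame(
    sample_id = sample_id,
    layout = cfg$layout,
    n_reads = cfg$n_reads,
    window_start = ws, window_end = we,
    true_start_region = position_to_start_region(ws, region_map),
    true_end_region = position_to_end_region(we, region_map),
    with_primer = cfg$with_primer,
    substitution_rate = cfg$substitution_rate,
    seed = cfg$seed,
    files = paste(basename(files), collapse = ";"),
    stringsAsFactors = FALSE
  )
  manifest_file <- file.path(dir, paste0(sample_id, "_truth.tsv"))
  utils::write.table(truth, manifest_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(files = files, manifest_file = manifest_file, truth = truth)
}

# ---- training corpus --------------------------------------------------------

#' Simulate a labeled feature corpus for primer-model training
#'
#' Generates `n_per_class` samples with retained primers and `n_per_class`
#' without, across the catalog's windows and a range of baseline quality
#' profiles, extracts the 16 quality features per sample, and returns the
#' labeled feature table. Deterministic per seed.
#'
#' @param n_per_class Samples per class (>= 10).
#' @param seed RNG seed.
#' @param reference A `ReferenceGene`.
#' @param n_reads_per_sample Reads generated per sample (default 300; the
#'   feature extractor pools the first 5 and next 5 cycles across reads, so
#'   hundreds of reads give stable statistics).
#' @param catalog Primer catalog.
#' @return Tibble with `sample_id`, the 16 feature columns and `label`
#'   (`"primer"` / `"no-primer"`).
#' @export
simulate_training_corpus <- function(n_per_class = 200L, seed = 42L,
                                     reference = load_reference(),
                                     n_reads_per_sample = 300L,
                                     catalog = load_primer_catalog()) {
  stopifnot(n_per_class >= 10L)
  set.seed(seed)
  n_tot <- 2L * n_per_class
  labels <- rep(c("primer", "no-primer"), each = n_per_class)
  pair_names <- catalog$name[1 + (seq_len(n_tot) - 1L) %% nrow(catalog)]
  q_means <- stats::runif(n_tot, 30, 38)
  q_sds <- stats::runif(n_tot, 2, 4)
  sig_means <- pmin(q_means + stats::runif(n_tot, 2.5, 4.5), 40)
  sig_sds <- stats::runif(n_tot, 0.3, 0.8)
  sample_seeds <- sample.int(2^31 - 2L, n_tot)

  rows <- lapply(seq_len(n_tot), function(i) {
    cfg_row <- catalog[catalog$name == pair_names[i], ]
    with_primer <- labels[i] == "primer"
    template <- paste0(
      if (with_primer) resolve_iupac(cfg_row$fwd_primer) else "",
      substr(reference$sequence, cfg_row$window_start + 1L,
             cfg_row$window_end + 1L)
    )
    set.seed(sample_seeds[i])
    reads <- simulate_read_set(template, n_reads_per_sample, 0.01,
                               q_means[i], q_sds[i],
                               sig_cycles = if (with_primer) 10L else 0L,
                               sig_mean = sig_means[i], sig_sd = sig_sds[i])
    feats <- extract_features(reads)
    c(list(sample_id = sprintf("corpus_%04d", i)), as.list(feats),
      list(label = labels[i]))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}
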