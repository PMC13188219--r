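# Independent brute-force oracles used to pin down expected values.
# These are deliberately naive re-derivations, not calls into the package.

# full Gotoh DP over complete matrices; free reference end gaps; score only
oracle_semiglobal_score <- function(q, r, match = 2, mismatch = -3,
                                    go = -5, ge = -2) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Iq <- matrix(NEG, n + 1, m + 1)
  Ir <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 1:n) Iq[i + 1, 1] <- go + i * ge
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (qs[i] == rs[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], Iq[i, j], Ir[i, j])
      Iq[i + 1, j + 1] <- max(M[i, j + 1] + go + ge,
                              Iq[i, j + 1] + ge,
                              Ir[i, j + 1] + go + ge)
      Ir[i + 1, j + 1] <- max(M[i + 1, j] + go + ge,
                              Iq[i + 1, j] + go + ge,
                              Ir[i + 1, j] + ge)
    }
  }
  max(M[n + 1, ], Iq[n + 1, ])
}

oracle_semiglobal_best <- function(q, r, ...) {
  max(oracle_semiglobal_score(q, r, ...),
      oracle_semiglobal_score(oracle_revcomp(q), r, ...))
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# positionwise coverage by direct counting over every reference position
oracle_region_coverage <- function(starts, ends, region_map, ref_length) {
  per_pos <- vapply(0:(ref_length - 1), function(p) {
    mean(starts <= p & p <= ends)
  }, numeric(1))
  vapply(seq_len(nrow(region_map)), function(k) {
    mean(per_pos[(region_map$start[k]:region_map$end[k]) + 1])
  }, numeric(1))
}

# naive re-computation of the 8 segment statistics
oracle_segment_stats <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  qtl <- function(p) {  # type-7 linear interpolation, written out
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s <- sort(x)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  med <- if (n %% 2 == 1) sort(x)[(n + 1) / 2] else
    mean(sort(x)[n / 2 + 0:1])
  c(count = n, mean = sum(x) / n, median = med,
    sd = sqrt(sum((x - sum(x) / n)^2) / n),
    min = min(x), max = max(x), q25 = qtl(0.25), q75 = qtl(0.75))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
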