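# shared fixtures, built in code at test time

ref_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- load_reference()
    val
  }
})

map_fixture <- function() load_region_map(reference = ref_fixture())

# a toy two-region map used for the mapping-rule unit tests
toy_map <- function() {
  tab <- data.frame(name = paste0("V", 1:9),
                    start = c(10L, 30L, 50L, 70L, 90L, 110L, 130L, 150L, 170L),
                    end = c(19L, 39L, 59L, 79L, 99L, 119L, 139L, 159L, 179L))
  validate_region_map(tab)
}

make_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (length(seqs)) paste0("r", seq_along(seqs)) else character(0)
  }
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(n) rep(40L, n))
  hvr_reads(ids, seqs, quals)
}

write_fastq_lines <- function(path, ids, seqs, quals) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

quiet_read_fastq <- function(...) suppressWarnings(read_fastq(...))
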