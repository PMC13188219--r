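#' Load the 16S reference gene
#'
#' Reads a single-record FASTA file and returns the reference the whole
#' coordinate system is expressed in. All positions elsewhere in the package
#' are 0-based and inclusive, so a reference of length `L` spans positions
#' `0 .. L-1` (1541 bases and maximum position 1540 for the bundled
#' E. coli-style reference).
#'
#' @param path Path to a FASTA file with exactly one record. Defaults to the
#'   bundled synthetic reference, which carries the real conserved
#'   primer-binding loci at canonical *E. coli* coordinates.
#' @param max_ambiguous_frac Maximum tolerated fraction of non-ACGT characters
#'   (after mapping U to T). Default 0: any other IUPAC code is an error.
#' @return A `ReferenceGene`: list with `id`, `sequence` (uppercase ACGT
#'   string) and `length`.
#' @export
load_reference <- function(path = hvr_default_reference_path(),
                           max_ambiguous_frac = 0) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("reference FASTA is empty: ", path)
  if (length(recs) > 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(recs))
  }
  seq <- toupper(as.character(recs[[1]]))
  seq <- chartr("U", "T", seq)
  n_bad <- nchar(seq) - sum(charmatch_count(seq, c("A", "C", "G", "T")))
  if (nchar(seq) == 0L) stop("reference sequence is empty")
  if (n_bad / nchar(seq) > max_ambiguous_frac) {
    stop("reference contains ", n_bad,
         " non-ACGT characters (allowed fraction ", max_ambiguous_frac, ")")
  }
  structure(
    list(id = sub("\\s.*$", "", names(recs)[1]),
         sequence = seq,
         length = nchar(seq)),
    class = "hvr_reference"
  )
}

# count of characters of `s` belonging to `alphabet`
charmatch_count <- function(s, alphabet) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars %in% alphabet
}

#' Path to the bundled reference FASTA
#' @return File path of the packaged synthetic 16S reference.
#' @export
hvr_default_reference_path <- function() {
  system.file("extdata", "synthetic_16s_reference.fasta", package = "hvrscan",
              mustWork = TRUE)
}

#' @export
print.hvr_reference <- function(x, ...) {
  cat("<hvr_reference> ", x$id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Load a V1-V9 hypervariable region boundary map
#'
#' The map is a 9-row table (V1..V9, ascending, non-overlapping) of 0-based
#' inclusive positions on the reference. Every region call in the package
#' flows through this table, so swapping in an alternative boundary
#' convention is a matter of pointing at a different file.
#'
#' @param path A 3-column headered TSV (`name`, `start`, `end`); `NULL` loads
#'   the packaged default table.
#' @param reference Optional `ReferenceGene` used to check that boundaries lie
#'   within the gene.
#' @return A `RegionMap`: data.frame with columns `name`, `start`, `end`.
#' @export
load_region_map <- function(path = NULL, reference = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_region_map.tsv",
                        package = "hvrscan", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("region map file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_region_map(tab, reference = reference)
}

#' Validate a region boundary table
#'
#' @param tab data.frame with columns `name`, `start`, `end` (0-based
#'   inclusive).
#' @inheritParams load_region_map
#' @return The validated map with class `hvr_region_map`.
#' @export
validate_region_map <- function(tab, reference = NULL) {
  req <- c("name", "start", "end")
  if (!all(req %in% names(tab))) {
    stop("region map needs columns: ", paste(req, collapse = ", "))
  }
  tab <- tab[, req]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  expected <- paste0("V", 1:9)
  if (nrow(tab) != 9L || !identical(tab$name, expected)) {
    stop("region map must contain exactly V1..V9 in ascending order")
  }
  if (any(is.na(tab$start)) || any(is.na(tab$end))) {
    stop("region map has non-integer coordinates")
  }
  if (any(tab$start > tab$end)) stop("region map has start > end")
  if (any(tab$start < 0L)) stop("region map has negative coordinates")
  if (!is.null(reference) && any(tab$end > reference$length - 1L)) {
    stop("region map extends beyond the reference (length ",
         reference$length, ")")
  }
  # strictly increasing, pairwise disjoint intervals
  if (any(tab$start[-1] <= tab$end[-9])) {
    stop("region map intervals overlap or are out of order")
  }
  class(tab) <- c("hvr_region_map", "data.frame")
  tab
}

#' Write a region map to TSV
#'
#' @param map A `RegionMap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("name", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map an alignment start position to a hypervariable region
#'
#' A position inside a region returns that region. A position in a conserved
#' gap is attributed to the next region downstream, because an amplicon whose
#' trimmed start lies in the conserved primer-binding stretch upstream of Vk
#' sequences Vk first (e.g. the 515F trim point, position 532, maps to V4).
#' Positions past the end of V9 return the sentinel `"beyond-V9"`.
#'
#' @param pos 0-based reference position(s); vectorised.
#' @param map A `RegionMap`.
#' @return Character vector of region names or `"beyond-V9"`.
#' @export
position_to_start_region <- function(pos, map) {
  check_positions(pos)
  idx <- vapply(pos, function(p) {
    w <- which(map$end >= p)
    if (length(w) == 0L) NA_integer_ else w[1]
  }, integer(1))
  ifelse(is.na(idx), "beyond-V9", map$name[idx])
}

#' Map an alignment end position to a hypervariable region
#'
#' Mirror of [position_to_start_region()]: a conserved-gap position is
#' attributed to the region upstream (the last variable region the amplicon
#' read through). Positions before the start of V1 return `"before-V1"`.
#'
#' @inheritParams position_to_start_region
#' @return Character vector of region names or `"before-V1"`.
#' @export
position_to_end_region <- function(pos, map) {
  check_positions(pos)
  idx <- vapply(pos, function(p) {
    w <- which(map$start <= p)
    if (length(w) == 0L) NA_integer_ else w[length(w)]
  }, integer(1))
  ifelse(is.na(idx), "before-V1", map$name[idx])
}

check_positions <- function(pos) {
  if (length(pos) == 0L || any(!is.finite(pos)) || any(pos < 0)) {
    stop("positions must be finite and >= 0")
  }
}
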