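#' Read a chromosome-sizes table
#'
#' Reads a genome index from a samtools FAI file (five tab-separated columns,
#' the first two being chromosome name and length) or a plain two-column
#' `chrom<TAB>length` TSV. The row order of the file is preserved.
#'
#' @param path Path to a FAI or two-column chromosome-sizes file.
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @examples
#' p <- tempfile(fileext = ".fai")
#' writeLines(c("chr1\t1000000", "chr2\t2000000"), p)
#' read_genome_index(p)
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Genome index file not found: %s", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    abort(sprintf("Genome index file is empty: %s", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, character(1), 1)
  len_chr <- vapply(fields, function(f) {
    if (length(f) < 2) NA_character_ else f[2]
  }, character(1))
  len <- suppressWarnings(as.numeric(len_chr))
  bad <- which(is.na(len) | is.na(chrom) | !nzchar(chrom))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed genome index line %d: %s", bad[1], lines[bad[1]]
    ))
  }
  genome_index(tibble(chrom = chrom, length = as.integer(len)))
}

#' Construct and validate a genome index
#'
#' @param genome A data frame with columns `chrom` and `length`.
#' @return A validated tibble with columns `chrom` and `length`.
#' @export
genome_index <- function(genome) {
  assert_columns(genome, c("chrom", "length"), "genome")
  genome <- as_tibble(genome[, c("chrom", "length")])
  genome$chrom <- as.character(genome$chrom)
  genome$length <- as.integer(genome$length)
  if (anyDuplicated(genome$chrom)) {
    dup <- unique(genome$chrom[duplicated(genome$chrom)])
    abort(sprintf(
      "Duplicate chromosome name(s) in genome index: %s",
      paste(dup, collapse = ", ")
    ))
  }
  if (any(is.na(genome$length)) || any(genome$length < 1)) {
    abort("Chromosome lengths must be integers >= 1.")
  }
  genome
}

#' Total genome length of an index
#'
#' @param genome A genome index tibble (see [genome_index()]).
#' @return Total length in bp.
#' @export
genome_length <- function(genome) {
  genome <- genome_index(genome)
  sum(as.numeric(genome$length))
}

same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$length, b$length)
}
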