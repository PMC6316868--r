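bed_block_cols <- c(
  "chrom", "start", "end", "block_id", "block_scr", "strand",
  "copies", "fraction_passing", "b_space_bp",
  "carrier_scaled_mean", "reference_scaled_mean", "n_passing"
)

#' Write B blocks as a BED6+ file
#'
#' Columns: chrom, start (0-based), end (half-open), block id, block-level
#' SCR as score, strand (always `.`), then estimated copy number, passing
#' fraction, B-space contribution (length x copies), per-block scaled
#' coverage means and the passing-position count. Numeric fields are
#' written at full precision so a write/read round trip is bit-exact.
#' Lines starting with `#` carry provenance and are skipped on read.
#'
#' @param blocks Block tibble (from [filter_blocks()] /
#'   [estimate_copy_number()]), sorted by (chrom, start).
#' @param path Output path.
#' @param header Optional character vector of provenance lines (written
#'   as `#`-prefixed comments).
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path, header = NULL) {
  assert_columns(blocks, c("chrom", "start", "end"), "blocks")
  if (nrow(blocks) > 1) {
    o <- order(blocks$chrom, blocks$start)
    if (!identical(o, seq_len(nrow(blocks)))) {
      abort("Blocks must be sorted by (chrom, start) before writing.")
    }
  }
  lines <- character(0)
  if (!is.null(header)) {
    lines <- paste0("#", header)
  }
  if (nrow(blocks) > 0) {
    get <- function(col, default = NA_real_) {
      if (col %in% names(blocks)) blocks[[col]] else rep(default, nrow(blocks))
    }
    body <- paste(
      blocks$chrom,
      blocks$start,
      blocks$end,
      get("block_id", NA_character_),
      fmt_num(get("block_scr")),
      ".",
      fmt_num(get("copies")),
      fmt_num(get("fraction_passing")),
      fmt_num(get("b_space_bp")),
      fmt_num(get("carrier_scaled_mean")),
      fmt_num(get("reference_scaled_mean")),
      get("n_passing", NA_integer_),
      sep = "\t"
    )
    lines <- c(lines, body)
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a B-block BED file written by [write_blocks()]
#'
#' @param path Path to a block BED6+ file.
#' @return Block tibble with the same columns [write_blocks()] emits.
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) abort(sprintf("Block file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    block_id = character(), block_scr = numeric(), strand = character(),
    copies = numeric(), fraction_passing = numeric(),
    b_space_bp = numeric(), carrier_scaled_mean = numeric(),
    reference_scaled_mean = numeric(), n_passing = integer()
  )
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(bed_block_cols))) {
    abort(sprintf(
      "Malformed block line %d in %s (expected %d fields, found %d).",
      which(nf != length(bed_block_cols))[1], path,
      length(bed_block_cols), nf[which(nf != length(bed_block_cols))[1]]
    ))
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  suppressWarnings(tibble(
    chrom = col(1),
    start = as.integer(col(2)),
    end = as.integer(col(3)),
    block_id = col(4),
    block_scr = as.numeric(col(5)),
    strand = col(6),
    copies = as.numeric(col(7)),
    fraction_passing = as.numeric(col(8)),
    b_space_bp = as.numeric(col(9)),
    carrier_scaled_mean = as.numeric(col(10)),
    reference_scaled_mean = as.numeric(col(11)),
    n_passing = as.integer(col(12))
  ))
}
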