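#' Estimate B-located copy number per block
#'
#' Two regimes, switched on the block-mean scaled coverage of the
#' B-lacking reference: where the reference scaled coverage is at least 1
#' (ordinary mappability), the haploid B against the diploid A background
#' gives `copies = 2 * block_scr - 2` (the factor 2 converts the
#' haploid/diploid ratio, minus the two A-genome copies). Where the
#' reference scaled coverage is below 1 (poor alignment would inflate the
#' ratio), a single reference copy is assumed and
#' `copies = 2 * carrier_scaled_mean` is used instead. Estimates are kept
#' fractional (no rounding) and clamped at 0.
#'
#' @param blocks Block tibble carrying `block_scr`, `carrier_scaled_mean`
#'   and `reference_scaled_mean` (from [filter_blocks()] or
#'   [annotate_intervals][filter_blocks]).
#' @return The tibble with added columns `copies`, `estimator`
#'   (`"scr"` or `"female_scaled"`) and `b_space_bp` (= length x copies).
#' @examples
#' b <- tibble::tibble(
#'   chrom = "chr1", start = 0, end = 1000, block_scr = 3,
#'   carrier_scaled_mean = 3, reference_scaled_mean = 1
#' )
#' estimate_copy_number(b)$copies # 4
#' @export
estimate_copy_number <- function(blocks) {
  assert_columns(blocks, c("block_scr", "carrier_scaled_mean",
                           "reference_scaled_mean"), "blocks")
  use_scr <- blocks$reference_scaled_mean >= 1
  copies <- ifelse(
    use_scr,
    blocks$block_scr * 2 - 2,
    blocks$carrier_scaled_mean * 2
  )
  blocks$copies <- pmax(copies, 0)
  blocks$estimator <- ifelse(use_scr, "scr", "female_scaled")
  len <- if ("length" %in% names(blocks)) blocks$length else blocks$end - blocks$start
  blocks$b_space_bp <- len * blocks$copies
  blocks
}

#' Block-size summary statistics
#'
#' @param blocks Block tibble with `start`/`end` (or `length`).
#' @return One-row tibble: `n_blocks`, `mean_bp`, `sd_bp` (sample sd),
#'   `median_bp`, `max_bp`. Zero blocks gives a zero-count row with NA
#'   statistics.
#' @export
summarize_blocks <- function(blocks) {
  len <- if (nrow(blocks) == 0) {
    numeric(0)
  } else if ("length" %in% names(blocks)) {
    blocks$length
  } else {
    blocks$end - blocks$start
  }
  tibble(
    n_blocks = length(len),
    mean_bp = if (length(len) > 0) mean(len) else NA_real_,
    sd_bp = if (length(len) > 1) sd(len) else if (length(len) == 1) 0 else NA_real_,
    median_bp = if (length(len) > 0) median(len) else NA_real_,
    max_bp = if (length(len) > 0) max(len) else NA_real_
  )
}

#' Block-length histogram at 1 bp resolution
#'
#' @param blocks Block tibble.
#' @param binwidth Bin width in bp (default 1).
#' @return Tibble with columns `length` (bin lower bound) and `n`.
#' @export
block_length_histogram <- function(blocks, binwidth = 1) {
  len <- if (nrow(blocks) == 0) integer(0) else {
    if ("length" %in% names(blocks)) blocks$length else blocks$end - blocks$start
  }
  if (length(len) == 0) return(tibble(length = integer(), n = integer()))
  bin <- as.integer(floor(len / binwidth) * binwidth)
  count(tibble(length = bin), .data$length, name = "n")
}

#' A-space / B-space length accounting for one sample
#'
#' Sums block lengths over the reference genome ("A space") and block
#' lengths weighted by estimated copy number ("B space"), for the
#' sample's own blocks and, when given, for the shared core intervals
#' re-quantified against this sample's coverage (the copy number of a
#' core interval is sample specific).
#'
#' @param blocks Block tibble with `copies`/`b_space_bp` (run
#'   [estimate_copy_number()] first).
#' @param core_quant Optional core intervals annotated against *this*
#'   sample and run through [estimate_copy_number()]; see
#'   [quantify_sample()] for the usual entry point.
#' @return One-row tibble: block counts and size stats, `a_space_bp`,
#'   `b_space_bp`, `core_a_space_bp`, `core_b_space_bp`,
#'   `core_pct_of_b` (100 x core/total in B space; NA when the total is
#'   zero or no core set was given).
#' @export
quantify_blocks <- function(blocks, core_quant = NULL) {
  if (nrow(blocks) > 0 && !"b_space_bp" %in% names(blocks)) {
    abort("Run estimate_copy_number() before quantify_blocks().")
  }
  stats <- summarize_blocks(blocks)
  a_bp <- footprint_bp(blocks)
  b_bp <- if (nrow(blocks) > 0) sum(blocks$b_space_bp) else 0
  core_a <- core_b <- NA_real_
  if (!is.null(core_quant)) {
    if (nrow(core_quant) > 0 && !"b_space_bp" %in% names(core_quant)) {
      abort("`core_quant` must carry copy estimates (estimate_copy_number()).")
    }
    core_a <- footprint_bp(core_quant)
    core_b <- if (nrow(core_quant) > 0) sum(core_quant$b_space_bp) else 0
  }
  dplyr::bind_cols(
    stats,
    tibble(
      a_space_bp = a_bp,
      b_space_bp = b_bp,
      core_a_space_bp = core_a,
      core_b_space_bp = core_b,
      core_pct_of_b = ifelse(!is.na(core_b) & b_bp > 0,
                             100 * core_b / b_bp, NA_real_)
    )
  )
}

#' Quantify one sample's blocks and re-quantified core intervals
#'
#' Convenience wrapper for the per-sample report row: estimates copy
#' numbers for the sample's blocks, re-annotates the shared core
#' intervals against this sample's coverage (core copy numbers are
#' sample specific), and assembles the A-space/B-space totals together
#' with the calling-stage counters.
#'
#' @param calls A `bblock_calls` object from [call_blocks()].
#' @param scr The `scr_tbl` the calls were made from.
#' @param core Optional core-block tibble from [core_blocks()].
#' @return One-row tibble (see [quantify_blocks()]) prefixed with
#'   `sample_id` and `pct_passing`.
#' @export
quantify_sample <- function(calls, scr, core = NULL) {
  stopifnot(inherits(calls, "bblock_calls"))
  blocks <- estimate_copy_number(calls$blocks)
  core_quant <- NULL
  if (!is.null(core)) {
    core_quant <- if (nrow(core) > 0) {
      estimate_copy_number(annotate_intervals(
        select(core, "chrom", "start", "end"), scr,
        scr_min = calls$thresholds$scr_min, alpha = calls$thresholds$alpha
      ))
    } else {
      core
    }
  }
  dplyr::bind_cols(
    tibble(
      sample_id = calls$sample_id,
      pct_passing = calls$counters$pct_passing
    ),
    quantify_blocks(blocks, core_quant)
  )
}
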