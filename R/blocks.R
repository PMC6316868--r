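#' Positions passing the SCR and binomial thresholds
#'
#' A base passes when `scr >= scr_min` **and** `pvalue <= alpha` (both
#' comparisons inclusive). Defaults are the block-calling thresholds:
#' SCR at least 3 (at least 4 B-located copies) and p at most 0.001.
#'
#' @param scr An `scr_tbl` from [scr_table()].
#' @param scr_min Minimum scaled coverage ratio (inclusive).
#' @param alpha Maximum binomial p-value (inclusive).
#' @return Tibble of passing bases with columns `chrom`, `pos`, sorted.
#' @export
call_passing_positions <- function(scr, scr_min = 3, alpha = 0.001) {
  assert_columns(scr, c("chrom", "pos", "scr", "pvalue"), "scr")
  if (scr_min <= 0 || alpha <= 0) abort("Thresholds must be positive.")
  keep <- scr$scr >= scr_min & scr$pvalue <= alpha
  out <- tibble(chrom = scr$chrom[keep], pos = scr$pos[keep])
  arrange(out, .data$chrom, .data$pos)
}

#' Merge passing positions within a gap into raw intervals
#'
#' Consecutive passing positions whose distance (difference of base
#' positions) is at most `gap` fall into one interval; the interval spans
#' the first through the last passing base (half-open, end = last + 1).
#' Positions exactly `gap` apart merge.
#'
#' @param positions Tibble with columns `chrom`, `pos` (sorted, unique).
#' @param gap Maximum merge distance in bp.
#' @return Tibble of raw intervals (`chrom`, `start`, `end`), 0-based
#'   half-open, sorted.
#' @examples
#' merge_within_gap(
#'   tibble::tibble(chrom = "chr1", pos = c(100, 350, 700)), gap = 300
#' )
#' @export
merge_within_gap <- function(positions, gap = 300) {
  assert_columns(positions, c("chrom", "pos"), "positions")
  if (nrow(positions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  positions <- arrange(positions, .data$chrom, .data$pos)
  out <- lapply(split(positions$pos, positions$chrom), function(p) {
    p <- unique(p)
    br <- which(diff(p) > gap)
    s_idx <- c(1L, br + 1L)
    e_idx <- c(br, length(p))
    list(start = p[s_idx], end = p[e_idx] + 1L)
  })
  bind_rows(lapply(names(out), function(ch) {
    tibble(chrom = ch, start = as.integer(out[[ch]]$start),
           end = as.integer(out[[ch]]$end))
  }))
}

# Per-interval coverage statistics from a dense SCR table.
# Intervals must lie on chromosomes present in `scr`; `scr` must be dense
# (one row per base, positions ascending within chromosome), as produced
# by scr_table().
annotate_intervals <- function(intervals, scr, scr_min = 3, alpha = 0.001) {
  assert_columns(scr, c("chrom", "pos", "carrier_scaled",
                        "reference_scaled", "scr", "pvalue"), "scr")
  assert_intervals(intervals, "intervals")
  n <- nrow(intervals)
  if (n == 0) {
    return(mutate(intervals,
      length = integer(0), n_passing = integer(0),
      fraction_passing = numeric(0), carrier_scaled_mean = numeric(0),
      reference_scaled_mean = numeric(0), block_scr = numeric(0)
    ))
  }
  pass <- scr$scr >= scr_min & scr$pvalue <= alpha
  res <- vector("list", 0)
  for (ch in unique(intervals$chrom)) {
    sel <- scr$chrom == ch
    if (!any(sel)) {
      abort(sprintf("SCR table has no data for chromosome %s.", ch))
    }
    cs <- scr$carrier_scaled[sel]
    rs <- scr$reference_scaled[sel]
    pp <- pass[sel]
    L <- length(cs)
    CF <- c(0, cumsum(cs))
    CR <- c(0, cumsum(rs))
    CP <- c(0, cumsum(pp))
    iv <- intervals[intervals$chrom == ch, ]
    if (any(iv$end > L)) {
      abort(sprintf("Interval beyond chromosome %s end (%d bp).", ch, L))
    }
    len <- iv$end - iv$start
    sum_f <- CF[iv$end + 1] - CF[iv$start + 1]
    sum_r <- CR[iv$end + 1] - CR[iv$start + 1]
    npass <- as.integer(CP[iv$end + 1] - CP[iv$start + 1])
    mf <- sum_f / len
    mr <- sum_r / len
    res[[length(res) + 1]] <- mutate(iv,
      length = as.integer(len),
      n_passing = npass,
      fraction_passing = npass / len,
      carrier_scaled_mean = mf,
      reference_scaled_mean = mr,
      block_scr = ifelse(mr > 0, mf / mr, ifelse(mf > 0, Inf, 0))
    )
  }
  arrange(bind_rows(res), .data$chrom, .data$start)
}

#' Filter raw intervals into B blocks
#'
#' Removes intervals of length at most `min_len` bp and intervals where at
#' most `min_frac` of spanned positions pass both per-base thresholds
#' (both removals inclusive, so retained blocks have length strictly
#' greater than `min_len` and passing fraction strictly greater than
#' `min_frac`). Fills per-block coverage means and the block-level SCR,
#' computed as the ratio of mean scaled coverages over the block (robust
#' to per-base zeros).
#'
#' @param intervals Raw intervals from [merge_within_gap()].
#' @param scr The `scr_tbl` the intervals were called from.
#' @param min_len Blocks of length `<= min_len` are removed.
#' @param min_frac Blocks with passing fraction `<= min_frac` are removed.
#' @param scr_min,alpha Per-base thresholds used for the passing fraction.
#' @return Tibble of blocks with columns `chrom`, `start`, `end`,
#'   `block_id`, `length`, `n_passing`, `fraction_passing`,
#'   `carrier_scaled_mean`, `reference_scaled_mean`, `block_scr`.
#' @export
filter_blocks <- function(intervals, scr, min_len = 500, min_frac = 0.10,
                          scr_min = 3, alpha = 0.001) {
  ann <- annotate_intervals(intervals, scr, scr_min = scr_min, alpha = alpha)
  keep <- ann$length > min_len & ann$fraction_passing > min_frac
  out <- ann[keep, , drop = FALSE]
  sample_id <- attr(scr, "carrier_id") %||% "sample"
  out$block_id <- if (nrow(out) > 0) {
    sprintf("%s_b%05d", sample_id, seq_len(nrow(out)))
  } else character(0)
  select(out, "chrom", "start", "end", "block_id", dplyr::everything())
}

#' Call B blocks from a per-base SCR table
#'
#' Runs the full block-calling chain: per-base thresholding
#' ([call_passing_positions()]), merging within a gap
#' ([merge_within_gap()]) and length/fraction filtering
#' ([filter_blocks()]). Stage counters (bases passing, raw intervals,
#' retained blocks) are kept for reporting.
#'
#' @param scr An `scr_tbl` from [scr_table()].
#' @param scr_min,alpha Per-base thresholds (inclusive).
#' @param merge_gap Merge distance in bp.
#' @param min_len,min_frac Block filters (exclusive retention bounds).
#' @return A `bblock_calls` object; use [tidy()] for the block table,
#'   [glance()] for one-row stage counters, [autoplot()] for the
#'   block-length histogram.
#' @export
call_blocks <- function(scr, scr_min = 3, alpha = 0.001, merge_gap = 300,
                        min_len = 500, min_frac = 0.10) {
  positions <- call_passing_positions(scr, scr_min = scr_min, alpha = alpha)
  raw <- merge_within_gap(positions, gap = merge_gap)
  blocks <- filter_blocks(raw, scr,
    min_len = min_len, min_frac = min_frac,
    scr_min = scr_min, alpha = alpha
  )
  check_block_invariants(blocks, min_len, min_frac, merge_gap)
  structure(
    list(
      blocks = blocks,
      thresholds = list(
        scr_min = scr_min, alpha = alpha, merge_gap = merge_gap,
        min_len = min_len, min_frac = min_frac
      ),
      counters = tibble(
        n_bases = nrow(scr),
        n_passing = nrow(positions),
        pct_passing = 100 * nrow(positions) / nrow(scr),
        n_raw_intervals = nrow(raw),
        n_blocks = nrow(blocks)
      ),
      genome = attr(scr, "genome"),
      sample_id = attr(scr, "carrier_id") %||% "sample",
      reference_id = attr(scr, "reference_id") %||% "reference"
    ),
    class = "bblock_calls"
  )
}

# Block invariants, asserted on every calling run.
check_block_invariants <- function(blocks, min_len, min_frac, merge_gap) {
  if (nrow(blocks) == 0) return(invisible(TRUE))
  stopifnot(
    all(blocks$end - blocks$start > min_len),
    all(blocks$fraction_passing > min_frac),
    all(blocks$fraction_passing <= 1),
    all(blocks$n_passing >= 1)
  )
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    if (nrow(b) > 1) {
      sep <- b$start[-1] - b$end[-nrow(b)]
      # adjacent blocks must be > merge_gap apart in position terms:
      # next start - (last passing base of previous) > gap
      stopifnot(all(b$start[-1] - (b$end[-nrow(b)] - 1L) > merge_gap))
      stopifnot(all(sep >= 0))
    }
  }
  invisible(TRUE)
}

#' @export
print.bblock_calls <- function(x, ...) {
  cat(sprintf(
    "<bblock_calls> sample=%s vs %s\n", x$sample_id, x$reference_id
  ))
  cat(sprintf(
    "  %.4f%% of bases passing (SCR >= %g, p <= %g); %d raw intervals; %d blocks\n",
    x$counters$pct_passing, x$thresholds$scr_min, x$thresholds$alpha,
    x$counters$n_raw_intervals, x$counters$n_blocks
  ))
  invisible(x)
}

#' @rdname call_blocks
#' @param x A `bblock_calls` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bblock_calls <- function(x, ...) x$blocks

#' @rdname call_blocks
#' @exportS3Method generics::glance
glance.bblock_calls <- function(x, ...) {
  dplyr::bind_cols(
    tibble(sample_id = x$sample_id, reference_id = x$reference_id),
    x$counters
  )
}
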