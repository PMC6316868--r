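#' Core blocks: bases covered in at least k of N samples
#'
#' Base-resolution intersection across per-sample block sets: a base is
#' "core" when blocks of at least `k` of the `N` samples cover it.
#' Maximal runs of core bases form the core intervals; no re-merging and
#' no length re-filter is applied, so core intervals may be shorter than
#' the per-sample block minimum (larger blocks fragment at sample
#' boundaries). The reported `support` is the minimum per-base sample
#' count within the interval.
#'
#' @param block_sets List of N block tibbles (columns `chrom`, `start`,
#'   `end`), one per sample.
#' @param k Minimum number of supporting samples (1 <= k <= N).
#' @return Tibble with columns `chrom`, `start`, `end`, `support`,
#'   sorted, non-overlapping.
#' @export
core_blocks <- function(block_sets, k) {
  if (!is.list(block_sets) || length(block_sets) == 0) {
    abort("`block_sets` must be a non-empty list of block tibbles.")
  }
  N <- length(block_sets)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > N) {
    abort(sprintf("`k` must be between 1 and the number of samples (%d).", N))
  }
  # union within each sample first: support counts samples, not intervals
  all_iv <- bind_rows(lapply(block_sets, function(b) {
    assert_columns(b, c("chrom", "start", "end"), "block set")
    reduce_intervals(select(b, "chrom", "start", "end"))
  }))
  if (nrow(all_iv) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer()))
  }
  out <- lapply(split(all_iv, all_iv$chrom), function(iv) {
    # Sweep over breakpoints: +1 at starts, -1 at ends, piecewise-constant
    # sample count on the segments between consecutive breakpoints.
    ev_pos <- c(iv$start, iv$end)
    ev_del <- c(rep(1L, nrow(iv)), rep(-1L, nrow(iv)))
    o <- order(ev_pos)
    ev_pos <- ev_pos[o]
    ev_del <- ev_del[o]
    bp <- unique(ev_pos)
    cnt_at <- cumsum(ev_del)
    # count on segment [bp[i], bp[i+1]) = running sum after all events at bp[i]
    last_idx <- findInterval(bp, ev_pos)
    seg_cnt <- cnt_at[last_idx]
    seg_s <- bp[-length(bp)]
    seg_e <- bp[-1]
    seg_n <- seg_cnt[-length(seg_cnt)]
    keep <- seg_n >= k
    if (!any(keep)) return(NULL)
    s <- seg_s[keep]
    e <- seg_e[keep]
    n <- seg_n[keep]
    # merge adjacent qualifying segments; support = min count over the run
    run <- cumsum(c(1L, as.integer(s[-1] != e[-length(e)])))
    tibble(
      chrom = iv$chrom[1],
      start = as.integer(tapply(s, run, min)),
      end = as.integer(tapply(e, run, max)),
      support = as.integer(tapply(n, run, min))
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer()))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write core blocks as BED with a support column
#'
#' @param core Core-block tibble from [core_blocks()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_core_blocks <- function(core, path, header = NULL) {
  assert_columns(core, c("chrom", "start", "end", "support"), "core")
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("#", header)
  if (nrow(core) > 0) {
    lines <- c(lines, paste(
      core$chrom, core$start, core$end,
      sprintf("core%05d", seq_len(nrow(core))),
      core$support, ".", sep = "\t"
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
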