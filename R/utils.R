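# Internal validation helpers shared across modules.

assert_columns <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Intervals are 0-based half-open throughout the package.
assert_intervals <- function(x, what = deparse(substitute(x)), genome = NULL) {
  assert_columns(x, c("chrom", "start", "end"), what)
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(x$end <= x$start | x$start < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` has %d invalid interval(s) (need 0 <= start < end); first at row %d.",
      what, length(bad), bad[1]
    ))
  }
  if (!is.null(genome)) {
    len <- setNames(genome$length, genome$chrom)
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(sprintf(
        "`%s` uses chromosome(s) absent from the genome index: %s.",
        what, paste(unknown, collapse = ", ")
      ))
    }
    oob <- which(x$end > len[x$chrom])
    if (length(oob) > 0) {
      abort(sprintf(
        "`%s` has interval(s) beyond chromosome end; first at row %d (%s:%d-%d).",
        what, oob[1], x$chrom[oob[1]], x$start[oob[1]], x$end[oob[1]]
      ))
    }
  }
  invisible(x)
}

# Sum of interval lengths (bp) of a (possibly empty) interval tibble.
footprint_bp <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

# Union (reduce) of intervals per chromosome; returns sorted disjoint tibble.
reduce_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  parts <- split(x, x$chrom)
  out <- lapply(parts, function(p) {
    s <- p$start
    e <- p$end
    keep_s <- s[1]
    res_s <- integer(0)
    res_e <- integer(0)
    cur_e <- e[1]
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        if (s[i] <= cur_e) {
          cur_e <- max(cur_e, e[i])
        } else {
          res_s <- c(res_s, keep_s)
          res_e <- c(res_e, cur_e)
          keep_s <- s[i]
          cur_e <- e[i]
        }
      }
    }
    res_s <- c(res_s, keep_s)
    res_e <- c(res_e, cur_e)
    tibble(chrom = p$chrom[1], start = res_s, end = res_e)
  })
  bind_rows(out)
}

# Total overlap (bp) between two disjoint-within-themselves interval sets.
overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]
    bi <- b[b$chrom == ch, ]
    ra <- IRanges::IRanges(start = ai$start + 1, end = ai$end)
    rb <- IRanges::IRanges(start = bi$start + 1, end = bi$end)
    total <- total + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  total
}

fmt_num <- function(x) {
  # Full-precision, locale-independent numeric formatting for text outputs
  # (round-trips through as.numeric bit-exactly).
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    sprintf("%.17g", v)
  }, character(1))
}
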