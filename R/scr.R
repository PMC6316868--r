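#' Scale a depth track by its genome-wide mean depth
#'
#' Adds a `scaled` column: raw depth at each base divided by the sample's
#' genome-wide mean depth. By construction the genome-wide mean of the
#' scaled values is exactly 1.
#'
#' @param track A `depth_track` with positive mean depth.
#' @return The track with an added `scaled` column.
#' @export
scale_coverage <- function(track) {
  stopifnot(is_depth_track(track))
  mu <- track_mean_depth(track)
  if (is.null(mu) || mu <= 0) {
    abort("empty coverage: genome-wide mean depth is 0, cannot scale.")
  }
  track$scaled <- track$depth / mu
  track
}

#' Expected read-origin frequencies for the per-base binomial test
#'
#' Given the genome-wide mean depths of the B-carrier and the B-lacking
#' reference sample, the expected frequency of carrier reads at a base is
#' `p = carrier_mean / (carrier_mean + reference_mean)` and `q = 1 - p`.
#'
#' @param carrier_mean,reference_mean Positive genome-wide mean depths.
#' @return A list with elements `p` and `q` (`p + q == 1`).
#' @export
binom_params <- function(carrier_mean, reference_mean) {
  if (!is.numeric(carrier_mean) || !is.numeric(reference_mean) ||
      carrier_mean <= 0 || reference_mean <= 0) {
    abort("Mean depths must be positive numbers.")
  }
  p <- carrier_mean / (carrier_mean + reference_mean)
  list(p = p, q = 1 - p)
}

#' Upper-tail binomial p-value for excess carrier coverage
#'
#' Returns `P(X >= x)` for `X ~ Binomial(n, p)`, where `x` is the raw
#' carrier depth at a base, `n` the summed carrier + reference depth, and
#' `p` the expected carrier-read frequency from [binom_params()]. Computed
#' via the regularized incomplete beta function (`stats::pbinom`), which is
#' stable for n well beyond 10,000. `x = 0` gives 1 by convention.
#'
#' @param x Integer vector, observed carrier depth (0 <= x <= n).
#' @param n Integer vector, total depth at the base.
#' @param p Scalar expected carrier-read frequency in (0, 1).
#' @return Numeric vector of upper-tail p-values in `[0, 1]`.
#' @examples
#' binom_upper_tail(10, 10, 0.5) # 0.5^10
#' @export
binom_upper_tail <- function(x, n, p) {
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
    abort("`p` must be a single number strictly inside (0, 1).")
  }
  if (any(x < 0) || any(n < 0) || any(x > n)) {
    abort("Need 0 <= x <= n for the binomial upper tail.")
  }
  out <- pbinom(x - 1, n, p, lower.tail = FALSE)
  out[x == 0] <- 1
  out
}

#' Per-base scaled coverage ratio and binomial test
#'
#' Builds the per-base comparison table between a B-carrier sample and a
#' B-lacking reference on the same genome: scaled coverages of both
#' samples, their ratio SCR = carrier_scaled / reference_scaled, and the
#' upper-tail binomial p-value for carrier excess. Conventions where the
#' ratio is undefined: reference scaled 0 with carrier scaled > 0 gives
#' `Inf` (passes any SCR threshold; the binomial test still gates
#' significance), and 0/0 gives 0. Bases with zero total depth get
#' p-value 1.
#'
#' @param carrier `depth_track` of the B-carrying sample (the numerator).
#' @param reference `depth_track` of the B-lacking sample (the denominator).
#' @return A tibble with columns `chrom`, `pos`, `carrier_depth`,
#'   `reference_depth`, `carrier_scaled`, `reference_scaled`, `scr`,
#'   `pvalue`; attributes carry the genome, sample ids, mean depths and the
#'   binomial `p`.
#' @export
scr_table <- function(carrier, reference) {
  stopifnot(is_depth_track(carrier), is_depth_track(reference))
  if (!same_genome(track_genome(carrier), track_genome(reference))) {
    abort("Carrier and reference tracks are on different genome indexes.")
  }
  mu_c <- track_mean_depth(carrier)
  mu_r <- track_mean_depth(reference)
  if (mu_c <= 0 || mu_r <= 0) abort("empty coverage: mean depth is 0.")
  pq <- binom_params(mu_c, mu_r)

  cs <- carrier$depth / mu_c
  rs <- reference$depth / mu_r
  scr <- ifelse(rs > 0, cs / rs, ifelse(cs > 0, Inf, 0))
  x <- carrier$depth
  ntot <- carrier$depth + reference$depth
  pv <- rep(1, length(x))
  nz <- ntot > 0 & x > 0
  pv[nz] <- pbinom(x[nz] - 1, ntot[nz], pq$p, lower.tail = FALSE)

  out <- tibble(
    chrom = carrier$chrom,
    pos = carrier$pos,
    carrier_depth = carrier$depth,
    reference_depth = reference$depth,
    carrier_scaled = cs,
    reference_scaled = rs,
    scr = scr,
    pvalue = pv
  )
  structure(
    out,
    genome = track_genome(carrier),
    carrier_id = track_sample(carrier),
    reference_id = track_sample(reference),
    carrier_mean = mu_c,
    reference_mean = mu_r,
    p = pq$p,
    class = c("scr_tbl", class(out))
  )
}

#' Export per-base tracks as bedGraph for genome-browser inspection
#'
#' Writes one of the per-base columns of an SCR table as a bedGraph with
#' runs of equal value collapsed to intervals.
#'
#' @param scr An `scr_tbl` from [scr_table()].
#' @param path Output path.
#' @param column One of `"carrier_scaled"`, `"reference_scaled"`, `"scr"`,
#'   `"neg_log10_p"`.
#' @return `path`, invisibly.
#' @export
write_scr_bedgraph <- function(scr, path,
                               column = c("scr", "carrier_scaled",
                                          "reference_scaled", "neg_log10_p")) {
  column <- match.arg(column)
  assert_columns(scr, c("chrom", "pos"), "scr")
  val <- if (column == "neg_log10_p") -log10(pmax(scr$pvalue, 1e-300)) else scr[[column]]
  val[is.infinite(val)] <- .Machine$double.xmax
  lines <- character(0)
  for (ch in unique(scr$chrom)) {
    sel <- scr$chrom == ch
    v <- val[sel]
    p <- scr$pos[sel]
    r <- rle(v)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%s", ch, p[starts_i], p[ends_i] + 1L, fmt_num(r$values)
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
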