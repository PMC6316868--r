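# Shared fixture builders: tiny genomes and hand-constructed tracks.

toy_genome <- function(lengths = 10000L, chroms = NULL) {
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(lengths))
  tibble::tibble(chrom = chroms, length = as.integer(lengths))
}

# Dense constant-depth track.
constant_track <- function(genome, depth, sample_id = "s", role = "b_carrier") {
  data <- dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    tibble::tibble(
      chrom = genome$chrom[i],
      pos = 0:(genome$length[i] - 1L),
      depth = depth
    )
  }))
  depth_track(data, genome, sample_id = sample_id, role = role)
}

# Constant baseline with rectangular bumps: bumps is a tibble
# (chrom, start, end, depth).
bump_track <- function(genome, baseline, bumps, sample_id = "s",
                       role = "b_carrier") {
  data <- dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    v <- rep(baseline, genome$length[i])
    b <- bumps[bumps$chrom == genome$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      v[(b$start[j] + 1):b$end[j]] <- b$depth[j]
    }
    tibble::tibble(chrom = genome$chrom[i], pos = 0:(genome$length[i] - 1L),
                   depth = v)
  }))
  depth_track(data, genome, sample_id = sample_id, role = role)
}

# Hand-built per-base table accepted by the block-calling functions.
fake_scr <- function(chrom, scr, pvalue, carrier_scaled = scr,
                     reference_scaled = 1) {
  n <- max(length(scr), length(pvalue))
  tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = 0:(n - 1L),
    carrier_scaled = rep_len(carrier_scaled, n),
    reference_scaled = rep_len(reference_scaled, n),
    scr = rep_len(scr, n),
    pvalue = rep_len(pvalue, n)
  )
}

# Independent exact-summation oracle for the upper binomial tail:
# direct factorial-form pmf terms summed in log space (independent of the
# incomplete-beta route used by the implementation).
binom_tail_oracle <- function(x, n, p) {
  if (x <= 0) return(1)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Naive O(n^2) clustering oracle for gap-merging of positions.
merge_oracle <- function(pos, gap) {
  pos <- sort(unique(pos))
  if (length(pos) == 0) return(list(start = integer(), end = integer()))
  cluster <- integer(length(pos))
  cluster[1] <- 1L
  for (i in seq_along(pos)[-1]) {
    linked <- FALSE
    for (j in seq_len(i - 1)) {
      if (abs(pos[i] - pos[j]) <= gap) {
        cluster[i] <- cluster[j]
        linked <- TRUE
        break
      }
    }
    if (!linked) cluster[i] <- max(cluster[seq_len(i - 1)]) + 1L
  }
  starts <- as.integer(tapply(pos, cluster, min))
  ends <- as.integer(tapply(pos, cluster, max) + 1L)
  o <- order(starts)
  list(start = starts[o], end = ends[o])
}

# Brute-force per-base >=k-of-N support oracle on a toy chromosome.
core_oracle <- function(block_sets, k, chrom_len, chrom = "chr1") {
  cov <- integer(chrom_len)
  for (b in block_sets) {
    b <- b[b$chrom == chrom, , drop = FALSE]
    covered <- logical(chrom_len)
    for (j in seq_len(nrow(b))) {
      covered[(b$start[j] + 1):b$end[j]] <- TRUE
    }
    cov <- cov + covered
  }
  core <- cov >= k
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep] - 1L, end = ends[keep])
}

random_blocks <- function(chrom_len, n, chrom = "chr1", max_w = 400) {
  s <- sort(sample.int(chrom_len - max_w, n))
  w <- sample.int(max_w, n)
  tibble::tibble(chrom = chrom, start = s, end = pmin(s + w, chrom_len))
}
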