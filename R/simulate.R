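default_sim_genome <- function() {
  tibble(chrom = c("chr1", "chr2"), length = c(1000000L, 1000000L))
}

#' Configuration for the paired coverage simulator
#'
#' Defines a diploid A-genome baseline for both samples, with the
#' B-carrying female additionally carrying a haploid B chromosome made of
#' multiples of selected A segments. Expected depth is proportional to
#' copy number: inside a planted segment with `copies = c` the female
#' expectation is `mean_depth_female * (2 + b_ploidy * c) / 2`, baseline
#' elsewhere. Decoys and artifacts emulate the failure modes of real
#' short-read data: simple A-genome duplications in the female (expected
#' SCR 2, below the calling threshold), mappability dropouts scaling both
#' samples' depth (driving the reference's scaled coverage below 1 and
#' exercising the female-scaled copy estimator), and retrogene modes
#' (`true_retrogene`: female elevation over exons only;
#' `divergent_intron`: both samples elevated across the whole gene, the
#' signature of an old full-gene copy whose introns diverged).
#'
#' @param genome Genome index tibble; default two chromosomes of 1 Mb.
#' @param mean_depth_female,mean_depth_male Genome-wide mean depths
#'   (reads/base); defaults 15x and 25x, within the 11.75-52.42x range of
#'   typical resequencing experiments.
#' @param noise `"poisson"` (default), `"negative_binomial"` (overdispersed,
#'   see `dispersion`) or `"none"` (rounded expectations; the noise-free
#'   limit used for analytic checks).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.1.
#' @param segments Tibble `chrom`, `start`, `end`, `copies` (>= 1) of
#'   planted B-homologous segments; must be pairwise disjoint.
#' @param a_duplications Tibble `chrom`, `start`, `end` of simple
#'   duplications in the female A genome (depth x2 in the female only).
#' @param dropouts Tibble `chrom`, `start`, `end`, `retention` (< 1) of
#'   low-mappability regions scaling both samples' expected depth.
#' @param retrogenes Tibble `chrom`, `start`, `end`, `mode`
#'   (`"true_retrogene"`/`"divergent_intron"`), `copies`, plus an `exons`
#'   list column of data frames with `start`/`end`.
#' @param b_ploidy Number of B chromosomes per cell (default 1, a single
#'   haploid B).
#' @param seed Integer seed; simulation is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = default_sim_genome(),
                       mean_depth_female = 15, mean_depth_male = 25,
                       noise = c("poisson", "negative_binomial", "none"),
                       dispersion = 0.1,
                       segments = NULL, a_duplications = NULL,
                       dropouts = NULL, retrogenes = NULL,
                       b_ploidy = 1, seed = 1L) {
  noise <- match.arg(noise)
  genome <- genome_index(genome)
  if (mean_depth_female <= 0 || mean_depth_male <= 0) {
    abort("Mean depths must be positive.")
  }
  if (!is.null(segments) && nrow(segments) > 0) {
    assert_columns(segments, c("chrom", "start", "end", "copies"), "segments")
    assert_intervals(segments, "segments", genome = genome)
    if (any(segments$copies < 1)) {
      abort("Planted segment copy numbers must be >= 1.")
    }
    red <- reduce_intervals(select(segments, "chrom", "start", "end"))
    if (footprint_bp(red) != footprint_bp(segments)) {
      abort("Planted segments must be pairwise disjoint.")
    }
  }
  for (nm in c("a_duplications", "dropouts")) {
    iv <- get(nm)
    if (!is.null(iv) && nrow(iv) > 0) assert_intervals(iv, nm, genome = genome)
  }
  if (!is.null(dropouts) && nrow(dropouts) > 0) {
    assert_columns(dropouts, "retention", "dropouts")
    if (any(dropouts$retention <= 0 | dropouts$retention >= 1)) {
      abort("Dropout retention must be in (0, 1).")
    }
  }
  if (!is.null(retrogenes) && nrow(retrogenes) > 0) {
    assert_columns(retrogenes, c("chrom", "start", "end", "mode", "copies",
                                 "exons"), "retrogenes")
    if (!all(retrogenes$mode %in% c("true_retrogene", "divergent_intron"))) {
      abort("Retrogene mode must be true_retrogene or divergent_intron.")
    }
  }
  structure(list(
    genome = genome,
    mean_depth_female = mean_depth_female,
    mean_depth_male = mean_depth_male,
    noise = noise, dispersion = dispersion,
    segments = segments, a_duplications = a_duplications,
    dropouts = dropouts, retrogenes = retrogenes,
    b_ploidy = b_ploidy, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Randomly place disjoint B segments for a simulation
#'
#' Greedy random placement of `n` non-overlapping segments with lengths
#' uniform in `[min_len, max_len]`, copy numbers drawn from `copies`, and
#' at least `min_gap` bp between segments (so merged block calls cannot
#' bridge two truth segments).
#'
#' @param genome Genome index tibble.
#' @param n Number of segments.
#' @param min_len,max_len Segment length bounds (bp).
#' @param copies Pool of true copy numbers to sample from.
#' @param min_gap Minimum separation between segments (bp).
#' @return Segment tibble suitable for [sim_config()].
#' @export
plant_segments <- function(genome, n = 20, min_len = 1000, max_len = 20000,
                           copies = c(4, 8, 16, 50), min_gap = 2000) {
  genome <- genome_index(genome)
  placed <- tibble(chrom = character(), start = integer(), end = integer(),
                   copies = numeric())
  tries <- 0
  while (nrow(placed) < n && tries < 10000 * n) {
    tries <- tries + 1
    i <- sample.int(nrow(genome), 1, prob = genome$length)
    len <- sample(min_len:max_len, 1)
    if (genome$length[i] <= len) next
    s <- sample.int(genome$length[i] - len, 1)
    e <- s + len
    same <- placed[placed$chrom == genome$chrom[i], ]
    if (nrow(same) > 0 &&
        any(s < same$end + min_gap & e > same$start - min_gap)) {
      next
    }
    placed <- bind_rows(placed, tibble(
      chrom = genome$chrom[i], start = as.integer(s), end = as.integer(e),
      copies = sample(copies, 1)
    ))
  }
  if (nrow(placed) < n) {
    abort("Could not place the requested segments; genome too crowded.")
  }
  arrange(placed, .data$chrom, .data$start)
}

#' Simulate a B-carrier / B-lacking depth-track pair with ground truth
#'
#' Draws per-base depths around the expected coverage surface implied by
#' the configuration (see [sim_config()]) and returns dense depth tracks
#' for both samples plus a truth table of everything planted. The same
#' seed always yields bit-identical tracks.
#'
#' @param config A `sim_config`.
#' @return A list of class `b_sim`: `female` and `male` (`depth_track`s),
#'   `truth` (tibble: `chrom`, `start`, `end`, `type`, `copies`,
#'   `retention`) and `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  draw <- function(lambda) {
    switch(config$noise,
      poisson = rpois(length(lambda), lambda),
      negative_binomial = rnbinom(length(lambda), mu = lambda,
                                  size = 1 / config$dispersion),
      none = as.integer(round(lambda))
    )
  }
  truth <- list()
  add_truth <- function(iv, type, copies = NA_real_, retention = NA_real_) {
    if (is.null(iv) || nrow(iv) == 0) return()
    truth[[length(truth) + 1]] <<- tibble(
      chrom = iv$chrom, start = as.integer(iv$start), end = as.integer(iv$end),
      type = type,
      copies = if ("copies" %in% names(iv)) iv$copies else copies,
      retention = if ("retention" %in% names(iv)) iv$retention else retention
    )
  }

  withr::with_seed(config$seed, {
    fem <- vector("list", nrow(g))
    mal <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      L <- g$length[i]
      ch <- g$chrom[i]
      ff <- rep(1, L) # expected-depth factor, female
      mf <- rep(1, L) # expected-depth factor, male
      seg <- config$segments
      if (!is.null(seg)) {
        for (j in which(seg$chrom == ch)) {
          idx <- (seg$start[j] + 1):seg$end[j]
          ff[idx] <- (2 + config$b_ploidy * seg$copies[j]) / 2
        }
      }
      dup <- config$a_duplications
      if (!is.null(dup)) {
        for (j in which(dup$chrom == ch)) {
          idx <- (dup$start[j] + 1):dup$end[j]
          ff[idx] <- ff[idx] * 2
        }
      }
      rg <- config$retrogenes
      if (!is.null(rg)) {
        for (j in which(rg$chrom == ch)) {
          if (rg$mode[j] == "true_retrogene") {
            ex <- rg$exons[[j]]
            for (k in seq_len(nrow(ex))) {
              idx <- (ex$start[k] + 1):ex$end[k]
              ff[idx] <- (2 + config$b_ploidy * rg$copies[j]) / 2
            }
          } else { # divergent_intron: whole-gene elevation in both samples
            idx <- (rg$start[j] + 1):rg$end[j]
            ff[idx] <- ff[idx] * 2
            mf[idx] <- mf[idx] * 2
          }
        }
      }
      dr <- config$dropouts
      if (!is.null(dr)) {
        for (j in which(dr$chrom == ch)) {
          idx <- (dr$start[j] + 1):dr$end[j]
          ff[idx] <- ff[idx] * dr$retention[j]
          mf[idx] <- mf[idx] * dr$retention[j]
        }
      }
      fem[[i]] <- tibble(
        chrom = rep(ch, L), pos = 0:(L - 1L),
        depth = as.integer(draw(config$mean_depth_female * ff))
      )
      mal[[i]] <- tibble(
        chrom = rep(ch, L), pos = 0:(L - 1L),
        depth = as.integer(draw(config$mean_depth_male * mf))
      )
    }
    female <- depth_track(bind_rows(fem), g, sample_id = "sim_female",
                          role = "b_carrier")
    male <- depth_track(bind_rows(mal), g, sample_id = "sim_male",
                        role = "nob_reference")

    add_truth(config$segments, "b_segment")
    add_truth(config$a_duplications, "a_duplication", copies = 2)
    add_truth(config$dropouts, "mappability_dropout")
    rg <- config$retrogenes
    if (!is.null(rg) && nrow(rg) > 0) {
      add_truth(rg[, c("chrom", "start", "end", "copies")],
                type = ifelse(rg$mode == "true_retrogene",
                              "retrogene", "divergent_intron"))
      for (j in seq_len(nrow(rg))) {
        ex <- rg$exons[[j]]
        if (nrow(ex) > 0) {
          add_truth(tibble(chrom = rg$chrom[j], start = ex$start, end = ex$end,
                           copies = rg$copies[j]),
                    type = paste0(ifelse(rg$mode[j] == "true_retrogene",
                                         "retrogene", "divergent_intron"),
                                  "_exon"))
        }
      }
    }
    truth_tbl <- if (length(truth) > 0) {
      arrange(bind_rows(truth), .data$chrom, .data$start)
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             type = character(), copies = numeric(), retention = numeric())
    }
    structure(
      list(female = female, male = male, truth = truth_tbl, config = config),
      class = "b_sim"
    )
  })
}

#' Score called blocks against simulator ground truth
#'
#' A truth segment counts as recovered when the called blocks overlapping
#' it cover at least 50% of the segment and the overlap is at least 50%
#' of those blocks' combined length (reciprocal overlap). Precision is
#' the fraction of the called footprint lying inside the truth footprint
#' expanded by `tolerance` bp on each side. Breakpoint error is the mean
#' of the start- and end-edge distances between a recovered segment and
#' the span of its overlapping blocks.
#'
#' @param blocks Called block tibble (ideally after
#'   [estimate_copy_number()], so copy errors can be scored).
#' @param truth Truth tibble from [simulate_pair()]; only rows with
#'   `type == "b_segment"` are scored as positives.
#' @param tolerance Breakpoint slack for the precision footprint (bp).
#' @return List with `per_segment` (one row per truth segment:
#'   `overlap_bp`, `recovered`, `breakpoint_error`, `est_copies`,
#'   `copy_rel_error`) and `metrics` (one row: `sensitivity`, `precision`,
#'   `mean_breakpoint_error`, `mean_copy_rel_error`, `n_segments`,
#'   `n_recovered`, `called_footprint_bp`).
#' @export
evaluate_recovery <- function(blocks, truth, tolerance = 300) {
  segs <- truth[truth$type == "b_segment", , drop = FALSE]
  have_copies <- "copies" %in% names(blocks)
  per <- lapply(seq_len(nrow(segs)), function(i) {
    tch <- segs$chrom[i]; ts <- segs$start[i]; te <- segs$end[i]
    b <- blocks[blocks$chrom == tch & blocks$end > ts & blocks$start < te, ,
                drop = FALSE]
    ov <- if (nrow(b) > 0) sum(pmin(b$end, te) - pmax(b$start, ts)) else 0
    called_len <- if (nrow(b) > 0) sum(b$end - b$start) else 0
    recovered <- ov >= 0.5 * (te - ts) && ov >= 0.5 * called_len && ov > 0
    bp_err <- if (nrow(b) > 0) {
      (abs(min(b$start) - ts) + abs(max(b$end) - te)) / 2
    } else {
      NA_real_
    }
    est <- if (nrow(b) > 0 && have_copies) {
      w <- pmin(b$end, te) - pmax(b$start, ts)
      sum(w * b$copies) / sum(w)
    } else {
      NA_real_
    }
    tibble(
      chrom = tch, start = ts, end = te, true_copies = segs$copies[i],
      overlap_bp = ov, recovered = recovered, breakpoint_error = bp_err,
      est_copies = est,
      copy_rel_error = if (is.na(est)) NA_real_ else
        abs(est - segs$copies[i]) / segs$copies[i]
    )
  })
  per <- if (length(per) > 0) bind_rows(per) else tibble(
    chrom = character(), start = integer(), end = integer(),
    true_copies = numeric(), overlap_bp = numeric(), recovered = logical(),
    breakpoint_error = numeric(), est_copies = numeric(),
    copy_rel_error = numeric()
  )
  footprint <- reduce_intervals(blocks[, c("chrom", "start", "end")])
  fp_bp <- footprint_bp(footprint)
  precision <- if (fp_bp == 0) NA_real_ else {
    expanded <- reduce_intervals(tibble(
      chrom = segs$chrom,
      start = pmax(segs$start - tolerance, 0),
      end = segs$end + tolerance
    ))
    overlap_bp(footprint, expanded) / fp_bp
  }
  rec <- per$recovered %in% TRUE
  metrics <- tibble(
    sensitivity = if (nrow(per) > 0) mean(per$recovered) else NA_real_,
    precision = precision,
    mean_breakpoint_error = if (any(rec)) mean(per$breakpoint_error[rec]) else NA_real_,
    mean_copy_rel_error = if (any(rec & !is.na(per$copy_rel_error))) {
      mean(per$copy_rel_error[rec], na.rm = TRUE)
    } else {
      NA_real_
    },
    n_segments = nrow(per),
    n_recovered = sum(rec),
    called_footprint_bp = fp_bp
  )
  list(per_segment = per, metrics = metrics)
}
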