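#' Construct a per-base depth track
#'
#' A depth track is a dense tibble with one row per base of the genome:
#' columns `chrom`, `pos` (0-based start of the base) and `depth`
#' (non-negative integer read depth). Bases absent from `data` are filled
#' with depth 0, and zeros count toward the genome-wide mean depth — the
#' mean used for coverage scaling is total depth divided by total genome
#' length. Sample metadata travels as attributes (`sample_id`, `role`,
#' `genome`, `mean_depth`).
#'
#' @param data A data frame with columns `chrom`, `pos` (0-based) and
#'   `depth`; may be sparse (missing bases are depth 0).
#' @param genome Genome index tibble (see [genome_index()]).
#' @param sample_id Sample label used in block ids and reports.
#' @param role One of `"b_carrier"`, `"nob_reference"`, `"control"`.
#' @param mean_depth Optional externally supplied genome-wide mean depth;
#'   must agree with the recomputed value within 1e-6 relative.
#' @return A `depth_track` tibble (dense, one row per base).
#' @export
depth_track <- function(data, genome, sample_id = "sample",
                        role = c("b_carrier", "nob_reference", "control"),
                        mean_depth = NULL) {
  role <- match.arg(role)
  genome <- genome_index(genome)
  assert_columns(data, c("chrom", "pos", "depth"), "data")
  if (nrow(data) > 0) {
    unknown <- setdiff(unique(data$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(sprintf(
        "Depth data uses chromosome(s) absent from the genome index: %s",
        paste(unknown, collapse = ", ")
      ))
    }
    if (any(data$depth < 0)) {
      abort("Negative depth values are not allowed.")
    }
    len <- setNames(genome$length, genome$chrom)
    oob <- which(data$pos < 0 | data$pos >= len[data$chrom])
    if (length(oob) > 0) {
      i <- oob[1]
      abort(sprintf(
        "Depth position out of chromosome bounds: %s pos %d (0-based, length %d).",
        data$chrom[i], data$pos[i], len[data$chrom[i]]
      ))
    }
  }
  parts <- if (nrow(data) > 0) split(data, factor(data$chrom, levels = genome$chrom)) else NULL
  dense <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    v <- integer(L)
    p <- parts[[genome$chrom[i]]]
    if (!is.null(p) && nrow(p) > 0) {
      v[p$pos + 1L] <- as.integer(p$depth)
    }
    dense[[i]] <- tibble(
      chrom = rep(genome$chrom[i], L),
      pos = 0:(L - 1L),
      depth = v
    )
  }
  out <- bind_rows(dense)
  mu <- sum(as.numeric(out$depth)) / genome_length(genome)
  if (!is.null(mean_depth)) {
    if (abs(mean_depth - mu) > 1e-6 * max(mu, .Machine$double.eps)) {
      abort(sprintf(
        "Supplied mean depth %.8g disagrees with recomputed value %.8g.",
        mean_depth, mu
      ))
    }
  }
  new_depth_track(out, genome, sample_id, role, mu)
}

new_depth_track <- function(tbl, genome, sample_id, role, mean_depth) {
  structure(
    as_tibble(tbl),
    genome = genome,
    sample_id = sample_id,
    role = role,
    mean_depth = mean_depth,
    class = c("depth_track", class(as_tibble(tbl)))
  )
}

#' @rdname depth_track
#' @param x A `depth_track`.
#' @export
is_depth_track <- function(x) inherits(x, "depth_track")

#' Accessors for depth-track metadata
#'
#' @param x A `depth_track`.
#' @return `track_mean_depth()` the genome-wide mean depth (reads/base);
#'   `track_genome()` the genome index; `track_sample()` the sample id;
#'   `track_role()` the sample role.
#' @export
track_mean_depth <- function(x) attr(x, "mean_depth")

#' @rdname track_mean_depth
#' @export
track_genome <- function(x) attr(x, "genome")

#' @rdname track_mean_depth
#' @export
track_sample <- function(x) attr(x, "sample_id") %||% "sample"

#' @rdname track_mean_depth
#' @export
track_role <- function(x) attr(x, "role")

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf(
    "<depth_track> sample=%s role=%s chroms=%d genome=%.0f bp mean_depth=%.4f\n",
    track_sample(x), track_role(x), nrow(track_genome(x)),
    genome_length(track_genome(x)), track_mean_depth(x)
  ))
  NextMethod()
}

#' Read a per-base depth file
#'
#' Reads either a samtools-depth-style TSV (`chrom<TAB>pos<TAB>depth`,
#' positions 1-based) or a bedGraph (`chrom<TAB>start<TAB>end<TAB>depth`,
#' 0-based half-open). The dialect is auto-detected from the file
#' extension (`.bedgraph`/`.bg` means bedGraph) and can be overridden.
#' Bases absent from the file get depth 0; the genome-wide mean depth is
#' computed over all bases including those zeros.
#'
#' @param path Path to the depth file.
#' @param genome Genome index tibble.
#' @param sample_id,role Sample metadata, see [depth_track()].
#' @param format `"auto"`, `"depth"` (1-based TSV) or `"bedgraph"`.
#' @return A `depth_track`.
#' @export
read_depth <- function(path, genome, sample_id = basename(path),
                       role = c("b_carrier", "nob_reference", "control"),
                       format = c("auto", "depth", "bedgraph")) {
  role <- match.arg(role)
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Depth file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedgraph" else "depth"
  }
  if (format == "depth") {
    tbl <- readr::read_tsv(
      path,
      col_names = c("chrom", "pos1", "depth"),
      col_types = readr::cols(
        chrom = readr::col_character(),
        pos1 = readr::col_double(),
        depth = readr::col_double()
      ),
      comment = "#", progress = FALSE
    )
    if (any(is.na(tbl$pos1)) || any(is.na(tbl$depth))) {
      abort(sprintf("Malformed depth record in %s.", path))
    }
    sparse <- tibble(
      chrom = tbl$chrom,
      pos = as.integer(tbl$pos1 - 1), # 1-based file -> 0-based internal
      depth = tbl$depth
    )
  } else {
    tbl <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "depth"),
      col_types = readr::cols(
        chrom = readr::col_character(),
        start = readr::col_double(),
        end = readr::col_double(),
        depth = readr::col_double()
      ),
      comment = "#", progress = FALSE
    )
    tbl <- tbl[!grepl("^track", tbl$chrom), , drop = FALSE]
    if (nrow(tbl) > 0 && any(tbl$end <= tbl$start)) {
      abort(sprintf("Malformed bedGraph interval in %s.", path))
    }
    w <- as.integer(tbl$end - tbl$start)
    sparse <- tibble(
      chrom = rep(tbl$chrom, w),
      pos = as.integer(sequence(w, from = tbl$start)),
      depth = rep(tbl$depth, w)
    )
  }
  depth_track(sparse, genome, sample_id = sample_id, role = role)
}

#' Write a depth track as a samtools-depth-style TSV
#'
#' Zero-depth bases are omitted (the reader restores them), so files stay
#' compact; positions are written 1-based to match the `samtools depth`
#' dialect.
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(track, path) {
  stopifnot(is_depth_track(track))
  nz <- track[track$depth > 0, c("chrom", "pos", "depth")]
  readr::write_tsv(
    tibble(chrom = nz$chrom, pos = nz$pos + 1L, depth = nz$depth),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
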