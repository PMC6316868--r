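#' Run the end-to-end B-block analysis
#'
#' Orchestrates the whole workflow for a table of samples: load depth
#' tracks, build per-base SCR tables against the B-lacking reference,
#' call blocks, intersect B-carrier block sets into core blocks, estimate
#' copy numbers, assemble per-sample A-space/B-space reports and
#' (optionally) gene-overlap reports. All outputs are written under
#' `out_dir` with a provenance comment header (configuration hash and
#' thresholds); identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param samples Tibble with columns `sample_id`, `role` (one
#'   `nob_reference` plus any number of `b_carrier`/`control` rows) and
#'   `path` (depth TSV or bedGraph). A `depth_track` list column `track`
#'   may be supplied instead of `path`.
#' @param genome Genome index tibble or path to a FAI/chrom-sizes file.
#' @param out_dir Output directory (created if needed).
#' @param annotation Optional path to a BED/GFF3 gene annotation, or a
#'   gene tibble from [read_genes()].
#' @param scr_min,alpha,merge_gap,min_len,min_frac Calling thresholds;
#'   defaults are the standard ones (SCR >= 3, p <= 0.001, merge within
#'   300 bp, keep blocks > 500 bp with > 10% passing positions).
#' @param core_k Samples required for a core base; default is
#'   `n_carriers - 1` (all-but-one, the "at least 12 of 13" rule), or 1
#'   for a single carrier.
#' @return Invisibly, a list: `calls` (named list of `bblock_calls`),
#'   `blocks` (named list of copy-annotated block tibbles), `core`,
#'   `quant` (per-sample report tibble), `genes` (named list of overlap
#'   reports, if annotated), `shared_genes`, `files`, `provenance`.
#' @export
run_pipeline <- function(samples, genome, out_dir,
                         annotation = NULL,
                         scr_min = 3, alpha = 0.001, merge_gap = 300,
                         min_len = 500, min_frac = 0.10,
                         core_k = NULL) {
  assert_columns(samples, c("sample_id", "role"), "samples")
  if (is.character(genome)) genome <- read_genome_index(genome)
  genome <- genome_index(genome)
  if (anyDuplicated(samples$sample_id)) abort("Duplicate sample_id in `samples`.")
  bad_role <- setdiff(samples$role, c("b_carrier", "nob_reference", "control"))
  if (length(bad_role) > 0) {
    abort(sprintf("Unknown sample role(s): %s", paste(bad_role, collapse = ", ")))
  }
  ref_rows <- which(samples$role == "nob_reference")
  if (length(ref_rows) != 1) {
    abort("Exactly one `nob_reference` sample is required.")
  }
  carriers <- which(samples$role %in% c("b_carrier", "control"))
  if (length(carriers) == 0) {
    abort("At least one `b_carrier` or `control` sample is required.")
  }
  n_b <- sum(samples$role == "b_carrier")
  core_k <- core_k %||% max(1L, n_b - 1L)
  if (n_b > 0 && (core_k < 1 || core_k > n_b)) {
    abort(sprintf("`core_k` must be between 1 and the %d B carriers.", n_b))
  }
  # fail fast on missing files before any computation
  if (!"track" %in% names(samples)) {
    assert_columns(samples, "path", "samples")
    missing <- samples$path[!file.exists(samples$path)]
    if (length(missing) > 0) {
      abort(sprintf("Depth file(s) not found: %s", paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(annotation) && is.character(annotation) &&
      !file.exists(annotation)) {
    abort(sprintf("Annotation file not found: %s", annotation))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  load_track <- function(i) {
    if ("track" %in% names(samples) && !is.null(samples$track[[i]])) {
      tr <- samples$track[[i]]
      stopifnot(is_depth_track(tr))
      if (!same_genome(track_genome(tr), genome)) {
        abort(sprintf("Sample %s is on a different genome index.",
                      samples$sample_id[i]))
      }
      tr
    } else {
      read_depth(samples$path[i], genome, sample_id = samples$sample_id[i],
                 role = samples$role[i])
    }
  }

  config <- list(
    samples = samples[, intersect(c("sample_id", "role", "path"), names(samples))],
    thresholds = list(scr_min = scr_min, alpha = alpha, merge_gap = merge_gap,
                      min_len = min_len, min_frac = min_frac, core_k = core_k),
    genome = genome
  )
  prov <- c(
    sprintf("bblockr %s", as.character(packageVersion("bblockr"))),
    sprintf("config_hash=%s", rlang::hash(config)),
    sprintf("scr_min=%g alpha=%g merge_gap=%d min_len=%d min_frac=%g core_k=%d",
            scr_min, alpha, merge_gap, min_len, min_frac, core_k)
  )

  reference <- load_track(ref_rows)
  genes <- NULL
  if (!is.null(annotation)) {
    genes <- if (is.character(annotation)) {
      read_genes(annotation, genome = genome)
    } else {
      annotation
    }
  }

  calls <- list()
  blocks <- list()
  scrs <- list()
  files <- list()
  for (i in carriers) {
    sid <- samples$sample_id[i]
    tr <- load_track(i)
    scr <- scr_table(tr, reference)
    cl <- call_blocks(scr, scr_min = scr_min, alpha = alpha,
                      merge_gap = merge_gap, min_len = min_len,
                      min_frac = min_frac)
    bl <- estimate_copy_number(cl$blocks)
    bed <- file.path(out_dir, paste0(sid, ".blocks.bed"))
    write_blocks(bl, bed, header = c(prov, sprintf("sample=%s", sid)))
    calls[[sid]] <- cl
    blocks[[sid]] <- bl
    scrs[[sid]] <- scr
    files[[paste0(sid, "_blocks")]] <- bed
  }

  carrier_ids <- samples$sample_id[samples$role == "b_carrier"]
  core <- if (length(carrier_ids) > 0) {
    core_blocks(blocks[carrier_ids], k = core_k)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           support = integer())
  }
  core_bed <- file.path(out_dir, "core.blocks.bed")
  write_core_blocks(core, core_bed, header = prov)
  files$core_blocks <- core_bed

  quant <- bind_rows(lapply(names(calls), function(sid) {
    quantify_sample(calls[[sid]], scrs[[sid]], core = core)
  }))
  quant_tsv <- file.path(out_dir, "quantification.tsv")
  readr::write_lines(paste0("#", prov), quant_tsv)
  readr::write_tsv(quant, quant_tsv, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  files$quantification <- quant_tsv

  gene_reports <- NULL
  shared <- NULL
  if (!is.null(genes)) {
    gene_reports <- lapply(names(blocks), function(sid) {
      genes_in_blocks(genes, blocks[[sid]])
    })
    names(gene_reports) <- names(blocks)
    for (sid in names(gene_reports)) {
      gp <- file.path(out_dir, paste0(sid, ".genes.tsv"))
      rep_tbl <- gene_reports[[sid]]
      flat <- mutate(rep_tbl,
                     blocks_hit = vapply(rep_tbl$blocks_hit, paste,
                                         character(1), collapse = ","))
      readr::write_lines(paste0("#", prov), gp)
      readr::write_tsv(flat, gp, append = TRUE, col_names = TRUE,
                       progress = FALSE)
      files[[paste0(sid, "_genes")]] <- gp
    }
    if (length(gene_reports) >= 2) {
      sets <- lapply(gene_reports, function(r) r$gene_id)
      shared <- shared_gene_counts(
        sets, mode = if (length(sets) <= 5) "venn" else "at_least"
      )
      jsonlite::write_json(
        shared, file.path(out_dir, "shared_genes.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
      )
      files$shared_genes <- file.path(out_dir, "shared_genes.json")
    }
  }

  summary <- list(
    provenance = prov,
    thresholds = config$thresholds,
    samples = lapply(names(calls), function(sid) {
      as.list(glance(calls[[sid]]))
    }),
    core = list(n_intervals = nrow(core), a_space_bp = footprint_bp(core))
  )
  sm <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$summary <- sm

  invisible(list(
    calls = calls, blocks = blocks, core = core, quant = quant,
    genes = gene_reports, shared_genes = shared, files = files,
    provenance = prov
  ))
}
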