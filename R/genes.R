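#' Read gene annotations from BED or GFF3
#'
#' Gene-level intervals are what block overlap is computed against. For
#' GFF3, records of type `gene` are used and exon intervals (linked
#' through their transcript parents) are attached as a list column so
#' intron-only overlaps can be flagged. For BED, each record is one gene
#' (BED12 block structure, when present, populates the exon column).
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param genome Optional genome index; gene intervals are validated
#'   against chromosome bounds when given.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and a list column `exons` (each element a data
#'   frame with `start`/`end`, possibly empty).
#' @export
read_genes <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  is_gff <- grepl("\\.(gff3?|gtf)$", tolower(path))
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) abort(sprintf("Malformed annotation %s: %s", path,
                                      conditionMessage(e)))
  )
  if (is_gff) {
    meta <- as.data.frame(gr)
    types <- tolower(as.character(meta$type %||% "gene"))
    gsel <- types == "gene"
    if (!any(gsel)) abort(sprintf("No `gene` records found in %s.", path))
    gid <- as.character(meta$ID %||% meta$Name %||% meta$gene_id)[gsel]
    if (all(is.na(gid))) {
      abort(sprintf("Gene records in %s lack ID/Name attributes.", path))
    }
    genes <- tibble(
      gene_id = gid,
      chrom = as.character(meta$seqnames)[gsel],
      start = meta$start[gsel] - 1L,
      end = meta$end[gsel]
    )
    # exon -> transcript -> gene linkage (one level of Parent indirection)
    parent_of <- function(p) vapply(p, function(z) {
      if (length(z) == 0) NA_character_ else as.character(z[[1]])
    }, character(1))
    ids <- as.character(meta$ID %||% rep(NA_character_, nrow(meta)))
    parents <- if ("Parent" %in% names(meta)) parent_of(meta$Parent) else
      rep(NA_character_, nrow(meta))
    tx_parent <- setNames(parents, ids)
    esel <- types == "exon"
    exon_gene <- parents[esel]
    hop <- exon_gene %in% ids[!gsel & !is.na(ids)] & !(exon_gene %in% genes$gene_id)
    exon_gene[hop] <- tx_parent[exon_gene[hop]]
    exons_tbl <- tibble(
      gene_id = exon_gene,
      start = meta$start[esel] - 1L,
      end = meta$end[esel]
    )
    genes$exons <- lapply(genes$gene_id, function(g) {
      e <- exons_tbl[!is.na(exons_tbl$gene_id) & exons_tbl$gene_id == g,
                     c("start", "end")]
      as.data.frame(e)
    })
  } else {
    meta <- as.data.frame(gr)
    gid <- if ("name" %in% names(meta)) as.character(meta$name) else
      sprintf("gene%05d", seq_len(nrow(meta)))
    genes <- tibble(
      gene_id = gid,
      chrom = as.character(meta$seqnames),
      start = meta$start - 1L,
      end = meta$end
    )
    if ("blocks" %in% names(meta) || !is.null(gr$blocks)) {
      bl <- gr$blocks
      genes$exons <- lapply(seq_along(bl), function(i) {
        b <- bl[[i]]
        data.frame(start = genes$start[i] + BiocGenerics::start(b) - 1L,
                   end = genes$start[i] + BiocGenerics::end(b))
      })
    } else {
      genes$exons <- rep(list(data.frame(start = integer(), end = integer())),
                         nrow(genes))
    }
  }
  if (anyNA(genes$gene_id)) {
    abort(sprintf("Malformed annotation %s: gene without an identifier.", path))
  }
  if (!is.null(genome)) assert_intervals(genes, "genes", genome = genome_index(genome))
  arrange(genes, .data$chrom, .data$start, .data$gene_id)
}

#' Genes overlapping B blocks
#'
#' One record per annotated gene with at least 1 bp of overlap with the
#' sample's blocks. A gene is `complete` when its interval is fully
#' contained in the union of the blocks (large B-derived regions are often
#' fragmented into several block calls, so containment is tested against
#' the union, not any single block), otherwise `partial`. Overlap is
#' gene-level; when exon intervals are available and the overlap touches
#' no exon, the record is flagged `intron_only` and a warning is raised
#' (intronic insertions can masquerade as B-located genes).
#'
#' @param genes Gene tibble from [read_genes()] (columns `gene_id`,
#'   `chrom`, `start`, `end`, optional `exons` list column).
#' @param blocks Block tibble (columns `chrom`, `start`, `end`, optional
#'   `block_id`).
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `overlap_class` (`"complete"`/`"partial"`), `overlapping_bp`,
#'   `blocks_hit` (list of block ids), `intron_only` (logical; NA when no
#'   exon structure is known), ordered by (chrom, start, gene_id).
#' @export
genes_in_blocks <- function(genes, blocks) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  assert_intervals(blocks, "blocks")
  if (nrow(genes) == 0 || nrow(blocks) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), overlap_class = character(),
      overlapping_bp = integer(), blocks_hit = list(),
      intron_only = logical()
    ))
  }
  if (!"block_id" %in% names(blocks)) {
    blocks$block_id <- sprintf("b%05d", seq_len(nrow(blocks)))
  }
  res <- vector("list", 0)
  for (ch in intersect(unique(genes$chrom), unique(blocks$chrom))) {
    g <- genes[genes$chrom == ch, ]
    b <- blocks[blocks$chrom == ch, ]
    gr <- IRanges::IRanges(start = g$start + 1, end = g$end)
    br <- IRanges::IRanges(start = b$start + 1, end = b$end)
    bu <- IRanges::reduce(br)
    # overlap bp against the union of blocks
    hits_u <- IRanges::findOverlaps(gr, bu)
    ov <- IRanges::pintersect(
      gr[S4Vectors::queryHits(hits_u)], bu[S4Vectors::subjectHits(hits_u)]
    )
    ov_bp <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits_u), sum)
    idx <- as.integer(names(ov_bp))
    if (length(idx) == 0) next
    # ids of the original (possibly fragmented) blocks hit
    hits_b <- IRanges::findOverlaps(gr, br)
    hit_ids <- split(b$block_id[S4Vectors::subjectHits(hits_b)],
                     S4Vectors::queryHits(hits_b))
    gsel <- g[idx, ]
    gsel$overlapping_bp <- as.integer(ov_bp)
    gsel$overlap_class <- ifelse(
      gsel$overlapping_bp == gsel$end - gsel$start, "complete", "partial"
    )
    gsel$blocks_hit <- lapply(as.character(idx), function(i) {
      unname(hit_ids[[i]]) %||% character(0)
    })
    gsel$intron_only <- vapply(seq_len(nrow(gsel)), function(i) {
      ex <- if ("exons" %in% names(gsel)) gsel$exons[[i]] else NULL
      if (is.null(ex) || nrow(ex) == 0) return(NA)
      er <- IRanges::IRanges(start = ex$start + 1, end = ex$end)
      sum(IRanges::width(IRanges::intersect(IRanges::reduce(er), bu))) == 0
    }, logical(1))
    res[[length(res) + 1]] <- gsel
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(genes_in_blocks(genes[0, ], blocks[0, ]))
  }
  out <- select(out, "gene_id", "chrom", "start", "end", "overlap_class",
                "overlapping_bp", "blocks_hit", "intron_only")
  out <- arrange(out, .data$chrom, .data$start, .data$gene_id)
  n_intr <- sum(out$intron_only %in% TRUE)
  if (n_intr > 0) {
    warn(sprintf(
      "%d gene(s) overlap blocks only in introns; such hits can reflect intronic insertions rather than B-located gene copies.",
      n_intr
    ))
  }
  out
}

#' Shared-gene counts across samples
#'
#' Partitions the union of per-sample gene-id sets into Venn regions
#' (every membership pattern over the samples) and tallies "shared by at
#' least k samples" totals. Full Venn enumeration is limited to 5 sets;
#' for more samples use `mode = "at_least"`.
#'
#' @param sets Named list of character vectors (gene ids per sample).
#' @param mode `"venn"` (default, 2-5 sets) or `"at_least"` (any N).
#' @return A list with `regions` (tibble: `pattern` e.g. `"101"`,
#'   `members`, `count`; only in venn mode), `at_least` (tibble: `k`,
#'   `count` of genes present in >= k sets) and `n_union`.
#' @export
shared_gene_counts <- function(sets, mode = c("venn", "at_least")) {
  mode <- match.arg(mode)
  if (!is.list(sets) || length(sets) < 2) {
    abort("`sets` must be a list of at least two gene-id vectors.")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- sprintf("set%d", seq_along(sets))
  }
  N <- length(sets)
  if (mode == "venn" && N > 5) {
    abort("Full Venn partition is limited to 5 sets; use mode = \"at_least\".")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  n_sets_per_gene <- rowSums(membership)
  at_least <- tibble(
    k = seq_len(N),
    count = vapply(seq_len(N), function(k) sum(n_sets_per_gene >= k), integer(1))
  )
  regions <- NULL
  if (mode == "venn") {
    pattern <- apply(membership, 1, function(m) paste0(as.integer(m), collapse = ""))
    all_patterns <- apply(
      expand.grid(rep(list(c(1L, 0L)), N))[, N:1, drop = FALSE], 1,
      paste0, collapse = ""
    )
    all_patterns <- all_patterns[all_patterns != strrep("0", N)]
    counts <- table(factor(pattern, levels = all_patterns))
    regions <- tibble(
      pattern = all_patterns,
      members = vapply(all_patterns, function(p) {
        paste(names(sets)[strsplit(p, "")[[1]] == "1"], collapse = "&")
      }, character(1)),
      count = as.integer(counts)
    )
  }
  list(regions = regions, at_least = at_least, n_union = length(universe))
}
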