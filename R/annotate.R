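#' Read gene records from a GFF3 annotation
#'
#' Imports a GFF3 file and keeps only features of type `gene`, returning
#' their coordinates (1-based inclusive) and identifiers sorted by chromosome
#' then start. Duplicate gene IDs are an error.
#'
#' @param path GFF3 file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `gene_name` (`NA` when absent).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$gene_id)
  nms <- if (!is.null(gr$Name)) as.character(gr$Name) else rep(NA_character_, length(gr))
  genes <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ids,
    gene_name = nms
  )
  if (anyNA(genes$gene_id)) stop("gene feature without an ID attribute", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene IDs in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(genes, .data$chrom, .data$start)
}

#' Map detected regions onto gene intervals
#'
#' A gene is assigned to a region when their intervals (both 1-based
#' inclusive) intersect by at least one base pair; strand is ignored. Genes
#' partially covered by a region count. The mapping is invariant to the order
#' of regions and genes.
#'
#' @param regions Region tibble (e.g. from [detect_dsrs()]) with `id`,
#'   `chrom`, `start`, `end`.
#' @param genes Gene tibble from [read_gff_genes()].
#' @return List with `per_region` (tibble: region columns plus `gene_id`,
#'   `gene_name`, one row per region-gene hit; regions with no hit appear
#'   with `NA` gene) and `unique_genes` (deduplicated tibble of hit genes).
#' @export
map_regions_to_genes <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    per <- dplyr::mutate(regions, gene_id = NA_character_,
                         gene_name = NA_character_)
    return(list(per_region = per,
                unique_genes = genes[0, c("gene_id", "gene_name")]))
  }
  rg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end)
  )
  gg <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(rg, gg, ignore.strand = TRUE)
  hit_tbl <- tibble::tibble(
    region_row = S4Vectors::queryHits(hits),
    gene_row = S4Vectors::subjectHits(hits)
  )
  per_region <- regions |>
    dplyr::mutate(region_row = dplyr::row_number()) |>
    dplyr::left_join(hit_tbl, by = "region_row") |>
    dplyr::mutate(
      gene_id = genes$gene_id[.data$gene_row],
      gene_name = genes$gene_name[.data$gene_row]
    ) |>
    dplyr::select(-"region_row", -"gene_row")
  uniq <- genes[sort(unique(hit_tbl$gene_row)), c("gene_id", "gene_name")]
  list(per_region = per_region, unique_genes = tibble::as_tibble(uniq))
}
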