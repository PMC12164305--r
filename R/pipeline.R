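#' Manhattan-plot export table for a pair scan
#'
#' Produces the table a genome-wide FST Manhattan plot consumes: chromosome,
#' position, cumulative genome position, FST and label per SNP, with the two
#' realized quantile thresholds attached as attributes
#' (`fst_threshold_extreme`, `fst_threshold_sig`).
#'
#' @param scan A `pair_scan` from [run_pair_scan()].
#' @return Tibble with `chrom`, `pos`, `cum_pos`, `fst`, `label`.
#' @export
export_manhattan <- function(scan) {
  stopifnot(inherits(scan, "pair_scan"))
  s <- scan$stats
  chroms <- unique(s$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch) {
    max(s$pos[s$chrom == ch])
  }, numeric(1))))[seq_along(chroms)]
  names(offsets) <- chroms
  out <- tibble::tibble(
    chrom = s$chrom, pos = s$pos,
    cum_pos = s$pos + offsets[s$chrom],
    fst = s$fst, label = s$label
  )
  attr(out, "fst_threshold_extreme") <- scan$fst_threshold_extreme
  attr(out, "fst_threshold_sig") <- scan$fst_threshold_sig
  out
}

#' Run configuration for an end-to-end analysis
#'
#' @param vcf Path to the input VCF, or `NULL` when simulating.
#' @param sample_map Path to the sample-to-population TSV, or `NULL` when
#'   simulating.
#' @param sim A [sim_config()] used instead of `vcf` when supplied.
#' @param qc A [qc_config()].
#' @param scan A [scan_config()].
#' @param pairs Two-column data frame of population pairs to scan; default
#'   all pairs among non-outgroup populations present after QC.
#' @param gff Optional GFF3 path; annotation is skipped when `NULL`.
#' @param out_dir Output directory.
#' @param seed Integer seed (forwarded to the simulator when `sim` is used).
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, sample_map = NULL, sim = NULL,
                       qc = qc_config(), scan = scan_config(), pairs = NULL,
                       gff = NULL, out_dir = tempfile("fstscan_run_"),
                       seed = 1L) {
  if (is.null(sim) && (is.null(vcf) || is.null(sample_map))) {
    stop("supply either `sim` or both `vcf` and `sample_map`", call. = FALSE)
  }
  structure(
    list(vcf = vcf, sample_map = sample_map, sim = sim, qc = qc, scan = scan,
         pairs = pairs, gff = gff, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline: QC, structure, pair scans, annotation
#'
#' Orchestrates an end-to-end analysis from a single configuration and writes
#' every stage product into the output directory: QC report, IBS distance
#' matrix, neighbor-joining tree (newick), MDS coordinates, pairwise weighted
#' FST table, per-pair SNP statistics, region tables (TSV and 0-based
#' half-open BED), gene mappings when a GFF3 is supplied, and a run manifest.
#' Re-running with identical inputs reproduces identical files.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results: `panel`,
#'   `qc_report`, `dist`, `tree`, `mds`, `fst_pairs`, `scans` (named list of
#'   `pair_scan`), `gene_maps` (or `NULL`), `paths`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    paths[[name]] <<- path
  }

  if (!is.null(cfg$sim)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed
    panel <- simulate_panel(sim_cfg)$panel
  } else {
    panel <- read_vcf(cfg$vcf, cfg$sample_map)
  }

  qc <- apply_qc(panel, cfg$qc)
  g <- qc$genotypes
  message("qc: ", utils::tail(qc$report$remaining, 1), " of ",
          qc$report$remaining[1], " SNPs retained")
  emit("qc_report.tsv", function(p) write_tsv_plain(qc$report, p))

  d <- ibs_dist(g)
  emit("ibs_distance.tsv", function(p) {
    write_tsv_plain(cbind(sample_id = rownames(d), as.data.frame(unclass(d))), p)
  })
  tree <- nj_tree(d)
  emit("nj_tree.nwk", function(p) write_newick(tree, p))
  mds <- classical_mds(d, k = 2)
  emit("mds_coordinates.tsv", function(p) write_tsv_plain(mds$coordinates, p))

  fst_pairs <- pairwise_fst(g)
  emit("pairwise_fst.tsv", function(p) write_tsv_plain(fst_pairs, p))

  pairs <- cfg$pairs
  if (is.null(pairs)) {
    pops <- unique(g$samples$population)
    pairs <- as.data.frame(t(utils::combn(pops, 2)))
  }
  scans <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    key <- paste0(a, "_vs_", b)
    sc <- run_pair_scan(g, a, b, cfg$scan)
    message("scan ", key, ": ", nrow(sc$regions), " regions")
    scans[[key]] <- sc
    emit(paste0("snp_stats_", key, ".tsv"),
         function(p) write_tsv_plain(export_manhattan(sc), p))
    emit(paste0("dsr_", key, ".tsv"),
         function(p) write_tsv_plain(sc$regions, p))
    emit(paste0("dsr_", key, ".bed"), function(p) {
      r <- sc$regions
      utils::write.table(
        data.frame(r$chrom, r$start - 1L, r$end, r$id),
        p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    })
  }

  gene_maps <- NULL
  if (!is.null(cfg$gff)) {
    genes <- read_gff_genes(cfg$gff)
    gene_maps <- lapply(scans, function(sc) {
      map_regions_to_genes(sc$regions, genes)
    })
    for (key in names(gene_maps)) {
      gm <- gene_maps[[key]]
      emit(paste0("region_genes_", key, ".tsv"),
           function(p) write_tsv_plain(gm$per_region, p))
      emit(paste0("unique_genes_", key, ".tsv"),
           function(p) write_tsv_plain(gm$unique_genes, p))
    }
  }

  emit("manifest.txt", function(p) {
    writeLines(c(
      paste0("fstscan version: ", as.character(utils::packageVersion("fstscan"))),
      paste0("seed: ", cfg$seed),
      paste0("input: ", if (is.null(cfg$sim)) cfg$vcf else "simulated panel"),
      paste0("qc: max_missing_rate=", cfg$qc$max_missing_rate,
             " min_maf=", cfg$qc$min_maf, " hwe_alpha=", cfg$qc$hwe_alpha),
      paste0("scan: q_extreme=", cfg$scan$q_extreme, " q_sig=", cfg$scan$q_sig,
             " alpha=", cfg$scan$alpha, " break_len=", cfg$scan$break_len,
             " min_run=", cfg$scan$min_run),
      paste0("pairs: ", paste(names(scans), collapse = ", "))
    ), p)
  })

  invisible(list(panel = panel, qc_report = qc$report, dist = d, tree = tree,
                 mds = mds, fst_pairs = fst_pairs, scans = scans,
                 gene_maps = gene_maps, paths = paths))
}
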