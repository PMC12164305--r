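#' Genotype panel container
#'
#' Couples a samples x SNPs alternate-allele dosage matrix (entries 0, 1, 2 or
#' `NA` for missing) with per-variant and per-sample metadata tibbles.
#'
#' @param dosages Integer matrix, samples in rows, SNPs in columns.
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (comma-separated when multi-allelic), one row per SNP column.
#' @param samples Tibble with columns `sample_id`, `population`, one row per
#'   dosage row.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, samples) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) != nrow(dosages) || nrow(variants) != ncol(dosages)) {
    stop("dosage dimensions must match samples and variants", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  rownames(dosages) <- samples$sample_id
  structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " SNPs; populations: ",
      paste(unique(x$samples$population), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of SNPs in a panel
#' @param g A `geno_matrix`.
#' @return Integer SNP count.
#' @export
n_snps <- function(g) ncol(g$dosages)

#' Subset a panel to selected SNP columns
#' @param g A `geno_matrix`.
#' @param keep Logical or integer index over SNPs.
#' @return A `geno_matrix`.
#' @export
subset_snps <- function(g, keep) {
  geno_matrix(g$dosages[, keep, drop = FALSE], g$variants[keep, ], g$samples)
}

gt_to_dosage <- function(gt) {
  # "0/0"->0, "0/1"/"1/0"->1, "1/1"->2; "|" accepted; any "." -> NA
  gt <- sub(":.*$", "", gt)
  out <- integer(length(gt))
  out[] <- NA_integer_
  clean <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gt[clean], "[/|]")
  out[clean] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
  out
}

#' Read a VCF genotype panel with population labels
#'
#' Parses a VCF v4.2 file (GT field required) into a [geno_matrix()]. Genotype
#' coding: `0/0` is dosage 0, `0/1` or `1/0` dosage 1, `1/1` dosage 2; phased
#' separators are accepted; half calls and `./.` are missing. Multi-allelic
#' records are retained with their full ALT list so the biallelic QC stage can
#' act on them (their dosages count non-reference alleles).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample_map Either a path to a two-column tab-separated file
#'   (`sample_id`, `population`, no header required) or a data frame with
#'   those columns. Every VCF sample must appear in the map.
#' @return A `geno_matrix`.
#' @export
read_vcf <- function(path, sample_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  dos <- t(apply(gt, 2, gt_to_dosage))
  if (ncol(gt) == 1) dos <- matrix(dos, nrow = 1)
  vcf_samples <- colnames(gt)

  if (is.character(sample_map) && length(sample_map) == 1) {
    sm <- utils::read.table(sample_map, sep = "\t", header = FALSE,
                            col.names = c("sample_id", "population"),
                            colClasses = "character")
    if (identical(sm$sample_id[1], "sample_id")) sm <- sm[-1, ]
  } else {
    sm <- as.data.frame(sample_map)[, c("sample_id", "population")]
  }
  miss <- setdiff(vcf_samples, sm$sample_id)
  if (length(miss)) {
    stop("samples missing from map: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- tibble::tibble(
    sample_id = vcf_samples,
    population = sm$population[match(vcf_samples, sm$sample_id)]
  )
  variants <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF,
    alt = fix$ALT
  )
  geno_matrix(dos, variants, samples)
}

#' Write a panel as VCF v4.2
#'
#' Emits a minimal GT-only VCF that round-trips losslessly through
#' [read_vcf()]. Missing genotypes are written as `./.`.
#'
#' @param g A `geno_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  v <- g$variants
  chroms <- unique(v$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fstscan",
    sprintf("##contig=<ID=%s>", chroms),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(g$dosages), ncol = ncol(g$dosages))
  ok <- !is.na(g$dosages)
  gt[ok] <- gt_code[g$dosages[ok] + 1L]
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample-to-population map
#' @param g A `geno_matrix`.
#' @param path Output path for the two-column tab-separated map.
#' @return Invisibly, `path`.
#' @export
write_sample_map <- function(g, path) {
  utils::write.table(g$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Quality-control configuration
#'
#' Thresholds for the staged SNP filters of [apply_qc()]: biallelic-only,
#' autosomes-only, per-SNP missing rate, joint minor-allele frequency, and a
#' per-population Hardy-Weinberg exact test.
#'
#' @param max_missing_rate Remove SNPs whose missing-call rate is strictly
#'   greater than this (default 0.10).
#' @param min_maf Remove SNPs whose minor-allele frequency, computed jointly
#'   over all samples on non-missing alleles, is below this (default 0.10; a
#'   MAF exactly at the threshold is kept).
#' @param hwe_alpha Remove SNPs whose Hardy-Weinberg exact p-value falls below
#'   this in any single population (default 0.01).
#' @param autosomes Chromosome names retained by the autosome filter; defaults
#'   to "1".."18", the pig autosomes.
#' @return A `qc_config` list.
#' @export
qc_config <- function(max_missing_rate = 0.10, min_maf = 0.10,
                      hwe_alpha = 0.01, autosomes = as.character(1:18)) {
  stopifnot(max_missing_rate > 0, max_missing_rate < 1,
            min_maf > 0, min_maf < 1, hwe_alpha > 0, hwe_alpha < 1)
  structure(
    list(max_missing_rate = max_missing_rate, min_maf = min_maf,
         hwe_alpha = hwe_alpha, autosomes = autosomes),
    class = "qc_config"
  )
}

#' Exact Hardy-Weinberg test p-value
#'
#' Exact conditional test on the heterozygote count: given the sample size and
#' minor-allele count, heterozygote counts follow the Levene-Haldane
#' distribution; the p-value sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed count
#' (two-sided by point probability, with a relative tolerance of 1e-7 on the
#' comparison). Vectorised over genotype-count triples.
#'
#' @param n_aa Count of one homozygote class.
#' @param n_ab Heterozygote count.
#' @param n_bb Count of the other homozygote class.
#' @return Numeric p-values in (0, 1]. A site with no genotypes returns 1.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  len <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, len); n_ab <- rep_len(n_ab, len); n_bb <- rep_len(n_bb, len)
  vapply(seq_len(len), function(i) {
    hwe_exact_p_one(n_aa[i], n_ab[i], n_bb[i])
  }, numeric(1))
}

hwe_exact_p_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n < 1) return(1)
  na <- 2L * n_aa + n_ab           # allele A count
  n_minor <- min(na, 2L * n - na)
  if (n_minor == 0L) return(1)     # monomorphic: single configuration
  # possible het counts share parity with the minor-allele count
  h <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(h) = log[ n! 2^h / (n_hom1! h! n_hom2!) * na! nb! / (2n)! ]
  hom1 <- (n_minor - h) / 2
  hom2 <- n - (n_minor + h) / 2
  logp <- lgamma(n + 1) + h * log(2) - lgamma(hom1 + 1) - lgamma(h + 1) -
    lgamma(hom2 + 1) + lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  p_obs <- logp[match(n_ab, h)]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

genotype_counts_by_pop <- function(g) {
  # list per population: matrix 3 x SNPs of (hom-ref, het, hom-alt) counts
  pops <- unique(g$samples$population)
  out <- lapply(pops, function(p) {
    rows <- g$samples$population == p
    d <- g$dosages[rows, , drop = FALSE]
    rbind(
      n0 = colSums(d == 0L, na.rm = TRUE),
      n1 = colSums(d == 1L, na.rm = TRUE),
      n2 = colSums(d == 2L, na.rm = TRUE)
    )
  })
  stats::setNames(out, pops)
}

#' Apply staged SNP quality control with a removal ledger
#'
#' Filters SNPs in five ordered stages and reports, per stage, how many SNPs
#' were removed and how many remain:
#' \enumerate{
#'   \item `biallelic` — drop sites with more than one ALT allele;
#'   \item `autosomes` — drop sites off the configured autosome list;
#'   \item `missing_rate` — drop sites with missing-call rate strictly above
#'     the threshold;
#'   \item `maf` — drop sites whose joint minor-allele frequency (non-missing
#'     alleles, all samples pooled) is below the threshold;
#'   \item `hwe` — drop sites whose Hardy-Weinberg exact p-value is below
#'     `hwe_alpha` in any single population.
#' }
#'
#' @param g A `geno_matrix`.
#' @param cfg A [qc_config()].
#' @return List with `genotypes` (the filtered `geno_matrix`) and `report`
#'   (tibble: `stage`, `removed`, `remaining`, first row the input count).
#' @export
apply_qc <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "qc_config"))
  stages <- character(0); removed <- integer(0); remaining <- integer(0)
  note <- function(name, keep_n, prev_n) {
    stages <<- c(stages, name)
    removed <<- c(removed, prev_n - keep_n)
    remaining <<- c(remaining, keep_n)
  }
  n0 <- n_snps(g)

  keep <- !grepl(",", g$variants$alt)
  g <- subset_snps(g, keep); note("biallelic", n_snps(g), n0)

  prev <- n_snps(g)
  keep <- g$variants$chrom %in% cfg$autosomes
  g <- subset_snps(g, keep); note("autosomes", n_snps(g), prev)

  prev <- n_snps(g)
  miss_rate <- colMeans(is.na(g$dosages))
  g <- subset_snps(g, miss_rate <= cfg$max_missing_rate)
  note("missing_rate", n_snps(g), prev)

  prev <- n_snps(g)
  alt_n <- colSums(g$dosages, na.rm = TRUE)
  tot_n <- 2L * colSums(!is.na(g$dosages))
  af <- ifelse(tot_n > 0, alt_n / tot_n, 0)
  maf <- pmin(af, 1 - af)
  g <- subset_snps(g, maf >= cfg$min_maf)
  note("maf", n_snps(g), prev)

  prev <- n_snps(g)
  keep <- rep(TRUE, n_snps(g))
  for (cnt in genotype_counts_by_pop(g)) {
    p <- hwe_vectorised(cnt["n0", ], cnt["n1", ], cnt["n2", ])
    keep <- keep & p >= cfg$hwe_alpha
  }
  g <- subset_snps(g, keep)
  note("hwe", n_snps(g), prev)

  if (n_snps(g) == 0) warning("no SNPs remain after quality control")

  report <- tibble::tibble(
    stage = c("input", stages),
    removed = c(0L, as.integer(removed)),
    remaining = c(n0, as.integer(remaining))
  )
  list(genotypes = g, report = report)
}

hwe_vectorised <- function(n0, n1, n2) {
  # deduplicate identical count triples before the exact test
  key <- paste(n0, n1, n2)
  u <- !duplicated(key)
  p_u <- hwe_exact_p(n0[u], n1[u], n2[u])
  p_u[match(key, key[u])]
}
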