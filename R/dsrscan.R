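#' Scan configuration for differential-selection-region detection
#'
#' @param q_extreme Upper-tail quantile for the "extremely significant" FST
#'   threshold (default 0.0001, the top 0.01\% of SNPs).
#' @param q_sig Upper-tail quantile for the "significant" FST threshold
#'   (default 0.005, the top 0.5\%).
#' @param alpha Cutoff on the Bonferroni-corrected Fisher p-value
#'   (default 0.05).
#' @param break_len Number of consecutive nonsignificant SNPs that terminates
#'   region extension (default 2).
#' @param min_run Minimum count of significant SNPs for an uninterrupted
#'   stretch to qualify as a region without an extreme seed (default 6, i.e.
#'   "more than five").
#' @return A `scan_config` list.
#' @export
scan_config <- function(q_extreme = 1e-4, q_sig = 5e-3, alpha = 0.05,
                        break_len = 2L, min_run = 6L) {
  stopifnot(q_extreme > 0, q_sig > q_extreme, q_sig < 1,
            alpha > 0, alpha < 1, break_len >= 1, min_run >= 1)
  structure(
    list(q_extreme = q_extreme, q_sig = q_sig, alpha = alpha,
         break_len = as.integer(break_len), min_run = as.integer(min_run)),
    class = "scan_config"
  )
}

#' Per-population allele counts
#'
#' Alternate-allele count is the sum of dosages over non-missing samples; the
#' reference count is twice the non-missing sample count minus that.
#'
#' @param g A `geno_matrix`.
#' @param pops Character vector of population labels (default: all).
#' @return Tibble, one row per SNP, with `chrom`, `pos`, and for each
#'   population `<pop>_ref` and `<pop>_alt` integer columns.
#' @export
pop_allele_counts <- function(g, pops = unique(g$samples$population)) {
  out <- tibble::tibble(chrom = g$variants$chrom, pos = g$variants$pos)
  for (p in pops) {
    rows <- g$samples$population == p
    if (!any(rows)) stop("population not present: ", p, call. = FALSE)
    d <- g$dosages[rows, , drop = FALSE]
    alt <- colSums(d, na.rm = TRUE)
    nn <- colSums(!is.na(d))
    out[[paste0(p, "_ref")]] <- as.integer(2L * nn - alt)
    out[[paste0(p, "_alt")]] <- as.integer(alt)
  }
  out
}

fisher_p_one <- function(r1, a1, r2, a2) {
  # two-sided point-probability Fisher p for the allelic 2x2 table
  m1 <- r1 + a1; m2 <- r2 + a2; k <- a1 + a2
  if (m1 == 0L || m2 == 0L || k == 0L || k == m1 + m2) return(1)
  xs <- max(0L, k - m2):min(k, m1)
  probs <- stats::dhyper(xs, m1, m2, k)
  p_obs <- probs[match(a1, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test on allelic 2x2 tables
#'
#' For each SNP the 2x2 table of (ref, alt) allele counts in two populations
#' is tested against the hypergeometric null; the two-sided p-value sums the
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed one (within relative tolerance 1e-7). A table with
#' a zero margin returns 1 by convention. Vectorised over SNPs, with
#' duplicate tables computed once.
#'
#' @param ref1,alt1 Integer vectors: allele counts in population 1.
#' @param ref2,alt2 Integer vectors: allele counts in population 2.
#' @return Numeric p-values in (0, 1].
#' @export
fisher_two_sided <- function(ref1, alt1, ref2, alt2) {
  len <- length(ref1)
  stopifnot(length(alt1) == len, length(ref2) == len, length(alt2) == len)
  key <- paste(ref1, alt1, ref2, alt2)
  u <- which(!duplicated(key))
  p_u <- vapply(u, function(i) {
    fisher_p_one(ref1[i], alt1[i], ref2[i], alt2[i])
  }, numeric(1))
  p_u[match(key, key[u])]
}

#' Bonferroni adjustment
#'
#' @param p P-values in (0, 1].
#' @param m Number of tests (default: `length(p)`).
#' @return `min(1, p * m)`, vectorised.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Per-SNP FST between two allele frequencies
#'
#' Moment estimator under the Nicholson drift model: with
#' \eqn{\bar p = (p_1 + p_2)/2}, FST is the between-population variance
#' \eqn{[(p_1-\bar p)^2 + (p_2-\bar p)^2]/2} divided by
#' \eqn{\bar p(1-\bar p)}. Bounded in \[0, 1\]; equals 1 at a fixed
#' difference and 0 when the frequencies agree. Undefined (NA) when
#' \eqn{\bar p} is 0 or 1.
#'
#' @param p1,p2 Sample alternate-allele frequencies in \[0, 1\].
#' @return Numeric FST values, `NA` where undefined.
#' @export
snp_fst <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE))
  pbar <- (p1 + p2) / 2
  num <- ((p1 - pbar)^2 + (p2 - pbar)^2) / 2
  den <- pbar * (1 - pbar)
  ifelse(den > 0, num / den, NA_real_)
}

#' Two-tier significance labels for scanned SNPs
#'
#' Applies the two-tier rule: a SNP is *extreme* when its FST reaches the
#' top-`q_extreme` rank threshold and its corrected p-value is below `alpha`;
#' it is *significant* when its FST reaches the top-`q_sig` threshold under
#' the same p-value gate (every extreme SNP also satisfies this); all other
#' SNPs, including those with undefined FST, are *nonsignificant*. Rank
#' thresholds are the FST values at rank `ceiling(q * m)` among the `m`
#' defined-FST SNPs of the scan, ties included.
#'
#' @param stats Tibble with at least `fst` and `p_bonf` columns.
#' @param cfg A [scan_config()].
#' @return `stats` with a `label` factor column
#'   (`extreme`/`significant`/`nonsignificant`) plus attributes
#'   `fst_threshold_extreme` and `fst_threshold_sig`.
#' @export
classify_snps <- function(stats, cfg = scan_config()) {
  fst <- stats$fst
  defined <- !is.na(fst)
  m <- sum(defined)
  if (m < 1 / cfg$q_extreme) {
    warning("fewer than 1/q_extreme defined SNPs; extreme threshold ",
            "degenerates toward the maximum FST value")
  }
  sorted <- sort(fst[defined], decreasing = TRUE)
  thr_extreme <- sorted[min(m, max(1L, ceiling(cfg$q_extreme * m)))]
  thr_sig <- sorted[min(m, max(1L, ceiling(cfg$q_sig * m)))]
  gate <- !is.na(stats$p_bonf) & stats$p_bonf < cfg$alpha
  lab <- rep("nonsignificant", nrow(stats))
  lab[defined & gate & fst >= thr_sig] <- "significant"
  lab[defined & gate & fst >= thr_extreme] <- "extreme"
  out <- stats
  out$label <- factor(lab, levels = c("extreme", "significant", "nonsignificant"))
  attr(out, "fst_threshold_extreme") <- thr_extreme
  attr(out, "fst_threshold_sig") <- thr_sig
  out
}

# blocks of SNP indices free of any run of `break_len` consecutive
# nonsignificant labels; the building block of the seed-and-extend rule
label_blocks <- function(is_nonsig, break_len) {
  n <- length(is_nonsig)
  if (n == 0) return(list())
  r <- rle(is_nonsig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  breaks <- which(r$values & r$lengths >= break_len)
  cut_from <- starts[breaks]; cut_to <- ends[breaks]
  block_start <- c(1L, cut_to + 1L)
  block_end <- c(cut_from - 1L, n)
  keep <- block_start <= block_end
  purrr::map2(block_start[keep], block_end[keep], seq.int)
}

#' Seed-and-extend detection of differential selection regions
#'
#' Two rules produce candidate regions on each chromosome, operating in
#' SNP-index (marker) order:
#' \enumerate{
#'   \item seed-and-extend — from every extreme SNP, extend in both
#'     directions until a run of `break_len` consecutive nonsignificant SNPs
#'     (or the chromosome end) is met, then trim the ends to the outermost
#'     non-nonsignificant SNP;
#'   \item seedless runs — any maximal stretch free of such a run that
#'     contains at least `min_run` significant SNPs qualifies even without an
#'     extreme seed.
#' }
#' Overlapping candidates are merged and regions are numbered sequentially
#' genome-wide (chromosome order, then position). A lone extreme SNP forms a
#' one-SNP region.
#'
#' @param stats Labelled SNP tibble (from [classify_snps()]) with `chrom`,
#'   `pos`, `label`, sorted by position within chromosome.
#' @param cfg A [scan_config()].
#' @return Tibble of regions: `id` ("DSR1".."DSRn"), `chrom`, `start`, `end`
#'   (1-based inclusive, at the outermost qualifying SNPs), `n_snps_spanned`,
#'   `n_significant` (including extreme SNPs), `n_extreme`.
#' @export
detect_dsrs <- function(stats, cfg = scan_config()) {
  chroms <- unique(stats$chrom)
  out <- purrr::map_dfr(chroms, function(ch) {
    s <- stats[stats$chrom == ch, ]
    if (is.unsorted(s$pos, strictly = TRUE)) {
      stop("SNPs must be sorted by position within chromosome", call. = FALSE)
    }
    lab <- as.character(s$label)
    nonsig <- lab == "nonsignificant"
    blocks <- label_blocks(nonsig, cfg$break_len)
    regions <- list()
    for (idx in blocks) {
      sig_idx <- idx[!nonsig[idx]]
      if (length(sig_idx) == 0) next
      has_seed <- any(lab[sig_idx] == "extreme")
      n_sig <- length(sig_idx)   # extreme SNPs also count as significant
      if (!has_seed && n_sig < cfg$min_run) next
      span <- sig_idx[1]:sig_idx[length(sig_idx)]
      regions[[length(regions) + 1L]] <- tibble::tibble(
        chrom = ch,
        start = s$pos[span[1]],
        end = s$pos[span[length(span)]],
        n_snps_spanned = length(span),
        n_significant = n_sig,
        n_extreme = sum(lab[sig_idx] == "extreme")
      )
    }
    dplyr::bind_rows(regions)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_snps_spanned = integer(),
                          n_significant = integer(), n_extreme = integer()))
  }
  out <- merge_regions(out)
  out <- out[order(match(out$chrom, chroms), out$start), ]
  out$id <- paste0("DSR", seq_len(nrow(out)))
  dplyr::relocate(out, "id")
}

merge_regions <- function(regions) {
  # overlap-only merge within chromosomes; counts are summed on merge
  regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      grp = cumsum(.data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                            default = -Inf))
    ) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_snps_spanned = max(.data$n_snps_spanned),
      n_significant = max(.data$n_significant),
      n_extreme = max(.data$n_extreme),
      .groups = "drop"
    ) |>
    dplyr::select(-"grp")
}

#' Full differential-selection scan for one breed pair
#'
#' Composes the scan for two populations of a QC'd panel: allele counts,
#' allelic Fisher's exact test, Bonferroni correction over the SNPs entering
#' this pair scan, per-SNP FST, two-tier classification, and seed-and-extend
#' region detection. Deterministic.
#'
#' @param g A `geno_matrix` (quality control already applied).
#' @param pop_a,pop_b Population labels.
#' @param cfg A [scan_config()].
#' @return List of class `pair_scan` with `stats` (per-SNP tibble: `chrom`,
#'   `pos`, `p1`, `p2`, `fst`, `fisher_p`, `p_bonf`, `label`), `regions`
#'   (tibble from [detect_dsrs()]), `pop_a`, `pop_b`, `config`, and realized
#'   thresholds `fst_threshold_extreme` / `fst_threshold_sig`.
#' @export
run_pair_scan <- function(g, pop_a, pop_b, cfg = scan_config()) {
  counts <- pop_allele_counts(g, c(pop_a, pop_b))
  r1 <- counts[[paste0(pop_a, "_ref")]]; a1 <- counts[[paste0(pop_a, "_alt")]]
  r2 <- counts[[paste0(pop_b, "_ref")]]; a2 <- counts[[paste0(pop_b, "_alt")]]
  p1 <- ifelse(r1 + a1 > 0, a1 / (r1 + a1), NA_real_)
  p2 <- ifelse(r2 + a2 > 0, a2 / (r2 + a2), NA_real_)
  stats <- tibble::tibble(
    chrom = counts$chrom, pos = counts$pos,
    p1 = p1, p2 = p2,
    fst = snp_fst(ifelse(is.na(p1), 0, p1), ifelse(is.na(p2), 0, p2)),
    fisher_p = fisher_two_sided(r1, a1, r2, a2)
  )
  stats$fst[is.na(p1) | is.na(p2)] <- NA_real_
  stats$p_bonf <- bonferroni_adjust(stats$fisher_p, m = nrow(stats))
  stats <- classify_snps(stats, cfg)
  regions <- detect_dsrs(stats, cfg)
  structure(
    list(stats = stats, regions = regions, pop_a = pop_a, pop_b = pop_b,
         config = cfg,
         fst_threshold_extreme = attr(stats, "fst_threshold_extreme"),
         fst_threshold_sig = attr(stats, "fst_threshold_sig")),
    class = "pair_scan"
  )
}

#' @export
print.pair_scan <- function(x, ...) {
  cat("<pair_scan> ", x$pop_a, " vs ", x$pop_b, ": ",
      nrow(x$stats), " SNPs, ", nrow(x$regions), " regions; thresholds ",
      format(x$fst_threshold_extreme, digits = 4), " (extreme) / ",
      format(x$fst_threshold_sig, digits = 4), " (significant)\n", sep = "")
  invisible(x)
}

#' Tidy per-SNP statistics of a pair scan
#' @param x A `pair_scan`.
#' @param ... Unused.
#' @return The per-SNP stats tibble.
#' @method tidy pair_scan
#' @export
tidy.pair_scan <- function(x, ...) x$stats

#' One-row summary of a pair scan
#' @param x A `pair_scan`.
#' @param ... Unused.
#' @return One-row tibble with SNP/region tallies and realized thresholds.
#' @method glance pair_scan
#' @export
glance.pair_scan <- function(x, ...) {
  tibble::tibble(
    pop_a = x$pop_a, pop_b = x$pop_b,
    n_snps = nrow(x$stats),
    n_extreme = sum(x$stats$label == "extreme"),
    n_significant = sum(x$stats$label != "nonsignificant"),
    n_regions = nrow(x$regions),
    fst_threshold_extreme = x$fst_threshold_extreme,
    fst_threshold_sig = x$fst_threshold_sig
  )
}

#' Manhattan plot of a pair scan
#'
#' @param object A `pair_scan`.
#' @param ... Unused.
#' @return A ggplot of per-SNP FST by cumulative genome position, with the
#'   realized two-tier thresholds as horizontal lines.
#' @method autoplot pair_scan
#' @export
autoplot.pair_scan <- function(object, ...) {
  mh <- export_manhattan(object)
  ggplot2::ggplot(mh, ggplot2::aes(.data$cum_pos, .data$fst,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(mh, "fst_threshold_extreme"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(mh, "fst_threshold_sig"),
                        linetype = "dotted") +
    ggplot2::labs(x = "cumulative position", y = expression(F[ST])) +
    ggplot2::theme_minimal()
}
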