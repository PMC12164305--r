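#' Simulation configuration for multi-population genotype panels
#'
#' Builds the configuration object consumed by [simulate_frequencies()] and
#' [simulate_genotypes()]. Populations drift away from a shared ancestral
#' allele frequency under the Balding-Nichols parameterisation of the
#' Nicholson model: for ancestral frequency \eqn{\pi} and drift coefficient
#' \eqn{c}, the population frequency is Beta-distributed with mean \eqn{\pi}
#' and variance \eqn{c\,\pi(1-\pi)}.
#'
#' Drift can be specified either as a flat per-population vector (a star
#' topology: every population drifts independently from the ancestor) or as a
#' two-level tree via `pop_tree`, in which groups of populations first drift
#' together along a shared branch and then each population drifts from its
#' group node. Under the star model two populations with drift `c` each show a
#' pairwise differentiation of approximately `c`; under the tree model
#' pairwise differentiation is approximately the summed drift along the
#' non-shared branches, so branch values act as additive calibration targets.
#'
#' @param pop_sizes Named integer vector of diploid sample counts, one per
#'   population. All sizes must be at least 2.
#' @param drift Named numeric vector of per-population drift coefficients in
#'   (0, 1), aligned with `pop_sizes`. Ignored when `pop_tree` is supplied.
#' @param n_snps Total number of SNPs, split across `chromosomes`.
#' @param chromosomes Data frame with columns `chrom`, `n_snps`, `length_bp`.
#'   Defaults to spreading `n_snps` as evenly as possible over 18 autosomes
#'   named "1".."18" of 100 Mb each.
#' @param planted_regions Data frame with columns `chrom`, `start_snp`,
#'   `end_snp` (1-based SNP indices within the chromosome), `c_sel` (the
#'   elevated drift applied inside the region) and `pop` (the population that
#'   diverges there). `NULL` for no planted selection.
#' @param pop_tree Optional two-level drift tree: a list with elements
#'   `groups` (named list mapping group name to population names),
#'   `group_drift` (named numeric, branch from the ancestor to each group
#'   node) and `pop_drift` (named numeric, branch from the group node to each
#'   population). A group drift of 0 means the group node coincides with the
#'   ancestor.
#' @param ancestral_freq_range Length-2 numeric; ancestral frequencies are
#'   drawn Uniform(lo, hi). The default (0.1, 0.9) keeps most sites common
#'   enough to survive a MAF filter.
#' @param missing_rate Probability in \[0, 1) that any single genotype call is
#'   set to missing.
#' @param seed Integer seed governing every stochastic draw.
#'
#' @return An object of class `sim_config`.
#' @seealso [sim_config_three_breeds()] for the default study-like panel.
#' @export
sim_config <- function(pop_sizes,
                       drift = NULL,
                       n_snps = 10000L,
                       chromosomes = NULL,
                       planted_regions = NULL,
                       pop_tree = NULL,
                       ancestral_freq_range = c(0.1, 0.9),
                       missing_rate = 0,
                       seed = 1L) {
  if (is.null(names(pop_sizes)) || anyDuplicated(names(pop_sizes))) {
    stop("`pop_sizes` must be uniquely named", call. = FALSE)
  }
  if (any(pop_sizes < 2)) {
    stop("all population sizes must be >= 2", call. = FALSE)
  }
  pops <- names(pop_sizes)

  if (is.null(pop_tree)) {
    if (is.null(drift)) stop("supply either `drift` or `pop_tree`", call. = FALSE)
    drift <- drift[pops]
    if (anyNA(drift)) stop("`drift` must name every population", call. = FALSE)
    pop_tree <- list(
      groups = stats::setNames(as.list(pops), pops),
      group_drift = stats::setNames(rep(0, length(pops)), pops),
      pop_drift = drift
    )
  } else {
    tree_pops <- unlist(pop_tree$groups, use.names = FALSE)
    if (!setequal(tree_pops, pops)) {
      stop("`pop_tree$groups` must partition the populations", call. = FALSE)
    }
    drift <- pop_tree$pop_drift[pops]
  }
  branch <- c(pop_tree$group_drift, pop_tree$pop_drift)
  if (any(branch < 0) || any(branch >= 1) || any(pop_tree$pop_drift <= 0)) {
    stop("drift coefficients must lie in (0, 1)", call. = FALSE)
  }

  if (is.null(chromosomes)) {
    n_chr <- 18L
    per <- rep(n_snps %/% n_chr, n_chr)
    extra <- n_snps %% n_chr
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    chromosomes <- tibble::tibble(
      chrom = as.character(seq_len(n_chr)),
      n_snps = as.integer(per),
      length_bp = 1e8
    )
    chromosomes <- chromosomes[chromosomes$n_snps > 0L, ]
  }
  chromosomes <- tibble::as_tibble(chromosomes)
  if (sum(chromosomes$n_snps) != n_snps) {
    stop("per-chromosome SNP counts must sum to `n_snps`", call. = FALSE)
  }

  if (!is.null(planted_regions)) {
    planted_regions <- tibble::as_tibble(planted_regions)
    ok_chrom <- planted_regions$chrom %in% chromosomes$chrom
    if (!all(ok_chrom)) stop("planted region on unknown chromosome", call. = FALSE)
    nn <- chromosomes$n_snps[match(planted_regions$chrom, chromosomes$chrom)]
    if (any(planted_regions$start_snp < 1) || any(planted_regions$end_snp > nn) ||
        any(planted_regions$start_snp > planted_regions$end_snp)) {
      stop("planted regions must lie within chromosome SNP bounds", call. = FALSE)
    }
    if (any(planted_regions$c_sel <= max(drift)) || any(planted_regions$c_sel >= 1)) {
      stop("`c_sel` must exceed every background drift and lie below 1", call. = FALSE)
    }
    if (!all(planted_regions$pop %in% pops)) {
      stop("planted region `pop` must be a known population", call. = FALSE)
    }
    by_chr <- split(planted_regions, planted_regions$chrom)
    for (pr in by_chr) {
      pr <- pr[order(pr$start_snp), ]
      if (nrow(pr) > 1 && any(pr$start_snp[-1] <= pr$end_snp[-nrow(pr)])) {
        stop("planted regions must not overlap", call. = FALSE)
      }
    }
  }

  if (length(ancestral_freq_range) != 2 || ancestral_freq_range[1] <= 0 ||
      ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] >= ancestral_freq_range[2]) {
    stop("`ancestral_freq_range` must be (lo, hi) with 0 < lo < hi < 1", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }

  structure(
    list(
      pop_sizes = as.integer(stats::setNames(pop_sizes, pops)) |> stats::setNames(pops),
      drift = drift,
      pop_tree = pop_tree,
      n_snps = as.integer(n_snps),
      chromosomes = chromosomes,
      planted_regions = planted_regions,
      ancestral_freq_range = ancestral_freq_range,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default three-breed + outgroup configuration
#'
#' A panel emulating three island pig breeds sampled at 25/17/23 diploids plus
#' a small diverged outgroup, with a two-level drift tree tuned so that the
#' close pair (P1, P2) differentiates at roughly 0.09 and either distant pair
#' at roughly 0.17, while the outgroup sits far from all three.
#'
#' @param n_snps Total SNP count (default 20000).
#' @param missing_rate Per-genotype missing probability.
#' @param seed Integer seed.
#' @param planted_regions Optional planted-region table (see [sim_config()]).
#' @return A `sim_config`.
#' @export
sim_config_three_breeds <- function(n_snps = 20000L, missing_rate = 0.02,
                                    seed = 1L, planted_regions = NULL) {
  # pairwise differentiation is about the mean drift of the two non-shared
  # paths; drift compounds multiplicatively along a path,
  # 1 - (1-c1)(1-c2), so the shared inner branch of 0.088 gives the close
  # pair (0.09+0.09)/2 = 0.09 and either distant pair about
  # ((1-0.912*0.91) + 0.17)/2 = 0.17
  tree <- list(
    groups = list(inner = c("P1", "P2"), distal = "P3", outg = "OUT"),
    group_drift = c(inner = 0.088, distal = 0, outg = 0),
    pop_drift = c(P1 = 0.09, P2 = 0.09, P3 = 0.17, OUT = 0.6)
  )
  sim_config(
    pop_sizes = c(P1 = 25L, P2 = 17L, P3 = 23L, OUT = 6L),
    pop_tree = tree,
    n_snps = n_snps,
    missing_rate = missing_rate,
    seed = seed,
    planted_regions = planted_regions
  )
}

# deterministic per-chromosome sub-seed, kept within 32-bit integer range
chrom_seed <- function(seed, k, offset = 0L) {
  as.integer((as.numeric(seed) * 7919 + k * 104729 + offset) %% 2147483647)
}

#' Simulate population allele frequencies under Balding-Nichols drift
#'
#' Draws, for every SNP, an ancestral frequency \eqn{\pi \sim} Uniform(lo, hi)
#' and then a frequency for each population by propagating Beta draws down the
#' configured drift tree: at each branch with drift \eqn{c} the child
#' frequency is Beta with mean equal to the parent frequency \eqn{p} and
#' variance \eqn{c\,p(1-p)}. Inside a planted region the designated
#' population's terminal branch uses the elevated drift `c_sel` instead of its
#' background drift, producing a block of strongly differentiated SNPs.
#'
#' Beta draws that hit numerical 0 or 1 are clamped to
#' \code{[1e-9, 1 - 1e-9]} so downstream allele-count tables stay defined.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `freqs` (populations x
#'   SNPs matrix), `ancestral` (per-SNP ancestral frequency vector),
#'   `variants` (tibble: `chrom`, `pos`, `snp_index`,
#'   `planted`), `planted_intervals` (tibble of base-pair intervals, one row
#'   per planted region) and `pairwise_target_fst` (matrix of approximate
#'   expected pairwise differentiation from the drift tree).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- names(config$pop_sizes)
  tree <- config$pop_tree
  lo <- config$ancestral_freq_range[1]
  hi <- config$ancestral_freq_range[2]

  group_of <- character(0)
  for (g in names(tree$groups)) {
    group_of[tree$groups[[g]]] <- g
  }

  bn_draw <- function(p, c) {
    # Beta with mean p, variance c*p*(1-p); c -> 0 degenerates to p itself
    shape_scale <- (1 - c) / c
    q <- stats::rbeta(length(p), p * shape_scale, (1 - p) * shape_scale)
    pmin(pmax(q, 1e-9), 1 - 1e-9)
  }

  chrs <- config$chromosomes
  freq_blocks <- vector("list", nrow(chrs))
  anc_blocks <- vector("list", nrow(chrs))
  var_blocks <- vector("list", nrow(chrs))
  planted_rows <- list()

  for (k in seq_len(nrow(chrs))) {
    m <- chrs$n_snps[k]
    set.seed(chrom_seed(config$seed, k))
    pos <- sort(sample.int(chrs$length_bp[k], m))
    pi0 <- stats::runif(m, lo, hi)

    group_freq <- list()
    for (g in names(tree$groups)) {
      cg <- tree$group_drift[[g]]
      group_freq[[g]] <- if (cg > 0) bn_draw(pi0, cg) else pi0
    }

    planted_here <- NULL
    if (!is.null(config$planted_regions)) {
      planted_here <- config$planted_regions[config$planted_regions$chrom == chrs$chrom[k], ]
    }
    planted_mask <- rep(FALSE, m)

    fr <- matrix(NA_real_, nrow = length(pops), ncol = m,
                 dimnames = list(pops, NULL))
    for (p in pops) {
      cvec <- rep(tree$pop_drift[[p]], m)
      if (!is.null(planted_here) && nrow(planted_here) > 0) {
        for (i in seq_len(nrow(planted_here))) {
          idx <- planted_here$start_snp[i]:planted_here$end_snp[i]
          planted_mask[idx] <- TRUE
          if (planted_here$pop[i] == p) cvec[idx] <- planted_here$c_sel[i]
        }
      }
      fr[p, ] <- bn_draw(group_freq[[group_of[[p]]]], cvec)
    }
    freq_blocks[[k]] <- fr
    anc_blocks[[k]] <- pi0
    var_blocks[[k]] <- tibble::tibble(
      chrom = chrs$chrom[k], pos = pos, planted = planted_mask
    )
    if (!is.null(planted_here) && nrow(planted_here) > 0) {
      planted_rows[[length(planted_rows) + 1L]] <- tibble::tibble(
        chrom = chrs$chrom[k],
        start = pos[planted_here$start_snp],
        end = pos[planted_here$end_snp],
        pop = planted_here$pop,
        c_sel = planted_here$c_sel
      )
    }
  }

  variants <- dplyr::bind_rows(var_blocks)
  variants$snp_index <- seq_len(nrow(variants))

  # pairwise FST approximates the mean of the two non-shared path drifts
  target <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (i == j) next
      gi <- group_of[[pops[i]]]; gj <- group_of[[pops[j]]]
      di <- tree$pop_drift[[pops[i]]] + if (gi == gj) 0 else tree$group_drift[[gi]]
      dj <- tree$pop_drift[[pops[j]]] + if (gi == gj) 0 else tree$group_drift[[gj]]
      target[i, j] <- (di + dj) / 2
    }
  }

  structure(
    list(
      freqs = do.call(cbind, freq_blocks),
      ancestral = unlist(anc_blocks),
      variants = variants,
      planted_intervals = if (length(planted_rows)) dplyr::bind_rows(planted_rows)
                          else tibble::tibble(chrom = character(), start = integer(),
                                              end = integer(), pop = character(),
                                              c_sel = numeric()),
      pairwise_target_fst = target
    ),
    class = "sim_truth"
  )
}

#' Sample diploid genotypes from simulated population frequencies
#'
#' Each genotype is an independent Binomial(2, p) draw of alternate-allele
#' dosage at the population's frequency (Hardy-Weinberg sampling within
#' populations), after which calls are masked to missing with the configured
#' probability. Reference/alternate alleles are assigned random distinct
#' nucleotides per site.
#'
#' @param truth A `sim_truth` from [simulate_frequencies()].
#' @param config The matching [sim_config()].
#' @return A [geno_matrix()] with population labels attached to samples.
#' @export
simulate_genotypes <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (!identical(ncol(truth$freqs), config$n_snps)) {
    stop("truth set does not match configuration", call. = FALSE)
  }
  pops <- names(config$pop_sizes)
  n_tot <- sum(config$pop_sizes)
  m <- config$n_snps

  set.seed(chrom_seed(config$seed, 0L, offset = 1L))
  dos <- matrix(NA_integer_, nrow = n_tot, ncol = m)
  sample_ids <- character(n_tot)
  sample_pop <- character(n_tot)
  row0 <- 0L
  for (p in pops) {
    np <- config$pop_sizes[[p]]
    block <- matrix(
      stats::rbinom(np * m, 2L, rep(truth$freqs[p, ], each = np)),
      nrow = np, ncol = m
    )
    dos[row0 + seq_len(np), ] <- block
    sample_ids[row0 + seq_len(np)] <- sprintf("%s_%02d", p, seq_len(np))
    sample_pop[row0 + seq_len(np)] <- p
    row0 <- row0 + np
  }
  if (config$missing_rate > 0) {
    dos[stats::runif(length(dos)) < config$missing_rate] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt_shift <- sample.int(3L, m, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L]

  variants <- tibble::tibble(
    chrom = truth$variants$chrom,
    pos = truth$variants$pos,
    id = sprintf("snp_%d", seq_len(m)),
    ref = ref,
    alt = alt
  )
  samples <- tibble::tibble(sample_id = sample_ids, population = sample_pop)
  geno_matrix(dos, variants, samples)
}

#' Simulate a full genotype panel in one call
#'
#' Convenience wrapper chaining [simulate_frequencies()] and
#' [simulate_genotypes()].
#'
#' @param config A [sim_config()].
#' @return List with elements `panel` (a `geno_matrix`) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_panel <- function(config) {
  truth <- simulate_frequencies(config)
  list(panel = simulate_genotypes(truth, config), truth = truth)
}

#' Write a simulated panel as VCF + sample map (+ truth BED)
#'
#' Emits a VCF v4.2 with GT-only FORMAT, a tab-separated sample-to-population
#' map, and, when truth is supplied, a BED file (0-based half-open) of the
#' planted selected regions for benchmarking.
#'
#' @param panel A `geno_matrix`.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @param truth Optional `sim_truth` whose planted intervals are written as BED.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(panel, dir, prefix = "panel", truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  map <- file.path(dir, paste0(prefix, ".samples.tsv"))
  write_vcf(panel, vcf)
  write_sample_map(panel, map)
  paths <- c(vcf = vcf, sample_map = map)
  if (!is.null(truth) && nrow(truth$planted_intervals) > 0) {
    bed <- file.path(dir, paste0(prefix, ".truth.bed"))
    pi <- truth$planted_intervals
    utils::write.table(
      data.frame(pi$chrom, pi$start - 1L, pi$end, pi$pop),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    paths <- c(paths, truth_bed = bed)
  }
  invisible(paths)
}
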