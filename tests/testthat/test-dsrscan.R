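test_that("allele counts tally dosages per population", {
  d <- cbind(c(0L, 1L, 2L, NA, NA, NA), c(2L, 2L, 2L, 1L, 1L, 0L))
  g <- make_panel(d, rep(c("A", "B"), each = 3))
  tab <- pop_allele_counts(g)
  expect_equal(tab$A_ref[1], 3L); expect_equal(tab$A_alt[1], 3L)
  expect_equal(tab$B_ref[1], 0L); expect_equal(tab$B_alt[1], 0L)  # all missing
  expect_equal(tab$A_alt[2], 6L); expect_equal(tab$A_ref[2], 0L)  # all hom-alt
  expect_equal(tab$B_alt[2], 2L); expect_equal(tab$B_ref[2], 4L)
})

test_that("Fisher p-values match hand-enumerated tables", {
  expect_equal(fisher_two_sided(10L, 0L, 0L, 10L), 2 / 184756, tolerance = 1e-12)
  expect_equal(fisher_two_sided(5L, 5L, 5L, 5L), 1)
  expect_equal(fisher_two_sided(3L, 7L, 7L, 3L), 8263 / 46189, tolerance = 1e-12)
  # zero margin -> 1 by convention
  expect_equal(fisher_two_sided(0L, 0L, 3L, 3L), 1)
  expect_equal(fisher_two_sided(3L, 0L, 3L, 0L), 1)
})

test_that("Fisher p-values agree with the enumeration oracle and fisher.test", {
  set.seed(50)
  for (i in 1:200) {
    m1 <- sample(0:60, 1); m2 <- sample(0:60, 1)
    a1 <- if (m1 > 0) sample(0:m1, 1) else 0L
    a2 <- if (m2 > 0) sample(0:m2, 1) else 0L
    ours <- fisher_two_sided(m1 - a1, a1, m2 - a2, a2)
    expect_equal(ours, oracle_fisher(m1 - a1, a1, m2 - a2, a2),
                 tolerance = 1e-10)
    if (m1 > 0 && m2 > 0 && a1 + a2 > 0 && a1 + a2 < m1 + m2) {
      ft <- stats::fisher.test(matrix(c(m1 - a1, a1, m2 - a2, a2), 2,
                                      byrow = TRUE))$p.value
      expect_equal(ours, ft, tolerance = 1e-10)
    }
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 100), 0.1)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_equal(bonferroni_adjust(1e-8, 13614302), 0.13614302, tolerance = 1e-9)
})

test_that("per-SNP FST follows the moment formula", {
  expect_equal(snp_fst(0.5, 0.5), 0)
  expect_equal(snp_fst(1, 0), 1)
  expect_equal(snp_fst(0.8, 0.2), 0.36, tolerance = 1e-12)
  expect_true(is.na(snp_fst(0, 0)))
  expect_true(is.na(snp_fst(1, 1)))
  set.seed(3)
  p1 <- runif(100); p2 <- runif(100)
  f <- snp_fst(p1, p2)
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})

test_that("two-tier classification matches an independent sorting oracle", {
  set.seed(77)
  n <- 20000
  stats <- tibble::tibble(
    chrom = "1", pos = seq_len(n) * 10L,
    fst = stats::rbeta(n, 0.5, 3),
    p_bonf = sample(c(rep(1e-6, n / 2), rep(1, n / 2)))
  )
  cfg <- scan_config()
  lab <- classify_snps(stats, cfg)
  # independent oracle: sort and take top-k candidate sets, gate on p
  ord <- order(stats$fst, decreasing = TRUE)
  k_ext <- ceiling(cfg$q_extreme * n); k_sig <- ceiling(cfg$q_sig * n)
  thr_ext <- stats$fst[ord][k_ext]; thr_sig <- stats$fst[ord][k_sig]
  exp_ext <- stats$fst >= thr_ext & stats$p_bonf < cfg$alpha
  exp_sig <- stats$fst >= thr_sig & stats$p_bonf < cfg$alpha
  expect_equal(lab$label == "extreme", exp_ext)
  expect_equal(lab$label != "nonsignificant", exp_sig)
  expect_equal(attr(lab, "fst_threshold_extreme"), thr_ext)
  expect_equal(attr(lab, "fst_threshold_sig"), thr_sig)
  # every extreme SNP also satisfies the significant criteria
  expect_true(all(exp_sig[exp_ext]))
})

test_that("the corrected-p gate blanks all labels when nothing is significant", {
  stats <- tibble::tibble(chrom = "1", pos = 1:100 * 10L,
                          fst = seq(0, 1, length.out = 100), p_bonf = 1)
  lab <- suppressWarnings(classify_snps(stats, scan_config()))
  expect_true(all(lab$label == "nonsignificant"))
})

test_that("undefined FST is labelled nonsignificant", {
  stats <- tibble::tibble(chrom = "1", pos = 1:200 * 10L,
                          fst = c(NA, stats::runif(199)),
                          p_bonf = 1e-9)
  lab <- suppressWarnings(classify_snps(stats, scan_config()))
  expect_equal(as.character(lab$label[1]), "nonsignificant")
})

test_that("raising alpha or q_sig never removes a significant label", {
  set.seed(99)
  stats <- tibble::tibble(
    chrom = "1", pos = seq_len(3000) * 7L,
    fst = stats::rbeta(3000, 0.4, 2),
    p_bonf = stats::runif(3000)
  )
  base <- suppressWarnings(
    classify_snps(stats, scan_config(q_sig = 0.01, alpha = 0.3)))
  wider <- suppressWarnings(
    classify_snps(stats, scan_config(q_sig = 0.05, alpha = 0.6)))
  was_sig <- base$label != "nonsignificant"
  still_sig <- wider$label != "nonsignificant"
  expect_true(all(still_sig[was_sig]))
})

test_that("region detection matches the spec walk-through example", {
  lab <- c("nonsignificant", "significant", "extreme", "significant",
           "nonsignificant", "nonsignificant", "significant", "significant")
  stats <- tibble::tibble(
    chrom = "1", pos = 1:8, fst = NA_real_, p_bonf = NA_real_,
    label = factor(lab, levels = c("extreme", "significant", "nonsignificant"))
  )
  r <- detect_dsrs(stats, scan_config())
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 2L)
  expect_equal(r$end, 4L)
  expect_equal(r$n_extreme, 1L)
  expect_equal(r$n_significant, 3L)
})

test_that("the seedless rule needs strictly more than five significant SNPs", {
  mk <- function(n_sig) {
    lab <- c("nonsignificant", "nonsignificant", rep("significant", n_sig),
             "nonsignificant", "nonsignificant")
    tibble::tibble(chrom = "1", pos = seq_along(lab) * 5L,
                   fst = NA_real_, p_bonf = NA_real_,
                   label = factor(lab, levels = c("extreme", "significant",
                                                  "nonsignificant")))
  }
  expect_equal(nrow(detect_dsrs(mk(5), scan_config())), 0L)
  r <- detect_dsrs(mk(6), scan_config())
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_significant, 6L)
})

test_that("all-nonsignificant input and a lone extreme SNP behave correctly", {
  all_n <- tibble::tibble(chrom = "1", pos = 1:50 * 3L, fst = NA_real_,
                          p_bonf = NA_real_,
                          label = factor("nonsignificant",
                                         levels = c("extreme", "significant",
                                                    "nonsignificant")))
  expect_equal(nrow(detect_dsrs(all_n, scan_config())), 0L)
  lone <- all_n
  lone$label[25] <- "extreme"
  r <- detect_dsrs(lone, scan_config())
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, r$end)
  expect_equal(r$n_snps_spanned, 1L)
})

test_that("region detection equals the brute-force walker on random labels", {
  for (i in 1:150) {
    n <- sample(5:200, 1)
    stats <- random_labels(n, seed = 1000 + i)
    got <- detect_dsrs(stats, scan_config())
    want <- oracle_dsrs(as.character(stats$label), stats$pos)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start, info = paste("case", i))
      expect_equal(got$end, want$end, info = paste("case", i))
      expect_equal(got$n_snps_spanned, want$n_snps_spanned)
      expect_equal(got$n_significant, want$n_significant)
      expect_equal(got$n_extreme, want$n_extreme)
    }
  }
})

test_that("every reported region satisfies the seed or run criterion", {
  for (i in 1:20) {
    stats <- random_labels(300, seed = 7000 + i)
    r <- detect_dsrs(stats, scan_config())
    if (nrow(r) > 0) {
      expect_true(all(r$n_extreme >= 1 | r$n_significant >= 6))
      expect_true(all(r$start <= r$end))
      # regions within a chromosome do not overlap
      if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    }
  }
})

test_that("a pair scan recovers a planted sweep and is deterministic", {
  pr <- data.frame(chrom = "1", start_snp = 300L, end_snp = 349L,
                   c_sel = 0.6, pop = "A")
  cfg <- sim_config(
    pop_sizes = c(A = 25L, B = 17L), drift = c(A = .05, B = .05),
    n_snps = 5000L,
    chromosomes = data.frame(chrom = as.character(1:5), n_snps = 1000L,
                             length_bp = 1e8),
    planted_regions = pr, seed = 5L
  )
  sp <- simulate_panel(cfg)
  sc <- suppressWarnings(run_pair_scan(sp$panel, "A", "B"))
  ti <- sp$truth$planted_intervals
  hit <- any(sc$regions$chrom == ti$chrom &
               sc$regions$start <= ti$end & sc$regions$end >= ti$start)
  expect_true(hit)
  sc2 <- suppressWarnings(run_pair_scan(sp$panel, "A", "B"))
  expect_identical(sc$regions, sc2$regions)
  expect_identical(sc$stats, sc2$stats)
})

test_that("identical allele frequencies in both populations yield no regions", {
  d <- matrix(rep(c(0L, 1L, 2L, 1L, 0L), 20), nrow = 10, ncol = 10)
  g <- make_panel(d, rep(c("A", "B"), each = 5))
  sc <- suppressWarnings(run_pair_scan(g, "A", "B"))
  expect_equal(nrow(sc$regions), 0L)
  expect_true(all(sc$stats$fst == 0))
})
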