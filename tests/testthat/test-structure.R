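test_that("IBS sharing matches per-site enumeration", {
  r <- ibs_pair(c(0, 1, 2), c(2, 1, 0))
  expect_equal(r$ibs2, 1)
  expect_equal(r$ibs1, 0)
  expect_equal(r$n, 3)
  expect_equal(r$dst, 1 / 3)
  expect_equal(r$distance, 2 / 3)

  r2 <- ibs_pair(c(0, 0), c(1, 2))
  expect_equal(r2$dst, 0.25)
  expect_equal(r2$distance, 0.75)

  same <- ibs_pair(c(0, 1, 2, 1), c(0, 1, 2, 1))
  expect_equal(same$dst, 1)
  expect_equal(same$distance, 0)

  # missing sites drop out of N
  rm <- ibs_pair(c(0, NA, 2), c(1, 1, NA))
  expect_equal(rm$n, 1)
  expect_equal(rm$distance, 0.5)
  expect_error(ibs_pair(c(NA, NA), c(0, 1)), "non-missing")
})

test_that("IBS sharing is symmetric over random dosage vectors", {
  set.seed(100)
  for (i in 1:25) {
    g1 <- sample(c(0:2, NA), 40, replace = TRUE)
    g2 <- sample(c(0:2, NA), 40, replace = TRUE)
    if (!any(!is.na(g1) & !is.na(g2))) next
    expect_identical(ibs_pair(g1, g2), ibs_pair(g2, g1))
  }
})

test_that("the distance matrix agrees with pairwise calls and relabeling", {
  set.seed(7)
  d <- matrix(sample(c(0:2, NA), 5 * 60, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), nrow = 5)
  g <- make_panel(d, rep("A", 5))
  m <- ibs_dist(g)
  expect_true(isSymmetric(unclass(m)[1:5, 1:5]))
  expect_equal(unname(diag(m)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], ibs_pair(d[i, ], d[j, ])$distance)
  }
  # duplicate samples sit at distance zero
  g2 <- make_panel(rbind(d, d[1, ]), rep("A", 6))
  expect_equal(ibs_dist(g2)[1, 6], 0)
  # permuting samples permutes rows and columns identically
  perm <- c(3, 1, 5, 2, 4)
  gp <- make_panel(d[perm, ], rep("A", 5))
  mp <- ibs_dist(gp)
  expect_equal(unname(unclass(mp)[1:5, 1:5]),
               unname(unclass(m)[perm, perm]))
})

test_that("neighbor joining recovers hand-built additive distances", {
  # tree ((A:1,B:2):1,C:3,D:4)
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  # additive recovery: path distances equal the input matrix
  cd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(cd, dm, tolerance = 1e-10)
  # AB vs CD split present
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
})

test_that("three-taxon pendant lengths follow the closed form", {
  dm <- matrix(c(0, 4, 7,
                 4, 0, 9,
                 7, 9, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(dm)
  b <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(b[["a"]], (4 + 7 - 9) / 2)
  expect_equal(b[["b"]], (4 + 9 - 7) / 2)
  expect_equal(b[["c"]], (7 + 9 - 4) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(31)
  for (i in 1:100) {
    ref <- ape::rtree(10, br = function(n) stats::runif(n, 0.1, 2))
    dm <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("classical MDS reproduces Euclidean geometry", {
  # collinear points at 0, 3, 7
  x <- c(0, 3, 7)
  dm <- as.matrix(stats::dist(x))
  dimnames(dm) <- list(paste0("p", 1:3), paste0("p", 1:3))
  res <- suppressWarnings(classical_mds(dm, k = 2))
  co1 <- res$coordinates$MDS1
  expect_equal(unname(abs(diff(sort(co1)))), c(3, 4), tolerance = 1e-8)
  expect_lt(abs(res$eigenvalues[2]), 1e-8)

  # random 2-D point set: reconstructed distances equal inputs
  set.seed(12)
  pts <- matrix(stats::rnorm(20), ncol = 2)
  dm2 <- as.matrix(stats::dist(pts))
  dimnames(dm2) <- list(paste0("q", 1:10), paste0("q", 1:10))
  res2 <- classical_mds(dm2, k = 2)
  rec <- as.matrix(stats::dist(cbind(res2$coordinates$MDS1,
                                     res2$coordinates$MDS2)))
  expect_lt(max(abs(rec - unname(dm2))), 1e-8)
  expect_true(all(diff(res2$eigenvalues) <= 1e-12))

  # degenerate all-zero distances embed at the origin
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  res3 <- suppressWarnings(classical_mds(z, k = 2))
  expect_true(all(abs(as.matrix(res3$coordinates[, -1])) < 1e-12))
})

test_that("Weir-Cockerham components match the frozen hand evaluation", {
  g <- make_panel(
    cbind(c(2L, 2L, 1L, 0L, 0L, 0L, 1L, 1L)),
    rep(c("A", "B"), each = 4)
  )
  f <- wc_weighted_fst(g, "A", "B")
  comp <- tidy(f)
  expect_equal(comp$a, 0.03125, tolerance = 1e-12)
  expect_equal(comp$b, 0.0625, tolerance = 1e-12)
  expect_equal(comp$c, 0.1875, tolerance = 1e-12)
  expect_equal(f$theta, 1 / 9, tolerance = 1e-12)
  expect_equal(glance(f)$n_snps_used, 1L)
})

test_that("monomorphic and fixed-difference SNPs behave as expected", {
  d <- cbind(
    rep(0L, 40),                        # monomorphic in both: excluded
    c(rep(2L, 20), rep(0L, 20))         # fixed difference
  )
  g <- make_panel(d, rep(c("A", "B"), each = 20))
  f <- wc_weighted_fst(g, "A", "B")
  expect_equal(f$n_snps_used, 1L)
  comp <- tidy(f)
  expect_false(comp$defined[1])
  per_snp <- comp$a[2] / (comp$a[2] + comp$b[2] + comp$c[2])
  expect_gt(per_snp, 0.95)
})

test_that("weighted FST is calibrated to the drift coefficient", {
  cfg <- sim_config(pop_sizes = c(A = 25L, B = 17L), drift = c(A = .12, B = .12),
                    n_snps = 20000L, seed = 17L)
  f <- wc_weighted_fst(simulate_panel(cfg)$panel, "A", "B")
  expect_lt(abs(f$theta - 0.12), 0.02)
  # near-zero drift stays near zero
  cfg0 <- sim_config(pop_sizes = c(A = 25L, B = 17L), drift = c(A = .01, B = .01),
                     n_snps = 20000L, seed = 18L)
  f0 <- wc_weighted_fst(simulate_panel(cfg0)$panel, "A", "B")
  expect_lt(f0$theta, 0.03)
})

test_that("the three-breed fixture yields the expected structure", {
  sp <- simulate_panel(sim_config_three_breeds(n_snps = 8000L, seed = 6L))
  d <- ibs_dist(sp$panel)
  tr <- nj_tree(d)
  out_tips <- grep("^OUT", tr$tip.label, value = TRUE)
  rooted <- ape::root(tr, outgroup = out_tips, resolve.root = TRUE)
  close_tips <- grep("^P1_|^P2_", tr$tip.label, value = TRUE)
  expect_true(ape::is.monophyletic(rooted, close_tips))
  pf <- pairwise_fst(sp$panel,
                     data.frame(a = c("P1", "P1", "P2"), b = c("P2", "P3", "P3")))
  expect_lt(pf$theta[1], pf$theta[2])
  expect_lt(pf$theta[1], pf$theta[3])
})
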