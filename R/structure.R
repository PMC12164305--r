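#' Identity-by-state sharing between two individuals
#'
#' Over the sites where both dosage vectors are non-missing, counts the loci
#' at which the pair shares two alleles (identical dosage, IBS2) or one allele
#' (dosages differing by 1, IBS1), and computes the average proportion of
#' alleles shared, `Dst = (IBS2 + 0.5 * IBS1) / N`, together with the genetic
#' distance `1 - Dst`.
#'
#' @param g1,g2 Equal-length dosage vectors (0, 1, 2 or `NA`).
#' @return A list with `ibs2`, `ibs1`, `n` (sites non-missing in both), `dst`
#'   and `distance`.
#' @export
ibs_pair <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length", call. = FALSE)
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n == 0) stop("no sites non-missing in both individuals", call. = FALSE)
  d <- abs(g1[ok] - g2[ok])
  ibs2 <- sum(d == 0)
  ibs1 <- sum(d == 1)
  dst <- (ibs2 + 0.5 * ibs1) / n
  list(ibs2 = ibs2, ibs1 = ibs1, n = n, dst = dst, distance = 1 - dst)
}

#' Pairwise IBS distance matrix
#'
#' Computes the symmetric matrix of `1 - Dst` genetic distances between all
#' sample pairs of a panel. `N` counts only sites non-missing in both members
#' of a pair. Internally uses the identity
#' `1 - Dst = mean(|d_i - d_j|) / 2` over shared sites, evaluated with dense
#' cross-products for speed.
#'
#' @param g A `geno_matrix`.
#' @return A symmetric numeric matrix (class `ibs_dist`) with sample ids as
#'   dimnames, zero diagonal, and a `samples` attribute carrying population
#'   labels.
#' @export
ibs_dist <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  if (nrow(d) < 2) stop("need at least two samples", call. = FALSE)
  V <- (!is.na(d)) * 1           # validity indicator
  G0 <- (d == 0L); G0[is.na(G0)] <- FALSE; G0 <- G0 * 1
  G1 <- (d == 1L); G1[is.na(G1)] <- FALSE; G1 <- G1 * 1
  G2 <- (d == 2L); G2[is.na(G2)] <- FALSE; G2 <- G2 * 1
  N <- tcrossprod(V)
  if (any(N[upper.tri(N)] == 0)) {
    stop("a sample pair shares no non-missing sites", call. = FALSE)
  }
  # sum over shared sites of |d_i - d_j|: 1 per (0,1)/(1,2) pair, 2 per (0,2)
  diff1 <- tcrossprod(G0 + G2, G1)
  diff_sum <- diff1 + t(diff1) + 2 * (tcrossprod(G0, G2) + tcrossprod(G2, G0))
  m <- diff_sum / (2 * N)
  diag(m) <- 0
  dimnames(m) <- list(g$samples$sample_id, g$samples$sample_id)
  attr(m, "samples") <- g$samples
  class(m) <- c("ibs_dist", class(m))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the Saitou-Nei neighbor-joining tree (exact on additive distances)
#' and returns it as an `ape` \code{phylo} object with a trifurcating root.
#' Negative branch lengths are retained as computed unless `clamp_negative`
#' is set.
#'
#' @param d A symmetric distance matrix (e.g. from [ibs_dist()]) or `dist`.
#' @param clamp_negative If `TRUE`, negative branch lengths are set to zero.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  if (clamp_negative) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Write a tree in newick format
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances, eigendecomposes, and scales the top
#' eigenvectors by the square roots of their (positive) eigenvalues. When
#' fewer than `k` positive eigenvalues exist, the embedding is truncated with
#' a warning. Coordinates are defined only up to sign and rotation.
#'
#' @param d A symmetric distance matrix or `dist`.
#' @param k Number of dimensions requested.
#' @return A list of class `mds_result` with `coordinates` (tibble:
#'   `sample_id`, optional `population`, `MDS1`..`MDSk`) and `eigenvalues`
#'   (non-increasing, length `k`, padded with `NA` if truncated).
#' @export
classical_mds <- function(d, k = 2) {
  m <- as.matrix(d)
  smp <- attr(d, "samples")
  fit <- stats::cmdscale(stats::as.dist(m), k = min(k, nrow(m) - 1), eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalues; embedding truncated")
  }
  co <- fit$points
  kk <- ncol(co)
  coords <- tibble::tibble(sample_id = rownames(m))
  if (!is.null(smp)) coords$population <- smp$population
  for (j in seq_len(kk)) coords[[paste0("MDS", j)]] <- co[, j]
  eig <- fit$eig[seq_len(k)]
  if (kk < k) eig[(kk + 1):k] <- NA_real_
  structure(list(coordinates = coords, eigenvalues = eig),
            class = "mds_result")
}

wc_components <- function(g, pop_a, pop_b) {
  # Weir & Cockerham (1984) per-SNP variance components for two populations
  rows_a <- g$samples$population == pop_a
  rows_b <- g$samples$population == pop_b
  if (sum(rows_a) < 2 || sum(rows_b) < 2) {
    stop("both populations need at least two samples", call. = FALSE)
  }
  da <- g$dosages[rows_a, , drop = FALSE]
  db <- g$dosages[rows_b, , drop = FALSE]
  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  p1 <- colSums(da, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(db, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(da == 1L, na.rm = TRUE) / n1
  h2 <- colSums(db == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2

  defined <- n1 >= 1 & n2 >= 1 & nbar > 1
  mono <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  defined <- defined & !mono & is.finite(a) & is.finite(b) & is.finite(c_)
  tibble::tibble(
    chrom = g$variants$chrom, pos = g$variants$pos,
    n1 = n1, n2 = n2, p1 = p1, p2 = p2,
    a = a, b = b, c = c_, defined = defined
  )
}

#' Weighted Weir-Cockerham FST between two populations
#'
#' Computes the Weir & Cockerham (1984) variance components per SNP — `a`
#' (among populations), `b` (among individuals within populations), `c`
#' (within individuals) — from sample sizes, allele frequencies and observed
#' heterozygosities, and returns the weighted (ratio-of-sums) estimate
#' \eqn{\theta = \sum a / \sum (a + b + c)} over SNPs with defined
#' components. SNPs monomorphic across both populations, or with a population
#' entirely missing, are excluded.
#'
#' @param g A `geno_matrix`.
#' @param pop_a,pop_b Population labels present in the panel.
#' @return A list of class `wc_fst` with `theta`, `pop_a`, `pop_b`,
#'   `n_snps_used`, and `components` (per-SNP tibble with columns `chrom`,
#'   `pos`, `p1`, `p2`, `a`, `b`, `c`, `defined`).
#' @export
wc_weighted_fst <- function(g, pop_a, pop_b) {
  comp <- wc_components(g, pop_a, pop_b)
  use <- comp$defined
  theta <- sum(comp$a[use]) / sum(comp$a[use] + comp$b[use] + comp$c[use])
  structure(
    list(theta = theta, pop_a = pop_a, pop_b = pop_b,
         n_snps_used = sum(use), components = comp),
    class = "wc_fst"
  )
}

#' @export
print.wc_fst <- function(x, ...) {
  cat("Weighted Weir-Cockerham FST (", x$pop_a, " vs ", x$pop_b, "): ",
      format(x$theta, digits = 4), " over ", x$n_snps_used, " SNPs\n", sep = "")
  invisible(x)
}

#' Pairwise weighted FST for all population pairs
#'
#' @param g A `geno_matrix`.
#' @param pairs Optional two-column matrix/data frame of population pairs;
#'   defaults to all unordered pairs present in the panel.
#' @return Tibble with columns `pop_a`, `pop_b`, `theta`, `n_snps_used`.
#' @export
pairwise_fst <- function(g, pairs = NULL) {
  if (is.null(pairs)) {
    pops <- unique(g$samples$population)
    pairs <- t(utils::combn(pops, 2))
  }
  pairs <- as.data.frame(pairs)
  purrr::map2_dfr(pairs[[1]], pairs[[2]], function(a, b) {
    f <- wc_weighted_fst(g, a, b)
    tibble::tibble(pop_a = a, pop_b = b, theta = f$theta,
                   n_snps_used = f$n_snps_used)
  })
}

#' Tidy per-SNP components of a Weir-Cockerham fit
#' @param x A `wc_fst` object.
#' @param ... Unused.
#' @return The per-SNP component tibble.
#' @method tidy wc_fst
#' @export
tidy.wc_fst <- function(x, ...) x$components

#' One-row summary of a Weir-Cockerham fit
#' @param x A `wc_fst` object.
#' @param ... Unused.
#' @return One-row tibble with `pop_a`, `pop_b`, `theta`, `n_snps_used`.
#' @method glance wc_fst
#' @export
glance.wc_fst <- function(x, ...) {
  tibble::tibble(pop_a = x$pop_a, pop_b = x$pop_b, theta = x$theta,
                 n_snps_used = x$n_snps_used)
}

#' Scatter plot of an MDS embedding
#' @param object An `mds_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mds_result
#' @export
autoplot.mds_result <- function(object, ...) {
  co <- object$coordinates
  p <- ggplot2::ggplot(co, ggplot2::aes(.data$MDS1, .data$MDS2))
  if ("population" %in% names(co)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$population))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}
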