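# Independent brute-force oracles used to validate the package's fast paths.

# Two-sided Fisher p by explicit hypergeometric enumeration with exact
# binomial coefficients (no dhyper), for a table [[r1, a1], [r2, a2]].
oracle_fisher <- function(r1, a1, r2, a2) {
  m1 <- r1 + a1; m2 <- r2 + a2; k <- a1 + a2
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  p_obs <- logp[xs == a1]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

# Exact HWE p by enumerating unnormalised Levene-Haldane weights and
# normalising by their sum (independent of the closed-form constant).
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n < 1) return(1)
  na <- 2 * n_aa + n_ab
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  h <- seq(nm %% 2, nm, by = 2)
  w <- vapply(h, function(hh) {
    hom1 <- (nm - hh) / 2
    hom2 <- n - (nm + hh) / 2
    exp(hh * log(2) - lfactorial(hom1) - lfactorial(hh) - lfactorial(hom2))
  }, numeric(1))
  pr <- w / sum(w)
  p_obs <- pr[h == n_ab]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Literal seed-and-extend region detector: walks outward from each extreme
# SNP until a run of `break_len` nonsignificant SNPs, collects seedless
# qualifying stretches, merges overlapping index intervals, and recounts.
oracle_dsrs <- function(labels, positions, break_len = 2L, min_run = 6L) {
  n <- length(labels)
  nonsig <- labels == "nonsignificant"
  extend <- function(i, step) {
    last_good <- i; run <- 0L; k <- i
    repeat {
      k <- k + step
      if (k < 1 || k > n) break
      if (nonsig[k]) {
        run <- run + 1L
        if (run >= break_len) break
      } else {
        run <- 0L
        last_good <- k
      }
    }
    last_good
  }
  cand <- list()
  for (i in which(labels == "extreme")) {
    cand[[length(cand) + 1L]] <- c(extend(i, -1L), extend(i, 1L))
  }
  # positions covered by any all-nonsignificant window of length break_len
  covered <- rep(FALSE, n)
  if (n >= break_len) {
    for (k in 1:(n - break_len + 1L)) {
      if (all(nonsig[k:(k + break_len - 1L)])) {
        covered[k:(k + break_len - 1L)] <- TRUE
      }
    }
  }
  # maximal uncovered stretches with enough significant SNPs
  k <- 1L
  while (k <= n) {
    if (!covered[k]) {
      j <- k
      while (j < n && !covered[j + 1L]) j <- j + 1L
      idx <- k:j
      sig <- idx[!nonsig[idx]]
      if (length(sig) >= min_run) {
        cand[[length(cand) + 1L]] <- c(sig[1], sig[length(sig)])
      }
      k <- j + 1L
    } else {
      k <- k + 1L
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      n_snps_spanned = integer(), n_significant = integer(),
                      n_extreme = integer()))
  }
  iv <- do.call(rbind, cand)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
      } else {
        merged[[length(merged) + 1L]] <- iv[i, ]
      }
    }
  }
  do.call(rbind, lapply(merged, function(span) {
    idx <- span[1]:span[2]
    data.frame(
      start = positions[span[1]], end = positions[span[2]],
      n_snps_spanned = length(idx),
      n_significant = sum(!nonsig[idx]),
      n_extreme = sum(labels[idx] == "extreme")
    )
  }))
}

# quadratic-time interval overlap (1-based inclusive)
oracle_overlaps <- function(regions, genes) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] == genes$chrom[j] &&
          regions$start[i] <= genes$end[j] &&
          genes$start[j] <= regions$end[i]) {
        hits[[length(hits) + 1L]] <- data.frame(
          id = regions$id[i], gene_id = genes$gene_id[j]
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(id = character(), gene_id = character()))
  }
  do.call(rbind, hits)
}

# small hand-built panel helper
make_panel <- function(dosages, populations,
                       chrom = rep("1", ncol(dosages)),
                       pos = seq_len(ncol(dosages)) * 100L) {
  n <- nrow(dosages)
  geno_matrix(
    dosages,
    variants = tibble::tibble(
      chrom = chrom, pos = pos,
      id = paste0("s", seq_len(ncol(dosages))),
      ref = "A", alt = "G"
    ),
    samples = tibble::tibble(
      sample_id = paste0("ind", seq_len(n)),
      population = populations
    )
  )
}

# random labelled SNP table for region-detector fuzzing
random_labels <- function(n, seed) {
  set.seed(seed)
  labels <- sample(c("extreme", "significant", "nonsignificant"), n,
                   replace = TRUE, prob = c(0.05, 0.2, 0.75))
  tibble::tibble(
    chrom = "1",
    pos = sort(sample.int(n * 50L, n)),
    fst = NA_real_, p_bonf = NA_real_,
    label = factor(labels, levels = c("extreme", "significant", "nonsignificant"))
  )
}
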