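# Shared fixtures and independent oracles built in code.

# small genotype matrix from an individuals x loci dosage matrix
make_geno <- function(dos, pops, chrom = NULL, pos = NULL) {
  L <- ncol(dos)
  if (is.null(chrom)) chrom <- paste0("L", seq_len(L))
  if (is.null(pos)) pos <- rep(1L, L)
  genotype_matrix(
    dos,
    tibble::tibble(locus_id = paste0("L", seq_len(L)), chrom = chrom,
                   pos = as.integer(pos)),
    tibble::tibble(individual = paste0("i", seq_len(nrow(dos))), pop = pops))
}

# 8-individual, 3-population fixture with missing data; expected W&C values
# frozen from a literal transcription of the 1984 variance components
wc_fixture <- function() {
  dos <- matrix(c(
    0, 0, 2, 1,
    1, 0, 2, 1,
    2, NA, 2, 1,
    1, 0, 0, 1,
    1, 1, 0, 1,
    2, 1, 0, 1,
    2, 2, 0, NA,
    2, 0, 0, 1), nrow = 8, byrow = TRUE)
  make_geno(dos, rep(c("A", "B", "C"), c(3, 2, 3)))
}

# Independent plain-loop Weir & Cockerham (1984) oracle: one locus at a
# time, scalar arithmetic straight from the published formulas.
oracle_wc_theta <- function(g) {
  pops <- split(seq_len(nrow(g$dosages)), g$individuals$pop)
  L <- ncol(g$dosages)
  a_sum <- b_sum <- c_sum <- 0
  per_locus <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    ns <- c(); ps <- c(); hs <- c()
    for (idx in pops) {
      d <- g$dosages[idx, l]
      d <- d[!is.na(d)]
      if (length(d) == 0) next
      ns <- c(ns, length(d))
      ps <- c(ps, sum(d) / (2 * length(d)))
      hs <- c(hs, mean(d == 1))
    }
    r <- length(ns)
    if (r < 2) next
    nbar <- mean(ns)
    if (nbar <= 1) next
    nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
    pbar <- sum(ns * ps) / sum(ns)
    s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hs) / sum(ns)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc != 0) per_locus[l] <- a / (a + b + cc)
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  list(per_locus = per_locus,
       multilocus = a_sum / (a_sum + b_sum + c_sum))
}

# Independent brute-force per-population diversity oracle (loops)
oracle_diversity <- function(g) {
  pops <- sort(unique(g$individuals$pop))
  out <- NULL
  for (pp in pops) {
    idx <- which(g$individuals$pop == pp)
    he_vals <- ho_vals <- c()
    for (l in seq_len(ncol(g$dosages))) {
      d <- g$dosages[idx, l]
      d <- d[!is.na(d)]
      n <- 2 * length(d)
      if (n < 2) next
      p <- sum(d) / n
      he_vals <- c(he_vals, 2 * p * (1 - p) * n / (n - 1))
      ho_vals <- c(ho_vals, mean(d == 1))
    }
    out <- rbind(out, data.frame(pop = pp, he = mean(he_vals),
                                 ho = mean(ho_vals)))
  }
  out
}

# Independent Mantel oracle: lower-triangle Pearson r plus joint
# row/column permutation p-value.
oracle_mantel <- function(d1, d2, n_perm = 199, seed = 42) {
  set.seed(seed)
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  cnt <- 0
  for (i in seq_len(n_perm)) {
    prm <- sample(nrow(d2))
    if (cor(d1[lt], d2[prm, prm][lt]) >= r_obs) cnt <- cnt + 1
  }
  list(r = r_obs, p = (1 + cnt) / (n_perm + 1))
}

# tiny deterministic raster stack: one linear-gradient layer, one constant
toy_stack <- function(nr = 4, nc = 5, epoch = "current") {
  grad <- outer(seq_len(nr), seq_len(nc), function(r, c) 2 * c + 0.5 * r)
  env_stack(list(grad = grad, flat = matrix(7, nr, nc)),
            xll = 100, yll = 30, cellsize = 1, epoch = epoch)
}

# small synthetic dataset reused across tests (cached per session)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(synth_config(
        n_neutral = 400, n_adaptive = 10, n_bioclim = 6, n_soil = 2,
        grid_nrow = 12, grid_ncol = 24, rng_seed = 11))
    cache
  }
})
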