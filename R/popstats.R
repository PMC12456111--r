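# SNP filtering and population-genetic summaries: allele-frequency tables,
# per-population diversity, pairwise Weir-Cockerham theta, genotype PCA.

#' Per-population allele frequencies and allele sample sizes
#'
#' @param g A [genotype_matrix()].
#' @return List of class `allele_freq_table`: `p` (pops x loci alternate
#'   allele frequency, `NA` where no alleles observed), `n` (allele sample
#'   size, 2 x non-missing genotypes), `het` (observed heterozygote
#'   fraction), `pops`.
#' @export
allele_freq_table <- function(g) {
  pops <- sort(unique(g$individuals$pop))
  pf <- factor(g$individuals$pop, levels = pops)
  d <- g$dosages
  obs <- !is.na(d)
  cnt <- rowsum(ifelse(obs, 1L, 0L), pf)          # genotypes per pop per locus
  alt <- rowsum(ifelse(obs, d, 0L), pf)           # alt alleles
  hets <- rowsum(ifelse(obs & d == 1L, 1L, 0L), pf)
  n <- 2L * cnt
  p <- ifelse(n > 0, alt / n, NA_real_)
  het <- ifelse(cnt > 0, hets / cnt, NA_real_)
  structure(list(p = p, n = n, het = het, pops = pops,
                 loci = g$loci$locus_id),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("<allele_freq_table> ", length(x$pops), " populations x ",
      ncol(x$p), " loci\n", sep = "")
  invisible(x)
}

#' Tidy an allele-frequency table into long form
#' @param x An [allele_freq_table()].
#' @param ... Unused.
#' @export
tidy.allele_freq_table <- function(x, ...) {
  tibble::tibble(pop = rep(x$pops, times = ncol(x$p)),
                 locus_id = rep(x$loci, each = length(x$pops)),
                 p = as.vector(x$p), n = as.vector(x$n))
}

#' Filter SNPs
#'
#' Applies, in order: (1) first SNP per locus group (`chrom`), (2) presence —
#' genotyped in at least `min_individual_presence` of individuals *and* in at
#' least `min_populations` populations, (3) global minor allele frequency
#' `>= maf_min`, (4) observed heterozygote fraction `<= max_obs_het`. The
#' per-rule removal counts are attached as attribute `"filter_log"`.
#'
#' @param g A [genotype_matrix()].
#' @param cfg A [run_config()].
#' @return Filtered [genotype_matrix()].
#' @export
filter_snps <- function(g, cfg = run_config()) {
  log <- integer(0)
  # 1. first SNP per locus group, in position order
  ord <- order(match(g$loci$chrom, unique(g$loci$chrom)), g$loci$pos)
  first <- !duplicated(g$loci$chrom[ord])
  keep1 <- sort(ord[first])
  log["first_snp_per_locus"] <- ncol(g$dosages) - length(keep1)
  g <- subset_loci(g, keep1)

  # 2. presence: >= 85% individuals and >= min_populations populations
  obs <- !is.na(g$dosages)
  ind_frac <- colMeans(obs)
  pf <- factor(g$individuals$pop)
  pop_presence <- colSums(rowsum(ifelse(obs, 1L, 0L), pf) > 0)
  min_pops <- min(cfg$min_populations, nlevels(pf))
  keep2 <- ind_frac >= cfg$min_individual_presence & pop_presence >= min_pops
  log["presence"] <- sum(!keep2)
  g <- subset_loci(g, keep2)

  # 3. global MAF
  p <- colMeans(g$dosages / 2, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep3 <- maf >= cfg$maf_min
  log["maf"] <- sum(!keep3)
  g <- subset_loci(g, keep3)

  # 4. observed heterozygosity
  hobs <- colMeans(g$dosages == 1L, na.rm = TRUE)
  keep4 <- hobs <= cfg$max_obs_het
  log["obs_het"] <- sum(!keep4)
  g <- subset_loci(g, keep4)

  if (ncol(g$dosages) == 0L)
    stop("no loci survive filtering; review thresholds")
  message("filter_snps removed ", paste(names(log), log, sep = "=",
                                        collapse = ", "),
          "; ", ncol(g$dosages), " loci retained")
  attr(g, "filter_log") <- log
  g
}

#' Per-population diversity statistics
#'
#' For every population and variant site with `n >= 2` sampled alleles:
#' unbiased gene diversity `H_E = 2p(1-p) n/(n-1)` (which for an SNP site
#' equals the per-variant-site nucleotide diversity pi), observed
#' heterozygote fraction `H_O`, both averaged over sites, and
#' `F_IS = 1 - mean(H_O)/mean(H_E)`. Sites monomorphic within a population
#' contribute zero diversity.
#'
#' @param g A [genotype_matrix()] (typically filtered).
#' @return Tibble: `pop`, `n_ind`, `n_sites`, `pi`, `ho`, `he`, `fis`.
#' @export
diversity <- function(g) {
  ft <- allele_freq_table(g)
  he_site <- ifelse(ft$n >= 2, 2 * ft$p * (1 - ft$p) * ft$n / (ft$n - 1),
                    NA_real_)
  ho_site <- ifelse(ft$n >= 2, ft$het, NA_real_)
  he <- unname(rowMeans(he_site, na.rm = TRUE))
  ho <- unname(rowMeans(ho_site, na.rm = TRUE))
  n_sites <- unname(rowSums(!is.na(he_site)))
  he[n_sites == 0] <- NA_real_
  ho[n_sites == 0] <- NA_real_
  tibble::tibble(
    pop = ft$pops,
    n_ind = as.integer(table(factor(g$individuals$pop, levels = ft$pops))),
    n_sites = n_sites,
    pi = he,
    ho = ho,
    he = he,
    fis = ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_))
}

# Weir & Cockerham (1984) variance components, vectorised over loci.
# n = alleles, p = alt freq, h = het fraction (matrices pops x loci).
# Per locus only populations with data enter (r varies by locus).
# Returns per-locus a, b, c; NA where fewer than 2 typed pops or nbar <= 1.
wc_components <- function(n, p, h) {
  nn <- n / 2                       # diploid sample sizes
  typed <- nn > 0
  p0 <- ifelse(typed, p, 0)
  h0 <- ifelse(typed, h, 0)
  r <- colSums(typed)
  ntot <- colSums(nn)
  nbar <- ntot / r
  nc <- (ntot - colSums(nn^2) / ntot) / (r - 1)
  pbar <- colSums(nn * p0) / ntot
  s2 <- colSums(nn * (p0 - rep(pbar, each = nrow(nn)))^2 * typed) /
    ((r - 1) * nbar)
  hbar <- colSums(nn * h0) / ntot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Multilocus Weir-Cockerham theta over a set of populations
#'
#' Ratio-of-sums combination of per-locus variance components.
#'
#' @param g A [genotype_matrix()] or [allele_freq_table()].
#' @return Scalar theta.
#' @export
global_fst <- function(g) {
  ft <- if (inherits(g, "allele_freq_table")) g else allele_freq_table(g)
  comp <- wc_components(ft$n, ft$p, ft$het)
  sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
}

# per-locus theta across all pops (used by the fdist-style scan)
per_locus_fst <- function(ft) {
  comp <- wc_components(ft$n, ft$p, ft$het)
  denom <- comp$a + comp$b + comp$c
  ifelse(is.na(denom) | denom == 0, NA_real_, comp$a / denom)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' Per pair of populations, per-locus Weir & Cockerham (1984) variance
#' components combined over loci as a ratio of sums; loci untyped in either
#' population are skipped for that pair.
#'
#' @param g A [genotype_matrix()] or [allele_freq_table()].
#' @return Symmetric matrix of theta with zero diagonal (small negatives are
#'   legitimate for an unbiased estimator); `NA` where a pair shares no
#'   typed loci.
#' @export
pairwise_fst <- function(g) {
  ft <- if (inherits(g, "allele_freq_table")) g else allele_freq_table(g)
  if (length(ft$pops) < 2) stop("need at least two populations")
  np <- length(ft$pops)
  out <- matrix(0, np, np, dimnames = list(ft$pops, ft$pops))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    sel <- c(i, j)
    comp <- wc_components(ft$n[sel, , drop = FALSE],
                          ft$p[sel, , drop = FALSE],
                          ft$het[sel, , drop = FALSE])
    denom <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
    ok <- sum(!is.na(comp$a)) > 0
    out[i, j] <- out[j, i] <-
      if (ok && denom != 0) sum(comp$a, na.rm = TRUE) / denom else NA_real_
  }
  out
}

#' Tidy a pairwise-F_ST (or any symmetric distance) matrix
#'
#' @param m Symmetric matrix with dimnames.
#' @param value Column name for the values.
#' @return Tibble of the strictly lower triangle: `pop1`, `pop2`, value.
#' @export
tidy_pairwise <- function(m, value = "fst") {
  idx <- which(lower.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(pop1 = rownames(m)[idx[, 1]],
                        pop2 = colnames(m)[idx[, 2]])
  out[[value]] <- m[idx]
  out
}

#' Genotype PCA (GCTA-style GRM convention)
#'
#' Loci are centred by `2p` and scaled by `sqrt(2p(1-p))` with `p` the global
#' allele frequency; missing dosages are mean-imputed per locus; individual
#' scores come from the eigen-decomposition of the individual covariance
#' (GRM).
#'
#' @param g A [genotype_matrix()].
#' @param n_pcs Number of PCs to return (default all).
#' @return List of class `genotype_pca`: `scores` (individuals x PCs),
#'   `eigenvalues`, `var_explained`, `pop_scores` (population means of the
#'   first three PCs), `individuals`.
#' @export
genotype_pca <- function(g, n_pcs = NULL) {
  d <- g$dosages
  n <- nrow(d)
  if (!is.null(n_pcs) && n_pcs >= n)
    stop("requested ", n_pcs, " PCs with only ", n, " individuals")
  p <- colMeans(d / 2, na.rm = TRUE)
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  x <- sweep(d, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0            # mean imputation after centring
  grm <- tcrossprod(x) / ncol(x)
  eg <- eigen(grm, symmetric = TRUE)
  ev <- eg$values
  k <- if (is.null(n_pcs)) n else n_pcs
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(k)], 0)), k)
  rownames(scores) <- g$individuals$individual
  colnames(scores) <- paste0("PC", seq_len(k))
  pop_scores <- rowsum(scores[, seq_len(min(3, k)), drop = FALSE],
                       g$individuals$pop)
  pop_scores <- pop_scores / as.integer(table(g$individuals$pop))
  structure(list(scores = scores, eigenvalues = ev,
                 var_explained = ev / sum(ev),
                 pop_scores = pop_scores,
                 individuals = g$individuals),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("<genotype_pca> ", nrow(x$scores), " individuals; PC1-3 explain ",
      sprintf("%.1f%%", 100 * sum(x$var_explained[1:3])), "\n", sep = "")
  invisible(x)
}

#' Tidy genotype PCA scores
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @export
tidy.genotype_pca <- function(x, ...) {
  dplyr::bind_cols(x$individuals,
                   tibble::as_tibble(x$scores[, 1:min(5, ncol(x$scores)),
                                              drop = FALSE]))
}

#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(n_individuals = nrow(x$scores),
                 pc1_var = x$var_explained[1],
                 pc2_var = x$var_explained[2],
                 pc3_var = x$var_explained[3])
}

#' @export
autoplot.genotype_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$pop)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]))
}
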