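# F_ST-outlier scans and the neutral/outlier partition.
#
# Two scans are implemented: a principal-component deviation scan (per-locus
# z-scores on K PCs, robust Mahalanobis distance, genomic-inflation-factor
# calibration against chi^2_K) and an F_ST-vs-heterozygosity scan against a
# Balding-Nichols island-model null calibrated to the trimmed mean observed
# F_ST. Loci flagged by every configured method form the outlier set; an
# externally produced flag file (e.g. a Bayesian F-model run) can join the
# intersection.

# Deterministic, order-invariant robust location/scatter: iteratively
# recompute mean and covariance from the points whose Mahalanobis distance
# falls below the 95% chi-square quantile. Outlying loci barely move the
# estimate; unlike subsampling estimators the result does not depend on
# locus order or the RNG state.
trimmed_cov <- function(x, n_iter = 5L, keep = 0.95) {
  centre <- colMeans(x)
  cv <- cov(x)
  cut <- qchisq(keep, df = ncol(x))
  for (i in seq_len(n_iter)) {
    d <- mahalanobis(x, centre, cv)
    w <- d <= cut * median(d) / qchisq(0.5, ncol(x))
    centre <- colMeans(x[w, , drop = FALSE])
    cv <- cov(x[w, , drop = FALSE])
  }
  list(center = centre, cov = cv)
}

#' Principal-component deviation outlier scan
#'
#' Regresses each locus's scaled dosages on the first `K` genotype PCs,
#' converts the `K` regression coefficients to z-scores, and measures each
#' locus's robust Mahalanobis distance in z-space. Distances are rescaled by
#' the genomic inflation factor (median distance / chi^2_K median) and
#' referred to chi^2_K; BH-adjusted q-values flag outliers at `alpha`.
#'
#' @param g A [genotype_matrix()].
#' @param K Number of principal components capturing neutral structure.
#' @param alpha FDR threshold for flagging.
#' @return Tibble: `locus_id`, `stat` (GIF-corrected distance), `p`, `q`,
#'   `flag`; the inflation factor is attached as attribute `"gif"`.
#' @export
pc_scan <- function(g, K = 3L, alpha = 0.05) {
  n <- nrow(g$dosages)
  if (K >= n) stop("K must be smaller than the number of individuals")
  d <- g$dosages
  p <- colMeans(d / 2, na.rm = TRUE)
  poly <- p > 0 & p < 1
  x <- sweep(d, 2, 2 * p)
  x <- sweep(x, 2, sqrt(pmax(2 * p * (1 - p), 1e-12)), "/")
  x[is.na(x)] <- 0
  pca <- genotype_pca(g, n_pcs = K)
  u <- qr.Q(qr(pca$scores[, seq_len(K), drop = FALSE]))  # orthonormal basis
  bhat <- crossprod(u, x)                                 # K x L coefficients
  res <- x - u %*% bhat
  sigma2 <- colSums(res^2) / (n - K - 1)
  z <- sweep(bhat, 2, sqrt(pmax(sigma2, 1e-12)), "/")
  z <- t(z)                                               # loci x K
  z[!poly, ] <- NA_real_
  zc <- z[poly, , drop = FALSE]
  rob <- trimmed_cov(zc)
  d2 <- rep(NA_real_, ncol(d))
  d2[poly] <- mahalanobis(zc, rob$center, rob$cov)
  gif <- median(d2, na.rm = TRUE) / qchisq(0.5, K)
  pval <- pchisq(d2 / gif, df = K, lower.tail = FALSE)
  qval <- p.adjust(pval, "BH")
  out <- tibble::tibble(locus_id = g$loci$locus_id,
                        stat = d2 / gif, p = pval, q = qval,
                        flag = !is.na(qval) & qval < alpha)
  attr(out, "gif") <- gif
  out
}

#' F_ST / heterozygosity outlier scan against a Balding-Nichols null
#'
#' Builds the neutral F_ST-heterozygosity envelope by simulating `n_sims`
#' loci under an island model whose F equals the trimmed mean of the observed
#' per-locus multilocus F_ST ("neutral mean F_ST"), matching the observed
#' per-population allele sample sizes. Each observed locus gets an upper-tail
#' p: the fraction of null loci in its expected-heterozygosity bin with F_ST
#' at least as large. A locus is flagged when its p falls in the top-1% tail
#' (`p < 0.01`) *and* its BH q-value is below `alpha`; both criteria are
#' reported individually.
#'
#' @param freqs An [allele_freq_table()].
#' @param n_sims Number of simulated null loci.
#' @param alpha FDR threshold.
#' @param n_bins Equal-width heterozygosity bins on `[0, 0.5]`.
#' @param trim Trim fraction for the calibration mean.
#' @return Tibble: `locus_id`, `fst`, `he`, `p`, `q`, `top_tail`, `flag`;
#'   calibrated F attached as attribute `"neutral_fst"`.
#' @export
fdist_scan <- function(freqs, n_sims = 1e5, alpha = 0.05, n_bins = 20L,
                       trim = 0.05) {
  if (length(freqs$pops) < 2) stop("need at least two populations")
  obs_fst <- per_locus_fst(freqs)
  pbar <- colSums(freqs$n * ifelse(freqs$n > 0, freqs$p, 0)) /
    pmax(colSums(freqs$n), 1)
  obs_he <- 2 * pbar * (1 - pbar)
  f0 <- mean(obs_fst, trim = trim, na.rm = TRUE)
  f0 <- min(max(f0, 1e-4), 0.99)

  # null: BN island model at F = f0, sample sizes = per-pop median alleles
  n_med <- apply(freqs$n, 1, function(x) max(2, median(x[x > 0])))
  np <- length(n_med)
  p_anc <- runif(n_sims, 0.01, 0.99)
  sh <- bn_shape(p_anc, f0)
  pk <- matrix(rbeta(np * n_sims, rep(sh$a, each = np), rep(sh$b, each = np)),
               nrow = np)
  cnt <- matrix(rbinom(np * n_sims, rep(n_med, times = n_sims), as.vector(pk)),
                nrow = np)
  nmat <- matrix(rep(n_med, times = n_sims), nrow = np)
  psim <- cnt / nmat
  # HWE heterozygote fraction within each simulated deme
  hsim <- 2 * psim * (1 - psim)
  sim_fst <- per_locus_fst(list(n = nmat, p = psim, het = hsim))
  sim_pbar <- colSums(nmat * psim) / colSums(nmat)
  sim_he <- 2 * sim_pbar * (1 - sim_pbar)

  brk <- seq(0, 0.5, length.out = n_bins + 1)
  bin_of <- function(he) pmin(pmax(findInterval(he, brk,
                                                rightmost.closed = TRUE), 1L),
                              n_bins)
  ob <- bin_of(obs_he); sb <- bin_of(sim_he)
  pval <- rep(NA_real_, length(obs_fst))
  for (b in sort(unique(ob))) {
    lo <- b; hi <- b
    sel <- which(sb >= lo & sb <= hi)
    # widen sparse bins until >= 100 null draws are available
    while (length(sel) < 100 && (lo > 1 || hi < n_bins)) {
      lo <- max(1L, lo - 1L); hi <- min(n_bins, hi + 1L)
      sel <- which(sb >= lo & sb <= hi)
    }
    if (hi - lo > 0)
      message("fdist_scan: bin ", b, " widened to [", lo, ",", hi, "]")
    idx <- which(ob == b)
    null_f <- sim_fst[sel]
    null_f <- null_f[!is.na(null_f)]
    pval[idx] <- vapply(obs_fst[idx], function(f) {
      if (is.na(f)) return(NA_real_)
      (1 + sum(null_f >= f)) / (1 + length(null_f))
    }, numeric(1))
  }
  qval <- p.adjust(pval, "BH")
  top <- !is.na(pval) & pval < 0.01
  out <- tibble::tibble(locus_id = freqs$loci, fst = obs_fst, he = obs_he,
                        p = pval, q = qval, top_tail = top,
                        flag = top & !is.na(qval) & qval < alpha)
  attr(out, "neutral_fst") <- f0
  out
}

#' Partition loci into neutral and outlier sets
#'
#' A locus is an outlier only when *every* configured method flags it
#' (intersection rule); all remaining loci are the neutral set. An optional
#' external flag table (e.g. from a Bayesian F-model scan run outside the
#' package) joins the intersection.
#'
#' @param reports Named list of scan tibbles, each with `locus_id` and
#'   `flag`.
#' @param external Optional tibble/data.frame with `locus_id` and a 0/1 or
#'   logical `flag` column, or a path to such a TSV.
#' @return List of class `outlier_partition`: `report` (per-locus tibble of
#'   per-method flags and final `class`), `neutral`, `outliers` (locus id
#'   vectors), `counts` (per method and intersection).
#' @export
partition_outliers <- function(reports, external = NULL) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  if (!is.null(external)) {
    if (is.character(external))
      external <- read.table(external, header = TRUE, sep = "\t")
    reports$external <- tibble::tibble(
      locus_id = as.character(external$locus_id),
      flag = as.logical(external$flag))
  }
  ids <- reports[[1]]$locus_id
  tab <- tibble::tibble(locus_id = ids)
  for (m in names(reports)) {
    stopifnot(setequal(reports[[m]]$locus_id, ids))
    tab[[paste0("flag_", m)]] <-
      reports[[m]]$flag[match(ids, reports[[m]]$locus_id)] %in% TRUE
  }
  flag_cols <- paste0("flag_", names(reports))
  hit <- Reduce(`&`, tab[flag_cols])
  tab$class <- ifelse(hit, "outlier", "neutral")
  counts <- c(vapply(tab[flag_cols], sum, integer(1)),
              intersection = sum(hit))
  message("outlier partition: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(list(report = tab,
                 neutral = ids[!hit],
                 outliers = ids[hit],
                 counts = counts),
            class = "outlier_partition")
}

#' @export
print.outlier_partition <- function(x, ...) {
  cat("<outlier_partition> ", length(x$outliers), " outlier(s) / ",
      length(x$neutral), " neutral loci\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.outlier_partition <- function(x, ...) x$report

#' @export
glance.outlier_partition <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$report),
                 n_outliers = length(x$outliers),
                 n_neutral = length(x$neutral))
}
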