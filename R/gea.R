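# Genotype-environment association: ridge latent-factor linear mixed model
# (one scan per environmental variable) and an RDA-loading scan, intersected
# into core candidate loci.

# Alternating ridge-LFMM solver for a single environmental variable.
# y: n x L centred response; x: centred length-n predictor; K latent factors.
# Returns U (n x K), effects b (length L), iterations, converged flag.
ridge_lfmm_solve <- function(y, x, K, lambda = 1e-5, max_iter = 200L,
                             tol = 1e-6) {
  n <- nrow(y)
  if (K >= min(dim(y))) stop("K must be below min(dim(response))")
  xtx <- sum(x^2) + lambda
  if (K == 0L)
    return(list(U = matrix(0, n, 0), b = drop(crossprod(x, y)) / xtx,
                iterations = 0L, converged = TRUE))
  sv <- svd(y, nu = K, nv = K)
  U <- sv$u %*% diag(sv$d[seq_len(K)], K)
  V <- sv$v
  b <- rep(0, ncol(y))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    b_new <- drop(crossprod(x, y - tcrossprod(U, V))) / xtx
    resid <- y - outer(x, b_new)
    sv <- svd(resid, nu = K, nv = K)
    U <- sv$u %*% diag(sv$d[seq_len(K)], K)
    V <- sv$v
    delta <- sqrt(sum((b_new - b)^2) / max(sum(b^2), 1e-12))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ridge LFMM did not converge; final relative change ",
            format(delta))
  list(U = U, b = b, iterations = it, converged = converged)
}

#' Latent-factor linear mixed model scan
#'
#' For each environmental variable, fits a ridge LFMM: latent factors come
#' from a truncated SVD of the response minus the environmental effect, and
#' per-locus effects from ridge regression of the deflated response on the
#' variable, alternated to convergence. Final per-locus z-scores are the
#' t-statistics of the variable in an OLS refit on (variable + latent
#' factors), calibrated by the genomic inflation factor
#' (`median(z^2) / median(chi^2_1)`); q-values are BH-adjusted per variable.
#'
#' @param y Response matrix: populations x loci allele frequencies (or
#'   individuals x loci dosages).
#' @param env Tibble with `pop` plus variable columns (or a numeric matrix).
#' @param K Number of latent factors (0 = plain per-locus regression).
#' @param lambda Ridge penalty.
#' @param alpha FDR threshold used for the `flag` column.
#' @return Tibble: `variable`, `locus_id`, `effect`, `z`, `p`, `q`, `flag`;
#'   per-variable inflation factors as attribute `"gif"`.
#' @export
lfmm_scan <- function(y, env, K = 3L, lambda = 1e-5, alpha = 0.05) {
  y <- as.matrix(y)
  xs <- env_values(env)
  loci <- colnames(y)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(y)))
  yc <- scale(y, center = TRUE, scale = FALSE)
  gifs <- numeric(0)
  out <- purrr::map_dfr(colnames(xs), function(v) {
    x <- as.numeric(scale(xs[, v]))
    fit <- ridge_lfmm_solve(yc, x, K = K, lambda = lambda)
    X <- cbind(1, x, fit$U)
    xtxi <- solve(crossprod(X))
    bhat <- xtxi %*% crossprod(X, yc)
    res <- yc - X %*% bhat
    df <- nrow(yc) - ncol(X)
    sigma2 <- colSums(res^2) / df
    se <- sqrt(pmax(sigma2 * xtxi[2, 2], 1e-300))
    z <- bhat[2, ] / se
    gif <- median(z^2) / qchisq(0.5, 1)
    gifs[[v]] <<- gif
    p <- pchisq(z^2 / gif, df = 1, lower.tail = FALSE)
    q <- p.adjust(p, "BH")
    tibble::tibble(variable = v, locus_id = loci, effect = bhat[2, ],
                   z = z, p = p, q = q, flag = q < alpha)
  })
  attr(out, "gif") <- gifs
  out
}

#' RDA-loading outlier scan
#'
#' Fits an RDA of the response on the environmental variables and flags loci
#' whose locus scores lie more than `sd_cutoff` standard deviations from the
#' mean on one or more of the scanned constrained axes (inclusive at the
#' boundary). By default every constrained axis is scanned: cline loci tied
#' to a single variable typically load on a later axis than the broad
#' structure-aligned gradients that dominate the first axes.
#'
#' @param y Response matrix (populations x loci).
#' @param env Environmental predictors.
#' @param sd_cutoff Standard-deviation cutoff (default 3).
#' @param n_axes Number of constrained axes to scan (clipped, with a
#'   warning, to the number available; default all available).
#' @return Tibble: `locus_id`, per-axis loadings (`axis1`..), `max_abs_z`
#'   (largest |standardised loading|), `flag`.
#' @export
rda_loading_scan <- function(y, env, sd_cutoff = 3, n_axes = NULL) {
  fit <- rda_fit(y, env, n_perm = 0)
  ld <- fit$loadings
  avail <- ncol(ld)
  if (is.null(n_axes)) n_axes <- avail
  if (n_axes > avail) {
    warning("n_axes clipped from ", n_axes, " to ", avail)
    n_axes <- avail
  }
  ld <- ld[, seq_len(n_axes), drop = FALSE]
  zs <- scale(ld)
  flag <- rowSums(abs(zs) >= sd_cutoff) > 0
  out <- tibble::tibble(locus_id = rownames(ld))
  for (a in seq_len(n_axes)) out[[paste0("axis", a)]] <- ld[, a]
  out$max_abs_z <- apply(abs(zs), 1, max)
  out$flag <- flag
  out
}

#' Intersect LFMM and RDA hits into core GEA candidates
#'
#' A locus is an LFMM hit when `q < alpha` for at least one variable and an
#' RDA hit when flagged on at least one scanned axis; core candidates are
#' the intersection, annotated with their associated variables.
#'
#' @param lfmm Output of [lfmm_scan()].
#' @param rda Output of [rda_loading_scan()].
#' @param alpha FDR threshold on the LFMM q-values.
#' @return List of class `gea_result`: `table` (per-locus flags), `core`
#'   (tibble `locus_id`, `variables`), `lfmm`, `rda`.
#' @export
core_candidates <- function(lfmm, rda, alpha = 0.05) {
  by_locus <- lfmm |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      lfmm_hit = any(.data$q < alpha),
      variables = paste(sort(unique(.data$variable[.data$q < alpha])),
                        collapse = ";"),
      min_q = min(.data$q), .groups = "drop")
  tab <- dplyr::left_join(by_locus,
                          dplyr::select(rda, "locus_id", rda_hit = "flag"),
                          by = "locus_id") |>
    dplyr::mutate(rda_hit = .data$rda_hit %in% TRUE,
                  core = .data$lfmm_hit & .data$rda_hit)
  core <- dplyr::filter(tab, .data$core) |>
    dplyr::select("locus_id", "variables", "min_q")
  message("GEA: ", sum(tab$lfmm_hit), " LFMM hit(s), ", sum(tab$rda_hit),
          " RDA hit(s), ", nrow(core), " core candidate(s)")
  structure(list(table = tab, core = core, lfmm = lfmm, rda = rda),
            class = "gea_result")
}

#' @export
print.gea_result <- function(x, ...) {
  cat("<gea_result> ", sum(x$table$lfmm_hit), " LFMM / ",
      sum(x$table$rda_hit), " RDA hits; ", nrow(x$core),
      " core candidate(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.gea_result <- function(x, ...) x$table

#' @export
glance.gea_result <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$table),
                 n_lfmm = sum(x$table$lfmm_hit),
                 n_rda = sum(x$table$rda_hit),
                 n_core = nrow(x$core))
}

#' Run the GEA scans within each genetic group
#'
#' Applies [lfmm_scan()], [rda_loading_scan()] and [core_candidates()] to the
#' population subset of each group.
#'
#' @param y Population x locus response matrix (rownames = pop labels).
#' @param env Environmental tibble (`pop` + variables).
#' @param groups Named vector or tibble (`pop`, `group`) assigning each
#'   population to a group.
#' @param K Latent factors for the within-group LFMM.
#' @param ... Passed to the scans.
#' @return Named list of `gea_result`, one per group.
#' @export
gea_by_group <- function(y, env, groups, K = 1L, ...) {
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$pop)
  pops <- rownames(y)
  split_pops <- split(pops, groups[pops])
  purrr::map(split_pops, function(ps) {
    sel <- pops %in% ps
    ysub <- y[sel, , drop = FALSE]
    keep <- apply(ysub, 2, sd) > 0
    envsub <- env[match(ps, env$pop), , drop = FALSE]
    core_candidates(
      lfmm_scan(ysub[, keep, drop = FALSE], envsub, K = K),
      rda_loading_scan(ysub[, keep, drop = FALSE], envsub))
  })
}
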