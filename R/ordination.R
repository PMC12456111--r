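# Environmental-distance construction, (partial) redundancy analysis and the
# variance-partitioning table. RDA machinery is delegated to vegan; the
# response is by default a centred population x locus allele-frequency
# matrix.

#' Euclidean distance on the first two environmental PCs
#'
#' Variables are z-scored, a PCA is run across populations, and pairwise
#' Euclidean distances are computed on the first two component scores.
#'
#' @param env Tibble with `pop` plus numeric variable columns, or a plain
#'   numeric matrix/data frame.
#' @param vars Optional subset of variable names (e.g. climate only).
#' @return Symmetric distance matrix (pops x pops).
#' @export
env_pca_distance <- function(env, vars = NULL) {
  x <- env_values(env, vars)
  if (ncol(x) < 3) stop("need at least three variables")
  keep <- apply(x, 2, sd) > 0
  if (!any(keep)) {
    # identical rows: all populations coincide in environmental space
    z <- matrix(0, nrow(x), nrow(x), dimnames = list(rownames(x),
                                                     rownames(x)))
    return(z)
  }
  if (!all(keep)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  d <- as.matrix(dist(pc$x[, 1:2, drop = FALSE]))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# pull the numeric matrix out of an env tibble
env_values <- function(env, vars = NULL) {
  if (is.matrix(env)) return(env)
  env <- as.data.frame(env)
  rn <- if ("pop" %in% names(env)) env$pop else rownames(env)
  x <- as.matrix(env[, setdiff(names(env), c("pop", "group")), drop = FALSE])
  if (!is.null(vars)) x <- x[, vars, drop = FALSE]
  rownames(x) <- rn
  x
}

#' (Partial) redundancy analysis of a response matrix
#'
#' Least-squares constrained ordination of `y` on `x`, optionally after
#' removing variance explained by conditioning variables `z` (both `y` and
#' `x` residualised on `z`). Wraps [vegan::rda()]; adjusted R^2 is Ezekiel's
#' formula via [vegan::RsquareAdj()], significance by permutation of
#' (residualised) response rows.
#'
#' @param y Numeric response matrix (rows = populations), e.g. allele
#'   frequencies; centred internally by vegan.
#' @param x Predictor tibble/matrix.
#' @param z Optional conditioning tibble/matrix.
#' @param n_perm Permutations for the overall test.
#' @param seed RNG seed for the permutation test.
#' @return List of class `rda_fit`: `model` (the vegan object), `r2`,
#'   `adj_r2`, `p`, `loadings` (locus scores on constrained axes),
#'   `eigenvalues`.
#' @export
rda_fit <- function(y, x, z = NULL, n_perm = 999L, seed = 1L) {
  y <- as.matrix(y)
  xm <- as.data.frame(env_values(x))
  # prune aliased (rank-deficient) predictors up front
  qx <- qr(scale(as.matrix(xm), scale = FALSE))
  if (qx$rank < ncol(xm)) {
    drop <- colnames(xm)[-qx$pivot[seq_len(qx$rank)]]
    warning("dropping aliased predictor(s): ", paste(drop, collapse = ", "))
    xm <- xm[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  dat <- xm
  if (!is.null(z)) {
    zm <- as.data.frame(env_values(z))
    names(zm) <- paste0("cond_", names(zm))
    dat <- cbind(dat, zm)
    fml <- stats::as.formula(paste(
      "y ~", paste(names(xm), collapse = " + "),
      "+ Condition(", paste(names(zm), collapse = " + "), ")"))
  } else {
    fml <- stats::as.formula(paste("y ~", paste(names(xm), collapse = " + ")))
  }
  mod <- vegan::rda(fml, data = dat)
  r2 <- vegan::RsquareAdj(mod)
  set.seed(seed)
  an <- try(vegan::anova.cca(mod, permutations = n_perm), silent = TRUE)
  pval <- if (inherits(an, "try-error")) NA_real_ else an$`Pr(>F)`[1]
  if (is.na(pval) && n_perm > 0 && !is.null(r2$r.squared) &&
      r2$r.squared > 1 - 1e-9)
    pval <- 1 / (n_perm + 1)  # perfect fit beats every permutation
  ld <- try(vegan::scores(mod, display = "species",
                          choices = seq_len(max(1, mod$CCA$rank)),
                          scaling = 0), silent = TRUE)
  if (inherits(ld, "try-error")) ld <- NULL
  structure(list(model = mod, r2 = r2$r.squared,
                 adj_r2 = if (is.null(r2$adj.r.squared)) NA_real_
                          else r2$adj.r.squared,
                 p = pval, loadings = ld,
                 eigenvalues = mod$CCA$eig),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("<rda_fit> adj R2 = ", sprintf("%.3f", x$adj_r2),
      ", p = ", format(x$p), ", ", length(x$eigenvalues),
      " constrained axis/axes\n", sep = "")
  invisible(x)
}

#' @export
glance.rda_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, adj_r2 = x$adj_r2, p = x$p,
                 n_axes = length(x$eigenvalues))
}

#' Variance partitioning across environment, geography and structure
#'
#' Runs the full RDA of the response on all three predictor sets and the
#' three partial RDAs in which each set is conditioned on the other two,
#' reporting adjusted R^2 (small negatives are legitimate) and permutation
#' p-values, plus the confounded remainder (full minus the three conditional
#' fractions).
#'
#' @param y Response matrix (populations x loci allele frequencies, centred
#'   by the RDA).
#' @param env Environmental predictors (pruned climate + soil).
#' @param geog Geographic predictors (retained MEM vectors).
#' @param struct Structure proxies (first three genetic PC population
#'   scores).
#' @param n_perm Permutations.
#' @param seed RNG seed.
#' @return Tibble of class `variance_partition`: `fraction`, `adj_r2`, `p`.
#' @export
variance_partition <- function(y, env, geog, struct, n_perm = 999L,
                               seed = 1L) {
  sets <- list(env = env_values(env), geog = env_values(geog),
               struct = env_values(struct))
  all_names <- unlist(lapply(sets, colnames))
  dup <- unique(all_names[duplicated(all_names)])
  if (length(dup))
    warning("predictor(s) present in more than one set (confounded): ",
            paste(dup, collapse = ", "))
  full_x <- do.call(cbind, unname(sets))
  fits <- list(
    full = rda_fit(y, full_x, n_perm = n_perm, seed = seed),
    `env|geog+struct` = rda_fit(y, sets$env, cbind(sets$geog, sets$struct),
                                n_perm = n_perm, seed = seed),
    `geog|env+struct` = rda_fit(y, sets$geog, cbind(sets$env, sets$struct),
                                n_perm = n_perm, seed = seed),
    `struct|env+geog` = rda_fit(y, sets$struct, cbind(sets$env, sets$geog),
                                n_perm = n_perm, seed = seed))
  tab <- purrr::map_dfr(names(fits), function(nm)
    tibble::tibble(fraction = nm, adj_r2 = fits[[nm]]$adj_r2,
                   p = fits[[nm]]$p))
  confounded <- tab$adj_r2[1] - sum(tab$adj_r2[-1])
  tab <- dplyr::bind_rows(tab,
                          tibble::tibble(fraction = "confounded",
                                         adj_r2 = confounded, p = NA_real_))
  class(tab) <- c("variance_partition", class(tab))
  tab
}

#' @export
autoplot.variance_partition <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$fraction != "full")
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction, .data$adj_r2)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "adjusted R²") +
    ggplot2::coord_flip()
}
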