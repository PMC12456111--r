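# Gradient-forest turnover modelling: per-SNP random-forest regressions of
# population allele frequencies on environmental predictors, aggregated into
# R^2-weighted predictor importances and cumulative-importance ("turnover")
# functions that map climate space into genetic-composition space.

#' Fit a gradient-forest turnover model
#'
#' Fits one random-forest regression (default 500 trees) per locus of the
#' population allele frequencies on the predictors. Loci with positive
#' out-of-bag R^2 are retained; predictor importance is the mean over
#' retained loci of (per-locus permutation-importance share x locus R^2).
#' Every split's impurity improvement is credited to its predictor at the
#' split value, binned along the predictor's observed range, normalised so
#' the total equals the predictor's weighted importance, and cumulatively
#' summed into the turnover function `F_p`.
#'
#' @param freqs [allele_freq_table()] or a populations x loci frequency
#'   matrix.
#' @param env Environmental tibble (`pop` + variables) or matrix; rows match
#'   the frequency matrix.
#' @param n_trees Trees per per-SNP forest.
#' @param mtry Predictors tried per split (default `ceiling(p/3)`).
#' @param min_split Minimum node size eligible for splitting.
#' @param n_bins Bins per predictor for the turnover functions.
#' @param seed RNG seed (forests are fully reproducible given it).
#' @return List of class `turnover_model`: `importance` (named, R^2
#'   weighted), `turnover` (per predictor: `breaks`, `cumulative`),
#'   `locus_r2`, `ranking`, `n_trees`, `n_bins`, `seed`.
#' @export
fit_gradient_forest <- function(freqs, env, n_trees = 500L, mtry = NULL,
                                min_split = 5L, n_bins = 201L, seed = 1L) {
  y <- if (inherits(freqs, "allele_freq_table")) freqs$p else as.matrix(freqs)
  x <- env_values(env)
  stopifnot(nrow(y) == nrow(x))
  if (nrow(x) < 5) stop("need at least five populations")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  loci <- colnames(y)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(y)))

  set.seed(seed)
  ranges <- apply(x, 2, range)
  breaks <- lapply(seq_len(p), function(j)
    seq(ranges[1, j], ranges[2, j], length.out = n_bins + 1))
  names(breaks) <- colnames(x)
  bin_mass <- matrix(0, n_bins, p, dimnames = list(NULL, colnames(x)))
  imp_sum <- setNames(numeric(p), colnames(x))
  locus_r2 <- setNames(rep(NA_real_, length(loci)), loci)
  n_retained <- 0L

  for (l in seq_along(loci)) {
    yl <- y[, l]
    ok <- !is.na(yl)
    if (sum(ok) < 5 || sd(yl[ok]) == 0) next
    fit <- gf_forest_cpp(x[ok, , drop = FALSE], yl[ok], as.integer(n_trees),
                         as.integer(mtry), as.integer(min_split))
    pred <- fit$oob_pred
    use <- !is.na(pred)
    r2 <- 1 - mean((yl[ok][use] - pred[use])^2) / var(yl[ok])
    locus_r2[l] <- r2
    if (is.na(r2) || r2 <= 0) next
    n_retained <- n_retained + 1L
    raw <- pmax(fit$importance, 0)
    share <- if (sum(raw) > 0) raw / sum(raw) else rep(0, p)
    imp_sum <- imp_sum + share * r2
    # credit split improvements, scaled so this locus's total mass is r2
    tot_imp <- sum(fit$split_improvement)
    if (tot_imp > 0) {
      wgt <- fit$split_improvement / tot_imp * r2
      for (j in seq_len(p)) {
        sel <- fit$split_var == j
        if (!any(sel)) next
        b <- pmin(pmax(findInterval(fit$split_value[sel], breaks[[j]],
                                    rightmost.closed = TRUE), 1L), n_bins)
        agg <- rowsum(wgt[sel], b)
        bin_mass[as.integer(rownames(agg)), j] <-
          bin_mass[as.integer(rownames(agg)), j] + agg[, 1]
      }
    }
  }
  if (n_retained == 0L) stop("no predictable turnover: no locus has positive OOB R^2")

  importance <- imp_sum / n_retained
  turnover <- lapply(seq_len(p), function(j) {
    mass <- bin_mass[, j]
    tot <- sum(mass)
    cum <- if (tot > 0) cumsum(mass) / tot * importance[j]
           else rep(0, n_bins)
    list(breaks = breaks[[j]], cumulative = cum)
  })
  names(turnover) <- colnames(x)
  structure(list(importance = importance,
                 turnover = turnover,
                 locus_r2 = locus_r2,
                 n_retained = n_retained,
                 ranking = names(sort(importance, decreasing = TRUE)),
                 n_trees = n_trees, n_bins = n_bins, seed = seed),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("<turnover_model> ", length(x$importance), " predictor(s), ",
      x$n_retained, " locus/loci with positive OOB R^2, ",
      x$n_trees, " trees\n", sep = "")
  cat("  top predictors: ",
      paste(head(x$ranking, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a turnover function
#'
#' Linear interpolation of the cumulative-importance curve; values outside
#' the training range are clamped to it (extrapolated turnover is undefined
#' by the method), so `F_p(min) = 0` and `F_p(max)` equals the predictor's
#' total importance.
#'
#' @param model A [fit_gradient_forest()] model.
#' @param variable Predictor name.
#' @param values Numeric vector.
#' @return Numeric vector of cumulative importances.
#' @export
eval_turnover <- function(model, variable, values) {
  tv <- model$turnover[[variable]]
  if (is.null(tv)) stop("predictor '", variable, "' not in the model")
  br <- tv$breaks
  v <- pmin(pmax(values, br[1]), br[length(br)])
  stats::approx(br, c(0, tv$cumulative), xout = v, rule = 2)$y
}

#' Tidy turnover curves
#' @param x A `turnover_model`.
#' @param ... Unused.
#' @return Tibble: `variable`, `value` (bin upper edge), `cumulative`.
#' @export
tidy.turnover_model <- function(x, ...) {
  purrr::map_dfr(names(x$turnover), function(v)
    tibble::tibble(variable = v,
                   value = x$turnover[[v]]$breaks[-1],
                   cumulative = x$turnover[[v]]$cumulative))
}

#' @export
glance.turnover_model <- function(x, ...) {
  tibble::tibble(n_predictors = length(x$importance),
                 n_retained_loci = x$n_retained,
                 total_importance = sum(x$importance),
                 top_predictor = x$ranking[1])
}

#' @export
autoplot.turnover_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$value, .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = "predictor value", y = "cumulative importance")
}

#' Serialise / restore a turnover model as JSON
#' @param model A `turnover_model`.
#' @param path JSON path.
#' @export
write_turnover_model <- function(model, path) {
  m <- unclass(model)
  m$importance <- as.list(m$importance)    # keep names in JSON objects
  m$locus_r2 <- as.list(m$locus_r2)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_turnover_model
#' @export
read_turnover_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$importance <- unlist(m$importance)
  m$locus_r2 <- unlist(m$locus_r2)
  m$turnover <- lapply(m$turnover, function(tv)
    list(breaks = as.numeric(tv$breaks),
         cumulative = as.numeric(tv$cumulative)))
  class(m) <- "turnover_model"
  m
}

#' Prune correlated environmental variables by gradient-forest importance
#'
#' While any pair of variables has `|Pearson r| > r_max`, the pair with the
#' largest |r| loses its lower-importance member; removals are messaged.
#'
#' @param env Environmental tibble (`pop` + variables).
#' @param model A `turnover_model` providing importances (or a named numeric
#'   vector of importances).
#' @param r_max Correlation threshold.
#' @return `env` with the dropped columns removed.
#' @export
prune_variables <- function(env, model, r_max = 0.75) {
  imp <- if (inherits(model, "turnover_model")) model$importance else model
  x <- env_values(env)
  stopifnot(all(colnames(x) %in% names(imp)))
  dropped <- character(0)
  repeat {
    cc <- abs(cor(x))
    diag(cc) <- 0
    if (max(cc) <= r_max) break
    idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    pair <- colnames(x)[idx]
    loser <- pair[which.min(imp[pair])]
    dropped <- c(dropped, loser)
    x <- x[, setdiff(colnames(x), loser), drop = FALSE]
  }
  if (length(dropped))
    message("prune_variables dropped: ", paste(dropped, collapse = ", "))
  env[, !(names(env) %in% dropped), drop = FALSE]
}

#' Transform an environmental stack into genetic-composition space
#'
#' Applies each predictor's turnover function to its raster layer (values
#' clamped to the training range).
#'
#' @param model A `turnover_model`.
#' @param stack An [env_stack()]; must contain every model predictor.
#' @return An [env_stack()] of transformed layers.
#' @export
transform_env <- function(model, stack) {
  miss <- setdiff(names(model$turnover), names(stack$layers))
  if (length(miss))
    stop("predictor(s) missing from stack: ", paste(miss, collapse = ", "))
  layers <- lapply(names(model$turnover), function(v) {
    m <- stack$layers[[v]]
    out <- m
    ok <- !is.na(m)
    out[ok] <- eval_turnover(model, v, m[ok])
    out
  })
  names(layers) <- names(model$turnover)
  env_stack(layers, xll = stack$xll, yll = stack$yll,
            cellsize = stack$cellsize, crs = stack$crs, epoch = stack$epoch)
}
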