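# Genomic-vulnerability surfaces: local, migration-constrained forward, and
# reverse genetic offsets on the turnover-transformed environment, their RGB
# composite, and the regression-based risk of non-adaptedness (RONA).

# composition matrix of unmasked cells: rows = cells (column-major ids),
# cols = predictors; plus their centre coordinates
composition_matrix <- function(model, stack) {
  tr <- transform_env(model, stack)
  cc <- cell_centres(stack)
  ok <- !as.vector(stack$mask)
  comp <- do.call(cbind, lapply(tr$layers, as.vector))[ok, , drop = FALSE]
  list(comp = comp, cells = cc[ok, ], nrow = stack$nrow, ncol = stack$ncol)
}

check_grids_match <- function(a, b) {
  if (!identical(stack_dim(a), stack_dim(b)) ||
      abs(a$xll - b$xll) > 1e-9 || abs(a$yll - b$yll) > 1e-9 ||
      abs(a$cellsize - b$cellsize) > 1e-12)
    stop("current and future stacks are on different grids")
  if (!setequal(names(a$layers), names(b$layers)))
    stop("current and future stacks carry different variables")
}

grid_from_values <- function(vals, cells, nr, nc) {
  m <- matrix(NA_real_, nr, nc)
  m[cbind(cells$row, cells$col)] <- vals
  m
}

#' Local genetic offset
#'
#' Euclidean distance, per grid cell, between the current and future genetic
#' compositions (turnover-transformed environments).
#'
#' @param model A [fit_gradient_forest()] turnover model.
#' @param current,future [env_stack()]s on the same grid with the model's
#'   predictors.
#' @return Matrix (grid) of offsets, `NA` on masked cells.
#' @export
local_offset <- function(model, current, future) {
  check_grids_match(current, future)
  a <- composition_matrix(model, current)
  b <- composition_matrix(model, future)
  vals <- sqrt(rowSums((a$comp - b$comp)^2))
  grid_from_values(vals, a$cells, current$nrow, current$ncol)
}

# squared distances between two composition matrices (rows x rows)
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Forward genetic offset under a migration constraint
#'
#' Per cell, the minimum Euclidean distance between the cell's current
#' composition and the future composition of any cell within `radius_km`
#' great-circle km (the cell itself included); `Inf` means unlimited
#' migration.
#'
#' @inheritParams local_offset
#' @param radius_km Maximum migration distance in km (`Inf` = unlimited).
#' @return Matrix (grid) of offsets.
#' @export
forward_offset <- function(model, current, future, radius_km = Inf) {
  check_grids_match(current, future)
  if (is.finite(radius_km) && radius_km < current$cellsize * 111.32 / 2)
    warning("radius below one cell; forward offset reduces to local offset")
  a <- composition_matrix(model, current)
  b <- composition_matrix(model, future)
  d2 <- cross_dist2(a$comp, b$comp)
  if (is.finite(radius_km)) {
    km <- outer(seq_len(nrow(a$cells)), seq_len(nrow(b$cells)),
                function(i, j) haversine_km(a$cells$lon[i], a$cells$lat[i],
                                            b$cells$lon[j], b$cells$lat[j]))
    d2[km > radius_km] <- Inf
  }
  vals <- sqrt(apply(d2, 1, min))
  vals[!is.finite(vals)] <- NA_real_
  grid_from_values(vals, a$cells, current$nrow, current$ncol)
}

#' Reverse genetic offset
#'
#' Per cell, the minimum distance between the cell's *future* composition and
#' the *current* composition of any cell in the range: how well any extant
#' population is preadapted to that future climate.
#'
#' @inheritParams local_offset
#' @return Matrix (grid) of offsets.
#' @export
reverse_offset <- function(model, current, future) {
  check_grids_match(current, future)
  a <- composition_matrix(model, current)
  b <- composition_matrix(model, future)
  d2 <- cross_dist2(b$comp, a$comp)
  vals <- sqrt(apply(d2, 1, min))
  grid_from_values(vals, b$cells, current$nrow, current$ncol)
}

#' Compute the full offset surface for one scenario
#'
#' @inheritParams local_offset
#' @param radii_km Forward-offset migration radii.
#' @param locus_set Tag recorded on the result (e.g. `"neutral"`,
#'   `"core_adaptive"`).
#' @return List of class `offset_surface`: `local`, `forward` (named list
#'   per radius), `reverse`, plus grid metadata and tags.
#' @export
offset_surface <- function(model, current, future,
                           radii_km = c(50, 100, 200, 500, Inf),
                           locus_set = "neutral") {
  fw <- lapply(radii_km, function(r) forward_offset(model, current, future, r))
  names(fw) <- ifelse(is.finite(radii_km), paste0(radii_km, "km"), "unlimited")
  structure(list(local = local_offset(model, current, future),
                 forward = fw,
                 reverse = reverse_offset(model, current, future),
                 radii_km = radii_km,
                 epoch = future$epoch, locus_set = locus_set,
                 xll = current$xll, yll = current$yll,
                 cellsize = current$cellsize),
            class = "offset_surface")
}

#' @export
print.offset_surface <- function(x, ...) {
  cat("<offset_surface> epoch '", x$epoch, "', locus set '", x$locus_set,
      "'\n  mean local offset ", sprintf("%.4g", mean(x$local, na.rm = TRUE)),
      "; forward radii: ", paste(names(x$forward), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy an offset surface into long form
#' @param x An `offset_surface`.
#' @param ... Unused.
#' @export
tidy.offset_surface <- function(x, ...) {
  grids <- c(list(local = x$local), x$forward, list(reverse = x$reverse))
  purrr::map_dfr(names(grids), function(nm) {
    m <- grids[[nm]]
    tibble::tibble(metric = nm,
                   row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   offset = as.vector(m))
  })
}

#' @export
glance.offset_surface <- function(x, ...) {
  tibble::tibble(
    epoch = x$epoch, locus_set = x$locus_set,
    mean_local = mean(x$local, na.rm = TRUE),
    mean_forward_unlimited = mean(x$forward[[length(x$forward)]],
                                  na.rm = TRUE),
    mean_reverse = mean(x$reverse, na.rm = TRUE))
}

#' RGB composite of local, forward and reverse offsets
#'
#' Each band is min-max scaled to `[0, 255]` over unmasked cells (R = local,
#' G = forward at the chosen radius, B = reverse); a constant band maps to 0
#' with a warning. Scaling bounds are kept so offsets can be recovered up to
#' quantisation.
#'
#' @param surface An [offset_surface()].
#' @param forward_radius Name of the forward grid to use (default the last,
#'   i.e. unlimited).
#' @return List of class `offset_rgb`: `r`, `g`, `b` integer matrices and
#'   `bounds` (per-band min/max).
#' @export
rgb_composite <- function(surface,
                          forward_radius = names(surface$forward)[length(surface$forward)]) {
  bands <- list(r = surface$local,
                g = surface$forward[[forward_radius]],
                b = surface$reverse)
  bounds <- list()
  scaled <- purrr::imap(bands, function(m, nm) {
    rng <- range(m, na.rm = TRUE)
    bounds[[nm]] <<- rng
    if (diff(rng) == 0) {
      warning("constant band '", nm, "' mapped to 0")
      return(m * 0)
    }
    round((m - rng[1]) / diff(rng) * 255)
  })
  structure(c(scaled, list(bounds = bounds,
                           forward_radius = forward_radius)),
            class = "offset_rgb")
}

#' Risk of non-adaptedness (RONA)
#'
#' For each environmental variable and each associated core locus, fits the
#' linear regression of the locus's population allele frequencies on the
#' variable; regressions with slope p < 0.05 are kept. RONA of a population
#' for a locus is `|a * v_future + b - p_current|`; the per-population,
#' per-variable summary is the regression-R^2-weighted mean over kept loci
#' with its weighted standard error.
#'
#' @param freqs [allele_freq_table()] or populations x loci frequency matrix
#'   (rownames = pops).
#' @param core Tibble with `locus_id` and `variables` (";"-separated
#'   associated variables, as in [core_candidates()]`$core`), or a
#'   `gea_result`.
#' @param env_current,env_future Environmental tibbles (`pop` + variables),
#'   rows aligned with `freqs`.
#' @param slope_alpha Slope p-value threshold for keeping a locus.
#' @param weighted Weight by regression R^2 (otherwise uniform).
#' @return Tibble of class `rona_table`: `pop`, `variable`, `rona`, `se`,
#'   `n_loci`.
#' @export
rona <- function(freqs, core, env_current, env_future, slope_alpha = 0.05,
                 weighted = TRUE) {
  p <- if (inherits(freqs, "allele_freq_table")) freqs$p else as.matrix(freqs)
  if (inherits(core, "gea_result")) core <- core$core
  assoc <- tidyr::separate_rows(core[, c("locus_id", "variables")],
                                "variables", sep = ";") |>
    dplyr::rename(variable = "variables") |>
    dplyr::filter(.data$variable != "")
  pops <- env_current$pop
  out <- purrr::map_dfr(unique(assoc$variable), function(v) {
    vc <- env_current[[v]]; vf <- env_future[[v]]
    loci <- assoc$locus_id[assoc$variable == v]
    per_locus <- purrr::map_dfr(loci, function(l) {
      yv <- p[, l]
      fit <- summary(lm(yv ~ vc))
      if (nrow(fit$coefficients) < 2 ||
          fit$coefficients[2, 4] >= slope_alpha) return(NULL)
      a <- fit$coefficients[2, 1]; b <- fit$coefficients[1, 1]
      tibble::tibble(pop = pops, locus_id = l,
                     rona = abs(a * vf + b - yv),
                     w = if (weighted) fit$r.squared else 1)
    })
    if (nrow(per_locus) == 0) {
      warning("no locus with a significant slope for '", v, "'")
      return(tibble::tibble(pop = pops, variable = v, rona = NA_real_,
                            se = NA_real_, n_loci = 0L))
    }
    per_locus |>
      dplyr::group_by(.data$pop) |>
      dplyr::summarise(
        variable = v,
        n_loci = dplyr::n(),
        se = {
          wm <- sum(.data$w * .data$rona) / sum(.data$w)
          sqrt(sum(.data$w * (.data$rona - wm)^2) / sum(.data$w) /
                 dplyr::n())
        },
        rona = sum(.data$w * .data$rona) / sum(.data$w),
        .groups = "drop") |>
      dplyr::select("pop", "variable", "rona", "se", "n_loci")
  })
  class(out) <- c("rona_table", class(out))
  out
}

#' @export
autoplot.rona_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$pop, .data$rona)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rona - .data$se,
                                        ymax = .data$rona + .data$se),
                           width = 0.3) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "RONA (weighted mean ± SE)")
}

#' Plot an offset grid
#' @param m Offset matrix (as returned by [local_offset()]).
#' @param title Plot title.
#' @export
plot_offset_grid <- function(m, title = "genetic offset") {
  df <- tibble::tibble(row = rep(seq_len(nrow(m)), ncol(m)),
                       col = rep(seq_len(ncol(m)), each = nrow(m)),
                       offset = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$offset)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL)
}
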