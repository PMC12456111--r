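# Synthetic landscape + genotype generator. Emulates the sampling design the
# downstream analyses assume: 27 populations (2-17 diploids each) in three
# genetic groups on a spatially structured environment, ~thousands of
# Balding-Nichols neutral loci plus a small set of logistic-cline loci tied
# to specific climate variables.

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study design the package targets: 27 populations of
#' 2-17 diploid individuals in 3 genetic groups, 3,000 neutral and 30
#' adaptive (cline) loci, 19 bioclimatic + 5 soil variables on a 1-degree
#' East-Asia-sized grid, 5% genotype missingness, and a future climate equal
#' to the current one plus a structured perturbation.
#'
#' @param n_pops Number of populations.
#' @param ind_range Min/max diploid individuals per population (uniform).
#' @param n_neutral,n_adaptive Locus counts.
#' @param n_groups Number of genetic groups.
#' @param f_between Balding-Nichols F between groups.
#' @param f_within Balding-Nichols F of populations within their group.
#' @param ibd_range_km Optional range (km) of an exponential spatial
#'   correlation among within-group population frequencies (Gaussian copula
#'   over the Balding-Nichols marginals). Off (0) by default: realised
#'   isolation by distance already arises from the spatial arrangement of
#'   the group hierarchy, and locus-level spatial autocorrelation inflates
#'   chance environmental clines in neutral loci.
#' @param beta_range Absolute slope range of adaptive logistic clines, on the
#'   z-scale of the driver variable; signs random.
#' @param adaptive_drivers Variables eligible as cline drivers; `NULL`
#'   (default) picks the `min(5, n_bioclim)` mutually least-correlated
#'   bioclim layers, mirroring the idea that distinct selective pressures
#'   act along distinct climate axes.
#' @param missing_rate Uniform genotype missingness rate.
#' @param n_bioclim,n_soil Number of climate / soil raster variables.
#' @param grid_nrow,grid_ncol,cellsize,lon0,lat0 Grid geometry (degrees).
#' @param gradient_range Value range of each bioclim linear gradient across
#'   the grid (native units).
#' @param sine_amp,noise_sd Amplitude of the low-frequency sinusoid and SD of
#'   white noise added to each bioclim layer.
#' @param soil_sd,soil_smooth SD and smoothing radius (cells) of the
#'   independent soil random fields.
#' @param delta_frac Future shift per bioclim variable, as a fraction of that
#'   layer's spatial SD (applied with a mild north-south modulation so the
#'   perturbation is spatially structured); soil layers do not change.
#' @param rng_seed Seed controlling all randomness.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_pops = 27L, ind_range = c(2L, 17L),
                         n_neutral = 3000L, n_adaptive = 30L,
                         n_groups = 3L, f_between = 0.25, f_within = 0.10,
                         ibd_range_km = 0, beta_range = c(1, 2),
                         adaptive_drivers = NULL, missing_rate = 0.05,
                         n_bioclim = 19L, n_soil = 5L,
                         grid_nrow = 20L, grid_ncol = 50L, cellsize = 1,
                         lon0 = 95, lat0 = 25,
                         gradient_range = 10, sine_amp = 4, noise_sd = 0.5,
                         soil_sd = 1, soil_smooth = 3L,
                         delta_frac = 0.5, rng_seed = 1L) {
  stopifnot(f_between > 0, f_between < 1, f_within > 0, f_within < 1,
            n_groups >= 1, n_pops >= n_groups, missing_rate >= 0,
            missing_rate < 1)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# Greedy selection of k mutually least-correlated variables: distinct
# selective pressures correspond to distinct climate axes, so cline drivers
# default to the most mutually independent bioclim layers.
pick_distinct_vars <- function(x, k) {
  cc <- abs(cor(x))
  vars <- colnames(x)
  sel <- vars[which.min(colSums(cc))]
  while (length(sel) < k) {
    cand <- setdiff(vars, sel)
    worst <- vapply(cand, function(v) max(cc[v, sel]), numeric(1))
    sel <- c(sel, cand[which.min(worst)])
  }
  sel
}

# Smooth a matrix with a separable box kernel of half-width w.
smooth_field <- function(m, w) {
  if (w < 1) return(m)
  k <- rep(1, 2 * w + 1)
  pad_apply <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], w), x, rep(x[n], w))
    as.numeric(stats::filter(xp, k / length(k), sides = 2))[(w + 1):(w + n)]
  }
  m <- apply(m, 2, pad_apply)
  t(apply(m, 1, pad_apply))
}

#' Simulate current and future environmental rasters plus population sites
#'
#' Bioclim layers are a linear gradient (random direction) plus a
#' low-frequency sinusoid plus white noise; soil layers are independent
#' smoothed random fields. The future stack equals the current one plus a
#' per-variable shift modulated along the north-south axis. Populations are
#' placed in `n_groups` spatial clusters spanning the west-east gradient.
#'
#' @param cfg A [synth_config()].
#' @return List with `current` and `future` [env_stack()]s and `pops`, a
#'   tibble of `pop`, `lon`, `lat`, `group`.
#' @export
simulate_landscape <- function(cfg) {
  set.seed(cfg$rng_seed)
  nr <- cfg$grid_nrow; nc <- cfg$grid_ncol
  if (nr * nc < 4L * cfg$n_pops)
    stop("grid too small for ", cfg$n_pops, " populations")
  # normalised cell coordinates in [0, 1]
  xx <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  yy <- matrix(rep((nr - seq_len(nr) + 0.5) / nr, times = nc), nr, nc)
  vars <- c(paste0("bio", seq_len(cfg$n_bioclim)),
            if (cfg$n_soil > 0) paste0("soil", seq_len(cfg$n_soil)))
  layers <- list(); deltas <- list()
  for (v in vars) {
    if (grepl("^bio", v)) {
      theta <- runif(1, 0, 2 * pi)
      proj <- cos(theta) * xx + sin(theta) * yy
      sine <- cfg$sine_amp * sin(2 * pi * (runif(1, 0.5, 1.5) * xx +
                                           runif(1, 0.5, 1.5) * yy) +
                                 runif(1, 0, 2 * pi))
      base <- cfg$gradient_range * proj + sine +
        matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
      layers[[v]] <- base
      deltas[[v]] <- cfg$delta_frac * sd(base) * (1 + 0.5 * (yy - 0.5))
    } else {
      f <- smooth_field(matrix(rnorm(nr * nc), nr, nc), cfg$soil_smooth)
      layers[[v]] <- cfg$soil_sd * f / max(sd(f), 1e-12)
      deltas[[v]] <- matrix(0, nr, nc)
    }
  }
  cur <- env_stack(layers, xll = cfg$lon0, yll = cfg$lat0,
                   cellsize = cfg$cellsize, epoch = "current")
  fut <- env_stack(purrr::map2(layers, deltas, `+`),
                   xll = cfg$lon0, yll = cfg$lat0,
                   cellsize = cfg$cellsize, epoch = "future")
  # population sites: group centres spread along x, pops scattered around them
  centres <- cbind(x = (seq_len(cfg$n_groups) - 0.5) / cfg$n_groups,
                   y = runif(cfg$n_groups, 0.3, 0.7))
  group <- sort(rep_len(seq_len(cfg$n_groups), cfg$n_pops))
  px <- pmin(pmax(centres[group, "x"] + rnorm(cfg$n_pops, 0, 0.10), 0.02), 0.98)
  py <- pmin(pmax(centres[group, "y"] + rnorm(cfg$n_pops, 0, 0.15), 0.02), 0.98)
  pops <- tibble::tibble(
    pop = sprintf("P%02d", seq_len(cfg$n_pops)),
    lon = cfg$lon0 + px * nc * cfg$cellsize,
    lat = cfg$lat0 + py * nr * cfg$cellsize,
    group = paste0("G", group))
  list(current = cur, future = fut, pops = pops)
}

# Balding-Nichols beta parameters for mean p and differentiation F.
bn_shape <- function(p, f) {
  list(a = p * (1 - f) / f, b = (1 - p) * (1 - f) / f)
}

#' Simulate genotypes over a landscape
#'
#' Neutral loci follow a hierarchical Balding-Nichols model (ancestral ->
#' group -> population) with an optional Gaussian-copula spatial correlation
#' among within-group population frequencies (isolation by distance).
#' Adaptive loci have population frequencies `plogis(alpha + beta * z)` of a
#' standardised driver variable; genotypes are Binomial(2, p) with uniform
#' missingness.
#'
#' @param cfg A [synth_config()].
#' @param env Per-population environment tibble (`pop` + variables), rows in
#'   the same order as the landscape's population frame.
#' @param pops Population frame from [simulate_landscape()] (needs `group`,
#'   `lon`, `lat`).
#' @return List: `genotypes` (a [genotype_matrix()]), `truth` (tibble of
#'   adaptive loci: `locus_id`, `driver`, `alpha`, `beta`), `pop_freqs`
#'   (pops x loci matrix of simulated frequencies).
#' @export
simulate_genotypes <- function(cfg, env, pops) {
  set.seed(cfg$rng_seed + 1L)
  np <- nrow(pops)
  stopifnot(np == cfg$n_pops, all(env$pop == pops$pop))
  n_ind <- sample(cfg$ind_range[1]:cfg$ind_range[2], np, replace = TRUE)
  grp <- as.integer(factor(pops$group))
  n_loci <- cfg$n_neutral + cfg$n_adaptive
  freqs <- matrix(0, np, n_loci)

  # spatial copula correlation for within-group frequency draws
  L_by_group <- lapply(seq_len(max(grp)), function(gi) {
    idx <- which(grp == gi)
    if (length(idx) < 2 || cfg$ibd_range_km <= 0) return(NULL)
    d <- geo_distance_matrix(pops[idx, ])
    R <- exp(-as.matrix(d) / cfg$ibd_range_km)
    chol(R + diag(1e-8, length(idx)))
  })

  for (l in seq_len(cfg$n_neutral)) {
    p_anc <- runif(1, 0.05, 0.95)
    sh_g <- bn_shape(p_anc, cfg$f_between)
    p_grp <- if (max(grp) > 1) rbeta(max(grp), sh_g$a, sh_g$b)
             else rep(p_anc, 1)
    for (gi in seq_len(max(grp))) {
      idx <- which(grp == gi)
      sh <- bn_shape(min(max(p_grp[gi], 5e-3), 1 - 5e-3), cfg$f_within)
      if (!is.null(L_by_group[[gi]])) {
        z <- drop(crossprod(L_by_group[[gi]], rnorm(length(idx))))
        # qbeta loses precision deep in the tail of near-degenerate betas;
        # the affected frequencies are ~0/1 either way
        freqs[idx, l] <- suppressWarnings(stats::qbeta(pnorm(z), sh$a, sh$b))
      } else {
        freqs[idx, l] <- rbeta(length(idx), sh$a, sh$b)
      }
    }
  }

  truth <- NULL
  if (cfg$n_adaptive > 0) {
    pool <- cfg$adaptive_drivers
    if (is.null(pool)) {
      bio <- grep("^bio", names(env), value = TRUE)
      pool <- pick_distinct_vars(env_values(env, bio),
                                 min(5L, length(bio)))
    }
    drivers <- sample(pool, cfg$n_adaptive, replace = TRUE)
    beta <- runif(cfg$n_adaptive, cfg$beta_range[1], cfg$beta_range[2]) *
      sample(c(-1, 1), cfg$n_adaptive, replace = TRUE)
    alpha <- rnorm(cfg$n_adaptive, 0, 0.5)
    for (a in seq_len(cfg$n_adaptive)) {
      z <- as.numeric(scale(env[[drivers[a]]]))
      freqs[, cfg$n_neutral + a] <- stats::plogis(alpha[a] + beta[a] * z)
    }
    truth <- tibble::tibble(
      locus_id = sprintf("adap_%04d", seq_len(cfg$n_adaptive)),
      driver = drivers, alpha = alpha, beta = beta)
  }

  locus_id <- c(sprintf("neut_%05d", seq_len(cfg$n_neutral)),
                if (cfg$n_adaptive > 0) truth$locus_id)
  dos <- matrix(NA_integer_, sum(n_ind), n_loci)
  ind_pop <- rep(seq_len(np), n_ind)
  for (k in seq_len(np)) {
    rows <- which(ind_pop == k)
    dos[rows, ] <- rbinom(length(rows) * n_loci, 2,
                          rep(freqs[k, ], each = length(rows)))
  }
  if (cfg$missing_rate > 0)
    dos[runif(length(dos)) < cfg$missing_rate] <- NA_integer_
  g <- genotype_matrix(
    dos,
    tibble::tibble(locus_id = locus_id, chrom = locus_id, pos = 1L),
    tibble::tibble(individual = sprintf("%s_i%02d", pops$pop[ind_pop],
                                        sequence(n_ind)),
                   pop = pops$pop[ind_pop]))
  dimnames(freqs) <- list(pops$pop, locus_id)
  list(genotypes = g, truth = truth, pop_freqs = freqs)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: landscape, per-population environment, genotypes.
#'
#' @param cfg A [synth_config()].
#' @return List with `current`, `future`, `pops`, `env`, `genotypes`,
#'   `truth`, `pop_freqs`.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  land <- simulate_landscape(cfg)
  env <- extract_env_at_points(land$current, land$pops)
  gen <- simulate_genotypes(cfg, env, land$pops)
  c(land, list(env = env), gen)
}

#' Write a synthetic dataset to disk in the package's external formats
#'
#' Emits VCF + popmap, coordinates CSV, env CSV, current/future ASCII grids
#' and the adaptive-locus truth table.
#'
#' @param ds Result of [simulate_dataset()].
#' @param dir Output directory.
#' @return Named list of written paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    coords = file.path(dir, "coords.csv"),
    env = file.path(dir, "env.csv"),
    truth = file.path(dir, "truth.csv"))
  write_vcf_genotypes(ds$genotypes, paths$vcf)
  write_popmap(ds$genotypes, paths$popmap)
  write.table(ds$pops, paths$coords, sep = ",", quote = FALSE,
              row.names = FALSE)
  write_env_csv(ds$env, paths$env)
  if (!is.null(ds$truth))
    write.table(ds$truth, paths$truth, sep = ",", quote = FALSE,
                row.names = FALSE)
  paths$rasters_current <- write_raster_stack(ds$current,
                                              file.path(dir, "current"))
  paths$rasters_future <- write_raster_stack(ds$future,
                                             file.path(dir, "future"))
  invisible(paths)
}
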