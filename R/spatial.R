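# Geographic distances, distance-based Moran eigenvector maps, Mantel tests.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix between populations
#'
#' Haversine distances on a sphere of radius 6371.0088 km.
#'
#' @param pops Tibble with `pop`, `lon`, `lat` (decimal degrees, WGS84).
#' @return Symmetric km matrix with zero diagonal, dimnames = pop labels.
#' @export
geo_distance_matrix <- function(pops) {
  stopifnot(all(abs(pops$lat) <= 90), all(abs(pops$lon) <= 180))
  lat <- pops$lat * pi / 180
  lon <- pops$lon * pi / 180
  n <- nrow(pops)
  dlat <- outer(lat, lat, `-`)
  dlon <- outer(lon, lon, `-`)
  h <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  d <- 2 * EARTH_RADIUS_KM * asin(pmin(sqrt(pmax(h, 0)), 1))
  diag(d) <- 0
  dimnames(d) <- list(pops$pop, pops$pop)
  d
}

# haversine between two coordinate sets (vectorised, km)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  lat1 <- lat1 * pi / 180; lat2 <- lat2 * pi / 180
  dlat <- lat2 - lat1
  dlon <- (lon2 - lon1) * pi / 180
  h <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(pmax(h, 0)), 1))
}

# Moran's I of x under a symmetric weight matrix w (zero diagonal).
morans_i <- function(x, w) {
  xc <- x - mean(x)
  (length(x) / sum(w)) * sum(w * outer(xc, xc)) / sum(xc^2)
}

#' Distance-based Moran eigenvector maps
#'
#' dbMEM construction: the geographic distance matrix is truncated at the
#' longest edge of its minimum spanning tree (larger distances are replaced
#' by 4x the truncation distance), double-centred and eigen-decomposed
#' (via [vegan::pcnm()]); eigenvectors with positive eigenvalues are kept.
#' Each retained vector gets a positive-autocorrelation Moran's I permutation
#' test under the binary within-truncation connectivity.
#'
#' @param pops Tibble with `pop`, `lon`, `lat`.
#' @param n_perm Permutations for the Moran's I test.
#' @param alpha Significance level for retention.
#' @param max_k Optional cap on the number of retained vectors.
#' @param seed Seed for the permutation test.
#' @return List of class `mem_basis`: `vectors` (pops x k, all positive
#'   eigenvectors), `values`, `moran` tibble (`mem`, `moran_i`, `p`,
#'   `significant`), `retained` (matrix of the retained vectors),
#'   `truncation` (km).
#' @export
build_mems <- function(pops, n_perm = 999L, alpha = 0.05, max_k = NULL,
                       seed = 1L) {
  if (nrow(pops) < 4) stop("need at least four populations")
  d <- geo_distance_matrix(pops)
  if (any(d[lower.tri(d)] == 0))
    stop("duplicate coordinates between populations; refusing to jitter")
  st <- vegan::spantree(stats::as.dist(d))
  thr <- max(st$dist)
  pc <- vegan::pcnm(stats::as.dist(d), threshold = thr)
  vec <- pc$vectors                       # positive-eigenvalue vectors
  rownames(vec) <- pops$pop
  w <- (d <= thr & d > 0) * 1
  set.seed(seed)
  moran <- purrr::map_dfr(seq_len(ncol(vec)), function(j) {
    obs <- morans_i(vec[, j], w)
    perm <- vapply(seq_len(n_perm),
                   function(i) morans_i(sample(vec[, j]), w), numeric(1))
    tibble::tibble(mem = colnames(vec)[j], moran_i = obs,
                   p = (1 + sum(perm >= obs)) / (n_perm + 1))
  })
  moran$significant <- moran$p < alpha & moran$moran_i > 0
  keep <- which(moran$significant)
  if (!is.null(max_k)) keep <- head(keep, max_k)
  structure(list(vectors = vec, values = pc$values[pc$values > 0],
                 moran = moran,
                 retained = vec[, keep, drop = FALSE],
                 truncation = thr),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat("<mem_basis> ", ncol(x$vectors), " positive eigenvector(s), ",
      ncol(x$retained), " significant; truncation ",
      sprintf("%.1f km", x$truncation), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mem_basis <- function(x, ...) x$moran

#' Mantel test between two distance matrices
#'
#' Pearson correlation over lower-triangle entries with a one-sided
#' (upper-tail) permutation p-value, `p = (1 + #[r_perm >= r]) / (n_perm+1)`,
#' permuting rows and columns of the second matrix jointly (delegated to
#' [vegan::mantel()]).
#'
#' @param d1,d2 Symmetric matrices (or `dist`) of equal size.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Tibble: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  stopifnot(identical(dim(m1), dim(m2)))
  if (sd(m1[lower.tri(m1)]) == 0 || sd(m2[lower.tri(m2)]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       permutations = n_perm)
  tibble::tibble(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Isolation by distance and by environment
#'
#' Runs Mantel tests of a genetic distance matrix (default: pairwise
#' Weir-Cockerham F_ST, optionally linearised as `fst/(1-fst)`) against
#' geographic distance (IBD) and against Euclidean distance on the first two
#' PCs of the standardised environmental variables (IBE).
#'
#' @param fst Pairwise F_ST matrix (see [pairwise_fst()]).
#' @param pops Population tibble (`pop`, `lon`, `lat`), rows matching `fst`.
#' @param env Environmental tibble (`pop` + variables), rows matching `fst`.
#' @param linearise Use `fst/(1-fst)` as the genetic distance.
#' @param n_perm Permutations.
#' @param seed RNG seed.
#' @return Tibble with one row per test (`test`, `r`, `p`, `n_perm`).
#' @export
ibd_ibe <- function(fst, pops, env, linearise = FALSE, n_perm = 999L,
                    seed = 1L) {
  gd <- if (linearise) fst / (1 - fst) else fst
  dplyr::bind_rows(
    dplyr::mutate(mantel_test(gd, geo_distance_matrix(pops),
                              n_perm = n_perm, seed = seed), test = "IBD"),
    dplyr::mutate(mantel_test(gd, env_pca_distance(env),
                              n_perm = n_perm, seed = seed), test = "IBE")) |>
    dplyr::relocate("test")
}
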