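# frequencies that are noiseless step functions of a single predictor
step_case <- function(n_pops = 30, c_at = 0.5, n_loci = 12) {
  e <- seq(0, 1, length.out = n_pops)
  y <- sapply(seq_len(n_loci), function(i)
    ifelse(e > c_at, 0.9, 0.1))
  colnames(y) <- paste0("L", seq_len(n_loci))
  list(env = tibble::tibble(pop = paste0("p", seq_len(n_pops)), e = e),
       y = y, e = e)
}

test_that("turnover concentrates where the allele frequencies actually turn", {
  cs <- step_case()
  m <- fit_gradient_forest(cs$y, cs$env, n_trees = 100, seed = 1)
  tv <- m$turnover$e
  # >= 80% of the cumulative rise happens within one bin of the step
  rise <- diff(c(0, tv$cumulative))
  mids <- (tv$breaks[-1] + tv$breaks[-length(tv$breaks)]) / 2
  spacing <- diff(cs$e[1:2])   # resolution of the training gradient
  near <- abs(mids - 0.5) <= spacing
  expect_gte(sum(rise[near]) / sum(rise), 0.8)
  # F(min) = 0 and F(max) = the predictor's importance
  expect_equal(eval_turnover(m, "e", min(cs$e)), 0)
  expect_equal(eval_turnover(m, "e", max(cs$e)),
               unname(m$importance["e"]), tolerance = 1e-12)
})

test_that("an uninformative predictor gets negligible importance", {
  ratio <- vapply(1:10, function(i) {
    set.seed(i)
    cs <- step_case()
    cs$env$noise <- rnorm(nrow(cs$env))
    m <- fit_gradient_forest(cs$y, cs$env, n_trees = 60, seed = i)
    m$importance["noise"] / max(m$importance)
  }, numeric(1))
  expect_lt(mean(ratio), 0.05)
})

test_that("same seed and data give an identical model", {
  ds <- small_dataset()
  ft <- allele_freq_table(ds$genotypes)
  y <- ft$p[, 1:60]
  m1 <- fit_gradient_forest(y, ds$env, n_trees = 40, seed = 7)
  m2 <- fit_gradient_forest(y, ds$env, n_trees = 40, seed = 7)
  expect_identical(m1$importance, m2$importance)
  expect_identical(m1$turnover, m2$turnover)
  expect_identical(m1$locus_r2, m2$locus_r2)
})

test_that("total turnover mass equals total weighted importance (conservation)", {
  ds <- small_dataset()
  ft <- allele_freq_table(ds$genotypes)
  m <- fit_gradient_forest(ft$p[, 1:80], ds$env, n_trees = 50, seed = 2)
  total_turnover <- sum(vapply(m$turnover, function(tv)
    tv$cumulative[length(tv$cumulative)], numeric(1)))
  expect_equal(total_turnover, sum(m$importance), tolerance = 1e-9)
  # every turnover function is nondecreasing
  for (tv in m$turnover)
    expect_true(all(diff(c(0, tv$cumulative)) >= -1e-12))
})

test_that("model JSON round-trips and transform matches direct evaluation", {
  cs <- step_case()
  m <- fit_gradient_forest(cs$y, cs$env, n_trees = 40, seed = 1)
  p <- tempfile(fileext = ".json")
  write_turnover_model(m, p)
  m2 <- read_turnover_model(p)
  expect_equal(m2$importance, m$importance, tolerance = 1e-12)
  expect_equal(m2$turnover$e$cumulative, m$turnover$e$cumulative,
               tolerance = 1e-12)
  expect_equal(eval_turnover(m2, "e", c(0.2, 0.6)),
               eval_turnover(m, "e", c(0.2, 0.6)), tolerance = 1e-12)
})

test_that("variable pruning drops the lower-importance member of tight pairs", {
  set.seed(1)
  n <- 20
  a <- rnorm(n)
  env <- tibble::tibble(pop = paste0("p", 1:n), a = a, b = a,
                        c = rnorm(n))
  imp <- c(a = 3, b = 1, c = 2)
  out <- suppressMessages(prune_variables(env, imp))
  expect_setequal(setdiff(names(out), "pop"), c("a", "c"))

  # nothing above the threshold: unchanged
  env2 <- tibble::tibble(pop = paste0("p", 1:n), a = rnorm(n), b = rnorm(n))
  expect_identical(suppressMessages(
    prune_variables(env2, c(a = 1, b = 2))), env2)

  # correlation chain a~b~c: result matches a brute-force greedy oracle
  greedy_oracle <- function(x, imp, r_max) {
    vars <- colnames(x)
    repeat {
      cc <- abs(cor(x[, vars, drop = FALSE])); diag(cc) <- 0
      if (max(cc) <= r_max) return(sort(vars))
      ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      loser <- rownames(cc)[ij][which.min(imp[rownames(cc)[ij]])]
      vars <- setdiff(vars, loser)
    }
  }
  set.seed(9)
  base <- rnorm(40)
  x <- cbind(a = base + rnorm(40, 0, 0.25),
             b = base + rnorm(40, 0, 0.25),
             c = base + rnorm(40, 0, 0.25),
             d = rnorm(40), e = rnorm(40))
  imp3 <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  env3 <- dplyr::bind_cols(tibble::tibble(pop = paste0("p", 1:40)),
                           tibble::as_tibble(x))
  out3 <- suppressMessages(prune_variables(env3, imp3, r_max = 0.75))
  expect_equal(sort(setdiff(names(out3), "pop")),
               greedy_oracle(x, imp3, 0.75))
})

test_that("transform clamps to the training range and preserves rank order", {
  cs <- step_case()
  m <- fit_gradient_forest(cs$y, cs$env, n_trees = 40, seed = 1)
  nr <- 5; nc <- 6
  vals <- matrix(seq(-0.5, 1.5, length.out = nr * nc), nr, nc)
  st <- env_stack(list(e = vals), xll = 0, yll = 0, cellsize = 1)
  tr <- transform_env(m, st)
  # below training minimum -> 0; above maximum -> total importance
  expect_equal(tr$layers$e[vals < 0], rep(0, sum(vals < 0)))
  expect_equal(tr$layers$e[vals > 1],
               rep(unname(m$importance["e"]), sum(vals > 1)))
  # monotone in the raw value
  ord <- order(as.vector(vals))
  expect_true(all(diff(tr$layers$e[ord]) >= -1e-12))

  # transform commutes with cropping
  tr_crop <- crop_stack(tr, 2:4, 3:5)
  crop_tr <- transform_env(m, crop_stack(st, 2:4, 3:5))
  expect_equal(tr_crop$layers, crop_tr$layers, tolerance = 1e-12)

  expect_error(transform_env(m, env_stack(list(zzz = vals), 0, 0, 1)),
               "missing")
})
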