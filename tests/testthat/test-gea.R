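# build a small population-frequency response with one planted cline
cline_case <- function(seed, n_pops = 27, n_loci = 120, beta = 1.5,
                       struct_sd = 0.5) {
  set.seed(seed)
  x <- rnorm(n_pops)
  u <- rnorm(n_pops, 0, struct_sd)       # one latent structure axis
  y <- matrix(plogis(rnorm(n_loci * n_pops, rep(rnorm(n_loci), each = n_pops),
                           0.6) + rep(u, n_loci) * 0.8),
              nrow = n_pops)
  y[, 1] <- plogis(0.2 + beta * x + 0.3 * u)    # planted cline on locus 1
  colnames(y) <- paste0("L", seq_len(n_loci))
  env <- tibble::tibble(pop = paste0("p", seq_len(n_pops)), driver = x,
                        other = rnorm(n_pops))
  list(y = y, env = env, x = x)
}

test_that("ridge LFMM with K = 0 equals per-locus simple regression", {
  cs <- cline_case(1, n_loci = 100)
  lf <- lfmm_scan(cs$y, cs$env["driver"] |>
                    dplyr::mutate(pop = cs$env$pop), K = 0)
  # plain per-locus OLS p-values, same GIF calibration applied
  z <- apply(cs$y, 2, function(yy) {
    f <- summary(lm(scale(yy, scale = FALSE) ~ scale(cs$x)))
    f$coefficients[2, 3]
  })
  gif <- median(z^2) / qchisq(0.5, 1)
  p_ols <- pchisq(z^2 / gif, 1, lower.tail = FALSE)
  expect_lt(max(abs(lf$p - p_ols)), 1e-6)
})

test_that("LFMM recovers a planted cline and respects a permuted control", {
  hits <- vapply(1:25, function(i) {
    cs <- cline_case(i, n_loci = 80, beta = 1.2)
    lf <- lfmm_scan(cs$y, cs$env, K = 1)
    sub <- lf[lf$variable == "driver", ]
    sub$locus_id[which.min(sub$p)] == "L1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)   # planted locus has the smallest p

  # destroying the env-genotype link removes the signal
  null_q <- vapply(1:20, function(i) {
    cs <- cline_case(i + 500, n_loci = 80, beta = 1.2)
    set.seed(i)
    cs$env$driver <- sample(cs$env$driver)
    lf <- lfmm_scan(cs$y, cs$env, K = 1)
    min(lf$q[lf$variable == "driver" & lf$locus_id == "L1"])
  }, numeric(1))
  expect_gte(mean(null_q >= 0.05), 0.9)
})

test_that("LFMM p-values are uniform on null loci", {
  set.seed(4)
  n_pops <- 27
  y <- matrix(plogis(matrix(rnorm(3000 * n_pops, 0, 0.8), n_pops)),
              nrow = n_pops)
  colnames(y) <- paste0("L", 1:3000)
  env <- tibble::tibble(pop = paste0("p", 1:n_pops), v = rnorm(n_pops))
  lf <- lfmm_scan(y, env, K = 2)
  expect_gt(ks.test(lf$p, "punif")$p.value, 0.01)
})

test_that("RDA loading scan calibrates on Gaussian scores and finds constructions", {
  # flagged fraction on exactly-Gaussian loadings ~ 2 * pnorm(-3)
  set.seed(1)
  z <- matrix(rnorm(2e5), ncol = 2)
  flag <- rowSums(abs(scale(z)) >= 3) > 0
  per_axis_rate <- mean(abs(scale(z[, 1])) >= 3)
  expect_equal(per_axis_rate, 2 * pnorm(-3), tolerance = 0.25)

  # a locus that is a pure multiple of an env variable loads on axis 1
  set.seed(2)
  n <- 24
  env <- tibble::tibble(pop = paste0("p", 1:n), v = rnorm(n))
  y <- matrix(plogis(matrix(rnorm(60 * n, 0, 0.5), n)), nrow = n)
  y[, 7] <- 0.5 + 0.2 * scale(env$v)
  colnames(y) <- paste0("L", 1:60)
  rd <- rda_loading_scan(y, env, n_axes = 1)
  expect_true(rd$flag[rd$locus_id == "L7"])
  expect_equal(unname(which.max(abs(rd$axis1))), 7L)

  # an infinite cutoff flags nothing
  rd0 <- rda_loading_scan(y, env, sd_cutoff = Inf)
  expect_equal(sum(rd0$flag), 0L)

  # clipping n_axes warns
  expect_warning(rda_loading_scan(y, env, n_axes = 5), "clipped")
})

test_that("core candidates are the LFMM/RDA intersection with variables attached", {
  lfmm <- tibble::tibble(
    variable = "v",
    locus_id = letters[1:6],
    effect = 0, z = 0,
    p = c(1e-6, 1e-6, 1e-6, 0.5, 0.9, 0.2),
    q = c(0.001, 0.002, 0.003, 0.8, 0.9, 0.5))
  lfmm$flag <- lfmm$q < 0.05
  rda <- tibble::tibble(locus_id = letters[1:6],
                        flag = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  core <- suppressMessages(core_candidates(lfmm, rda))
  expect_setequal(core$core$locus_id, c("b", "c"))
  expect_equal(core$core$variables, c("v", "v"))
  expect_true(all(core$table$core ==
                    (core$table$lfmm_hit & core$table$rda_hit)))

  # empty LFMM hits give an empty core
  lfmm0 <- dplyr::mutate(lfmm, q = 0.9, flag = FALSE)
  expect_equal(nrow(suppressMessages(core_candidates(lfmm0, rda))$core), 0L)
})

test_that("recovery is monotone in planted effect size", {
  recov <- vapply(c(0.5, 1, 2), function(beta) {
    hits <- vapply(1:15, function(i) {
      cs <- cline_case(i + 40, n_pops = 16, n_loci = 60, beta = beta)
      lf <- lfmm_scan(cs$y, cs$env, K = 1)
      any(lf$q[lf$variable == "driver" & lf$locus_id == "L1"] < 0.05)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(recov) >= 0))
  expect_gte(recov[3], 0.8)
})

test_that("per-group scans run on population subsets", {
  ds <- small_dataset()
  ft <- allele_freq_table(ds$genotypes)
  y <- ft$p
  y[is.na(y)] <- 0.5
  rownames(y) <- ft$pops
  res <- suppressWarnings(suppressMessages(
    gea_by_group(y, ds$env, ds$pops[, c("pop", "group")], K = 1)))
  expect_setequal(names(res), unique(ds$pops$group))
  expect_s3_class(res[[1]], "gea_result")
})
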