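test_that("filter_snps applies each rule and logs removal counts", {
  # 10 loci, 4 violating exactly one rule each:
  #  L2 is a second SNP on the tag of L1; L3 missing in too many individuals;
  #  L4 has MAF < 0.05; L5 is all-heterozygote (Hobs > 0.5)
  n <- 20
  good <- function() sample(0:2, n, replace = TRUE, prob = c(.4, .3, .3))
  set.seed(42)
  dos <- cbind(good(), good(), good(), good(), good(),
               good(), good(), good(), good(), good())
  dos[, 3] <- c(rep(NA, 4), good()[5:n])        # 80% presence < 85%
  dos[, 4] <- c(1L, rep(0L, n - 1))             # MAF = 1/40 = 0.025
  dos[, 5] <- rep(1L, n)                        # Hobs = 1
  g <- make_geno(dos, rep(c("A", "B"), each = 10),
                 chrom = c("tag1", "tag1", paste0("tag", 2:9)),
                 pos = c(10L, 20L, rep(1L, 8)))
  cfg <- run_config(min_populations = 2)
  expect_message(out <- filter_snps(g, cfg), "retained")
  expect_equal(ncol(out$dosages), 6L)
  expect_equal(unname(attr(out, "filter_log")), c(1L, 1L, 1L, 1L))
  expect_false(any(c("L2", "L3", "L4", "L5") %in% out$loci$locus_id))

  # a clean matrix passes through unchanged (idempotence)
  out2 <- suppressMessages(filter_snps(out, cfg))
  expect_identical(out2$dosages, out$dosages)

  # MAF 0.04 is below the 0.05 threshold
  d2 <- cbind(c(rep(1L, 2), rep(0L, 23)), good()[1:25])
  d2[1:25, 2] <- rep(c(0L, 1L, 2L), length.out = 25)
  g2 <- make_geno(d2, rep(c("A", "B"), c(13, 12)))
  out3 <- suppressMessages(filter_snps(g2, run_config(min_populations = 2)))
  expect_false("L1" %in% out3$loci$locus_id)  # MAF = 2/50 = 0.04

  expect_error(suppressMessages(
    filter_snps(make_geno(matrix(1L, 4, 1), rep("A", 4)),
                run_config(min_populations = 1))), "threshold")
})

test_that("diversity matches hand-enumerated pairwise differences", {
  # one site, two diploids {0, 2}: 4 of 6 allele pairs differ -> pi = 2/3
  g <- make_geno(matrix(c(0L, 2L), 2, 1), c("A", "A"))
  d <- diversity(g)
  expect_equal(d$pi, 2 / 3)
  expect_equal(d$he, 2 / 3)
  expect_equal(d$ho, 0)

  # all individuals heterozygous: H_O = 1
  g2 <- make_geno(matrix(1L, 3, 1), rep("A", 3))
  expect_equal(diversity(g2)$ho, 1)

  # monomorphic-within-population site contributes zero diversity
  g3 <- make_geno(cbind(c(0L, 2L), c(2L, 2L)), c("A", "A"))
  expect_equal(diversity(g3)$pi, mean(c(2 / 3, 0)))

  # population with < 2 alleles everywhere reports missing
  g4 <- make_geno(matrix(c(0L, NA), 2, 1), c("A", "B"))
  expect_true(is.na(diversity(g4)$pi[2]))

  # brute-force oracle agreement on a random instance
  ds <- small_dataset()
  d5 <- diversity(ds$genotypes)
  orc <- oracle_diversity(ds$genotypes)
  expect_equal(d5$he, orc$he, tolerance = 1e-10)
  expect_equal(d5$ho, orc$ho, tolerance = 1e-10)
})

test_that("Weir-Cockerham theta matches frozen and loop oracles", {
  g <- wc_fixture()
  ft <- allele_freq_table(g)
  # frozen from an independent transcription of the 1984 formulas
  expect_equal(unname(adaptscape:::per_locus_fst(ft)),
               c(0.2089914945, -0.0086526576, 1, 0), tolerance = 1e-9)
  expect_equal(global_fst(ft), 0.377042956, tolerance = 1e-9)
  pw <- pairwise_fst(g)
  expect_equal(pw["A", "B"], 0.3836633663, tolerance = 1e-9)
  expect_equal(pw["A", "C"], 0.5021834061, tolerance = 1e-9)
  expect_equal(pw["B", "C"], 0.0954198473, tolerance = 1e-9)
  expect_true(isSymmetric(pw))
  expect_equal(diag(pw), setNames(rep(0, 3), c("A", "B", "C")))

  # plain-loop oracle on random <= 5-individual instances
  for (s in 1:5) {
    set.seed(s)
    dos <- matrix(sample(c(0:2, NA), 5 * 8, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 5, 8)
    gg <- make_geno(dos, c("A", "A", "B", "B", "B"))
    orc <- oracle_wc_theta(gg)
    expect_equal(global_fst(gg), orc$multilocus, tolerance = 1e-10)
    expect_equal(unname(adaptscape:::per_locus_fst(allele_freq_table(gg))),
                 orc$per_locus, tolerance = 1e-10)
  }
})

test_that("fixed difference gives theta = 1; identical pops give theta <= 0", {
  g <- make_geno(cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L)),
                 c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(g)["A", "B"], 1)

  # two populations with identical genotype columns
  g2 <- make_geno(matrix(c(0L, 1L, 0L, 1L), 4, 3), c("A", "A", "B", "B"))
  th <- pairwise_fst(g2)["A", "B"]
  expect_lte(th, 0)
  expect_equal(th, oracle_wc_theta(g2)$multilocus, tolerance = 1e-12)

  # a pair with no overlapping loci is missing
  g3 <- make_geno(rbind(c(0L, NA), c(1L, NA), c(NA, 1L), c(NA, 2L)),
                  c("A", "A", "B", "B"))
  expect_true(is.na(pairwise_fst(g3)["A", "B"]))
})

test_that("genotype PCA separates simulated groups and conserves variance", {
  cfg <- synth_config(n_pops = 10, n_groups = 2, f_between = 0.3,
                      f_within = 0.02, n_neutral = 300, n_adaptive = 0,
                      n_bioclim = 3, n_soil = 0, grid_nrow = 8,
                      grid_ncol = 16, rng_seed = 1)
  ds <- simulate_dataset(cfg)
  pca <- genotype_pca(ds$genotypes)
  grp <- ds$pops$group[match(ds$genotypes$individuals$pop, ds$pops$pop)]
  s1 <- pca$scores[grp == "G1", 1]
  s2 <- pca$scores[grp == "G2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # zero overlap on PC1

  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$var_explained) <= 1e-12))

  # duplicated individuals land on identical scores
  g <- ds$genotypes
  gdup <- genotype_matrix(g$dosages[c(1, 1, 2:8), ], g$loci,
                          tibble::tibble(
                            individual = paste0("d", 1:9),
                            pop = g$individuals$pop[c(1, 1, 2:8)]))
  pd <- genotype_pca(gdup, n_pcs = 4)
  expect_equal(pd$scores[1, ], pd$scores[2, ], tolerance = 1e-8)

  expect_error(genotype_pca(g, n_pcs = nrow(g$dosages)), "individuals")
})
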