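# End-to-end orchestration: stage graph with content-hash caching over the
# on-disk artifacts, from (synthetic or supplied) inputs to offsets and RONA.

#' Assign populations to genetic groups
#'
#' K-means on the population-mean scores of the first two genotype PCs;
#' used when no external group assignment is supplied.
#'
#' @param pca A [genotype_pca()].
#' @param k Number of groups.
#' @param seed RNG seed.
#' @return Tibble `pop`, `group`.
#' @export
assign_groups <- function(pca, k = 3L, seed = 1L) {
  set.seed(seed)
  km <- stats::kmeans(pca$pop_scores[, 1:2], centers = k, nstart = 20)
  tibble::tibble(pop = rownames(pca$pop_scores),
                 group = paste0("G", km$cluster))
}

stage_hash <- function(files, extra = NULL) {
  files <- files[file.exists(files)]
  h <- unname(tools::md5sum(files))
  paste(c(h, if (!is.null(extra)) rawToChar(serialize(extra, NULL,
                                                      ascii = TRUE))),
        collapse = "|")
}

#' Run the full landscape-genomics pipeline
#'
#' Executes the stage graph (simulate -> filter -> stats -> outliers ->
#' ibd_ibe -> varpart -> gea -> gf -> offset -> rona) under `out_dir`. Each
#' stage records an md5 content hash of its input files plus the relevant
#' configuration; re-running with identical inputs and config skips the
#' stage. A manifest (seed, config echo, stage status) is written alongside
#' the artifacts.
#'
#' @param cfg A [run_config()].
#' @param synth A [synth_config()] driving the synthetic inputs (stage 1).
#' @param out_dir Output directory.
#' @return Tibble (`stage`, `status`, `outputs`) of class `stage_graph`.
#' @export
run_pipeline <- function(cfg = run_config(), synth = synth_config(),
                         out_dir = tempfile("adaptscape_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  status <- character(0)
  pth <- function(...) file.path(out_dir, ...)

  run_stage <- function(name, inputs, outputs, conf, fun) {
    h <- stage_hash(inputs, conf)
    cached <- !is.null(manifest$stages[[name]]) &&
      identical(manifest$stages[[name]]$hash, h) &&
      all(file.exists(outputs))
    if (cached) {
      status[name] <<- "cached"
    } else {
      ok <- try(fun(), silent = FALSE)
      if (inherits(ok, "try-error"))
        stop("pipeline stage '", name, "' failed (see log above)")
      manifest$stages[[name]] <<- list(hash = h)
      status[name] <<- "ran"
    }
    outputs
  }

  # -- simulate ---------------------------------------------------------
  sim_out <- c(pth("genotypes.vcf"), pth("popmap.tsv"), pth("coords.csv"),
               pth("env.csv"), pth("truth.csv"))
  run_stage("simulate", character(0), sim_out, unclass(synth), function() {
    ds <- simulate_dataset(synth)
    write_synthetic_dataset(ds, out_dir)
  })

  # -- filter -----------------------------------------------------------
  filt_out <- pth("filtered_dosages.tsv")
  run_stage("filter", sim_out[1:2], filt_out,
            cfg[c("maf_min", "max_obs_het", "min_individual_presence",
                  "min_populations")], function() {
    g <- read_vcf_genotypes(pth("genotypes.vcf"), pth("popmap.tsv"))
    gf <- filter_snps(g, cfg)
    write_dosage_tsv(gf, filt_out)
  })

  # -- stats ------------------------------------------------------------
  stats_out <- c(pth("diversity.csv"), pth("pairwise_fst.csv"),
                 pth("pca_scores.csv"), pth("groups.csv"))
  run_stage("stats", filt_out, stats_out, NULL, function() {
    g <- read_dosage_tsv(filt_out)
    write.table(diversity(g), stats_out[1], sep = ",", quote = FALSE,
                row.names = FALSE)
    fst <- pairwise_fst(g)
    write.table(data.frame(pop = rownames(fst), fst, check.names = FALSE),
                stats_out[2], sep = ",", quote = FALSE, row.names = FALSE)
    pca <- genotype_pca(g, n_pcs = min(10L, nrow(g$dosages) - 1L))
    write.table(tidy(pca), stats_out[3], sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(assign_groups(pca, seed = cfg$rng_seed), stats_out[4],
                sep = ",", quote = FALSE, row.names = FALSE)
  })

  # -- outliers ---------------------------------------------------------
  outl_out <- pth("outlier_report.csv")
  run_stage("outliers", filt_out,
            outl_out, cfg[c("k_latent", "fdr_alpha", "fdist_sims")],
            function() {
    g <- read_dosage_tsv(filt_out)
    set.seed(cfg$rng_seed)
    part <- partition_outliers(list(
      pc_scan = pc_scan(g, K = cfg$k_latent, alpha = cfg$fdr_alpha),
      fdist_scan = fdist_scan(allele_freq_table(g),
                              n_sims = cfg$fdist_sims,
                              alpha = cfg$fdr_alpha)))
    write.table(part$report, outl_out, sep = ",", quote = FALSE,
                row.names = FALSE)
  })

  # -- ibd_ibe ----------------------------------------------------------
  ibd_out <- pth("ibd_ibe.csv")
  run_stage("ibd_ibe", c(filt_out, pth("coords.csv"), pth("env.csv"),
                         outl_out), ibd_out,
            cfg["n_permutations"], function() {
    g <- neutral_subset(filt_out, outl_out)
    pops <- read_env_csv(pth("coords.csv"))
    env <- read_env_csv(pth("env.csv"))
    res <- ibd_ibe(pairwise_fst(g), pops, env,
                   n_perm = cfg$n_permutations, seed = cfg$rng_seed)
    write.table(res, ibd_out, sep = ",", quote = FALSE, row.names = FALSE)
  })

  # -- varsel: GF-importance ranking + correlation pruning --------------
  varsel_out <- pth("env_pruned.csv")
  run_stage("varsel", c(filt_out, pth("env.csv")), varsel_out,
            cfg[c("corr_prune", "n_trees", "varsel_max_loci")], function() {
    g <- read_dosage_tsv(filt_out)
    env <- read_env_csv(pth("env.csv"))
    ft <- allele_freq_table(g)
    set.seed(cfg$rng_seed)
    sub <- sort(sample(ncol(ft$p), min(cfg$varsel_max_loci, ncol(ft$p))))
    rank_model <- fit_gradient_forest(ft$p[, sub, drop = FALSE], env,
                                      n_trees = cfg$n_trees,
                                      seed = cfg$rng_seed)
    write_env_csv(prune_variables(env, rank_model, r_max = cfg$corr_prune),
                  varsel_out)
  })

  # -- varpart ----------------------------------------------------------
  var_out <- c(pth("mem.csv"), pth("variance_partition.csv"))
  run_stage("varpart", c(filt_out, pth("coords.csv"), varsel_out,
                         outl_out), var_out,
            cfg[c("n_permutations", "corr_prune")], function() {
    g <- neutral_subset(filt_out, outl_out)
    pops <- read_env_csv(pth("coords.csv"))
    env <- read_env_csv(varsel_out)
    mems <- build_mems(pops, n_perm = cfg$n_permutations,
                       seed = cfg$rng_seed)
    write.table(tidy(mems), var_out[1], sep = ",", quote = FALSE,
                row.names = FALSE)
    geog <- if (ncol(mems$retained) >= 1) mems$retained
            else mems$vectors[, 1:3, drop = FALSE]
    pca <- genotype_pca(g, n_pcs = 3L)
    y <- freq_response(g)
    vp <- variance_partition(y, env, geog, pca$pop_scores,
                             n_perm = cfg$n_permutations,
                             seed = cfg$rng_seed)
    write.table(vp, var_out[2], sep = ",", quote = FALSE, row.names = FALSE)
  })

  # -- gea --------------------------------------------------------------
  gea_out <- c(pth("gea_lfmm.csv"), pth("gea_core.csv"))
  run_stage("gea", c(filt_out, varsel_out, outl_out), gea_out,
            cfg[c("k_latent", "fdr_alpha", "rda_sd_cutoff")], function() {
    g <- neutral_subset(filt_out, outl_out)
    env <- read_env_csv(varsel_out)
    y <- freq_response(g)
    lf <- lfmm_scan(y, env, K = cfg$k_latent, alpha = cfg$fdr_alpha)
    rd <- rda_loading_scan(y, env, sd_cutoff = cfg$rda_sd_cutoff)
    core <- core_candidates(lf, rd, alpha = cfg$fdr_alpha)
    write.table(lf, gea_out[1], sep = ",", quote = FALSE, row.names = FALSE)
    write.table(core$core, gea_out[2], sep = ",", quote = FALSE,
                row.names = FALSE)
  })

  # -- gf ---------------------------------------------------------------
  gf_out <- pth("turnover_model.json")
  run_stage("gf", c(filt_out, varsel_out, outl_out, gea_out[2]), gf_out,
            cfg[c("n_trees", "gf_max_loci")], function() {
    g <- neutral_subset(filt_out, outl_out)
    env <- read_env_csv(varsel_out)
    ft <- allele_freq_table(g)
    core <- read.table(gea_out[2], sep = ",", header = TRUE,
                       colClasses = "character")
    set.seed(cfg$rng_seed)
    keep <- union(sort(sample(ncol(ft$p),
                              min(cfg$gf_max_loci, ncol(ft$p)))),
                  match(core$locus_id, colnames(ft$p)))
    keep <- keep[!is.na(keep)]
    model <- fit_gradient_forest(ft$p[, keep, drop = FALSE], env,
                                 n_trees = cfg$n_trees,
                                 seed = cfg$rng_seed)
    write_turnover_model(model, gf_out)
  })

  # -- offset -----------------------------------------------------------
  off_out <- pth("offset_summary.csv")
  run_stage("offset", gf_out, off_out, cfg["migration_radii_km"],
            function() {
    model <- read_turnover_model(gf_out)
    cur <- read_raster_stack(list.files(pth("current"), full.names = TRUE),
                             epoch = "current")
    fut <- read_raster_stack(list.files(pth("future"), full.names = TRUE),
                             epoch = "future")
    keep <- intersect(names(model$turnover), names(cur$layers))
    model$turnover <- model$turnover[keep]
    surf <- offset_surface(model, cur, fut, radii_km = cfg$migration_radii_km)
    write_ascii_grid(surf$local, pth("local_offset.asc"), surf$xll,
                     surf$yll, surf$cellsize)
    for (nm in names(surf$forward))
      write_ascii_grid(surf$forward[[nm]],
                       pth(paste0("forward_offset_", nm, ".asc")),
                       surf$xll, surf$yll, surf$cellsize)
    write_ascii_grid(surf$reverse, pth("reverse_offset.asc"), surf$xll,
                     surf$yll, surf$cellsize)
    write.table(glance(surf), off_out, sep = ",", quote = FALSE,
                row.names = FALSE)
  })

  # -- rona -------------------------------------------------------------
  rona_out <- pth("rona.csv")
  run_stage("rona", c(filt_out, pth("env.csv"), gea_out[2]), rona_out,
            NULL, function() {
    g <- read_dosage_tsv(filt_out)
    env <- read_env_csv(pth("env.csv"))
    core <- tibble::as_tibble(read.table(gea_out[2], sep = ",",
                                         header = TRUE,
                                         colClasses = "character"))
    cur <- read_raster_stack(list.files(pth("current"), full.names = TRUE))
    fut <- read_raster_stack(list.files(pth("future"), full.names = TRUE))
    pops <- read_env_csv(pth("coords.csv"))
    env_fut <- extract_env_at_points(fut, pops)
    if (nrow(core) > 0) {
      rn <- rona(allele_freq_table(g), core, env, env_fut)
      write.table(rn, rona_out, sep = ",", quote = FALSE, row.names = FALSE)
    } else {
      write.table(tibble::tibble(pop = character(), variable = character(),
                                 rona = numeric(), se = numeric(),
                                 n_loci = integer()),
                  rona_out, sep = ",", quote = FALSE, row.names = FALSE)
    }
  })

  manifest$seed <- cfg$rng_seed
  manifest$config <- lapply(unclass(cfg), function(v)
    if (is.numeric(v)) as.character(v) else v)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  out <- tibble::tibble(stage = names(status), status = unname(status))
  class(out) <- c("stage_graph", class(out))
  attr(out, "out_dir") <- out_dir
  out
}

# filtered genotypes minus F_ST outliers
neutral_subset <- function(filt_path, outlier_path) {
  g <- read_dosage_tsv(filt_path)
  rep <- read.table(outlier_path, sep = ",", header = TRUE)
  neutral <- rep$locus_id[rep$class == "neutral"]
  subset_loci(g, g$loci$locus_id %in% neutral)
}

# population x locus allele-frequency response matrix
freq_response <- function(g) {
  ft <- allele_freq_table(g)
  p <- ft$p
  # mean-impute the rare pop x locus holes so ordinations get a full matrix
  for (j in seq_len(ncol(p))) {
    miss <- is.na(p[, j])
    if (any(miss)) p[miss, j] <- mean(p[, j], na.rm = TRUE)
  }
  rownames(p) <- ft$pops
  colnames(p) <- ft$loci
  p
}
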