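# Genotype container and readers/writers for the external formats the
# pipeline touches (VCF + popmap, dosage TSV, env CSV, YAML run config).

#' Construct a genotype matrix object
#'
#' Dosages are alternate-allele counts per diploid individual: 0, 1 or 2, with
#' `NA` as the missing-genotype sentinel (never 0 — 0 is a legal homozygote).
#'
#' @param dosages Integer matrix, individuals x loci; entries in `{0,1,2,NA}`.
#' @param loci Tibble with `locus_id`, `chrom`, `pos`; `chrom` doubles as the
#'   locus-group id for the first-SNP-per-locus filter (RAD tags map one tag
#'   per `chrom` in de-novo Stacks output).
#' @param individuals Tibble with `individual`, `pop`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, loci, individuals) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(nrow(dosages) == nrow(individuals),
            ncol(dosages) == nrow(loci))
  if (anyDuplicated(loci$locus_id))
    stop("locus ids must be unique")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (nrow(individuals) < 1L || !all(nchar(individuals$pop) > 0))
    stop("every individual needs a population label")
  rownames(dosages) <- individuals$individual
  colnames(dosages) <- loci$locus_id
  structure(list(dosages = dosages,
                 loci = tibble::as_tibble(loci),
                 individuals = tibble::as_tibble(individuals)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " loci, ",
      length(unique(x$individuals$pop)), " populations, ",
      sprintf("%.1f%%", 100 * mean(is.na(x$dosages))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

n_pops <- function(g) length(unique(g$individuals$pop))

subset_loci <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$loci[keep, , drop = FALSE], g$individuals)
}

subset_individuals <- function(g, keep) {
  genotype_matrix(g$dosages[keep, , drop = FALSE], g$loci,
                  g$individuals[keep, , drop = FALSE])
}

#' Read a Stacks-style population map
#'
#' @param path Two-column tab-separated file: individual, population.
#' @return Tibble with `individual`, `pop`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("individual", "pop"),
                   colClasses = "character")
  tibble::as_tibble(pm)
}

#' Read biallelic genotypes from a VCF
#'
#' Parses GT fields of biallelic SNP records into alternate-allele dosages.
#' Multi-allelic records are dropped (count logged via message); `./.` becomes
#' the missing sentinel `NA`. Every VCF sample must appear in the popmap.
#'
#' @param vcf_path Path to a VCF 4.x file (plain or gzipped).
#' @param popmap_path Path to a tab-separated individual -> population map.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(vcf_path, popmap_path) {
  popmap <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] %in% c(".", "") |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  if (any(multi))
    message("dropping ", sum(multi), " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(rownames(gt), colnames(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  samples <- colnames(gt)
  missing_in_map <- setdiff(samples, popmap$individual)
  if (length(missing_in_map))
    stop("individual(s) in VCF missing from popmap: ",
         paste(missing_in_map, collapse = ", "))
  # dosage = count of '1' alleles; any '.' allele -> NA
  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  dos <- (allele1 == "1") + (allele2 == "1")
  dos[allele1 == "." | allele2 == "." | is.na(gt)] <- NA_integer_
  dos <- t(dos)  # individuals x loci
  loci <- tibble::tibble(
    locus_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                      paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                      fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]))
  ind <- tibble::tibble(individual = samples,
                        pop = popmap$pop[match(samples, popmap$individual)])
  genotype_matrix(dos, loci, ind)
}

#' Write genotypes as a minimal VCF
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=adaptscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individuals$individual),
                     collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$locus_id[j],
                       "A", "T", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a population map
#'
#' @param g A [genotype_matrix()] (or a tibble with `individual`, `pop`).
#' @param path Output path.
#' @export
write_popmap <- function(g, path) {
  ind <- if (inherits(g, "genotype_matrix")) g$individuals else g
  write.table(ind[, c("individual", "pop")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from a TSV (fallback for non-VCF deposits)
#'
#' Expects a header row of locus ids, a first column `individual`, a second
#' column `pop`, and integer dosages (`NA` for missing).
#'
#' @param path Path to the TSV.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  dos <- as.matrix(tab[, -(1:2), drop = FALSE])
  loci <- tibble::tibble(locus_id = colnames(dos),
                         chrom = colnames(dos),
                         pos = 1L)
  genotype_matrix(dos, loci,
                  tibble::tibble(individual = as.character(tab[[1]]),
                                 pop = as.character(tab[[2]])))
}

#' Write the dosage-TSV fallback format
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- data.frame(individual = g$individuals$individual,
                    pop = g$individuals$pop, g$dosages,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-population environmental tables
#'
#' CSV with a `pop` column and one numeric column per variable.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_env_csv <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  tab$pop <- as.character(tab$pop)
  if (anyNA(tab)) stop("environmental table contains missing values")
  tibble::as_tibble(tab)
}

#' @rdname read_env_csv
#' @param env Tibble with `pop` plus variable columns.
#' @export
write_env_csv <- function(env, path) {
  write.table(env, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Thresholds mirror the standard RAD-seq filtering and scan settings used
#' throughout the package: MAF >= 0.05, maximum observed heterozygosity 0.5,
#' locus genotyped in >= 85% of individuals and >= 19 populations, three
#' latent factors / genetic PCs as structure proxies, RDA loading cutoff 3 SD,
#' BH FDR 0.05, correlation pruning at |r| > 0.75, migration radii
#' 50/100/200/500/unlimited km, 500 trees per SNP forest and 999 permutations.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    maf_min = 0.05,
    max_obs_het = 0.5,
    min_individual_presence = 0.85,
    min_populations = 19L,
    k_latent = 3L,
    rda_sd_cutoff = 3,
    fdr_alpha = 0.05,
    corr_prune = 0.75,
    migration_radii_km = c(50, 100, 200, 500, Inf),
    n_trees = 500L,
    n_permutations = 999L,
    fdist_sims = 1e6,
    varsel_max_loci = 500L,
    gf_max_loci = 1000L,
    rng_seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$maf_min >= 0, cfg$maf_min < 0.5,
            cfg$max_obs_het > 0, cfg$max_obs_het <= 1,
            cfg$min_individual_presence > 0, cfg$min_individual_presence <= 1,
            cfg$fdr_alpha > 0, cfg$fdr_alpha < 1,
            cfg$corr_prune > 0, cfg$corr_prune <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a YAML run configuration
#' @param path YAML path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$migration_radii_km))
    vals$migration_radii_km <-
      as.numeric(ifelse(vals$migration_radii_km %in% c("Inf", ".inf"),
                        Inf, vals$migration_radii_km))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg A [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals$migration_radii_km <- as.character(vals$migration_radii_km)
  yaml::write_yaml(vals, path)
  invisible(path)
}
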