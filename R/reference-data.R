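#' Reference cowpea trial: published genotype means
#'
#' Summary tables transcribed from a published multi-environment cowpea
#' (*Vigna unguiculata*) variety trial run in northern Ghana: 17 genotypes
#' (16 advanced breeding lines plus the check *Songotra*) evaluated in a
#' randomized complete block design with 3 blocks over 3 years, for eight
#' maturity and yield traits. The raw plot data were not deposited; these
#' genotype-level summaries are the in-package reference fixture for the
#' correlation, PCA and clustering stages and for consistency checks on the
#' genetic-parameter equations.
#'
#' Traits: days to 50 % flowering (DFF, days), days to 90 % pod maturity
#' (DNPM, days), plant height at maturity (PHM, cm), pods per plant (NPP),
#' pod yield (PODWT, t/ha), seeds per pod (NSP), grain yield (GWT, t/ha) and
#' hundred-seed weight (HSW, g).
#'
#' @return `cowpea_means()`: tibble with `genotype`, `trait`, `mean`, `sd`
#'   (17 genotypes x 8 traits).
#' @export
cowpea_means <- function() {
  out <- readr::read_csv(ref_file("cowpea_genotype_means.csv"),
                         show_col_types = FALSE, progress = FALSE)
  out$genotype <- factor(out$genotype, levels = unique(out$genotype))
  out$trait <- factor(out$trait, levels = unique(out$trait))
  out
}

#' @rdname cowpea_means
#' @return `cowpea_trait_summary()`: tibble with the per-trait footer of the
#'   published mean table: `grand_mean`, `grand_sd`, `lsd_05`, `cv_pct`.
#' @export
cowpea_trait_summary <- function() {
  readr::read_csv(ref_file("cowpea_trait_summary.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname cowpea_means
#' @return `cowpea_genetic_parameters()`: tibble with the published per-trait
#'   variance components and genetic parameters: `var_e`, `var_g`, `var_p`,
#'   `h2` (%), `gcv`, `pcv`, `ga`, `gam` (%).
#' @export
cowpea_genetic_parameters <- function() {
  readr::read_csv(ref_file("cowpea_genetic_parameters.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname cowpea_means
#' @return `cowpea_pca_reference()`: list with `loadings` (tibble, trait x
#'   PC1..PC5) and `summary` (tibble: `component`, `eigenvalue`,
#'   `variability_pct`, `cumulative_pct`) as published.
#' @export
cowpea_pca_reference <- function() {
  list(
    loadings = readr::read_csv(ref_file("cowpea_pca_loadings.csv"),
                               show_col_types = FALSE, progress = FALSE),
    summary = readr::read_csv(ref_file("cowpea_pca_summary.csv"),
                              show_col_types = FALSE, progress = FALSE)
  )
}

ref_file <- function(name) {
  path <- system.file("extdata", name, package = "gentrial")
  if (path == "") {
    # during development (pkgload), fall back to the source tree
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) abort(paste0("reference file not found: ", name))
  path
}
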