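#' Pipeline configuration
#'
#' Collects every tunable of the full analysis under one object. Defaults
#' follow the conventional choices for variety-trial reports: alpha = 0.05
#' for LSD and correlation significance, selection intensity i = 2.06 (top
#' 5 %), k = 3 clusters, loading-importance threshold 0.3, combined-analysis
#' effective replication.
#'
#' @param input Path to a trial CSV (long or wide); `NULL` to simulate.
#' @param design A [trial_design()] (used when `input` is `NULL`).
#' @param spec A [multitrait_spec()] or single [variance_spec()] (used when
#'   `input` is `NULL`). Default: [cowpea_sim_spec()].
#' @param traits Optional trait subset; every listed trait must be present.
#' @param alpha Significance level for LSD and correlation.
#' @param i Selection intensity constant for genetic advance.
#' @param r_effective `"combined"` or `"per_environment"` (see
#'   [genetic_summary()]).
#' @param genotype_denominator F-test denominator for genotype in the
#'   combined ANOVA (see [combined_anova()]).
#' @param scale_pca,scale_cluster Standardize traits before PCA distances /
#'   clustering (PCA is always on the correlation matrix; this flag is kept
#'   for the cluster stage).
#' @param k Number of clusters to cut.
#' @param loading_threshold Importance cutoff for PCA loadings.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed governing simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, design = trial_design(17, 3, 3),
                            spec = NULL, traits = NULL, alpha = 0.05,
                            i = 2.06, r_effective = "combined",
                            genotype_denominator = "pooled_error",
                            scale_pca = TRUE, scale_cluster = TRUE, k = 3,
                            loading_threshold = 0.3,
                            out_dir = "gentrial-output", seed = 1) {
  if (inherits(spec, "variance_spec")) {
    spec <- multitrait_spec(list(trait1 = spec))
  }
  cfg <- list(input = input, design = design, spec = spec, traits = traits,
              alpha = alpha, i = i, r_effective = r_effective,
              genotype_denominator = genotype_denominator,
              scale_pca = scale_pca, scale_cluster = scale_cluster,
              k = as.integer(k), loading_threshold = loading_threshold,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]. A simulation
#' is described under `design:` (`g`, `e`, `r`) and `traits_spec:` (one block
#' per trait with `mu`, `var_g`, `var_env`, `var_ge`, `var_block`,
#' `var_resid`) plus an optional `correlation:` (list of rows).
#'
#' @param file Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  design <- if (!is.null(y$design)) {
    trial_design(y$design$g, y$design$e, y$design$r)
  } else {
    trial_design(17, 3, 3)
  }
  spec <- NULL
  if (!is.null(y$traits_spec)) {
    specs <- purrr::map(y$traits_spec, function(s) {
      variance_spec(mu = s$mu, var_g = s$var_g,
                    var_env = s$var_env %||% 0, var_ge = s$var_ge %||% 0,
                    var_block = s$var_block %||% 0, var_resid = s$var_resid)
    })
    R <- if (!is.null(y$correlation)) do.call(rbind, y$correlation) else NULL
    spec <- multitrait_spec(specs, genetic_correlation = R)
  }
  args <- y[intersect(names(y), c("input", "traits", "alpha", "i",
                                  "r_effective", "genotype_denominator",
                                  "scale_pca", "scale_cluster", "k",
                                  "loading_threshold", "out_dir", "seed"))]
  do.call(pipeline_config, c(list(design = design, spec = spec), args))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full trial analysis pipeline
#'
#' Ingests (or simulates) a trial, then runs every stage: per-trait ANOVA
#' (combined over environments when there are several), genetic parameter
#' summary, LSD mean separation, trait correlations, PCA and UPGMA
#' clustering. Writes one CSV per result table plus a Newick dendrogram and a
#' machine-readable `manifest.json` (package/R versions, seed, config hash,
#' file list — no timestamps, so a rerun with the same config and seed is
#' byte-identical).
#'
#' @param cfg A [pipeline_config()] (or path to a YAML config).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with every stage result (`data`, `anova`,
#'   `genetics`, `means`, `correlation`, `pca`, `importance`, `clusters`,
#'   `manifest`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  data <- run_stage("input", {
    if (!is.null(cfg$input)) {
      read_trial_table(cfg$input, quiet = TRUE)
    } else {
      spec <- cfg$spec %||% cowpea_sim_spec()
      simulate_multitrait(cfg$design, spec, seed = cfg$seed)
    }
  })
  if (!is.null(cfg$traits)) {
    missing <- setdiff(cfg$traits, levels(data$trait))
    if (length(missing) > 0) {
      abort(paste0("pipeline stage 'input' failed: trait column(s) not in data: ",
                   paste(missing, collapse = ", ")))
    }
    data <- as_trial_table(data[as.character(data$trait) %in% cfg$traits, ])
  }
  dc <- design_counts(data)
  say("input: %d genotypes x %d environments x %d blocks, %d traits",
      dc$g, dc$e, dc$r, dc$n_traits)

  anova_fits <- run_stage("anova", {
    purrr::map(levels(data$trait), function(tr) {
      if (dc$e > 1) {
        combined_anova(data, tr, genotype_denominator = cfg$genotype_denominator)
      } else {
        rcbd_anova(data, tr)
      }
    })
  })
  names(anova_fits) <- levels(data$trait)
  anova_tbl <- dplyr::bind_rows(
    purrr::imap(anova_fits, function(f, tr) dplyr::mutate(tidy(f), trait = tr,
                                                          .before = 1)))
  say("anova: %d traits (%s layout)", length(anova_fits),
      ifelse(dc$e > 1, "combined", "rcbd"))

  genetics <- run_stage("genetics",
                        genetic_summary(data, r_effective = cfg$r_effective,
                                        i = cfg$i, classify = TRUE))
  means <- run_stage("means", mean_separation(data, alpha = cfg$alpha))
  correlation <- run_stage("correlate",
                           trait_correlation(genotype_means(data), alpha = cfg$alpha))
  pca <- run_stage("pca", trait_pca(genotype_means(data)))
  importance <- run_stage("pca", important_traits(pca, cfg$loading_threshold))
  clusters <- run_stage("cluster",
                        hierarchical_cluster(genotype_means(data), k = cfg$k,
                                             scale = cfg$scale_cluster))

  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(out, name))
    name
  }
  files <- run_stage("write", c(
    w({
      d <- as_tibble(data)
      d[] <- lapply(d, function(col) if (is.factor(col)) as.character(col) else col)
      d
    }, "trial_data.csv"),
    w(anova_tbl, "anova_tables.csv"),
    w(as_tibble(genetics), "genetic_parameters.csv"),
    w(as_tibble(means), "genotype_means.csv"),
    w(glance(means), "means_footer.csv"),
    w(tidy(correlation), "correlations.csv"),
    w(tidy(pca, "eigenvalues"), "pca_summary.csv"),
    w(tidy(pca, "loadings"), "pca_loadings.csv"),
    w(tidy(pca, "scores"), "pca_scores.csv"),
    w(importance, "pca_importance.csv"),
    w(tidy(clusters), "cluster_members.csv")
  ))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(clusters, file.path(out, "dendrogram.nwk"))
    files <- c(files, "dendrogram.nwk")
  }
  manifest <- list(
    package = "gentrial",
    package_version = as.character(utils::packageVersion("gentrial")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    design = list(g = dc$g, e = dc$e, r = dc$r, traits = dc$n_traits),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("wrote %d files to %s", length(files) + 1, out)

  invisible(list(data = data, anova = anova_fits, genetics = genetics,
                 means = means, correlation = correlation, pca = pca,
                 importance = importance, clusters = clusters,
                 manifest = manifest))
}
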