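#' Variance specification for one simulated trait
#'
#' Defines the additive linear model used by the trial generator,
#' `y_ijk = mu + G_i + E_j + GE_ij + B_k(j) + eps_ijk`, where every effect is
#' an independent zero-mean Gaussian draw with the stated variance (trait
#' units squared). The implied plot variance is the sum of the components.
#'
#' @param mu Trait grand mean, in trait units.
#' @param var_g Genotypic variance.
#' @param var_env Environment (year/location) variance.
#' @param var_ge Genotype-by-environment interaction variance.
#' @param var_block Block-within-environment variance.
#' @param var_resid Residual (plot error) variance.
#' @return A list of class `variance_spec`.
#' @export
variance_spec <- function(mu, var_g, var_env = 0, var_ge = 0, var_block = 0,
                          var_resid) {
  vars <- c(var_g = var_g, var_env = var_env, var_ge = var_ge,
            var_block = var_block, var_resid = var_resid)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    abort("all variance components must be finite and nonnegative")
  }
  structure(list(mu = mu, var_g = var_g, var_env = var_env, var_ge = var_ge,
                 var_block = var_block, var_resid = var_resid),
            class = "variance_spec")
}

#' Trial design for the simulator
#'
#' @param g Number of genotypes (>= 2).
#' @param e Number of environments (>= 1).
#' @param r Blocks (complete replicates) per environment (>= 2).
#' @param seed Optional integer seed; a fixed seed makes the whole draw
#'   reproducible. Can be overridden per call in [simulate_trial()].
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(g, e, r, seed = NULL) {
  if (g < 2) abort("need g >= 2 genotypes")
  if (e < 1) abort("need e >= 1 environments")
  if (r < 2) abort("need r >= 2 blocks per environment")
  structure(list(g = as.integer(g), e = as.integer(e), r = as.integer(r),
                 seed = seed),
            class = "trial_design")
}

#' Multi-trait simulation specification
#'
#' Couples several per-trait [variance_spec()]s through a genetic correlation
#' matrix: the genotype effects of all traits are drawn jointly from a
#' multivariate Gaussian whose correlation is `genetic_correlation`, while all
#' other effects stay independent across traits.
#'
#' @param specs Named list of [variance_spec()] objects, one per trait.
#' @param genetic_correlation Symmetric positive semi-definite matrix with
#'   unit diagonal, one row/column per trait (in the order of `specs`).
#'   Defaults to the identity (independent genotype effects).
#' @return A list of class `multitrait_spec`.
#' @export
multitrait_spec <- function(specs, genetic_correlation = NULL) {
  if (is.null(names(specs)) || any(names(specs) == "")) {
    abort("`specs` must be a named list (one name per trait)")
  }
  ok <- vapply(specs, inherits, logical(1), what = "variance_spec")
  if (!all(ok)) abort("every element of `specs` must be a variance_spec()")
  k <- length(specs)
  if (is.null(genetic_correlation)) genetic_correlation <- diag(k)
  R <- as.matrix(genetic_correlation)
  if (!isTRUE(all.equal(dim(R), c(k, k)))) {
    abort(sprintf("genetic_correlation must be %d x %d", k, k))
  }
  if (max(abs(R - t(R))) > 1e-10) abort("genetic_correlation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) abort("genetic_correlation must have unit diagonal")
  if (any(abs(R) > 1 + 1e-10)) abort("genetic correlations must lie in [-1, 1]")
  lambda_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_min < -1e-8) {
    abort(sprintf(
      "genetic_correlation is not positive semi-definite (smallest eigenvalue %.6g)",
      lambda_min))
  }
  dimnames(R) <- list(names(specs), names(specs))
  structure(list(traits = specs, correlation = R), class = "multitrait_spec")
}

# symmetric PSD square root (tiny negative eigenvalues clamped to zero)
psd_sqrt <- function(R) {
  ed <- eigen(R, symmetric = TRUE)
  ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
}

#' Simulate a single-trait RCBD multi-environment trial
#'
#' Draws one balanced trial from the additive model described in
#' [variance_spec()]. Given the same design, spec and seed the output is
#' identical call to call.
#'
#' @param design A [trial_design()].
#' @param spec A [variance_spec()].
#' @param trait Trait label for the output table.
#' @param seed Integer seed; defaults to `design$seed`. `NULL` uses the
#'   current RNG state.
#' @return A `trial_table` tibble with `g * e * r` plots.
#' @examples
#' simulate_trial(trial_design(17, 3, 3, seed = 42),
#'                variance_spec(mu = 40.37, var_g = 9.35, var_resid = 2.68))
#' @export
simulate_trial <- function(design, spec, trait = "trait1", seed = design$seed) {
  stopifnot(inherits(design, "trial_design"), inherits(spec, "variance_spec"))
  ms <- multitrait_spec(setNames(list(spec), trait))
  simulate_multitrait(design, ms, seed = seed)
}

#' Simulate a multi-trait RCBD multi-environment trial
#'
#' As [simulate_trial()], but genotype effects across traits are drawn
#' jointly with the genetic correlation requested in [multitrait_spec()];
#' environment, G-by-E, block and residual effects remain independent across
#' traits. One seed governs the whole draw.
#'
#' @param design A [trial_design()].
#' @param spec A [multitrait_spec()].
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A `trial_table` tibble with `g * e * r` plots per trait.
#' @export
simulate_multitrait <- function(design, spec, seed = design$seed) {
  stopifnot(inherits(design, "trial_design"), inherits(spec, "multitrait_spec"))
  if (is.null(seed)) {
    draw_multitrait(design, spec)
  } else {
    withr::with_seed(as.integer(seed), draw_multitrait(design, spec))
  }
}

draw_multitrait <- function(design, spec) {
  g <- design$g; e <- design$e; r <- design$r
  traits <- names(spec$traits)
  k <- length(traits)
  sd_g <- sqrt(vapply(spec$traits, `[[`, numeric(1), "var_g"))
  # joint genotype effects: rows = genotypes, cols = traits
  Z <- matrix(rnorm(g * k), nrow = g, ncol = k)
  G <- Z %*% psd_sqrt(spec$correlation)
  G <- sweep(G, 2, sd_g, `*`)
  gi <- rep(seq_len(g), times = e * r)
  ei <- rep(rep(seq_len(e), each = g), times = r)
  bi <- rep(seq_len(r), each = g * e)
  pieces <- vector("list", k)
  for (t in seq_len(k)) {
    sp <- spec$traits[[t]]
    E  <- rnorm(e,     sd = sqrt(sp$var_env))
    GE <- matrix(rnorm(g * e, sd = sqrt(sp$var_ge)), g, e)
    B  <- matrix(rnorm(e * r, sd = sqrt(sp$var_block)), e, r)
    eps <- rnorm(g * e * r, sd = sqrt(sp$var_resid))
    y <- sp$mu + G[gi, t] + E[ei] + GE[cbind(gi, ei)] + B[cbind(ei, bi)] + eps
    pieces[[t]] <- tibble(
      genotype = sprintf("G%02d", gi),
      environment = sprintf("E%d", ei),
      block = sprintf("B%d", bi),
      trait = traits[t],
      value = y
    )
  }
  as_trial_table(dplyr::bind_rows(pieces))
}

#' Cowpea-like default simulation specification
#'
#' A ready-made [multitrait_spec()] emulating the reference cowpea trial
#' shipped with the package: eight maturity/yield traits with grand means from
#' the published genotype-mean table, genotypic and residual variances from
#' the published variance-component table, and a genetic correlation matrix
#' equal to the correlation of the published genotype means (so the simulated
#' trait relationships reproduce the published sign pattern by construction).
#' Environment, G-by-E and block variances are zero: the reference analysis
#' decomposes plot variance into genotypic and error components only.
#'
#' @return A `multitrait_spec` for 8 traits.
#' @seealso [cowpea_means()], [cowpea_genetic_parameters()]
#' @export
cowpea_sim_spec <- function() {
  gp <- cowpea_genetic_parameters()
  ts <- cowpea_trait_summary()
  tab <- dplyr::left_join(gp[, c("trait", "var_g", "var_e")],
                          ts[, c("trait", "grand_mean")], by = "trait")
  specs <- purrr::pmap(tab, function(trait, var_g, var_e, grand_mean) {
    variance_spec(mu = grand_mean, var_g = var_g, var_resid = var_e)
  })
  names(specs) <- tab$trait
  m <- means_matrix(cowpea_means())
  multitrait_spec(specs, genetic_correlation = cor(m[, tab$trait]))
}
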