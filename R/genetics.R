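#' Method-of-moments variance components from RCBD mean squares
#'
#' Under the RCBD expected-mean-squares model, the genotypic variance is
#' estimated as `sigma_g^2 = (MS_G - MS_E) / r`, the error (environmental)
#' variance as `sigma_e^2 = MS_E`, and the phenotypic variance as their sum.
#' `r` is the number of plots averaged into each genotype mean: the number of
#' blocks for a single-environment analysis, blocks times environments for an
#' analysis combined over environments.
#'
#' A negative raw estimate (when `MS_G < MS_E`) is truncated to zero in
#' `var_g` and flagged in `truncated`; the raw value is kept in `var_g_raw`.
#'
#' @param ms_g Genotype mean square(s), >= 0.
#' @param ms_e Error mean square(s), >= 0.
#' @param r Effective replication (>= 1).
#' @return A tibble with columns `ms_g`, `ms_e`, `r_effective`, `var_e`,
#'   `var_g_raw`, `var_g`, `var_p`, `truncated`. Vectorised over `ms_g`/`ms_e`.
#' @examples
#' variance_components(ms_g = 86.83, ms_e = 2.68, r = 9)
#' @export
variance_components <- function(ms_g, ms_e, r) {
  if (length(r) != 1 || !is.finite(r) || r < 1) {
    abort("`r` must be a single replication count >= 1")
  }
  if (any(ms_g < 0) || any(ms_e < 0)) abort("mean squares must be nonnegative")
  var_g_raw <- (ms_g - ms_e) / r
  truncated <- var_g_raw < 0
  if (any(truncated)) {
    warn(sprintf("%d negative genotypic variance estimate(s) truncated to 0 (MS_G < MS_E)",
                 sum(truncated)))
  }
  var_g <- pmax(var_g_raw, 0)
  tibble(ms_g = ms_g, ms_e = ms_e, r_effective = r,
         var_e = ms_e, var_g_raw = var_g_raw, var_g = var_g,
         var_p = var_g + ms_e, truncated = truncated)
}

#' Genotypic and phenotypic coefficients of variation
#'
#' `GCV = 100 * sigma_g / mu` and `PCV = 100 * sigma_p / mu`: the genotypic
#' and phenotypic standard deviations as percentages of the trait grand mean.
#' PCV >= GCV always (the phenotypic variance contains the error variance).
#'
#' @param vc Variance components, as returned by [variance_components()] (any
#'   data frame with `var_g` and `var_p` columns works).
#' @param mu Trait grand mean(s), > 0.
#' @return A tibble with columns `gcv` and `pcv`, in percent.
#' @examples
#' vc <- variance_components(86.83, 2.68, 9)
#' coefficients_of_variation(vc, mu = 40.37)
#' @export
coefficients_of_variation <- function(vc, mu) {
  check_vc(vc, c("var_g", "var_p"))
  if (any(!is.finite(mu)) || any(mu <= 0)) abort("`mu` must be positive")
  tibble(gcv = 100 * sqrt(vc$var_g) / mu, pcv = 100 * sqrt(vc$var_p) / mu)
}

#' Broad-sense heritability (%)
#'
#' `h2 = 100 * sigma_g^2 / sigma_p^2`: the share of phenotypic variance
#' attributable to (total) genetic effects.
#'
#' @inheritParams coefficients_of_variation
#' @return Numeric vector of heritabilities on the 0-100 scale.
#' @export
broad_sense_heritability <- function(vc) {
  check_vc(vc, c("var_g", "var_p"))
  if (any(vc$var_p <= 0)) abort("phenotypic variance must be positive (degenerate trait)")
  100 * vc$var_g / vc$var_p
}

#' Expected genetic advance under truncation selection
#'
#' `GA = i * sigma_p * h2` with `h2` as a proportion, the expected gain in the
#' trait mean from selecting the best fraction of genotypes (the default
#' intensity `i = 2.06` corresponds to selecting the top 5 %). `GAM` expresses
#' the gain as a percentage of the grand mean.
#'
#' @inheritParams coefficients_of_variation
#' @param h2 Broad-sense heritability on the 0-100 scale (as printed in
#'   summary tables).
#' @param mu Trait grand mean(s), > 0.
#' @param i Standardized selection differential (default 2.06, 5 % intensity).
#' @return A tibble with `ga` (trait units) and `gam` (%).
#' @export
genetic_advance <- function(vc, h2, mu, i = 2.06) {
  check_vc(vc, "var_p")
  if (any(!is.finite(mu)) || any(mu <= 0)) abort("`mu` must be positive")
  if (any(vc$var_p < 0)) abort("phenotypic variance must be nonnegative")
  ga <- i * sqrt(vc$var_p) * (h2 / 100)
  tibble(ga = ga, gam = 100 * ga / mu)
}

check_vc <- function(vc, cols) {
  if (!is.data.frame(vc) || !all(cols %in% names(vc))) {
    abort(paste0("`vc` must contain column(s): ", paste(cols, collapse = ", ")))
  }
  invisible(vc)
}

#' Per-trait genetic parameter summary
#'
#' Runs the ANOVA for every trait (combined over environments when the table
#' has several), extracts the genotype and error mean squares, and assembles
#' the full genetic-parameter table: variance components, broad-sense
#' heritability, GCV/PCV, genetic advance and GAM.
#'
#' @param data A balanced trial table.
#' @param r_effective `"combined"` (default) uses `e * r` plots per genotype
#'   mean in the variance-component equation; `"per_environment"` uses `r`.
#' @param i Selection intensity constant (default 2.06 = top 5 %).
#' @param classify Add conventional low/moderate/high bands (GCV/PCV at
#'   10/20 %, heritability at 30/60 %, GAM at 10/20 %). These cutoffs are a
#'   literature convention, not part of the estimation.
#' @return A tibble of class `genetic_summary`, one row per trait: `trait`,
#'   `mu`, `ms_g`, `ms_e`, `r_effective`, `var_e`, `var_g_raw`, `var_g`,
#'   `var_p`, `h2`, `gcv`, `pcv`, `ga`, `gam` (and `*_class` bands when
#'   `classify = TRUE`).
#' @examples
#' d <- simulate_trial(trial_design(17, 3, 3, seed = 11),
#'                     variance_spec(mu = 40.37, var_g = 9.35, var_resid = 2.68),
#'                     trait = "DFF")
#' genetic_summary(d)
#' @export
genetic_summary <- function(data, r_effective = c("combined", "per_environment"),
                            i = 2.06, classify = FALSE) {
  r_effective <- match.arg(r_effective)
  tt <- as_trial_table(data)
  dc <- design_counts(tt)
  if (!dc$balanced) abort("genetic_summary() needs a balanced trial table")
  rows <- purrr::map(levels(tt$trait), function(tr) {
    fit <- if (dc$e > 1) combined_anova(tt, tr) else rcbd_anova(tt, tr)
    r_eff <- if (dc$e > 1 && r_effective == "combined") dc$e * dc$r else dc$r
    tab <- fit$table
    ms_g <- tab$ms[tab$term == "genotype"]
    vc <- variance_components(ms_g, fit$ms_error, r_eff)
    h2 <- broad_sense_heritability(vc)
    cvs <- coefficients_of_variation(vc, fit$grand_mean)
    adv <- genetic_advance(vc, h2, fit$grand_mean, i = i)
    dplyr::bind_cols(tibble(trait = tr, mu = fit$grand_mean), vc,
                     tibble(h2 = h2), cvs, adv)
  })
  out <- dplyr::bind_rows(rows)
  if (classify) {
    out$gcv_class <- band(out$gcv, 10, 20)
    out$pcv_class <- band(out$pcv, 10, 20)
    out$h2_class <- band(out$h2, 30, 60)
    out$gam_class <- band(out$gam, 10, 20)
  }
  attr(out, "i") <- i
  class(out) <- c("genetic_summary", class(out))
  out
}

band <- function(x, lo, hi) {
  dplyr::case_when(x < lo ~ "low", x <= hi ~ "moderate", TRUE ~ "high")
}

#' @rdname genetic_summary
#' @param x A `genetic_summary`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble with trait count, selection intensity,
#'   heritability range and count of truncated variance estimates.
#' @export
glance.genetic_summary <- function(x, ...) {
  tibble(n_traits = nrow(x), i = attr(x, "i"),
         h2_min = min(x$h2), h2_max = max(x$h2),
         n_truncated = sum(x$truncated))
}
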