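#' RCBD analysis of variance for one trait in one environment
#'
#' Classical randomized-complete-block ANOVA: sources are genotype (df g-1),
#' block (df r-1) and error (df (g-1)(r-1)). F for genotype and block is the
#' source mean square over the error mean square; when the error mean square
#' is zero the F statistic and p-value are reported as `NA` (a sentinel, never
#' infinity).
#'
#' Balanced data use the closed-form sums-of-squares decomposition. Unbalanced
#' data (missing plots) are refused unless `allow_unbalanced = TRUE`, in which
#' case missing plots are deleted, a sequential least-squares fit
#' (blocks before genotypes) supplies the sums of squares, and degrees of
#' freedom are reduced accordingly.
#'
#' @param data A trial table (any data frame accepted by [as_trial_table()]).
#' @param trait Trait label to analyse.
#' @param environment Environment label; may be omitted when the table
#'   contains a single environment.
#' @param allow_unbalanced Analyse unbalanced data by plot deletion.
#' @return An object of class `trial_anova`; see [tidy.trial_anova()].
#' @examples
#' d <- simulate_trial(trial_design(17, 1, 3, seed = 7),
#'                     variance_spec(mu = 40, var_g = 9, var_resid = 3),
#'                     trait = "DFF")
#' fit <- rcbd_anova(d, "DFF")
#' tidy(fit)
#' @export
rcbd_anova <- function(data, trait, environment = NULL, allow_unbalanced = FALSE) {
  tt <- as_trial_table(data)
  sub <- pick_trait(tt, trait)
  if (is.null(environment)) {
    envs <- unique(as.character(sub$environment))
    if (length(envs) > 1) {
      abort("table has several environments; pass `environment` or use combined_anova()")
    }
    environment <- envs[1]
  } else {
    sub <- sub[as.character(sub$environment) == environment, , drop = FALSE]
    if (nrow(sub) == 0) abort(paste0("environment not found: ", environment))
  }
  gf <- droplevels(sub$genotype)
  bf <- droplevels(sub$block)
  g <- nlevels(gf); r <- nlevels(bf)
  if (g < 2) abort("need at least 2 genotypes")
  if (r < 2) abort("need at least 2 blocks")
  y <- sub$value
  balanced <- !anyNA(y) && nrow(sub) == g * r &&
    !any(duplicated(data.frame(gf, bf)))
  if (!balanced && !allow_unbalanced) {
    abort("unbalanced or incomplete layout; rerun with allow_unbalanced = TRUE to analyse by plot deletion")
  }

  if (balanced) {
    grand <- mean(y)
    ss_tot <- sum((y - grand)^2)
    mg <- tapply(y, gf, mean)
    mb <- tapply(y, bf, mean)
    ss_g <- r * sum((mg - grand)^2)
    ss_b <- g * sum((mb - grand)^2)
    ss_err <- ss_tot - ss_g - ss_b
    df <- c(g - 1L, r - 1L, (g - 1L) * (r - 1L))
    ss <- c(ss_g, ss_b, ss_err)
  } else {
    keep <- !is.na(y)
    fit <- aov(value ~ block + genotype,
               data = data.frame(value = y[keep], block = bf[keep], genotype = gf[keep]))
    a <- summary(fit)[[1]]
    grand <- mean(y[keep])
    ss <- c(a["genotype", "Sum Sq"], a["block", "Sum Sq"], a["Residuals", "Sum Sq"])
    df <- as.integer(c(a["genotype", "Df"], a["block", "Df"], a["Residuals", "Df"]))
  }
  build_anova(terms = c("genotype", "block", "error"), df = df, ss = ss,
              trait = trait, layout = "rcbd", environment = environment,
              grand_mean = grand, g = g, e = 1L, r = r, n_per_mean = r,
              f_num = c("genotype", "block"))
}

#' Combined ANOVA over environments for one trait
#'
#' RCBD analysis combined over environments (years/locations) with blocks
#' nested within environment. Sources: genotype (g-1), environment (e-1),
#' block-within-environment e(r-1), genotype-by-environment (g-1)(e-1) and
#' pooled error e(g-1)(r-1). By default every F statistic uses the pooled
#' error mean square as denominator; `genotype_denominator = "interaction"`
#' tests genotype against the G-by-E mean square instead (the conservative
#' choice when environments are regarded as random).
#'
#' @inheritParams rcbd_anova
#' @param genotype_denominator `"pooled_error"` (default) or `"interaction"`.
#' @return An object of class `trial_anova`.
#' @export
combined_anova <- function(data, trait,
                           genotype_denominator = c("pooled_error", "interaction"),
                           allow_unbalanced = FALSE) {
  genotype_denominator <- match.arg(genotype_denominator)
  tt <- as_trial_table(data)
  sub <- pick_trait(tt, trait)
  gf <- droplevels(sub$genotype)
  ef <- droplevels(sub$environment)
  bf <- droplevels(sub$block)
  g <- nlevels(gf); e <- nlevels(ef); r <- nlevels(bf)
  if (e < 2) abort("single environment: use rcbd_anova()")
  if (g < 2) abort("need at least 2 genotypes")
  if (r < 2) abort("need at least 2 blocks per environment")
  y <- sub$value
  balanced <- !anyNA(y) && nrow(sub) == g * e * r &&
    !any(duplicated(data.frame(gf, ef, bf)))
  if (!balanced && !allow_unbalanced) {
    abort("unbalanced or incomplete layout; rerun with allow_unbalanced = TRUE to analyse by plot deletion")
  }
  terms <- c("genotype", "environment", "block_in_environment",
             "genotype_x_environment", "error")
  if (balanced) {
    gi <- as.integer(gf); ei <- as.integer(ef); bi <- as.integer(bf)
    grand <- mean(y)
    ss_tot <- sum((y - grand)^2)
    mg <- tapply(y, gi, mean)
    me <- tapply(y, ei, mean)
    meb <- tapply(y, list(ei, bi), mean)            # e x r
    mge <- tapply(y, list(gi, ei), mean)            # g x e
    ss_g <- e * r * sum((mg - grand)^2)
    ss_e <- g * r * sum((me - grand)^2)
    ss_b <- g * sum(sweep(meb, 1, me)^2)
    ss_ge <- r * sum((sweep(sweep(mge, 1, mg), 2, me) + grand)^2)
    ss_err <- ss_tot - ss_g - ss_e - ss_b - ss_ge
    df <- c(g - 1L, e - 1L, e * (r - 1L), (g - 1L) * (e - 1L),
            e * (g - 1L) * (r - 1L))
    ss <- c(ss_g, ss_e, ss_b, ss_ge, ss_err)
  } else {
    keep <- !is.na(y)
    d <- data.frame(value = y[keep], genotype = gf[keep],
                    environment = ef[keep], block = bf[keep])
    fit <- aov(value ~ environment + environment:block + genotype +
                 genotype:environment, data = d)
    a <- summary(fit)[[1]]
    rn <- trimws(rownames(a))
    grand <- mean(d$value)
    pick <- function(nm) a[match(nm, rn), ]
    ss <- c(pick("genotype")[["Sum Sq"]], pick("environment")[["Sum Sq"]],
            pick("environment:block")[["Sum Sq"]],
            pick("environment:genotype")[["Sum Sq"]] %||%
              pick("genotype:environment")[["Sum Sq"]],
            pick("Residuals")[["Sum Sq"]])
    df <- as.integer(c(pick("genotype")[["Df"]], pick("environment")[["Df"]],
                       pick("environment:block")[["Df"]],
                       pick("environment:genotype")[["Df"]] %||%
                         pick("genotype:environment")[["Df"]],
                       pick("Residuals")[["Df"]]))
  }
  out <- build_anova(terms = terms, df = df, ss = ss, trait = trait,
                     layout = "combined", environment = NA_character_,
                     grand_mean = grand, g = g, e = e, r = r,
                     n_per_mean = e * r,
                     f_num = c("genotype", "environment",
                               "block_in_environment", "genotype_x_environment"))
  if (genotype_denominator == "interaction") {
    ms_ge <- out$table$ms[out$table$term == "genotype_x_environment"]
    df_ge <- out$table$df[out$table$term == "genotype_x_environment"]
    i <- which(out$table$term == "genotype")
    if (is.finite(ms_ge) && ms_ge > 0) {
      out$table$statistic[i] <- out$table$ms[i] / ms_ge
      out$table$p.value[i] <- pf(out$table$statistic[i], out$table$df[i],
                                 df_ge, lower.tail = FALSE)
    } else {
      out$table$statistic[i] <- NA_real_
      out$table$p.value[i] <- NA_real_
    }
    out$genotype_denominator <- "interaction"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

pick_trait <- function(tt, trait) {
  if (length(trait) != 1) abort("`trait` must be a single label")
  sub <- tt[as.character(tt$trait) == trait, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("trait not found: ", trait))
  }
  sub
}

build_anova <- function(terms, df, ss, trait, layout, environment, grand_mean,
                        g, e, r, n_per_mean, f_num) {
  ms <- ifelse(df > 0, ss / df, NA_real_)
  err <- length(terms)  # error row is last
  ms_err <- ms[err]
  df_err <- df[err]
  statistic <- rep(NA_real_, length(terms))
  p.value <- rep(NA_real_, length(terms))
  if (is.finite(ms_err) && ms_err > 0) {
    idx <- match(f_num, terms)
    statistic[idx] <- ms[idx] / ms_err
    p.value[idx] <- pf(statistic[idx], df[idx], df_err, lower.tail = FALSE)
  }
  structure(
    list(
      table = tibble(term = terms, df = as.integer(df), ss = ss, ms = ms,
                     statistic = statistic, p.value = p.value),
      trait = trait, layout = layout, environment = environment,
      grand_mean = grand_mean, g = g, e = e, r = r,
      n_per_mean = n_per_mean, ms_error = ms_err, df_error = df_err,
      genotype_denominator = "pooled_error"
    ),
    class = "trial_anova"
  )
}

#' @export
print.trial_anova <- function(x, ...) {
  cat(sprintf("# %s ANOVA for trait '%s'%s\n",
              ifelse(x$layout == "rcbd", "RCBD", "Combined"), x$trait,
              ifelse(is.na(x$environment), "",
                     paste0(" (environment ", x$environment, ")"))))
  print(x$table, ...)
  invisible(x)
}

#' Tidy a trial ANOVA
#'
#' @param x A `trial_anova` from [rcbd_anova()] or [combined_anova()].
#' @param ... Unused.
#' @return `tidy()`: the source table as a tibble (`term`, `df`, `ss`, `ms`,
#'   `statistic`, `p.value`).
#' @export
tidy.trial_anova <- function(x, ...) x$table

#' @rdname tidy.trial_anova
#' @return `glance()`: a one-row tibble with the trait, layout, design counts,
#'   grand mean, error mean square/df, CV% and the genotype F and p.
#' @export
glance.trial_anova <- function(x, ...) {
  i <- which(x$table$term == "genotype")
  tibble(trait = x$trait, layout = x$layout, g = x$g, e = x$e, r = x$r,
         grand_mean = x$grand_mean, ms_error = x$ms_error,
         df_error = x$df_error,
         cv = cv_percent(x),
         f_genotype = x$table$statistic[i], p_genotype = x$table$p.value[i])
}

#' Least significant difference
#'
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * MS_error / n_per_mean)`: the
#' smallest absolute difference between two genotype means declared
#' significant at level `alpha`.
#'
#' @param fit A `trial_anova`.
#' @param alpha Significance level in (0, 1).
#' @param n_per_mean Plots averaged into each genotype mean; defaults to `r`
#'   for a single-environment fit and `e * r` for a combined fit.
#' @return The LSD, in trait units.
#' @export
lsd_value <- function(fit, alpha = 0.05, n_per_mean = NULL) {
  stopifnot(inherits(fit, "trial_anova"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1)")
  }
  if (is.null(n_per_mean)) n_per_mean <- fit$n_per_mean
  if (!is.finite(fit$df_error) || fit$df_error < 1) {
    abort("error row with df >= 1 required for an LSD")
  }
  qt(1 - alpha / 2, fit$df_error) * sqrt(2 * fit$ms_error / n_per_mean)
}

#' Coefficient of variation (%)
#'
#' `CV = 100 * sqrt(MS_error) / grand mean`: residual plot-to-plot noise as a
#' percentage of the trait's grand mean.
#'
#' @param fit A `trial_anova`.
#' @param grand_mean Defaults to the grand mean stored in `fit`.
#' @return CV in percent (nonnegative).
#' @export
cv_percent <- function(fit, grand_mean = NULL) {
  stopifnot(inherits(fit, "trial_anova"))
  if (is.null(grand_mean)) grand_mean <- fit$grand_mean
  if (!is.finite(grand_mean) || grand_mean == 0) {
    abort("grand mean must be nonzero to express a CV")
  }
  100 * sqrt(fit$ms_error) / abs(grand_mean)
}

#' Compact letter display from an LSD
#'
#' Genotypes whose means differ by at most `lsd` share at least one letter;
#' genotypes differing by more than `lsd` share none. Letters are assigned to
#' maximal runs of the means sorted in descending order ('a' = the run
#' containing the largest mean); ties keep input order.
#'
#' @param means Named numeric vector of genotype means, or a data frame with
#'   columns `genotype` and `mean`.
#' @param lsd Least significant difference (nonnegative).
#' @return Named character vector of letter groups, in input order.
#' @examples
#' letter_groups(c(A = 10, B = 10, C = 20), lsd = 1)
#' @export
letter_groups <- function(means, lsd) {
  if (is.data.frame(means)) {
    means <- setNames(means$mean, as.character(means$genotype))
  }
  if (is.null(names(means))) abort("`means` must be named by genotype")
  if (!is.numeric(lsd) || length(lsd) != 1 || !is.finite(lsd) || lsd < 0) {
    abort("`lsd` must be a single nonnegative number")
  }
  n <- length(means)
  ord <- order(-means)           # stable: ties keep input order
  m <- as.numeric(means[ord])
  # maximal runs [i, j] with m[i] - m[j] <= lsd
  pool <- c(letters, paste0(rep(letters, each = 26), letters))
  groups <- character(n)
  prev_end <- 0L
  letter_i <- 0L
  for (i in seq_len(n)) {
    j <- i
    while (j < n && m[i] - m[j + 1] <= lsd) j <- j + 1L
    if (j > prev_end) {          # not contained in the previous run
      letter_i <- letter_i + 1L
      if (letter_i > length(pool)) abort("too many letter groups")
      groups[i:j] <- paste0(groups[i:j], pool[letter_i])
      prev_end <- j
    }
  }
  out <- character(n)
  out[ord] <- groups
  setNames(out, names(means))
}

#' Genotype mean separation with LSD and letter groups
#'
#' For each trait: fits the ANOVA (combined over environments when the table
#' has several, single-environment RCBD otherwise), computes genotype means
#' and standard deviations, the LSD at `alpha`, the CV%, and a compact letter
#' display.
#'
#' @param data A trial table.
#' @param traits Traits to separate; default all.
#' @param alpha Significance level for the LSD.
#' @return A tibble of class `mean_separation` with columns `genotype`,
#'   `trait`, `n`, `mean`, `sd`, `group`. Per-trait LSD, CV% and grand means
#'   are available via [glance.mean_separation()].
#' @export
mean_separation <- function(data, traits = NULL, alpha = 0.05) {
  tt <- as_trial_table(data)
  if (is.null(traits)) traits <- levels(tt$trait)
  dc <- design_counts(tt)
  gm <- genotype_means(tt, traits = traits)
  stats_rows <- purrr::map(traits, function(tr) {
    fit <- if (dc$e > 1) combined_anova(tt, tr) else rcbd_anova(tt, tr)
    lsd <- lsd_value(fit, alpha = alpha)
    tibble(trait = tr, grand_mean = fit$grand_mean, lsd = lsd,
           cv = cv_percent(fit), alpha = alpha,
           ms_error = fit$ms_error, df_error = fit$df_error)
  })
  stats <- dplyr::bind_rows(stats_rows)
  out <- purrr::map(traits, function(tr) {
    sub <- gm[as.character(gm$trait) == tr, ]
    lsd <- stats$lsd[stats$trait == tr]
    sub$group <- unname(letter_groups(setNames(sub$mean, as.character(sub$genotype)),
                                      lsd))
    sub
  })
  out <- dplyr::bind_rows(out)
  attr(out, "stats") <- stats
  class(out) <- c("mean_separation", class(out))
  out
}

#' @rdname mean_separation
#' @param x A `mean_separation` table.
#' @param ... Unused.
#' @return `glance()`: per-trait tibble with `grand_mean`, `lsd`, `cv`,
#'   `alpha`, `ms_error`, `df_error`.
#' @export
glance.mean_separation <- function(x, ...) attr(x, "stats")
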