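#' Coerce a data frame to a validated plot-level trial table
#'
#' A trial table holds one row per plot and trait: the observation of one
#' genotype, in one block of one environment (a year or a location), for one
#' measured trait. It is the canonical long form every other function in the
#' package consumes. Wide field-book layouts (one column per trait) are
#' accepted and pivoted internally.
#'
#' Genotype, environment, block and trait labels are kept in order of first
#' appearance (stored as factors), so output tables reproduce the input row
#' order rather than sorting alphabetically.
#'
#' @param x A data frame. Either long (columns `genotype`, `environment`,
#'   `block`, `trait`, `value`) or wide (columns `genotype`, `environment`,
#'   `block`, plus one numeric column per trait).
#' @param traits Optional character vector restricting (and ordering) the
#'   traits kept from a wide table. Ignored for long input.
#' @return A tibble of class `trial_table` with columns `genotype`,
#'   `environment`, `block` and `trait` (factors in input order) and numeric
#'   `value`. Missing observations are kept as `NA` rows, never dropped.
#' @examples
#' d <- simulate_trial(trial_design(g = 5, e = 2, r = 3, seed = 1),
#'                     variance_spec(mu = 50, var_g = 4, var_resid = 1))
#' as_trial_table(d)
#' @export
as_trial_table <- function(x, traits = NULL) {
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  keys <- c("genotype", "environment", "block")
  missing_keys <- setdiff(keys, names(x))
  if (length(missing_keys) > 0) {
    abort(paste0("trial table is missing required column(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  long <- all(c("trait", "value") %in% names(x))
  if (!long) {
    trait_cols <- setdiff(names(x), keys)
    if (!is.null(traits)) {
      missing_tr <- setdiff(traits, trait_cols)
      if (length(missing_tr) > 0) {
        abort(paste0("trait column(s) not found: ",
                     paste(missing_tr, collapse = ", ")))
      }
      trait_cols <- traits
    }
    if (length(trait_cols) == 0) {
      abort("no trait columns found (need `trait`+`value` or wide trait columns)")
    }
    for (b in trait_cols[!vapply(x[trait_cols], is.numeric, logical(1))]) {
      chr <- trimws(as.character(x[[b]]))
      num <- suppressWarnings(as.numeric(chr))
      bad_row <- which(is.na(num) & !is.na(chr) & chr != "")[1]
      if (!is.na(bad_row)) {
        abort(paste0("trait column '", b, "' is not numeric (first offending row: ",
                     bad_row, ")"))
      }
      x[[b]] <- num
    }
    x <- tidyr::pivot_longer(x, cols = dplyr::all_of(trait_cols),
                             names_to = "trait", values_to = "value")
  }
  if (!is.numeric(x$value)) {
    chr <- as.character(x$value)
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(is.na(num) & !is.na(chr) & trimws(chr) != "")
    if (length(bad) > 0) {
      abort(paste0("non-numeric trait value '", chr[bad[1]], "' in row ", bad[1]))
    }
    x$value <- num
  }
  if (any(is.infinite(x$value), na.rm = TRUE)) {
    abort("trait values must be finite (found Inf/-Inf)")
  }
  for (k in c(keys, "trait")) {
    x[[k]] <- factor(as.character(x[[k]]), levels = unique(as.character(x[[k]])))
  }
  dup <- duplicated(x[, c(keys, "trait")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0("duplicate (genotype, environment, block, trait) key: (",
                 x$genotype[i], ", ", x$environment[i], ", ", x$block[i],
                 ", ", x$trait[i], ")"))
  }
  out <- x[, c(keys, "trait", "value")]
  class(out) <- c("trial_table", class(out))
  out
}

#' Read a plot-level trial table from CSV
#'
#' Accepts the long dialect (`genotype,environment,block,trait,value`) or the
#' wide field-book dialect (`genotype,environment,block,<trait1>,...`); both
#' are normalised to the long form.
#'
#' @param file Path to a CSV file (UTF-8).
#' @inheritParams as_trial_table
#' @param quiet If `FALSE` (default), print the design counts after reading.
#' @return A `trial_table` tibble (see [as_trial_table()]).
#' @export
read_trial_table <- function(file, traits = NULL, quiet = FALSE) {
  # parse all cells as text: numeric coercion happens in as_trial_table()
  # through base R's correctly rounded strtod, so decimal text written by
  # write_trial_table() round-trips bit for bit
  raw <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  out <- as_trial_table(raw, traits = traits)
  if (!quiet) {
    dc <- design_counts(out)
    message(sprintf("trial table: %d genotypes x %d environments x %d blocks, %d traits%s",
                    dc$g, dc$e, dc$r, dc$n_traits,
                    if (dc$balanced) " (balanced)" else " (UNBALANCED)"))
  }
  out
}

#' Write a trial table to CSV
#'
#' Values are written as full-precision decimal text (`format(..., digits =
#' 17)`), so a write/read round trip preserves every value bit for bit.
#'
#' @param x A trial table (see [as_trial_table()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trial_table <- function(x, file) {
  x <- as_trial_table(x)
  out <- dplyr::mutate(
    x,
    dplyr::across(c("genotype", "environment", "block", "trait"), as.character),
    value = vapply(.data$value, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  )
  readr::write_csv(out, file, na = "")
  invisible(file)
}

#' Design counts of a trial table
#'
#' @param x A trial table.
#' @return One-row tibble with `g` (genotypes), `e` (environments), `r`
#'   (blocks per environment), `n_traits`, `n_plots` and `balanced` (`TRUE`
#'   when every genotype x environment x block x trait cell is present exactly
#'   once with a non-missing value).
#' @export
design_counts <- function(x) {
  x <- as_trial_table(x)
  g <- nlevels(x$genotype)
  e <- nlevels(x$environment)
  n_traits <- nlevels(x$trait)
  r_by_env <- tapply(as.character(x$block), as.character(x$environment),
                     function(b) length(unique(b)))
  r <- max(r_by_env)
  complete <- nrow(x) == g * e * r * n_traits &&
    length(unique(r_by_env)) == 1 &&
    !anyNA(x$value)
  tibble(g = g, e = e, r = r, n_traits = n_traits,
         n_plots = nrow(x) / n_traits, balanced = complete)
}

#' @export
print.trial_table <- function(x, ...) {
  dc <- design_counts(x)
  cat(sprintf("# Trial table: %d genotypes x %d environments x %d blocks, %d trait(s)%s\n",
              dc$g, dc$e, dc$r, dc$n_traits,
              if (dc$balanced) "" else " [unbalanced]"))
  NextMethod()
}

#' Per-genotype trait means and standard deviations
#'
#' Summarises a plot-level trial table into the genotype-mean table that the
#' correlation, PCA and clustering stages consume. Two standard deviations
#' are reported: `sd` over all plots of the genotype, and `sd_env` over its
#' per-environment means (publications often print the latter when a trial is
#' summarised over years).
#'
#' @param x A trial table.
#' @param traits Optional character vector of traits to keep.
#' @return A tibble with columns `genotype`, `trait`, `n`, `mean`, `sd`,
#'   `sd_env`.
#' @export
genotype_means <- function(x, traits = NULL) {
  x <- as_trial_table(x)
  if (!is.null(traits)) {
    x <- dplyr::filter(x, .data$trait %in% traits)
    x$trait <- factor(as.character(x$trait), levels = traits)
  }
  n_obs <- tapply(x$value, list(x$genotype, x$trait), function(v) sum(!is.na(v)))
  if (any(n_obs == 0)) {
    idx <- which(n_obs == 0, arr.ind = TRUE)[1, ]
    abort(paste0("genotype '", rownames(n_obs)[idx[1]], "' has no observations for trait '",
                 colnames(n_obs)[idx[2]], "'"))
  }
  env_means <- dplyr::summarise(
    dplyr::group_by(x, .data$genotype, .data$trait, .data$environment),
    m = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  sd_env <- dplyr::summarise(
    dplyr::group_by(env_means, .data$genotype, .data$trait),
    sd_env = sd(.data$m), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$genotype, .data$trait),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  dplyr::left_join(out, sd_env, by = c("genotype", "trait"))
}

#' Grand mean per trait
#'
#' The unweighted mean over all plots. For a balanced design this equals the
#' mean of the genotype means.
#'
#' @param x A trial table.
#' @return A tibble with columns `trait` and `grand_mean`.
#' @export
grand_means <- function(x) {
  x <- as_trial_table(x)
  dplyr::summarise(dplyr::group_by(x, .data$trait),
                   grand_mean = mean(.data$value, na.rm = TRUE),
                   .groups = "drop")
}

# Accepts either a genotype_means()-style long tibble (genotype, trait, mean)
# or a wide tibble (genotype + one numeric column per trait); returns a
# numeric matrix, genotypes in rows.
means_matrix <- function(m) {
  stopifnot(is.data.frame(m))
  m <- as_tibble(m)
  if (!"genotype" %in% names(m)) abort("means table needs a `genotype` column")
  if (all(c("trait", "mean") %in% names(m))) {
    trait_levels <- if (is.factor(m$trait)) levels(m$trait) else unique(as.character(m$trait))
    wide <- tidyr::pivot_wider(m[, c("genotype", "trait", "mean")],
                               names_from = "trait", values_from = "mean")
    wide <- wide[, c("genotype", trait_levels)]
  } else {
    num <- vapply(m, is.numeric, logical(1))
    num["genotype"] <- FALSE
    keep <- names(m)[num]
    if (length(keep) == 0) abort("means table has no numeric trait columns")
    wide <- m[, c("genotype", keep)]
  }
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- as.character(wide$genotype)
  if (anyNA(mat)) abort("means table contains missing values")
  mat
}
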