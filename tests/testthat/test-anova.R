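test_that("RCBD sums of squares match the brute-force definition and aov", {
  d <- toy_rcbd()
  fit <- rcbd_anova(d, "y")
  td <- tidy(fit)
  oracle <- brute_rcbd_ss(d)
  expect_equal(td$ss[td$term == "genotype"], oracle$genotype, tolerance = 1e-12)
  expect_equal(td$ss[td$term == "block"], oracle$block, tolerance = 1e-12)
  expect_equal(td$ss[td$term == "error"], oracle$error, tolerance = 1e-10)
  expect_equal(td$df, c(2L, 1L, 2L))
  # cross-check against the reference linear-model fit
  a <- summary(aov(value ~ block + genotype, data = d))[[1]]
  expect_equal(td$ss[td$term == "genotype"],
               a[trimws(rownames(a)) == "genotype", "Sum Sq"])
  expect_equal(td$statistic[td$term == "genotype"],
               a[trimws(rownames(a)) == "genotype", "F value"])
  expect_equal(td$p.value[td$term == "genotype"],
               a[trimws(rownames(a)) == "genotype", "Pr(>F)"])
})

test_that("constant data gives zero SS and undefined (NA) F, never 1 or Inf", {
  d <- toy_rcbd()
  d$value <- 5
  td <- tidy(rcbd_anova(d, "y"))
  expect_true(all(td$ss < 1e-20))
  expect_true(all(is.na(td$statistic)))
  expect_true(all(is.na(td$p.value)))
})

test_that("combined ANOVA matches brute force on a 2x2x2 toy", {
  d <- toy_combined()
  fit <- combined_anova(d, "y")
  td <- tidy(fit)
  oracle <- brute_combined_ss(d)
  expect_equal(td$ss, unlist(oracle[c("genotype", "environment", "block",
                                      "ge", "error")]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(td$df), nrow(d) - 1)
})

test_that("combined SS/df decomposition agrees with aov across random layouts", {
  for (case in list(c(3, 2, 2, 11), c(5, 3, 3, 12), c(4, 2, 3, 13))) {
    d <- sim1(g = case[1], e = case[2], r = case[3], seed = case[4],
              var_env = 2, var_ge = 1, var_block = 0.5)
    td <- tidy(combined_anova(d, "trait1"))
    # SS and df additivity
    grand <- mean(d$value)
    expect_equal(sum(td$ss), sum((d$value - grand)^2), tolerance = 1e-8)
    expect_equal(sum(td$df), nrow(d) - 1)
    # independent fit
    a <- summary(aov(value ~ environment + genotype + environment:block +
                       genotype:environment, data = d))[[1]]
    rn <- trimws(rownames(a))
    expect_equal(td$ss[td$term == "genotype"], a[rn == "genotype", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(td$ss[td$term == "genotype_x_environment"],
                 a[rn %in% c("genotype:environment", "environment:genotype"),
                   "Sum Sq"], tolerance = 1e-8)
    expect_equal(td$ss[td$term == "block_in_environment"],
                 a[rn == "environment:block", "Sum Sq"], tolerance = 1e-8)
    expect_equal(td$ss[td$term == "error"], a[rn == "Residuals", "Sum Sq"],
                 tolerance = 1e-8)
  }
})

test_that("relabelling blocks leaves the genotype SS unchanged", {
  d <- sim1(g = 5, e = 2, r = 3, seed = 21, var_block = 2)
  ss_g <- function(x) {
    td <- tidy(combined_anova(x, "trait1"))
    td$ss[td$term == "genotype"]
  }
  ref <- ss_g(d)
  d2 <- d
  d2$block <- factor(c(B1 = "B3", B2 = "B1", B3 = "B2")[as.character(d$block)])
  expect_equal(ss_g(d2), ref, tolerance = 1e-10)
})

test_that("without G-by-E variance the interaction F is centred on 1", {
  fs <- vapply(1:300, function(s) {
    d <- sim1(g = 6, e = 3, r = 2, seed = 5000 + s, var_g = 1, var_ge = 0,
              var_resid = 1)
    td <- tidy(combined_anova(d, "trait1"))
    td$statistic[td$term == "genotype_x_environment"]
  }, numeric(1))
  # E[F] = d2/(d2-2) = 30/28 with d2 = 3*5*1 = 15... pooled df = 15; use a band
  expect_gt(mean(fs), 0.85)
  expect_lt(mean(fs), 1.35)
})

test_that("the interaction denominator option tests genotype against MS_GxE", {
  d <- sim1(g = 6, e = 3, r = 2, seed = 31, var_ge = 2)
  f1 <- combined_anova(d, "trait1")
  f2 <- combined_anova(d, "trait1", genotype_denominator = "interaction")
  t1 <- tidy(f1); t2 <- tidy(f2)
  ms_ge <- t1$ms[t1$term == "genotype_x_environment"]
  expect_equal(t2$statistic[t2$term == "genotype"],
               t1$ms[t1$term == "genotype"] / ms_ge)
  # other rows unchanged
  expect_equal(t2$statistic[t2$term == "environment"],
               t1$statistic[t1$term == "environment"])
})

test_that("single-environment data routed through combined_anova is refused", {
  d <- toy_rcbd()
  expect_error(combined_anova(d, "y"), "rcbd_anova")
  d2 <- toy_combined()
  expect_error(rcbd_anova(d2, "y"), "combined_anova")
})

test_that("unbalanced data are refused unless plot deletion is requested", {
  d <- toy_combined()
  d$value[3] <- NA
  expect_error(combined_anova(d, "y"), "allow_unbalanced")
  fit <- combined_anova(d, "y", allow_unbalanced = TRUE)
  expect_equal(sum(tidy(fit)$df), 6)  # one plot deleted: N-1 = 6
})

test_that("LSD equals the textbook formula and behaves monotonically", {
  d <- toy_rcbd()
  fit <- rcbd_anova(d, "y")
  oracle <- brute_rcbd_ss(d)
  ms_e <- oracle$error / 2
  expect_equal(lsd_value(fit, 0.05), qt(0.975, 2) * sqrt(2 * ms_e / 2))
  expect_equal(lsd_value(fit, 0.05, n_per_mean = 4),
               qt(0.975, 2) * sqrt(2 * ms_e / 4))
  # smaller alpha -> strictly larger LSD
  expect_gt(lsd_value(fit, 0.01), lsd_value(fit, 0.05))
  expect_gt(lsd_value(fit, 0.05), lsd_value(fit, 0.5))
  expect_error(lsd_value(fit, 1.2), "alpha")
})

test_that("LSD approaches the normal limit for large error df", {
  fit <- gentrial:::build_anova(
    terms = c("genotype", "block", "error"),
    df = c(3L, 3L, 100000L), ss = c(10, 1, 2 * 100000),
    trait = "y", layout = "rcbd", environment = "E1", grand_mean = 20,
    g = 4, e = 1L, r = 4, n_per_mean = 4, f_num = c("genotype", "block")
  )
  # MS_E = 2, n = 4 -> sqrt(2*2/4) = 1, so LSD -> 1.96
  expect_equal(lsd_value(fit, 0.05), 1.96, tolerance = 1e-3)
})

test_that("CV follows 100*sqrt(MS_E)/mean", {
  d <- toy_rcbd()
  fit <- rcbd_anova(d, "y")
  oracle <- brute_rcbd_ss(d)
  expect_equal(cv_percent(fit), 100 * sqrt(oracle$error / 2) / mean(d$value))
  expect_equal(cv_percent(fit, grand_mean = 20), 100 * sqrt(oracle$error / 2) / 20)
  d0 <- d; d0$value <- c(-1, 1, -2, 2, 3, -3)  # grand mean exactly zero
  expect_error(cv_percent(rcbd_anova(d0, "y")), "nonzero")
})

test_that("letter groups implement the shared-letter-iff-within-LSD rule", {
  expect_equal(letter_groups(c(A = 10, B = 10, C = 20), lsd = 1),
               c(A = "b", B = "b", C = "a"))
  # all within one LSD: a single shared letter
  expect_equal(unique(letter_groups(c(a = 1, b = 1.2, c = 0.9), lsd = 0.5)), "a")
  # property: share a letter <=> |difference| <= lsd
  set.seed(8)
  for (rep in 1:25) {
    m <- setNames(round(rnorm(8, sd = 2), 2), paste0("g", 1:8))
    lsd <- runif(1, 0.2, 3)
    gr <- letter_groups(m, lsd)
    for (i in 1:7) for (j in (i + 1):8) {
      shares <- length(intersect(strsplit(gr[[i]], "")[[1]],
                                 strsplit(gr[[j]], "")[[1]])) > 0
      expect_equal(shares, unname(abs(m[i] - m[j]) <= lsd),
                   label = sprintf("pair %d-%d lsd=%.2f", i, j, lsd))
    }
  }
})

test_that("top grain-yield genotypes share the leading letter at the published LSD", {
  gwt <- cowpea_means() |> dplyr::filter(trait == "GWT")
  lsd <- cowpea_trait_summary()$lsd_05[cowpea_trait_summary()$trait == "GWT"]
  gr <- letter_groups(setNames(gwt$mean, as.character(gwt$genotype)), lsd)
  expect_true(grepl("a", gr[["SARI-3-11-100"]]))  # 1.99 t/ha
  expect_true(grepl("a", gr[["SARVX-09-004"]]))   # 1.95 t/ha
  # the check cultivar (1.68) must not share the top letter
  expect_false(grepl("a", gr[["Songotra"]]))
})

test_that("mean separation assembles means, letters, LSD and CV per trait", {
  d <- simulate_multitrait(
    trial_design(8, 2, 3, seed = 17),
    multitrait_spec(list(y1 = variance_spec(50, var_g = 25, var_resid = 4),
                         y2 = variance_spec(10, var_g = 1, var_resid = 0.5)))
  )
  ms <- mean_separation(d)
  expect_s3_class(ms, "mean_separation")
  expect_equal(nrow(ms), 16)
  st <- glance(ms)
  expect_equal(st$trait, c("y1", "y2"))
  expect_true(all(st$lsd > 0))
  expect_true(all(st$cv >= 0))
  # letters consistent with the LSD rule within each trait
  y1 <- ms[ms$trait == "y1", ]
  lsd <- st$lsd[st$trait == "y1"]
  expect_equal(unname(letter_groups(setNames(y1$mean, as.character(y1$genotype)), lsd)),
               y1$group)
})
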