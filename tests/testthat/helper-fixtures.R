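# small hand-listed toys reused across tests

# 3 genotypes x 2 blocks, one environment
toy_rcbd <- function() {
  tibble::tibble(
    genotype = rep(c("A", "B", "C"), each = 2),
    environment = "E1",
    block = rep(c("B1", "B2"), times = 3),
    trait = "y",
    value = c(10, 12, 15, 14, 20, 23)
  )
}

# 2 genotypes x 2 environments x 2 blocks
toy_combined <- function() {
  tibble::tibble(
    genotype = rep(c("A", "B"), each = 4),
    environment = rep(rep(c("E1", "E2"), each = 2), times = 2),
    block = rep(c("B1", "B2"), times = 4),
    trait = "y",
    value = c(10, 11, 14, 13, 17, 19, 16, 18)
  )
}

# quick single-trait simulation shorthand
sim1 <- function(g, e, r, seed, mu = 40, var_g = 9, var_resid = 3, ...) {
  gentrial::simulate_trial(
    gentrial::trial_design(g, e, r, seed = seed),
    gentrial::variance_spec(mu = mu, var_g = var_g, var_resid = var_resid, ...)
  )
}
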