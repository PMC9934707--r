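# Cohort simulator: genotype sampling, causal-diagram phenotypes, recall
# discretisation and two-sample study construction.

test_that("dosages follow binomial(2, f) sampling and are reproducible", {
  cfg <- sim_config(seed = 11, n_variants_child_specific = 1,
                    n_variants_adult_specific = 0, n_variants_shared = 0,
                    maf_range = c(0.5, 0.5))
  g <- simulate_genotypes(cfg, 4)
  expect_true(all(g$dosage %in% c(0, 1, 2)))
  expect_equal(g$variants$eaf, 0.5)

  g2 <- simulate_genotypes(cfg, 4)
  expect_identical(g$dosage, g2$dosage)

  cfg3 <- sim_config(seed = 12, n_variants_child_specific = 1000,
                     n_variants_adult_specific = 0, n_variants_shared = 0,
                     maf_range = c(0.05, 0.5))
  g3 <- simulate_genotypes(cfg3, 2000)
  f_hat <- colMeans(g3$dosage) / 2
  f_true <- g3$variants$eaf
  se <- sqrt(f_true * (1 - f_true) / (2 * 2000))
  within4 <- mean(abs(f_hat - f_true) <= 4 * se)
  expect_gte(within4, 0.99)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(seed = 1, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(seed = 1, binary_prevalence = 1), "binary_prevalence")
  expect_error(sim_config(seed = 1, n_exposure_cohort = 0), "n_exposure_cohort")
  expect_error(sim_config(seed = 1, recall_proportions = c(0.5, 0.5, 0.1)),
               "recall_proportions")
  expect_error(sim_config(), "seed")
  # partition mismatch between config and genotypes
  g <- simulate_genotypes(sim_config(seed = 2), 50)
  cfg_other <- sim_config(seed = 2, n_variants_shared = 10)
  expect_error(simulate_phenotypes(g, cfg_other), "partition")
})

test_that("null configuration yields uncorrelated standard-normal traits", {
  cfg <- sim_config(seed = 21, effect_sd_child = 0, effect_sd_adult = 0,
                    gamma_child_to_adult = 0, delta_child_direct = 0,
                    delta_adult_direct = 0, confounder_strength = 0,
                    n_exposure_cohort = 8000)
  g <- simulate_genotypes(cfg, 8000)
  ph <- simulate_phenotypes(g, cfg)
  for (v in c("child_bmi_true", "adult_bmi", "outcome")) {
    expect_lt(abs(mean(ph[[v]])), 0.05)
    expect_lt(abs(sd(ph[[v]]) - 1), 0.04)
  }
  # only the tiny fixed sex/age nuisance couples the traits
  expect_lt(abs(cor(ph$child_bmi_true, ph$adult_bmi)), 0.04)
  expect_lt(abs(cor(ph$child_bmi_true, ph$outcome)), 0.04)
  expect_lt(abs(cor(ph$adult_bmi, ph$outcome)), 0.04)
})

test_that("population regression of outcome on child equals the path product", {
  # no direct child effect, no shared variants, no confounding:
  # slope(outcome ~ child) = gamma * delta_adult = 0.2
  cfg <- sim_config(seed = 31, n_variants_shared = 0,
                    gamma_child_to_adult = 0.5, delta_child_direct = 0,
                    delta_adult_direct = 0.4, confounder_strength = 0,
                    n_exposure_cohort = 50000)
  g <- simulate_genotypes(cfg, 50000)
  ph <- simulate_phenotypes(g, cfg)
  fit <- lm(outcome ~ child_bmi_true, data = ph)
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 0.2), 3 * se)
})

test_that("trait scales are standardised to unit variance", {
  cfg <- sim_config(seed = 41, n_exposure_cohort = 12000)
  g <- simulate_genotypes(cfg, 12000)
  ph <- simulate_phenotypes(g, cfg)
  for (v in c("child_bmi_true", "adult_bmi", "outcome"))
    expect_lt(abs(sd(ph[[v]]) - 1), 0.02)
})

test_that("directional pleiotropy shifts per-variant outcome effects", {
  cfg <- sim_config(seed = 51, n_variants_child_specific = 0,
                    n_variants_adult_specific = 0, n_variants_shared = 60,
                    effect_sd_child = 0.05, effect_sd_adult = 0.05,
                    gamma_child_to_adult = 0, delta_child_direct = 0,
                    delta_adult_direct = 0, confounder_strength = 0,
                    pleiotropy_mean = 0.05, pleiotropy_sd = 0,
                    n_exposure_cohort = 40000)
  g <- simulate_genotypes(cfg, 40000)
  ph <- simulate_phenotypes(g, cfg)
  gw <- run_gwas(g, ph$outcome)
  # with all paths zero, the only variant-outcome effect is the injected
  # constant pleiotropy of 0.05 per allele
  expect_lt(abs(mean(gw$BETA) - 0.05), 0.01)
})

test_that("binary outcomes hit the configured prevalence", {
  cfg <- sim_config(seed = 61, outcome_kind = "binary",
                    binary_prevalence = 0.12, n_exposure_cohort = 10000)
  g <- simulate_genotypes(cfg, 10000)
  ph <- simulate_phenotypes(g, cfg)
  expect_true(all(ph$outcome %in% c(0, 1)))
  expect_lt(abs(mean(ph$outcome) - 0.12), 0.02)
})

test_that("recall discretisation respects proportions, order and ties", {
  expect_identical(discretize_recall(c(-2, 0, 2), rep(1, 3) / 3),
                   c("thinner", "same", "plumper"))
  # constant input collapses into one category (value-based tie policy)
  expect_length(unique(discretize_recall(rep(1.3, 10), c(0.3, 0.4, 0.3))), 1L)
  expect_error(discretize_recall(rnorm(5), c(0.4, 0.4, 0.4)), "sum")

  set.seed(71)
  x <- rnorm(10000)
  props <- c(0.32, 0.51, 0.17)
  cat <- discretize_recall(x, props)
  sizes <- table(factor(cat, levels = c("thinner", "same", "plumper")))
  expect_equal(as.numeric(sizes) / 10000, props, tolerance = 1e-3)
  # monotone: no thinner value above any plumper value
  expect_lte(max(x[cat == "thinner"]), min(x[cat == "plumper"]))
  # empirical-quantile cutting agrees with the theoretical quantile cut up
  # to cutpoint sampling noise...
  q <- qnorm(cumsum(props)[1:2])
  theo <- ifelse(x <= q[1], "thinner", ifelse(x <= q[2], "same", "plumper"))
  expect_lt(mean(cat != theo), 0.02)
  # ...and stratum means match truncated-normal moments (theoretical cut
  # removes the shared cutpoint-noise component the per-stratum SE bound
  # does not cover)
  bounds <- list(thinner = c(-Inf, q[1]), same = c(q[1], q[2]),
                 plumper = c(q[2], Inf))
  for (lab in names(bounds)) {
    o <- oracle_truncnorm(0, 1, bounds[[lab]][1], bounds[[lab]][2])
    n_k <- sum(theo == lab)
    expect_lt(abs(mean(x[theo == lab]) - o$mean), 3 * o$sd / sqrt(n_k))
  }
})

test_that("two-sample studies share variants but not individuals", {
  cfg <- sim_config(seed = 81, n_exposure_cohort = 300,
                    n_outcome_cohort = 200)
  st <- make_two_sample_studies(cfg)
  expect_length(intersect(st$exposure$genotypes$ids,
                          st$outcome$genotypes$ids), 0L)
  expect_identical(st$exposure$genotypes$variants$id,
                   st$outcome$genotypes$variants$id)
  st2 <- make_two_sample_studies(cfg)
  expect_identical(st$exposure$genotypes$dosage,
                   st2$exposure$genotypes$dosage)
  expect_identical(st$outcome$phenotypes, st2$outcome$phenotypes)
})

test_that("null-effect exposure and outcome GWAS effects are uncorrelated", {
  cfg <- sim_config(seed = 91, effect_sd_child = 0, effect_sd_adult = 0,
                    delta_child_direct = 0, delta_adult_direct = 0,
                    confounder_strength = 0,
                    n_exposure_cohort = 2000, n_outcome_cohort = 2000)
  st <- make_two_sample_studies(cfg)
  be <- run_gwas(st$exposure$genotypes,
                 st$exposure$phenotypes$child_bmi_true)$BETA
  bo <- run_gwas(st$outcome$genotypes, st$outcome$phenotypes$outcome)$BETA
  expect_lt(abs(cor(be, bo)), 3 / sqrt(length(be)))
})

test_that("LD panels carry correlated blocks and ordered positions", {
  p <- simulate_ld_panel(n_blocks = 6, block_size = 4, n_individuals = 800,
                         switch_prob = 0.05, seed = 5)
  expect_true(all(diff(p$variants$pos) > 0))
  # adjacent variants within a block are strongly correlated
  r2_within <- ld_r2(p, "ld1", "ld2")
  expect_gt(r2_within, 0.5)
  # variants from different blocks are not
  r2_across <- ld_r2(p, "ld1", "ld24")
  expect_lt(r2_across, 0.05)
})
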