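# Harmonisation, proxy lookup, and the MR estimators.

test_that("allele harmonisation keeps, flips and drops correctly", {
  exp_ss <- make_ss(c("a", "b", "c", "d"),
                    ea = c("A", "A", "A", "A"),
                    oa = c("G", "G", "T", "T"),
                    eaf = c(0.3, 0.3, 0.10, 0.50),
                    beta = c(0.1, 0.1, 0.1, 0.1))
  out_ss <- make_ss(c("a", "b", "c", "d"),
                    ea = c("A", "G", "A", "A"),
                    oa = c("G", "A", "T", "T"),
                    eaf = c(0.3, 0.7, 0.12, 0.48),
                    beta = c(0.05, -0.2, 0.07, 0.02),
                    trait = "y")
  h <- harmonise(exp_ss, out_ss)
  # direct match kept as-is
  expect_equal(h$beta_out[h$SNP == "a"], 0.05)
  # swapped alleles: outcome effect re-oriented
  expect_equal(h$beta_out[h$SNP == "b"], 0.2)
  # palindromic with clear frequencies on the same side: kept
  expect_equal(h$beta_out[h$SNP == "c"], 0.07)
  # palindromic inside the ambiguity zone: dropped
  expect_false("d" %in% h$SNP)
  drops <- attr(h, "drops")
  expect_equal(drops$reason[drops$SNP == "d"], "ambiguous")

  # palindromic with clear frequencies on opposite sides: flipped
  out2 <- make_ss("c", ea = "A", oa = "T", eaf = 0.88, beta = 0.07,
                  trait = "y")
  exp2 <- make_ss("c", ea = "A", oa = "T", eaf = 0.10, beta = 0.1)
  h2 <- harmonise(exp2, out2)
  expect_equal(h2$beta_out, -0.07)

  # empty post-harmonisation set errors
  out3 <- make_ss("zzz", ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                  trait = "y")
  expect_error(harmonise(exp_ss, out3), "no variants")
})

test_that("proxy lookup enforces the correlation and distance rules", {
  panel <- simulate_ld_panel(n_blocks = 4, block_size = 3,
                             n_individuals = 2000, switch_prob = 0.02,
                             span_bp = 2e5, seed = 13)
  v <- panel$variants
  # outcome table holds every panel variant except the first
  out_ss <- make_ss(v$id[-1], ea = v$ea[-1], oa = v$oa[-1],
                    eaf = v$eaf[-1], beta = rnorm(nrow(v) - 1, 0, 0.02),
                    bp = v$pos[-1], trait = "y")
  pr <- find_proxy(v$id[1], out_ss, panel)
  expect_false(is.null(pr))
  expect_equal(as.character(pr), "ld2")  # same-block neighbour
  expect_gt(attr(pr, "r2"), 0.8)

  # high-r2 candidate beyond the window is refused
  pr_far <- find_proxy(v$id[1], out_ss, panel, window = 10)
  expect_null(pr_far)
  # insufficient correlation is refused
  pr_weak <- find_proxy(v$id[1], out_ss, panel, r2_min = 0.9999)
  expect_null(pr_weak)
  expect_error(find_proxy("nope", out_ss, panel), "absent from panel")

  sub <- proxy_substitute(v$id[1], out_ss, panel)
  expect_equal(unname(sub$map[v$id[1]]), "ld2")
  expect_true(v$id[1] %in% sub$outcome$SNP)
})

test_that("IVW reduces to the Wald ratio and matches the WLS oracle", {
  h1 <- make_hset(bx = 0.5, se_x = 0.01, by = 0.1, se_y = 0.05)
  f1 <- mr_fit(h1, "ivw")
  expect_equal(f1$results$method, "wald_ratio")
  expect_equal(f1$results$estimate, 0.2, tolerance = 1e-12)
  expect_equal(f1$results$se, 0.1, tolerance = 1e-12)

  h0 <- make_hset(bx = c(0.2, 0.3), se_x = 0.01, by = c(0, 0), se_y = 0.02)
  expect_equal(mr_fit(h0, "ivw")$results$estimate, 0)
  expect_error(mr_fit(make_hset(c(0, 0), 0.01, c(0.1, 0.2), 0.02), "ivw"),
               "non-identified")

  set.seed(14)
  for (rep in 1:5) {
    k <- sample(5:40, 1)
    bx <- rnorm(k, 0, 0.1); by <- 0.25 * bx + rnorm(k, 0, 0.02)
    sey <- runif(k, 0.01, 0.05)
    h <- make_hset(bx, 0.01, by, sey)
    o <- oracle_wls_origin(bx, by, 1 / sey^2)
    f <- mr_fit(h, "ivw")$results
    expect_equal(f$estimate, o$est, tolerance = 1e-10)
    expect_equal(f$se, o$se, tolerance = 1e-10)
  }
})

test_that("IVW and MVMR are invariant to per-variant allele sign flips", {
  set.seed(15)
  k <- 20
  bx <- rnorm(k, 0, 0.1); bx2 <- rnorm(k, 0, 0.1)
  by <- 0.3 * bx + 0.2 * bx2 + rnorm(k, 0, 0.02)
  flip <- sample(c(-1, 1), k, replace = TRUE)
  h <- make_hset(bx, 0.01, by, 0.02, bx2 = bx2)
  hf <- make_hset(flip * bx, 0.01, flip * by, 0.02, bx2 = flip * bx2)
  expect_equal(mr_fit(h, "ivw")$results$estimate,
               mr_fit(hf, "ivw")$results$estimate, tolerance = 1e-12)
  expect_equal(mr_fit(h, "mvmr")$results$estimate,
               mr_fit(hf, "mvmr")$results$estimate, tolerance = 1e-12)
})

test_that("Egger recovers exact slopes and intercepts and needs 3 variants", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h_exact <- make_hset(bx, 0.01, 0.3 * bx, 0.02)
  r <- mr_fit(h_exact, "egger")$results
  expect_equal(r$estimate[r$method == "egger"], 0.3, tolerance = 1e-12)
  expect_equal(r$estimate[r$method == "egger_intercept"], 0,
               tolerance = 1e-12)

  h_pleio <- make_hset(bx, 0.01, 0.3 * bx + 0.05, 0.02)
  r2 <- mr_fit(h_pleio, "egger")$results
  expect_equal(r2$estimate[r2$method == "egger_intercept"], 0.05,
               tolerance = 1e-12)

  expect_error(mr_fit(make_hset(c(0.1, 0.2), 0.01, c(0, 0), 0.02), "egger"),
               "3 instruments")

  # matches the weighted-with-intercept oracle on noisy data
  set.seed(16)
  bx <- abs(rnorm(30, 0, 0.1)); by <- 0.2 * bx + rnorm(30, 0, 0.03)
  sey <- runif(30, 0.01, 0.04)
  o <- oracle_wls_intercept(bx, by, 1 / sey^2)
  r3 <- mr_fit(make_hset(bx, 0.01, by, sey), "egger")$results
  expect_equal(r3$estimate[r3$method == "egger"], o$slope,
               tolerance = 1e-10)
  expect_equal(r3$se[r3$method == "egger"], o$se_slope, tolerance = 1e-10)
  expect_equal(r3$estimate[r3$method == "egger_intercept"], o$intercept,
               tolerance = 1e-10)
})

test_that("MVMR matches the normal-equations oracle and reduces to IVW", {
  set.seed(17)
  k <- 50
  bx1 <- rnorm(k, 0, 0.1)
  bx2 <- 0.5 * bx1 + rnorm(k, 0, 0.08)   # correlated exposure effects
  by <- 0.1 * bx1 + 0.4 * bx2 + rnorm(k, 0, 0.02)
  sey <- runif(k, 0.01, 0.05)
  h <- make_hset(bx1, 0.01, by, sey, bx2 = bx2)
  o <- oracle_wls_multi(cbind(bx1, bx2), by, 1 / sey^2)
  r <- mr_fit(h, "mvmr")$results
  expect_equal(r$estimate, unname(o$est), tolerance = 1e-10)
  expect_equal(r$se, unname(o$se), tolerance = 1e-10)

  # exact noiseless coefficients
  by_ex <- 0 * bx1 + 0.4 * bx2
  r_ex <- mr_fit(make_hset(bx1, 0.01, by_ex, 0.02, bx2 = bx2),
                 "mvmr")$results
  expect_equal(r_ex$estimate, c(0, 0.4), tolerance = 1e-10)

  # secondary exposure all zero: primary coefficient equals univariable IVW
  h0 <- make_hset(bx1, 0.01, by, sey, bx2 = rep(0, k))
  r0 <- mr_fit(h0, "mvmr")$results
  ivw <- mr_fit(make_hset(bx1, 0.01, by, sey), "ivw")$results
  expect_equal(r0$estimate[1], ivw$estimate, tolerance = 1e-10)
  expect_true(is.na(r0$estimate[2]))

  # collinear exposure effects are refused
  h_col <- make_hset(bx1, 0.01, by, sey, bx2 = 2 * bx1)
  expect_error(mr_fit(h_col, "mvmr"), "collinear")
})

test_that("Steiger filtering matches per-variant variance recomputation", {
  h <- make_hset(bx = c(0.05, 0.02, 0.04), se_x = 0.01,
                 by = c(0.02, 0.05, 0.04), se_y = 0.02,
                 eaf = c(0.3, 0.3, 0.2))
  out <- steiger_filter(h)
  expect_setequal(out$SNP, c("v1", "v3"))
  exc <- attr(out, "steiger_excluded")
  expect_equal(exc$SNP, "v2")
  expect_equal(exc$var_exposure, 2 * 0.02^2 * 0.3 * 0.7, tolerance = 1e-12)
  expect_equal(exc$var_outcome, 2 * 0.05^2 * 0.3 * 0.7, tolerance = 1e-12)

  # mixed toy set against brute-force recomputation
  set.seed(18)
  k <- 10
  bx <- rnorm(k, 0, 0.05); by <- rnorm(k, 0, 0.05)
  eaf <- runif(k, 0.05, 0.95)
  hm <- make_hset(bx, 0.01, by, 0.02, eaf = eaf)
  keep_oracle <- hm$SNP[
    vapply(seq_len(k), function(j) {
      maf <- min(eaf[j], 1 - eaf[j])
      2 * bx[j]^2 * maf * (1 - maf) >= 2 * by[j]^2 * maf * (1 - maf)
    }, logical(1))]
  expect_identical(steiger_filter(hm)$SNP, keep_oracle)
  expect_lte(nrow(steiger_filter(hm)), nrow(hm))
  expect_warning(steiger_filter(make_hset(0.01, 0.01, 0.5, 0.02)),
                 "every instrument")
})

test_that("mr_fit objects support the standard S3 methods", {
  set.seed(19)
  bx <- rnorm(10, 0, 0.1); by <- 0.3 * bx + rnorm(10, 0, 0.02)
  f <- mr_fit(make_hset(bx, 0.01, by, 0.02), "ivw")
  expect_output(print(f), "ivw")
  expect_named(coef(f), "ivw:x1")
  ci <- confint(f)
  expect_equal(unname(ci[1, ]),
               c(f$results$estimate - qnorm(0.975) * f$results$se,
                 f$results$estimate + qnorm(0.975) * f$results$se),
               tolerance = 1e-10)
  pdf(NULL)
  expect_silent(plot(f))
  dev.off()
  expect_output(summary(f), "ivw")
})
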