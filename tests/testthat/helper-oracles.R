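# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different computational routes (explicit normal
# equations, plain double loops, closed forms) than the package internals.

# Weighted least squares through the origin, one predictor.
oracle_wls_origin <- function(bx, by, w) {
  X <- matrix(bx, ncol = 1)
  XtWX <- t(X) %*% (w * X)
  est <- solve(XtWX, t(X) %*% (w * by))[1, 1]
  list(est = est, se = sqrt(solve(XtWX)[1, 1]))
}

# Weighted least squares with intercept (Egger oracle), t-based SEs.
oracle_wls_intercept <- function(bx, by, w) {
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  est <- solve(XtWX, t(X) %*% (w * by))[, 1]
  resid <- by - X %*% est
  sigma2 <- sum(w * resid^2) / (length(by) - 2)
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  list(intercept = unname(est[1]), slope = unname(est[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]))
}

# Multivariable WLS through the origin (normal equations).
oracle_wls_multi <- function(X, by, w) {
  XtWX <- t(X) %*% (w * X)
  est <- solve(XtWX, t(X) %*% (w * by))[, 1]
  list(est = est, se = sqrt(diag(solve(XtWX))))
}

# Independent greedy-clumping reference: plain loops, cor() per pair,
# same rule set (strict < window distance, r2 within 1 Mb radius else 0,
# ties in p broken by chr/pos/id).
oracle_clump <- function(stats_df, panel, p_thresh, r2_thresh, window) {
  df <- as.data.frame(stats_df)
  df <- df[order(df$P, df$CHR, df$BP, df$SNP), ]
  assigned <- setNames(rep(FALSE, nrow(df)), df$SNP)
  indices <- character(0)
  for (i in seq_len(nrow(df))) {
    s <- df$SNP[i]
    if (assigned[s] || is.na(df$P[i]) || df$P[i] > p_thresh) next
    assigned[s] <- TRUE
    indices <- c(indices, s)
    for (j in seq_len(nrow(df))) {
      t <- df$SNP[j]
      if (assigned[t] || df$CHR[j] != df$CHR[i]) next
      d <- abs(df$BP[j] - df$BP[i])
      r2 <- 0
      if (d <= 1e6) {
        a <- panel$dosage[, s]; b <- panel$dosage[, t]
        if (var(a) > 0 && var(b) > 0) r2 <- cor(a, b)^2
      }
      if (d < window || r2 > r2_thresh) assigned[t] <- TRUE
    }
  }
  indices
}

# Closed-form truncated-normal moments on (a, b) for N(mu, sigma).
oracle_truncnorm <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  m <- mu + sigma * (dnorm(al) - dnorm(be)) / Z
  t1 <- if (is.finite(al)) al * dnorm(al) else 0
  t2 <- if (is.finite(be)) be * dnorm(be) else 0
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((dnorm(al) - dnorm(be)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Build a harmonised_set directly from effect vectors (bypasses GWAS and
# harmonisation; for estimator-level tests).
make_hset <- function(bx, se_x, by, se_y, eaf = NULL, bx2 = NULL,
                      se_x2 = NULL, n_exp = 10000, n_out = 10000,
                      outcome_kind = "quantitative") {
  k <- length(bx)
  if (is.null(eaf)) eaf <- rep(0.3, k)
  h <- data.frame(
    SNP = paste0("v", seq_len(k)), EA = "A", OA = "G", EAF = eaf,
    beta_exp = bx, se_exp = se_x, beta_out = by, se_out = se_y,
    n_exp = n_exp, n_out = n_out, proxy = NA_character_,
    stringsAsFactors = FALSE
  )
  exposures <- "x1"
  if (!is.null(bx2)) {
    h$beta_exp2 <- bx2
    h$se_exp2 <- if (is.null(se_x2)) se_x else se_x2
    h$n_exp2 <- n_exp
    exposures <- c("x1", "x2")
  }
  structure(h, exposures = exposures, outcome = "y",
            outcome_kind = outcome_kind,
            drops = data.frame(SNP = character(0), reason = character(0)),
            class = c("harmonised_set", "data.frame"))
}

# Minimal sumstats builder for harmonisation tests.
make_ss <- function(snp, ea, oa, eaf, beta, se = 0.02, chr = 1,
                    bp = seq_along(snp) * 1e5, p = NULL, n = 10000,
                    trait = "t", kind = "quantitative") {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  sumstats(data.frame(SNP = snp, CHR = chr, BP = bp, EA = ea, OA = oa,
                      EAF = eaf, BETA = beta, SE = se, P = p, N = n,
                      stringsAsFactors = FALSE),
           trait = trait, kind = kind)
}

# Summary-statistic two-sample study generator for estimator Monte-Carlo:
# true standardised exposure effects theta, causal slope, optional constant
# pleiotropy on the outcome side. With `oriented = TRUE` the variants come
# pre-oriented to the exposure-increasing allele (all theta > 0), the
# setting in which a constant pleiotropic offset is directional.
sim_summary_study <- function(k, theta_sd = 0.08, slope = 0.3,
                              pleiotropy = 0, se_x = 0.01, se_y = 0.01,
                              oriented = FALSE) {
  theta <- if (oriented) runif(k, 0.05, 0.2) else rnorm(k, 0, theta_sd)
  bx <- theta + rnorm(k, 0, se_x)
  by <- slope * theta + pleiotropy + rnorm(k, 0, se_y)
  make_hset(bx, rep(se_x, k), by, rep(se_y, k))
}

# Acceptance-scenario configuration: the causal-diagram parameter-recovery
# study (no direct childhood effect, child-to-adult path 0.5, adulthood
# direct effect 0.6, strong instruments).
recovery_config <- function(seed, n = 20000) {
  sim_config(
    n_variants_child_specific = 75, n_variants_adult_specific = 75,
    n_variants_shared = 0, effect_sd_child = 0.14, effect_sd_adult = 0.14,
    gamma_child_to_adult = 0.5, delta_child_direct = 0,
    delta_adult_direct = 0.6, confounder_strength = 0.2,
    n_exposure_cohort = n, n_outcome_cohort = n, seed = seed)
}

# One parameter-recovery replicate: individual-level two-sample study,
# GWAS of both exposures and the outcome, univariable childhood IVW on the
# child-specific panel and MVMR on the full panel.
recovery_replicate <- function(seed, n = 20000) {
  cfg <- recovery_config(seed, n)
  st <- make_two_sample_studies(cfg)
  g <- st$exposure$genotypes
  child_ids <- g$variants$id[g$variants$class == "child"]
  gw_c <- run_gwas(g, st$exposure$phenotypes$child_bmi_true, trait = "child")
  gw_a <- run_gwas(g, st$exposure$phenotypes$adult_bmi, trait = "adult")
  gw_o <- run_gwas(st$outcome$genotypes, st$outcome$phenotypes$outcome,
                   trait = "outcome")
  gw_cc <- sumstats(as.data.frame(gw_c[gw_c$SNP %in% child_ids, ]), "child")
  uni <- mr_fit(harmonise(gw_cc, gw_o), "ivw", se_method = "jackknife")$results
  mv <- mr_fit(harmonise(gw_c, gw_o, exposure2 = gw_a), "mvmr",
               se_method = "jackknife")$results
  c(ivw = uni$estimate, ivw_se = uni$se,
    mv_child = mv$estimate[1], mv_child_se = mv$se[1],
    mv_adult = mv$estimate[2], mv_adult_se = mv$se[2])
}
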