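# Association testing, QC filtering, LD and clumping.

test_that("quantitative GWAS matches the closed-form OLS oracle", {
  cfg <- sim_config(seed = 201, n_variants_child_specific = 8,
                    n_variants_adult_specific = 0, n_variants_shared = 0)
  g <- simulate_genotypes(cfg, 400)
  set.seed(1)
  y <- rnorm(400) + 0.2 * g$dosage[, 3]
  gw <- run_gwas(g, y)
  for (j in c(1, 3, 8)) {
    fit <- summary(lm(y ~ g$dosage[, j]))
    expect_equal(gw$BETA[j], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(gw$SE[j], fit$coefficients[2, 2], tolerance = 1e-10)
    expect_equal(gw$P[j], fit$coefficients[2, 4], tolerance = 1e-10)
  }
  expect_equal(gw$EAF, unname(colMeans(g$dosage)) / 2)
})

test_that("noiseless phenotype recovers the planted effect exactly", {
  cfg <- sim_config(seed = 211, n_variants_child_specific = 5,
                    n_variants_adult_specific = 0, n_variants_shared = 0)
  g <- simulate_genotypes(cfg, 200)
  y <- 0.3 * g$dosage[, 2]
  gw <- run_gwas(g, y)
  expect_equal(gw$BETA[2], 0.3, tolerance = 1e-10)
  expect_lt(gw$P[2], 1e-100)
})

test_that("GWAS type-I error and p-value uniformity hold under the null", {
  cfg <- sim_config(seed = 221, n_variants_child_specific = 1000,
                    n_variants_adult_specific = 0, n_variants_shared = 0)
  g <- simulate_genotypes(cfg, 500)
  set.seed(2)
  y <- rnorm(500)
  gw <- run_gwas(g, y)
  frac <- mean(gw$P < 0.05)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
  expect_gt(ks.test(gw$P, "punif")$p.value, 0.01)
})

test_that("covariate residualisation removes nuisance signal", {
  cfg <- sim_config(seed = 231, n_variants_child_specific = 10,
                    n_variants_adult_specific = 0, n_variants_shared = 0)
  g <- simulate_genotypes(cfg, 800)
  set.seed(3)
  covs <- data.frame(sex = rbinom(800, 1, 0.5), age = runif(800, 40, 70))
  y <- 2 * covs$sex + 0.1 * covs$age + rnorm(800)
  gw <- run_gwas(g, y, covariates = covs)
  # residualised phenotype carries no genetic signal: calibrated nulls
  expect_gt(min(gw$P), 1e-4)
})

test_that("monomorphic variants are flagged and binary GWAS matches glm", {
  v <- data.frame(id = c("a", "b"), chr = 1L, pos = c(100L, 200L),
                  ea = "A", oa = "G", eaf = c(0.3, 0.5))
  set.seed(4)
  d <- cbind(rep(0, 300), rbinom(300, 2, 0.4))
  g <- genotype_matrix(paste0("i", 1:300), v, d)
  y <- rbinom(300, 1, plogis(-1 + 0.5 * d[, 2]))
  gw <- run_gwas(g, y, kind = "binary")
  expect_false(gw$OK[1])
  expect_equal(gw$SE[1], Inf)
  fit <- summary(glm(y ~ d[, 2], family = binomial()))
  expect_equal(gw$BETA[2], fit$coefficients[2, 1], tolerance = 1e-8)
  expect_equal(gw$P[2], fit$coefficients[2, 4], tolerance = 1e-8)
})

test_that("QC filtering applies the MAF and INFO rules and is idempotent", {
  df <- data.frame(SNP = paste0("s", 1:5), CHR = 1L, BP = 1:5 * 1000L,
                   EA = "A", OA = "G",
                   EAF = c(0.005, 0.5, 0.996, 0.3, 0.2),
                   BETA = 0.1, SE = 0.02, P = 0.5, N = 1000L,
                   INFO = c(1, 0.79, 1, 0.81, NA))
  ss <- sumstats(df, "t")
  out <- qc_filter(ss)
  expect_setequal(out$SNP, c("s4", "s5"))
  removed <- attr(out, "removed")
  expect_equal(unname(removed["maf"]), 2L)
  expect_equal(unname(removed["info"]), 1L)

  again <- qc_filter(out)
  expect_identical(again$SNP, out$SNP)
  expect_equal(sum(attr(again, "removed")), 0L)
  empty <- qc_filter(ss[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("LD r2 behaves at the edges and under independence", {
  p <- simulate_ld_panel(n_blocks = 2, block_size = 2, n_individuals = 5000,
                         switch_prob = 0.5, seed = 6)
  expect_equal(ld_r2(p, "ld1", "ld1"), 1.0)
  # duplicated dosage column
  v <- p$variants[1:2, ]
  dup <- genotype_matrix(p$ids, v, cbind(p$dosage[, 1], p$dosage[, 1]))
  expect_equal(ld_r2(dup, v$id[1], v$id[2]), 1.0)
  # independent blocks at n = 5000
  expect_lt(ld_r2(p, "ld2", "ld3"), 0.01)
  mono <- genotype_matrix(p$ids, v, cbind(p$dosage[, 1], rep(1, 5000)))
  expect_error(ld_r2(mono, v$id[1], v$id[2]), "monomorphic")
})

clump_stats <- function(panel, p) {
  v <- panel$variants
  sumstats(data.frame(SNP = v$id, CHR = v$chr, BP = v$pos, EA = v$ea,
                      OA = v$oa, EAF = v$eaf, BETA = 0.1, SE = 0.02,
                      P = p, N = 1000L, stringsAsFactors = FALSE), "t")
}

test_that("clumping removes correlated and nearby signals", {
  # two perfectly correlated variants 300 kb apart: r2 rule dominates
  set.seed(7)
  d <- rbinom(500, 2, 0.3)
  v <- data.frame(id = c("v1", "v2"), chr = 1L, pos = c(1e6L, 1.3e6L),
                  ea = "A", oa = "G", eaf = mean(d) / 2)
  panel <- genotype_matrix(paste0("i", 1:500), v, cbind(d, d))
  st <- clump_stats(panel, c(1e-10, 1e-9))
  res <- ld_clump(st, panel)
  expect_equal(res$SNP, "v1")
  expect_equal(attr(res, "members")[["v1"]], "v2")

  # two independent variants 100 kb apart: distance rule removes one
  d2 <- rbinom(500, 2, 0.4)
  v$pos <- c(1e6L, 1.1e6L)
  panel2 <- genotype_matrix(paste0("i", 1:500), v, cbind(d, d2))
  res2 <- ld_clump(clump_stats(panel2, c(1e-9, 1e-10)), panel2)
  expect_equal(res2$SNP, "v2")  # smaller p wins the index slot

  # nothing significant: empty result, not an error
  res3 <- ld_clump(clump_stats(panel2, c(0.5, 0.9)), panel2)
  expect_equal(nrow(res3), 0L)
})

test_that("greedy clumping matches the brute-force oracle on random panels", {
  for (seed in c(301, 302, 303, 304, 305)) {
    panel <- simulate_ld_panel(n_blocks = 10, block_size = 5,
                               n_individuals = 600, switch_prob = 0.15,
                               span_bp = 4e6, seed = seed)
    set.seed(seed)
    p <- 10^(-runif(50, 4, 12))
    st <- clump_stats(panel, p)
    mine <- ld_clump(st, panel, p_thresh = 1e-4, r2_thresh = 0.05,
                     window = 250000)
    orac <- oracle_clump(st, panel, p_thresh = 1e-4, r2_thresh = 0.05,
                         window = 250000)
    expect_identical(mine$SNP, orac)
    # invariant: every retained pair is distant and uncorrelated
    if (nrow(mine) > 1) {
      for (i in 1:(nrow(mine) - 1)) for (j in (i + 1):nrow(mine)) {
        same_chr <- mine$CHR[i] == mine$CHR[j]
        d <- abs(mine$BP[i] - mine$BP[j])
        expect_true(!same_chr || d >= 250000)
        if (same_chr && d <= 1e6)
          expect_lte(ld_r2(panel, mine$SNP[i], mine$SNP[j]), 0.05)
      }
    }
  }
})

test_that("summary statistics survive a TSV round trip", {
  cfg <- sim_config(seed = 241, n_variants_child_specific = 6,
                    n_variants_adult_specific = 0, n_variants_shared = 0)
  g <- simulate_genotypes(cfg, 100)
  set.seed(5)
  gw <- run_gwas(g, rnorm(100), trait = "bmi")
  f <- tempfile(fileext = ".tsv")
  write_sumstats(gw, f)
  back <- read_sumstats(f, trait = "bmi")
  expect_equal(back$BETA, gw$BETA, tolerance = 1e-12)
  expect_equal(back$SNP, gw$SNP)
  expect_equal(attr(back, "trait"), "bmi")
})
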