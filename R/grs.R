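# Genetic-risk-score construction and instrument-validation metrics.

#' Build a genetic risk score
#'
#' Per-individual weighted sum of effect-allele dosages. Dosages are
#' oriented to each weight's effect allele before weighting: if the weight's
#' effect/other alleles are swapped relative to the genotype records, the
#' dosage is flipped to `2 - d`. Unmatchable alleles raise an error naming
#' the variant. Weight variants missing from the genotypes are an error by
#' default; with `allow_missing = TRUE` they are skipped with a warning.
#'
#' @param genotypes A [genotype_matrix()].
#' @param weights A [sumstats()] table whose `BETA` column provides the
#'   per-allele weights.
#' @param allow_missing Skip weight variants absent from the genotypes
#'   (with a warning) instead of erroring.
#' @return Named numeric vector of scores, one per individual.
#' @export
build_grs <- function(genotypes, weights, allow_missing = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  missing <- setdiff(weights$SNP, v$id)
  if (length(missing)) {
    if (!allow_missing)
      stop("weight variants missing from genotypes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    warning("skipping ", length(missing),
            " weight variant(s) missing from genotypes")
    weights <- weights[!weights$SNP %in% missing, , drop = FALSE]
  }
  if (nrow(weights) == 0L) stop("no usable weight variants", call. = FALSE)
  score <- numeric(length(genotypes$ids))
  for (k in seq_len(nrow(weights))) {
    j <- match(weights$SNP[k], v$id)
    d <- genotypes$dosage[, j]
    if (weights$EA[k] == v$ea[j] && weights$OA[k] == v$oa[j]) {
      # aligned
    } else if (weights$EA[k] == v$oa[j] && weights$OA[k] == v$ea[j]) {
      d <- 2 - d
    } else {
      stop("cannot harmonise alleles for variant ", weights$SNP[k],
           call. = FALSE)
    }
    score <- score + weights$BETA[k] * d
  }
  names(score) <- genotypes$ids
  score
}

#' Variance explained by instruments (closed form)
#'
#' `sum(2 * beta^2 * MAF * (1 - MAF))` with `MAF = min(EAF, 1 - EAF)`: the
#' variance of a unit-variance trait explained by independent variants with
#' per-allele effects `betas` in trait-SD units.
#'
#' @param betas Per-allele effects (SD units).
#' @param eafs Effect-allele frequencies in (0, 1).
#' @return Fraction of variance explained.
#' @examples
#' variance_explained_formula(1, 0.5)  # 0.5
#' @export
variance_explained_formula <- function(betas, eafs) {
  if (length(betas) != length(eafs))
    stop("'betas' and 'eafs' must have equal length", call. = FALSE)
  if (any(!is.finite(eafs)) || any(eafs <= 0 | eafs >= 1))
    stop("'eafs' must lie strictly inside (0, 1)", call. = FALSE)
  maf <- pmin(eafs, 1 - eafs)
  sum(2 * betas^2 * maf * (1 - maf))
}

#' Regression R-squared of a genetic score against a phenotype
#'
#' Squared Pearson correlation between score and phenotype.
#'
#' @param scores,phenotype Equal-length numeric vectors, n >= 3.
#' @return Fraction in \[0, 1\].
#' @export
grs_regression_r2 <- function(scores, phenotype) {
  if (length(scores) != length(phenotype) || length(scores) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::var(scores) == 0)
    stop("zero-variance score", call. = FALSE)
  if (stats::var(phenotype) == 0)
    stop("zero-variance phenotype", call. = FALSE)
  stats::cor(scores, phenotype)^2
}

# Rank-based (Mann-Whitney) AUC of scores against a binary label.
rank_auc <- function(scores, label) {
  r <- rank(scores)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Extreme-value prediction metrics for a genetic score
#'
#' Labels individuals whose standardised phenotype exceeds +1 SD and
#' evaluates the score as a predictor of that label: rank-based
#' (Mann-Whitney) AUC, and the odds ratio per 1 SD of score from a logistic
#' regression of the label on the standardised score with a Wald 95% CI.
#' Perfect separation is reported with `converged = FALSE` (AUC is still
#' valid; the OR is not).
#'
#' @param scores Numeric score vector (non-degenerate).
#' @param phenotype Numeric phenotype; standardised internally.
#' @return List with `auc`, `odds_ratio_per_sd`, `ci_low`, `ci_high`, `p`,
#'   `n`, `n_extreme`, `converged`.
#' @export
extreme_prediction <- function(scores, phenotype) {
  if (length(scores) != length(phenotype))
    stop("'scores' and 'phenotype' must have equal length", call. = FALSE)
  if (stats::var(scores) == 0)
    stop("zero-variance score", call. = FALSE)
  if (stats::var(phenotype) == 0)
    stop("both extreme and non-extreme classes must be non-empty",
         call. = FALSE)
  z <- as.vector(scale(phenotype))
  label <- as.integer(z > 1)
  if (sum(label) == 0L || sum(label) == length(label))
    stop("both extreme and non-extreme classes must be non-empty",
         call. = FALSE)
  auc <- rank_auc(scores, label)
  s <- as.vector(scale(scores))
  fit <- suppressWarnings(stats::glm(label ~ s, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  logor <- cf["s", 1]; se <- cf["s", 2]
  converged <- fit$converged && abs(logor) < 20 && se < 100
  list(auc = auc,
       odds_ratio_per_sd = exp(logor),
       ci_low = exp(logor - 1.96 * se),
       ci_high = exp(logor + 1.96 * se),
       p = cf["s", 4],
       n = length(label), n_extreme = sum(label),
       converged = converged)
}

#' Instrument F-statistic from variance explained
#'
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)`: the multi-instrument
#' F-statistic implied by the fraction of exposure variance explained by k
#' instruments in a sample of n. The conventional adequacy threshold is
#' F > 10.
#'
#' @param r2 Fraction of variance explained, in \[0, 1).
#' @param n Sample size.
#' @param k Number of instruments (n > k + 1 >= 2).
#' @return The F-statistic.
#' @export
instrument_f_statistic <- function(r2, n, k) {
  stopifnot_scalar_number(r2, "r2", lo = 0, hi = 1)
  if (r2 >= 1) stop("'r2' must be < 1", call. = FALSE)
  stopifnot_scalar_number(n, "n", lo = 1)
  stopifnot_scalar_number(k, "k", lo = 1)
  if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
  (r2 / (1 - r2)) * ((n - k - 1) / k)
}

#' Validation report for a genetic risk score
#'
#' Convenience wrapper computing the full set of instrument-validation
#' metrics in one validation cohort: regression R-squared, closed-form
#' variance explained, extreme-value prediction (AUC and OR per score SD)
#' and the implied instrument F-statistic.
#'
#' @param genotypes Validation-cohort [genotype_matrix()].
#' @param weights [sumstats()] weights (clumped instruments).
#' @param phenotype Phenotype vector in the validation cohort.
#' @return An object of class `grs_report`.
#' @export
grs_report <- function(genotypes, weights, phenotype) {
  score <- build_grs(genotypes, weights)
  r2 <- grs_regression_r2(score, phenotype)
  ext <- extreme_prediction(score, phenotype)
  k <- nrow(weights)
  n <- length(phenotype)
  structure(list(
    score = score,
    r2_regression = r2,
    var_explained_formula = variance_explained_formula(weights$BETA,
                                                       weights$EAF),
    auc = ext$auc,
    odds_ratio_per_sd = ext$odds_ratio_per_sd,
    or_ci = c(ext$ci_low, ext$ci_high),
    or_p = ext$p,
    f_statistic = instrument_f_statistic(r2, n, k),
    n = n, n_variants = k
  ), class = "grs_report")
}

#' @export
print.grs_report <- function(x, ...) {
  cat(sprintf("grs_report: %d variants, n = %d\n", x$n_variants, x$n))
  cat(sprintf("  regression R2 = %.4f; formula variance explained = %.4f\n",
              x$r2_regression, x$var_explained_formula))
  cat(sprintf("  extreme (>1 SD) prediction: AUC = %.3f, OR per score SD = %.3f [%.3f, %.3f]\n",
              x$auc, x$odds_ratio_per_sd, x$or_ci[1], x$or_ci[2]))
  cat(sprintf("  instrument F = %.2f\n", x$f_statistic))
  invisible(x)
}
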