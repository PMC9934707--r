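# Cohort simulation under the assumed causal diagram:
#   child  = G b_child + c U + nuisance + e1
#   adult  = gamma child + G b_adult + c U + nuisance + e2
#   outcome = delta_c child + delta_a adult + G b_pleio + c U + nuisance + e3
# Residual variances are solved analytically so every trait has exact unit
# population variance; path coefficients are therefore exact structural
# SD/SD effects.

# fixed nuisance covariate effects (exercise residualisation, not confounding)
.NUIS_SEX <- 0.1    # per unit sex (0/1), var contribution 0.0025
.NUIS_AGE <- 0.005  # per year, age ~ U(40,70), var contribution 0.001875
.NUIS_VAR <- .NUIS_SEX^2 * 0.25 + .NUIS_AGE^2 * (30^2 / 12)

#' Simulate phenotypes under the causal diagram
#'
#' Generates childhood BMI, adulthood BMI and an outcome for the individuals
#' in `genotypes`, under the structural model of the configuration: a
#' child-to-adult path, direct effects of both exposures on the outcome, a
#' hidden standard-normal confounder affecting exposures and outcome, and
#' optional direct variant-to-outcome (pleiotropic) effects at shared
#' variants. Traits are constructed with exact unit population variance.
#' Small fixed sex/age nuisance effects (independent of genotype) are added
#' to every trait so that covariate residualisation is exercised downstream.
#'
#' A binary outcome is drawn from a logistic model on the same linear
#' predictor, with the intercept solved numerically so that the expected
#' prevalence matches `binary_prevalence`.
#'
#' @param genotypes A [genotype_matrix()] simulated under the same `config`.
#' @param config The [sim_config()] that produced `genotypes`.
#' @param seed Seed for the phenotype noise; defaults to the config seed.
#' @return A data frame (one row per individual): `iid`, `child_bmi_true`,
#'   `adult_bmi`, `recall`, `outcome`, `sex`, `age`, `centre`, `confounder`.
#'   The confounder column is carried for diagnostics only and is excluded
#'   by [write_phenotypes()] from analysis-facing output.
#' @export
simulate_phenotypes <- function(genotypes, config, seed = config$seed) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  model <- draw_model(config)
  m <- nrow(model$variants)
  if (ncol(genotypes$dosage) != m)
    stop(sprintf(
      "variant partition in config (%d variants) does not match genotypes (%d)",
      m, ncol(genotypes$dosage)), call. = FALSE)

  n <- nrow(genotypes$dosage)
  f <- model$variants$eaf
  v2pq <- 2 * f * (1 - f)
  G <- sweep(genotypes$dosage, 2L, 2 * f)  # centred at population mean
  cc <- config$confounder_strength
  gam <- config$gamma_child_to_adult
  dc <- config$delta_child_direct
  da <- config$delta_adult_direct

  sg_c <- sum(model$b_child^2 * v2pq)
  sg_a <- sum(model$b_adult^2 * v2pq)
  cov_sh <- sum(model$b_child * model$b_adult * v2pq)

  v1 <- 1 - sg_c - cc^2 - .NUIS_VAR
  v2 <- 1 - (gam^2 + sg_a + cc^2 + .NUIS_VAR +
               2 * gam * (cov_sh + cc^2 + .NUIS_VAR))
  if (v1 <= 0 || v2 <= 0)
    stop("configured genetic/confounder variance exceeds unit trait variance",
         call. = FALSE)

  set.seed(seed %% 2147483647L)
  U <- stats::rnorm(n)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 40, 70)
  centre <- factor(sample(paste0("c", 1:10), n, replace = TRUE))
  nuis <- .NUIS_SEX * (sex - 0.5) + .NUIS_AGE * (age - 55)

  child <- as.vector(G %*% model$b_child) + cc * U + nuis +
    stats::rnorm(n, 0, sqrt(v1))
  adult <- gam * child + as.vector(G %*% model$b_adult) + cc * U + nuis +
    stats::rnorm(n, 0, sqrt(v2))

  # linear predictor of the outcome and its exact population variance
  b_tot <- dc * model$b_child + da * (gam * model$b_child + model$b_adult) +
    model$b_pleio
  u_coef <- cc * (dc + da * (1 + gam) + 1)
  n_coef <- dc + da * (1 + gam) + 1
  var_lp <- sum(b_tot^2 * v2pq) + u_coef^2 + n_coef^2 * .NUIS_VAR +
    (dc + da * gam)^2 * v1 + da^2 * v2
  lp <- dc * child + da * adult + as.vector(G %*% model$b_pleio) + cc * U +
    nuis

  if (config$outcome_kind == "quantitative") {
    v3 <- 1 - var_lp
    if (v3 <= 0)
      stop("configured outcome signal variance exceeds unit trait variance",
           call. = FALSE)
    outcome <- lp + stats::rnorm(n, 0, sqrt(v3))
  } else {
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + lp)) - config$binary_prevalence,
      lower = -40, upper = 40, tol = 1e-10)$root
    outcome <- stats::rbinom(n, 1L, stats::plogis(alpha + lp))
  }

  recall <- discretize_recall(child, config$recall_proportions)

  data.frame(
    iid = genotypes$ids, child_bmi_true = child, adult_bmi = adult,
    recall = recall, outcome = outcome, sex = sex, age = age,
    centre = centre, confounder = U, stringsAsFactors = FALSE
  )
}

#' Discretise a continuous childhood measure into recall categories
#'
#' Assigns "thinner" / "same" / "plumper" labels by empirical quantile
#' cutpoints at the cumulative category proportions, emulating a 3-level
#' body-size recall question. Cutpoints are order statistics (quantile type
#' 1), so category sizes match the proportions to within rounding and the
#' assignment is monotone in the underlying value. Tied values always share
#' a category (cutpoints act on values, not ranks); a constant input vector
#' therefore collapses into the single lowest category.
#'
#' @param child_values Numeric vector (SD units).
#' @param proportions Length-3 positive probabilities summing to 1
#'   (tolerance 1e-9).
#' @return Character vector of labels in
#'   `c("thinner", "same", "plumper")`.
#' @examples
#' discretize_recall(c(-2, 0, 2), c(1, 1, 1) / 3)
#' @export
discretize_recall <- function(child_values, proportions) {
  if (!is.numeric(proportions) || length(proportions) != 3L ||
      any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("'proportions' must be 3 positive probabilities summing to 1",
         call. = FALSE)
  if (!is.numeric(child_values) || length(child_values) == 0L ||
      any(!is.finite(child_values)))
    stop("'child_values' must be finite numeric", call. = FALSE)
  q <- stats::quantile(child_values, probs = cumsum(proportions)[1:2],
                       type = 1, names = FALSE)
  out <- ifelse(child_values <= q[1], "thinner",
                ifelse(child_values <= q[2], "same", "plumper"))
  out
}

#' Simulate a two-sample study pair
#'
#' Generates an exposure cohort and a non-overlapping outcome cohort sharing
#' one variant panel (and one set of true variant effects) but with disjoint
#' individuals and independent genotype and phenotype noise — the setting of
#' two-sample Mendelian randomisation. Deterministic given the config seed:
#' each cohort draws from its own named substream.
#'
#' @param config A [sim_config()].
#' @return An object of class `two_sample_study`: a list with elements
#'   `exposure` and `outcome`, each a list holding `genotypes` and
#'   `phenotypes`.
#' @export
make_two_sample_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ge <- simulate_genotypes(config, config$n_exposure_cohort,
                           seed = substream_seed(config$seed, "exposure_genotypes"),
                           id_prefix = "expo")
  go <- simulate_genotypes(config, config$n_outcome_cohort,
                           seed = substream_seed(config$seed, "outcome_genotypes"),
                           id_prefix = "outc")
  pe <- simulate_phenotypes(ge, config,
                            seed = substream_seed(config$seed, "exposure_phenotypes"))
  po <- simulate_phenotypes(go, config,
                            seed = substream_seed(config$seed, "outcome_phenotypes"))
  structure(list(exposure = list(genotypes = ge, phenotypes = pe),
                 outcome = list(genotypes = go, phenotypes = po),
                 config = config),
            class = "two_sample_study")
}

#' @export
print.two_sample_study <- function(x, ...) {
  cat(sprintf("two_sample_study: exposure n=%d, outcome n=%d, %d variants, outcome %s\n",
              length(x$exposure$genotypes$ids), length(x$outcome$genotypes$ids),
              nrow(x$exposure$genotypes$variants), x$config$outcome_kind))
  invisible(x)
}
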