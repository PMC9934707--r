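#' Simulation configuration for the assumed causal diagram
#'
#' Bundles every parameter of the generative model used by the cohort
#' simulator: the variant panel (counts of child-specific, adult-specific and
#' shared-effect variants with their allele-frequency range and per-allele
#' effect-size distributions), the structural path coefficients of the causal
#' diagram (the child-to-adult path `gamma_child_to_adult`, the direct effects
#' `delta_child_direct` and `delta_adult_direct` of each exposure on the
#' outcome), hidden confounding, optional directional pleiotropy, cohort
#' sizes for the two non-overlapping samples, and the outcome model.
#'
#' All traits generated under a config have exact unit population variance, so
#' path coefficients are in SD-per-SD units (log-odds per exposure SD for a
#' binary outcome) and per-allele variant effects are in SD units of the
#' trait.
#'
#' Defaults describe the study conditions exercised throughout the package's
#' validation: strong instruments (per-exposure genetic variance about 0.37
#' across 100 causal variants), a child-to-adult path of 0.5, no direct
#' childhood effect on the outcome and an adulthood direct effect of 0.6,
#' mirroring the lifecourse hypothesis the estimators are designed to
#' disentangle.
#'
#' @param n_variants_child_specific,n_variants_adult_specific,n_variants_shared
#'   Variant counts per effect class (non-negative; at least one variant in
#'   total). Shared variants affect both exposures with correlated effects.
#' @param maf_range Length-2 numeric, allele-frequency range in (0, 1).
#' @param effect_sd_child,effect_sd_adult SD of per-allele variant effects on
#'   each exposure (trait-SD units per allele).
#' @param shared_effect_cor Correlation of child/adult effects at shared
#'   variants, in \[-1, 1\].
#' @param gamma_child_to_adult Path coefficient of childhood BMI on adulthood
#'   BMI (SD/SD).
#' @param delta_child_direct,delta_adult_direct Direct effects of each
#'   exposure on the outcome (SD/SD; log-OR per SD when
#'   `outcome_kind = "binary"`).
#' @param confounder_strength Effect of the hidden standard-normal confounder
#'   on both exposures and the outcome (SD/SD).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of direct variant-to-
#'   outcome effects at shared variants (SD units per allele); both zero
#'   disables pleiotropy.
#' @param n_exposure_cohort,n_outcome_cohort Individuals per cohort.
#' @param outcome_kind `"quantitative"` or `"binary"`.
#' @param binary_prevalence Target outcome prevalence in (0, 1) for binary
#'   outcomes; the logistic intercept is solved numerically to achieve it.
#' @param recall_proportions Length-3 probabilities of the
#'   thinner/same/plumper recall categories (must sum to 1).
#' @param seed Integer seed; mandatory. All randomness in the simulator flows
#'   from it through named substreams.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_exposure_cohort = 500, n_outcome_cohort = 500)
#' cfg
#' @export
sim_config <- function(n_variants_child_specific = 50L,
                       n_variants_adult_specific = 50L,
                       n_variants_shared = 50L,
                       maf_range = c(0.05, 0.5),
                       effect_sd_child = 0.1,
                       effect_sd_adult = 0.1,
                       shared_effect_cor = 0.5,
                       gamma_child_to_adult = 0.5,
                       delta_child_direct = 0,
                       delta_adult_direct = 0.6,
                       confounder_strength = 0.2,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       n_exposure_cohort = 20000L,
                       n_outcome_cohort = 20000L,
                       outcome_kind = c("quantitative", "binary"),
                       binary_prevalence = 0.1,
                       recall_proportions = c(0.32, 0.51, 0.17),
                       seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  outcome_kind <- match.arg(outcome_kind)

  for (nm in c("n_variants_child_specific", "n_variants_adult_specific",
               "n_variants_shared"))
    stopifnot_scalar_number(get(nm), nm, lo = 0, integer = TRUE)
  n_var <- n_variants_child_specific + n_variants_adult_specific +
    n_variants_shared
  if (n_var < 1) stop("at least one variant is required", call. = FALSE)

  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(!is.finite(maf_range)))
    stop("'maf_range' must be two finite frequencies", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
    stop("'maf_range' must satisfy 0 < low <= high < 1", call. = FALSE)

  stopifnot_scalar_number(effect_sd_child, "effect_sd_child", lo = 0)
  stopifnot_scalar_number(effect_sd_adult, "effect_sd_adult", lo = 0)
  stopifnot_scalar_number(shared_effect_cor, "shared_effect_cor", -1, 1)
  stopifnot_scalar_number(gamma_child_to_adult, "gamma_child_to_adult")
  stopifnot_scalar_number(delta_child_direct, "delta_child_direct")
  stopifnot_scalar_number(delta_adult_direct, "delta_adult_direct")
  stopifnot_scalar_number(confounder_strength, "confounder_strength")
  stopifnot_scalar_number(pleiotropy_mean, "pleiotropy_mean")
  stopifnot_scalar_number(pleiotropy_sd, "pleiotropy_sd", lo = 0)
  stopifnot_scalar_number(n_exposure_cohort, "n_exposure_cohort", lo = 1,
                          integer = TRUE)
  stopifnot_scalar_number(n_outcome_cohort, "n_outcome_cohort", lo = 1,
                          integer = TRUE)
  stopifnot_scalar_number(binary_prevalence, "binary_prevalence", 0, 1,
                          strict = TRUE)
  if (!is.numeric(recall_proportions) || length(recall_proportions) != 3L ||
      any(recall_proportions <= 0) ||
      abs(sum(recall_proportions) - 1) > 1e-9)
    stop("'recall_proportions' must be 3 positive probabilities summing to 1",
         call. = FALSE)

  structure(list(
    n_variants_child_specific = as.integer(n_variants_child_specific),
    n_variants_adult_specific = as.integer(n_variants_adult_specific),
    n_variants_shared = as.integer(n_variants_shared),
    maf_range = as.numeric(maf_range),
    effect_sd_child = effect_sd_child,
    effect_sd_adult = effect_sd_adult,
    shared_effect_cor = shared_effect_cor,
    gamma_child_to_adult = gamma_child_to_adult,
    delta_child_direct = delta_child_direct,
    delta_adult_direct = delta_adult_direct,
    confounder_strength = confounder_strength,
    pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    n_exposure_cohort = as.integer(n_exposure_cohort),
    n_outcome_cohort = as.integer(n_outcome_cohort),
    outcome_kind = outcome_kind,
    binary_prevalence = binary_prevalence,
    recall_proportions = as.numeric(recall_proportions),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  variants: %d child-specific, %d adult-specific, %d shared (MAF %.3g-%.3g)\n",
              x$n_variants_child_specific, x$n_variants_adult_specific,
              x$n_variants_shared, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  effects: sd_child %.3g, sd_adult %.3g, shared cor %.2f\n",
              x$effect_sd_child, x$effect_sd_adult, x$shared_effect_cor))
  cat(sprintf("  paths: gamma %.3g, delta_child %.3g, delta_adult %.3g, confounder %.3g\n",
              x$gamma_child_to_adult, x$delta_child_direct,
              x$delta_adult_direct, x$confounder_strength))
  if (x$pleiotropy_mean != 0 || x$pleiotropy_sd != 0)
    cat(sprintf("  pleiotropy: mean %.3g, sd %.3g\n",
                x$pleiotropy_mean, x$pleiotropy_sd))
  cat(sprintf("  cohorts: %d exposure, %d outcome; outcome %s\n",
              x$n_exposure_cohort, x$n_outcome_cohort, x$outcome_kind))
  invisible(x)
}

# Population model drawn deterministically from the config seed: variant
# frequencies, positions and the per-allele effect vectors. Shared across
# cohorts so two-sample studies see one variant panel.
draw_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "panel"))
  m <- config$n_variants_child_specific + config$n_variants_adult_specific +
    config$n_variants_shared
  freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  chr <- ((seq_len(m) - 1L) %% 22L) + 1L
  pos <- integer(m)
  for (c in unique(chr)) {
    idx <- which(chr == c)
    pos[idx] <- 1000000L * seq_along(idx)  # 1 Mb spacing: effectively unlinked
  }
  class_lab <- rep(c("child", "adult", "shared"),
                   times = c(config$n_variants_child_specific,
                             config$n_variants_adult_specific,
                             config$n_variants_shared))
  b_child <- b_adult <- b_pleio <- numeric(m)
  is_c <- class_lab == "child"; is_a <- class_lab == "adult"
  is_s <- class_lab == "shared"
  b_child[is_c] <- stats::rnorm(sum(is_c), 0, config$effect_sd_child)
  b_adult[is_a] <- stats::rnorm(sum(is_a), 0, config$effect_sd_adult)
  if (any(is_s)) {
    # correlated child/adult effects at shared variants
    rho <- config$shared_effect_cor
    z1 <- stats::rnorm(sum(is_s)); z2 <- stats::rnorm(sum(is_s))
    b_child[is_s] <- config$effect_sd_child * z1
    b_adult[is_s] <- config$effect_sd_adult * (rho * z1 + sqrt(1 - rho^2) * z2)
    if (config$pleiotropy_mean != 0 || config$pleiotropy_sd > 0)
      b_pleio[is_s] <- stats::rnorm(sum(is_s), config$pleiotropy_mean,
                                    config$pleiotropy_sd)
  }
  # Rescale each exposure's effect vector so the realised genetic variance
  # equals its target sum(effect_sd^2 * 2 f (1 - f)) exactly: each cohort
  # realises the configured heritability rather than a chi-squared draw
  # around it (scalar rescaling preserves the shared-effect correlation).
  v2pq <- 2 * freq * (1 - freq)
  for (nm in c("b_child", "b_adult")) {
    b <- get(nm)
    realised <- sum(b^2 * v2pq)
    affected <- b != 0
    if (realised > 0) {
      sd_cfg <- if (nm == "b_child") config$effect_sd_child
                else config$effect_sd_adult
      target <- sd_cfg^2 * sum(v2pq[affected])
      assign(nm, b * sqrt(target / realised))
    }
  }
  list(
    variants = data.frame(
      id = paste0("rs", seq_len(m)), chr = chr, pos = pos,
      ea = "A", oa = "G", eaf = freq, info = 1,
      class = class_lab, stringsAsFactors = FALSE
    ),
    b_child = b_child, b_adult = b_adult, b_pleio = b_pleio
  )
}
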