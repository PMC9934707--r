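# Reconstruction of a continuous childhood BMI from 3-level recall
# categories, anchored to an external reference distribution, followed by
# rank-based inverse-normal transformation.

#' Reference distribution for childhood BMI reconstruction
#'
#' Describes the external distribution (e.g. measured age-11 BMI in a birth
#' cohort) from which category-conditional values are sampled. Category
#' proportions are interpreted as quantiles of this distribution: cumulative
#' sums of the first two proportions split it into thinner/same/plumper
#' strata. The lognormal family is parameterised so that the natural scale
#' has the stated mean and SD (moment inversion), accommodating the right
#' skew of childhood BMI.
#'
#' @param mean Mean on the natural (kg/m^2) scale; must be positive for the
#'   lognormal family.
#' @param sd Standard deviation on the natural scale (> 0).
#' @param family `"normal"` or `"lognormal"`.
#' @param category_proportions Length-3 positive probabilities summing to 1
#'   for thinner/same/plumper.
#' @return An object of class `reference_distribution` with fields `mean`,
#'   `sd`, `family`, `category_quantiles` (the two cumulative cut
#'   probabilities) and, for the lognormal family, `meanlog`/`sdlog`.
#' @examples
#' fit_reference_distribution(18, 3, "normal", c(1, 1, 1) / 3)
#' @export
fit_reference_distribution <- function(mean, sd,
                                       family = c("normal", "lognormal"),
                                       category_proportions) {
  family <- match.arg(family)
  stopifnot_scalar_number(sd, "sd")
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  stopifnot_scalar_number(mean, "mean")
  if (!is.numeric(category_proportions) ||
      length(category_proportions) != 3L ||
      any(category_proportions <= 0) ||
      abs(sum(category_proportions) - 1) > 1e-9)
    stop("'category_proportions' must be 3 positive probabilities summing to 1",
         call. = FALSE)
  out <- list(mean = mean, sd = sd, family = family,
              category_quantiles = cumsum(category_proportions)[1:2])
  if (family == "lognormal") {
    if (mean <= 0)
      stop("lognormal family requires a positive mean", call. = FALSE)
    sdlog2 <- log(1 + (sd / mean)^2)
    out$sdlog <- sqrt(sdlog2)
    out$meanlog <- log(mean) - sdlog2 / 2
  }
  structure(out, class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("reference_distribution: %s(mean %.3g, sd %.3g), cut quantiles %.3g / %.3g\n",
              x$family, x$mean, x$sd,
              x$category_quantiles[1], x$category_quantiles[2]))
  invisible(x)
}

refdist_quantile <- function(refdist, p) {
  if (refdist$family == "normal")
    stats::qnorm(p, refdist$mean, refdist$sd)
  else
    stats::qlnorm(p, refdist$meanlog, refdist$sdlog)
}

#' Assign continuous childhood BMI values from recall categories
#'
#' Each individual receives an independent draw from the reference
#' distribution truncated to their recall category's stratum: cumulative
#' probability (0, q1\] for "thinner", (q1, q2\] for "same" and (q2, 1) for
#' "plumper". Sampling is by inverse-CDF on a uniform draw inside the
#' stratum, so every value lies strictly inside its own stratum bounds.
#' Deterministic given `seed`.
#'
#' @param categories Character (or factor) vector with values in
#'   `c("thinner", "same", "plumper")`.
#' @param refdist A [fit_reference_distribution()] object.
#' @param seed Integer seed.
#' @return Numeric vector of reconstructed BMI values (kg/m^2).
#' @export
assign_continuous_bmi <- function(categories, refdist, seed) {
  stopifnot(inherits(refdist, "reference_distribution"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  categories <- as.character(categories)
  bad <- setdiff(unique(categories), c("thinner", "same", "plumper"))
  if (length(bad))
    stop("unknown recall category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  q1 <- refdist$category_quantiles[1]
  q2 <- refdist$category_quantiles[2]
  lo <- c(thinner = 0, same = q1, plumper = q2)[categories]
  hi <- c(thinner = q1, same = q2, plumper = 1)[categories]
  set.seed(seed %% 2147483647L)
  u <- lo + stats::runif(length(categories)) * (hi - lo)
  refdist_quantile(refdist, u)
}

#' Rank-based inverse-normal transformation
#'
#' Maps values onto standard-normal quantiles via Blom scores:
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving their average rank.
#' The output is strictly monotone in the input ranks and has sample mean 0
#' (exactly, up to floating point, in the absence of ties).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Numeric vector in SD units.
#' @examples
#' rank_inverse_normalise(c(1, 2, 3))
#' @export
rank_inverse_normalise <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric", call. = FALSE)
  if (length(unique(values)) < 2L)
    stop("at least 2 distinct values are required", call. = FALSE)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}
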