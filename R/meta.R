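# Fixed-effect meta-analysis of MR results across outcome studies, and
# odds-ratio scale conversion.

#' Fixed-effect meta-analysis of MR results
#'
#' Pools estimates for the same exposure-outcome pair across outcome
#' studies under a fixed-effect (common true effect) assumption, by inverse
#' variance: `est = sum(est_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = sqrt(1 / sum(1 / se_i^2))`. Computation is delegated to
#' [metafor::rma.uni()] with `method = "FE"`. Binary-outcome results are
#' pooled on the log-OR scale; results already exponentiated to the OR
#' scale are refused.
#'
#' @param results A data frame of MR result rows (as in `mr_fit()$results`,
#'   needing at least `estimate`, `se`, `scale`), or a list of `mr_fit`
#'   objects / result data frames which are row-bound first.
#' @return A single-row result data frame with `method = "meta"`.
#' @export
fixed_effect_meta <- function(results) {
  if (inherits(results, "mr_fit")) results <- results$results
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      if (inherits(r, "mr_fit")) r$results else as.data.frame(r)))
  results <- as.data.frame(results)
  if (nrow(results) < 1L) stop("nothing to meta-analyse", call. = FALSE)
  if ("scale" %in% names(results)) {
    if (length(unique(results$scale)) > 1L)
      stop("cannot meta-analyse results on mixed scales", call. = FALSE)
    if (results$scale[1] == "or")
      stop("meta-analyse on the log-OR scale, not the OR scale",
           call. = FALSE)
  }
  if ("exposure" %in% names(results) &&
      length(unique(results$exposure)) > 1L)
    stop("results mix exposures", call. = FALSE)
  fit <- metafor::rma.uni(yi = results$estimate, sei = results$se,
                          method = "FE")
  est <- as.numeric(fit$b)
  se <- fit$se
  mk_row("meta",
         if ("exposure" %in% names(results)) results$exposure[1] else NA,
         if ("outcome" %in% names(results))
           paste(unique(results$outcome), collapse = "+") else NA,
         est, se, 2 * stats::pnorm(-abs(est / se)),
         if ("n_variants" %in% names(results))
           max(results$n_variants) else NA_integer_,
         NA_real_,
         if ("scale" %in% names(results)) results$scale[1] else "sd")
}

#' Convert a log-OR MR result to the odds-ratio scale
#'
#' Exponentiates the point estimate and confidence bounds; the p-value is
#' unchanged and the `se` column keeps its log-scale value (flagged by the
#' `scale` column turning to `"or"`). Refuses results that are not on the
#' log-OR scale.
#'
#' @param result An `mr_fit` object or a result data frame with a
#'   `scale` column equal to `"log_or"`.
#' @return The result data frame on the OR scale.
#' @export
to_odds_ratio <- function(result) {
  df <- if (inherits(result, "mr_fit")) result$results
        else as.data.frame(result)
  if (!"scale" %in% names(df) || any(df$scale != "log_or"))
    stop("result is not on the log-OR scale", call. = FALSE)
  df$estimate <- exp(df$estimate)
  df$ci_low <- exp(df$ci_low)
  df$ci_high <- exp(df$ci_high)
  df$scale <- "or"
  df
}
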