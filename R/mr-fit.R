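# The MR estimation engine: one fitting function returning a classed object,
# with IVW (inverse-variance-weighted), MR-Egger and multivariable (MVMR)
# methods.

#' Fit a Mendelian-randomisation model
#'
#' The central estimator of the package. Given a [harmonise()]d set of
#' variant-exposure and variant-outcome effects, estimates the causal effect
#' of the exposure(s) on the outcome:
#'
#' * `"ivw"` — inverse-variance-weighted regression of outcome effects on
#'   exposure effects through the origin, each variant weighted by
#'   `1 / se_out^2`. Standard errors per `se_method`. A single instrument
#'   degenerates to the Wald ratio and is labelled `"wald_ratio"`.
#' * `"egger"` — weighted linear regression of outcome on exposure effects
#'   *with* an intercept, variants re-oriented internally so all exposure
#'   effects are non-negative. The slope is a pleiotropy-robust causal
#'   estimate; the intercept estimates the average directional pleiotropic
#'   effect. Inference is t-based with k - 2 degrees of freedom and
#'   estimated residual scale. Requires >= 3 instruments.
#' * `"mvmr"` — weighted multiple regression of outcome effects on both
#'   exposures' effects without intercept; each coefficient is that
#'   exposure's direct effect conditional on the other. Requires >= 3
#'   instruments and non-collinear exposure effects. An exposure whose
#'   effects are all zero is unidentified and reported as `NA`.
#'
#' Estimates are in SD-per-SD units, or log odds ratio per exposure SD when
#' the outcome is binary (`scale` column `"log_or"`; see [to_odds_ratio()]).
#' Univariable fits carry the instrument F-statistic implied by the
#' closed-form variance explained.
#'
#' @param h A [harmonise()]d set (`harmonised_set`); `"mvmr"` requires one
#'   built with a secondary exposure.
#' @param method One of `"ivw"`, `"egger"`, `"mvmr"`.
#' @param se_method Standard-error model for IVW and MVMR. `"fixed"`
#'   (default): plain fixed-effect SEs, exact when exposure effects are
#'   noiseless and weights correct. `"random"`: multiplicative
#'   random-effects — the fixed-effect SE inflated by the root of the
#'   heterogeneity scale `max(1, Q / (k - p))`; appropriate under balanced
#'   pleiotropy or estimated exposure effects. `"jackknife"`: delete-one-
#'   variant jackknife over instruments; consistent under
#'   errors-in-exposure-effects (including correlated errors across
#'   exposures) without further inputs, and the recommended choice for
#'   finite-sample two-sample MVMR simulation studies.
#' @return An object of class `mr_fit`: a list with `results` (data frame
#'   with columns `method`, `exposure`, `outcome`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n_variants`, `f_statistic`, `scale`), the
#'   harmonised `data`, and the `method`. Methods: [print.mr_fit()],
#'   [summary.mr_fit()], [coef.mr_fit()], [confint.mr_fit()],
#'   [plot.mr_fit()].
#' @export
mr_fit <- function(h, method = c("ivw", "egger", "mvmr"),
                   se_method = c("fixed", "random", "jackknife")) {
  stopifnot(inherits(h, "harmonised_set"))
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  scale <- if (identical(attr(h, "outcome_kind"), "binary")) "log_or" else "sd"
  exposures <- attr(h, "exposures")
  outcome <- attr(h, "outcome")
  k <- nrow(h)
  w <- 1 / h$se_out^2

  res <- switch(method,
    ivw = {
      if (all(h$beta_exp == 0))
        stop("non-identified: all exposure effects are zero", call. = FALSE)
      if (k == 1L) {
        est <- h$beta_out / h$beta_exp
        se <- abs(h$se_out / h$beta_exp)
        mk_row("wald_ratio", exposures[1], outcome, est, se,
               2 * stats::pnorm(-abs(est / se)), k,
               f_stat_safe(h$beta_exp, h$EAF, h$n_exp, k), scale)
      } else {
        denom <- sum(w * h$beta_exp^2)
        est <- sum(w * h$beta_exp * h$beta_out) / denom
        se <- sqrt(1 / denom)
        if (se_method == "random") {
          q <- sum(w * (h$beta_out - est * h$beta_exp)^2)
          se <- se * sqrt(max(1, q / (k - 1)))
        } else if (se_method == "jackknife") {
          loo <- vapply(seq_len(k), function(i) {
            sum(w[-i] * h$beta_exp[-i] * h$beta_out[-i]) /
              sum(w[-i] * h$beta_exp[-i]^2)
          }, numeric(1))
          se <- sqrt((k - 1) / k * sum((loo - mean(loo))^2))
        }
        mk_row("ivw", exposures[1], outcome, est, se,
               2 * stats::pnorm(-abs(est / se)), k,
               f_stat_safe(h$beta_exp, h$EAF, h$n_exp, k), scale)
      }
    },
    egger = {
      if (k < 3L)
        stop("MR-Egger requires at least 3 instruments", call. = FALSE)
      s <- ifelse(h$beta_exp < 0, -1, 1)
      bx <- s * h$beta_exp
      by <- s * h$beta_out
      fit <- stats::lm(by ~ bx, weights = w)
      # summary() warns on noiseless (exact-fit) inputs; harmless here
      cf <- suppressWarnings(summary(fit)$coefficients)
      rbind(
        mk_row("egger", exposures[1], outcome, cf["bx", 1], cf["bx", 2],
               2 * stats::pt(-abs(cf["bx", 3]), df = k - 2), k,
               f_stat_safe(h$beta_exp, h$EAF, h$n_exp, k), scale),
        mk_row("egger_intercept", exposures[1], outcome,
               cf["(Intercept)", 1], cf["(Intercept)", 2],
               2 * stats::pt(-abs(cf["(Intercept)", 3]), df = k - 2), k,
               NA_real_, scale)
      )
    },
    mvmr = {
      if (!"beta_exp2" %in% names(h))
        stop("'mvmr' needs a harmonised set with a secondary exposure",
             call. = FALSE)
      if (k < 3L)
        stop("MVMR requires at least 3 instruments", call. = FALSE)
      X <- cbind(h$beta_exp, h$beta_exp2)
      colnames(X) <- exposures
      zero <- apply(X, 2L, function(c) all(c == 0))
      Xf <- X[, !zero, drop = FALSE]
      if (ncol(Xf) == 0L)
        stop("non-identified: all exposure effects are zero", call. = FALSE)
      XtWX <- crossprod(Xf, Xf * w)
      if (ncol(Xf) > 1L && kappa(XtWX, exact = TRUE) > 1e10)
        stop("weak conditional instruments: exposure effects are collinear",
             call. = FALSE)
      est_f <- solve(XtWX, crossprod(Xf, w * h$beta_out))[, 1]
      se_f <- sqrt(diag(solve(XtWX)))
      if (se_method == "random" && k > ncol(Xf)) {
        q <- sum(w * (h$beta_out - as.vector(Xf %*% est_f))^2)
        se_f <- se_f * sqrt(max(1, q / (k - ncol(Xf))))
      } else if (se_method == "jackknife") {
        loo <- vapply(seq_len(k), function(i) {
          solve(crossprod(Xf[-i, , drop = FALSE],
                          Xf[-i, , drop = FALSE] * w[-i]),
                crossprod(Xf[-i, , drop = FALSE],
                          w[-i] * h$beta_out[-i]))[, 1]
        }, numeric(ncol(Xf)))
        loo <- matrix(loo, nrow = ncol(Xf))
        se_f <- sqrt((k - 1) / k *
                       rowSums((loo - rowMeans(loo))^2))
      }
      est <- se_f_all <- stats::setNames(rep(NA_real_, 2L), exposures)
      est[colnames(Xf)] <- est_f
      se_f_all[colnames(Xf)] <- se_f
      do.call(rbind, lapply(exposures, function(e) {
        mk_row("mvmr", e, outcome, est[[e]], se_f_all[[e]],
               if (is.na(est[[e]])) NA_real_
               else 2 * stats::pnorm(-abs(est[[e]] / se_f_all[[e]])),
               k, NA_real_, scale)
      }))
    }
  )
  structure(list(results = res, data = h, method = method,
                 se_method = se_method, call = match.call()),
            class = "mr_fit")
}

mk_row <- function(method, exposure, outcome, est, se, p, k, f, scale) {
  data.frame(method = method, exposure = exposure, outcome = outcome,
             estimate = est, se = se,
             ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
             p = p, n_variants = k, f_statistic = f, scale = scale,
             stringsAsFactors = FALSE)
}

f_stat_safe <- function(betas, eafs, n_exp, k) {
  n <- round(mean(n_exp))
  if (n <= k + 1) return(NA_real_)
  r2 <- variance_explained_formula(betas, eafs)
  if (r2 >= 1) return(NA_real_)
  instrument_f_statistic(r2, n, k)
}

#' Inverse-variance-weighted MR
#'
#' Convenience wrapper: `mr_fit(h, method = "ivw")`.
#' @inheritParams mr_fit
#' @return An `mr_fit` object.
#' @export
mr_ivw <- function(h, se_method = "fixed")
  mr_fit(h, "ivw", se_method = se_method)

#' MR-Egger regression
#'
#' Convenience wrapper: `mr_fit(h, method = "egger")`. The returned results
#' hold both the slope (causal estimate) and the intercept (average
#' directional pleiotropy).
#' @inheritParams mr_fit
#' @return An `mr_fit` object with rows `egger` and `egger_intercept`.
#' @export
mr_egger <- function(h) mr_fit(h, "egger")

#' Multivariable MR
#'
#' Convenience wrapper: `mr_fit(h, method = "mvmr")`, yielding each
#' exposure's direct effect conditional on the other.
#' @inheritParams mr_fit
#' @return An `mr_fit` object with one row per exposure.
#' @export
mr_mvmr <- function(h, se_method = "fixed")
  mr_fit(h, "mvmr", se_method = se_method)

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mendelian randomisation fit (%s): %s -> %s\n",
              x$method, paste(attr(x$data, "exposures"), collapse = " + "),
              attr(x$data, "outcome")))
  df <- x$results
  df$estimate <- signif(df$estimate, digits)
  df$se <- signif(df$se, digits)
  df$ci_low <- signif(df$ci_low, digits)
  df$ci_high <- signif(df$ci_high, digits)
  df$p <- signif(df$p, 3)
  df$f_statistic <- signif(df$f_statistic, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  x <- object
  print(x)
  d <- attr(x$data, "drops")
  if (!is.null(d) && nrow(d))
    cat(sprintf("Harmonisation dropped %d variant(s) (%s)\n", nrow(d),
                paste(unique(d$reason), collapse = ", ")))
  if (any(!is.na(x$data$proxy)))
    cat(sprintf("%d variant(s) proxied\n", sum(!is.na(x$data$proxy))))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$estimate,
                  paste(object$results$method, object$results$exposure,
                        sep = ":"))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$results$estimate - z * object$results$se,
             object$results$estimate + z * object$results$se)
  rownames(m) <- paste(object$results$method, object$results$exposure,
                       sep = ":")
  colnames(m) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  m
}

#' Scatter plot of variant effects with the fitted causal slope
#'
#' @param x An `mr_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  graphics::plot(h$beta_exp, h$beta_out,
                 xlab = "variant-exposure effect (SD/allele)",
                 ylab = "variant-outcome effect",
                 pch = 19, col = "grey30", ...)
  graphics::segments(h$beta_exp, h$beta_out - 1.96 * h$se_out,
                     h$beta_exp, h$beta_out + 1.96 * h$se_out,
                     col = "grey70")
  r <- x$results
  if (x$method == "egger") {
    graphics::abline(a = r$estimate[r$method == "egger_intercept"],
                     b = r$estimate[r$method == "egger"], col = "firebrick")
  } else {
    slope <- r$estimate[r$exposure == attr(h, "exposures")[1]][1]
    graphics::abline(a = 0, b = slope, col = "firebrick")
  }
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  invisible(x)
}

#' Steiger directionality filtering
#'
#' Excludes instruments that explain more variance in the outcome than in
#' the exposure — a guard against reverse causation. Both variances use the
#' closed form `2 * beta^2 * MAF * (1 - MAF)` on the harmonised effects
#' (equivalent to comparing `|beta_exp|` and `|beta_out|` here, since MAF is
#' shared); for binary outcomes this is an approximation on the log-OR
#' scale.
#'
#' @param h A [harmonise()]d set.
#' @param exposure Which exposure's effects to compare against the outcome:
#'   1 (primary, default) or 2.
#' @return The filtered `harmonised_set` (possibly empty, with a warning),
#'   with attribute `steiger_excluded`: a data frame of removed variants
#'   with both variance values.
#' @export
steiger_filter <- function(h, exposure = 1L) {
  stopifnot(inherits(h, "harmonised_set"))
  bx <- if (exposure == 1L) h$beta_exp else h$beta_exp2
  if (is.null(bx)) stop("no such exposure in harmonised set", call. = FALSE)
  maf <- pmin(h$EAF, 1 - h$EAF)
  v_exp <- 2 * bx^2 * maf * (1 - maf)
  v_out <- 2 * h$beta_out^2 * maf * (1 - maf)
  keep <- v_exp >= v_out
  excluded <- data.frame(SNP = h$SNP[!keep], var_exposure = v_exp[!keep],
                         var_outcome = v_out[!keep], stringsAsFactors = FALSE)
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("Steiger filtering removed every instrument")
  attrs <- attributes(h)
  for (a in c("exposures", "outcome", "outcome_kind", "drops"))
    attr(out, a) <- attrs[[a]]
  class(out) <- class(h)
  attr(out, "steiger_excluded") <- excluded
  out
}
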