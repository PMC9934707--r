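# Per-variant association testing and summary-statistic QC.

#' Construct a summary-statistics table
#'
#' Standard per-variant association results for one trait in one cohort.
#' Columns follow the tab-delimited dialect used throughout the package:
#' `SNP, CHR, BP, EA, OA, EAF, BETA, SE, P, N` with optional `INFO` and a
#' logical `OK` convergence flag.
#'
#' @param df Data frame with at least the columns above (except `INFO`/`OK`).
#' @param trait Trait identifier.
#' @param kind `"quantitative"` (BETA in SD units per allele) or `"binary"`
#'   (BETA is a log odds ratio per allele).
#' @return A `sumstats` data frame with attributes `trait` and `kind`.
#' @export
sumstats <- function(df, trait, kind = c("quantitative", "binary")) {
  kind <- match.arg(kind)
  req <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  if (!all(req %in% names(df)))
    stop("summary statistics need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$SNP)) stop("duplicate variant ids", call. = FALSE)
  if (!"OK" %in% names(df)) df$OK <- TRUE
  structure(as.data.frame(df), trait = trait, kind = kind,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: trait '%s' (%s), %d variants\n",
              attr(x, "trait"), attr(x, "kind"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Genome-wide association scan on a dosage matrix
#'
#' Quantitative traits: the phenotype is residualised on the covariates by
#' ordinary least squares, optionally rank-inverse-normalised, and each
#' variant's effect is the simple-regression slope of the residualised
#' phenotype on dosage with a two-sided t-test (a deliberate substitution of
#' covariate-adjusted least squares for a linear mixed model; the simulated
#' cohorts carry no relatedness). Binary traits: per-variant logistic
#' regression of the outcome on dosage plus covariates, Wald p-values.
#'
#' Monomorphic variants are emitted with `BETA = 0`, `SE = Inf`, `P = NA` and
#' `OK = FALSE` so that downstream QC can drop them; non-converged or
#' separated logistic fits are flagged the same way.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Numeric vector (0/1 for binary), one value per
#'   individual.
#' @param covariates Optional data frame of covariates (numeric or factor).
#' @param kind `"quantitative"` or `"binary"`.
#' @param normalise If `TRUE`, rank-inverse-normalise the (residualised)
#'   quantitative phenotype before testing.
#' @param trait Trait label carried on the output.
#' @return A [sumstats()] table; `EAF` is recomputed from the dosages.
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL,
                     kind = c("quantitative", "binary"),
                     normalise = FALSE, trait = "trait") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  kind <- match.arg(kind)
  D <- genotypes$dosage
  n <- nrow(D)
  if (length(phenotype) != n)
    stop("phenotype length does not match genotype individuals",
         call. = FALSE)
  eaf <- colMeans(D) / 2
  v <- genotypes$variants

  if (kind == "quantitative") {
    y <- phenotype
    if (!is.null(covariates))
      y <- stats::residuals(stats::lm(y ~ ., data = as.data.frame(covariates)))
    if (normalise) y <- rank_inverse_normalise(y)
    yc <- y - mean(y)
    dm <- colMeans(D)
    Sxx <- colSums(D^2) - n * dm^2
    Sxy <- as.vector(crossprod(D, yc))
    Syy <- sum(yc^2)
    mono <- Sxx <= 0
    beta <- ifelse(mono, 0, Sxy / ifelse(mono, 1, Sxx))
    rss <- pmax(Syy - beta * Sxy, 0)
    se <- ifelse(mono, Inf, sqrt(rss / (n - 2) / ifelse(mono, 1, Sxx)))
    tstat <- beta / se
    p <- ifelse(mono, NA_real_, 2 * stats::pt(-abs(tstat), df = n - 2))
    ok <- !mono
  } else {
    if (!all(phenotype %in% c(0, 1)))
      stop("binary phenotype must be coded 0/1", call. = FALSE)
    cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
    m <- ncol(D)
    beta <- se <- p <- numeric(m)
    ok <- logical(m)
    for (j in seq_len(m)) {
      g <- D[, j]
      if (stats::var(g) == 0) {
        beta[j] <- 0; se[j] <- Inf; p[j] <- NA_real_; ok[j] <- FALSE
        next
      }
      dat <- if (is.null(cov_df)) data.frame(y = phenotype, g = g)
             else cbind(data.frame(y = phenotype, g = g), cov_df)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = dat, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      beta[j] <- cf["g", 1]; se[j] <- cf["g", 2]; p[j] <- cf["g", 4]
      # flag non-convergence / separation (exploding estimates)
      ok[j] <- fit$converged && abs(beta[j]) < 20 && se[j] < 100
    }
  }

  sumstats(data.frame(
    SNP = v$id, CHR = v$chr, BP = v$pos, EA = v$ea, OA = v$oa,
    EAF = eaf, BETA = beta, SE = se, P = p, N = n,
    INFO = if ("info" %in% names(v)) v$info else NA_real_,
    OK = ok, stringsAsFactors = FALSE
  ), trait = trait, kind = kind)
}

#' Quality-control filtering of summary statistics
#'
#' Retains variants with `maf_min < EAF < 1 - maf_min` and, where an INFO
#' imputation-quality column is present and non-missing, `INFO > info_min`.
#' Rows flagged `OK = FALSE` (monomorphic or non-converged fits) are also
#' removed. The filter is idempotent; counts removed per rule are attached
#' as attribute `removed`.
#'
#' @param stats A [sumstats()] table.
#' @param maf_min Minor/effect allele frequency bound (default 0.01, i.e.
#'   keep 0.01 < EAF < 0.99).
#' @param info_min INFO score bound (default 0.8, exclusive).
#' @return The filtered [sumstats()] table.
#' @export
qc_filter <- function(stats, maf_min = 0.01, info_min = 0.8) {
  stopifnot(inherits(stats, "sumstats"))
  if (nrow(stats) == 0L) {
    attr(stats, "removed") <- c(maf = 0L, info = 0L, not_ok = 0L)
    return(stats)
  }
  keep_maf <- stats$EAF > maf_min & stats$EAF < 1 - maf_min
  has_info <- "INFO" %in% names(stats) & !all(is.na(stats$INFO))
  keep_info <- if (has_info) is.na(stats$INFO) | stats$INFO > info_min
               else rep(TRUE, nrow(stats))
  keep_ok <- if ("OK" %in% names(stats)) stats$OK else rep(TRUE, nrow(stats))
  removed <- c(maf = sum(!keep_maf),
               info = sum(keep_maf & !keep_info),
               not_ok = sum(keep_maf & keep_info & !keep_ok))
  out <- stats[keep_maf & keep_info & keep_ok, , drop = FALSE]
  rownames(out) <- NULL
  out <- sumstats(out, trait = attr(stats, "trait"), kind = attr(stats, "kind"))
  attr(out, "removed") <- removed
  out
}
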