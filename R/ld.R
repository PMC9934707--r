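# Linkage-disequilibrium computation and greedy clumping of association
# signals into independent instruments.

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of the two variants' dosage vectors in a
#' reference panel.
#'
#' @param panel A [genotype_matrix()] reference panel.
#' @param variant_a,variant_b Variant ids present in the panel.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(panel, variant_a, variant_b) {
  stopifnot(inherits(panel, "genotype_matrix"))
  for (v in c(variant_a, variant_b))
    if (!v %in% panel$variants$id)
      stop("variant not in panel: ", v, call. = FALSE)
  a <- panel$dosage[, variant_a]
  b <- panel$dosage[, variant_b]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD undefined for a monomorphic variant", call. = FALSE)
  stats::cor(a, b)^2
}

#' Greedy LD clumping of association signals
#'
#' Defines independent genome-wide-significant instruments: repeatedly take
#' the smallest-p unassigned variant with `p <= p_thresh` as an index, and
#' assign to it every unassigned variant that lies within `window` base
#' pairs on the same chromosome OR is correlated with it at `r2 > r2_thresh`
#' (r-squared evaluated in the reference panel within a 1 Mb radius of the
#' index; beyond that radius it is treated as zero). Removal on distance
#' *or* correlation makes the retained index set satisfy both independence
#' criteria jointly: every same-chromosome index pair is >= `window` apart
#' and has `r2 <= r2_thresh`.
#'
#' Ties in p are broken by (chromosome, position, id) lexicographic order
#' for reproducibility. "Within `window`" uses a strict `< window`
#' comparison on 1-based positions.
#'
#' @param stats A [sumstats()] table (ideally post-[qc_filter()]).
#' @param panel [genotype_matrix()] reference panel sharing variant ids with
#'   `stats`.
#' @param p_thresh Index significance threshold (default 5e-8).
#' @param r2_thresh LD threshold between independent signals (default 0.001).
#' @param window Distance between independent signals in bp (default
#'   250000).
#' @return An object of class `clump_result`: a data frame of index variants
#'   (`SNP`, `CHR`, `BP`, `P`, `n_members`) sorted by ascending p, with a
#'   `members` attribute listing clumped-away variant ids per index and the
#'   thresholds used. No variant passing `p_thresh` yields an empty result.
#' @export
ld_clump <- function(stats, panel, p_thresh = 5e-8, r2_thresh = 0.001,
                     window = 250000) {
  stopifnot(inherits(stats, "sumstats"), inherits(panel, "genotype_matrix"))
  if (!all(stats$SNP %in% panel$variants$id))
    stop("all summary-statistic variants must be present in the panel",
         call. = FALSE)
  df <- as.data.frame(stats)
  ord <- order(df$P, df$CHR, df$BP, df$SNP)
  df <- df[ord, , drop = FALSE]
  m <- nrow(df)
  assigned <- rep(FALSE, m)

  # centred, scaled panel columns for fast correlations
  P <- panel$dosage[, df$SNP, drop = FALSE]
  P <- sweep(P, 2L, colMeans(P))
  sds <- sqrt(colSums(P^2))

  idx_rows <- integer(0)
  members <- list()
  for (i in seq_len(m)) {
    if (assigned[i] || is.na(df$P[i]) || df$P[i] > p_thresh) next
    assigned[i] <- TRUE
    cand <- which(!assigned & df$CHR == df$CHR[i])
    mem <- character(0)
    if (length(cand)) {
      dist <- abs(df$BP[cand] - df$BP[i])
      near <- dist < window
      r2 <- rep(0, length(cand))
      eval_r2 <- which(dist <= 1e6 & sds[cand] > 0 & sds[i] > 0)
      if (length(eval_r2) && sds[i] > 0) {
        r2[eval_r2] <- (as.vector(crossprod(P[, i], P[, cand[eval_r2],
                                                      drop = FALSE])) /
                          (sds[i] * sds[cand[eval_r2]]))^2
      }
      take <- near | r2 > r2_thresh
      if (any(take)) {
        assigned[cand[take]] <- TRUE
        mem <- df$SNP[cand[take]]
      }
    }
    idx_rows <- c(idx_rows, i)
    members[[df$SNP[i]]] <- mem
  }

  res <- df[idx_rows, c("SNP", "CHR", "BP", "P"), drop = FALSE]
  res$n_members <- vapply(res$SNP, function(s) length(members[[s]]),
                          integer(1))
  rownames(res) <- NULL
  structure(res, members = members,
            thresholds = list(p_thresh = p_thresh, r2_thresh = r2_thresh,
                              window = window),
            class = c("clump_result", "data.frame"))
}

#' @export
print.clump_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("clump_result: %d index variants (p <= %g, r2 <= %g, window %d bp)\n",
              nrow(x), th$p_thresh, th$r2_thresh, th$window))
  print(as.data.frame(x), ...)
  invisible(x)
}
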