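# Allele harmonisation and proxy-variant lookup for two-sample MR.

is_palindromic <- function(ea, oa) {
  pair <- paste(pmin(ea, oa), pmax(ea, oa), sep = "/")
  pair %in% c("A/T", "C/G")
}

# Decide orientation of one table's row against the reference alleles.
# Returns list(flip = TRUE/FALSE) or list(drop = reason).
orient_alleles <- function(ea, oa, eaf, ref_ea, ref_oa, ref_eaf,
                           eaf_ambiguity) {
  if (is_palindromic(ref_ea, ref_oa)) {
    if (!is_palindromic(ea, oa)) return(list(drop = "allele_mismatch"))
    if (abs(eaf - 0.5) <= eaf_ambiguity || abs(ref_eaf - 0.5) <= eaf_ambiguity)
      return(list(drop = "ambiguous"))
    return(list(flip = (eaf - 0.5) * (ref_eaf - 0.5) < 0))
  }
  if (ea == ref_ea && oa == ref_oa) return(list(flip = FALSE))
  if (ea == ref_oa && oa == ref_ea) return(list(flip = TRUE))
  list(drop = "allele_mismatch")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns every instrument variant present in all tables to a single effect
#' allele (the primary exposure's): direct allele matches are kept; swapped
#' allele pairs flip the other table's effect sign and allele frequency;
#' strand-ambiguous (palindromic A/T or C/G) variants are oriented by
#' allele-frequency agreement when both frequencies are clearly away from
#' 0.5 (`|EAF - 0.5| > eaf_ambiguity`) and dropped as ambiguous otherwise.
#' Unmatchable allele pairs are dropped with reason.
#'
#' @param exposure Primary-exposure [sumstats()] restricted to the
#'   instrument variants (e.g. clumped indices).
#' @param outcome Outcome [sumstats()].
#' @param exposure2 Optional secondary-exposure [sumstats()] for
#'   multivariable MR; every retained variant must carry an effect in it.
#' @param eaf_ambiguity Half-width of the frequency zone around 0.5 inside
#'   which palindromic variants cannot be oriented (default 0.08).
#' @param proxy_map Optional named character vector (index id -> proxy id)
#'   recording proxy substitutions performed by [proxy_substitute()];
#'   carried into the output's `proxy` column.
#' @return An object of class `harmonised_set`: a data frame with one row
#'   per retained variant (`SNP`, `EA`, `OA`, `EAF`, `beta_exp`, `se_exp`,
#'   optional `beta_exp2`/`se_exp2`, `beta_out`, `se_out`, `n_exp`, `n_out`,
#'   `proxy`) and attributes `exposures`, `outcome`, `outcome_kind` and
#'   `drops` (a data frame of dropped variants with reasons). Empty
#'   post-harmonisation sets are an error.
#' @export
harmonise <- function(exposure, outcome, exposure2 = NULL,
                      eaf_ambiguity = 0.08, proxy_map = NULL) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ids <- intersect(exposure$SNP, outcome$SNP)
  if (!is.null(exposure2)) ids <- intersect(ids, exposure2$SNP)
  drops <- data.frame(SNP = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  add_drop <- function(d, snp, reason)
    rbind(d, data.frame(SNP = snp, reason = reason, stringsAsFactors = FALSE))
  for (s in setdiff(exposure$SNP, ids))
    drops <- add_drop(drops, s, "absent_from_other_table")

  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    s <- ids[k]
    e <- exposure[exposure$SNP == s, ]
    o <- outcome[outcome$SNP == s, ]
    ori <- orient_alleles(o$EA, o$OA, o$EAF, e$EA, e$OA, e$EAF,
                          eaf_ambiguity)
    if (!is.null(ori$drop)) { drops <- add_drop(drops, s, ori$drop); next }
    b_out <- if (ori$flip) -o$BETA else o$BETA
    row <- data.frame(
      SNP = s, EA = e$EA, OA = e$OA, EAF = e$EAF,
      beta_exp = e$BETA, se_exp = e$SE,
      beta_out = b_out, se_out = o$SE,
      n_exp = e$N, n_out = o$N,
      proxy = if (!is.null(proxy_map) && s %in% names(proxy_map))
        unname(proxy_map[s]) else NA_character_,
      stringsAsFactors = FALSE
    )
    if (!is.null(exposure2)) {
      e2 <- exposure2[exposure2$SNP == s, ]
      ori2 <- orient_alleles(e2$EA, e2$OA, e2$EAF, e$EA, e$OA, e$EAF,
                             eaf_ambiguity)
      if (!is.null(ori2$drop)) { drops <- add_drop(drops, s, ori2$drop); next }
      row$beta_exp2 <- if (ori2$flip) -e2$BETA else e2$BETA
      row$se_exp2 <- e2$SE
      row$n_exp2 <- e2$N
    }
    rows[[k]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no variants remain after harmonisation", call. = FALSE)
  h <- do.call(rbind, rows)
  rownames(h) <- NULL
  exposures <- attr(exposure, "trait")
  if (!is.null(exposure2)) exposures <- c(exposures, attr(exposure2, "trait"))
  structure(h, exposures = exposures, outcome = attr(outcome, "trait"),
            outcome_kind = attr(outcome, "kind"), drops = drops,
            class = c("harmonised_set", "data.frame"))
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("harmonised_set: %d variants; exposure(s): %s; outcome: %s (%s)\n",
              nrow(x), paste(attr(x, "exposures"), collapse = " + "),
              attr(x, "outcome"), attr(x, "outcome_kind")))
  d <- attr(x, "drops")
  if (nrow(d)) cat(sprintf("  dropped %d variant(s): %s\n", nrow(d),
                           paste(names(table(d$reason)),
                                 table(d$reason), collapse = ", ")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Find a proxy variant for a missing instrument
#'
#' When an instrument is absent from the outcome table, searches the
#' outcome's variants on the same chromosome within `window` bp of the
#' index for the one most correlated with it in the reference panel, and
#' returns it if `r2 > r2_min`. The sign of the dosage correlation (with
#' both variants on their recorded effect alleles) is attached so the
#' proxy's effect can be oriented to the index.
#'
#' @param missing_variant Index variant id (must be in the panel).
#' @param outcome_table Outcome [sumstats()].
#' @param panel [genotype_matrix()] reference panel.
#' @param r2_min Minimum r-squared for an acceptable proxy (default 0.8,
#'   exclusive).
#' @param window Maximum index-proxy distance in bp (default 250000,
#'   inclusive).
#' @return The proxy variant id (character, with attributes `r2` and
#'   `sign`), or `NULL` if no candidate qualifies.
#' @export
find_proxy <- function(missing_variant, outcome_table, panel,
                       r2_min = 0.8, window = 250000) {
  stopifnot(inherits(panel, "genotype_matrix"))
  pv <- panel$variants
  i <- match(missing_variant, pv$id)
  if (is.na(i))
    stop("index variant absent from panel: ", missing_variant, call. = FALSE)
  cand <- pv$id[pv$chr == pv$chr[i] &
                  abs(pv$pos - pv$pos[i]) <= window &
                  pv$id != missing_variant]
  cand <- intersect(cand, outcome_table$SNP)
  if (!length(cand)) return(NULL)
  di <- panel$dosage[, missing_variant]
  if (stats::var(di) == 0) return(NULL)
  r <- vapply(cand, function(s) {
    d <- panel$dosage[, s]
    if (stats::var(d) == 0) return(0)
    stats::cor(di, d)
  }, numeric(1))
  best <- which.max(r^2)
  if (r[best]^2 <= r2_min) return(NULL)
  structure(cand[best], r2 = unname(r[best]^2), sign = unname(sign(r[best])))
}

#' Substitute proxies for instruments missing from an outcome table
#'
#' For each instrument id absent from the outcome summary statistics, looks
#' up the best proxy via [find_proxy()] and, if found, inserts a synthetic
#' outcome row under the index id: the proxy's effect (sign-oriented to the
#' index through the panel dosage correlation), standard error and sample
#' size, with the index's alleles and panel frequency.
#'
#' @inheritParams find_proxy
#' @param instrument_ids Character vector of instrument variant ids.
#' @param outcome_table Outcome [sumstats()].
#' @return List with `outcome` (augmented [sumstats()]) and `map` (named
#'   character vector, index id -> proxy id, possibly empty).
#' @export
proxy_substitute <- function(instrument_ids, outcome_table, panel,
                             r2_min = 0.8, window = 250000) {
  missing <- setdiff(instrument_ids, outcome_table$SNP)
  map <- character(0)
  out <- as.data.frame(outcome_table)
  pv <- panel$variants
  for (s in missing) {
    if (!s %in% pv$id) next
    pr <- find_proxy(s, outcome_table, panel, r2_min = r2_min,
                     window = window)
    if (is.null(pr)) next
    prow <- out[out$SNP == as.character(pr), , drop = FALSE]
    i <- match(s, pv$id)
    sgn <- attr(pr, "sign")
    prow$SNP <- s
    prow$CHR <- pv$chr[i]; prow$BP <- pv$pos[i]
    prow$EA <- pv$ea[i]; prow$OA <- pv$oa[i]
    prow$BETA <- sgn * prow$BETA
    prow$EAF <- if (sgn >= 0) prow$EAF else 1 - prow$EAF
    out <- rbind(out, prow)
    map[s] <- as.character(pr)
  }
  list(outcome = sumstats(out, trait = attr(outcome_table, "trait"),
                          kind = attr(outcome_table, "kind")),
       map = map)
}
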