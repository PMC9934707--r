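# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage substreams derived from one base seed.
# Offsets are fixed named constants so the same stage always draws the same
# stream; the modulus keeps seeds inside R's 32-bit integer range.
substream_seed <- function(seed, stream) {
  offsets <- c(
    panel = 11L, exposure_genotypes = 23L, outcome_genotypes = 37L,
    exposure_phenotypes = 53L, outcome_phenotypes = 71L,
    recall = 97L, grs = 113L, mr = 131L, ld_panel = 151L,
    extra_outcome = 173L
  )
  if (!stream %in% names(offsets)) stop("unknown random substream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]]) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf,
                                    strict = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok)
    stop(sprintf("'%s' = %g is outside %s%g, %g%s", name, x,
                 if (strict) "(" else "[", lo, hi,
                 if (strict) ")" else "]"), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# Truncated mean of a standard normal on (a, b); used by tests and docs as
# well as internally, hence lives here.
truncnorm_mean <- function(a, b) {
  (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}
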