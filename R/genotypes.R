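#' Genotype matrix container
#'
#' A light container for imputation-style dosage data: individual ids, a
#' variant record table (`id`, `chr`, `pos` (1-based), `ea`, `oa`, `eaf`,
#' optional `info`) and an individuals-by-variants dosage matrix with values
#' in \[0, 2\].
#'
#' @param ids Character vector of individual ids.
#' @param variants Data frame of variant records with at least columns
#'   `id`, `chr`, `pos`, `ea`, `oa`, `eaf`.
#' @param dosage Numeric matrix, `length(ids)` rows by `nrow(variants)`
#'   columns.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ids, variants, dosage) {
  ids <- as.character(ids)
  req <- c("id", "chr", "pos", "ea", "oa", "eaf")
  if (!all(req %in% names(variants)))
    stop("variant records need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != length(ids) || ncol(dosage) != nrow(variants))
    stop("dosage dimensions must match individual and variant counts",
         call. = FALSE)
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids", call. = FALSE)
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  for (c in unique(variants$chr)) {
    p <- variants$pos[variants$chr == c]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", c,
           call. = FALSE)
  }
  dimnames(dosage) <- list(ids, variants$id)
  structure(list(ids = ids, variants = variants, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              length(x$ids), nrow(x$variants)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Simulate genotype dosages under Hardy-Weinberg sampling
#'
#' Draws each variant's dosages as binomial(2, f) with allele frequency f
#' taken from the configuration's variant panel (frequencies uniform over
#' `maf_range`). Variants are mutually independent (no LD); use
#' [simulate_ld_panel()] for correlated reference panels.
#'
#' @param config A [sim_config()].
#' @param n_individuals Number of individuals to draw.
#' @param seed Seed for the dosage draws; defaults to the config seed.
#'   The variant panel itself is always derived from the config seed, so two
#'   calls with different `seed` share variants but not genotypes.
#' @param id_prefix Prefix for generated individual ids.
#' @return A [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(sim_config(seed = 1), 10)
#' dim(g)
#' @export
simulate_genotypes <- function(config, n_individuals,
                               seed = config$seed, id_prefix = "id") {
  stopifnot(inherits(config, "sim_config"))
  stopifnot_scalar_number(n_individuals, "n_individuals", lo = 1,
                          integer = TRUE)
  model <- draw_model(config)
  m <- nrow(model$variants)
  set.seed(seed %% 2147483647L)
  dosage <- matrix(stats::rbinom(n_individuals * m, 2L,
                                 rep(model$variants$eaf, each = n_individuals)),
                   nrow = n_individuals, ncol = m)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n_individuals))
  genotype_matrix(ids, model$variants, dosage)
}

#' Simulate a reference panel with linkage disequilibrium
#'
#' Builds blocks of correlated variants for exercising LD computation,
#' clumping and proxy lookup. Within a block, haplotypes of successive
#' variants are copied from their left neighbour and re-drawn with
#' probability `switch_prob`, giving adjacent-variant correlation about
#' `1 - switch_prob` that decays with distance in the block. Blocks are
#' mutually independent. Positions are drawn uniformly over `span_bp` on one
#' chromosome so that some correlated and uncorrelated pairs fall on either
#' side of typical distance windows.
#'
#' @param n_blocks Number of independent LD blocks.
#' @param block_size Variants per block.
#' @param n_individuals Panel size.
#' @param switch_prob Haplotype re-draw probability between adjacent variants.
#' @param maf_range Allele-frequency range for block founder variants.
#' @param span_bp Chromosome span over which positions are scattered.
#' @param chromosome Chromosome label.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_ld_panel <- function(n_blocks = 10, block_size = 5,
                              n_individuals = 1000, switch_prob = 0.1,
                              maf_range = c(0.1, 0.5), span_bp = 5e6,
                              chromosome = 1L, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(seed %% 2147483647L)
  m <- n_blocks * block_size
  h1 <- matrix(0L, n_individuals, m)
  h2 <- matrix(0L, n_individuals, m)
  col <- 0L
  for (b in seq_len(n_blocks)) {
    f <- stats::runif(1, maf_range[1], maf_range[2])
    a1 <- stats::rbinom(n_individuals, 1L, f)
    a2 <- stats::rbinom(n_individuals, 1L, f)
    for (k in seq_len(block_size)) {
      col <- col + 1L
      if (k > 1L) {
        sw1 <- stats::runif(n_individuals) < switch_prob
        sw2 <- stats::runif(n_individuals) < switch_prob
        a1 <- ifelse(sw1, stats::rbinom(n_individuals, 1L, f), a1)
        a2 <- ifelse(sw2, stats::rbinom(n_individuals, 1L, f), a2)
      }
      h1[, col] <- a1
      h2[, col] <- a2
    }
  }
  pos <- sort(sample.int(span_bp, m))
  variants <- data.frame(
    id = paste0("ld", seq_len(m)), chr = chromosome, pos = pos,
    ea = "A", oa = "G", eaf = colMeans(h1 + h2) / 2, info = 1,
    stringsAsFactors = FALSE
  )
  # guard against monomorphic columns (possible at small n): nudge one entry
  dos <- h1 + h2
  mono <- which(variants$eaf %in% c(0, 1))
  for (j in mono) {
    dos[1, j] <- ifelse(dos[1, j] > 0, dos[1, j] - 1L, 1L)
    variants$eaf[j] <- mean(dos[, j]) / 2
  }
  genotype_matrix(sprintf("p%06d", seq_len(n_individuals)), variants, dos)
}
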