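# Configuration-driven end-to-end pipeline:
# simulate -> reconstruct -> gwas -> clump -> grs -> mr -> report.
# Every stage reads its inputs from, and persists its outputs to, the run
# directory, so any stage can be re-run in isolation and reproduces its
# outputs bit-for-bit.

pipeline_defaults <- function() {
  list(
    seed = NULL,
    simulation = list(
      n_variants_child_specific = 50L, n_variants_adult_specific = 50L,
      n_variants_shared = 50L, maf_range = c(0.05, 0.5),
      effect_sd_child = 0.1, effect_sd_adult = 0.1, shared_effect_cor = 0.5,
      gamma_child_to_adult = 0.5, delta_child_direct = 0,
      delta_adult_direct = 0.6, confounder_strength = 0.2,
      pleiotropy_mean = 0, pleiotropy_sd = 0,
      n_exposure_cohort = 20000L, n_outcome_cohort = 20000L,
      outcome_kind = "quantitative", binary_prevalence = 0.1,
      recall_proportions = c(0.32, 0.51, 0.17),
      outcome_studies = 1L
    ),
    reference = list(mean = 17.8, sd = 2.6, family = "normal"),
    gwas = list(normalise = TRUE),
    qc = list(maf_min = 0.01, info_min = 0.8),
    clump = list(p_thresh = 5e-8, r2_thresh = 0.001, window = 250000),
    proxy = list(r2_min = 0.8, window = 250000),
    mr = list(eaf_ambiguity = 0.08, egger_flag_p = 0.01,
              se_method = "fixed")
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), merges it over the
#' documented defaults, enforces numeric ranges and rejects unknown keys
#' (error in strict mode, warning with `strict = FALSE`). The seed is
#' mandatory. The fully resolved configuration is what the run manifest
#' records.
#'
#' @param config Path to a YAML file, or a named list.
#' @param strict Treat unknown keys as errors (default) or warnings.
#' @return The resolved configuration, class `mr_config`.
#' @export
validate_config <- function(config, strict = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  defaults <- pipeline_defaults()

  complain <- function(msg) if (strict) stop(msg, call. = FALSE)
                            else warning(msg, call. = FALSE)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top))
    complain(paste("unknown config key(s):",
                   paste(unknown_top, collapse = ", ")))
  out <- defaults
  for (sec in intersect(names(config), names(defaults))) {
    if (sec == "seed") { out$seed <- config$seed; next }
    unknown <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      complain(paste0("unknown key(s) in '", sec, "': ",
                      paste(unknown, collapse = ", ")))
    for (k in intersect(names(config[[sec]]), names(defaults[[sec]])))
      out[[sec]][[k]] <- config[[sec]][[k]]
  }
  if (is.null(out$seed)) stop("seed required", call. = FALSE)
  stopifnot_scalar_number(out$seed, "seed", integer = TRUE)

  stopifnot_scalar_number(out$clump$p_thresh, "clump$p_thresh", 0, 1,
                          strict = FALSE)
  if (out$clump$p_thresh <= 0) stop("clump$p_thresh must be > 0",
                                    call. = FALSE)
  stopifnot_scalar_number(out$clump$r2_thresh, "clump$r2_thresh", 0, 1)
  stopifnot_scalar_number(out$clump$window, "clump$window", lo = 1)
  stopifnot_scalar_number(out$proxy$r2_min, "proxy$r2_min", 0, 1)
  stopifnot_scalar_number(out$proxy$window, "proxy$window", lo = 1)
  stopifnot_scalar_number(out$qc$maf_min, "qc$maf_min", 0, 0.5)
  stopifnot_scalar_number(out$qc$info_min, "qc$info_min", 0, 1)
  stopifnot_scalar_number(out$mr$eaf_ambiguity, "mr$eaf_ambiguity", 0, 0.5)
  stopifnot_scalar_number(out$mr$egger_flag_p, "mr$egger_flag_p", 0, 1)
  stopifnot_scalar_number(out$simulation$outcome_studies,
                          "simulation$outcome_studies", lo = 1,
                          integer = TRUE)
  if (!out$reference$family %in% c("normal", "lognormal"))
    stop("reference$family must be 'normal' or 'lognormal'", call. = FALSE)
  # validate simulation block by constructing the config object
  sim_args <- out$simulation
  sim_args$outcome_studies <- NULL
  do.call(sim_config, c(sim_args, list(seed = out$seed)))
  structure(out, class = "mr_config")
}

config_sim <- function(cfg) {
  sim_args <- cfg$simulation
  sim_args$outcome_studies <- NULL
  do.call(sim_config, c(sim_args, list(seed = cfg$seed)))
}

pipeline_covariates <- function(ph)
  data.frame(sex = ph$sex, age = ph$age, centre = factor(ph$centre))

outcome_file <- function(dir, s, what)
  file.path(dir, sprintf("outcome%d_%s", s, what))

#' Run the lifecourse MR pipeline
#'
#' Executes the requested stages in order, reading each stage's inputs from
#' and writing its outputs to `out_dir`:
#'
#' 1. `simulate` — two-sample study under the causal diagram; genotypes as
#'    VCF (DS dosages), phenotypes as TSV. Additional outcome studies
#'    (`simulation$outcome_studies`) share the variant panel.
#' 2. `reconstruct` — continuous childhood BMI from recall categories
#'    anchored to the reference distribution, added to the exposure
#'    phenotype table as `child_bmi_recon`.
#' 3. `gwas` — rank-inverse-normalised, covariate-residualised GWAS of the
#'    reconstructed childhood and measured adulthood BMI in the exposure
#'    cohort, and of the outcome in each outcome cohort.
#' 4. `clump` — QC filtering and greedy LD clumping of each exposure GWAS
#'    (LD panel: the exposure cohort).
#' 5. `grs` — genetic-risk-score validation of both instrument sets in the
#'    outcome cohort (regression R2, closed-form variance explained,
#'    extreme-value AUC/OR, F-statistics), including cross-prediction of
#'    the other time point's phenotype.
#' 6. `mr` — per outcome study: univariable IVW and MR-Egger for each
#'    exposure, Steiger-filtered IVW, and MVMR on the jointly re-clumped
#'    union of both instrument sets; proxy substitution for instruments
#'    missing from the outcome table; fixed-effect meta-analysis across
#'    outcome studies when there are several.
#' 7. `report` — human-readable exposure-by-outcome table of univariable
#'    and multivariable estimates (odds ratios for binary outcomes).
#'
#' A JSON run manifest (resolved config, per-stage seeds, thresholds,
#' variant counts in/out of every filter, output checksums and timings) is
#' updated as stages complete.
#'
#' @param config Path to YAML config, list, or a resolved `mr_config`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @param strict Passed to [validate_config()].
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = "all", strict = TRUE) {
  cfg <- if (inherits(config, "mr_config")) config
         else validate_config(config, strict = strict)
  all_stages <- c("simulate", "reconstruct", "gwas", "clump", "grs", "mr",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else list(config = unclass(cfg), stages = list())

  for (st in stages) {
    t0 <- Sys.time()
    info <- tryCatch(
      switch(st,
        simulate = stage_simulate(cfg, out_dir),
        reconstruct = stage_reconstruct(cfg, out_dir),
        gwas = stage_gwas(cfg, out_dir),
        clump = stage_clump(cfg, out_dir),
        grs = stage_grs(cfg, out_dir),
        mr = stage_mr(cfg, out_dir),
        report = stage_report(cfg, out_dir)
      ),
      error = function(e) {
        done <- names(manifest$stages)
        stop(sprintf("pipeline stage '%s' failed: %s (completed stages: %s)",
                     st, conditionMessage(e),
                     if (length(done)) paste(done, collapse = ", ")
                     else "none"), call. = FALSE)
      })
    info$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    info$checksums <- as.list(tools::md5sum(
      file.path(out_dir, info$outputs %||% character(0))))
    manifest$stages[[st]] <- info
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  invisible(out_dir)
}

stage_simulate <- function(cfg, dir) {
  sim <- config_sim(cfg)
  study <- make_two_sample_studies(sim)
  write_genotypes_vcf(study$exposure$genotypes,
                      file.path(dir, "exposure.vcf.gz"))
  write_phenotypes(study$exposure$phenotypes,
                   file.path(dir, "exposure_phenotypes.tsv"))
  outputs <- c("exposure.vcf.gz", "exposure_phenotypes.tsv")
  n_studies <- cfg$simulation$outcome_studies
  cohorts <- list(study$outcome)
  if (n_studies > 1L) {
    for (s in 2:n_studies) {
      g <- simulate_genotypes(sim, sim$n_outcome_cohort,
                              seed = substream_seed(sim$seed, "extra_outcome") + s,
                              id_prefix = sprintf("out%d_", s))
      p <- simulate_phenotypes(g, sim,
                               seed = substream_seed(sim$seed, "extra_outcome") + 1000L + s)
      cohorts[[s]] <- list(genotypes = g, phenotypes = p)
    }
  }
  for (s in seq_len(n_studies)) {
    write_genotypes_vcf(cohorts[[s]]$genotypes,
                        outcome_file(dir, s, "genotypes.vcf.gz"))
    write_phenotypes(cohorts[[s]]$phenotypes,
                     outcome_file(dir, s, "phenotypes.tsv"))
    outputs <- c(outputs, sprintf("outcome%d_genotypes.vcf.gz", s),
                 sprintf("outcome%d_phenotypes.tsv", s))
  }
  list(outputs = outputs,
       seeds = list(base = cfg$seed),
       n_variants = nrow(study$exposure$genotypes$variants))
}

stage_reconstruct <- function(cfg, dir) {
  ph <- read_phenotypes(file.path(dir, "exposure_phenotypes.tsv"))
  refdist <- fit_reference_distribution(
    cfg$reference$mean, cfg$reference$sd, cfg$reference$family,
    cfg$simulation$recall_proportions)
  ph$child_bmi_recon <- assign_continuous_bmi(
    ph$recall, refdist, seed = substream_seed(cfg$seed, "recall"))
  write_phenotypes(ph, file.path(dir, "exposure_phenotypes.tsv"))
  list(outputs = "exposure_phenotypes.tsv",
       seeds = list(recall = substream_seed(cfg$seed, "recall")),
       refdist = list(mean = refdist$mean, sd = refdist$sd,
                      family = refdist$family,
                      category_quantiles = refdist$category_quantiles))
}

stage_gwas <- function(cfg, dir) {
  g <- read_genotypes_vcf(file.path(dir, "exposure.vcf.gz"))
  ph <- read_phenotypes(file.path(dir, "exposure_phenotypes.tsv"))
  if (!"child_bmi_recon" %in% names(ph))
    stop("run the 'reconstruct' stage first")
  covs <- pipeline_covariates(ph)
  gw_child <- run_gwas(g, ph$child_bmi_recon, covs,
                       normalise = cfg$gwas$normalise, trait = "child_bmi")
  gw_adult <- run_gwas(g, ph$adult_bmi, covs,
                       normalise = cfg$gwas$normalise, trait = "adult_bmi")
  write_sumstats(gw_child, file.path(dir, "gwas_child.tsv"))
  write_sumstats(gw_adult, file.path(dir, "gwas_adult.tsv"))
  outputs <- c("gwas_child.tsv", "gwas_adult.tsv")
  kind <- cfg$simulation$outcome_kind
  for (s in seq_len(cfg$simulation$outcome_studies)) {
    go <- read_genotypes_vcf(outcome_file(dir, s, "genotypes.vcf.gz"))
    po <- read_phenotypes(outcome_file(dir, s, "phenotypes.tsv"))
    gw_out <- run_gwas(go, po$outcome, pipeline_covariates(po), kind = kind,
                       normalise = (kind == "quantitative") &&
                         cfg$gwas$normalise,
                       trait = sprintf("outcome_study%d", s))
    write_sumstats(gw_out, outcome_file(dir, s, "gwas.tsv"))
    outputs <- c(outputs, sprintf("outcome%d_gwas.tsv", s))
  }
  list(outputs = outputs, n = nrow(ph))
}

stage_clump <- function(cfg, dir) {
  panel <- read_genotypes_vcf(file.path(dir, "exposure.vcf.gz"))
  counts <- list()
  for (tr in c("child", "adult")) {
    gw <- read_sumstats(file.path(dir, sprintf("gwas_%s.tsv", tr)),
                        trait = paste0(tr, "_bmi"))
    qcd <- qc_filter(gw, cfg$qc$maf_min, cfg$qc$info_min)
    cl <- ld_clump(qcd, panel, cfg$clump$p_thresh, cfg$clump$r2_thresh,
                   cfg$clump$window)
    write_clump(cl, file.path(dir, sprintf("clump_%s.tsv", tr)))
    counts[[tr]] <- list(input = nrow(gw), post_qc = nrow(qcd),
                         qc_removed = as.list(attr(qcd, "removed")),
                         indices = nrow(cl))
  }
  list(outputs = c("clump_child.tsv", "clump_adult.tsv"),
       thresholds = cfg$clump, counts = counts)
}

read_instruments <- function(dir, tr) {
  cl <- utils::read.delim(file.path(dir, sprintf("clump_%s.tsv", tr)),
                          stringsAsFactors = FALSE)
  gw <- read_sumstats(file.path(dir, sprintf("gwas_%s.tsv", tr)),
                      trait = paste0(tr, "_bmi"))
  list(ids = cl$SNP, stats = gw)
}

stage_grs <- function(cfg, dir) {
  g <- read_genotypes_vcf(outcome_file(dir, 1L, "genotypes.vcf.gz"))
  po <- read_phenotypes(outcome_file(dir, 1L, "phenotypes.tsv"))
  rows <- list(); metrics <- list()
  for (tr in c("child", "adult")) {
    ins <- read_instruments(dir, tr)
    if (!length(ins$ids)) next
    w <- ins$stats[ins$stats$SNP %in% ins$ids, , drop = FALSE]
    w <- sumstats(w, attr(ins$stats, "trait"), attr(ins$stats, "kind"))
    score <- build_grs(g, w)
    for (phn in c("child_bmi_true", "adult_bmi")) {
      ext <- extreme_prediction(score, po[[phn]])
      r2 <- grs_regression_r2(score, po[[phn]])
      rows[[length(rows) + 1L]] <- data.frame(
        score = paste0(tr, "_bmi_grs"), phenotype = phn,
        n = length(score), n_variants = nrow(w),
        r2_regression = r2,
        var_explained_formula = variance_explained_formula(w$BETA, w$EAF),
        auc = ext$auc, odds_ratio_per_sd = ext$odds_ratio_per_sd,
        or_ci_low = ext$ci_low, or_ci_high = ext$ci_high, or_p = ext$p,
        f_statistic = instrument_f_statistic(r2, length(score), nrow(w)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no instruments survived clumping; cannot build scores")
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "grs_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, file.path(dir, "grs_metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(outputs = c("grs_report.tsv", "grs_metrics.json"))
}

stage_mr <- function(cfg, dir) {
  kind <- cfg$simulation$outcome_kind
  child <- read_instruments(dir, "child")
  adult <- read_instruments(dir, "adult")
  panel <- read_genotypes_vcf(file.path(dir, "exposure.vcf.gz"))
  # MVMR instrument set: union of both exposures' indices, re-clumped
  # jointly on the smaller p across exposures so the union is independent.
  union_ids <- union(child$ids, adult$ids)
  drops_log <- list()
  mv_ids <- character(0)
  if (length(union_ids) >= 3L) {
    comb <- as.data.frame(child$stats[child$stats$SNP %in% union_ids, ])
    pa <- adult$stats$P[match(comb$SNP, adult$stats$SNP)]
    comb$P <- pmin(comb$P, pa, na.rm = TRUE)
    comb <- sumstats(comb, "union", "quantitative")
    mv_ids <- ld_clump(comb, panel, p_thresh = 1, cfg$clump$r2_thresh,
                       cfg$clump$window)$SNP
  }
  results <- list()
  for (s in seq_len(cfg$simulation$outcome_studies)) {
    out_stats <- read_sumstats(outcome_file(dir, s, "gwas.tsv"),
                               trait = sprintf("outcome_study%d", s),
                               kind = kind)
    out_panel <- read_genotypes_vcf(outcome_file(dir, s, "genotypes.vcf.gz"))
    study_lab <- sprintf("study%d", s)
    for (tr in c("child", "adult")) {
      ins <- if (tr == "child") child else adult
      if (length(ins$ids) < 1L) next
      exp_stats <- sumstats(
        as.data.frame(ins$stats[ins$stats$SNP %in% ins$ids, ]),
        attr(ins$stats, "trait"), attr(ins$stats, "kind"))
      pr <- proxy_substitute(ins$ids, out_stats, out_panel,
                             cfg$proxy$r2_min, cfg$proxy$window)
      h <- harmonise(exp_stats, pr$outcome,
                     eaf_ambiguity = cfg$mr$eaf_ambiguity,
                     proxy_map = pr$map)
      drops_log[[paste(tr, study_lab, sep = "_")]] <-
        as.list(table(attr(h, "drops")$reason))
      fit_i <- mr_fit(h, "ivw", se_method = cfg$mr$se_method)
      rws <- fit_i$results
      if (nrow(h) >= 3L) rws <- rbind(rws, mr_fit(h, "egger")$results)
      hs <- steiger_filter(h)
      if (nrow(hs) >= 1L) {
        st <- mr_fit(hs, "ivw", se_method = cfg$mr$se_method)$results
        st$method <- paste0(st$method, "_steiger")
        rws <- rbind(rws, st)
      }
      rws$study <- study_lab
      results[[length(results) + 1L]] <- rws
    }
    if (length(mv_ids) >= 3L) {
      exp1 <- sumstats(as.data.frame(
        child$stats[child$stats$SNP %in% mv_ids, ]), "child_bmi",
        "quantitative")
      exp2 <- sumstats(as.data.frame(
        adult$stats[adult$stats$SNP %in% mv_ids, ]), "adult_bmi",
        "quantitative")
      pr <- proxy_substitute(mv_ids, out_stats, out_panel,
                             cfg$proxy$r2_min, cfg$proxy$window)
      hmv <- harmonise(exp1, pr$outcome, exposure2 = exp2,
                       eaf_ambiguity = cfg$mr$eaf_ambiguity,
                       proxy_map = pr$map)
      if (nrow(hmv) >= 3L) {
        rws <- mr_fit(hmv, "mvmr")$results
        rws$study <- study_lab
        results[[length(results) + 1L]] <- rws
      }
    }
  }
  res <- do.call(rbind, results)
  # meta-analysis across outcome studies
  if (cfg$simulation$outcome_studies > 1L) {
    for (me in unique(res$method)) {
      if (me == "egger_intercept") next
      for (ex in unique(res$exposure[res$method == me])) {
        sub <- res[res$method == me & res$exposure == ex &
                     !is.na(res$estimate), , drop = FALSE]
        if (nrow(sub) < 2L) next
        mrow <- fixed_effect_meta(sub)
        mrow$method <- paste0("meta_", me)
        mrow$study <- "meta"
        res <- rbind(res, mrow)
      }
    }
  }
  res$flag_pleiotropy <- res$method == "egger_intercept" &
    !is.na(res$p) & res$p < cfg$mr$egger_flag_p
  res <- res[, c("method", "exposure", "outcome", "study", "estimate",
                 "se", "ci_low", "ci_high", "p", "n_variants",
                 "f_statistic", "scale", "flag_pleiotropy")]
  utils::write.table(res, file.path(dir, "mr_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = list(clump = cfg$clump, proxy = cfg$proxy,
                           qc = cfg$qc, mr = cfg$mr),
         mvmr_instruments = mv_ids, harmonisation_drops = drops_log),
    file.path(dir, "mr_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(outputs = c("mr_results.tsv", "mr_manifest.json"),
       n_results = nrow(res))
}

stage_report <- function(cfg, dir) {
  res <- utils::read.delim(file.path(dir, "mr_results.tsv"),
                           stringsAsFactors = FALSE)
  binary <- any(res$scale == "log_or")
  fmt <- function(rw) {
    if (!nrow(rw) || is.na(rw$estimate[1])) return("-")
    if (binary && rw$scale[1] == "log_or") {
      o <- to_odds_ratio(rw[1, ])
      sprintf("OR %.3f [%.3f, %.3f]", o$estimate, o$ci_low, o$ci_high)
    } else
      sprintf("%.3f [%.3f, %.3f]", rw$estimate[1], rw$ci_low[1],
              rw$ci_high[1])
  }
  pick <- function(me, ex, st) {
    res[res$method == me & res$exposure == ex & res$study == st, ,
        drop = FALSE]
  }
  studies <- unique(res$study)
  rows <- list()
  for (st in studies) {
    for (ex in unique(res$exposure)) {
      uni <- pick(if (st == "meta") "meta_ivw" else "ivw", ex, st)
      mv <- pick(if (st == "meta") "meta_mvmr" else "mvmr", ex, st)
      if (!nrow(uni) && !nrow(mv)) next
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = ex,
        outcome = if (nrow(uni)) uni$outcome[1] else mv$outcome[1],
        study = st, mr = fmt(uni), mvmr = fmt(mv),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(outputs = "report.tsv")
}
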