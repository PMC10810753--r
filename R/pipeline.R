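#' Pipeline configuration
#'
#' Collects every constant of the end-to-end analysis in one list: pedigree
#' size, generating biometric structure, gaze rendering settings, validity
#' thresholds, the exploration window, chance level, FDR target and output
#' directory. Defaults mirror the study dimensions this pipeline emulates:
#' 155 MZ and 130 DZ same-sex pairs with about 12% incomplete pairs, six
#' 20 s trials at 120 Hz, validity thresholds of 25% valid samples / 5 s
#' valid data / at least one AOI look, at least four valid trials per
#' infant, a 10 s exploration window, chance level 1/5, and a generating
#' bivariate AE structure with orienting heritability 0.19, preference A
#' split 0.16 shared / 0.29 unique, and 97% of preference E unique.
#'
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @param n_mz,n_dz Twin-pair counts.
#' @param incomplete_rate Proportion of single-twin pairs.
#' @param spec Generating `twin_spec` (2 traits: orienting, preference).
#' @param gaze [gaze_params()] list.
#' @param scenes Scene list.
#' @param min_valid_prop,min_valid_s,min_valid_trials Validity thresholds.
#' @param explore_window_ms Exploration window (ms).
#' @param outcome_beta Generating standardized slope of the simulated
#'   longitudinal outcome on face preference.
#' @param outcome_resid_icc Exchangeable within-pair residual correlation of
#'   the outcome.
#' @param fdr_q FDR target.
#' @param profile_cis Compute profile-likelihood CIs in the twin stages
#'   (slower).
#' @param write_raw_gaze Also write the rendered gaze streams to CSV.
#' @param out_dir Output directory (`NULL`: return results only).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_mz = 155L, n_dz = 130L,
                            incomplete_rate = 0.12,
                            spec = bivariate_ae_spec(0.19, 0.16, 0.29, 0.97),
                            gaze = gaze_params(), scenes = default_scenes(),
                            min_valid_prop = 0.25, min_valid_s = 5,
                            min_valid_trials = 4L,
                            explore_window_ms = 10000,
                            outcome_beta = 0.14, outcome_resid_icc = 0.3,
                            fdr_q = 0.05, profile_cis = FALSE,
                            write_raw_gaze = FALSE, out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_mz = as.integer(n_mz),
              n_dz = as.integer(n_dz), incomplete_rate = incomplete_rate,
              spec = spec, gaze = gaze, scenes = scenes,
              min_valid_prop = min_valid_prop, min_valid_s = min_valid_s,
              min_valid_trials = as.integer(min_valid_trials),
              explore_window_ms = explore_window_ms,
              chance = chance_level(scenes[[1]]),
              outcome_beta = outcome_beta,
              outcome_resid_icc = outcome_resid_icc,
              fdr_q = fdr_q, profile_cis = profile_cis,
              write_raw_gaze = write_raw_gaze, out_dir = out_dir)
  stopifnot(cfg$min_valid_prop > 0, cfg$min_valid_s > 0,
            cfg$min_valid_trials > 0)
  structure(cfg, class = "pipeline_config")
}

#' Write or read the scalar part of a pipeline configuration as YAML
#'
#' Serialises every scalar setting (seeds, sizes, thresholds, generating
#' standardized components); scenes and function-valued settings are
#' reconstructed from defaults on read.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_yaml` returns a `pipeline_config`.
#' @export
write_pipeline_yaml <- function(config, path) {
  scal <- config[c("seed", "n_mz", "n_dz", "incomplete_rate",
                   "min_valid_prop", "min_valid_s", "min_valid_trials",
                   "explore_window_ms", "outcome_beta", "outcome_resid_icc",
                   "fdr_q", "profile_cis", "write_raw_gaze")]
  scal$gaze <- unclass(config$gaze)
  yaml::write_yaml(scal, path)
  invisible(path)
}

#' @rdname write_pipeline_yaml
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  gz <- do.call(gaze_params, y$gaze)
  y$gaze <- NULL
  do.call(pipeline_config, c(y, list(gaze = gz)))
}

#' Reshape per-infant phenotypes into a pair-structured twin dataset
#'
#' Twin order within a pair follows ascending `infant_id`; pairs with a
#' single retained infant keep the co-twin's traits as `NA` (handled by
#' FIML downstream).
#'
#' @param phenotypes Data frame with `infant_id, pair_id, zygosity,
#'   age_days, sex` and the trait columns.
#' @param traits Trait column names.
#' @return A `twin_data` object.
#' @export
phenotypes_to_twin_data <- function(phenotypes,
                                    traits = c("face_orienting",
                                               "face_preference")) {
  sp <- split(phenotypes, phenotypes$pair_id)
  rows <- lapply(sp, function(p) {
    p <- p[order(p$infant_id), ]
    out <- data.frame(pair_id = p$pair_id[1], zygosity = p$zygosity[1],
                      age_days = p$age_days[1], sex = p$sex[1],
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      out[[paste0(tr, "_t1")]] <- p[[tr]][1]
      out[[paste0(tr, "_t2")]] <- if (nrow(p) > 1) p[[tr]][2] else NA_real_
    }
    out
  })
  twin_pair_dataset(do.call(rbind, rows), traits = traits)
}

# univariate + bivariate model battery on one twin dataset
.model_battery <- function(td, profile_cis = FALSE) {
  full <- fit_model(td, c("A", "C", "E"))
  nested <- list(AE = fit_model(td, c("A", "E")),
                 CE = fit_model(td, c("C", "E")),
                 E = fit_model(td, "E"))
  comparisons <- lapply(names(nested), function(nm)
    compare_models(full, nested[[nm]], label = nm))
  names(comparisons) <- names(nested)
  sel <- select_best(comparisons)
  std <- standardize_components(sel$fit, ci = profile_cis)
  list(full = full, nested = nested, comparisons = comparisons,
       selected = sel, decomposition = std)
}

#' Run the full simulate-extract-model-associate pipeline
#'
#' Executes every stage on synthetic data: twin-pedigree simulation, gaze
#' rendering (in pair chunks to bound memory), phenotype extraction with
#' validity filtering, gaze-quality adjustment, descriptive statistics and
#' chance tests, univariate and bivariate twin-model batteries with
#' nested-model selection, simulated longitudinal outcomes analysed by
#' cluster-robust estimating equations, and FDR control. Progress and
#' filter casualty counts are logged via `message()`. With `out_dir` set,
#' per-stage CSV/JSON files and a plain-text report are written; reruns
#' with the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return List with the per-stage results (`phenotypes`, `qc`,
#'   `descriptives`, `chance_tests`, `quality_log`, `correlations`,
#'   `univariate`, `bivariate`, `gee`, `fdr`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  message("[simulate] pedigree: ", config$n_mz, " MZ + ", config$n_dz, " DZ pairs")
  twins <- simulate_twin_phenotypes(config$spec, config$n_mz, config$n_dz,
                                    config$incomplete_rate, seed = seed + 1L)

  message("[render+extract] gaze streams at ",
          config$gaze$sampling_rate_hz, " Hz, ",
          config$gaze$n_trials, " trials x ",
          config$gaze$trial_duration_s, " s")
  chunks <- split(seq_len(nrow(twins)),
                  ceiling(seq_len(nrow(twins)) / 20))
  phen_parts <- list(); qc_parts <- list()
  raw_path <- if (!is.null(out_dir) && config$write_raw_gaze)
    file.path(out_dir, "gaze_raw.csv") else NULL
  for (ci in seq_along(chunks)) {
    sub <- twins[chunks[[ci]], ]
    attr(sub, "traits") <- attr(twins, "traits")
    class(sub) <- class(twins)
    gaze <- simulate_gaze_cohort(sub, config$gaze, config$scenes,
                                 seed = seed + 1000L + ci)
    if (!is.null(raw_path)) write_gaze_csv(gaze, raw_path, append = ci > 1)
    ext <- extract_phenotypes(gaze, config$scenes,
                              demographics = attr(gaze, "truth")[
                                c("infant_id", "age_days", "sex")],
                              min_valid_prop = config$min_valid_prop,
                              min_valid_s = config$min_valid_s,
                              min_valid_trials = config$min_valid_trials,
                              explore_window_ms = config$explore_window_ms)
    phen_parts[[ci]] <- ext$phenotypes
    qc_parts[[ci]] <- ext$qc
  }
  phen <- do.call(rbind, phen_parts)
  qc <- do.call(rbind, qc_parts)
  n_infants_rendered <- sum(twins$present_t1) + sum(twins$present_t2)
  message("[filter] trials excluded: ", sum(!qc$valid), " of ", nrow(qc),
          "; infants excluded (<", config$min_valid_trials,
          " valid trials): ", n_infants_rendered - nrow(phen))

  message("[quality] gaze-quality screening")
  qual <- regress_out_quality(phen)
  phen_adj <- qual$phenotypes

  measures <- c("face_orienting", "face_preference", "exploration")
  descr <- do.call(rbind, lapply(measures, function(m) data.frame(
    measure = m, mean = mean(phen[[m]]), sd = sd(phen[[m]]),
    min = min(phen[[m]]), max = max(phen[[m]]),
    skewness = skewness_coef(phen[[m]]), stringsAsFactors = FALSE)))
  twin_no <- ifelse(grepl("_1$", phen_adj$infant_id), 1L, 2L)
  chance_tests <- list()
  for (m in c("face_orienting", "face_preference"))
    for (tw in 1:2)
      chance_tests[[paste0(m, "_twin", tw)]] <-
        test_against_chance(phen_adj[[m]][twin_no == tw], config$chance)

  message("[twin models] univariate batteries")
  uni <- list()
  for (m in measures) {
    td <- phenotypes_to_twin_data(phen_adj, traits = m)
    uni[[m]] <- .model_battery(td, config$profile_cis)
  }
  message("[twin models] bivariate battery (orienting x preference)")
  td2 <- phenotypes_to_twin_data(phen_adj,
                                 traits = c("face_orienting",
                                            "face_preference"))
  corr <- twin_correlations(td2, ci = config$profile_cis)
  sat_free <- fit_saturated(td2)
  biv <- .model_battery(td2, config$profile_cis)
  sat_check <- compare_models(sat_free, biv$full, label = "ACE vs fully sat.")

  message("[associate] simulated outcome, cluster-robust GEE")
  phen_adj$age_scaled <- as.numeric(scale(phen_adj$age_days))
  outc <- simulate_outcomes(phen_adj, "face_preference",
                            beta = config$outcome_beta,
                            resid_icc = config$outcome_resid_icc,
                            seed = seed + 5L)
  gee <- gee_fit(outc, outcome = "outcome", predictors = measures,
                 covariates = c("age_scaled", "sex"), cluster = "pair_id")
  fdr <- cbind(gee$coefficients[c("term", "p")],
               fdr_stepup(gee$coefficients$p, config$fdr_q)[
                 c("rank", "threshold", "significant")])

  res <- list(config = config, twins = twins, phenotypes = phen,
              phenotypes_adjusted = phen_adj, qc = qc,
              quality_log = qual$log, descriptives = descr,
              chance_tests = chance_tests, correlations = corr,
              univariate = uni, bivariate = biv,
              bivariate_sat_check = sat_check, gee = gee, fdr = fdr)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  write_phenotypes_csv(res$phenotypes, file.path(out_dir, "phenotypes.csv"))
  write.csv(res$qc, file.path(out_dir, "trial_qc.csv"), row.names = FALSE)
  write.csv(res$descriptives, file.path(out_dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(res$correlations, file.path(out_dir, "twin_correlations.csv"),
            row.names = FALSE)
  write_fit_json(res$bivariate$full,
                 file.path(out_dir, "bivariate_ace.json"),
                 comparisons = res$bivariate$comparisons)
  write.csv(res$fdr, file.path(out_dir, "gee_fdr.csv"), row.names = FALSE)
  rep_path <- file.path(out_dir, "report.txt")
  con <- file(rep_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Twin gaze pipeline report (seed %d)", res$config$seed)
  w("")
  w("Descriptives (n = %d infants):", nrow(res$phenotypes))
  for (r in seq_len(nrow(res$descriptives)))
    w("  %-18s mean %.6g sd %.6g range %.6g-%.6g skewness %.6g",
      res$descriptives$measure[r], res$descriptives$mean[r],
      res$descriptives$sd[r], res$descriptives$min[r],
      res$descriptives$max[r], res$descriptives$skewness[r])
  w("")
  w("Twin correlations:")
  for (r in seq_len(nrow(res$correlations)))
    w("  %-24s %-28s %s  %.3f", res$correlations$quantity[r],
      res$correlations$trait[r], res$correlations$zygosity[r],
      res$correlations$estimate[r])
  w("")
  w("Bivariate model comparison (full ACE: -2LL %.6g, %d params, AIC %.6g):",
    res$bivariate$full$minus2LL, res$bivariate$full$n_params,
    res$bivariate$full$AIC)
  for (nm in names(res$bivariate$comparisons)) {
    cp <- res$bivariate$comparisons[[nm]]
    w("  %-3s -2LL %.6g params %d df %d AIC %.6g  dchi2 %.6g ddf %d p %.4g",
      nm, cp$nested$minus2LL, cp$nested$n_params, cp$nested$df,
      cp$nested$AIC, cp$delta_chi2, cp$delta_df, cp$p_value)
  }
  w("  selected: %s", res$bivariate$selected$label)
  biv <- res$bivariate$decomposition
  if (!is.null(biv$bivariate)) {
    a <- biv$bivariate[biv$bivariate$component == "A", ]
    if (nrow(a))
      w("  preference A split: shared %.6g, unique %.6g; implied r_Ph %.6g",
        a$shared, a$unique, biv$r_Ph)
  }
  w("")
  w("GEE associations (outcome on looking measures; cluster-robust):")
  for (r in seq_len(nrow(res$fdr)))
    w("  %-18s p %.4g  FDR threshold %.3g  %s", res$fdr$term[r],
      res$fdr$p[r], res$fdr$threshold[r],
      if (res$fdr$significant[r]) "significant" else "ns")
  invisible(rep_path)
}
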