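.gaze_cols <- c("infant_id", "pair_id", "zygosity", "trial_index",
                "stimulus_id", "t_ms", "x_px", "y_px", "valid")

#' Read and write tidy gaze-sample tables
#'
#' The on-disk contract is one CSV row per gaze sample with columns
#' `infant_id, pair_id, zygosity, trial_index, stimulus_id, t_ms, x_px,
#' y_px, valid`. Reading rejects files with missing or renamed columns
#' (naming them) and non-monotone time stamps within a trial; writing and
#' reading round-trip losslessly.
#'
#' @param path CSV file path.
#' @param gaze A tidy gaze table.
#' @param append Append without header (used for chunked writes).
#' @return `read_gaze_csv` returns the gaze data frame.
#' @export
read_gaze_csv <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.gaze_cols, names(g))
  if (length(miss))
    stop("gaze file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- vapply(split(g$t_ms, paste(g$infant_id, g$trial_index)),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    stop("non-monotone time column in trial(s): ",
         paste(head(names(bad)[bad], 5), collapse = ", "))
  g[.gaze_cols]
}

#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(gaze, path, append = FALSE) {
  miss <- setdiff(.gaze_cols, names(gaze))
  if (length(miss))
    stop("gaze table lacks column(s): ", paste(miss, collapse = ", "))
  write.table(gaze[.gaze_cols], path, sep = ",", row.names = FALSE,
              col.names = !append, append = append, qmethod = "double")
  invisible(path)
}

.phen_cols <- c("infant_id", "pair_id", "zygosity", "age_days", "sex",
                "face_orienting", "face_preference", "exploration",
                "n_valid_trials", "mean_prop_missing")

#' Read and write participant phenotype tables
#'
#' One row per infant with identifiers, demographics, the three looking
#' phenotypes and the two gaze-quality covariates.
#'
#' @param phenotypes Phenotype data frame.
#' @param path CSV file path.
#' @return `read_phenotypes_csv` returns the phenotype data frame.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  miss <- setdiff(.phen_cols, names(phenotypes))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  write.csv(phenotypes[.phen_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.phen_cols, names(p))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  p[.phen_cols]
}

#' Serialize a fitted twin model to JSON
#'
#' Writes the model type/components, estimates, fit statistics and (when
#' supplied) a model-comparison table, with numbers at 6 significant digits
#' so reports diff cleanly.
#'
#' @param fit A `twin_fit`.
#' @param path Output path.
#' @param comparisons Optional list of `twin_comparison` objects.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, comparisons = NULL) {
  obj <- list(
    type = fit$type,
    traits = fit$traits,
    components = if (fit$type == "biometric") fit$components else NULL,
    equate = if (fit$type == "saturated") fit$equate else NULL,
    estimates = if (fit$type == "biometric")
      list(paths = lapply(fit$paths, function(L) signif(L, 6)),
           means = signif(fit$means, 6),
           beta_age = signif(fit$beta_age, 6),
           beta_sex = signif(fit$beta_sex, 6))
    else list(parameters = as.list(signif(fit$par_named, 6))),
    minus2LL = signif(fit$minus2LL, 6), n_params = fit$n_params,
    n_data = fit$n_data, df = fit$df, AIC = signif(fit$AIC, 6),
    converged = fit$converged
  )
  if (!is.null(comparisons))
    obj$comparisons <- lapply(comparisons, function(cp) list(
      label = cp$label, delta_chi2 = signif(cp$delta_chi2, 6),
      delta_df = cp$delta_df, p_value = signif(cp$p_value, 6),
      nested_minus2LL = signif(cp$nested$minus2LL, 6),
      nested_n_params = cp$nested$n_params,
      nested_df = cp$nested$df, nested_AIC = signif(cp$nested$AIC, 6),
      retain_nested = cp$retain_nested))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
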