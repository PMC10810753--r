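# parameter packing for ACE-family models: one lower-triangular Cholesky
# factor per component, then trait means, then covariate effects

.ace_npl <- function(k) k * (k + 1) / 2

.ace_unpack <- function(par, k, comps, covariates) {
  npl <- .ace_npl(k)
  paths <- list()
  pos <- 0
  for (cm in comps) {
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- par[pos + seq_len(npl)]
    paths[[cm]] <- L
    pos <- pos + npl
  }
  means <- par[pos + seq_len(k)]; pos <- pos + k
  if (covariates) {
    beta_age <- par[pos + seq_len(k)]; pos <- pos + k
    beta_sex <- par[pos + seq_len(k)]
  } else beta_age <- beta_sex <- rep(0, k)
  list(paths = paths, means = means, beta_age = beta_age, beta_sex = beta_sex)
}

.ace_objective <- function(prep, comps, covariates) {
  function(par) {
    up <- .ace_unpack(par, prep$k, comps, covariates)
    sig <- .sigma_from_paths(up$paths)
    M <- .mean_matrix(prep, up$means, up$beta_age, up$beta_sex)
    val <- .fiml_groups_m2ll(sig$MZ, sig$DZ, M, prep)
    if (!is.finite(val)) 1e10 else val
  }
}

.ace_start <- function(prep, comps, covariates) {
  k <- prep$k
  vbar <- apply(prep$Y, 2, var, na.rm = TRUE)
  vtrait <- (vbar[seq_len(k)] + vbar[k + seq_len(k)]) / 2
  mtrait <- (colMeans(prep$Y, na.rm = TRUE)[seq_len(k)] +
               colMeans(prep$Y, na.rm = TRUE)[k + seq_len(k)]) / 2
  nc <- length(comps)
  start <- c()
  for (cm in comps) {
    L <- diag(sqrt(vtrait / nc), k)
    if (k > 1) {
      cc <- stats::cov(prep$Y[, 1], prep$Y[, 2], use = "complete.obs")
      L[2, 1] <- cc / (nc * max(L[1, 1], 1e-3))
    }
    start <- c(start, L[lower.tri(L, diag = TRUE)])
  }
  start <- c(start, mtrait)
  if (covariates) start <- c(start, rep(0, 2 * k))
  start
}

# sign convention: flip Cholesky columns so diagonal paths are >= 0
.ace_fix_signs <- function(paths) {
  lapply(paths, function(L) {
    for (cc in seq_len(ncol(L))) if (L[cc, cc] < 0) L[, cc] <- -L[, cc]
    L
  })
}

#' Fit an ACE-family twin model by full-information maximum likelihood
#'
#' Minimises the FIML deviance of a Cholesky-parameterised biometric model
#' over a twin-pair dataset, using multi-start quasi-Newton (BFGS)
#' optimisation. Components are any subset of A, C, D and E containing E;
#' C and D cannot be combined in one model (the classical identification
#' limit with MZ/DZ data). Covariates (z-scaled age, sex 0/1) enter the mean
#' model only, equated across twins and zygosity.
#'
#' @param data A `twin_data` object (1 or 2 traits).
#' @param components Character subset of `c("A","C","D","E")`; E mandatory.
#' @param covariates Include age and sex effects on the means.
#' @param n_restarts Optimizer restarts; the fit is flagged non-converged if
#'   the restart optima disagree by more than 1e-4 in deviance.
#' @return A `twin_fit` object: path matrices, means, covariate effects,
#'   `minus2LL`, `n_params`, `n_data`, `df`, `AIC`, `converged`, and the
#'   implied per-zygosity covariance matrices.
#' @examples
#' spec <- univariate_spec(a2 = 0.5)
#' d <- simulate_twin_phenotypes(spec, 200, 200, seed = 1)
#' fit <- fit_model(d, c("A", "E"))
#' standardize_components(fit)
#' @export
fit_model <- function(data, components = c("A", "C", "E"), covariates = TRUE,
                      n_restarts = 5) {
  components <- match.arg(components, c("A", "C", "D", "E"),
                          several.ok = TRUE)
  if (!"E" %in% components) stop("E is mandatory (likelihood must be proper)")
  if (all(c("C", "D") %in% components))
    stop("C and D are not jointly identifiable from MZ/DZ data")
  comps <- intersect(c("A", "C", "D", "E"), components)  # canonical order
  prep <- .twin_prep(data)
  obj <- .ace_objective(prep, comps, covariates)
  start <- .ace_start(prep, comps, covariates)
  opt <- .optimize_multistart(obj, start, n_restarts = n_restarts)
  up <- .ace_unpack(opt$par, prep$k, comps, covariates)
  up$paths <- .ace_fix_signs(up$paths)
  sig <- .sigma_from_paths(up$paths)
  n_params <- length(start)
  stats <- model_fit_stats(opt$value, n_params, prep$n_data)
  structure(
    list(type = "biometric", components = comps, traits = prep$traits,
         paths = up$paths, means = up$means,
         beta_age = up$beta_age, beta_sex = up$beta_sex,
         minus2LL = stats$minus2LL, n_params = n_params,
         n_data = prep$n_data, df = stats$df, AIC = stats$AIC,
         converged = opt$converged, restart_values = opt$restart_values,
         implied = sig, covariates = covariates,
         par = opt$par, prep = prep),
    class = "twin_fit"
  )
}

#' @export
print.twin_fit <- function(x, ...) {
  if (x$type == "biometric") {
    cat(sprintf("%s twin model (%s), %d trait(s)\n",
                paste(x$components, collapse = ""),
                if (x$converged) "converged" else "NOT converged",
                length(x$traits)))
  } else {
    cat(sprintf("Saturated twin model (%s)%s\n",
                if (x$converged) "converged" else "NOT converged",
                if (length(x$equate))
                  paste0(", equated: ", paste(x$equate, collapse = ", "))
                else ""))
  }
  cat(sprintf("  -2LL = %.2f on df = %d (%d parameters, %d data values), AIC = %.2f\n",
              x$minus2LL, x$df, x$n_params, x$n_data, x$AIC))
  if (x$type == "biometric") {
    std <- standardize_components(x)
    for (t in seq_along(x$traits)) {
      comps <- std$components[std$components$trait == x$traits[t], ]
      cat(sprintf("  %s: %s\n", x$traits[t],
                  paste(sprintf("%s2 = %.3f", tolower(comps$component),
                                comps$estimate), collapse = ", ")))
    }
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# saturated models

# label builders implementing the equality-constraint sets
.sat_layout <- function(k, equate) {
  zygs <- c("MZ", "DZ")
  part <- function(cond, x) if (cond) x else ""
  mean_lab <- function(z, o, t)
    paste0("m", part(!("means_zyg" %in% equate), paste0("_", z)),
           part(!("means_order" %in% equate), paste0("_o", o)), "_t", t)
  sd_lab <- function(z, o, t)
    paste0("s", part(!("vars_zyg" %in% equate), paste0("_", z)),
           part(!("vars_order" %in% equate), paste0("_o", o)), "_t", t)
  mean_ids <- array("", c(2, 2, k), dimnames = list(zygs, NULL, NULL))
  sd_ids <- mean_ids
  for (zi in 1:2) for (o in 1:2) for (t in seq_len(k)) {
    mean_ids[zi, o, t] <- mean_lab(zygs[zi], o, t)
    sd_ids[zi, o, t] <- sd_lab(zygs[zi], o, t)
  }
  # correlation slots: (i, j) indices into the stacked 2k-vector
  corr <- NULL
  for (z in zygs) {
    if (k == 1) {
      corr <- rbind(corr, data.frame(zyg = z, i = 1, j = 2,
                                     label = paste0("c_r_", z)))
    } else {
      zp <- part(!("corrs_zyg" %in% equate), paste0("_", z))
      op <- function(o) part(!("corrs_order" %in% equate), paste0("_o", o))
      corr <- rbind(
        corr,
        data.frame(zyg = z, i = 1, j = 2, label = paste0("c_ph", zp, op(1))),
        data.frame(zyg = z, i = 3, j = 4, label = paste0("c_ph", zp, op(2))),
        data.frame(zyg = z, i = 1, j = 3, label = paste0("c_wt1_", z)),
        data.frame(zyg = z, i = 2, j = 4, label = paste0("c_wt2_", z)),
        data.frame(zyg = z, i = 1, j = 4, label = paste0("c_ct", zp, op(1))),
        data.frame(zyg = z, i = 2, j = 3, label = paste0("c_ct", zp, op(2)))
      )
    }
  }
  labels <- unique(c(as.vector(mean_ids), as.vector(sd_ids), corr$label))
  list(mean_ids = mean_ids, sd_ids = sd_ids, corr = corr, labels = labels)
}

.sat_sigma <- function(par, layout, k, zyg) {
  zi <- if (zyg == "MZ") 1 else 2
  # stacked order must match the data: twin-1 traits then twin-2 traits
  sd_labs <- as.vector(t(matrix(layout$sd_ids[zi, , ], nrow = 2)))
  s <- exp(par[sd_labs])
  R <- diag(2 * k)
  cz <- layout$corr[layout$corr$zyg == zyg, ]
  for (r in seq_len(nrow(cz))) {
    v <- tanh(par[cz$label[r]])
    R[cz$i[r], cz$j[r]] <- v
    R[cz$j[r], cz$i[r]] <- v
  }
  diag(s) %*% R %*% diag(s)
}

.sat_objective <- function(prep, layout, covariates) {
  k <- prep$k
  function(par_raw) {
    par <- setNames(par_raw[seq_along(layout$labels)], layout$labels)
    if (covariates) {
      beta_age <- par_raw[length(layout$labels) + seq_len(k)]
      beta_sex <- par_raw[length(layout$labels) + k + seq_len(k)]
    } else beta_age <- beta_sex <- rep(0, k)
    sig_mz <- .sat_sigma(par, layout, k, "MZ")
    sig_dz <- .sat_sigma(par, layout, k, "DZ")
    M <- matrix(0, prep$n, 2 * k)
    for (zi in 1:2) {
      z <- c("MZ", "DZ")[zi]
      rows <- prep$zyg == z
      for (o in 1:2) for (t in seq_len(k)) {
        col <- (o - 1) * k + t
        M[rows, col] <- par[layout$mean_ids[zi, o, t]] +
          beta_age[t] * prep$age_z[rows] + beta_sex[t] * prep$sex[rows]
      }
    }
    val <- .fiml_groups_m2ll(sig_mz, sig_dz, M, prep)
    if (!is.finite(val)) 1e10 else val
  }
}

.sat_start <- function(prep, layout, covariates) {
  k <- prep$k
  acc <- setNames(vector("list", length(layout$labels)), layout$labels)
  push <- function(lab, v) acc[[lab]] <<- c(acc[[lab]], v)
  for (zi in 1:2) {
    z <- c("MZ", "DZ")[zi]
    Yz <- prep$Y[prep$zyg == z, , drop = FALSE]
    cm <- colMeans(Yz, na.rm = TRUE)
    cs <- apply(Yz, 2, sd, na.rm = TRUE)
    cs[!is.finite(cs) | cs == 0] <- 1
    Cz <- suppressWarnings(stats::cor(Yz, use = "pairwise.complete.obs"))
    Cz[!is.finite(Cz)] <- 0
    for (o in 1:2) for (t in seq_len(k)) {
      col <- (o - 1) * k + t
      push(layout$mean_ids[zi, o, t], cm[col])
      push(layout$sd_ids[zi, o, t], log(cs[col]))
    }
    cz <- layout$corr[layout$corr$zyg == z, ]
    for (r in seq_len(nrow(cz)))
      push(cz$label[r], atanh(max(min(Cz[cz$i[r], cz$j[r]], 0.9), -0.9)))
  }
  start <- vapply(acc, function(v) mean(v), numeric(1))
  if (covariates) start <- c(start, rep(0, 2 * k))
  unname(start)
}

#' Fit a saturated twin model, optionally under equality constraints
#'
#' The saturated model frees the means, variances and correlations of the
#' twin-pair observation vector separately per zygosity (and twin order),
#' with covariate effects on the means retained. Equality-constraint sets
#' reduce it; comparing constrained against free fits tests the twin-design
#' assumptions (equal means/variances across twin order and zygosity; for
#' two traits, equal phenotypic and cross-trait cross-twin correlations).
#'
#' @param data A `twin_data` object.
#' @param equate Character subset of `c("means_order","means_zyg",
#'   "vars_order","vars_zyg","corrs_order","corrs_zyg")`. `corrs_*` equate
#'   the phenotypic and CTCT correlations (two-trait data); within-trait
#'   cross-twin correlations always stay zygosity-specific.
#' @param covariates Include age/sex effects on the means.
#' @param n_restarts Optimizer restarts.
#' @return A `twin_fit` of type `"saturated"`; the named parameter vector is
#'   in `$par_named` (correlations on the atanh scale).
#' @export
fit_saturated <- function(data, equate = character(), covariates = TRUE,
                          n_restarts = 5) {
  bad <- setdiff(equate, c("means_order", "means_zyg", "vars_order",
                           "vars_zyg", "corrs_order", "corrs_zyg"))
  if (length(bad)) stop("unknown constraint(s): ", paste(bad, collapse = ", "))
  prep <- .twin_prep(data)
  layout <- .sat_layout(prep$k, equate)
  obj <- .sat_objective(prep, layout, covariates)
  start <- .sat_start(prep, layout, covariates)
  opt <- .optimize_multistart(obj, start, n_restarts = n_restarts)
  n_params <- length(start)
  stats <- model_fit_stats(opt$value, n_params, prep$n_data)
  par_named <- setNames(opt$par[seq_along(layout$labels)], layout$labels)
  structure(
    list(type = "saturated", equate = equate, traits = prep$traits,
         layout = layout, par_named = par_named,
         beta_age = if (covariates)
           opt$par[length(layout$labels) + seq_len(prep$k)] else rep(0, prep$k),
         beta_sex = if (covariates)
           opt$par[length(layout$labels) + prep$k + seq_len(prep$k)] else rep(0, prep$k),
         minus2LL = stats$minus2LL, n_params = n_params,
         n_data = prep$n_data, df = stats$df, AIC = stats$AIC,
         converged = opt$converged, restart_values = opt$restart_values,
         implied = list(MZ = .sat_sigma(par_named, layout, prep$k, "MZ"),
                        DZ = .sat_sigma(par_named, layout, prep$k, "DZ")),
         covariates = covariates, par = opt$par, prep = prep),
    class = "twin_fit"
  )
}

# ---------------------------------------------------------------------------
# model comparison and selection

#' Likelihood-ratio comparison of nested twin models
#'
#' `delta_chi2 = nested minus2LL - full minus2LL`, `delta_df` the parameter
#' difference, p-value from the upper tail of the chi-squared distribution.
#' The nested model is retained when `p >= alpha` (no significant decrement
#' in fit).
#'
#' @param full,nested Fitted models (`twin_fit` or [model_fit_stats()]
#'   objects) on the same data; `nested` must have fewer parameters.
#' @param alpha Retention level (default 0.05).
#' @param label Optional name for the nested model.
#' @return A `twin_comparison`: `delta_chi2`, `delta_df`, `p_value`,
#'   `aic_diff` (nested minus full), `retain_nested`, and the inputs.
#' @examples
#' full <- model_fit_stats(1167.82, 15, 1072)
#' ae <- model_fit_stats(1169.33, 12, 1072)
#' compare_models(full, ae)  # delta chi2 = 1.51, delta df = 3
#' @export
compare_models <- function(full, nested, alpha = 0.05, label = NULL) {
  if (nested$n_params >= full$n_params)
    stop("'nested' must have fewer parameters than 'full'")
  if (!is.null(full$n_data) && !is.null(nested$n_data) &&
      full$n_data != nested$n_data)
    stop("models were fitted to different data sizes")
  delta <- nested$minus2LL - full$minus2LL
  if (delta < -0.01)
    stop("nested model fits better than full beyond tolerance; ",
         "models are mis-ordered or the optimizer failed")
  delta <- max(delta, 0)
  ddf <- full$n_params - nested$n_params
  p <- pchisq(delta, ddf, lower.tail = FALSE)
  structure(
    list(label = label, delta_chi2 = delta, delta_df = ddf, p_value = p,
         aic_diff = nested$AIC - full$AIC,
         retain_nested = p >= alpha, alpha = alpha,
         full = full, nested = nested),
    class = "twin_comparison"
  )
}

#' @export
print.twin_comparison <- function(x, ...) {
  cat(sprintf("%sdelta chi2 = %.2f (delta df = %d), p = %.3g -> %s\n",
              if (!is.null(x$label)) paste0(x$label, ": ") else "",
              x$delta_chi2, x$delta_df, x$p_value,
              if (x$retain_nested) "retain nested" else "reject nested"))
  invisible(x)
}

#' Select the best-fitting nested model
#'
#' Among nested models that are not significantly worse than the full model
#' (`p >= alpha`), returns the one with the lowest AIC (ties broken by
#' fewest parameters). If no nested model is retained, the full model is
#' returned.
#'
#' @param comparisons Non-empty list of `twin_comparison` objects sharing
#'   the same full model.
#' @param alpha Retention level.
#' @return List with `fit` (the selected model object), `label` and
#'   `selected_nested` (FALSE when the full model is kept).
#' @export
select_best <- function(comparisons, alpha = 0.05) {
  if (!length(comparisons)) stop("empty candidate list")
  retained <- Filter(function(cp) cp$p_value >= alpha, comparisons)
  if (!length(retained)) {
    full <- comparisons[[1]]$full
    return(list(fit = full, label = "full", selected_nested = FALSE))
  }
  aics <- vapply(retained, function(cp) cp$nested$AIC, numeric(1))
  npars <- vapply(retained, function(cp) cp$nested$n_params, numeric(1))
  ord <- order(aics, npars)
  best <- retained[[ord[1]]]
  list(fit = best$nested,
       label = if (!is.null(best$label)) best$label else "nested",
       selected_nested = TRUE)
}
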