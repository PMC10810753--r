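# position of entry (i, j) within lower.tri(diag = TRUE) column-major packing
.lt_index <- function(k, i, j) {
  before <- if (j > 1) sum(k - seq_len(j - 1) + 1) else 0
  before + (i - j + 1)
}

#' Standardized variance decomposition of a fitted twin model
#'
#' Per-trait standardized components are squared paths over the implied total
#' trait variance (summing to 1 by construction). For two-trait Cholesky
#' fits the trait-2 variance is further split into portions shared with and
#' unique from trait 1 (`a21^2/V2` and `a22^2/V2`, analogously for C/D/E),
#' and the genetic correlation `r_A = A12 / sqrt(A11 A22)` and implied
#' phenotypic correlation `r_Ph` are reported.
#'
#' @param fit A biometric `twin_fit`.
#' @param ci Also compute 95% profile-likelihood CIs (slower).
#' @param level Confidence level for `ci = TRUE`.
#' @return A `variance_decomposition`: data frame `components` (trait,
#'   component, estimate, optional lower/upper) plus, for two traits,
#'   `bivariate` (shared/unique splits per component) and the correlations
#'   `r_A`, `r_Ph`.
#' @export
standardize_components <- function(fit, ci = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"), fit$type == "biometric")
  k <- length(fit$traits)
  V <- diag(fit$implied$within)
  if (any(V <= 0)) stop("zero total implied variance")
  comps <- setdiff(fit$components, character(0))
  rows <- list()
  for (cm in comps) {
    L <- fit$paths[[cm]]
    for (t in seq_len(k)) {
      est <- sum(L[t, ]^2) / V[t]
      rows[[paste(cm, t)]] <- data.frame(
        trait = fit$traits[t], component = cm, estimate = est,
        stringsAsFactors = FALSE)
    }
  }
  components <- do.call(rbind, rows)
  rownames(components) <- NULL
  out <- list(components = components, traits = fit$traits)
  if (k == 2) {
    biv <- list()
    for (cm in comps) {
      L <- fit$paths[[cm]]
      biv[[cm]] <- data.frame(
        component = cm,
        shared = L[2, 1]^2 / V[2], unique = L[2, 2]^2 / V[2],
        stringsAsFactors = FALSE)
    }
    out$bivariate <- do.call(rbind, biv)
    rownames(out$bivariate) <- NULL
    if ("A" %in% comps) {
      A <- tcrossprod(fit$paths$A)
      out$r_A <- if (A[1, 1] > 0 && A[2, 2] > 0)
        A[1, 2] / sqrt(A[1, 1] * A[2, 2]) else NA_real_
    }
    out$r_Ph <- fit$implied$within[1, 2] / sqrt(V[1] * V[2])
  }
  if (ci) {
    components$lower <- NA_real_; components$upper <- NA_real_
    for (r in seq_len(nrow(components))) {
      cmp <- paste0(tolower(components$component[r]), "2")
      b <- profile_ci(fit, cmp, trait = match(components$trait[r], fit$traits),
                      level = level)
      components$lower[r] <- b["lower"]; components$upper[r] <- b["upper"]
    }
    out$components <- components
  }
  structure(out, class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Standardized variance components:\n")
  print(x$components, row.names = FALSE)
  if (!is.null(x$bivariate)) {
    cat("Trait-2 shared/unique split:\n")
    print(x$bivariate, row.names = FALSE)
    if (!is.null(x$r_A) && !is.na(x$r_A))
      cat(sprintf("r_A = %.3f, ", x$r_A))
    cat(sprintf("implied r_Ph = %.3f\n", x$r_Ph))
  }
  invisible(x)
}

# constrained profile deviance for a standardized component fixed at v.
# The constrained paths (one trait row of one component, or a single
# Cholesky entry) are substituted from the component value: with
# Rest = (trait total variance contributed by all other paths),
# norm^2 = v * Rest / (1 - v) makes the standardized share exactly v.
.profile_deviance <- function(fit, positions, trait_row, v, start_free) {
  prep <- fit$prep
  base_obj <- .ace_objective(prep, fit$components, fit$covariates)
  k <- prep$k
  npar <- length(fit$par)
  nfix <- length(positions)
  n_angles <- max(nfix - 1, 0)
  obj <- function(free_par) {
    rem <- free_par[seq_len(npar - nfix)]
    full <- numeric(npar)
    full[-positions] <- rem
    up <- .ace_unpack(full, k, fit$components, fit$covariates)
    rest <- sum(vapply(up$paths, function(L) sum(L[trait_row, ]^2),
                       numeric(1)))
    norm2 <- v * rest / (1 - v)
    if (nfix == 1) {
      p <- sqrt(norm2)
      vals <- vapply(c(p, -p), function(pp) {
        full[positions] <- pp
        base_obj(full)
      }, numeric(1))
      min(vals)
    } else {
      phi <- free_par[npar - nfix + 1]
      full[positions] <- sqrt(norm2) * c(cos(phi), sin(phi))
      base_obj(full)
    }
  }
  start <- c(start_free$rem, start_free$angles)
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  opt$value
}

#' Profile-likelihood confidence interval for a standardized component
#'
#' The 95% likelihood-based interval is the set of component values whose
#' constrained refit raises the deviance by at most `qchisq(level, 1)`
#' (3.841 at 95%); bounds are clipped to `[0, 1]`. Components at the
#' boundary give a lower bound of 0. The chi-squared reference is used
#' unmixed, the standard convention in the twin literature.
#'
#' @param fit A biometric `twin_fit`.
#' @param component One of `"a2","c2","d2","e2"` (per-trait totals) or, for
#'   two-trait fits, `"shared_a2","unique_a2","shared_c2","unique_c2",
#'   "shared_e2","unique_e2"` (single Cholesky paths to trait 2).
#' @param trait Trait index for the per-trait totals.
#' @param level Confidence level.
#' @return Named numeric vector `c(lower, upper)` with attribute
#'   `"estimate"`.
#' @export
profile_ci <- function(fit, component, trait = 1, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"), fit$type == "biometric")
  if (!fit$converged) warning("profiling a non-converged fit")
  k <- length(fit$traits)
  crit <- qchisq(level, 1)
  split_part <- grepl("^(shared|unique)_", component)
  letter <- toupper(sub("2$", "", sub("^(shared|unique)_", "", component)))
  if (!letter %in% fit$components)
    stop("component ", letter, " is not in the fitted model")
  ci_comp <- which(fit$components == letter)
  offset <- (ci_comp - 1) * .ace_npl(k)
  if (split_part) {
    if (k != 2) stop("shared/unique components require a two-trait fit")
    trait_row <- 2
    col <- if (grepl("^shared_", component)) 1 else 2
    positions <- offset + .lt_index(k, 2, col)
  } else {
    trait_row <- trait
    positions <- offset + vapply(seq_len(trait), function(cc)
      .lt_index(k, trait, cc), numeric(1))
  }
  V <- diag(fit$implied$within)
  L <- fit$paths[[letter]]
  vhat <- if (split_part) L[2, if (grepl("^shared_", component)) 1 else 2]^2 / V[2]
    else sum(L[trait_row, ]^2) / V[trait_row]
  start_free <- list(
    rem = fit$par[-positions],
    angles = if (length(positions) == 2)
      atan2(fit$par[positions[2]], fit$par[positions[1]]) else numeric(0))
  prof <- function(v) .profile_deviance(fit, positions, trait_row, v, start_free)
  f <- function(v) prof(v) - fit$minus2LL - crit
  eps <- 1e-6; vmax <- 0.999
  vhat_in <- min(max(vhat, eps), vmax)
  lower <- if (f(eps) <= 0) 0 else
    uniroot(f, c(eps, vhat_in), tol = 1e-4)$root
  upper <- if (f(vmax) <= 0) 1 else
    uniroot(f, c(vhat_in, vmax), tol = 1e-4)$root
  out <- c(lower = max(0, lower), upper = min(1, upper))
  attr(out, "estimate") <- vhat
  out
}

# profile a single raw parameter of a fitted model (used for saturated-model
# correlations, on the atanh scale); returns the two deviance crossings
.profile_fixed_param <- function(objective, par_hat, m2ll_hat, idx, crit) {
  prof <- function(val) {
    red <- function(p) {
      full <- numeric(length(par_hat))
      full[-idx] <- p; full[idx] <- val
      objective(full)
    }
    optim(par_hat[-idx], red, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-10))$value
  }
  f <- function(val) prof(val) - m2ll_hat - crit
  step <- max(abs(par_hat[idx]), 0.25) * 0.5
  bound <- function(dir) {
    v0 <- par_hat[idx]
    for (i in 1:40) {
      v1 <- v0 + dir * step
      if (f(v1) > 0)
        return(uniroot(function(v) f(v), c(min(v0, v1), max(v0, v1)),
                       tol = 1e-4)$root)
      v0 <- v1
    }
    v0  # no crossing found within the search range
  }
  c(lower = bound(-1), upper = bound(+1))
}

#' Twin and cross-trait cross-twin correlations
#'
#' Derived from the constrained saturated model in which means and variances
#' are equated across twin order and zygosity and correlations are equated
#' across twin order/direction, while zygosity-specific correlations are
#' retained. Returns MZ and DZ within-pair correlations per trait and, for
#' two traits, the phenotypic and CTCT correlations per zygosity, with
#' profile-likelihood CIs.
#'
#' @param data A `twin_data` object.
#' @param ci Compute profile-likelihood CIs (slower).
#' @param level Confidence level.
#' @param covariates Include age/sex effects on the means.
#' @return Data frame with columns `quantity, trait, zygosity, estimate,
#'   lower, upper`; the constrained saturated fit is attached as attribute
#'   `"fit"`.
#' @export
twin_correlations <- function(data, ci = TRUE, level = 0.95,
                              covariates = TRUE) {
  fit <- fit_saturated(data, equate = c("means_order", "means_zyg",
                                        "vars_order", "vars_zyg",
                                        "corrs_order"),
                       covariates = covariates)
  if (!fit$converged) warning("constrained saturated fit did not converge")
  traits <- fit$traits
  k <- length(traits)
  slots <- list()
  for (z in c("MZ", "DZ")) {
    if (k == 1) {
      slots[[paste0("r_", z)]] <- list(quantity = "twin_correlation",
                                       trait = traits[1], zyg = z,
                                       label = paste0("c_r_", z))
    } else {
      slots[[paste0("wt1_", z)]] <- list(quantity = "twin_correlation",
                                         trait = traits[1], zyg = z,
                                         label = paste0("c_wt1_", z))
      slots[[paste0("wt2_", z)]] <- list(quantity = "twin_correlation",
                                         trait = traits[2], zyg = z,
                                         label = paste0("c_wt2_", z))
      slots[[paste0("ph_", z)]] <- list(quantity = "phenotypic_correlation",
                                        trait = paste(traits, collapse = ":"),
                                        zyg = z, label = paste0("c_ph_", z))
      slots[[paste0("ct_", z)]] <- list(quantity = "ctct_correlation",
                                        trait = paste(traits, collapse = ":"),
                                        zyg = z, label = paste0("c_ct_", z))
    }
  }
  objective <- .sat_objective(fit$prep, fit$layout, fit$covariates)
  crit <- qchisq(level, 1)
  rows <- lapply(slots, function(sl) {
    idx <- match(sl$label, fit$layout$labels)
    est <- tanh(fit$par[idx])
    lo <- up <- NA_real_
    if (ci) {
      b <- .profile_fixed_param(objective, fit$par, fit$minus2LL, idx, crit)
      lo <- tanh(b["lower"]); up <- tanh(b["upper"])
    }
    data.frame(quantity = sl$quantity, trait = sl$trait, zygosity = sl$zyg,
               estimate = est, lower = lo, upper = up,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
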