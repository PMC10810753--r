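# Internal FIML machinery shared by the ACE-family and saturated fitters.
#
# Data are held pair-wise: the observation vector of a pair stacks twin 1's
# traits then twin 2's traits; an absent co-twin simply deletes its rows and
# columns from the implied moments (full-information maximum likelihood).

# run code under a private RNG stream, restoring the caller's state
.with_local_seed <- function(seed, fun) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

.twin_prep <- function(data) {
  stopifnot(inherits(data, "twin_data"))
  traits <- attr(data, "traits")
  k <- length(traits)
  df <- as.data.frame(data)
  cols <- c(paste0(traits, "_t1"), paste0(traits, "_t2"))
  Y <- as.matrix(df[cols])
  obs <- !is.na(Y)
  sd_age <- sd(df$age_days)
  age_z <- if (is.na(sd_age) || sd_age == 0) rep(0, nrow(df)) else
    (df$age_days - mean(df$age_days)) / sd_age
  key <- paste(df$zygosity, apply(obs, 1, paste, collapse = ""))
  groups <- lapply(split(seq_len(nrow(df)), key), function(rows) {
    list(rows = rows, zyg = df$zygosity[rows[1]],
         obs = which(obs[rows[1], ]))
  })
  list(Y = Y, obs = obs, k = k, traits = traits, n = nrow(df),
       age_z = age_z, sex = df$sex, zyg = df$zygosity,
       pair_id = df$pair_id, groups = groups, n_data = sum(obs))
}

# -2 log-likelihood summed over pairs, vectorised within missingness groups
.fiml_groups_m2ll <- function(sig_mz, sig_dz, M, prep, on_singular = "inf") {
  tot <- 0
  for (g in prep$groups) {
    S <- (if (g$zyg == "MZ") sig_mz else sig_dz)[g$obs, g$obs, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      if (on_singular == "error")
        stop("singular restricted covariance for pair(s) ",
             paste(head(prep$pair_id[g$rows], 3), collapse = ", "))
      return(Inf)
    }
    R <- prep$Y[g$rows, g$obs, drop = FALSE] - M[g$rows, g$obs, drop = FALSE]
    V <- backsolve(ch, t(R), transpose = TRUE)
    tot <- tot + length(g$rows) *
      (length(g$obs) * log(2 * pi) + 2 * sum(log(diag(ch)))) + sum(V * V)
  }
  tot
}

# mean matrix (n x 2k): per-trait intercept + covariate effects, identical
# for both twins of a pair
.mean_matrix <- function(prep, means, beta_age, beta_sex) {
  M <- matrix(0, prep$n, 2 * prep$k)
  for (t in seq_len(prep$k)) {
    mu <- means[t] + beta_age[t] * prep$age_z + beta_sex[t] * prep$sex
    M[, t] <- mu
    M[, prep$k + t] <- mu
  }
  M
}

.sigma_from_paths <- function(paths) {
  k <- nrow(paths$E)
  zero <- matrix(0, k, k)
  A <- if (is.null(paths$A)) zero else tcrossprod(paths$A)
  C <- if (is.null(paths$C)) zero else tcrossprod(paths$C)
  D <- if (is.null(paths$D)) zero else tcrossprod(paths$D)
  E <- tcrossprod(paths$E)
  W <- A + C + D + E
  list(MZ = rbind(cbind(W, A + C + D), cbind(A + C + D, W)),
       DZ = rbind(cbind(W, 0.5 * A + C + 0.25 * D),
                  cbind(0.5 * A + C + 0.25 * D, W)),
       within = W)
}

#' Implied twin-pair moments from Cholesky path estimates
#'
#' Assembles the per-zygosity covariance of the stacked twin-pair trait
#' vector from biometric path matrices: within-twin block `A + C + D + E`,
#' cross-twin block `A + C + D` (MZ) or `0.5 A + C + 0.25 D` (DZ), with each
#' component the outer product of its lower-triangular Cholesky factor. The
#' result is symmetric and positive semi-definite by construction.
#'
#' @param path_a,path_c,path_d,path_e Lower-triangular path matrices
#'   (`NULL` omits the component; E is mandatory).
#' @return List with `MZ` and `DZ` covariance matrices and the within-twin
#'   block `within`.
#' @examples
#' implied_moments(path_a = sqrt(0.46), path_e = sqrt(0.54))$MZ
#' @export
implied_moments <- function(path_a = NULL, path_c = NULL, path_d = NULL,
                            path_e) {
  as_m <- function(x) if (is.null(x)) NULL else as.matrix(x)
  .sigma_from_paths(list(A = as_m(path_a), C = as_m(path_c),
                         D = as_m(path_d), E = as_m(path_e)))
}

#' FIML deviance of a twin dataset under given parameter values
#'
#' Computes `-2 log L = sum_i [k_i log(2 pi) + log|Sigma_i| +
#' (y_i - mu_i)' Sigma_i^{-1} (y_i - mu_i)]` over pairs, where the implied
#' moments are restricted to each pair's observed entries (absent co-twins
#' are marginalised by row/column deletion).
#'
#' @param data A `twin_data` object.
#' @param path_a,path_c,path_d,path_e Lower-triangular path matrices.
#' @param means Per-trait intercepts.
#' @param beta_age,beta_sex Per-trait covariate effects (age z-scaled within
#'   the dataset; sex 0/1).
#' @return The deviance (a single number). A singular restricted covariance
#'   raises an error naming the offending pair.
#' @export
fiml_minus2ll <- function(data, path_a = NULL, path_c = NULL, path_d = NULL,
                          path_e, means = 0, beta_age = 0, beta_sex = 0) {
  prep <- .twin_prep(data)
  as_m <- function(x) if (is.null(x)) NULL else as.matrix(x)
  sig <- .sigma_from_paths(list(A = as_m(path_a), C = as_m(path_c),
                                D = as_m(path_d), E = as_m(path_e)))
  M <- .mean_matrix(prep, rep_len(means, prep$k),
                    rep_len(beta_age, prep$k), rep_len(beta_sex, prep$k))
  .fiml_groups_m2ll(sig$MZ, sig$DZ, M, prep, on_singular = "error")
}

#' Fit statistics from a deviance, parameter count and data size
#'
#' Applies the reporting conventions used throughout the package:
#' `df = (total non-missing observed data values) - n_params` and
#' `AIC = -2LL - 2 df` (lower is better).
#'
#' @param minus2LL Model deviance.
#' @param n_params Number of free parameters.
#' @param n_data Total count of non-missing observed data values.
#' @return List of class `twin_fit_stats` with `minus2LL`, `n_params`,
#'   `n_data`, `df` and `AIC`.
#' @examples
#' model_fit_stats(1169.33, 12, 1072)  # df 1060, AIC -950.67
#' @export
model_fit_stats <- function(minus2LL, n_params, n_data) {
  df <- n_data - n_params
  structure(list(minus2LL = minus2LL, n_params = n_params, n_data = n_data,
                 df = df, AIC = minus2LL - 2 * df),
            class = "twin_fit_stats")
}

# shared multi-start quasi-Newton driver; objective must be finite-valued
.optimize_multistart <- function(objective, start, n_restarts = 5,
                                 seed = 20260925, maxit = 1000) {
  runs <- .with_local_seed(seed, function() {
    lapply(seq_len(n_restarts), function(r) {
      s <- if (r == 1) start else
        start * (1 + 0.3 * rnorm(length(start))) + 0.05 * rnorm(length(start))
      tryCatch(optim(s, objective, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-12)),
               error = function(e) NULL)
    })
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("all optimizer restarts failed")
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  agree <- sum(vals <= min(vals) + 1e-4)
  list(par = best$par, value = best$value,
       converged = best$convergence == 0 && (length(runs) == 1 || agree >= 2),
       restart_values = sort(vals))
}
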