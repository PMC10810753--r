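#' One-sample test against chance level
#'
#' Tests whether looking proportions exceed the chance level implied by the
#' display (0.2 for five equally available objects). The Shapiro-Wilk test
#' selects the procedure: a two-sided one-sample t-test when normality is
#' not rejected, otherwise the Wilcoxon signed-rank test (values exactly at
#' chance are dropped before ranking, the standard signed-rank convention).
#' The effect size is `d = (mean - chance) / s.d.` regardless of the test.
#'
#' @param values Numeric vector (n >= 3, not all equal).
#' @param chance Chance level (default 0.2).
#' @param shapiro_alpha Normality-test level for the branch (default 0.05).
#' @return List of class `chance_test`: `test` ("t" or "wilcoxon"),
#'   `statistic`, `df` (t only), `p`, `d`, `mean_ci` (t-based CI for the
#'   mean), `shapiro_p`, `n`.
#' @export
test_against_chance <- function(values, chance = 0.2, shapiro_alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (sd(values) == 0) stop("degenerate input: all values equal")
  sw <- shapiro.test(values)
  d <- (mean(values) - chance) / sd(values)
  se <- sd(values) / sqrt(n)
  mean_ci <- mean(values) + qt(c(0.025, 0.975), n - 1) * se
  if (sw$p.value >= shapiro_alpha) {
    tt <- t.test(values, mu = chance)
    res <- list(test = "t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(values, mu = chance))
    res <- list(test = "wilcoxon", statistic = unname(wt$statistic),
                df = NA_real_, p = wt$p.value)
  }
  structure(c(res, list(d = d, mean_ci = mean_ci, shapiro_p = sw$p.value,
                        n = n, chance = chance)),
            class = "chance_test")
}

#' @export
print.chance_test <- function(x, ...) {
  cat(sprintf("%s test vs chance %.2f: statistic = %.2f, p = %.3g, d = %.2f\n",
              if (x$test == "t") "t" else "Wilcoxon signed-rank",
              x$chance, x$statistic, x$p, x$d))
  invisible(x)
}

#' Adjusted Fisher-Pearson skewness coefficient
#'
#' The standardized third moment with the small-sample adjustment
#' `sqrt(n(n-1))/(n-2)` (the convention reported by most statistics
#' software).
#'
#' @param values Numeric vector (n >= 3, positive variance).
#' @return Skewness coefficient.
#' @export
skewness_coef <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance")
  g1 <- mean((values - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Linear estimating equations with cluster-robust standard errors
#'
#' Independence-working-correlation linear model: point estimates equal
#' least squares; the covariance is the cluster sandwich (per-cluster score
#' outer products, HC0-type, no small-sample adjustment), so clusters of
#' size 1 reduce exactly to heteroskedasticity-robust errors. The outcome
#' and continuous predictors are z-scaled so slopes are standardized;
#' binary 0/1 columns are left on their natural scale. All predictors are
#' entered together; the effect size is `delta R^2` against the
#' covariate-only null, with `R^2` the squared correlation between fitted
#' and observed outcome.
#'
#' @param data Data frame of children (one row per child).
#' @param outcome Outcome column name.
#' @param predictors Predictor column names.
#' @param covariates Covariate column names fitted in both the null and the
#'   full model (default `c("age_scaled","sex")` when present).
#' @param cluster Cluster id column (twin-pair id).
#' @param conf_level CI level (default 0.95, normal-theory).
#' @return List of class `gee_result`: `coefficients` (term, beta, se,
#'   lower, upper, p), `r2`, `r2_null`, `delta_r2`, `n`, `n_clusters`.
#' @export
gee_fit <- function(data, outcome, predictors, covariates = NULL,
                    cluster = "pair_id", conf_level = 0.95) {
  if (is.null(covariates))
    covariates <- intersect(c("age_scaled", "sex"), names(data))
  use <- c(outcome, predictors, covariates, cluster)
  miss <- setdiff(use, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[use]), use, drop = FALSE]
  if (length(unique(d[[cluster]])) < 2) stop("need at least 2 clusters")
  is_binary <- function(x) is.numeric(x) && all(x %in% c(0, 1))
  for (cn in c(outcome, predictors, covariates)) {
    x <- d[[cn]]
    if (!is.numeric(x)) stop("column ", cn, " must be numeric")
    if (sd(x) == 0) stop("zero-variance column: ", cn)
    if (!is_binary(x)) d[[cn]] <- as.numeric(scale(x))
  }
  rhs <- c(predictors, covariates)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(sprintf("`%s`", rhs), collapse = "+")))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  V <- sandwich::vcovCL(fit, cluster = d[[cluster]], type = "HC0",
                        cadjust = FALSE)
  b <- coef(fit)
  se <- sqrt(diag(V))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  keep <- setdiff(names(b), "(Intercept)")
  coefs <- data.frame(
    term = gsub("`", "", keep),
    beta = unname(b[keep]), se = unname(se[keep]),
    lower = unname(b[keep] - zq * se[keep]),
    upper = unname(b[keep] + zq * se[keep]),
    p = unname(2 * pnorm(-abs(b[keep] / se[keep]))),
    stringsAsFactors = FALSE
  )
  r2 <- cor(fitted(fit), d[[outcome]])^2
  r2_null <- if (length(covariates)) {
    fml0 <- stats::as.formula(paste(outcome, "~",
                                    paste(sprintf("`%s`", covariates),
                                          collapse = "+")))
    cor(fitted(lm(fml0, data = d)), d[[outcome]])^2
  } else 0
  structure(list(coefficients = coefs, r2 = r2, r2_null = r2_null,
                 delta_r2 = r2 - r2_null, n = nrow(d),
                 n_clusters = length(unique(d[[cluster]])),
                 cluster = cluster, vcov = V),
            class = "gee_result")
}

#' @export
print.gee_result <- function(x, ...) {
  cat(sprintf("Cluster-robust linear estimating equations (n = %d, %d clusters)\n",
              x$n, x$n_clusters))
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("R2 = %.4f (null %.4f), delta R2 = %.4f\n",
              x$r2, x$r2_null, x$delta_r2))
  invisible(x)
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' Sorts the p-values ascending, assigns rank-`i` threshold `i q / m`, and
#' flags as significant every test up to the largest rank whose p-value is
#' at or below its threshold.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return Data frame in the input order: `p, rank, threshold, significant`.
#' @export
fdr_stepup <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  rank <- integer(m); rank[ord] <- seq_len(m)
  threshold <- rank * q / m
  ok <- which(p[ord] <= seq_len(m) * q / m)
  cutoff <- if (length(ok)) max(ok) else 0L
  significant <- rank <= cutoff
  data.frame(p = p, rank = rank, threshold = threshold,
             significant = significant)
}
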