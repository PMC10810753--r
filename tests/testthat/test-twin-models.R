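# moderate simulated datasets reused across blocks
.uni_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_twin_phenotypes(univariate_spec(a2 = 0.5, c2 = 0.2),
                                         400, 400, incomplete_rate = 0.1,
                                         seed = 101)
    cache
  }
})

test_that("toy-dataset optimum matches an exhaustive grid search", {
  set.seed(55)
  td <- toy_twin_data(rnorm(6), rnorm(6), rep(c("MZ", "DZ"), 3))
  fit <- fit_model(td, c("A", "E"), covariates = FALSE)
  grid <- expand.grid(a = seq(0.01, 1.6, by = 0.01),
                      e = seq(0.05, 1.6, by = 0.01))
  mu <- fit$means  # profile the grid at the fitted mean
  vals <- mapply(function(a, e)
    fiml_minus2ll(td, path_a = a, path_e = e, means = mu),
    grid$a, grid$e)
  expect_lt(fit$minus2LL, min(vals) + 1e-3)
  expect_lt(abs(fit$minus2LL - min(vals)), 0.05)
})

test_that("null data give near-zero A and C at moderate n", {
  d <- simulate_twin_phenotypes(univariate_spec(), 1500, 1500, seed = 71)
  fit <- fit_model(d, c("A", "C", "E"))
  std <- standardize_components(fit)$components
  expect_lt(std$estimate[std$component == "A"], 0.05)
  expect_lt(std$estimate[std$component == "C"], 0.05)
})

test_that("estimates are insensitive to FIML-handled missingness", {
  d <- .uni_data()
  fit <- fit_model(d, c("A", "C", "E"))
  expect_true(fit$converged)
  std <- standardize_components(fit)$components
  expect_lt(abs(std$estimate[std$component == "A"] - 0.5), 0.12)
  expect_lt(abs(std$estimate[std$component == "C"] - 0.2), 0.12)
  # df identity holds with absent co-twins
  n_obs <- sum(!is.na(d$trait_t1)) + sum(!is.na(d$trait_t2))
  expect_equal(fit$n_data, n_obs)
  expect_equal(fit$df, n_obs - fit$n_params)
  expect_equal(fit$AIC, fit$minus2LL - 2 * fit$df, tolerance = 1e-9)
})

test_that("adding parameters never worsens the optimized deviance", {
  d <- .uni_data()
  m_ace <- fit_model(d, c("A", "C", "E"))
  m_ae <- fit_model(d, c("A", "E"))
  m_ce <- fit_model(d, c("C", "E"))
  m_e <- fit_model(d, "E")
  expect_lte(m_ace$minus2LL, m_ae$minus2LL + 1e-4)
  expect_lte(m_ace$minus2LL, m_ce$minus2LL + 1e-4)
  expect_lte(m_ae$minus2LL, m_e$minus2LL + 1e-4)
  cmp <- compare_models(m_ace, m_e, label = "E")
  expect_gte(cmp$delta_chi2, 0)
  expect_lt(cmp$p_value, 0.001)
})

test_that("component constraints are enforced", {
  d <- .uni_data()
  expect_error(fit_model(d, c("A", "C")), "mandatory")
  expect_error(fit_model(d, c("A", "C", "D", "E")), "identifiable")
})

test_that("C-only data yield MZ equal to DZ correlations; A-only MZ twice DZ", {
  d_c <- simulate_twin_phenotypes(univariate_spec(c2 = 0.5), 2500, 2500,
                                  seed = 81)
  r <- function(d, z) cor(d$trait_t1[d$zygosity == z],
                          d$trait_t2[d$zygosity == z])
  expect_lt(abs(r(d_c, "MZ") - r(d_c, "DZ")), 0.05)
  d_a <- simulate_twin_phenotypes(univariate_spec(a2 = 0.5), 2500, 2500,
                                  seed = 82)
  expect_lt(abs(r(d_a, "MZ") - 2 * r(d_a, "DZ")), 0.07)
})

test_that("unconstrained saturated fit reproduces sample cell moments", {
  set.seed(91)
  n <- 150
  y1 <- rnorm(2 * n, 0.3, 1.1); y2 <- 0.5 * y1 + rnorm(2 * n, 0.1, 0.8)
  td <- toy_twin_data(y1, y2, rep(c("MZ", "DZ"), each = n))
  fit <- fit_saturated(td, covariates = FALSE)
  for (z in c("MZ", "DZ")) {
    rows <- td$zygosity == z
    Y <- cbind(td$y_t1[rows], td$y_t2[rows])
    ml_cov <- cov(Y) * (n - 1) / n  # ML (not n-1) covariance
    expect_equal(fit$implied[[z]], ml_cov, tolerance = 0.02)
  }
  expect_equal(fit$n_params, 10)
})

test_that("an injected twin-order mean effect is detected by the constraint test", {
  set.seed(92)
  n <- 200
  y1 <- rnorm(2 * n); y2 <- rnorm(2 * n) + 0.5  # large order effect
  td <- toy_twin_data(y1, y2, rep(c("MZ", "DZ"), each = n))
  free <- fit_saturated(td, covariates = FALSE)
  con <- fit_saturated(td, equate = c("means_order"), covariates = FALSE)
  cmp <- compare_models(free, con)
  expect_lt(cmp$p_value, 0.001)
})

test_that("fully saturated two-trait parameter count satisfies the df identity", {
  spec <- bivariate_ae_spec(0.19, 0.16, 0.29, 0.97)
  d <- simulate_twin_phenotypes(spec, 80, 63, incomplete_rate = 0.24,
                                seed = 95)
  n_infants <- sum(d$present_t1) + sum(d$present_t2)
  fit <- fit_saturated(d)
  expect_equal(fit$n_params, 32)
  expect_equal(fit$n_data, n_infants * 2)
  expect_equal(fit$df, n_infants * 2 - 32)
})

test_that("model comparison arithmetic and selection follow the conventions", {
  full <- model_fit_stats(1167.82, 15, 1072)
  ae <- model_fit_stats(1169.33, 12, 1072)
  e <- model_fit_stats(1211.82, 9, 1072)
  cmp_ae <- compare_models(full, ae, label = "AE")
  expect_equal(cmp_ae$delta_chi2, 1.51, tolerance = 1e-9)
  expect_equal(cmp_ae$delta_df, 3)
  cmp_e <- compare_models(full, e, label = "E")
  expect_equal(cmp_e$delta_chi2, 44, tolerance = 1e-9)
  expect_equal(cmp_e$delta_df, 6)
  # identical fits: delta 0, p 1
  same <- compare_models(full, model_fit_stats(1167.82, 12, 1072))
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p_value, 1)
  # mis-ordered models rejected
  expect_error(compare_models(ae, full), "fewer parameters")
  expect_error(compare_models(full, model_fit_stats(1100, 12, 1072)),
               "mis-ordered|better")
})

test_that("the retained model with lowest AIC is selected, full as fallback", {
  full <- model_fit_stats(1167.82, 15, 1072)
  ae <- model_fit_stats(1169.33, 12, 1072)   # p = 0.680, AIC -950.67
  ce <- model_fit_stats(1175.34, 12, 1072)   # p = 0.057, AIC -944.66
  e <- model_fit_stats(1211.82, 9, 1072)     # p < 0.001
  cmps <- list(AE = compare_models(full, ae, label = "AE"),
               CE = compare_models(full, ce, label = "CE"),
               E = compare_models(full, e, label = "E"))
  expect_equal(round(cmps$AE$p_value, 3), 0.680)
  expect_equal(round(cmps$CE$p_value, 3), 0.057)
  sel <- select_best(cmps)
  expect_equal(sel$label, "AE")
  expect_equal(sel$fit$AIC, -950.67, tolerance = 1e-9)
  # all nested rejected -> full returned
  worse <- list(compare_models(full, model_fit_stats(1250, 12, 1072),
                               label = "bad"))
  expect_false(select_best(worse)$selected_nested)
  # equal AIC tie: fewest parameters wins
  t1 <- model_fit_stats(1169.0, 12, 1072)       # AIC 1169 - 2*1060
  t2 <- model_fit_stats(1169.0 + 2, 11, 1072)   # same AIC, fewer params
  tie <- list(a = compare_models(full, t1, label = "p12"),
              b = compare_models(full, t2, label = "p11"))
  expect_equal(tie$a$nested$AIC, tie$b$nested$AIC)
  expect_equal(select_best(tie)$label, "p11")
  expect_error(select_best(list()), "empty")
})

test_that("near-duplicate co-twins drive the MZ correlation to one", {
  set.seed(96)
  y <- rnorm(80)
  td <- toy_twin_data(c(y, rnorm(60)),
                      c(y + 0.01 * rnorm(80), rnorm(60)),
                      rep(c("MZ", "DZ"), c(80, 60)))
  tc <- twin_correlations(td, ci = FALSE, covariates = FALSE)
  expect_gt(tc$estimate[tc$zygosity == "MZ"], 0.95)
  expect_lt(abs(tc$estimate[tc$zygosity == "DZ"]), 0.25)
})

test_that("constrained-saturated correlations agree with double-entry Pearson", {
  spec <- univariate_spec(a2 = 0.46)
  d <- simulate_twin_phenotypes(spec, 400, 400, seed = 97)
  tc <- twin_correlations(d, ci = FALSE, covariates = FALSE)
  for (z in c("MZ", "DZ")) {
    rows <- d$zygosity == z
    de <- cor(c(d$trait_t1[rows], d$trait_t2[rows]),
              c(d$trait_t2[rows], d$trait_t1[rows]))
    got <- tc$estimate[tc$zygosity == z & tc$quantity == "twin_correlation"]
    expect_lt(abs(got - de), 0.01)
  }
})

test_that("twin correlation CIs bracket the estimate and respond to n", {
  spec <- univariate_spec(a2 = 0.46)
  d <- simulate_twin_phenotypes(spec, 150, 120, seed = 98)
  tc <- twin_correlations(d, ci = TRUE, covariates = FALSE)
  mz <- tc[tc$zygosity == "MZ" & tc$quantity == "twin_correlation", ]
  expect_true(mz$lower < mz$estimate & mz$estimate < mz$upper)
  expect_gt(mz$upper - mz$lower, 0.05)
})

test_that("standardized components follow the path algebra", {
  # univariate: a = 0.6, e = 0.8 -> a2 = 0.36
  td <- toy_twin_data(rnorm(10), rnorm(10), rep(c("MZ", "DZ"), 5))
  fit <- fit_model(td, c("A", "E"), covariates = FALSE)
  fit$paths$A <- matrix(0.6); fit$paths$E <- matrix(0.8)
  fit$implied <- implied_moments(path_a = 0.6, path_e = 0.8)
  std <- standardize_components(fit)
  expect_equal(std$components$estimate[std$components$component == "A"],
               0.36, tolerance = 1e-12)
  # shared + unique A equals trait-2 total a2 for random bivariate paths
  set.seed(99)
  for (rep in 1:5) {
    La <- rbind(c(runif(1, 0.2, 0.7), 0), runif(2, 0.1, 0.6))
    Le <- rbind(c(runif(1, 0.4, 0.9), 0), runif(2, 0.2, 0.8))
    fit2 <- fit
    fit2$traits <- c("x", "y")
    fit2$components <- c("A", "E")
    fit2$paths <- list(A = La, E = Le)
    fit2$implied <- implied_moments(path_a = La, path_e = Le)
    std2 <- standardize_components(fit2)
    tot_a2 <- std2$components$estimate[std2$components$component == "A" &
                                         std2$components$trait == "y"]
    biv_a <- std2$bivariate[std2$bivariate$component == "A", ]
    expect_equal(biv_a$shared + biv_a$unique, tot_a2, tolerance = 1e-9)
    # implied phenotypic correlation from the cross-covariance algebra
    V <- diag(fit2$implied$within)
    expect_equal(std2$r_Ph,
                 (La[1, 1] * La[2, 1] + Le[1, 1] * Le[2, 1]) /
                   sqrt(V[1] * V[2]), tolerance = 1e-9)
  }
})

test_that("profile CI matches a dense grid scan on a small dataset", {
  spec <- univariate_spec(a2 = 0.45)
  d <- simulate_twin_phenotypes(spec, 120, 100, seed = 105)
  fit <- fit_model(d, c("A", "E"), covariates = FALSE)
  ci <- profile_ci(fit, "a2")
  # grid oracle: profile deviance over standardized a2 via constrained refits
  vhat <- attr(ci, "estimate")
  grid <- seq(0.01, 0.95, by = 0.01)
  prof <- vapply(grid, function(v) {
    obj <- function(par) {  # par = (e, mean); a from the constraint
      e <- par[1]
      a <- sqrt(v / (1 - v)) * abs(e)
      fiml_minus2ll(d, path_a = a, path_e = e, means = par[2])
    }
    optim(c(sqrt(1 - vhat), mean(c(d$trait_t1, d$trait_t2), na.rm = TRUE)),
          obj, method = "BFGS")$value
  }, numeric(1))
  inside <- grid[prof <= fit$minus2LL + qchisq(0.95, 1)]
  expect_lt(abs(min(inside) - ci["lower"]), 0.02)
  expect_lt(abs(max(inside) - ci["upper"]), 0.02)
  expect_true(ci["lower"] < vhat && vhat < ci["upper"])
})

test_that("a component that is truly zero has a boundary lower bound", {
  d <- simulate_twin_phenotypes(univariate_spec(a2 = 0.4), 250, 250,
                                seed = 106)
  fit <- fit_model(d, c("A", "C", "E"))
  ci_c <- profile_ci(fit, "c2")
  expect_equal(unname(ci_c["lower"]), 0)
  expect_lte(ci_c["lower"], attr(ci_c, "estimate"))
})
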