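test_that("effect size d is the exact closed form on any input", {
  # vector engineered to the reported overall moments
  x <- c(0.44 - 0.14, 0.44, 0.44 + 0.14, 0.44, 0.44 - 0.14, 0.44 + 0.14)
  x <- 0.44 + (x - mean(x)) / sd(x) * 0.14
  res <- test_against_chance(x, chance = 0.2)
  expect_equal(res$d, (0.44 - 0.2) / 0.14, tolerance = 1e-12)
  expect_equal(round(res$d, 2), 1.71)
  # values at chance give d = 0 (jittered to avoid degeneracy)
  y <- 0.2 + c(-1, 1, -1, 1, -1, 1) * 1e-6
  expect_equal(test_against_chance(y)$d, 0, tolerance = 1e-6)
  expect_error(test_against_chance(rep(0.3, 10)), "degenerate")
})

test_that("the Shapiro-Wilk branch selects t for normal and Wilcoxon for skewed data", {
  set.seed(42)
  xn <- rnorm(300, 0.44, 0.14)
  rn <- test_against_chance(xn)
  expect_equal(rn$test, "t")
  expect_equal(rn$statistic, unname(t.test(xn, mu = 0.2)$statistic))
  expect_equal(rn$df, 299)
  xs <- rbeta(300, 1.2, 4)  # right-skewed
  rs <- test_against_chance(xs)
  expect_equal(rs$test, "wilcoxon")
})

test_that("Wilcoxon statistic equals exhaustive signed-rank enumeration", {
  x <- c(0.31, 0.15, 0.42, 0.05, 0.55, 0.27)
  res <- suppressWarnings(test_against_chance(x, chance = 0.2,
                                              shapiro_alpha = 1))
  # force the Wilcoxon branch via shapiro_alpha = 1; enumerate V by hand
  d <- x - 0.2
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$statistic, V)
})

test_that("skewness matches a from-scratch third-moment computation", {
  expect_equal(skewness_coef(c(-1, 0, 1)), 0, tolerance = 1e-12)
  expect_gt(skewness_coef(c(0, 0, 0, 1)), 0)
  set.seed(8)
  for (rep in 1:5) {
    x <- rnorm(sample(10:200, 1))^sample(1:3, 1)
    n <- length(x)
    m3 <- sum((x - mean(x))^3) / n
    m2 <- sum((x - mean(x))^2) / n
    want <- m3 / m2^1.5 * sqrt(n * (n - 1)) / (n - 2)
    expect_equal(skewness_coef(x), want, tolerance = 1e-10)
  }
  expect_error(skewness_coef(rep(1, 5)), "variance")
})

test_that("cluster sandwich equals the brute-force score outer products", {
  set.seed(21)
  n <- 240
  d <- data.frame(pair_id = rep(sprintf("p%03d", 1:(n / 2)), each = 2),
                  x = rnorm(n), z = rnorm(n))
  d$y <- 0.3 * d$x + rnorm(n)
  fit <- gee_fit(d, "y", c("x", "z"), covariates = character(0))
  ds <- d
  ds$y <- as.numeric(scale(d$y)); ds$x <- as.numeric(scale(d$x))
  ds$z <- as.numeric(scale(d$z))
  X <- cbind(1, ds$x, ds$z)
  beta <- solve(crossprod(X), crossprod(X, ds$y))
  V <- sandwich_oracle(X, ds$y, beta, d$pair_id)
  expect_equal(fit$coefficients$beta, as.numeric(beta[2:3]),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$se, sqrt(diag(V))[2:3], tolerance = 1e-10)
})

test_that("point estimates are identical with and without clustering", {
  set.seed(22)
  n <- 200
  d <- data.frame(pair_id = rep(sprintf("p%03d", 1:(n / 2)), each = 2),
                  x = rnorm(n))
  d$y <- 0.4 * d$x + rnorm(n)
  d2 <- d; d2$unit <- sprintf("u%03d", seq_len(n))
  f_cl <- gee_fit(d, "y", "x", covariates = character(0))
  f_un <- gee_fit(d2, "y", "x", covariates = character(0), cluster = "unit")
  expect_equal(f_cl$coefficients$beta, f_un$coefficients$beta,
               tolerance = 1e-12)
  # singleton clusters reduce to HC0 least-squares errors
  ds <- d2; ds$ys <- as.numeric(scale(d2$y)); ds$xs <- as.numeric(scale(d2$x))
  lmfit <- lm(ys ~ xs, data = ds)
  hc0 <- sqrt(diag(sandwich::vcovHC(lmfit, type = "HC0")))
  expect_equal(f_un$coefficients$se, unname(hc0[2]), tolerance = 1e-10)
})

test_that("a singular design names the collinear column", {
  d <- data.frame(pair_id = rep(c("a", "b", "c"), each = 2),
                  x = rnorm(6))
  d$x2 <- 2 * d$x
  d$y <- rnorm(6)
  expect_error(gee_fit(d, "y", c("x", "x2"), covariates = character(0)),
               "collinear")
})

test_that("cluster-robust inference holds its nominal size, naive errors do not", {
  set.seed(31)
  n_pairs <- 400  # enough clusters for the sandwich to be near-unbiased
  reps <- 1000
  rej_robust <- logical(reps); rej_naive <- logical(reps)
  for (r in seq_len(reps)) {
    pid <- rep(seq_len(n_pairs), each = 2)
    # pair-clustered predictor and outcome, true slope zero
    x <- rnorm(n_pairs)[pid] * sqrt(0.7) + rnorm(2 * n_pairs) * sqrt(0.3)
    u <- rnorm(n_pairs)[pid]
    y <- sqrt(0.6) * u + sqrt(0.4) * rnorm(2 * n_pairs)
    X <- cbind(1, (x - mean(x)) / sd(x))
    ys <- (y - mean(y)) / sd(y)
    beta <- solve(crossprod(X), crossprod(X, ys))
    res <- ys - X %*% beta
    # naive OLS variance
    v_naive <- sum(res^2) / (length(ys) - 2) * solve(crossprod(X))[2, 2]
    V <- sandwich_oracle(X, ys, beta, pid)
    rej_robust[r] <- abs(beta[2] / sqrt(V[2, 2])) > qnorm(0.975)
    rej_naive[r] <- abs(beta[2] / sqrt(v_naive)) > qnorm(0.975)
  }
  expect_gt(mean(rej_robust), 0.03)
  expect_lt(mean(rej_robust), 0.07)
  expect_gt(mean(rej_naive), mean(rej_robust))
})

test_that("BH step-up reproduces the reported thresholds and flags", {
  res <- fdr_stepup(c(0.003, 0.248, 0.475, 0.530, 0.548), q = 0.05)
  expect_equal(sort(res$threshold), c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(res$threshold[1], 0.01)
  expect_identical(res$significant, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(fdr_stepup(rep(1, 8))$significant))
  expect_error(fdr_stepup(c(0.5, 1.2)), "0, 1|\\[0, 1\\]")
})

test_that("BH flags match the reference procedure and are monotone in q", {
  set.seed(51)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- fdr_stepup(p, q = 0.05)
    expect_identical(got$significant, bh_oracle(p, 0.05))
    # agreement with p.adjust as an independent reference
    expect_identical(got$significant, unname(p.adjust(p, "BH") <= 0.05))
    lo <- fdr_stepup(p, q = 0.01)
    expect_true(all(got$significant[lo$significant]))
  }
})
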