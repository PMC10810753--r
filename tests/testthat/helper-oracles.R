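# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths (loops instead of
# rle/chol/vectorised algebra) so agreement is evidence, not tautology.

# build a gaze_trial whose samples realise a given AOI-label schedule;
# NA labels land at the screen centre (outside every AOI)
make_trial_from_labels <- function(labels, scene = gaze_scene(1),
                                   valid = rep(1L, length(labels)),
                                   hz = 120) {
  a <- scene$aois
  cx <- (a$x0 + a$x1) / 2
  cy <- (a$y0 + a$y1) / 2
  i <- match(labels, a$label)
  x <- ifelse(is.na(i), scene$screen[1] / 2, cx[i])
  y <- ifelse(is.na(i), scene$screen[2] / 2, cy[i])
  x[valid == 0] <- NA_real_
  y[valid == 0] <- NA_real_
  gaze_trial(data.frame(t_ms = (seq_along(labels) - 1) * 1000 / hz,
                        x_px = x, y_px = y, valid = valid),
             scene, infant_id = "i1", trial_index = 1L)
}

# scalar state-machine look scanner: same rules as detect_looks, written
# as an explicit per-sample loop
naive_looks <- function(labels, valid, min_samples = 3, max_gap = 1,
                        hz = 120) {
  n <- length(labels)
  lab <- ifelse(valid == 1, labels, NA_character_)
  # bridge isolated invalid gaps
  i <- 1
  while (i <= n) {
    if (valid[i] == 0) {
      j <- i
      while (j < n && valid[j + 1] == 0) j <- j + 1
      if ((j - i + 1) <= max_gap && i > 1 && j < n &&
          !is.na(lab[i - 1]) && !is.na(lab[j + 1]) &&
          lab[i - 1] == lab[j + 1])
        lab[i:j] <- lab[i - 1]
      i <- j + 1
    } else i <- i + 1
  }
  out <- NULL
  i <- 1
  while (i <= n) {
    if (is.na(lab[i])) { i <- i + 1; next }
    j <- i
    while (j < n && !is.na(lab[j + 1]) && lab[j + 1] == lab[i]) j <- j + 1
    if ((j - i + 1) >= min_samples)
      out <- rbind(out, data.frame(label = lab[i],
                                   onset_ms = (i - 1) * 1000 / hz,
                                   n_samples = j - i + 1,
                                   stringsAsFactors = FALSE))
    i <- j + 1
  }
  if (is.null(out))
    out <- data.frame(label = character(0), onset_ms = numeric(0),
                      n_samples = integer(0))
  out
}

# multivariate-normal -2 log density from the closed form (solve/det)
m2ll_oracle <- function(y, mu, S) {
  r <- y - mu
  length(y) * log(2 * pi) + log(det(S)) +
    as.numeric(t(r) %*% solve(S) %*% r)
}

# Benjamini-Hochberg flags by explicit loop
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  pass <- logical(m)
  kmax <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) kmax <- i
  if (kmax > 0) pass[ord[seq_len(kmax)]] <- TRUE
  pass
}

# cluster sandwich covariance by per-cluster score outer products
sandwich_oracle <- function(X, y, beta, cluster) {
  res <- y - X %*% beta
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    s <- t(X[idx, , drop = FALSE]) %*% res[idx]
    meat <- meat + s %*% t(s)
  }
  bread %*% meat %*% bread
}

# small twin dataset straight from per-pair values (complete pairs)
toy_twin_data <- function(y1, y2, zyg, traits = "y", age = 168, sex = 0) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  df <- data.frame(pair_id = sprintf("p%03d", seq_len(nrow(y1))),
                   zygosity = zyg,
                   age_days = rep_len(age, nrow(y1)),
                   sex = rep_len(sex, nrow(y1)), stringsAsFactors = FALSE)
  for (j in seq_along(traits)) {
    df[[paste0(traits[j], "_t1")]] <- y1[, j]
    df[[paste0(traits[j], "_t2")]] <- y2[, j]
  }
  twin_pair_dataset(df, traits = traits)
}
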