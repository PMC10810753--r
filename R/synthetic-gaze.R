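#' Gaze-rendering parameters
#'
#' Settings for rendering latent looking traits as raw 120 Hz gaze-sample
#' streams over 20 s pop-out trials. The generative law is deliberately
#' minimal: a lognormal latency to the first saccade; a first-look AOI drawn
#' with a face probability tied to the infant's orienting trait (softmax over
#' the five objects with a face bonus); subsequent looks follow a Markov chain
#' that jumps uniformly among the other AOIs, with the mean dwell on the face
#' scaled so its stationary occupancy equals the infant's face dwell-share
#' parameter. Missingness is i.i.d. per-sample dropout plus geometric blink
#' bursts, at a per-infant rate drawn from a Beta distribution with mean 0.28
#' and s.d. 0.13.
#'
#' Latent (standardized) traits map to the unit-interval parameters through a
#' probit link calibrated by numerical integration so the cohort mean and
#' s.d. of the parameter hit the targets: first-look face probability
#' mean 0.30, and face dwell-share mean 0.44 / s.d. 0.14. The orienting
#' parameter s.d. defaults to 0.10 because the observed 6-trial proportion
#' adds binomial trial noise on top of the between-infant spread.
#'
#' @param sampling_rate_hz Nominal sampling rate (Hz).
#' @param trial_duration_s Trial length (s).
#' @param n_trials Trials per infant.
#' @param latency_meanlog,latency_sdlog Lognormal parameters of the latency to
#'   the first AOI look, in seconds.
#' @param object_dwell_mean_s Mean dwell per look on a non-face object (s);
#'   controls how many objects are visited in the 10 s exploration window.
#' @param glance_mean_s Mean duration of the initial orienting glance (s).
#' @param orient_mean,orient_sd Target cohort mean/s.d. of the per-infant
#'   first-look-at-face probability.
#' @param pref_mean,pref_sd Target cohort mean/s.d. of the per-infant face
#'   dwell-share parameter.
#' @param miss_mean,miss_sd Mean/s.d. of the per-infant missingness rate
#'   (Beta-distributed); set `miss_mean = 0` for no dropout.
#' @param blink_mean_samples Mean length of a blink burst, in samples.
#' @param dwell_noise `"exponential"` (stochastic dwells) or `"none"`
#'   (deterministic dwell schedule realising the face share exactly; used for
#'   round-trip testing).
#' @return A list of class `gaze_params`.
#' @export
gaze_params <- function(sampling_rate_hz = 120, trial_duration_s = 20,
                        n_trials = 6L,
                        latency_meanlog = log(0.4), latency_sdlog = 0.5,
                        object_dwell_mean_s = 1.5, glance_mean_s = 0.6,
                        orient_mean = 0.30, orient_sd = 0.10,
                        pref_mean = 0.44, pref_sd = 0.14,
                        miss_mean = 0.28, miss_sd = 0.13,
                        blink_mean_samples = 12,
                        dwell_noise = c("exponential", "none")) {
  structure(list(
    sampling_rate_hz = sampling_rate_hz, trial_duration_s = trial_duration_s,
    n_trials = as.integer(n_trials),
    latency_meanlog = latency_meanlog, latency_sdlog = latency_sdlog,
    object_dwell_mean_s = object_dwell_mean_s, glance_mean_s = glance_mean_s,
    orient_mean = orient_mean, orient_sd = orient_sd,
    pref_mean = pref_mean, pref_sd = pref_sd,
    miss_mean = miss_mean, miss_sd = miss_sd,
    blink_mean_samples = blink_mean_samples,
    dwell_noise = match.arg(dwell_noise)
  ), class = "gaze_params")
}

#' Calibrate a probit link from a standard-normal latent to a (0,1) parameter
#'
#' Finds `(m, s)` such that `g(z) = pnorm(m + s z)`, `z ~ N(0,1)`, has the
#' requested mean and standard deviation (by numerical integration). Keeps the
#' ACE structure of the latent approximately linear on the observed scale for
#' moderate spreads.
#'
#' @param target_mean,target_sd Desired moments of `g(z)`.
#' @return A function `g(z)` with attributes `m` and `s`.
#' @export
calibrate_probit_link <- function(target_mean, target_sd) {
  if (target_sd <= 0) {
    m <- qnorm(target_mean)
    g <- function(z) rep(target_mean, length(z))
    attr(g, "m") <- m; attr(g, "s") <- 0
    return(g)
  }
  moments <- function(par) {
    m <- par[1]; s <- exp(par[2])
    mu <- integrate(function(z) pnorm(m + s * z) * dnorm(z), -8, 8)$value
    m2 <- integrate(function(z) pnorm(m + s * z)^2 * dnorm(z), -8, 8)$value
    c(mu, sqrt(max(m2 - mu^2, 0)))
  }
  obj <- function(par) {
    mo <- moments(par)
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- optim(c(qnorm(target_mean), log(target_sd * 3)), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  m <- fit$par[1]; s <- exp(fit$par[2])
  g <- function(z) pnorm(m + s * z)
  attr(g, "m") <- m; attr(g, "s") <- s
  g
}

# jittered coordinate inside an AOI rectangle (inner 80% band)
.aoi_point <- function(aoi_row, n) {
  wx <- aoi_row$x1 - aoi_row$x0; wy <- aoi_row$y1 - aoi_row$y0
  cbind(x = aoi_row$x0 + wx * runif(n, 0.1, 0.9),
        y = aoi_row$y0 + wy * runif(n, 0.1, 0.9))
}

# one trial's look schedule: data.frame(label, dur_s), starting after latency
.trial_looks <- function(p_first, face_share, labels, gp) {
  t_aoi <- gp$trial_duration_s
  if (gp$dwell_noise == "none") {
    # deterministic round-robin realising the face share exactly
    first <- if (p_first >= 0.5) "face" else setdiff(labels, "face")[1]
    others <- setdiff(labels, "face")
    seq_lab <- unique(c(first, "face", others))
    durs <- ifelse(seq_lab == "face", face_share * t_aoi,
                   (1 - face_share) * t_aoi / length(others))
    return(data.frame(label = seq_lab, dur_s = durs, stringsAsFactors = FALSE))
  }
  d_obj <- gp$object_dwell_mean_s
  face_share <- min(max(face_share, 1e-3), 1 - 1e-3)
  # uniform jumps among the other four AOIs make embedded-chain visits
  # uniform, so occupancy is proportional to mean dwell
  d_face <- (length(labels) - 1) * d_obj * face_share / (1 - face_share)
  # short orienting glance (the first look, tied to the orienting trait),
  # then the dwell chain started in its stationary distribution: with
  # memoryless dwells this makes the expected face occupancy exact
  labs <- if (runif(1) < p_first) "face" else sample(setdiff(labels, "face"), 1)
  durs <- rexp(1, 1 / gp$glance_mean_s)
  t <- durs
  cur <- if (runif(1) < face_share) "face" else sample(setdiff(labels, "face"), 1)
  while (t < t_aoi) {
    d <- rexp(1, 1 / if (cur == "face") d_face else d_obj)
    labs <- c(labs, cur); durs <- c(durs, d); t <- t + d
    cur <- sample(setdiff(labels, cur), 1)
  }
  durs[length(durs)] <- durs[length(durs)] - (t - t_aoi)
  data.frame(label = labs, dur_s = durs, stringsAsFactors = FALSE)
}

# render one trial to a sample table
.render_trial <- function(p_first, face_share, miss_rate, scene, gp) {
  dt_ms <- 1000 / gp$sampling_rate_hz
  n_samp <- round(gp$trial_duration_s * gp$sampling_rate_hz)
  t_ms <- (seq_len(n_samp) - 1) * dt_ms
  lat_s <- if (gp$dwell_noise == "none") exp(gp$latency_meanlog) else
    rlnorm(1, gp$latency_meanlog, gp$latency_sdlog)
  lat_s <- min(lat_s, gp$trial_duration_s / 2)
  x <- rep(scene$screen[1] / 2, n_samp)  # gaze starts at screen centre
  y <- rep(scene$screen[2] / 2, n_samp)
  looks <- .trial_looks(p_first, face_share, scene$aois$label, gp)
  # map the look schedule (compressed into the post-latency window) to samples
  avail <- gp$trial_duration_s - lat_s
  looks$dur_s <- looks$dur_s * avail / sum(looks$dur_s)
  ends <- lat_s + cumsum(looks$dur_s)
  starts <- c(lat_s, head(ends, -1))
  for (i in seq_len(nrow(looks))) {
    idx <- which(t_ms / 1000 >= starts[i] & t_ms / 1000 < ends[i])
    if (!length(idx)) next
    row <- scene$aois[scene$aois$label == looks$label[i], ]
    pt <- .aoi_point(row, length(idx))
    x[idx] <- pt[, "x"]; y[idx] <- pt[, "y"]
  }
  valid <- rep(1L, n_samp)
  if (miss_rate > 0) {
    # split the target rate between i.i.d. dropout and blink bursts; each
    # mechanism gets 1 - sqrt(1 - r) so the union hits the target rate
    r_adj <- 1 - sqrt(1 - min(miss_rate, 0.99))
    valid[runif(n_samp) < r_adj] <- 0L
    exp_burst <- r_adj * n_samp / gp$blink_mean_samples
    n_burst <- rbinom(1, n_samp, exp_burst / n_samp)
    if (n_burst > 0) {
      st <- sample.int(n_samp, n_burst)
      len <- rgeom(n_burst, 1 / gp$blink_mean_samples) + 1
      for (b in seq_len(n_burst))
        valid[st[b]:min(n_samp, st[b] + len[b] - 1)] <- 0L
    }
  }
  x[valid == 0L] <- NA_real_; y[valid == 0L] <- NA_real_
  data.frame(t_ms = t_ms, x_px = x, y_px = y, valid = valid)
}

#' Render a twin cohort as raw gaze-sample streams
#'
#' Turns each present infant's latent orienting and preference traits into
#' per-infant first-look and dwell-share parameters (calibrated probit links)
#' and renders six (or `n_trials`) 20 s trials of 120 Hz gaze samples over the
#' pop-out scenes. Gaze sits at the screen centre until the first saccade,
#' mirroring the gaze-contingent trial start.
#'
#' @param twins A `twin_data` object whose traits include `orienting` and
#'   `preference` latent values (as produced by [simulate_twin_phenotypes()]).
#' @param gp A [gaze_params()] list.
#' @param scenes List of `gaze_scene`s (recycled over trials).
#' @param seed Integer seed.
#' @return A tidy data frame with columns `infant_id, pair_id, zygosity,
#'   trial_index, stimulus_id, t_ms, x_px, y_px, valid`, and an attribute
#'   `truth` holding the per-infant generating parameters.
#' @export
simulate_gaze_cohort <- function(twins, gp = gaze_params(),
                                 scenes = default_scenes(), seed = 1L) {
  for (sc in scenes) validate_scene(sc)
  set.seed(seed)
  infants <- .cohort_infants(twins)
  g_or <- calibrate_probit_link(gp$orient_mean, gp$orient_sd)
  g_pr <- calibrate_probit_link(gp$pref_mean, gp$pref_sd)
  infants$p_first <- g_or(infants$orienting)
  infants$dwell_share <- g_pr(infants$preference)
  infants$miss_rate <- .rbeta_ms(nrow(infants), gp$miss_mean, gp$miss_sd)
  out <- vector("list", nrow(infants) * gp$n_trials)
  k <- 0
  for (i in seq_len(nrow(infants))) {
    for (tr in seq_len(gp$n_trials)) {
      sc <- scenes[[((tr - 1) %% length(scenes)) + 1]]
      samp <- .render_trial(infants$p_first[i], infants$dwell_share[i],
                            infants$miss_rate[i], sc, gp)
      k <- k + 1
      out[[k]] <- cbind(
        data.frame(infant_id = infants$infant_id[i],
                   pair_id = infants$pair_id[i],
                   zygosity = infants$zygosity[i],
                   trial_index = tr, stimulus_id = sc$stimulus_id,
                   stringsAsFactors = FALSE),
        samp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- infants
  res
}

# per-infant table (present twins only) with latent trait columns
.cohort_infants <- function(twins) {
  traits <- attr(twins, "traits")
  need <- c("orienting", "preference")
  if (!all(need %in% traits))
    stop("twin dataset must carry 'orienting' and 'preference' traits")
  rows <- list()
  for (tw in 1:2) {
    suf <- paste0("_t", tw)
    lat_cols <- paste0(need, "_latent", suf)
    use_lat <- all(lat_cols %in% names(twins))
    src <- if (use_lat) lat_cols else paste0(need, suf)
    present <- if (paste0("present", suf) %in% names(twins))
      twins[[paste0("present", suf)]] else !is.na(twins[[src[1]]])
    d <- data.frame(
      infant_id = paste0(twins$pair_id, "_", tw),
      pair_id = twins$pair_id, zygosity = twins$zygosity,
      age_days = twins$age_days, sex = twins$sex,
      orienting = twins[[src[1]]], preference = twins[[src[2]]],
      stringsAsFactors = FALSE)
    rows[[tw]] <- d[present, ]
  }
  out <- rbind(rows[[1]], rows[[2]])
  out[order(out$pair_id, out$infant_id), ]
}

# Beta draw parameterised by mean and s.d. (degenerate cases allowed)
.rbeta_ms <- function(n, m, s) {
  if (m <= 0) return(rep(0, n))
  if (s <= 0) return(rep(m, n))
  nu <- m * (1 - m) / s^2 - 1
  if (nu <= 0) stop("infeasible Beta mean/sd")
  rbeta(n, m * nu, (1 - m) * nu)
}

#' Simulate longitudinal parent-report outcomes
#'
#' Builds a standardized outcome with a chosen standardized association to a
#' predictor: `outcome = beta * predictor + covariate effects + residual`,
#' residual variance `1 - beta^2`, optionally with exchangeable within-pair
#' residual correlation to exercise cluster-robust inference.
#'
#' @param phenotypes Data frame with one row per child, containing the
#'   predictor column, `pair_id`, and optionally `age_days` and `sex`.
#' @param predictor Name of the (standardized) predictor column.
#' @param beta Generating standardized slope, `|beta| < 1`.
#' @param resid_icc Exchangeable within-pair correlation of the residual.
#' @param beta_age,beta_sex Covariate effects added to the linear predictor.
#' @param seed Integer seed.
#' @return `phenotypes` with an added `outcome` column.
#' @export
simulate_outcomes <- function(phenotypes, predictor, beta, resid_icc = 0,
                              beta_age = 0, beta_sex = 0, seed = 1L) {
  if (abs(beta) >= 1) stop("|beta| must be < 1 for a standardized outcome")
  set.seed(seed)
  x <- phenotypes[[predictor]]
  x <- (x - mean(x)) / sd(x)
  n <- length(x)
  pid <- factor(phenotypes$pair_id)
  u <- rnorm(nlevels(pid))[as.integer(pid)]
  eps <- sqrt(resid_icc) * u + sqrt(1 - resid_icc) * rnorm(n)
  lin <- beta * x
  if (beta_age != 0 && "age_days" %in% names(phenotypes))
    lin <- lin + beta_age * as.numeric(scale(phenotypes$age_days))
  if (beta_sex != 0 && "sex" %in% names(phenotypes))
    lin <- lin + beta_sex * phenotypes$sex
  phenotypes$outcome <- lin + sqrt(1 - beta^2) * eps
  phenotypes
}
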