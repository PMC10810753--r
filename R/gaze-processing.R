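#' One trial of gaze samples
#'
#' Bundles an infant's timestamped gaze samples for one stimulus with the
#' scene (AOI layout) shown on that trial. Sample times must be strictly
#' increasing; the nominal inter-sample gap is 1/120 s.
#'
#' @param samples Data frame with columns `t_ms, x_px, y_px, valid` (0/1).
#' @param scene A `gaze_scene`.
#' @param infant_id,trial_index Identifiers carried through to measures.
#' @return An object of class `gaze_trial`.
#' @export
gaze_trial <- function(samples, scene, infant_id = NA_character_,
                       trial_index = NA_integer_) {
  need <- c("t_ms", "x_px", "y_px", "valid")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing sample columns: ", paste(miss, collapse = ", "))
  if (nrow(samples) > 1 && any(diff(samples$t_ms) <= 0))
    stop("sample times must be strictly increasing")
  structure(list(infant_id = infant_id, trial_index = trial_index,
                 stimulus_id = scene$stimulus_id,
                 samples = samples, scene = scene),
            class = "gaze_trial")
}

#' Detect looks (AOI dwell episodes) in a trial
#'
#' A look is a maximal run of at least `min_samples` consecutive samples
#' assigned to the same AOI. A single invalid (missing) sample inside a run
#' is tolerated and inherits the flanking AOI when both neighbours agree
#' (interpolation-lite, up to `max_gap` consecutive invalid samples); valid
#' samples outside every AOI always break a run. Runs shorter than
#' `min_samples` are discarded.
#'
#' @param trial A `gaze_trial`.
#' @param min_samples Minimum run length (default 3 samples, about 25 ms at
#'   120 Hz).
#' @param max_gap Maximum bridged gap of invalid samples inside a run.
#' @return Data frame with one row per look: `label, onset_ms, offset_ms,
#'   duration_ms, n_samples`, ordered by onset. Empty trials give zero rows.
#' @export
detect_looks <- function(trial, min_samples = 3L, max_gap = 1L) {
  s <- trial$samples
  empty <- data.frame(label = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), duration_ms = numeric(0),
                      n_samples = integer(0), stringsAsFactors = FALSE)
  if (nrow(s) == 0) return(empty)
  lab <- rep(NA_character_, nrow(s))
  ok <- s$valid == 1
  lab[ok] <- assign_aoi(s$x_px[ok], s$y_px[ok], trial$scene)
  # bridge short invalid gaps flanked by the same AOI
  if (max_gap > 0) {
    inv <- which(!ok)
    if (length(inv)) {
      r <- rle(!ok)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (g in which(r$values & r$lengths <= max_gap)) {
        i0 <- starts[g]; i1 <- ends[g]
        if (i0 > 1 && i1 < nrow(s) &&
            !is.na(lab[i0 - 1]) && identical(lab[i0 - 1], lab[i1 + 1]))
          lab[i0:i1] <- lab[i0 - 1]
      }
    }
  }
  key <- ifelse(is.na(lab), ".none", lab)
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values != ".none" & r$lengths >= min_samples
  if (!any(keep)) return(empty)
  dt <- if (nrow(s) > 1) stats::median(diff(s$t_ms)) else 1000 / 120
  looks <- data.frame(
    label = r$values[keep],
    onset_ms = s$t_ms[starts[keep]],
    offset_ms = s$t_ms[ends[keep]] + dt,
    n_samples = r$lengths[keep],
    stringsAsFactors = FALSE
  )
  looks$duration_ms <- looks$n_samples * dt
  looks[order(looks$onset_ms),
        c("label", "onset_ms", "offset_ms", "duration_ms", "n_samples")]
}

#' Trial validity per the exclusion rules
#'
#' A trial is valid iff the proportion of valid (non-missing) samples is at
#' least `min_valid_prop`, the summed duration of valid samples is at least
#' `min_valid_s` seconds, and at least one look at an AOI was made. Reasons
#' enumerate every failed criterion.
#'
#' @param trial A `gaze_trial`.
#' @param min_valid_prop Minimum proportion of valid samples (default 0.25).
#' @param min_valid_s Minimum summed valid-sample time in seconds (default 5).
#' @param looks Optional precomputed look table from [detect_looks()].
#' @param ... Passed to [detect_looks()].
#' @return List with `valid` (logical) and `reasons` (character vector,
#'   empty when valid).
#' @export
trial_validity <- function(trial, min_valid_prop = 0.25, min_valid_s = 5,
                           looks = NULL, ...) {
  s <- trial$samples
  if (is.null(looks)) looks <- detect_looks(trial, ...)
  reasons <- character(0)
  prop_valid <- if (nrow(s)) mean(s$valid == 1) else 0
  dt <- if (nrow(s) > 1) stats::median(diff(s$t_ms)) else 1000 / 120
  valid_s <- sum(s$valid == 1) * dt / 1000
  if (prop_valid < min_valid_prop)
    reasons <- c(reasons, sprintf("valid proportion %.3f < %.2f", prop_valid,
                                  min_valid_prop))
  if (valid_s < min_valid_s)
    reasons <- c(reasons, sprintf("valid duration %.2f s < %g s", valid_s,
                                  min_valid_s))
  if (nrow(looks) == 0) reasons <- c(reasons, "no AOI look")
  list(valid = length(reasons) == 0, reasons = reasons,
       prop_valid = prop_valid, valid_s = valid_s)
}

#' Per-trial looking measures
#'
#' Computes the per-trial constituents of the three primary phenotypes:
#' `first_aoi` (label of the earliest-onset look), `prop_face` (target-AOI
#' look time over total AOI look time, whole trial), `n_objects_10s`
#' (distinct AOIs among looks with onset inside the exploration window) and
#' `prop_missing` (1 minus the valid-sample proportion). Measures other than
#' `prop_missing` are `NA` on invalid trials.
#'
#' @param trial A `gaze_trial`.
#' @param target_aoi AOI treated as the target (default `"face"`; any AOI can
#'   be designated, e.g. `"car"` for sensitivity analyses).
#' @param explore_window_ms Exploration window from trial start (default
#'   10,000 ms).
#' @param ... Validity thresholds and look-detection settings, passed on.
#' @return One-row data frame of class `trial_measures`.
#' @export
trial_measures <- function(trial, target_aoi = "face",
                           explore_window_ms = 10000, ...) {
  dots <- list(...)
  look_args <- dots[names(dots) %in% c("min_samples", "max_gap")]
  val_args <- dots[names(dots) %in% c("min_valid_prop", "min_valid_s")]
  looks <- do.call(detect_looks, c(list(trial), look_args))
  v <- do.call(trial_validity, c(list(trial, looks = looks), val_args))
  out <- data.frame(
    infant_id = trial$infant_id, trial_index = trial$trial_index,
    stimulus_id = trial$stimulus_id,
    valid = v$valid,
    reasons = paste(v$reasons, collapse = "; "),
    first_aoi = NA_character_, prop_face = NA_real_,
    n_objects_10s = NA_integer_,
    prop_missing = 1 - v$prop_valid,
    stringsAsFactors = FALSE
  )
  if (!v$valid || nrow(looks) == 0) return(structure(out, class = c("trial_measures", "data.frame")))
  out$first_aoi <- looks$label[which.min(looks$onset_ms)]
  tot <- sum(looks$duration_ms)
  out$prop_face <- sum(looks$duration_ms[looks$label == target_aoi]) / tot
  out$n_objects_10s <- length(unique(looks$label[looks$onset_ms < explore_window_ms]))
  structure(out, class = c("trial_measures", "data.frame"))
}

#' Aggregate trial measures to participant phenotypes
#'
#' Unweighted means over valid trials; an infant is retained only with at
#' least `min_valid_trials` valid trials. `face_orienting` is the proportion
#' of valid trials whose first look was at the target AOI, `face_preference`
#' the mean of `prop_face`, `exploration` the mean of `n_objects_10s`, and
#' `mean_prop_missing` the mean missing-sample proportion over valid trials.
#'
#' @param measures Data frame of per-trial rows (from [trial_measures()]),
#'   possibly several infants.
#' @param min_valid_trials Retention threshold (default 4).
#' @param target_aoi Label counted for first looks.
#' @return Data frame with one row per retained infant.
#' @export
aggregate_participant <- function(measures, min_valid_trials = 4L,
                                  target_aoi = "face") {
  sp <- split(measures, measures$infant_id)
  rows <- lapply(sp, function(m) {
    vm <- m[m$valid, , drop = FALSE]
    if (nrow(vm) < min_valid_trials) return(NULL)
    data.frame(
      infant_id = m$infant_id[1],
      face_orienting = mean(vm$first_aoi == target_aoi),
      face_preference = mean(vm$prop_face),
      exploration = mean(vm$n_objects_10s),
      n_valid_trials = nrow(vm),
      mean_prop_missing = mean(vm$prop_missing),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(infant_id = character(0), face_orienting = numeric(0),
                      face_preference = numeric(0), exploration = numeric(0),
                      n_valid_trials = integer(0),
                      mean_prop_missing = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract participant phenotypes from a raw gaze table
#'
#' Full gaze-processing driver: splits a tidy gaze-sample table into trials,
#' scores each trial, applies the validity filter, and aggregates to one row
#' per infant (carrying pair/zygosity/age/sex through). Also returns the
#' trial-level QC table with validity reasons.
#'
#' @param gaze Tidy gaze table with columns `infant_id, pair_id, zygosity,
#'   trial_index, stimulus_id, t_ms, x_px, y_px, valid` plus optional
#'   `age_days, sex` (or supply `demographics`).
#' @param scenes List of `gaze_scene`s indexed by stimulus id.
#' @param demographics Optional data frame `infant_id, pair_id, zygosity,
#'   age_days, sex` merged onto the output.
#' @param ... Thresholds passed to [trial_measures()] /
#'   [aggregate_participant()].
#' @return List with `phenotypes` (one row per retained infant) and `qc`
#'   (one row per trial).
#' @export
extract_phenotypes <- function(gaze, scenes = default_scenes(),
                               demographics = NULL, ...) {
  dots <- list(...)
  agg_args <- dots[names(dots) %in% c("min_valid_trials")]
  tm_args <- dots[setdiff(names(dots), "min_valid_trials")]
  idx <- split(seq_len(nrow(gaze)),
               paste(gaze$infant_id, gaze$trial_index, sep = "\r"))
  qc <- lapply(idx, function(rows) {
    g <- gaze[rows, ]
    sc <- scenes[[((g$stimulus_id[1] - 1) %% length(scenes)) + 1]]
    tr <- gaze_trial(g[c("t_ms", "x_px", "y_px", "valid")], sc,
                     infant_id = g$infant_id[1],
                     trial_index = g$trial_index[1])
    do.call(trial_measures, c(list(tr), tm_args))
  })
  qc <- do.call(rbind, qc)
  rownames(qc) <- NULL
  phen <- do.call(aggregate_participant,
                  c(list(qc), agg_args,
                    if ("target_aoi" %in% names(tm_args))
                      tm_args["target_aoi"]))
  meta_cols <- intersect(c("infant_id", "pair_id", "zygosity", "age_days", "sex"),
                         names(gaze))
  meta <- unique(gaze[meta_cols])
  if (!is.null(demographics)) meta <- merge(meta, demographics, all.x = TRUE)
  phen <- merge(meta, phen, by = "infant_id")
  list(phenotypes = phen[order(phen$infant_id), ], qc = qc)
}

#' Regress gaze-quality covariates out of phenotypes when they matter
#'
#' Tests each phenotype against the two gaze-quality covariates
#' (`mean_prop_missing`, `n_valid_trials`) with a pair-clustered GEE; if
#' either covariate is significant at `alpha`, the phenotype is replaced by
#' the residuals of a linear fit on both covariates with the grand mean added
#' back (so chance-level comparisons stay interpretable). Otherwise the
#' phenotype is left unchanged.
#'
#' @param phenotypes Phenotype table from [extract_phenotypes()] (needs
#'   `pair_id` for clustering).
#' @param which_phenotypes Columns to screen.
#' @param alpha Significance level for the quality association (default 0.05).
#' @return List with `phenotypes` (possibly adjusted) and `log` (one row per
#'   screened phenotype: covariate p-values and whether it was adjusted).
#' @export
regress_out_quality <- function(phenotypes,
                                which_phenotypes = c("face_orienting",
                                                     "face_preference",
                                                     "exploration"),
                                alpha = 0.05) {
  quality <- c("mean_prop_missing", "n_valid_trials")
  usable <- quality[vapply(quality, function(q)
    sd(phenotypes[[q]], na.rm = TRUE) > 0, logical(1))]
  log_rows <- list()
  for (ph in which_phenotypes) {
    pvals <- setNames(rep(NA_real_, 2), quality)
    adjust <- FALSE
    if (length(usable)) {
      fit <- gee_fit(phenotypes, outcome = ph, predictors = usable,
                     covariates = character(0), cluster = "pair_id")
      pv <- fit$coefficients$p[match(usable, fit$coefficients$term)]
      pvals[usable] <- pv
      adjust <- any(pv < alpha)
    }
    if (adjust) {
      fml <- stats::as.formula(paste(ph, "~", paste(usable, collapse = "+")))
      lmfit <- lm(fml, data = phenotypes)
      phenotypes[[ph]] <- resid(lmfit) + mean(phenotypes[[ph]], na.rm = TRUE)
    }
    log_rows[[ph]] <- data.frame(phenotype = ph,
                                 p_prop_missing = pvals[[1]],
                                 p_n_valid = pvals[[2]],
                                 adjusted = adjust, stringsAsFactors = FALSE)
  }
  list(phenotypes = phenotypes, log = do.call(rbind, log_rows))
}
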