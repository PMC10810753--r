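#' Generative specification for ACE-structured twin traits
#'
#' Describes the latent biometric structure used to simulate twin phenotypes:
#' lower-triangular Cholesky path matrices for additive genetic (A), shared
#' environment (C), non-shared environment (E) and, optionally, dominance (D)
#' influences, plus mean-model terms (trait intercepts and age/sex covariate
#' effects). Traits are standardized: when `standardized = TRUE` the implied
#' total variance of every trait (row sums of squared paths across all
#' components) must equal 1 to within 1e-8, and E must contribute positive
#' variance to every trait so the likelihood of any rendered dataset is proper.
#'
#' @param path_a,path_c,path_e Lower-triangular `k x k` path matrices (scalars
#'   accepted for `k = 1`).
#' @param path_d Optional lower-triangular dominance path matrix.
#' @param trait_names Character vector of length `k`.
#' @param trait_means Per-trait intercepts.
#' @param beta_age,beta_sex Per-trait covariate effects on the mean (age on
#'   the z-scaled day scale; sex coded 0 = female, 1 = male).
#' @param standardized Enforce unit implied variance per trait.
#' @return An object of class `twin_spec`.
#' @examples
#' generative_spec(path_a = sqrt(0.46), path_e = sqrt(0.54))
#' @export
generative_spec <- function(path_a = 0, path_c = 0, path_e = 1, path_d = NULL,
                            trait_names = NULL, trait_means = 0,
                            beta_age = 0, beta_sex = 0, standardized = TRUE) {
  as_lower <- function(m, k) {
    m <- as.matrix(m)
    if (length(m) == 1 && k > 1) m <- diag(rep(as.numeric(m), k))
    if (!all(dim(m) == k)) stop("path matrices must share one dimension")
    if (any(abs(m[upper.tri(m)]) > 0)) stop("path matrices must be lower triangular")
    m
  }
  k <- nrow(as.matrix(path_e))
  path_a <- as_lower(path_a, k); path_c <- as_lower(path_c, k)
  path_e <- as_lower(path_e, k)
  if (!is.null(path_d)) path_d <- as_lower(path_d, k)
  if (is.null(trait_names))
    trait_names <- if (k == 1) "trait" else paste0("trait", seq_len(k))
  comps <- list(A = path_a, C = path_c, E = path_e)
  if (!is.null(path_d)) comps$D <- path_d
  total <- Reduce(`+`, lapply(comps, function(L) rowSums(L^2)))
  if (standardized && any(abs(total - 1) > 1e-8))
    stop("spec declared standardized but implied trait variances are ",
         paste(signif(total, 6), collapse = ", "))
  e_var <- rowSums(path_e^2)
  if (any(e_var <= 0))
    stop("E must contribute positive variance to every trait")
  structure(
    list(k = k, trait_names = trait_names,
         path_a = path_a, path_c = path_c, path_e = path_e, path_d = path_d,
         trait_means = rep_len(trait_means, k),
         beta_age = rep_len(beta_age, k), beta_sex = rep_len(beta_sex, k),
         standardized = standardized),
    class = "twin_spec"
  )
}

#' Convenience constructors from standardized variance components
#'
#' `univariate_spec` builds a one-trait spec from standardized components
#' summing to 1. `bivariate_ae_spec` builds the two-trait AE Cholesky spec
#' used for orienting/preference analyses from the reported decomposition:
#' trait-1 heritability, the shared and unique additive-genetic contributions
#' to trait 2, and the proportion of trait-2 non-shared environment that is
#' unique (not shared with trait 1).
#'
#' @param a2,c2,d2 Standardized variance components (e2 is the remainder).
#' @param ... Passed to [generative_spec()].
#' @return A `twin_spec`.
#' @export
univariate_spec <- function(a2 = 0, c2 = 0, d2 = 0, ...) {
  e2 <- 1 - a2 - c2 - d2
  if (e2 <= 0) stop("components leave no non-shared environmental variance")
  generative_spec(path_a = sqrt(a2), path_c = sqrt(c2), path_e = sqrt(e2),
                  path_d = if (d2 > 0) sqrt(d2) else NULL, ...)
}

#' @rdname univariate_spec
#' @param a2_trait1 Standardized A of trait 1 (trait-1 E is the remainder).
#' @param a2_shared,a2_unique Standardized A contributions to trait 2 shared
#'   with / unique from trait 1.
#' @param e_unique_prop Proportion of trait-2 E unique to trait 2.
#' @export
bivariate_ae_spec <- function(a2_trait1, a2_shared, a2_unique, e_unique_prop,
                              ...) {
  e2_1 <- 1 - a2_trait1
  e2_2 <- 1 - a2_shared - a2_unique
  if (min(e2_1, e2_2) <= 0) stop("trait E variance must be positive")
  path_a <- rbind(c(sqrt(a2_trait1), 0),
                  c(sqrt(a2_shared), sqrt(a2_unique)))
  path_e <- rbind(c(sqrt(e2_1), 0),
                  c(sqrt((1 - e_unique_prop) * e2_2), sqrt(e_unique_prop * e2_2)))
  generative_spec(path_a = path_a, path_c = matrix(0, 2, 2), path_e = path_e,
                  trait_names = c("orienting", "preference"), ...)
}

#' Closed-form implied twin-pair covariance
#'
#' Assembles the per-zygosity `2k x 2k` covariance of the twin-pair trait
#' vector `(twin1 traits, twin2 traits)` from a generative spec:
#' within-twin block `A + C + D + E`; cross-twin block `A + C + D` for MZ
#' pairs and `0.5 A + C + 0.25 D` for DZ pairs, with `A = L_A L_A'` etc.
#'
#' @param spec A `twin_spec`.
#' @return List with elements `MZ` and `DZ`.
#' @export
implied_twin_covariance <- function(spec) {
  A <- tcrossprod(spec$path_a); C <- tcrossprod(spec$path_c)
  E <- tcrossprod(spec$path_e)
  D <- if (is.null(spec$path_d)) matrix(0, spec$k, spec$k) else tcrossprod(spec$path_d)
  W <- A + C + D + E
  build <- function(X) rbind(cbind(W, X), cbind(X, W))
  out <- list(MZ = build(A + C + D), DZ = build(0.5 * A + C + 0.25 * D))
  for (z in names(out)) {
    ev <- eigen(out[[z]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12)
      stop("implied ", z, " covariance is not positive definite; rejected spec")
  }
  out
}

# shared-pair ages: Normal(168, 9) days truncated to [145, 203] (cohort at
# the 5-month visit)
.sample_pair_ages <- function(n, mean = 168, sd = 9, lo = 145, hi = 203) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

#' Simulate twin-pair phenotypes with ACE structure
#'
#' Draws a pedigree of MZ and DZ same-sex pairs and realises the latent traits
#' through the factor structure of the classical twin design: MZ co-twins
#' share their A (and D) factor scores exactly, DZ co-twins share them with
#' correlation 0.5 (0.25 for D), C factors are shared within every pair, and E
#' factors are independent. Pair members always share sex and age (in days).
#' With `incomplete_rate > 0` a random subset of pairs has exactly one twin
#' present (the co-twin's traits set to `NA`), exercising the FIML
#' missing-data path downstream.
#'
#' @param spec A `twin_spec` (must be standardized).
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (>= 1).
#' @param incomplete_rate Proportion of pairs with a single present twin,
#'   in `[0, 1)`.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `twin_data` data frame (one row per pair, wide twin-1/twin-2
#'   columns) with the per-twin latent trait values attached as columns
#'   `<trait>_latent_t1/_t2` — ground truth for round-trip tests.
#' @export
simulate_twin_phenotypes <- function(spec, n_mz, n_dz, incomplete_rate = 0,
                                     seed = 1L) {
  stopifnot(inherits(spec, "twin_spec"), n_mz >= 1, n_dz >= 1,
            incomplete_rate >= 0, incomplete_rate < 1)
  implied_twin_covariance(spec)  # rejects non-PD specs up front
  set.seed(seed)
  n <- n_mz + n_dz
  k <- spec$k
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  age <- .sample_pair_ages(n)
  sex <- rbinom(n, 1, 0.5)
  age_z <- (age - 168) / 9

  lat1 <- matrix(0, n, k); lat2 <- matrix(0, n, k)
  for (z in c("MZ", "DZ")) {
    idx <- which(zyg == z)
    nz <- length(idx)
    # factor scores with within-pair correlation r per latent factor
    sub <- function(L, r) {
      zc <- matrix(rnorm(nz * k), nz, k)
      z1 <- sqrt(r) * zc + sqrt(1 - r) * matrix(rnorm(nz * k), nz, k)
      z2 <- sqrt(r) * zc + sqrt(1 - r) * matrix(rnorm(nz * k), nz, k)
      list(t1 = z1 %*% t(L), t2 = z2 %*% t(L))
    }
    a <- sub(spec$path_a, if (z == "MZ") 1 else 0.5)
    c_ <- sub(spec$path_c, 1)
    e <- sub(spec$path_e, 0)
    d <- if (is.null(spec$path_d)) list(t1 = 0, t2 = 0) else
      sub(spec$path_d, if (z == "MZ") 1 else 0.25)
    lat1[idx, ] <- a$t1 + c_$t1 + e$t1 + d$t1
    lat2[idx, ] <- a$t2 + c_$t2 + e$t2 + d$t2
  }
  mean_part <- outer(rep(1, n), spec$trait_means) +
    outer(age_z, spec$beta_age) + outer(sex, spec$beta_sex)
  y1 <- lat1 + mean_part
  y2 <- lat2 + mean_part

  present1 <- rep(TRUE, n); present2 <- rep(TRUE, n)
  if (incomplete_rate > 0) {
    inc <- runif(n) < incomplete_rate
    drop2 <- runif(n) < 0.5
    present1[inc & !drop2] <- FALSE
    present2[inc & drop2] <- FALSE
  }
  y1[!present1, ] <- NA; y2[!present2, ] <- NA

  df <- data.frame(pair_id = sprintf("P%04d", seq_len(n)), zygosity = zyg,
                   age_days = age, sex = sex, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    df[[paste0(spec$trait_names[j], "_t1")]] <- y1[, j]
    df[[paste0(spec$trait_names[j], "_t2")]] <- y2[, j]
  }
  df$present_t1 <- present1
  df$present_t2 <- present2
  for (j in seq_len(k)) {
    df[[paste0(spec$trait_names[j], "_latent_t1")]] <- lat1[, j]
    df[[paste0(spec$trait_names[j], "_latent_t2")]] <- lat2[, j]
  }
  twin_pair_dataset(df, traits = spec$trait_names)
}

#' Pair-structured twin dataset
#'
#' Validates and tags a wide data frame as a `twin_data` object: one row per
#' pair with columns `pair_id`, `zygosity` (`"MZ"`/`"DZ"`), `age_days`, `sex`
#' (0/1) and, for every trait `x`, `x_t1`/`x_t2` values (NA marks an absent
#' co-twin). At least one twin must be present in every retained pair.
#'
#' @param df Wide data frame as described above.
#' @param traits Character vector of trait base names.
#' @return `df` with class `twin_data` and a `traits` attribute.
#' @export
twin_pair_dataset <- function(df, traits) {
  need <- c("pair_id", "zygosity", "age_days", "sex",
            paste0(rep(traits, each = 2), c("_t1", "_t2")))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  y1 <- as.matrix(df[paste0(traits, "_t1")])
  y2 <- as.matrix(df[paste0(traits, "_t2")])
  both_absent <- apply(is.na(y1), 1, all) & apply(is.na(y2), 1, all)
  if (any(both_absent))
    stop(sum(both_absent), " pair(s) have no present twin")
  structure(df, class = c("twin_data", "data.frame"), traits = traits)
}

#' @export
print.twin_data <- function(x, ...) {
  traits <- attr(x, "traits")
  cat(sprintf("Twin pair dataset: %d pairs (%d MZ, %d DZ), traits: %s\n",
              nrow(x), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"),
              paste(traits, collapse = ", ")))
  n_inc <- sum(is.na(x[[paste0(traits[1], "_t1")]]) |
                 is.na(x[[paste0(traits[1], "_t2")]]))
  cat(sprintf("  incomplete pairs: %d\n", n_inc))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... (", nrow(x) - 4, " more pairs)\n", sep = "")
  invisible(x)
}
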