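#' Simulate a SYNTAX-stratified patient cohort
#'
#' Generates a synthetic cohort table with the statistical structure of a
#' post-PCI observational study: a non-negative integer SYNTAX score, four
#' serum lipid measures correlated with the score through a Gaussian copula,
#' binary risk-factor covariates, and a MACCE (major adverse cardiovascular
#' and cerebrovascular event) flag whose probability depends on the SYNTAX
#' group. Identical arguments and seed give an identical table.
#'
#' The copula is single-factor: a latent standard normal score variable
#' `z0` drives each lipid latent as `r * z0 + sqrt(1 - r^2) * e`, so the
#' latent correlation between score and lipid `j` is exactly `r_target[j]`
#' (always a feasible correlation structure). A full latent correlation
#' matrix across `(score, lipids)` may be supplied instead via `sigma`; it
#' must be positive definite. Monotone marginal transforms (gamma score,
#' log-normal triglyceride and ApoB/ApoA1) attenuate the observable Pearson
#' correlations slightly below the latent targets.
#'
#' Default targets are the observed score-lipid correlations of the kind of
#' cohort the generator emulates (0.234, 0.237, 0.285, 0.298); default
#' covariate prevalences match that cohort's overall rates, and the default
#' group MACCE probabilities (0.1, 0.1, 0.4) encode a high-score excess risk.
#'
#' @param n Number of patients (>= 1). Default 90.
#' @param r_target Length-4 numeric, latent correlation between SYNTAX score
#'   and (total cholesterol, triglyceride, LDL-C, ApoB/ApoA1); each in (-1, 1).
#' @param event_prob Named or ordered length-3 vector of MACCE probabilities
#'   for the (low, medium, high) SYNTAX groups, each in `[0, 1]`.
#' @param covariate_prev Named prevalences for the binary covariates.
#' @param sigma Optional 5 x 5 latent correlation matrix (score, tc, tg,
#'   ldl, apo); overrides `r_target`. Must be symmetric positive definite.
#' @param score_shape,score_scale Gamma parameters of the SYNTAX-score
#'   marginal before rounding; defaults give mean 27, sd ~10, spanning 0-50.
#' @param seed Integer seed.
#' @return A tibble with one row per patient: `patient_id`, `syntax_score`,
#'   `syntax_group`, `total_cholesterol`, `triglyceride`, `ldl_c` (mmol/L),
#'   `apob_apoa1`, binary covariates, `macce`, `follow_up_years`.
#' @examples
#' coh <- simulate_cohort(n = 90, seed = 7)
#' dplyr::count(coh, syntax_group)
#' @export
simulate_cohort <- function(n = 90,
                            r_target = c(tc = 0.234, tg = 0.237, ldl = 0.285, apo = 0.298),
                            event_prob = c(low = 0.1, medium = 0.1, high = 0.4),
                            covariate_prev = c(
                              smoking = 0.52, diabetes = 0.20,
                              hypertension = 0.56, hyperlipidemia = 0.56,
                              unstable_angina = 0.50
                            ),
                            sigma = NULL,
                            score_shape = 7, score_scale = 27 / 7,
                            seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  if (length(r_target) != 4L || any(!is.finite(r_target)) || any(abs(r_target) >= 1)) {
    abort("`r_target` must be 4 correlations, each strictly inside (-1, 1).")
  }
  if (length(event_prob) != 3L || any(event_prob < 0) || any(event_prob > 1)) {
    abort("`event_prob` must be 3 probabilities in [0, 1].")
  }

  rng <- local_rng(seed)
  if (is.null(sigma)) {
    z0 <- rng$rnorm(n)
    zl <- vapply(r_target, function(r) {
      r * z0 + sqrt(1 - r^2) * rng$rnorm(n)
    }, numeric(n))
    if (n == 1L) zl <- matrix(zl, nrow = 1L)
  } else {
    if (!is.matrix(sigma) || any(dim(sigma) != 5L) || max(abs(sigma - t(sigma))) > 1e-8) {
      abort("`sigma` must be a symmetric 5 x 5 latent correlation matrix.")
    }
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) abort("`sigma` is not positive definite: infeasible correlation matrix.")
    z <- matrix(rng$rnorm(n * 5L), n, 5L) %*% ch
    z0 <- z[, 1]
    zl <- z[, 2:5, drop = FALSE]
  }

  score <- pmin(50, round(qgamma(pnorm(z0), shape = score_shape, scale = score_scale)))
  group <- syntax_group(score)

  u <- pnorm(zl)
  tc <- stats::qnorm(u[, 1], mean = 4.6, sd = 1.0)
  tg <- qlnorm(u[, 2], meanlog = log(1.5), sdlog = 0.40)
  ldl <- stats::qnorm(u[, 3], mean = 2.9, sd = 0.85)
  apo <- qlnorm(u[, 4], meanlog = log(0.80), sdlog = 0.28)

  covs <- vapply(covariate_prev, function(p) rng$rbinom(n, 1L, p) == 1L, logical(n))
  if (n == 1L) covs <- matrix(covs, nrow = 1L, dimnames = list(NULL, names(covariate_prev)))

  p_event <- unname(event_prob)[as.integer(group)]
  macce <- rng$rbinom(n, 1L, p_event) == 1L
  fup <- rng$runif(n, 2, 4)

  tibble(
    patient_id = seq_len(n),
    syntax_score = as.numeric(score),
    syntax_group = group,
    total_cholesterol = tc,
    triglyceride = tg,
    ldl_c = ldl,
    apob_apoa1 = apo,
    smoking = covs[, "smoking"],
    diabetes = covs[, "diabetes"],
    hypertension = covs[, "hypertension"],
    hyperlipidemia = covs[, "hyperlipidemia"],
    unstable_angina = covs[, "unstable_angina"],
    macce = macce,
    follow_up_years = fup
  )
}
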