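#' Specify one of the four candidate SCR observation models
#'
#' The candidate set crosses sex-specificity of the basal encounter rate
#' with sex-specificity of the spatial scale: Model 1 has both sex-specific,
#' Model 2 only sigma, Model 3 neither, Model 4 only the encounter rate.
#' Sex-specificity of the encounter rate is carried multiplicatively by the
#' cloglog offset `beta_sex` (the reported `lambda0` is the female baseline),
#' so `lambda0_sex_specific = FALSE` drops `beta_sex` from the model.
#'
#' @param lambda0_sex_specific include the male offset `beta_sex`?
#' @param sigma_sex_specific separate movement scales for the sexes?
#' @param theta detection-function exponent; 1 (the default) gives the fixed
#'   half-normal kernel.
#' @param M data-augmented super-population size.
#' @param include_playback include the playback indicator covariate?
#' @return an `scr_model_spec`.
#' @export
model_spec <- function(lambda0_sex_specific = TRUE, sigma_sex_specific = TRUE,
                       theta = 1, M = 250, include_playback = TRUE) {
  stopifnot(theta > 0, M >= 1)
  structure(list(lambda0_sex_specific = isTRUE(lambda0_sex_specific),
                 sigma_sex_specific = isTRUE(sigma_sex_specific),
                 theta = theta, M = as.integer(M),
                 include_playback = isTRUE(include_playback)),
            class = "scr_model_spec")
}

#' The four candidate models by number
#'
#' @param k model number 1-4.
#' @param ... passed to [model_spec()] (`theta`, `M`, `include_playback`).
#' @export
candidate_model <- function(k, ...) {
  switch(as.character(k),
         "1" = model_spec(TRUE,  TRUE,  ...),
         "2" = model_spec(FALSE, TRUE,  ...),
         "3" = model_spec(FALSE, FALSE, ...),
         "4" = model_spec(TRUE,  FALSE, ...),
         stop("model number must be 1, 2, 3 or 4"))
}

#' @export
print.scr_model_spec <- function(x, ...) {
  cat(sprintf(
    "SCR model spec: lambda0 %s, sigma %s, theta = %g, M = %d, playback %s\n",
    if (x$lambda0_sex_specific) "sex-specific (via beta_sex)" else "shared",
    if (x$sigma_sex_specific) "sex-specific" else "shared",
    x$theta, x$M, if (x$include_playback) "included" else "excluded"))
  invisible(x)
}

#' Parameter vector of the SCR observation and state model
#'
#' @param lambda0 basal encounter rate per occasion for a female whose
#'   activity centre sits at a trap-cell centroid (at 1 km of search effort).
#' @param sigma_F,sigma_M movement/detection spatial scales (km). Give
#'   `sigma_M = NULL` (or equal to `sigma_F`) for shared-sigma models.
#' @param beta_eff effect of log search-effort (km) on the cloglog scale.
#' @param beta_eff2 playback-indicator effect on the cloglog scale.
#' @param beta_sex male offset on the cloglog scale.
#' @param psi augmentation inclusion probability.
#' @param psi_sex probability an individual is male.
#' @return an `scr_params`.
#' @export
scr_params <- function(lambda0, sigma_F, sigma_M = NULL, beta_eff = 0,
                       beta_eff2 = 0, beta_sex = 0, psi = 0.5, psi_sex = 0.5) {
  if (is.null(sigma_M)) sigma_M <- sigma_F
  p <- list(lambda0 = lambda0, sigma_F = sigma_F, sigma_M = sigma_M,
            beta_eff = beta_eff, beta_eff2 = beta_eff2, beta_sex = beta_sex,
            psi = psi, psi_sex = psi_sex)
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (sigma_F <= 0 || sigma_M <= 0) stop("sigma must be > 0")
  if (psi < 0 || psi > 1 || psi_sex < 0 || psi_sex > 1)
    stop("psi and psi_sex must lie in [0, 1]")
  structure(p, class = "scr_params")
}

#' Half-normal distance term of the detection function
#'
#' `(d^2 / (2 sigma^2))^theta`; with `theta = 1` this is the exponent of the
#' half-normal kernel, subtracted from the cloglog linear predictor.
#'
#' @param d distance (km), >= 0.
#' @param sigma spatial scale (km), > 0.
#' @param theta exponent, default 1.
#' @export
distance_term <- function(d, sigma, theta = 1) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  (d^2 / (2 * sigma^2))^theta
}

#' Cloglog-scale linear predictor of detection
#'
#' `eta = log(lambda0) + beta_eff * log(search_km) + beta_eff2 * playback +
#' beta_sex * sex - distance_term(d, sigma[sex], theta)`. The log-effort
#' covariate is taken as 0 for playback-only cell-occasions (no search
#' driven), i.e. the 1 km-effort baseline. Cell-occasions with neither
#' search nor playback effort are structurally outside the model and are
#' rejected.
#'
#' @param params an `scr_params`.
#' @param sex 0 = female, 1 = male.
#' @param search_km search effort (km) in the cell-occasion.
#' @param playback playback indicator (0/1).
#' @param d distance from activity centre to the trap-cell centroid (km).
#' @param spec an `scr_model_spec`.
#' @export
linear_predictor <- function(params, sex, search_km, playback, d, spec) {
  if (any(search_km <= 0 & playback == 0))
    stop("inactive cell-occasion: search_km = 0 and playback = 0")
  sig <- if (spec$sigma_sex_specific)
    ifelse(sex == 1, params$sigma_M, params$sigma_F) else params$sigma_F
  bsex <- if (spec$lambda0_sex_specific) params$beta_sex else 0
  bpb <- if (spec$include_playback) params$beta_eff2 else 0
  logeff <- ifelse(search_km > 0, log(search_km), 0)
  log(params$lambda0) + params$beta_eff * logeff + bpb * playback +
    bsex * sex - distance_term(d, sig, spec$theta)
}

#' Detection probability from the cloglog scale
#'
#' `pi = 1 - exp(-exp(eta))`, the complementary log-log inverse link;
#' for small rates `pi` is approximately the encounter rate itself.
#' @param eta cloglog-scale linear predictor.
#' @export
detection_prob <- function(eta) {
  -expm1(-exp(eta))
}

#' Assemble validated capture data
#'
#' @param detections data frame with columns `individual`, `trap`, `occasion`
#'   (1-based trap index into `traps`); duplicate rows (same individual,
#'   trap, occasion) are collapsed to a single binary detection.
#' @param sex_obs per-individual sex: `"F"`, `"M"` or `"U"` (unknown), in
#'   individual order.
#' @param effort an `scr_effort`.
#' @param traps the matching `scr_trap_grid`.
#' @return an `scr_capture_data` with the detection list, `n_ind`, `sex_obs`
#'   coded 0/1/NA, and references to effort and traps.
#' @export
capture_data <- function(detections, sex_obs, effort, traps) {
  probs <- character()
  det <- unique(detections[, c("individual", "trap", "occasion")])
  if (nrow(det) == 0L) probs <- c(probs, "no detections")
  ids <- sort(unique(det$individual))
  n_ind <- length(ids)
  det$individual <- match(det$individual, ids)
  if (length(sex_obs) != n_ind)
    probs <- c(probs, sprintf("sex_obs has length %d but there are %d individuals",
                              length(sex_obs), n_ind))
  if (any(det$trap < 1 | det$trap > nrow(effort$search_km)))
    probs <- c(probs, "detection trap index outside the trap grid")
  if (any(det$occasion < 1 | det$occasion > effort$n_occasions))
    probs <- c(probs, "detection occasion outside [1, n_occasions]")
  if (!length(probs)) {
    active <- effort$search_km[cbind(det$trap, det$occasion)] > 0 |
      effort$playback[cbind(det$trap, det$occasion)] > 0
    if (!all(active)) {
      bad <- which(!active)
      probs <- c(probs, sprintf(
        "detection without effort (individual %s, trap %s, occasion %s)",
        det$individual[bad], det$trap[bad], det$occasion[bad]))
    }
  }
  if (length(probs))
    stop(paste(c("invalid capture data:", probs), collapse = "\n  "))
  sx <- rep(NA_integer_, n_ind)
  sx[sex_obs %in% c("F", "0", 0)] <- 0L
  sx[sex_obs %in% c("M", "1", 1)] <- 1L
  structure(list(detections = det, n_ind = n_ind, individual_ids = ids,
                 sex_obs = sx, effort = effort, traps = traps),
            class = "scr_capture_data")
}

#' @export
print.scr_capture_data <- function(x, ...) {
  cat(sprintf("SCR capture data: %d detections of %d individuals (%d F, %d M, %d unknown)\n",
              nrow(x$detections), x$n_ind, sum(x$sex_obs == 0, na.rm = TRUE),
              sum(x$sex_obs == 1, na.rm = TRUE), sum(is.na(x$sex_obs))))
  invisible(x)
}

#' Complete-data log likelihood
#'
#' Reference (pure R) evaluation of the complete-data log likelihood used by
#' the sampler and the harmonic-mean marginal-likelihood estimator: Bernoulli
#' detection terms over every active cell-occasion for each included
#' individual, plus the inclusion mass `Bernoulli(psi)` for all `M`
#' augmented individuals, and sex `Bernoulli(psi_sex)` and uniform
#' activity-centre mass for the included ones. Excluded individuals
#' (`z = 0`) contribute only their inclusion term.
#'
#' @param params an `scr_params`.
#' @param latent list with `z`, `s` (1-based habitat-pixel index) and `sex`
#'   (0/1), each of length `M`.
#' @param data an `scr_capture_data`; observed individuals are 1..n_ind and
#'   must have `z = 1`.
#' @param spec an `scr_model_spec`.
#' @param dist pixel x trap distance matrix over *habitat* pixels
#'   (see [habitat_distances()]).
#' @export
complete_data_loglik <- function(params, latent, data, spec, dist) {
  M <- spec$M
  z <- latent$z; s <- latent$s; sex <- latent$sex
  stopifnot(length(z) == M, length(s) == M, length(sex) == M)
  if (any(z[seq_len(data$n_ind)] != 1L))
    stop("observed individuals must have z = 1")
  n_hab <- nrow(dist)
  eff <- data$effort
  act <- which(eff$search_km > 0 | eff$playback > 0, arr.ind = TRUE)
  logeff <- ifelse(eff$search_km[act] > 0, log(eff$search_km[act]), 0)
  pb <- eff$playback[act]
  bpb <- if (spec$include_playback) params$beta_eff2 else 0
  bsex <- if (spec$lambda0_sex_specific) params$beta_sex else 0
  base <- log(params$lambda0) + params$beta_eff * logeff + bpb * pb

  det_key <- paste(data$detections$trap, data$detections$occasion)
  act_key <- paste(act[, 1], act[, 2])

  ll <- 0
  for (i in which(z == 1L)) {
    sig <- if (spec$sigma_sex_specific && sex[i] == 1) params$sigma_M else params$sigma_F
    dvec <- dist[s[i], act[, 1]]
    eta <- base + bsex * sex[i] - distance_term(dvec, sig, spec$theta)
    lam <- exp(eta)
    y <- numeric(length(lam))
    if (i <= data$n_ind) {
      di <- data$detections[data$detections$individual == i, , drop = FALSE]
      y[match(paste(di$trap, di$occasion), act_key)] <- 1
    }
    # log Bernoulli(y | pi), pi = 1 - exp(-lam)
    ll <- ll + sum(ifelse(y == 1, log(-expm1(-lam)), -lam))
    ll <- ll + log(params$psi) - log(n_hab) +
      ifelse(sex[i] == 1, log(params$psi_sex), log(1 - params$psi_sex))
  }
  ll + sum(z == 0L) * log(1 - params$psi)
}

#' Distances restricted to habitat pixels
#'
#' The sampler indexes activity centres by habitat pixel; this returns the
#' pixel x trap distance matrix for habitat pixels only, with the original
#' pixel indices as an attribute.
#' @inheritParams distance_matrix
#' @export
habitat_distances <- function(state_space, traps) {
  d <- distance_matrix(state_space, traps)
  keep <- which(state_space$habitat)
  structure(d[keep, , drop = FALSE], pixel_index = keep)
}

#' Default prior specification
#'
#' Weakly informative defaults: `log(lambda0) ~ Uniform(-20, 5)`,
#' `sigma ~ Uniform(0, sigma_max)`, regression effects `Normal(0, sd 10)`,
#' `psi` and `psi_sex` `Uniform(0, 1)`.
#' @param sigma_max upper bound (km) of the uniform prior on the spatial
#'   scales; the state-space buffer width is a natural choice.
#' @param beta_sd standard deviation of the normal priors on the betas.
#' @export
default_priors <- function(sigma_max = 15, beta_sd = 10) {
  structure(list(log_lambda0 = c(-20, 5), sigma_max = sigma_max,
                 beta_sd = beta_sd), class = "scr_priors")
}

#' Log prior density of a parameter vector
#'
#' @param params an `scr_params`.
#' @param spec an `scr_model_spec`.
#' @param priors an `scr_priors` from [default_priors()].
#' @return scalar; `-Inf` outside the support.
#' @export
log_prior <- function(params, spec, priors = default_priors()) {
  lp <- 0
  u <- log(params$lambda0)
  if (u < priors$log_lambda0[1] || u > priors$log_lambda0[2]) return(-Inf)
  lp <- lp - log(diff(priors$log_lambda0))
  sigs <- if (spec$sigma_sex_specific) c(params$sigma_F, params$sigma_M) else params$sigma_F
  if (any(sigs <= 0) || any(sigs >= priors$sigma_max)) return(-Inf)
  lp <- lp - length(sigs) * log(priors$sigma_max)
  betas <- params$beta_eff
  if (spec$include_playback) betas <- c(betas, params$beta_eff2)
  if (spec$lambda0_sex_specific) betas <- c(betas, params$beta_sex)
  lp <- lp + sum(stats::dnorm(betas, 0, priors$beta_sd, log = TRUE))
  if (params$psi < 0 || params$psi > 1 || params$psi_sex < 0 || params$psi_sex > 1)
    return(-Inf)
  lp
}

#' Conditional inclusion probability of an undetected augmented individual
#'
#' `p* = psi p0 / (psi p0 + 1 - psi)` where `p0` is the probability of an
#' all-zero encounter history for the individual's current activity centre
#' and sex; the Gibbs update draws `z ~ Bernoulli(p*)`.
#' @param psi current inclusion probability.
#' @param p0 probability of no detection across all active cell-occasions.
#' @export
inclusion_probability <- function(psi, p0) {
  psi * p0 / (psi * p0 + 1 - psi)
}
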