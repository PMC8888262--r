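#' MCMC chain configuration
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param burn_in initial iterations discarded (and, if `adapt`, used to tune
#'   proposal scales; adaptation is frozen afterwards so the post-burn-in
#'   kernel is fixed).
#' @param thin parameter-draw storage stride.
#' @param seed integer seed; each chain runs from a distinct sub-seed derived
#'   from it, so identical seed + config + data reproduce the fit exactly.
#' @param latent_thin storage stride for latent draws (activity centres,
#'   inclusion and sex indicators) and posterior predictive discrepancies.
#' @param s_window half-width, in pixels, of the discrete random-walk
#'   proposal for activity centres.
#' @param prop_sd named initial random-walk proposal scales on the sampling
#'   scales (`log_lambda0`, `log_sigma_F`, `log_sigma_M`, `beta_eff`,
#'   `beta_eff2`, `beta_sex`).
#' @param adapt tune proposal scales during burn-in (target acceptance 0.35)?
#' @param update_params set to `FALSE` to fix the parameters at their initial
#'   values and sample latent states only (used for exact small-instance
#'   cross-checks).
#' @export
chain_config <- function(n_chains = 4, n_iter = 51000, burn_in = 1000,
                         thin = 1, seed = 1, latent_thin = 10, s_window = 3,
                         prop_sd = c(log_lambda0 = 0.4, log_sigma_F = 0.12,
                                     log_sigma_M = 0.15, beta_eff = 0.2,
                                     beta_eff2 = 0.6, beta_sex = 0.4),
                         adapt = TRUE, update_params = TRUE) {
  stopifnot(n_chains >= 1, burn_in < n_iter, thin >= 1, latent_thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), latent_thin = as.integer(latent_thin),
                 s_window = as.integer(s_window), prop_sd = prop_sd,
                 adapt = isTRUE(adapt), update_params = isTRUE(update_params)),
            class = "scr_chain_config")
}

#' Fit a spatial capture-recapture model by Metropolis-within-Gibbs MCMC
#'
#' Runs independent chains of a data-augmentation sampler: Gibbs draws for
#' the inclusion indicators, `psi`, `psi_sex` and latent sexes; a discrete
#' random-walk Metropolis move for activity centres (uniform prior redraw for
#' excluded individuals); and random-walk Metropolis on transformed scales
#' for the detection parameters. Chains start from over-dispersed initial
#' values drawn from the priors truncated to plausible ranges.
#'
#' @param data an `scr_capture_data`.
#' @param state_space an `scr_state_space`.
#' @param spec an `scr_model_spec`.
#' @param config an `scr_chain_config`.
#' @param priors an `scr_priors`.
#' @param init optional list of initial values (`params` as `scr_params`,
#'   `s`, `z`, `sex`) recycled across chains; by default drawn per chain.
#' @return an `scr_fit` with per-chain parameter draws (`samples`, matrices
#'   with columns `lambda0`, `sigma_F`, `sigma_M`, `beta_eff`, `beta_eff2`,
#'   `beta_sex`, `psi`, `psi_sex`, `N_super`, `loglik`), stored latent draws,
#'   posterior-predictive discrepancies and acceptance rates.
#' @export
scr_fit <- function(data, state_space, spec, config = chain_config(),
                    priors = default_priors(sigma_max = default_sigma_max(state_space)),
                    init = NULL) {
  pre <- prepare_mcmc_inputs(data, state_space, spec)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed((config$seed + 7919L * ch) %% .Machine$integer.max)
    ini <- if (is.null(init)) draw_initial_values(pre, spec, priors, data)
           else init_to_internal(init, pre, spec, data)
    ctl <- list(n_iter = config$n_iter, burn_in = config$burn_in,
                thin = config$thin, latent_thin = config$latent_thin,
                s_window = config$s_window,
                prop_sd = as.numeric(config$prop_sd),
                adapt = config$adapt, update_params = config$update_params)
    chains[[ch]] <- .scr_mcmc_cpp(pre$d2, pre$act_trap - 1L, pre$act_logeff,
                                  pre$act_pb, pre$det_t - 1L, pre$det_ptr,
                                  pre$sex_obs_aug, data$n_ind,
                                  pre$hab_gx, pre$hab_gy, pre$gmap,
                                  state_space$nx, state_space$ny,
                                  unclass(spec), unclass(priors), ini, ctl)
  }
  structure(list(chains = chains, spec = spec, config = config,
                 priors = priors, data = data, state_space = state_space,
                 n_hab = nrow(pre$d2), hab_index = pre$hab_index),
            class = "scr_fit")
}

## Upper bound of the uniform prior on sigma: the buffer width, floored at a
## few pixel spacings so degenerate small test landscapes still admit
## resolvable movement scales.
default_sigma_max <- function(state_space) {
  max(state_space$buffer_km, 3 * state_space$delta)
}

## Assemble the flat structures the C++ sampler consumes.
prepare_mcmc_inputs <- function(data, state_space, spec) {
  eff <- data$effort
  act <- which(eff$search_km > 0 | eff$playback > 0, arr.ind = TRUE)
  act <- act[order(act[, 1], act[, 2]), , drop = FALSE]
  if (nrow(act) == 0L) stop("no active cell-occasions: all effort is zero")
  d <- habitat_distances(state_space, data$traps)
  hab_index <- attr(d, "pixel_index")

  det <- data$detections
  det <- det[order(det$individual, det$trap, det$occasion), , drop = FALSE]
  det_t <- match(paste(det$trap, det$occasion), paste(act[, 1], act[, 2]))
  det_ptr <- cumsum(c(0L, tabulate(det$individual, nbins = data$n_ind)))

  M <- spec$M
  if (M < data$n_ind) stop("M must be at least the number of observed individuals")
  sex_obs_aug <- rep(-1L, M)
  sex_obs_aug[seq_len(data$n_ind)] <- ifelse(is.na(data$sex_obs), -1L, data$sex_obs)

  gmap <- rep(-1L, state_space$nx * state_space$ny)
  gx <- state_space$gx[hab_index]
  gy <- state_space$gy[hab_index]
  gmap[gy * state_space$nx + gx + 1L] <- seq_along(hab_index) - 1L

  list(d2 = unname(d)^2, act_trap = act[, 1], act_occ = act[, 2],
       act_logeff = ifelse(eff$search_km[act] > 0, log(eff$search_km[act]), 0),
       act_pb = as.numeric(eff$playback[act]),
       det_t = det_t, det_ptr = as.integer(det_ptr),
       sex_obs_aug = sex_obs_aug, hab_gx = gx, hab_gy = gy,
       gmap = gmap, hab_index = hab_index,
       hab_cx = state_space$centroids[hab_index, 1],
       hab_cy = state_space$centroids[hab_index, 2])
}

## Over-dispersed initial values; bounded retries until the complete-data
## likelihood is finite.
draw_initial_values <- function(pre, spec, priors, data, max_tries = 20) {
  M <- spec$M
  n_hab <- nrow(pre$d2)
  for (k in seq_len(max_tries)) {
    lam0 <- exp(stats::runif(1, log(5e-4), log(0.05)))
    sig_lo <- min(1, priors$sigma_max * 0.3)
    sig_hi <- max(min(4, priors$sigma_max * 0.9), sig_lo * 1.5)
    sigF <- stats::runif(1, sig_lo, sig_hi)
    sigM <- if (spec$sigma_sex_specific) stats::runif(1, sig_lo, sig_hi) else sigF
    params <- c(lam0, sigF, sigM,
                stats::runif(1, 0.5, 4),                      # beta_eff
                if (spec$include_playback) stats::runif(1, -1, 1) else 0,
                if (spec$lambda0_sex_specific) stats::runif(1, -1, 1) else 0,
                stats::runif(1, 0.2, 0.8), stats::runif(1, 0.2, 0.8))
    z <- c(rep(1L, data$n_ind), stats::rbinom(M - data$n_ind, 1, 0.5))
    sex <- ifelse(pre$sex_obs_aug >= 0, pre$sex_obs_aug,
                  stats::rbinom(M, 1, 0.5))
    s <- init_activity_centres(pre, data, n_hab, M)
    ll <- .scr_detloglik_cpp(pre$d2, pre$act_trap - 1L, pre$act_logeff,
                             pre$act_pb, pre$det_t - 1L, pre$det_ptr,
                             data$n_ind, unclass(spec), params,
                             z, s, as.integer(sex))
    if (is.finite(ll))
      return(list(params = params, z = as.integer(z), s = as.integer(s),
                  sex = as.integer(sex)))
  }
  stop("could not find initial values with finite likelihood after ",
       max_tries, " attempts")
}

## Observed individuals start at the habitat pixel nearest the centroid of
## their detection traps; augmented individuals at uniform habitat pixels.
init_activity_centres <- function(pre, data, n_hab, M) {
  s <- sample.int(n_hab, M, replace = TRUE) - 1L
  tc <- data$traps$centroids
  for (i in seq_len(data$n_ind)) {
    di <- data$detections[data$detections$individual == i, , drop = FALSE]
    ctr <- colMeans(tc[di$trap, , drop = FALSE])
    # nearest habitat pixel via the distance matrix columns is not stored;
    # use squared distance to the first trap of the pixel rows instead
    s[i] <- which.min((pre$hab_cx - ctr[1])^2 + (pre$hab_cy - ctr[2])^2) - 1L
  }
  s
}

init_to_internal <- function(init, pre, spec, data) {
  p <- init$params
  params <- c(p$lambda0, p$sigma_F, p$sigma_M, p$beta_eff, p$beta_eff2,
              p$beta_sex, p$psi, p$psi_sex)
  list(params = params, z = as.integer(init$z), s = as.integer(init$s) - 1L,
       sex = as.integer(init$sex))
}

#' @export
print.scr_fit <- function(x, ...) {
  ns <- nrow(x$chains[[1]]$samples)
  cat(sprintf("SCR fit: %d chain(s) x %d stored draws (M = %d, %d observed individuals)\n",
              length(x$chains), ns, x$spec$M, x$data$n_ind))
  cat("Acceptance rates (chain 1):\n")
  print(round(x$chains[[1]]$acceptance, 3))
  invisible(x)
}

#' Pooled posterior draws of the parameters
#'
#' @param fit an `scr_fit`.
#' @param pars optional column subset.
#' @return matrix of pooled post-burn-in draws across chains.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  m <- do.call(rbind, lapply(fit$chains, `[[`, "samples"))
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}
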