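# Small in-code fixtures shared across test files.

# A unit-square extent polygon scaled to w x h km.
rect_poly <- function(w, h) cbind(c(0, w, w, 0), c(0, 0, h, h))

# Minimal survey: small extent, a couple of straight tracks, one playback.
tiny_survey <- function() {
  tracks <- data.frame(
    occasion = c(1, 1, 1, 1, 2, 2),
    segment_id = c(1, 1, 2, 2, 1, 1),
    x_km = c(0.2, 1.8, 0.5, 0.5, 0.1, 2.4),
    y_km = c(0.5, 0.5, 1.2, 2.6, 1.5, 1.5))
  playbacks <- data.frame(occasion = 2, x_km = 2.2, y_km = 1.5)
  ras <- rasterize_effort(tracks, playbacks, grid_cell_km2 = 1, n_occasions = 3)
  ss <- build_state_space(rect_poly(3, 3), buffer_km = 1, pixel_area_km2 = 0.5)
  list(tracks = tracks, playbacks = playbacks, traps = ras$traps,
       effort = ras$effort, state_space = ss)
}

# Tiny fixed-parameter instance used for enumeration cross-checks:
# few pixels, one trap, two occasions, M = 3, one observed individual.
tiny_instance <- function() {
  ss <- build_state_space(rect_poly(1, 1), buffer_km = 0.26, pixel_area_km2 = 0.5)
  tracks <- data.frame(occasion = c(1, 1, 2, 2), segment_id = 1,
                       x_km = c(0.1, 0.9, 0.2, 0.8), y_km = c(0.5, 0.5, 0.4, 0.4))
  ras <- rasterize_effort(tracks, NULL, 1, 2)
  spec <- model_spec(TRUE, TRUE, M = 3)
  det <- data.frame(individual = 1, trap = 1, occasion = 1)
  cd <- capture_data(det, "U", ras$effort, ras$traps)
  params <- scr_params(0.4, 0.8, 1.0, beta_eff = 1, beta_eff2 = 0,
                       beta_sex = -0.3, psi = 0.6, psi_sex = 0.4)
  list(ss = ss, traps = ras$traps, effort = ras$effort, spec = spec,
       capture = cd, params = params,
       dist = habitat_distances(ss, ras$traps))
}

# Exhaustive posterior over (z, s, sex) of the tiny instance at fixed
# parameters; independent of the sampler code path (direct probability
# arithmetic over all configurations).
enumerate_tiny <- function(ti) {
  ss <- ti$ss; eff <- ti$effort; spec <- ti$spec; params <- ti$params
  n_hab <- nrow(ti$dist)
  act <- which(eff$search_km > 0 | eff$playback > 0, arr.ind = TRUE)
  obs_t <- which(act[, 1] == 1 & act[, 2] == 1)
  indlik <- function(i, s, sex) {
    eta <- linear_predictor(params, sex, eff$search_km[act], eff$playback[act],
                            ti$dist[s, act[, 1]], spec)
    p <- detection_prob(eta)
    y <- rep(0, length(p)); if (i == 1) y[obs_t] <- 1
    prod(ifelse(y == 1, p, 1 - p))
  }
  tot <- 0; EN <- 0; Ps1 <- numeric(n_hab)
  for (z2 in 0:1) for (z3 in 0:1)
    for (s1 in 1:n_hab) for (s2 in 1:n_hab) for (s3 in 1:n_hab)
      for (x1 in 0:1) for (x2 in 0:1) for (x3 in 0:1) {
        z <- c(1, z2, z3); s <- c(s1, s2, s3); sx <- c(x1, x2, x3)
        w <- 1
        for (i in 1:3) {
          w <- w * params$psi^z[i] * (1 - params$psi)^(1 - z[i]) *
            params$psi_sex^sx[i] * (1 - params$psi_sex)^(1 - sx[i]) / n_hab
          if (z[i] == 1) w <- w * indlik(i, s[i], sx[i])
        }
        tot <- tot + w; EN <- EN + w * sum(z); Ps1[s1] <- Ps1[s1] + w
      }
  list(EN = EN / tot, Ps1 = Ps1 / tot, n_hab = n_hab)
}

# A quick small-landscape simulation config (fast fits in unit tests).
small_sim_config <- function(seed, ...) {
  sim_config(survey_poly = rect_poly(10, 8), buffer_km = 5,
             n_occasions = 25, km_per_occasion = 25, n_playbacks = 4,
             M = 80,
             params = scr_params(0.02, 1.2, 1.4, beta_eff = 2.5,
                                 beta_eff2 = 0.3, beta_sex = -0.3,
                                 psi = 0.45, psi_sex = 0.4),
             seed = seed, ...)
}
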