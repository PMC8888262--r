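test_that("half-normal distance term matches its closed form", {
  expect_equal(distance_term(0, 2), 0)
  expect_equal(distance_term(sqrt(2) * 3, 3), 1)
  expect_equal(distance_term(1.82, 1.82), 0.5)      # d = sigma -> 1/2
  # theta = 1 halving sigma at fixed d = sigma quadruples the term
  expect_equal(distance_term(1.5, 0.75), 4 * distance_term(1.5, 1.5))
  # monotone non-decreasing in d
  d <- seq(0, 10, by = 0.25)
  expect_true(all(diff(distance_term(d, 1.7)) >= 0))
  expect_error(distance_term(1, 0), "sigma")
})

test_that("cloglog linear predictor assembles the covariate effects", {
  spec <- model_spec(TRUE, TRUE)
  p <- scr_params(0.003, 1.82, 2.00, beta_eff = 3.65, beta_eff2 = 0.28,
                  beta_sex = -0.33, psi = 0.47, psi_sex = 0.32)
  # at 1 km effort the log-effort term vanishes: eta = log(lambda0)
  eta_f <- linear_predictor(p, sex = 0, search_km = 1, playback = 0, d = 0, spec)
  expect_equal(eta_f, log(0.003))
  # playback adds exactly beta_eff2
  eta_pb <- linear_predictor(p, 0, 1, 1, 0, spec)
  expect_equal(eta_pb - eta_f, 0.28)
  # male vs female at d = 0: difference is beta_sex
  eta_m <- linear_predictor(p, 1, 1, 0, 0, spec)
  expect_equal(eta_m - eta_f, -0.33)
  # inactive cell-occasions are structurally rejected
  expect_error(linear_predictor(p, 0, 0, 0, 1, spec), "inactive")
})

test_that("detection probability is the cloglog inverse and monotone", {
  expect_equal(detection_prob(log(0.003)), 1 - exp(-0.003))
  expect_equal(detection_prob(0), 1 - exp(-1))
  expect_equal(detection_prob(-Inf), 0)
  eta <- seq(-8, 2, by = 0.5)
  expect_true(all(diff(detection_prob(eta)) > 0))
  # composed with the predictor: increasing in effort, decreasing in distance
  spec <- model_spec(); p <- scr_params(0.01, 1.5, beta_eff = 2)
  eff <- c(0.5, 1, 2, 4)
  expect_true(all(diff(detection_prob(linear_predictor(p, 0, eff, 0, 1, spec))) > 0))
  d <- c(0, 1, 2, 4)
  expect_true(all(diff(detection_prob(linear_predictor(p, 0, 1, 0, d, spec))) < 0))
})

test_that("capture data validation enforces effort and collapses duplicates", {
  sv <- tiny_survey()
  # trap 1, occasion 1 has effort; duplicate rows collapse
  det <- data.frame(individual = c(1, 1, 2), trap = c(1, 1, 2), occasion = c(1, 1, 1))
  cd <- capture_data(det, c("F", "M"), sv$effort, sv$traps)
  expect_equal(nrow(cd$detections), 2)
  expect_equal(cd$sex_obs, c(0L, 1L))
  # detection in an effortless cell-occasion is rejected with specifics
  occ0 <- which(colSums(sv$effort$search_km) == 0 & colSums(sv$effort$playback) == 0)[1]
  bad <- data.frame(individual = 1, trap = 1, occasion = occ0)
  expect_error(capture_data(bad, "F", sv$effort, sv$traps), "without effort")
})

test_that("complete-data log likelihood matches hand-computed pieces", {
  ti <- tiny_instance()
  n_hab <- nrow(ti$dist)
  eff <- ti$effort
  act <- which(eff$search_km > 0 | eff$playback > 0, arr.ind = TRUE)
  latent <- list(z = c(1L, 1L, 0L), s = c(1L, 2L, 1L), sex = c(0L, 1L, 0L))
  ll <- complete_data_loglik(ti$params, latent, ti$capture, ti$spec, ti$dist)
  # independent assembly from the exported pieces
  p <- ti$params
  ll_hand <- log(1 - p$psi)                                  # z = 0 individual
  for (i in 1:2) {
    eta <- linear_predictor(p, latent$sex[i], eff$search_km[act],
                            eff$playback[act], ti$dist[latent$s[i], act[, 1]], ti$spec)
    pi_ <- detection_prob(eta)
    y <- rep(0, nrow(act))
    if (i == 1) y[act[, 1] == 1 & act[, 2] == 1] <- 1
    ll_hand <- ll_hand + sum(ifelse(y == 1, log(pi_), log(1 - pi_))) +
      log(p$psi) - log(n_hab) +
      ifelse(latent$sex[i] == 1, log(p$psi_sex), log(1 - p$psi_sex))
  }
  expect_equal(ll, ll_hand, tolerance = 1e-12)
  expect_error(complete_data_loglik(ti$params, list(z = c(0L, 1L, 1L),
                                                    s = c(1L, 1L, 1L),
                                                    sex = c(0L, 0L, 0L)),
                                    ti$capture, ti$spec, ti$dist),
               "z = 1")
})

test_that("R and C++ detection likelihoods agree", {
  ti <- tiny_instance()
  pre <- searchSCR:::prepare_mcmc_inputs(ti$capture, ti$ss, ti$spec)
  latent <- list(z = c(1L, 1L, 1L), s = c(1L, 3L, 2L), sex = c(1L, 0L, 1L))
  p <- ti$params
  llR <- complete_data_loglik(p, latent, ti$capture, ti$spec, ti$dist)
  # strip the state masses to compare the detection part only
  n_hab <- nrow(ti$dist)
  state_mass <- sum(latent$z) * (log(p$psi) - log(n_hab)) +
    sum(ifelse(latent$sex[latent$z == 1] == 1, log(p$psi_sex), log(1 - p$psi_sex))) +
    sum(latent$z == 0) * log(1 - p$psi)
  llC <- searchSCR:::.scr_detloglik_cpp(
    pre$d2, pre$act_trap - 1L, pre$act_logeff, pre$act_pb, pre$det_t - 1L,
    pre$det_ptr, ti$capture$n_ind, unclass(ti$spec),
    c(p$lambda0, p$sigma_F, p$sigma_M, p$beta_eff, p$beta_eff2, p$beta_sex,
      p$psi, p$psi_sex),
    latent$z, latent$s - 1L, latent$sex)
  expect_equal(llC, llR - state_mass, tolerance = 1e-9)
})

test_that("priors integrate support restrictions", {
  spec <- model_spec()
  pr <- default_priors(sigma_max = 15)
  p <- scr_params(0.003, 1.8, 2.0, beta_eff = 0, beta_eff2 = 0, beta_sex = 0,
                  psi = 0.5, psi_sex = 0.5)
  lp <- log_prior(p, spec, pr)
  # uniform pieces contribute constants; betas are Normal(0, 10) at 0
  expect_equal(lp, -log(25) - 2 * log(15) + 3 * dnorm(0, 0, 10, log = TRUE))
  expect_equal(log_prior(scr_params(0.003, 20, 20), spec, pr), -Inf)
  expect_equal(log_prior(scr_params(exp(6), 1, 1), spec, pr), -Inf)
})

test_that("inclusion probability follows the augmentation conditional", {
  expect_equal(inclusion_probability(0.3, 1), 0.3)       # no information
  expect_equal(inclusion_probability(0.9, 0), 0)         # certain detection
  expect_equal(inclusion_probability(0.47, 0.5), 0.235 / 0.765)
})

test_that("the four candidate models map to the sex-specificity grid", {
  grid <- rbind(c(TRUE, TRUE), c(FALSE, TRUE), c(FALSE, FALSE), c(TRUE, FALSE))
  for (k in 1:4) {
    m <- candidate_model(k)
    expect_equal(c(m$lambda0_sex_specific, m$sigma_sex_specific),
                 as.logical(grid[k, ]))
    expect_equal(m$theta, 1)
    expect_equal(m$M, 250L)
  }
  expect_error(candidate_model(5), "1, 2, 3 or 4")
})
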