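test_that("identical seed, config and data give bit-identical fits", {
  ti <- tiny_instance()
  cc <- chain_config(n_chains = 2, n_iter = 400, burn_in = 100, seed = 77,
                     latent_thin = 5)
  f1 <- scr_fit(ti$capture, ti$ss, ti$spec, cc)
  f2 <- scr_fit(ti$capture, ti$ss, ti$spec, cc)
  expect_identical(f1$chains[[1]]$samples, f2$chains[[1]]$samples)
  expect_identical(f1$chains[[2]]$s, f2$chains[[2]]$s)
  expect_identical(f1$chains[[1]]$T_rep, f2$chains[[1]]$T_rep)
  # a different seed moves the draws
  f3 <- scr_fit(ti$capture, ti$ss, ti$spec,
                chain_config(n_chains = 2, n_iter = 400, burn_in = 100,
                             seed = 78, latent_thin = 5))
  expect_false(identical(f1$chains[[1]]$samples, f3$chains[[1]]$samples))
})

test_that("latent posterior matches exhaustive enumeration on the tiny instance", {
  ti <- tiny_instance()
  en <- enumerate_tiny(ti)
  fit <- scr_fit(ti$capture, ti$ss, ti$spec,
                 chain_config(n_chains = 2, n_iter = 21000, burn_in = 1000,
                              seed = 9, latent_thin = 1, update_params = FALSE),
                 init = list(params = ti$params, z = c(1L, 1L, 1L),
                             s = c(1L, 1L, 1L), sex = c(0L, 0L, 0L)))
  dr <- posterior_draws(fit)
  # Monte-Carlo error via batch means (draws are autocorrelated)
  n <- nrow(dr)
  bm <- tapply(dr[, "N_super"], rep(1:40, each = ceiling(n / 40))[1:n], mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(dr[, "N_super"]) - en$EN), 3 * se + 1e-12)
  # activity-centre marginal of the observed individual
  lat <- searchSCR:::latent_draws(fit)
  ps <- tabulate(lat$s[, 1] + 1L, en$n_hab) / nrow(lat$s)
  expect_lt(max(abs(ps - en$Ps1)), 0.02)
})

test_that("psi Gibbs conditional matches an independent Metropolis sampler", {
  # Beta(1 + sum z, 1 + M - sum z) conjugacy vs a long random-walk
  # Metropolis run targeting the same conditional
  M <- 50; n1 <- 18
  target <- function(psi) dbeta(psi, 1 + n1, 1 + M - n1, log = TRUE)
  set.seed(5)
  cur <- 0.5; draws <- numeric(20000)
  for (k in seq_along(draws)) {
    prop <- cur + rnorm(1, sd = 0.1)
    if (prop > 0 && prop < 1 && log(runif(1)) < target(prop) - target(cur))
      cur <- prop
    draws[k] <- cur
  }
  draws <- draws[-(1:2000)]
  expect_equal(mean(draws), (1 + n1) / (2 + M), tolerance = 0.01)
  expect_equal(sd(draws), sqrt((1 + n1) * (1 + M - n1) / ((2 + M)^2 * (3 + M))),
               tolerance = 0.05)
})

test_that("N_super never drops below the observed count and z stays 1 for observed", {
  cfg <- small_sim_config(seed = 31)
  b <- generate_dataset(cfg)
  fit <- scr_fit(b$capture, b$state_space, cfg$spec,
                 chain_config(n_chains = 1, n_iter = 800, burn_in = 100, seed = 3))
  dr <- posterior_draws(fit)
  expect_true(all(dr[, "N_super"] >= b$capture$n_ind))
  lat <- searchSCR:::latent_draws(fit)
  expect_true(all(lat$z[, seq_len(b$capture$n_ind)] == 1L))
  # sexes of observed individuals stay at their recorded values
  expect_true(all(sweep(lat$sex[, seq_len(b$capture$n_ind), drop = FALSE], 2,
                        b$capture$sex_obs, "==")))
})

test_that("acceptance rates are bookkept in [0, 1] and adaptation targets them", {
  cfg <- small_sim_config(seed = 41)
  b <- generate_dataset(cfg)
  fit <- scr_fit(b$capture, b$state_space, cfg$spec,
                 chain_config(n_chains = 1, n_iter = 3000, burn_in = 1500, seed = 4))
  a <- fit$chains[[1]]$acceptance
  a <- a[!is.na(a)]
  expect_true(all(a >= 0 & a <= 1))
  # adapted blocks should sit in a sane band around the 0.35 target
  blocks <- intersect(names(a), c("log_lambda0", "log_sigma_F", "beta_eff"))
  expect_true(all(a[blocks] > 0.1 & a[blocks] < 0.7))
})

test_that("degenerate proposal scale leaves the chain stuck (flagged by rate 0)", {
  ti <- tiny_instance()
  cc <- chain_config(n_chains = 1, n_iter = 300, burn_in = 50, seed = 1,
                     prop_sd = c(log_lambda0 = 1e-10, log_sigma_F = 1e-10,
                                 log_sigma_M = 1e-10, beta_eff = 1e-10,
                                 beta_eff2 = 1e-10, beta_sex = 1e-10),
                     adapt = FALSE)
  fit <- scr_fit(ti$capture, ti$ss, ti$spec, cc)
  dr <- posterior_draws(fit)
  expect_lt(diff(range(dr[, "lambda0"])) / mean(dr[, "lambda0"]), 1e-6)
})

test_that("stored dimensions follow the thinning configuration", {
  ti <- tiny_instance()
  cc <- chain_config(n_chains = 3, n_iter = 500, burn_in = 100, thin = 2,
                     seed = 11, latent_thin = 20)
  fit <- scr_fit(ti$capture, ti$ss, ti$spec, cc)
  expect_length(fit$chains, 3)
  expect_equal(nrow(fit$chains[[1]]$samples), (500 - 100) / 2)
  expect_equal(nrow(fit$chains[[1]]$s), (500 - 100) / 20)
  expect_equal(ncol(fit$chains[[1]]$s), ti$spec$M)
})
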