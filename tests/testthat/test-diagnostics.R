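test_that("R-hat is ~1 on identical chains and large on separated chains", {
  set.seed(1)
  x <- rnorm(500)
  expect_lt(gelman_rubin(cbind(x, x, x)), 1 + 1e-8)
  far <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(far), 1.05)
  expect_gt(gelman_rubin(far), 3)
  expect_error(gelman_rubin(matrix(x, ncol = 1)), "2 chains")
})

test_that("HPD equals the brute-force shortest window and beats equal tails", {
  # sorted 1..100 at mass 0.95: all windows tie at width 94 -> first wins
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  expect_equal(hpd_interval(rep(3.5, 40)), c(3.5, 3.5))
  brute_hpd <- function(x, mass) {
    x <- sort(x); n <- length(x); m <- ceiling(mass * n)
    best <- c(Inf, NA, NA)
    for (i in 1:(n - m + 1))
      if (x[i + m - 1] - x[i] < best[1]) best <- c(x[i + m - 1] - x[i], x[i], x[i + m - 1])
    best[2:3]
  }
  set.seed(4)
  for (k in 1:20) {
    x <- rlnorm(200, sd = runif(1, 0.3, 1.5))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(hpd_interval(x, mass), brute_hpd(x, mass))
    # narrower than (or equal to) the equal-tail interval for the same mass
    q <- quantile(x, c((1 - mass) / 2, 1 - (1 - mass) / 2), names = FALSE)
    expect_lte(diff(hpd_interval(x, mass)), diff(q) + 1e-12)
  }
  expect_error(hpd_interval(1:100, 1.2), "mass")
})

test_that("harmonic-mean marginal likelihood has its closed-form special cases", {
  expect_equal(mlhm(rep(-123.45, 50)), -123.45)    # constant draws
  expect_equal(mlhm(-7.7), -7.7)                   # single draw
  expect_equal(mlhm(c(log(1), log(3))), -log((1 + 1 / 3) / 2))
  expect_equal(mlhm(c(log(1), log(3))), log(1.5))
  # invariant to adding a constant then subtracting it
  set.seed(2); ll <- rnorm(300, -400, 5)
  expect_equal(mlhm(ll + 1000) - 1000, mlhm(ll), tolerance = 1e-9)
  expect_error(mlhm(c(-1, NaN)), "non-finite")
})

test_that("pairwise correlations flag redundancy and handle constants", {
  set.seed(3)
  n <- 400
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.05); c_ <- rnorm(n)
  m <- cbind(a = a, b = b, c = c_, k = rep(2, n))
  pc <- pairwise_correlations(m, threshold = 0.9)
  expect_equal(pc$correlations["a", "a"], 1)
  expect_true(any(pc$flagged$par1 == "a" & pc$flagged$par2 == "b"))
  expect_false(any(pc$flagged$par2 == "c"))
  expect_true("k" %in% pc$constant)
  expect_true(is.na(pc$correlations["a", "k"]))
  expect_lt(abs(pc$correlations["a", "c"]), 0.2)
})

test_that("posterior summary reports mean/PSD/HPD/R-hat and derived N_super", {
  ti <- tiny_instance()
  fit <- scr_fit(ti$capture, ti$ss, ti$spec,
                 chain_config(n_chains = 2, n_iter = 600, burn_in = 100,
                              seed = 2, latent_thin = 5),
                 init = list(params = ti$params, z = c(1L, 1L, 1L),
                             s = c(1L, 1L, 1L), sex = c(0L, 0L, 0L)))
  sm <- posterior_summary(fit)
  expect_s3_class(sm, "scr_summary")
  expect_true(all(c("N_super", "psi", "sigma_F") %in% sm$parameter))
  expect_true(all(sm$psd >= 0))
  expect_true(all(sm$hpd_lower <= sm$hpd_upper))
  # N_super stays within [n observed, M]
  dr <- posterior_draws(fit)
  expect_true(all(dr[, "N_super"] >= 1 & dr[, "N_super"] <= 3))
  # summary table round-trips through CSV unchanged
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sm, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$mean, sm$mean, tolerance = 1e-12)
  expect_equal(back$parameter, sm$parameter)
})

test_that("psi and N_super are structurally correlated in any fit", {
  cfg <- small_sim_config(seed = 21)
  b <- generate_dataset(cfg)
  fit <- scr_fit(b$capture, b$state_space, cfg$spec,
                 chain_config(n_chains = 2, n_iter = 1500, burn_in = 300, seed = 1))
  pc <- pairwise_correlations(fit)
  expect_gt(pc$correlations["psi", "N_super"], 0.5)
})
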