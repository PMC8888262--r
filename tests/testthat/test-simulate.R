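test_that("population simulation follows psi and is seed-reproducible", {
  cfg <- small_sim_config(seed = 1)
  t1 <- simulate_population(cfg)
  t2 <- simulate_population(cfg)
  expect_identical(t1$z, t2$z)
  expect_identical(t1$s, t2$s)
  # psi = 1 includes everyone
  cfg1 <- small_sim_config(seed = 2)
  cfg1$params$psi <- 1
  expect_equal(sum(simulate_population(cfg1)$z), cfg1$M)
  # binomial mean across replicates: psi = 0.45, M = 80 -> ~36, SE ~ 0.5
  ns <- vapply(1:40, function(k) {
    cfgk <- small_sim_config(seed = 1000 + k)
    sum(simulate_population(cfgk)$z)
  }, numeric(1))
  se <- sqrt(0.45 * 0.55 * 80 / 40)
  expect_lt(abs(mean(ns) - 0.45 * 80), 4 * se)
})

test_that("simulated tracks respect the survey polygon and the length budget", {
  cfg <- small_sim_config(seed = 3)
  eb <- simulate_effort(cfg)
  expect_true(all(searchSCR:::points_in_polygon(
    cbind(eb$tracks$x_km, eb$tracks$y_km), cfg$survey_poly)))
  # each occasion drives exactly the configured length (trimmed final leg)
  per_occ <- tapply(seq_len(nrow(eb$tracks)), eb$tracks$occasion, function(idx) {
    v <- eb$tracks[idx, ]
    sum(sqrt(diff(v$x_km)^2 + diff(v$y_km)^2))
  })
  expect_equal(as.numeric(per_occ), rep(cfg$km_per_occasion, cfg$n_occasions),
               tolerance = 1e-9)
  # rasterized total equals generated total (clipping conservation)
  expect_equal(sum(eb$effort$search_km),
               cfg$km_per_occasion * cfg$n_occasions, tolerance = 1e-6)
  # playbacks land on track vertices in their occasion
  for (r in seq_len(nrow(eb$playbacks))) {
    same <- eb$tracks$occasion == eb$playbacks$occasion[r] &
      abs(eb$tracks$x_km - eb$playbacks$x_km[r]) < 1e-12
    expect_true(any(same))
  }
})

test_that("detections arise only from included individuals with effort", {
  cfg <- small_sim_config(seed = 4)
  b <- generate_dataset(cfg)
  det <- b$capture$detections
  act <- b$effort$search_km[cbind(det$trap, det$occasion)] > 0 |
    b$effort$playback[cbind(det$trap, det$occasion)] > 0
  expect_true(all(act))
  ti <- attr(b$capture, "truth_index")
  expect_true(all(b$truth$z[ti] == 1L))
  # observed sexes match the truth
  expect_equal(b$capture$sex_obs, b$truth$sex[ti])
  # lambda0 -> 0 gives no detections
  cfg0 <- small_sim_config(seed = 5)
  cfg0$params$lambda0 <- 1e-12
  tr <- simulate_population(cfg0)
  eb <- simulate_effort(cfg0)
  expect_warning(cd <- simulate_detections(tr, eb, cfg0), "no individuals")
  expect_equal(cd$n_ind, 0L)
})

test_that("generated bundles round-trip through the readers", {
  cfg <- small_sim_config(seed = 6)
  dir1 <- withr::local_tempdir()
  b <- generate_dataset(cfg, dir1)
  back <- read_survey_bundle(dir1)
  expect_equal(back$capture$detections, b$capture$detections,
               ignore_attr = "row.names")
  expect_equal(back$capture$sex_obs, b$capture$sex_obs)
  expect_equal(back$effort$search_km, b$effort$search_km, tolerance = 1e-9)
  expect_equal(back$traps$cell_ids, b$traps$cell_ids)
  expect_equal(nrow(back$state_space$centroids), nrow(b$state_space$centroids))
  # same seed -> byte-identical bundle
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, dir2)
  for (f in c("tracks.csv", "captures.csv", "effort.csv", "truth.json"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
})

test_that("the default configuration emulates the field survey's scale", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_occasions, 89L)
  expect_equal(cfg$n_playbacks, 14L)
  expect_equal(cfg$km_per_occasion * cfg$n_occasions, 2701)
  expect_equal(cfg$params$lambda0, 0.003)
  expect_equal(cfg$params$sigma_F, 1.82)
  expect_equal(cfg$params$sigma_M, 2.00)
  expect_equal(cfg$M, 250L)
  # survey polygon area ~358 km^2 (shoelace)
  p <- cfg$survey_poly
  n <- nrow(p); j <- c(2:n, 1)
  area <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  expect_equal(area, 358.4, tolerance = 1e-9)
  # state-space at the reported scale (~2400 km^2 at 0.5 km^2 pixels)
  ss <- build_state_space(p, cfg$buffer_km, cfg$pixel_area_km2)
  expect_gt(ss$total_area, 2000)
  expect_lt(ss$total_area, 2800)
  expect_error(sim_config(), "seed")
})

test_that("true_abundance counts included activity centres in a region", {
  cfg <- small_sim_config(seed = 8)
  b <- generate_dataset(cfg)
  tr_all <- true_abundance(b, rep(TRUE, nrow(b$state_space$centroids)))
  expect_equal(tr_all$N, sum(b$truth$z))
  tr_s <- true_abundance(b)
  expect_lte(tr_s$N, tr_all$N)
  expect_equal(tr_s$density_per_100km2, tr_s$N / tr_s$area_km2 * 100)
})

test_that("masked landscapes flow through generation and bundle IO", {
  mask <- list(cbind(c(2, 4, 4, 2), c(2, 2, 4, 4)))
  cfg <- small_sim_config(seed = 9)
  cfg$habitat_mask <- mask
  dirm <- withr::local_tempdir()
  b <- generate_dataset(cfg, dirm)
  expect_true(file.exists(file.path(dirm, "mask.geojson")))
  expect_lt(b$state_space$habitat_area, b$state_space$total_area)
  # no simulated activity centre sits in masked habitat
  expect_true(all(b$state_space$habitat[which(b$state_space$habitat)[b$truth$s]]))
  back <- read_survey_bundle(dirm)
  expect_equal(back$state_space$habitat, b$state_space$habitat)
})
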