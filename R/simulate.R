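#' Configuration for a synthetic survey
#'
#' Defaults emulate the scale of an 89-day unstructured vehicle survey of a
#' ~358 km^2 semi-arid community area: ~2700 km of search tracks, 14
#' playbacks, 1 km^2 trap cells, a 15 km buffered state-space of 0.5 km^2
#' pixels, a super-population of M = 250 and detection parameters at the
#' scale reported for lions (basal encounter rate 0.003, movement scales
#' 1.8-2.0 km, strong positive log-effort effect).
#'
#' @param survey_poly survey-area polygon (km); default a 22.4 x 16 km
#'   rectangle (358.4 km^2).
#' @param buffer_km state-space buffer width.
#' @param pixel_area_km2 state-space pixel area.
#' @param cell_km2 trap-cell area.
#' @param n_occasions daily sampling occasions.
#' @param km_per_occasion search-track length per occasion (km); the default
#'   gives ~2700 km in total.
#' @param waypoint_km mean leg length of the random-waypoint track generator
#'   (controls how clumped daily effort is).
#' @param long_leg_prob probability that a leg runs all the way to the next
#'   uniform waypoint (a long transect), mixing area coverage into the
#'   otherwise local daily search.
#' @param n_playbacks number of playback events across the survey.
#' @param params true `scr_params`.
#' @param M data-augmented super-population size.
#' @param spec model specification used to generate detections.
#' @param habitat_mask optional mask polygons (unsuitable habitat).
#' @param seed integer seed (mandatory: all randomness flows from it).
#' @export
sim_config <- function(survey_poly = cbind(c(0, 22.4, 22.4, 0), c(0, 0, 16, 16)),
                       buffer_km = 15, pixel_area_km2 = 0.5, cell_km2 = 1,
                       n_occasions = 89, km_per_occasion = 2701 / 89,
                       waypoint_km = 0.4, long_leg_prob = 0.03,
                       n_playbacks = 14,
                       params = scr_params(lambda0 = 0.003, sigma_F = 1.82,
                                           sigma_M = 2.00, beta_eff = 3.65,
                                           beta_eff2 = 0.28, beta_sex = -0.33,
                                           psi = 0.47, psi_sex = 0.32),
                       M = 250, spec = model_spec(M = M),
                       habitat_mask = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("seed required")
  stopifnot(n_occasions >= 1, km_per_occasion > 0, n_playbacks >= 0)
  structure(list(survey_poly = as_loop_list(survey_poly)[[1]],
                 buffer_km = buffer_km, pixel_area_km2 = pixel_area_km2,
                 cell_km2 = cell_km2, n_occasions = as.integer(n_occasions),
                 km_per_occasion = km_per_occasion, waypoint_km = waypoint_km,
                 long_leg_prob = long_leg_prob,
                 n_playbacks = as.integer(n_playbacks), params = params,
                 M = as.integer(M), spec = spec, habitat_mask = habitat_mask,
                 seed = as.integer(seed)),
            class = "scr_sim_config")
}

## named substreams so each component draws reproducibly from the one seed
substream <- function(config, k) set.seed((config$seed + 104729L * k) %% .Machine$integer.max)

#' Simulate the latent population
#'
#' `z_i ~ Bernoulli(psi)`, `sex_i ~ Bernoulli(psi_sex)`, activity centres
#' uniform over habitat pixels, for i = 1..M.
#'
#' @param config an `scr_sim_config`.
#' @param state_space the state-space to place activity centres in (built
#'   from the config's survey polygon if omitted).
#' @return an `scr_truth`: list with `z`, `sex`, `s` (habitat-pixel index),
#'   `s_xy` (km), and the state-space used.
#' @export
simulate_population <- function(config, state_space = NULL) {
  if (is.null(state_space))
    state_space <- build_state_space(config$survey_poly, config$buffer_km,
                                     config$pixel_area_km2, config$habitat_mask)
  hab <- which(state_space$habitat)
  if (!length(hab)) stop("no habitat pixels")
  substream(config, 1L)
  z <- stats::rbinom(config$M, 1, config$params$psi)
  sex <- stats::rbinom(config$M, 1, config$params$psi_sex)
  s <- sample(seq_along(hab), config$M, replace = TRUE)
  structure(list(z = z, sex = sex, s = s,
                 s_xy = state_space$centroids[hab[s], , drop = FALSE],
                 state_space = state_space),
            class = "scr_truth")
}

#' Simulate search tracks and playback events
#'
#' Per occasion, a random-waypoint polyline of the configured length inside
#' the survey polygon (legs drawn toward uniformly placed waypoints, scaled
#' to `waypoint_km`); playback events are placed at random track vertices on
#' random occasions. The tracks are then rasterized onto the trap grid.
#'
#' @param config an `scr_sim_config`.
#' @return list with `tracks` and `playbacks` data frames (CSV interchange
#'   layout), and their rasterization: `traps` and `effort`.
#' @export
simulate_effort <- function(config) {
  substream(config, 2L)
  poly <- config$survey_poly
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  rand_point <- function() {
    repeat {
      p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
      if (points_in_polygon(rbind(p), poly)) return(p)
    }
  }
  tracks <- vector("list", config$n_occasions)
  for (k in seq_len(config$n_occasions)) {
    target <- config$km_per_occasion
    pts <- list(rand_point())
    len <- 0
    while (len < target) {
      cur <- pts[[length(pts)]]
      wp <- rand_point()
      leg <- wp - cur
      leg_len <- sqrt(sum(leg^2))
      if (leg_len < 1e-9) next
      # mostly short local-search legs, occasionally a full transect to the
      # next waypoint: concentrates daily effort yet still covers the area
      use <- if (stats::runif(1) < config$long_leg_prob) leg_len
             else min(leg_len, config$waypoint_km * stats::rexp(1) + 0.5)
      nxt <- cur + leg / leg_len * use
      step <- sqrt(sum((nxt - cur)^2))
      if (len + step > target) {                    # trim to exact length
        nxt <- cur + (nxt - cur) * (target - len) / step
        step <- target - len
      }
      pts[[length(pts) + 1L]] <- nxt
      len <- len + step
    }
    m <- do.call(rbind, pts)
    tracks[[k]] <- data.frame(occasion = k, segment_id = 1L,
                              x_km = m[, 1], y_km = m[, 2])
  }
  tracks <- do.call(rbind, tracks)

  playbacks <- data.frame(occasion = integer(), x_km = numeric(), y_km = numeric())
  if (config$n_playbacks > 0) {
    occ <- sample.int(config$n_occasions, config$n_playbacks, replace = TRUE)
    rows <- vapply(occ, function(k) {
      cand <- which(tracks$occasion == k)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    playbacks <- data.frame(occasion = occ,
                            x_km = tracks$x_km[rows], y_km = tracks$y_km[rows])
  }
  ras <- rasterize_effort(tracks, playbacks, config$cell_km2, config$n_occasions)
  list(tracks = tracks, playbacks = playbacks,
       traps = ras$traps, effort = ras$effort)
}

#' Simulate detections given truth and effort
#'
#' For each included individual and each active cell-occasion, draws a
#' Bernoulli detection with the model's cloglog probability. Individuals
#' with no detections are unobserved: they are excluded from the returned
#' capture data but retained in the truth.
#'
#' @param truth an `scr_truth`.
#' @param effort_bundle result of [simulate_effort()].
#' @param config an `scr_sim_config`.
#' @return an `scr_capture_data`; the mapping of observed individuals to
#'   truth indices is in attribute `truth_index`.
#' @export
simulate_detections <- function(truth, effort_bundle, config) {
  substream(config, 3L)
  params <- config$params; spec <- config$spec
  eff <- effort_bundle$effort
  traps <- effort_bundle$traps
  act <- which(eff$search_km > 0 | eff$playback > 0, arr.ind = TRUE)
  tc <- traps$centroids
  rows <- list()
  for (i in which(truth$z == 1L)) {
    d <- sqrt((tc[act[, 1], 1] - truth$s_xy[i, 1])^2 +
              (tc[act[, 1], 2] - truth$s_xy[i, 2])^2)
    eta <- linear_predictor(params, truth$sex[i], eff$search_km[act],
                            eff$playback[act], d, spec)
    y <- stats::rbinom(nrow(act), 1, detection_prob(eta))
    if (any(y == 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        truth_index = i, trap = act[y == 1L, 1], occasion = act[y == 1L, 2])
  }
  if (!length(rows)) {
    warning("no individuals detected")
    det <- data.frame(individual = integer(), trap = integer(), occasion = integer())
    cd <- structure(list(detections = det, n_ind = 0L, individual_ids = integer(),
                         sex_obs = integer(), effort = eff, traps = traps),
                    class = "scr_capture_data")
    attr(cd, "truth_index") <- integer()
    return(cd)
  }
  det <- do.call(rbind, rows)
  obs_idx <- sort(unique(det$truth_index))
  det$individual <- match(det$truth_index, obs_idx)
  cd <- capture_data(det[, c("individual", "trap", "occasion")],
                     sex_obs = ifelse(truth$sex[obs_idx] == 1, "M", "F"),
                     effort = eff, traps = traps)
  attr(cd, "truth_index") <- obs_idx
  cd
}

#' Generate a complete synthetic survey
#'
#' Landscape, effort, population and detections from one seed; optionally
#' written to disk as the CSV/GeoJSON/JSON bundle the package readers
#' consume, making a fit on the bundle an end-to-end test of the pipeline.
#'
#' @param config an `scr_sim_config`.
#' @param dir optional output directory; created if needed.
#' @return an `scr_survey` bundle: `state_space`, `traps`, `effort`,
#'   `tracks`, `playbacks`, `capture` (an `scr_capture_data`), `truth`,
#'   `config`, plus `files` when written.
#' @export
generate_dataset <- function(config, dir = NULL) {
  state_space <- build_state_space(config$survey_poly, config$buffer_km,
                                   config$pixel_area_km2, config$habitat_mask)
  truth <- simulate_population(config, state_space)
  effb <- simulate_effort(config)
  capture <- simulate_detections(truth, effb, config)
  bundle <- structure(list(state_space = state_space, traps = effb$traps,
                           effort = effb$effort, tracks = effb$tracks,
                           playbacks = effb$playbacks, capture = capture,
                           truth = truth, config = config),
                      class = "scr_survey")
  if (!is.null(dir)) bundle$files <- write_survey_bundle(bundle, dir)
  bundle
}

#' True abundance and density of a synthetic survey within a region
#'
#' @param bundle an `scr_survey` (or an `scr_truth` plus explicit region).
#' @param region polygon or logical pixel mask; defaults to the survey
#'   polygon.
#' @return list with `N` (true included individuals in the region), `area_km2`
#'   and `density_per_100km2`.
#' @export
true_abundance <- function(bundle, region = NULL) {
  truth <- bundle$truth
  ss <- bundle$state_space
  if (is.null(region)) region <- bundle$config$survey_poly
  mask <- if (is.logical(region)) region else points_in_polygon(ss$centroids, region)
  hab <- which(ss$habitat)
  inr <- mask[hab[truth$s]]
  N <- sum(truth$z == 1L & inr)
  area <- sum(mask & ss$habitat) * ss$pixel_area
  list(N = N, area_km2 = area, density_per_100km2 = density_per_100km2(N, area))
}

#' @export
print.scr_survey <- function(x, ...) {
  cat("Synthetic SCR survey\n")
  print(x$state_space)
  print(x$effort)
  print(x$capture)
  cat(sprintf("  true N_super = %d\n", sum(x$truth$z)))
  invisible(x)
}
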