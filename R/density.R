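#' Posterior pixel density surface of activity centres
#'
#' Per state-space pixel, the posterior mean number of included activity
#' centres (mean over stored latent draws of `sum_i z_i 1[s_i = pixel]`).
#' The surface total equals the posterior mean of `N_super` over the same
#' draws (conservation).
#'
#' @param fit an `scr_fit` with stored latent draws.
#' @return an `scr_density_surface`: list with `value` (per-pixel posterior
#'   mean count, full state-space indexing with 0 for non-habitat),
#'   `pixel_area`, `per_100km2` conversion and the `scr_state_space`.
#' @export
pixel_density_surface <- function(fit) {
  ss <- fit$state_space
  draws <- latent_draws(fit)
  if (nrow(draws$s) == 0L) stop("no stored latent draws")
  counts <- numeric(fit$n_hab)
  for (r in seq_len(nrow(draws$s))) {
    on <- draws$z[r, ] == 1L
    if (any(on)) {
      t0 <- tabulate(draws$s[r, on] + 1L, nbins = fit$n_hab)
      counts <- counts + t0
    }
  }
  counts <- counts / nrow(draws$s)
  value <- numeric(nrow(ss$centroids))
  value[fit$hab_index] <- counts
  structure(list(value = value, pixel_area = ss$pixel_area,
                 per_100km2 = value / ss$pixel_area * 100,
                 state_space = ss, n_draws = nrow(draws$s)),
            class = "scr_density_surface")
}

#' @export
print.scr_density_surface <- function(x, ...) {
  cat(sprintf("SCR density surface: %d pixels, total %.2f activity centres (mean over %d draws)\n",
              length(x$value), sum(x$value), x$n_draws))
  invisible(x)
}

## Stack the stored latent draws of all chains.
latent_draws <- function(fit) {
  list(s = do.call(rbind, lapply(fit$chains, `[[`, "s")),
       z = do.call(rbind, lapply(fit$chains, `[[`, "z")),
       sex = do.call(rbind, lapply(fit$chains, `[[`, "sex")))
}

#' Posterior abundance within a region
#'
#' Counts, draw by draw, the included individuals whose activity centre
#' falls inside the region, and summarizes the draws (mean, PSD, 95% HPD).
#' Regions are additive: for disjoint regions the draw-wise counts add.
#'
#' @param fit an `scr_fit` with stored latent draws.
#' @param region either a polygon (matrix / list of loops, km) or a logical
#'   mask over state-space pixels.
#' @param mass HPD mass.
#' @return an `scr_region_abundance`: list with the per-draw counts
#'   (`draws`), `mean`, `psd`, `hpd`, and the region's habitat area (km^2).
#' @export
abundance_in_region <- function(fit, region, mass = 0.95) {
  ss <- fit$state_space
  if (is.logical(region)) {
    if (length(region) != nrow(ss$centroids))
      stop("logical region mask must have one entry per state-space pixel")
    mask <- region
  } else {
    mask <- points_in_polygon(ss$centroids, region)
  }
  if (!any(mask)) stop("empty region: no state-space pixel falls inside")
  hab_in <- which(mask[fit$hab_index])
  draws <- latent_draws(fit)
  inr <- matrix(FALSE, nrow(draws$s), ncol(draws$s))
  inr[] <- (draws$s + 1L) %in% hab_in
  n <- rowSums(inr & draws$z == 1L)
  structure(list(draws = n, mean = mean(n), psd = stats::sd(n),
                 hpd = hpd_interval(n, mass),
                 area_km2 = sum(mask & ss$habitat) * ss$pixel_area,
                 mask = mask),
            class = "scr_region_abundance")
}

#' @export
print.scr_region_abundance <- function(x, ...) {
  cat(sprintf("Region abundance: mean %.2f (PSD %.2f, 95%% HPD %.0f-%.0f) over %.1f km^2 habitat\n",
              x$mean, x$psd, x$hpd[1], x$hpd[2], x$area_km2))
  invisible(x)
}

#' Density per 100 km^2
#'
#' `D = N / area * 100`, applied to a scalar or draw-wise.
#' @param N abundance (scalar or draws).
#' @param area_km2 reference area (km^2), > 0.
#' @export
density_per_100km2 <- function(N, area_km2) {
  if (any(area_km2 <= 0)) stop("area_km2 must be > 0")
  N / area_km2 * 100
}

#' Buffer region from the sex-weighted movement scale
#'
#' The weighted mean movement scale `sigma_bar = psi_sex * sigma_M +
#' (1 - psi_sex) * sigma_F` defines a conservative buffer: the region is the
#' union of discs of radius `sigma_bar` around every trap-cell centroid,
#' discretized to habitat pixels.
#'
#' @param sigma_F,sigma_M posterior means (or point values) of the movement
#'   scales (km).
#' @param psi_sex posterior mean male proportion (weight on `sigma_M`).
#' @param traps an `scr_trap_grid`.
#' @param state_space an `scr_state_space`.
#' @return logical pixel mask with attributes `sigma_bar` and `area_km2`
#'   (habitat area of the region).
#' @export
weighted_sigma_buffer <- function(sigma_F, sigma_M, psi_sex, traps, state_space) {
  if (sigma_F <= 0 || sigma_M <= 0) stop("sigma must be > 0")
  if (psi_sex < 0 || psi_sex > 1) stop("psi_sex must lie in [0, 1]")
  if (nrow(traps$centroids) == 0L) stop("empty trap grid")
  sbar <- psi_sex * sigma_M + (1 - psi_sex) * sigma_F
  d <- distance_matrix(state_space, traps)
  mask <- apply(d, 1, min) <= sbar
  structure(mask, sigma_bar = sbar,
            area_km2 = sum(mask & state_space$habitat) * state_space$pixel_area)
}

#' Posterior sex ratio
#'
#' Female-to-male ratio implied by the male proportion:
#' `(1 - psi_sex) / psi_sex`, formatted as e.g. `"2.1F:1M"`.
#' @param psi_sex male proportion in (0, 1); a scalar (e.g. posterior mean).
#' @return the numeric ratio with attribute `label`.
#' @export
sex_ratio <- function(psi_sex) {
  if (psi_sex <= 0 || psi_sex >= 1) stop("psi_sex must lie strictly in (0, 1)")
  r <- (1 - psi_sex) / psi_sex
  structure(r, label = sprintf("%.1fF:1M", r))
}

#' Summarize a capture history
#'
#' Detection-frequency distribution (how many individuals were detected
#' once, twice, ...), total detections and individual count; the standard
#' first summary of an SCR capture data set.
#'
#' @param data an `scr_capture_data`, or a data frame of detections with an
#'   `individual` column.
#' @return list with `frequencies` (table of detections-per-individual),
#'   `n_individuals`, `n_detections`, `n_traps_per_individual` (mean number
#'   of distinct traps per individual).
#' @export
detection_summary <- function(data) {
  det <- if (inherits(data, "scr_capture_data")) data$detections else data
  cnt <- table(det$individual)
  ntr <- if (all(c("trap") %in% names(det)))
    mean(tapply(det$trap, det$individual, function(x) length(unique(x))))
  else NA_real_
  list(frequencies = table(factor(as.integer(cnt))),
       n_individuals = length(cnt),
       n_detections = sum(cnt),
       n_traps_per_individual = ntr)
}
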