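#' Build a discrete state-space of potential activity centres
#'
#' Lays a regular square lattice of equal-area pixels over the survey extent
#' plus a buffer, and flags pixels falling in unsuitable habitat. Pixel
#' centroids are spaced `sqrt(pixel_area_km2)` apart; a pixel belongs to the
#' state-space when its centroid lies within `buffer_km` of the extent
#' polygon. Habitat membership is decided by centroid-in-polygon against the
#' mask (even-odd rule, holes allowed), keeping the state-space fully
#' discrete.
#'
#' @param extent bounding polygon of the sampled area: a two-column matrix of
#'   vertices (km), or a `scr_trap_grid` whose cell centroids' convex hull is
#'   used.
#' @param buffer_km width of the buffer placed around `extent` (km).
#' @param pixel_area_km2 area of each state-space pixel (km^2).
#' @param habitat_mask polygons of *unsuitable* habitat (masked out), as a
#'   matrix, a list of loop matrices (holes allowed), or an `scr_raster` from
#'   [read_esri_ascii()] whose non-zero / non-NA cells are unsuitable.
#'   `NULL` means all pixels are habitat.
#' @return An object of class `scr_state_space` with elements `centroids`
#'   (n x 2 matrix, km), `habitat` (logical), `pixel_area`, `buffer_km`,
#'   `total_area` (= n pixels x pixel area, pre-mask), `habitat_area`,
#'   `extent` (the unbuffered polygon) and lattice metadata.
#' @examples
#' ext <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' ss <- build_state_space(ext, buffer_km = 2, pixel_area_km2 = 0.5)
#' ss$total_area
#' @export
build_state_space <- function(extent, buffer_km = 15, pixel_area_km2 = 0.5,
                              habitat_mask = NULL) {
  if (inherits(extent, "scr_trap_grid"))
    extent <- convex_hull_polygon(extent$centroids)
  loops <- as_loop_list(extent)
  if (length(loops) == 0L) stop("empty extent")
  extent <- loops[[1L]]
  if (buffer_km < 0) stop("buffer_km must be >= 0")
  if (pixel_area_km2 <= 0) stop("pixel_area_km2 must be > 0")

  delta <- sqrt(pixel_area_km2)
  xr <- range(extent[, 1]) + c(-buffer_km, buffer_km)
  yr <- range(extent[, 2]) + c(-buffer_km, buffer_km)
  nx <- lattice_count(diff(xr), delta)
  ny <- lattice_count(diff(yr), delta)
  cx <- xr[1] + (seq_len(nx) - 0.5) * delta
  cy <- yr[1] + (seq_len(ny) - 0.5) * delta
  cent <- cbind(x = rep(cx, times = ny), y = rep(cy, each = nx))
  gx <- rep(seq_len(nx) - 1L, times = ny)
  gy <- rep(seq_len(ny) - 1L, each = nx)

  keep <- dist_to_polygon(cent, extent) <= buffer_km + 1e-9
  cent <- cent[keep, , drop = FALSE]
  gx <- gx[keep]; gy <- gy[keep]
  if (nrow(cent) == 0L) stop("empty state-space: no pixel centroid falls inside the buffered extent")

  habitat <- rep(TRUE, nrow(cent))
  if (!is.null(habitat_mask)) {
    if (inherits(habitat_mask, "scr_raster")) {
      v <- raster_lookup(habitat_mask, cent)
      habitat <- !(!is.na(v) & v != 0)
    } else {
      habitat <- !points_in_polygon(cent, habitat_mask)
    }
    if (!any(habitat))
      stop("habitat mask removes every state-space pixel: zero habitat pixels remain")
  }

  structure(list(
    centroids = cent,
    habitat = habitat,
    pixel_area = pixel_area_km2,
    buffer_km = buffer_km,
    extent = extent,
    delta = delta,
    gx = gx, gy = gy, nx = nx, ny = ny,
    origin = c(xr[1], yr[1]),
    total_area = nrow(cent) * pixel_area_km2,
    habitat_area = sum(habitat) * pixel_area_km2
  ), class = "scr_state_space")
}

## Number of lattice steps covering a span, snapping to an exact multiple
## when the span divides evenly (within fp tolerance).
lattice_count <- function(span, delta) {
  r <- span / delta
  n <- if (abs(r - round(r)) < 1e-8) round(r) else ceiling(r)
  max(1L, as.integer(n))
}

#' @export
print.scr_state_space <- function(x, ...) {
  cat("SCR state-space\n")
  cat(sprintf("  pixels      : %d (%.3g km^2 each), %d habitat\n",
              nrow(x$centroids), x$pixel_area, sum(x$habitat)))
  cat(sprintf("  area        : %.1f km^2 total, %.1f km^2 habitat\n",
              x$total_area, x$habitat_area))
  cat(sprintf("  buffer      : %.1f km\n", x$buffer_km))
  invisible(x)
}

#' Pixel-to-trap distance matrix
#'
#' Euclidean distances (km) between every state-space pixel centroid and
#' every trap-cell centroid, precomputed once for the detection model.
#'
#' @param state_space an `scr_state_space`.
#' @param traps an `scr_trap_grid`.
#' @return numeric matrix, pixels x traps, in km.
#' @export
distance_matrix <- function(state_space, traps) {
  p <- state_space$centroids
  tr <- traps$centroids
  if (nrow(p) == 0L || nrow(tr) == 0L) stop("empty state-space or trap grid")
  dx <- outer(p[, 1], tr[, 1], "-")
  dy <- outer(p[, 2], tr[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

## Check every trap centroid lies within the unbuffered extent interior.
validate_traps_in_extent <- function(state_space, traps) {
  ok <- points_in_polygon(traps$centroids, state_space$extent)
  if (!all(ok))
    warning(sprintf("%d trap cell centroid(s) fall outside the unbuffered extent", sum(!ok)))
  invisible(all(ok))
}
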