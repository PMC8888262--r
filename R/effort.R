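#' Rasterize search tracks and playback events onto a trap-cell grid
#'
#' Converts raw effort logs into the trap x occasion covariate arrays the
#' detection model consumes. Each track polyline is clipped against a square
#' grid (cells of `grid_cell_km2`, anchored at the coordinate origin, cells
#' half-open on their upper edges) and per-cell lengths are summed by
#' occasion; playback events set a 0/1 indicator in their cell-occasion.
#' A "trap" is any grid cell that received search or playback effort on at
#' least one occasion; cells with zero total effort are excluded.
#'
#' @param tracks data frame with columns `occasion`, `segment_id`, `x_km`,
#'   `y_km`: ordered polyline vertices per segment. May be `NULL`/empty.
#' @param playbacks data frame with columns `occasion`, `x_km`, `y_km`
#'   (event locations), or `NULL`.
#' @param grid_cell_km2 trap-cell area (km^2), default 1.
#' @param n_occasions number of (daily) sampling occasions.
#' @return a list with `traps` (an `scr_trap_grid`: `centroids`, `cell_area`,
#'   `cell_ids` 0-based row-major within the active bounding grid, and the
#'   integer cell coordinates `ix`, `iy`) and `effort` (an `scr_effort`:
#'   matrices `search_km` and `playback`, traps x occasions, plus
#'   `n_occasions`). Duplicate playbacks collapsed into one indicator are
#'   counted in `effort$n_duplicate_playbacks`.
#' @export
rasterize_effort <- function(tracks, playbacks = NULL, grid_cell_km2 = 1,
                             n_occasions) {
  w <- sqrt(grid_cell_km2)
  n_occasions <- as.integer(n_occasions)
  if (n_occasions < 1L) stop("n_occasions must be >= 1")

  seg_cells <- list()
  if (!is.null(tracks) && nrow(tracks) > 0L) {
    check_occasions(tracks$occasion, n_occasions, "tracks")
    key <- interaction(tracks$occasion, tracks$segment_id, drop = TRUE)
    seg_cells <- lapply(split(seq_len(nrow(tracks)), key), function(idx) {
      v <- tracks[idx, , drop = FALSE]
      clip_polyline(v$x_km, v$y_km, w, v$occasion[1L])
    })
  }
  track_df <- if (length(seg_cells)) do.call(rbind, seg_cells) else
    data.frame(ix = integer(), iy = integer(), occasion = integer(), len = numeric())

  pb_df <- data.frame(ix = integer(), iy = integer(), occasion = integer())
  if (!is.null(playbacks) && nrow(playbacks) > 0L) {
    check_occasions(playbacks$occasion, n_occasions, "playbacks")
    pb_df <- data.frame(ix = floor(playbacks$x_km / w),
                        iy = floor(playbacks$y_km / w),
                        occasion = as.integer(playbacks$occasion))
  }

  all_cells <- unique(rbind(track_df[, c("ix", "iy")], pb_df[, c("ix", "iy")]))
  if (nrow(all_cells) == 0L) {
    warning("no effort supplied: empty trap grid")
    traps <- structure(list(centroids = cbind(x = numeric(), y = numeric()),
                            cell_area = grid_cell_km2, cell_ids = integer(),
                            ix = integer(), iy = integer()),
                       class = "scr_trap_grid")
    eff <- structure(list(search_km = matrix(0, 0, n_occasions),
                          playback = matrix(0L, 0, n_occasions),
                          n_occasions = n_occasions,
                          n_duplicate_playbacks = 0L),
                     class = "scr_effort")
    return(list(traps = traps, effort = eff))
  }

  # 0-based row-major ids over the bounding grid of active cells
  nx <- max(all_cells$ix) - min(all_cells$ix) + 1L
  id <- (all_cells$iy - min(all_cells$iy)) * nx + (all_cells$ix - min(all_cells$ix))
  o <- order(id)
  all_cells <- all_cells[o, , drop = FALSE]
  id <- id[o]
  cell_key <- paste(all_cells$ix, all_cells$iy)

  n_traps <- nrow(all_cells)
  search_km <- matrix(0, n_traps, n_occasions)
  playback <- matrix(0L, n_traps, n_occasions)

  if (nrow(track_df)) {
    ti <- match(paste(track_df$ix, track_df$iy), cell_key)
    for (r in seq_len(nrow(track_df)))
      search_km[ti[r], track_df$occasion[r]] <-
        search_km[ti[r], track_df$occasion[r]] + track_df$len[r]
  }
  n_dup <- 0L
  if (nrow(pb_df)) {
    pi_ <- match(paste(pb_df$ix, pb_df$iy), cell_key)
    for (r in seq_len(nrow(pb_df))) {
      if (playback[pi_[r], pb_df$occasion[r]] == 1L) n_dup <- n_dup + 1L
      playback[pi_[r], pb_df$occasion[r]] <- 1L
    }
    if (n_dup > 0L)
      message(sprintf("%d duplicate playback event(s) collapsed to a single indicator", n_dup))
  }

  traps <- structure(list(
    centroids = cbind(x = (all_cells$ix + 0.5) * w, y = (all_cells$iy + 0.5) * w),
    cell_area = grid_cell_km2,
    cell_ids = id,
    ix = all_cells$ix, iy = all_cells$iy
  ), class = "scr_trap_grid")
  eff <- structure(list(search_km = search_km, playback = playback,
                        n_occasions = n_occasions,
                        n_duplicate_playbacks = n_dup),
                   class = "scr_effort")
  list(traps = traps, effort = eff)
}

check_occasions <- function(occ, n_occasions, what) {
  if (any(is.na(occ)) || any(occ < 1L) || any(occ > n_occasions))
    stop(sprintf("%s: occasion outside [1, %d]", what, n_occasions))
}

## Clip one polyline to the square grid of width w (cells [kw, (k+1)w) so a
## point on a shared edge belongs to the higher-index cell). Returns per-cell
## lengths as a data frame (ix, iy, occasion, len).
clip_polyline <- function(x, y, w, occasion) {
  out_ix <- integer(); out_iy <- integer(); out_len <- numeric()
  for (k in seq_len(length(x) - 1L)) {
    x1 <- x[k]; y1 <- y[k]; x2 <- x[k + 1L]; y2 <- y[k + 1L]
    L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (L == 0) next
    # parameter values where the segment crosses grid lines
    ts <- c(0, 1)
    for (g in grid_lines(x1, x2, w)) ts <- c(ts, (g - x1) / (x2 - x1))
    for (g in grid_lines(y1, y2, w)) ts <- c(ts, (g - y1) / (y2 - y1))
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    for (m in seq_len(length(ts) - 1L)) {
      t0 <- ts[m]; t1 <- ts[m + 1L]
      if (t1 <= t0) next
      tm <- (t0 + t1) / 2
      out_ix <- c(out_ix, floor((x1 + tm * (x2 - x1)) / w))
      out_iy <- c(out_iy, floor((y1 + tm * (y2 - y1)) / w))
      out_len <- c(out_len, (t1 - t0) * L)
    }
  }
  if (!length(out_len))
    return(data.frame(ix = integer(), iy = integer(),
                      occasion = integer(), len = numeric()))
  agg <- stats::aggregate(len ~ ix + iy, data.frame(ix = out_ix, iy = out_iy, len = out_len), sum)
  data.frame(ix = agg$ix, iy = agg$iy, occasion = as.integer(occasion), len = agg$len)
}

## Interior grid-line coordinates strictly between a and b (multiples of w).
grid_lines <- function(a, b, w) {
  lo <- min(a, b); hi <- max(a, b)
  ks <- seq.int(ceiling(lo / w), floor(hi / w))
  g <- ks * w
  g[g > lo & g < hi]
}

#' @export
print.scr_trap_grid <- function(x, ...) {
  cat(sprintf("SCR trap grid: %d cells of %.3g km^2\n",
              nrow(x$centroids), x$cell_area))
  invisible(x)
}

#' @export
print.scr_effort <- function(x, ...) {
  cat(sprintf("SCR effort: %d traps x %d occasions, %.1f km searched, %d playback cell-occasions\n",
              nrow(x$search_km), x$n_occasions, sum(x$search_km), sum(x$playback)))
  invisible(x)
}

#' Convert an effort array to long format
#'
#' One row per trap-occasion with any effort, matching the CSV interchange
#' format (`trap_id`, `occasion`, `search_km`, `playback`).
#' @param effort an `scr_effort`.
#' @param traps the matching `scr_trap_grid`.
#' @return data frame.
#' @export
effort_to_long <- function(effort, traps) {
  idx <- which(effort$search_km > 0 | effort$playback > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(trap_id = traps$cell_ids[idx[, 1]],
             occasion = idx[, 2],
             search_km = effort$search_km[idx],
             playback = effort$playback[idx])
}
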