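#' Read survey input files
#'
#' The CSV interchange formats: tracks (`occasion`, `segment_id`, `x_km`,
#' `y_km`, ordered vertices), playbacks (`occasion`, `x_km`, `y_km`) and
#' capture histories (`individual_id`, `trap_id`, `occasion`, optional
#' `sex` in F/M/U).
#'
#' @param path file path.
#' @name survey_io
NULL

#' @rdname survey_io
#' @export
read_tracks_csv <- function(path) {
  x <- utils::read.csv(path)
  need_cols(x, c("occasion", "segment_id", "x_km", "y_km"), path)
  x
}

#' @rdname survey_io
#' @export
read_playbacks_csv <- function(path) {
  x <- utils::read.csv(path)
  need_cols(x, c("occasion", "x_km", "y_km"), path)
  x
}

#' @rdname survey_io
#' @export
read_captures_csv <- function(path) {
  x <- utils::read.csv(path)
  need_cols(x, c("individual_id", "trap_id", "occasion"), path)
  if (is.null(x$sex)) x$sex <- "U"
  x
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  invisible(df)
}

#' Write / read a long-format effort table
#'
#' Columns `trap_id`, `occasion`, `search_km`, `playback`; one row per
#' trap-occasion with effort.
#' @param effort an `scr_effort`.
#' @param traps the matching `scr_trap_grid`.
#' @param path CSV path.
#' @export
write_effort_csv <- function(effort, traps, path) {
  utils::write.csv(effort_to_long(effort, traps), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_effort_csv
#' @export
read_effort_csv <- function(path) {
  x <- utils::read.csv(path)
  need_cols(x, c("trap_id", "occasion", "search_km", "playback"), path)
  x
}

#' Read a habitat mask from GeoJSON
#'
#' Accepts Polygon / MultiPolygon geometries (Feature or FeatureCollection
#' wrappers allowed); all rings are returned as planar loop matrices (km),
#' holes included, suitable for the even-odd membership test.
#' @param path GeoJSON file.
#' @return list of loop matrices.
#' @export
read_habitat_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  loops <- list()
  collect <- function(geom) {
    if (is.null(geom)) return()
    if (geom$type == "Polygon") {
      for (ring in geom$coordinates)
        loops[[length(loops) + 1L]] <<- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) for (ring in poly)
        loops[[length(loops) + 1L]] <<- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    } else stop("unsupported GeoJSON geometry type: ", geom$type)
  }
  if (g$type == "FeatureCollection") for (f in g$features) collect(f$geometry)
  else if (g$type == "Feature") collect(g$geometry)
  else collect(g)
  loops
}

#' Write polygons as GeoJSON
#' @param loops list of loop matrices (first is the shell, rest holes).
#' @param path output file.
#' @export
write_polygons_geojson <- function(loops, path) {
  loops <- as_loop_list(loops)
  rings <- lapply(loops, function(p) {
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
    lapply(seq_len(nrow(p)), function(k) c(p[k, 1], p[k, 2]))
  })
  obj <- list(type = "Feature", properties = list(),
              geometry = list(type = "Polygon", coordinates = rings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write an ESRI ASCII grid
#'
#' @param path file path.
#' @return an `scr_raster`: list with `value` matrix (rows from north),
#'   `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  ln <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(ln[i:length(ln)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  structure(list(value = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = nodata),
            class = "scr_raster")
}

#' @rdname read_esri_ascii
#' @param raster an `scr_raster`, or an `scr_density_surface` (gridded onto
#'   its state-space lattice).
#' @export
write_esri_ascii <- function(raster, path) {
  if (inherits(raster, "scr_density_surface")) raster <- surface_to_raster(raster)
  m <- raster$value
  m[is.na(m)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", raster$xll),
               sprintf("yllcorner %.10g", raster$yll),
               sprintf("cellsize %.10g", raster$cellsize),
               sprintf("NODATA_value %.10g", raster$nodata)), con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

## value at points, by cell lookup
raster_lookup <- function(r, pts) {
  ic <- floor((pts[, 1] - r$xll) / r$cellsize) + 1L
  ir <- nrow(r$value) - floor((pts[, 2] - r$yll) / r$cellsize)
  ok <- ic >= 1L & ic <= ncol(r$value) & ir >= 1L & ir <= nrow(r$value)
  out <- rep(NA_real_, nrow(pts))
  out[ok] <- r$value[cbind(ir[ok], ic[ok])]
  out
}

surface_to_raster <- function(surf) {
  ss <- surf$state_space
  m <- matrix(NA_real_, nrow = ss$ny, ncol = ss$nx)
  m[cbind(ss$ny - ss$gy, ss$gx + 1L)] <- surf$value
  structure(list(value = m, xll = ss$origin[1], yll = ss$origin[2],
                 cellsize = ss$delta, nodata = -9999),
            class = "scr_raster")
}

#' Write a synthetic survey bundle to disk
#'
#' Writes `tracks.csv`, `playbacks.csv`, `captures.csv`, `effort.csv`,
#' `config.yaml`, `truth.json`, optionally `mask.geojson`, and a
#' `manifest.yaml` with the seed, package version and file checksums. The
#' same seed and config always produce a byte-identical bundle.
#' @param bundle an `scr_survey`.
#' @param dir output directory.
#' @return named vector of file paths (invisibly).
#' @export
write_survey_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c(tracks = p("tracks.csv"), playbacks = p("playbacks.csv"),
             captures = p("captures.csv"), effort = p("effort.csv"),
             config = p("config.yaml"), truth = p("truth.json"))
  wcsv <- function(d, f) utils::write.csv(format(d, trim = TRUE, digits = 12),
                                          f, row.names = FALSE, quote = FALSE)
  wcsv(bundle$tracks, files["tracks"])
  wcsv(bundle$playbacks, files["playbacks"])
  cd <- bundle$capture
  caps <- data.frame(individual_id = cd$detections$individual,
                     trap_id = bundle$traps$cell_ids[cd$detections$trap],
                     occasion = cd$detections$occasion,
                     sex = c("F", "M")[cd$sex_obs[cd$detections$individual] + 1L])
  caps$sex[is.na(caps$sex)] <- "U"
  wcsv(caps, files["captures"])
  write_effort_csv(bundle$effort, bundle$traps, files["effort"])
  cfg <- bundle$config
  yaml::write_yaml(list(
    survey_poly = list(x = cfg$survey_poly[, 1], y = cfg$survey_poly[, 2]),
    buffer_km = cfg$buffer_km, pixel_area_km2 = cfg$pixel_area_km2,
    cell_km2 = cfg$cell_km2, n_occasions = cfg$n_occasions,
    km_per_occasion = cfg$km_per_occasion, waypoint_km = cfg$waypoint_km,
    n_playbacks = cfg$n_playbacks, M = cfg$M, seed = cfg$seed,
    params = unclass(cfg$params),
    model = list(lambda0_sex_specific = cfg$spec$lambda0_sex_specific,
                 sigma_sex_specific = cfg$spec$sigma_sex_specific,
                 theta = cfg$spec$theta, M = cfg$spec$M,
                 include_playback = cfg$spec$include_playback)
  ), files["config"])
  jsonlite::write_json(list(z = bundle$truth$z, sex = bundle$truth$sex,
                            s = bundle$truth$s,
                            s_x = bundle$truth$s_xy[, 1],
                            s_y = bundle$truth$s_xy[, 2]),
                       files["truth"], digits = NA)
  if (!is.null(cfg$habitat_mask)) {
    files["mask"] <- p("mask.geojson")
    write_polygons_geojson(cfg$habitat_mask, files["mask"])
  }
  manifest <- list(package = "searchSCR",
                   version = as.character(utils::packageVersion("searchSCR")),
                   seed = cfg$seed,
                   md5 = as.list(tools::md5sum(unname(files))))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  files["manifest"] <- p("manifest.yaml")
  invisible(files)
}

#' Read a survey bundle back from disk
#'
#' Re-rasterizes the raw tracks and playbacks (deterministic), rebuilds the
#' state-space from the stored config and re-assembles validated capture
#' data; the returned pieces are ready for [scr_fit()].
#' @param dir bundle directory.
#' @export
read_survey_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- yaml::read_yaml(p("config.yaml"))
  mask <- if (file.exists(p("mask.geojson"))) read_habitat_geojson(p("mask.geojson")) else NULL
  tracks <- read_tracks_csv(p("tracks.csv"))
  playbacks <- read_playbacks_csv(p("playbacks.csv"))
  ras <- rasterize_effort(tracks, playbacks, cfg$cell_km2, cfg$n_occasions)
  poly <- cbind(cfg$survey_poly$x, cfg$survey_poly$y)
  ss <- build_state_space(poly, cfg$buffer_km, cfg$pixel_area_km2, mask)
  caps <- read_captures_csv(p("captures.csv"))
  det <- data.frame(individual = caps$individual_id,
                    trap = match(caps$trap_id, ras$traps$cell_ids),
                    occasion = caps$occasion)
  ids <- sort(unique(caps$individual_id))
  sex <- caps$sex[match(ids, caps$individual_id)]
  capture <- capture_data(det, sex, ras$effort, ras$traps)
  truth <- if (file.exists(p("truth.json")))
    jsonlite::fromJSON(p("truth.json")) else NULL
  spec <- model_spec(cfg$model$lambda0_sex_specific, cfg$model$sigma_sex_specific,
                     cfg$model$theta, cfg$model$M, cfg$model$include_playback)
  list(state_space = ss, traps = ras$traps, effort = ras$effort,
       capture = capture, truth = truth, config = cfg, spec = spec,
       survey_poly = poly)
}
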