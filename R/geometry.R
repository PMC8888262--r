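# Internal planar geometry helpers. All coordinates are kilometres in a
# local projected (planar) system; geodesy is out of scope.

#' @importFrom mgcv in.out
NULL

## Normalise polygon input to a list of loops, each a closed-or-open
## two-column matrix (x, y). Accepts a matrix (single loop) or a list of
## matrices / list(x=, y=) loops.
as_loop_list <- function(poly) {
  if (is.null(poly)) return(list())
  if (is.matrix(poly) || is.data.frame(poly)) poly <- list(poly)
  lapply(poly, function(p) {
    if (is.list(p) && !is.data.frame(p) && all(c("x", "y") %in% names(p)))
      p <- cbind(p$x, p$y)
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each polygon loop needs a two-column matrix with >= 3 vertices")
    storage.mode(p) <- "double"
    unname(p)
  })
}

## Even-odd point-in-polygon over all loops (holes supported).
points_in_polygon <- function(pts, poly) {
  loops <- as_loop_list(poly)
  if (length(loops) == 0L) return(rep(FALSE, nrow(pts)))
  bnd <- lapply(loops, function(p) list(x = p[, 1], y = p[, 2]))
  if (length(bnd) == 1L) bnd <- cbind(bnd[[1]]$x, bnd[[1]]$y)
  mgcv::in.out(bnd, as.matrix(pts))
}

## Distance from each point to a polygon boundary-or-interior:
## 0 for interior points, else min distance to any edge.
dist_to_polygon <- function(pts, poly) {
  loops <- as_loop_list(poly)
  pts <- as.matrix(pts)
  d <- rep(Inf, nrow(pts))
  for (p in loops) {
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
    for (k in seq_len(nrow(p) - 1L)) {
      d <- pmin(d, dist_point_segment(pts, p[k, ], p[k + 1L, ]))
    }
  }
  d[points_in_polygon(pts, poly)] <- 0
  d
}

dist_point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2)
}

## Convex hull of points as a closed loop matrix.
convex_hull_polygon <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) == 1L) {
    # degenerate: tiny square around the single point
    e <- 1e-6
    return(cbind(xy[1, 1] + c(-e, e, e, -e), xy[1, 2] + c(-e, -e, e, e)))
  }
  h <- grDevices::chull(xy)
  xy[h, , drop = FALSE]
}

#' @importFrom grDevices chull
NULL
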