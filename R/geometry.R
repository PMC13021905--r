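# Pixel/polygon geometry shared by the phantom, calibration and morphometry
# code. Convention (package-wide): single-channel images are R matrices with
# origin top-left; pixel (row r, col c) has its *center* at the 0-based
# continuous coordinate (x, y) = (c - 1, r - 1), x rightwards, y downwards.
# A pixel belongs to a polygon iff its center falls inside (center-in rule,
# even-odd winding). Polygons are n x 2 matrices of (x, y) vertices,
# implicitly closed.

as_polygon <- function(poly) {
  if (is.list(poly) && !is.null(poly$polygon)) poly <- poly$polygon
  p <- matrix(as.numeric(unlist(poly)), ncol = 2, byrow = !is.matrix(poly))
  if (is.matrix(poly)) p <- poly
  storage.mode(p) <- "double"
  p
}

#' Rasterize a polygon to a logical pixel mask
#'
#' Scanline even-odd fill under the center-in rule: a pixel is inside iff the
#' number of polygon edge crossings strictly to the left of its center is odd.
#' Horizontal edges are handled by the half-open rule `ymin <= y < ymax`.
#'
#' @param poly n x 2 matrix of (x, y) vertices (0-based pixel-center
#'   coordinates), implicitly closed.
#' @param dim image dimension `c(rows, cols)`.
#' @return logical matrix of dimension `dim`.
#' @keywords internal
polygon_mask <- function(poly, dim) {
  poly <- as_polygon(poly)
  if (nrow(poly) < 3) stop("degenerate polygon: need >= 3 vertices")
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(FALSE, nr, nc)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  x2 <- x1[nxt]; y2 <- y1[nxt]
  keep <- y1 != y2
  if (!any(keep)) return(mask)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  r_lo <- max(1L, as.integer(floor(min(ylo))) + 1L)
  r_hi <- min(nr, as.integer(ceiling(max(yhi))) + 1L)
  if (r_lo > r_hi) return(mask)
  centers <- 0:(nc - 1)
  for (r in r_lo:r_hi) {
    y <- r - 1
    hit <- (ylo <= y) & (y < yhi)
    if (!any(hit)) next
    xc <- x1[hit] + (y - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    mask[r, ] <- (findInterval(centers, sort(xc)) %% 2L) == 1L
  }
  mask
}

# Union mask of a list of polygons (empty list -> all-FALSE mask).
polygons_mask <- function(polys, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (p in polys) m <- m | polygon_mask(p, dim)
  m
}

# Signed shoelace area in the polygon's own (pixel) units^2.
shoelace_area_px <- function(poly) {
  poly <- as_polygon(poly)
  if (nrow(poly) < 3) stop("degenerate polygon: need >= 3 vertices")
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  nxt <- c(seq_len(n)[-1], 1L)
  sum(x * y[nxt] - x[nxt] * y) / 2
}

# Axis-aligned rectangle polygon covering continuous extent [x0,x1] x [y0,y1].
rect_polygon <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Euclidean distance between two (x, y) points, in pixels.
point_dist_px <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))
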