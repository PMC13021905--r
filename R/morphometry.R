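# Per-image keel morphometry: lengths, ossification degree, areas, the
# proportion of deviated area (POD), and the automatically placed density
# square. Lengths are straight-line landmark distances in cm, areas cm2,
# densities mmAleq.

#' Total and ossified keel length
#'
#' Euclidean distances between annotated landmarks scaled to cm:
#' cranial tip to caudal tip (total) and cranial tip to the caudalmost
#' ossified point (ossified).
#'
#' @param annotation a [radiograph_annotation()].
#' @return named numeric vector `c(total_length, ossified_length)` in cm.
#' @export
keel_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "radiograph_annotation"))
  cr <- require_landmark(annotation, "cranial_tip")
  ca <- require_landmark(annotation, "caudal_tip")
  os <- require_landmark(annotation, "caudalmost_ossified")
  scale_cm <- annotation$pixel_scale / 10
  total <- point_dist_px(cr, ca) * scale_cm
  ossified <- point_dist_px(cr, os) * scale_cm
  if (ossified > total + annotation$pixel_scale / 10)
    warning("ossified length exceeds total length beyond pixel tolerance")
  c(total_length = total, ossified_length = ossified)
}

#' Ossification degree and completeness
#'
#' Degree = ossified length / total length. The keel counts as completely
#' ossified only when the degree strictly exceeds 0.95 (surrounding fat at
#' the caudal tip can mimic incomplete ossification, so a 5% margin is
#' allowed; exactly 0.95 is *not* complete).
#'
#' @param total_length,ossified_length lengths in cm.
#' @return list with `degree` (fraction) and `fully_ossified` (logical).
#' @export
ossification_degree <- function(total_length, ossified_length) {
  if (!is.finite(total_length) || total_length <= 0)
    stop("domain error: total_length must be > 0")
  degree <- ossified_length / total_length
  list(degree = degree, fully_ossified = degree > 0.95)
}

#' Polygon area in cm2
#'
#' Absolute shoelace area scaled by the pixel size; orientation-independent.
#'
#' @param polygon n x 2 matrix of pixel `(x, y)` vertices.
#' @param pixel_scale mm per pixel.
#' @return area in cm2.
#' @export
polygon_area <- function(polygon, pixel_scale) {
  abs(shoelace_area_px(polygon)) * pixel_scale^2 / 100
}

#' Proportion of deviated keel bone area (POD)
#'
#' `100 * area(union of deviated regions within the keel outline) /
#' area(keel outline)`. Overlapping deviated polygons are not double
#' counted; deviated regions are clipped to the keel outline so POD <= 100.
#' Areas of the union/intersection are computed on the pixel grid under the
#' center-in rule.
#'
#' @param deviated_regions list of polygons.
#' @param keel_outline keel outline polygon.
#' @param pixel_scale mm per pixel (kept for interface symmetry; the ratio
#'   is scale-free).
#' @param supersample linear grid refinement factor for the raster (4 keeps
#'   the discretization error of the ratio well under 0.1 percentage points
#'   for keels spanning a few hundred pixels).
#' @return POD in percent.
#' @export
pod <- function(deviated_regions, keel_outline, pixel_scale = 1,
                supersample = 4L) {
  keel_outline <- as_polygon(keel_outline)
  if (abs(shoelace_area_px(keel_outline)) == 0)
    stop("domain error: keel outline has zero area")
  if (!length(deviated_regions)) return(0)
  # raster grid over the keel bounding box (plus margin), shifted so all
  # coordinates are positive and refined by `supersample`; POD is
  # translation invariant
  k <- max(1L, as.integer(supersample))
  all_pts <- rbind(keel_outline,
                   do.call(rbind, lapply(deviated_regions, as_polygon)))
  shift <- floor(apply(all_pts, 2, min)) - 2
  shift_poly <- function(p) sweep(as_polygon(p), 2, shift) * k
  keel_s <- shift_poly(keel_outline)
  ext <- ceiling(apply(rbind(keel_s,
                             do.call(rbind, lapply(deviated_regions,
                                                   shift_poly))), 2, max)) + 2
  dim <- c(ext[2], ext[1])
  kmask <- polygon_mask(keel_s, dim)
  if (!any(kmask)) stop("domain error: keel outline rasterizes to no pixels")
  dmask <- polygons_mask(lapply(deviated_regions, shift_poly), dim)
  100 * sum(dmask & kmask) / sum(kmask)
}

#' Place the density square
#'
#' The square sits at the midpoint of the straight line from the cranial tip
#' to the caudal tip (or, for incompletely ossified keels, to the caudalmost
#' ossified point); its side is 1/12 of the ossified length. A manual offset
#' recorded in the annotation shifts the center (used when the automatic
#' placement falls off deviated or highly curved keels). The square is
#' axis-aligned.
#'
#' @param annotation a [radiograph_annotation()].
#' @param ossified_length ossified length in cm.
#' @param fully_ossified logical; selects the caudal tip (`TRUE`) or the
#'   caudalmost ossified point (`FALSE`) as the line endpoint.
#' @return list with `center` (pixel `(x, y)`), `side` (cm) and `polygon`
#'   (pixel coordinates).
#' @export
place_density_square <- function(annotation, ossified_length,
                                 fully_ossified = TRUE) {
  stopifnot(inherits(annotation, "radiograph_annotation"))
  cr <- require_landmark(annotation, "cranial_tip")
  endpoint <- require_landmark(
    annotation, if (fully_ossified) "caudal_tip" else "caudalmost_ossified")
  if (point_dist_px(cr, endpoint) == 0)
    stop("annotation error: degenerate cranial-caudal segment")
  center <- (cr + endpoint) / 2
  if (!is.null(annotation$manual_square_offset))
    center <- center + as.numeric(annotation$manual_square_offset)
  side <- ossified_length / 12
  half_px <- side * 10 / annotation$pixel_scale / 2
  list(center = center, side = side,
       polygon = rect_polygon(center[1] - half_px, center[1] + half_px,
                              center[2] - half_px, center[2] + half_px))
}

#' Measure a radiograph
#'
#' Assembles the full per-image measurement record: lengths, ossification
#' degree and completeness, lateral and deviated area, POD, the density
#' square, and the radiographic density of the whole keel (including
#' fractures, excluding superimposition masks) and of the square.
#'
#' @param image numeric gray matrix.
#' @param annotation a [radiograph_annotation()].
#' @param curve a [fit_rodbard()] calibration.
#' @param image_id optional identifier carried into the output.
#' @return one-row data.frame (a `keel_measurement`): `total_length`,
#'   `ossified_length`, `ossification_degree`, `fully_ossified`,
#'   `lateral_area`, `deviated_area`, `pod`, `square_x`, `square_y`,
#'   `square_side`, `density_square`, `density_whole`.
#' @export
measure <- function(image, annotation, curve, image_id = NA_character_) {
  stopifnot(inherits(annotation, "radiograph_annotation"),
            inherits(curve, "rodbard_curve"))
  len <- keel_lengths(annotation)
  oss <- ossification_degree(len[["total_length"]], len[["ossified_length"]])
  lateral <- polygon_area(annotation$keel_outline, annotation$pixel_scale)
  pod_pct <- pod(annotation$deviated_regions, annotation$keel_outline,
                 annotation$pixel_scale)
  sq <- place_density_square(annotation, len[["ossified_length"]],
                             oss$fully_ossified)
  density_whole <- mean_mmAleq(image, curve, annotation$keel_outline,
                               annotation$exclusion_masks)
  density_square <- mean_mmAleq(image, curve, sq$polygon,
                                annotation$exclusion_masks)
  out <- data.frame(
    image_id = image_id,
    total_length = len[["total_length"]],
    ossified_length = len[["ossified_length"]],
    ossification_degree = oss$degree,
    fully_ossified = oss$fully_ossified,
    lateral_area = lateral,
    deviated_area = lateral * pod_pct / 100,
    pod = pod_pct,
    square_x = sq$center[1], square_y = sq$center[2],
    square_side = sq$side,
    density_square = density_square,
    density_whole = density_whole,
    stringsAsFactors = FALSE)
  class(out) <- c("keel_measurement", class(out))
  out
}
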