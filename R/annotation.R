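# Per-image annotation: the landmarks, polygons and wedge ROIs an observer
# marks on a radiograph, plus the pixel scale set from the wedge dimensions.

#' Radiograph annotation
#'
#' Container for everything measured by hand on one latero-lateral
#' radiograph: the pixel scale, the cranial/caudal tips and the caudalmost
#' ossified point, the keel outline polygon, deviated sub-regions, exclusion
#' masks (superimpositions), the wedge step ROIs with their known
#' thicknesses, and whether the image is evaluable for fractures.
#'
#' @param pixel_scale mm per pixel (> 0).
#' @param landmarks named list with `cranial_tip`, `caudal_tip`,
#'   `caudalmost_ossified`, each an `(x, y)` pixel point.
#' @param keel_outline simple polygon (n x 2 matrix of `(x, y)` vertices).
#' @param deviated_regions list of polygons.
#' @param exclusion_masks list of polygons excluded from density statistics.
#' @param wedge_steps list of `list(thickness_mm =, polygon =)` entries.
#' @param fracture_evaluable logical; `FALSE` when superimpositions block
#'   fracture scoring.
#' @param manual_square_offset optional `(dx, dy)` pixel shift applied to the
#'   automatically placed density square.
#' @return an object of class `radiograph_annotation`.
#' @export
radiograph_annotation <- function(pixel_scale, landmarks, keel_outline,
                                  deviated_regions = list(),
                                  exclusion_masks = list(),
                                  wedge_steps = list(),
                                  fracture_evaluable = TRUE,
                                  manual_square_offset = NULL) {
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop("annotation error: pixel_scale must be > 0")
  structure(list(pixel_scale = pixel_scale, landmarks = landmarks,
                 keel_outline = as_polygon(keel_outline),
                 deviated_regions = lapply(deviated_regions, as_polygon),
                 exclusion_masks = lapply(exclusion_masks, as_polygon),
                 wedge_steps = wedge_steps,
                 fracture_evaluable = isTRUE(fracture_evaluable),
                 manual_square_offset = manual_square_offset),
            class = "radiograph_annotation")
}

require_landmark <- function(annotation, name) {
  p <- annotation$landmarks[[name]]
  if (is.null(p) || length(p) != 2 || !all(is.finite(as.numeric(p))))
    stop(sprintf("annotation error: missing landmark '%s'", name))
  as.numeric(p)
}

poly_to_list <- function(p) lapply(seq_len(nrow(p)), function(i) unname(p[i, ]))
list_to_poly <- function(l) do.call(rbind, lapply(l, as.numeric))

#' Write / read annotation JSON
#'
#' Serializes a [radiograph_annotation()] to the on-disk JSON layout:
#' `pixel_scale_mm_per_px`, `wedge_steps` (thickness + polygon), `landmarks`,
#' `keel_outline`, `deviated_regions`, `exclusion_masks`,
#' `fracture_evaluable`. Polygons are ordered `[x, y]` vertex lists,
#' implicitly closed.
#'
#' @param annotation a [radiograph_annotation()].
#' @param path JSON file path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a `radiograph_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "radiograph_annotation"))
  obj <- list(
    pixel_scale_mm_per_px = annotation$pixel_scale,
    wedge_steps = lapply(annotation$wedge_steps, function(s)
      list(thickness_mm = s$thickness_mm, polygon = poly_to_list(s$polygon))),
    landmarks = lapply(annotation$landmarks, unname),
    keel_outline = poly_to_list(annotation$keel_outline),
    deviated_regions = lapply(annotation$deviated_regions, poly_to_list),
    exclusion_masks = lapply(annotation$exclusion_masks, poly_to_list),
    fracture_evaluable = annotation$fracture_evaluable)
  if (!is.null(annotation$manual_square_offset))
    obj$manual_square_offset <- unname(annotation$manual_square_offset)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  radiograph_annotation(
    pixel_scale = obj$pixel_scale_mm_per_px,
    landmarks = lapply(obj$landmarks, as.numeric),
    keel_outline = list_to_poly(obj$keel_outline),
    deviated_regions = lapply(obj$deviated_regions, list_to_poly),
    exclusion_masks = lapply(obj$exclusion_masks, list_to_poly),
    wedge_steps = lapply(obj$wedge_steps, function(s)
      list(thickness_mm = as.numeric(s$thickness_mm),
           polygon = list_to_poly(s$polygon))),
    fracture_evaluable = isTRUE(obj$fracture_evaluable),
    manual_square_offset =
      if (is.null(obj$manual_square_offset)) NULL
      else as.numeric(obj$manual_square_offset))
}

#' Write / read a phantom image as 16-bit grayscale TIFF
#'
#' Gray values are quantized to integers on `[0, 2^16 - 1]` at export (the
#' in-memory phantom keeps continuous detector-model grays).
#'
#' @param image numeric gray matrix.
#' @param path TIFF file path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns the gray matrix on the integer 16-bit scale.
#' @export
write_image_tiff <- function(image, path) {
  gmax <- 65535
  tiff::writeTIFF(pmin(pmax(round(image), 0), gmax) / gmax, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535)
}
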