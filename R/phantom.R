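# Synthetic latero-lateral radiograph phantoms: an aluminium step wedge plus
# a keel bone silhouette of fully known aluminium-equivalent thickness. The
# phantom is the testbed for the calibration and morphometry stages: every
# downstream quantity has a ground truth by construction.

#' Step wedge specification
#'
#' Geometry of the aluminium step wedge placed on the detector plate. The
#' default mirrors a home-built 2 cm x 17.8 cm wedge with 18 steps spanning
#' 0.5 mm to 4.75 mm of aluminium.
#'
#' @param n_steps number of steps (>= 2).
#' @param thickness_min,thickness_max thinnest/thickest step, mm aluminium.
#' @param width,length wedge footprint on the detector, mm.
#' @return an object of class `step_wedge_spec`.
#' @export
#' @examples
#' wedge_thickness_series(step_wedge_spec())
step_wedge_spec <- function(n_steps = 18L, thickness_min = 0.5,
                            thickness_max = 4.75, width = 20, length = 178) {
  if (!is.numeric(n_steps) || n_steps < 2 || n_steps != round(n_steps))
    stop("invalid step wedge spec: n_steps must be an integer >= 2")
  if (thickness_min <= 0 || thickness_min >= thickness_max)
    stop("invalid step wedge spec: need 0 < thickness_min < thickness_max")
  if (width <= 0 || length <= 0)
    stop("invalid step wedge spec: width and length must be positive")
  structure(list(n_steps = as.integer(n_steps), thickness_min = thickness_min,
                 thickness_max = thickness_max, width = width, length = length),
            class = "step_wedge_spec")
}

#' Step thicknesses of a wedge
#'
#' Strictly increasing arithmetic series of `n_steps` aluminium thicknesses
#' from `thickness_min` to `thickness_max`.
#'
#' @param spec a [step_wedge_spec()].
#' @return numeric vector of thicknesses in mm aluminium.
#' @export
wedge_thickness_series <- function(spec = step_wedge_spec()) {
  stopifnot(inherits(spec, "step_wedge_spec"))
  seq(spec$thickness_min, spec$thickness_max, length.out = spec$n_steps)
}

#' Detector transfer model
#'
#' Forward model of the digital radiograph: the gray value produced by a
#' given aluminium-equivalent thickness is the inverse of the four-parameter
#' Rodbard calibration `thickness(g) = d + (a - d) / (1 + (g/c)^b)`. `a` is
#' the thickness asymptote as gray -> 0 and `d` the asymptote as
#' gray -> Inf; with `a < d` brighter means thicker. Additive Gaussian gray
#' noise with sd `noise_sd` proxies detector read noise.
#'
#' @param a,b,c,d Rodbard parameters; `b > 0`, `c > 0`, `a != d`.
#' @param noise_sd gray-value noise standard deviation (>= 0).
#' @param bit_depth detector bit depth; grays clip to `[0, 2^bit_depth - 1]`.
#' @return an object of class `transfer_model`.
#' @export
transfer_model <- function(a = -0.5, b = 2, c = 30000, d = 8,
                           noise_sd = 0, bit_depth = 16L) {
  if (b <= 0 || c <= 0) stop("invalid transfer model: need b > 0 and c > 0")
  if (a == d) stop("invalid transfer model: a must differ from d")
  if (noise_sd < 0) stop("invalid transfer model: noise_sd must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth)),
            class = "transfer_model")
}

#' Noise-free gray value for a thickness
#'
#' Inverts the Rodbard thickness(gray) relation:
#' `gray = c * ((a - d)/(t - d) - 1)^(1/b)`. Thickness must lie strictly
#' between the model's asymptotes so the relation is invertible.
#'
#' @param transfer a [transfer_model()].
#' @param thickness mm aluminium equivalent (vectorized).
#' @return gray values (continuous, unquantized).
#' @export
render_gray <- function(transfer, thickness) {
  stopifnot(inherits(transfer, "transfer_model"))
  lo <- min(transfer$a, transfer$d); hi <- max(transfer$a, transfer$d)
  bad <- !is.finite(thickness) | thickness <= lo | thickness >= hi
  if (any(bad))
    stop(sprintf(
      "thickness outside the invertible domain (%g, %g) mmAleq", lo, hi))
  ratio <- (transfer$a - transfer$d) / (thickness - transfer$d) - 1
  transfer$c * ratio^(1 / transfer$b)
}

# Rodbard forward evaluation shared with the calibration module.
rodbard_eval <- function(g, a, b, c, d) d + (a - d) / (1 + (g / c)^b)

#' Keel phantom specification
#'
#' Geometry and composition of the synthetic bird. The keel is a symmetric
#' sine-lens ("crescent") polygon along a horizontal cranial->caudal axis;
#' its pixels carry `keel_thickness` on top of a uniform `tissue_thickness`
#' laid over an elliptical bird silhouette. A contiguous band of the lens is
#' marked as deviated (annotation only; deviation is a shape abnormality and
#' does not change thickness). Named thirds may receive a radiolucent
#' fracture gap where the bone thickness is removed.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_pitch mm per pixel.
#' @param keel_length,keel_depth chord length and maximal depth of the lens, cm.
#' @param ossified_fraction fraction of the chord that is ossified, in (0, 1].
#' @param keel_thickness,tissue_thickness mm aluminium equivalent.
#' @param deviation_fraction area fraction of the keel marked deviated, [0, 1).
#' @param fracture_sections subset of `c("cranial", "middle", "caudal")`.
#' @param gap_width fracture gap width, mm.
#' @param seed integer seed for the noise field.
#' @return an object of class `keel_phantom_spec`.
#' @export
keel_phantom_spec <- function(image_size = c(480L, 560L), pixel_pitch = 0.5,
                              keel_length = 12, keel_depth = 3,
                              ossified_fraction = 1, keel_thickness = 3,
                              tissue_thickness = 1, deviation_fraction = 0,
                              fracture_sections = character(),
                              gap_width = 2, seed = 1L) {
  if (any(image_size < 32)) stop("invalid keel phantom spec: image too small")
  if (pixel_pitch <= 0 || keel_length <= 0 || keel_depth <= 0 ||
      keel_thickness <= 0 || tissue_thickness < 0 || gap_width <= 0)
    stop("invalid keel phantom spec: physical dimensions must be positive")
  if (ossified_fraction <= 0 || ossified_fraction > 1)
    stop("invalid keel phantom spec: ossified_fraction must be in (0, 1]")
  if (deviation_fraction < 0 || deviation_fraction >= 1)
    stop("invalid keel phantom spec: deviation_fraction must be in [0, 1)")
  fracture_sections <- as.character(fracture_sections)
  if (!all(fracture_sections %in% c("cranial", "middle", "caudal")))
    stop("invalid keel phantom spec: fracture_sections must be a subset of ",
         "cranial/middle/caudal")
  structure(list(image_size = as.integer(image_size),
                 pixel_pitch = pixel_pitch, keel_length = keel_length,
                 keel_depth = keel_depth, ossified_fraction = ossified_fraction,
                 keel_thickness = keel_thickness,
                 tissue_thickness = tissue_thickness,
                 deviation_fraction = deviation_fraction,
                 fracture_sections = fracture_sections,
                 gap_width = gap_width, seed = as.integer(seed)),
            class = "keel_phantom_spec")
}

# Lens half-width (pixels) at chord fraction s in [0, 1].
lens_half_width <- function(s, depth_px) (depth_px / 2) * sin(pi * s)

# Lens outline polygon: cranial tip at (x0, y0), caudal tip at (x0 + L, y0).
lens_polygon <- function(x0, y0, length_px, depth_px, n = 100L) {
  s <- seq(0, 1, length.out = n)
  top <- cbind(x0 + s * length_px, y0 - lens_half_width(s, depth_px))
  bot <- cbind(x0 + rev(s) * length_px, y0 + lens_half_width(rev(s), depth_px))
  rbind(top, bot[-1, , drop = FALSE])
}

# Lens band polygon between chord fractions s1 < s2.
lens_band_polygon <- function(x0, y0, length_px, depth_px, s1, s2, n = 60L) {
  s <- seq(s1, s2, length.out = n)
  top <- cbind(x0 + s * length_px, y0 - lens_half_width(s, depth_px))
  bot <- cbind(x0 + rev(s) * length_px, y0 + lens_half_width(rev(s), depth_px))
  rbind(top, bot)
}

# Cumulative area fraction of the sine lens up to chord fraction s.
lens_area_cdf <- function(s) (1 - cos(pi * s)) / 2
lens_area_cdf_inv <- function(p) acos(1 - 2 * p) / pi

#' Generate a synthetic radiograph phantom
#'
#' Renders a 16-bit-style grayscale radiograph containing the step wedge and
#' a keel silhouette, together with the annotation a human observer would
#' supply and the ground truth every downstream measurement should recover.
#' Identical seeds give bit-identical images.
#'
#' @param wedge a [step_wedge_spec()].
#' @param keel a [keel_phantom_spec()].
#' @param transfer a [transfer_model()].
#' @return list with elements `image` (numeric matrix of continuous gray
#'   values; quantization happens only at TIFF export), `annotation` (a
#'   `radiograph_annotation`) and `truth` (a `phantom_truth` with the
#'   per-pixel `thickness_map` in mmAleq plus true morphometry).
#' @export
generate_phantom <- function(wedge = step_wedge_spec(),
                             keel = keel_phantom_spec(),
                             transfer = transfer_model()) {
  stopifnot(inherits(wedge, "step_wedge_spec"),
            inherits(keel, "keel_phantom_spec"),
            inherits(transfer, "transfer_model"))
  nr <- keel$image_size[1]; nc <- keel$image_size[2]
  px <- keel$pixel_pitch
  dim <- c(nr, nc)

  lo <- min(transfer$a, transfer$d); hi <- max(transfer$a, transfer$d)
  if (!(0 > lo))
    stop("inconsistent specs: transfer model must admit zero thickness ",
         "(bare detector); need min(a, d) < 0")
  if (keel$keel_thickness + keel$tissue_thickness >= hi ||
      keel$tissue_thickness >= hi)
    stop("inconsistent specs: keel + tissue thickness must lie strictly ",
         "below the transfer model's upper asymptote")

  # --- wedge: steps stacked top to bottom at the left margin ---------------
  margin <- 4
  w_px <- wedge$width / px
  step_h <- wedge$length / px / wedge$n_steps
  if (margin + wedge$length / px > nr - margin)
    stop("inconsistent specs: wedge does not fit the image height")
  thick <- wedge_thickness_series(wedge)
  thickness_map <- matrix(0, nr, nc)
  wedge_steps <- vector("list", wedge$n_steps)
  for (i in seq_len(wedge$n_steps)) {
    y0 <- margin + (i - 1) * step_h
    poly <- rect_polygon(margin, margin + w_px, y0, y0 + step_h)
    thickness_map[polygon_mask(poly, dim)] <- thick[i]
    wedge_steps[[i]] <- list(thickness_mm = thick[i], polygon = poly)
  }

  # --- bird silhouette and keel --------------------------------------------
  L_px <- keel$keel_length * 10 / px
  D_px <- keel$keel_depth * 10 / px
  pad_px <- 10 / px                     # 10 mm tissue margin around the keel
  x_cranial <- margin + w_px + pad_px + 8
  y_axis <- nr / 2
  if (x_cranial + L_px + pad_px > nc - margin)
    stop("inconsistent specs: keel does not fit the image width")
  if (y_axis - D_px / 2 - pad_px < 0 || y_axis + D_px / 2 + pad_px > nr)
    stop("inconsistent specs: keel does not fit the image height")

  th <- seq(0, 2 * pi, length.out = 121L)[-121L]
  cx <- x_cranial + L_px / 2
  ell <- cbind(cx + (L_px / 2 + pad_px) * cos(th),
               y_axis + (D_px / 2 + pad_px) * sin(th))
  bird <- polygon_mask(ell, dim)
  if (any(bird & thickness_map > 0))
    stop("inconsistent specs: bird silhouette overlaps the step wedge")
  thickness_map[bird] <- thickness_map[bird] + keel$tissue_thickness

  keel_poly <- lens_polygon(x_cranial, y_axis, L_px, D_px)
  kmask <- polygon_mask(keel_poly, dim)
  thickness_map[kmask] <- thickness_map[kmask] + keel$keel_thickness

  # --- fracture gaps: radiolucent bands orthogonal to the axis -------------
  centers <- c(cranial = 1 / 6, middle = 1 / 2, caudal = 5 / 6)
  fracture_masks <- list()
  for (sec in keel$fracture_sections) {
    half_s <- (keel$gap_width / px) / (2 * L_px)
    s0 <- centers[[sec]]
    band <- rect_polygon(x_cranial + (s0 - half_s) * L_px,
                         x_cranial + (s0 + half_s) * L_px,
                         y_axis - D_px, y_axis + D_px)
    m <- polygon_mask(band, dim) & kmask
    thickness_map[m] <- thickness_map[m] - keel$keel_thickness
    fracture_masks[[sec]] <- m
  }

  # --- deviated band -------------------------------------------------------
  deviated <- list()
  true_pod <- 0
  if (keel$deviation_fraction > 0) {
    s1 <- 0.25
    p2 <- lens_area_cdf(s1) + keel$deviation_fraction
    if (p2 >= 1)
      stop("inconsistent specs: deviation_fraction too large for the lens")
    s2 <- lens_area_cdf_inv(p2)
    dev_poly <- lens_band_polygon(x_cranial, y_axis, L_px, D_px, s1, s2)
    deviated <- list(dev_poly)
    true_pod <- 100 * abs(shoelace_area_px(dev_poly)) /
      abs(shoelace_area_px(keel_poly))
  }

  # --- render --------------------------------------------------------------
  gmax <- 2^transfer$bit_depth - 1
  image <- matrix(render_gray(transfer, thickness_map), nr, nc)
  if (transfer$noise_sd > 0) {
    set.seed(keel$seed)
    image <- image + matrix(stats::rnorm(nr * nc, 0, transfer$noise_sd), nr, nc)
  }
  image <- pmin(pmax(image, 0), gmax)

  landmarks <- list(
    cranial_tip = c(x_cranial, y_axis),
    caudal_tip = c(x_cranial + L_px, y_axis),
    caudalmost_ossified = c(x_cranial + keel$ossified_fraction * L_px, y_axis))

  annotation <- radiograph_annotation(
    pixel_scale = px, landmarks = landmarks, keel_outline = keel_poly,
    deviated_regions = deviated, exclusion_masks = list(),
    wedge_steps = wedge_steps,
    fracture_evaluable = TRUE)

  scores <- section_scores(
    fresh = as.integer(c("cranial", "middle", "caudal") %in%
                         keel$fracture_sections),
    callus = c(0L, 0L, 0L))

  truth <- structure(list(
    thickness_map = thickness_map,
    true_total_length = keel$keel_length,
    true_ossified_length = keel$ossified_fraction * keel$keel_length,
    true_pod = true_pod,
    true_section_scores = scores,
    keel_mask = kmask,
    fracture_masks = fracture_masks), class = "phantom_truth")

  list(image = image, annotation = annotation, truth = truth)
}

#' True mean aluminium-equivalent thickness inside a region
#'
#' Averages the phantom's ground-truth thickness map over the pixels of a
#' queried polygon (center-in rule), the oracle against which the calibrated
#' density pipeline is validated.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param roi_polygon polygon in pixel coordinates.
#' @return mean thickness in mmAleq.
#' @export
true_mean_density <- function(truth, roi_polygon) {
  stopifnot(inherits(truth, "phantom_truth"))
  m <- polygon_mask(roi_polygon, dim(truth$thickness_map))
  if (!any(m)) stop("empty ROI on the truth map")
  mean(truth$thickness_map[m])
}
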