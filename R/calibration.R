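# Per-image densitometry calibration: regress the known aluminium step
# thicknesses on the measured step gray values with a four-parameter Rodbard
# curve, then convert any gray value to millimetres aluminium equivalent
# (mmAleq).

#' Extract wedge calibration pairs from an image
#'
#' One (thickness, mean gray) pair per wedge step: the arithmetic mean of
#' the pixel gray values inside each step ROI polygon (center-in rule),
#' sorted by thickness.
#'
#' @param image numeric gray matrix.
#' @param annotation a [radiograph_annotation()] carrying `wedge_steps`.
#' @return data.frame with columns `thickness`, `mean_gray`, `n_pixels`.
#' @export
extract_step_grays <- function(image, annotation) {
  stopifnot(inherits(annotation, "radiograph_annotation"))
  steps <- annotation$wedge_steps
  if (length(steps) < 2)
    stop("extraction error: need at least 2 wedge step ROIs")
  out <- lapply(seq_along(steps), function(i) {
    s <- steps[[i]]
    poly <- as_polygon(s$polygon)
    if (any(poly[, 1] < -0.5 | poly[, 1] > ncol(image) - 0.5 |
            poly[, 2] < -0.5 | poly[, 2] > nrow(image) - 0.5))
      stop(sprintf("extraction error: step %d ROI outside the image", i))
    m <- polygon_mask(poly, dim(image))
    if (!any(m))
      stop(sprintf("extraction error: step %d ROI contains no pixels", i))
    data.frame(thickness = s$thickness_mm, mean_gray = mean(image[m]),
               n_pixels = sum(m))
  })
  out <- do.call(rbind, out)
  out[order(out$thickness), , drop = FALSE]
}

#' Fit the Rodbard calibration curve
#'
#' Least-squares fit of `thickness(g) = d + (a - d) / (1 + (g/c)^b)` to the
#' wedge pairs by Levenberg-Marquardt. Initialization: `a` at the thickness
#' observed at the smallest gray minus 10% of the thickness range, `d` at
#' the thickness at the largest gray plus 10%, `c` at the median gray,
#' `b = 1`; convergence tolerance 1e-10 on the sum of squares, at most
#' 10000 evaluations. The accepted fit must be strictly monotone over the
#' observed gray domain.
#'
#' @param pairs data.frame from [extract_step_grays()] (columns `thickness`,
#'   `mean_gray`); at least 5 pairs.
#' @return an object of class `rodbard_curve`: parameters `a`, `b`, `c`,
#'   `d`, `rmse` (mm), `gray_domain`, `n_pairs`.
#' @export
fit_rodbard <- function(pairs) {
  if (nrow(pairs) < 5)
    stop("insufficient data: need at least 5 calibration pairs")
  g <- pairs$mean_gray; t <- pairs$thickness
  if (any(diff(sort(t)) <= 0))
    stop("calibration failure: step thicknesses must be strictly increasing")
  if (diff(range(g)) == 0)
    stop("calibration failure: all step gray values identical")
  rng <- diff(range(t))
  start <- list(a = t[which.min(g)] - 0.1 * rng, b = 1,
                c = stats::median(g), d = t[which.max(g)] + 0.1 * rng)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      thickness ~ d + (a - d) / (1 + (mean_gray / c)^b),
      data = data.frame(thickness = t, mean_gray = g), start = start,
      lower = c(a = -Inf, b = 1e-6, c = 1e-6, d = -Inf),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxfev = 10000, maxiter = 1024)),
    error = function(e) stop("fit error: Rodbard fit did not converge (",
                             conditionMessage(e), ")"))
  p <- as.list(stats::coef(fit))
  domain <- range(g)
  grid <- seq(domain[1], domain[2], length.out = 256)
  dt <- diff(rodbard_eval(grid, p$a, p$b, p$c, p$d))
  if (!(all(dt > 0) || all(dt < 0)))
    stop("calibration failure: fitted curve is not monotone over the ",
         "observed gray domain")
  resid <- t - rodbard_eval(g, p$a, p$b, p$c, p$d)
  structure(list(a = p$a, b = p$b, c = p$c, d = p$d,
                 rmse = sqrt(mean(resid^2)), gray_domain = domain,
                 n_pairs = nrow(pairs)),
            class = "rodbard_curve")
}

#' @export
print.rodbard_curve <- function(x, ...) {
  cat(sprintf(
    "Rodbard calibration: t(g) = d + (a-d)/(1+(g/c)^b)\n  a = %.6g, b = %.6g, c = %.6g, d = %.6g\n  rmse = %.3g mm over %d pairs, gray domain [%.6g, %.6g]\n",
    x$a, x$b, x$c, x$d, x$rmse, x$n_pairs, x$gray_domain[1], x$gray_domain[2]))
  invisible(x)
}

#' Convert gray values to mmAleq
#'
#' Evaluates the calibration curve. Gray values outside the observed wedge
#' domain are evaluated (keels can be denser than the thickest step) but
#' flagged: a warning is raised and the result carries a logical
#' `extrapolated` attribute.
#'
#' @param curve a [fit_rodbard()] result.
#' @param gray gray values (> 0, vectorized).
#' @return thicknesses in mm aluminium equivalent.
#' @export
gray_to_mmAleq <- function(curve, gray) {
  stopifnot(inherits(curve, "rodbard_curve"))
  if (any(!is.finite(gray) | gray <= 0))
    stop("domain error: gray values must be positive")
  out <- rodbard_eval(gray, curve$a, curve$b, curve$c, curve$d)
  extra <- gray < curve$gray_domain[1] | gray > curve$gray_domain[2]
  if (any(extra))
    warning(sprintf(
      "%d gray value(s) outside the calibrated domain [%g, %g]; extrapolated",
      sum(extra), curve$gray_domain[1], curve$gray_domain[2]))
  attr(out, "extrapolated") <- extra
  out
}

#' Mean radiographic density of a region
#'
#' Converts every pixel inside the ROI (minus exclusion masks) to mmAleq and
#' averages. With a nonlinear calibration this differs from converting the
#' ROI's mean gray; `method = "mean_gray"` exposes that alternative.
#'
#' @param image numeric gray matrix.
#' @param curve a [fit_rodbard()] result.
#' @param roi_polygon polygon in pixel coordinates.
#' @param exclusion_masks list of polygons removed from the ROI.
#' @param method `"per_pixel"` (default) or `"mean_gray"`.
#' @return mean density in mmAleq.
#' @export
mean_mmAleq <- function(image, curve, roi_polygon, exclusion_masks = list(),
                        method = c("per_pixel", "mean_gray")) {
  method <- match.arg(method)
  m <- polygon_mask(roi_polygon, dim(image))
  if (length(exclusion_masks))
    m <- m & !polygons_mask(exclusion_masks, dim(image))
  if (!any(m))
    stop("empty ROI: no pixels remain after exclusions")
  if (method == "per_pixel") {
    mean(suppressWarnings(gray_to_mmAleq(curve, image[m])))
  } else {
    as.numeric(suppressWarnings(gray_to_mmAleq(curve, mean(image[m]))))
  }
}
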