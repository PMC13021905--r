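make_ann <- function(cranial, caudal, ossified = caudal, scale = 0.1,
                     keel = NULL, deviated = list(), offset = NULL) {
  if (is.null(keel))
    keel <- rbind(cranial, c(caudal[1], cranial[2] - 10), caudal,
                  c(cranial[1], cranial[2] + 10))
  radiograph_annotation(pixel_scale = scale,
                        landmarks = list(cranial_tip = cranial,
                                         caudal_tip = caudal,
                                         caudalmost_ossified = ossified),
                        keel_outline = keel, deviated_regions = deviated,
                        manual_square_offset = offset)
}

test_that("keel lengths are scaled landmark distances", {
  a <- make_ann(c(0, 0), c(1200, 0), scale = 0.1)
  expect_equal(unname(keel_lengths(a)), c(12, 12))
  # 3-4-5 triangle
  a <- make_ann(c(0, 0), c(300, 400), scale = 0.1)
  expect_equal(unname(keel_lengths(a))[1], 5)
  # coincident caudalmost-ossified and caudal tip
  a <- make_ann(c(0, 0), c(800, 0), ossified = c(800, 0), scale = 0.1)
  l <- keel_lengths(a)
  expect_equal(l[["ossified_length"]], l[["total_length"]])
  # missing landmark
  a$landmarks$caudal_tip <- NULL
  expect_error(keel_lengths(a), "landmark")
})

test_that("ossification degree applies the strict >95% rule", {
  expect_equal(ossification_degree(10, 10),
               list(degree = 1, fully_ossified = TRUE))
  # exactly 95% is NOT complete
  r <- ossification_degree(10, 9.5)
  expect_equal(r$degree, 0.95)
  expect_false(r$fully_ossified)
  expect_true(ossification_degree(10, 9.5 + 1e-9)$fully_ossified)
  expect_equal(ossification_degree(9.5, 4.75)$degree, 0.5)
  expect_error(ossification_degree(0, 0), "domain")
})

test_that("polygon areas match the shoelace formula and a raster oracle", {
  sq <- keelmetrics:::rect_polygon(0, 1, 0, 1)
  expect_equal(polygon_area(sq, 10), 1)           # unit px square at 10 mm/px
  expect_equal(polygon_area(sq[4:1, ], 10), 1)    # orientation invariant
  expect_error(polygon_area(sq[1:2, ], 10), "degenerate")
  # random simple 20-gon (star-shaped construction) vs fine-grid pixel count
  set.seed(5)
  th <- sort(runif(20, 0, 2 * pi))
  r <- runif(20, 40, 90)
  poly <- cbind(100 + r * cos(th), 100 + r * sin(th))
  area_px <- abs(keelmetrics:::shoelace_area_px(poly))
  mask <- keelmetrics:::polygon_mask(poly, c(200, 200))
  expect_lt(abs(sum(mask) - area_px) / area_px, 0.005)
})

test_that("pod is a clipped, union-based, invariant percentage", {
  keel <- keelmetrics:::rect_polygon(0, 200, 0, 100)
  expect_equal(pod(list(), keel, 1), 0)
  expect_equal(pod(list(keel), keel, 1), 100, tolerance = 1e-6)
  # two half-overlapping squares: union oracle by direct pixel count
  s1 <- keelmetrics:::rect_polygon(10, 50, 10, 50)
  s2 <- keelmetrics:::rect_polygon(30, 70, 10, 50)
  p <- pod(list(s1, s2), keel, 1)
  dim <- c(101, 201)
  union <- keelmetrics:::polygons_mask(list(s1, s2), dim)
  kmask <- keelmetrics:::polygon_mask(keel, dim)
  oracle <- 100 * sum(union & kmask) / sum(kmask)
  expect_lt(abs(p - oracle), 0.2)
  # exact union area is 40*40 + 40*40 - 20*40 = 2400 of 20000
  expect_lt(abs(p - 12), 0.2)
  # vertex-order reversal and translation invariance
  expect_equal(pod(list(s1[4:1, ], s2), keel, 1), p, tolerance = 1e-9)
  shift <- function(m) sweep(m, 2, c(-37, 13))
  expect_equal(pod(list(shift(s1), shift(s2)), shift(keel), 1), p,
               tolerance = 1e-9)
  # regions poking outside the keel are clipped so pod <= 100
  out <- keelmetrics:::rect_polygon(150, 400, -50, 300)
  expect_lte(pod(list(out, keel), keel, 1), 100)
  expect_error(pod(list(s1), keel[1:2, ], 1), "degenerate")
})

test_that("density square placement follows the midpoint / 1-in-12 rule", {
  a <- make_ann(c(0, 0), c(1200, 0), scale = 0.1)
  sq <- place_density_square(a, ossified_length = 12, fully_ossified = TRUE)
  expect_equal(sq$center, c(600, 0))
  expect_equal(sq$side, 1)
  # manual offset shifts the center only
  a2 <- make_ann(c(0, 0), c(1200, 0), scale = 0.1, offset = c(50, -20))
  sq2 <- place_density_square(a2, 12, TRUE)
  expect_equal(sq2$center, c(650, -20))
  expect_equal(sq2$side, 1)
  # side scales with the ossified length
  expect_equal(place_density_square(a, 9, TRUE)$side, 0.75)
  # incompletely ossified keels use the caudalmost ossified point
  a3 <- make_ann(c(0, 0), c(1200, 0), ossified = c(900, 0), scale = 0.1)
  sq3 <- place_density_square(a3, 9, fully_ossified = FALSE)
  expect_equal(sq3$center, c(450, 0))
  a3$landmarks$caudalmost_ossified <- c(0, 0)
  expect_error(place_density_square(a3, 9, FALSE), "degenerate")
})

test_that("measure assembles a truth-consistent record on phantoms", {
  ph <- make_phantom(keel_thickness = 3, tissue_thickness = 0,
                     deviation_fraction = 0, ossified_fraction = 0.8)
  curve <- fit_rodbard(extract_step_grays(ph$image, ph$annotation))
  m <- measure(ph$image, ph$annotation, curve, image_id = "ph1")
  expect_equal(m$pod, 0)
  expect_equal(m$density_whole, 3, tolerance = 1e-6)
  expect_equal(m$density_square, 3, tolerance = 1e-6)
  expect_equal(m$total_length, ph$truth$true_total_length, tolerance = 1e-9)
  expect_equal(m$ossified_length, ph$truth$true_ossified_length,
               tolerance = 1e-9)
  expect_equal(m$ossification_degree, 0.8, tolerance = 1e-9)
  expect_false(m$fully_ossified)
  expect_equal(m$square_side, ph$truth$true_ossified_length / 12)
  # lateral area against the rasterized truth mask (0.5% tolerance)
  area_mask <- sum(ph$truth$keel_mask) * ph$annotation$pixel_scale^2 / 100
  expect_lt(abs(m$lateral_area - area_mask) / area_mask, 0.005)
})

test_that("square and whole-keel densities agree on smooth phantom batches", {
  set.seed(9)
  dens <- t(vapply(1:8, function(i) {
    ph <- make_phantom(keel_thickness = 2 + 0.3 * i, tissue_thickness = 1,
                       seed = 100 + i, noise_sd = 30)
    curve <- fit_rodbard(extract_step_grays(ph$image, ph$annotation))
    m <- measure(ph$image, ph$annotation, curve)
    c(m$density_whole, m$density_square)
  }, c(0, 0)))
  expect_gt(cor(dens[, 1], dens[, 2]), 0.99)
})

test_that("ossified length beyond the total raises a warning, not clamping", {
  a <- make_ann(c(0, 0), c(1000, 0), ossified = c(1100, 0), scale = 0.1)
  expect_warning(l <- keel_lengths(a), "exceeds")
  expect_equal(l[["ossified_length"]], 11)  # value preserved
})
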