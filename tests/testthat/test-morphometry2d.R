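test_that("shape identities hold for a rasterized disk and a square", {
  m <- measure_objects_2d(raster_disk(20, 0.2))
  r <- m$records
  expect_gt(r$circularity, 0.95); expect_lt(r$circularity, 1.05)
  expect_gte(r$smoothness, 0.98); expect_lte(r$smoothness, 1)
  expect_lt(abs(r$length - 40) / 40, 0.02)
  expect_lt(abs(r$area - pi * 400) / (pi * 400), 0.01)
  sq <- measure_objects_2d(raster_square(40, 0.2))$records
  expect_lt(abs(sq$circularity - pi / 4) / (pi / 4), 0.02)
  expect_gte(sq$smoothness, 0.999)   # convex: hull = outer boundary
})

test_that("moment-ellipse axes recover ellipse dimensions within 3%", {
  or <- raster_ellipse_oracle(10, 4, 0.4, 0.1)
  r <- measure_objects_2d(or$labels)$records
  expect_lt(abs(r$length - or$length) / or$length, 0.03)
  expect_lt(abs(r$width - or$width) / or$width, 0.03)
  expect_lt(abs(r$area - or$area) / or$area, 0.03)
  expect_lt(abs(r$outer_perimeter - or$perimeter) / or$perimeter, 0.03)
})

test_that("random ellipses agree with the analytic oracle within 3%", {
  set.seed(17)
  for (k in 1:10) {
    a <- runif(1, 6, 14); b <- runif(1, 0.4, 1) * a
    th <- runif(1, 0, pi)
    or <- raster_ellipse_oracle(a, b, th, 0.15)
    r <- measure_objects_2d(or$labels)$records
    expect_lt(abs(r$area - or$area) / or$area, 0.03)
    expect_lt(abs(r$outer_perimeter - or$perimeter) / or$perimeter, 0.03)
    expect_lt(abs(r$length - or$length) / or$length, 0.03)
    expect_lt(abs(r$width - or$width) / or$width, 0.03)
  }
})

test_that("descriptors are invariant to translation and 90-degree rotation", {
  or <- raster_ellipse_oracle(8, 4, 0.3, 0.2)
  x <- unclass(or$labels)
  base <- measure_objects_2d(or$labels)$records
  shifted <- matrix(0L, nrow(x) + 20, ncol(x) + 20)
  shifted[13:(12 + nrow(x)), 8:(7 + ncol(x))] <- x
  rs <- measure_objects_2d(label_map(shifted, 0.2))$records
  rot <- measure_objects_2d(label_map(t(x)[rev(seq_len(ncol(x))), ], 0.2))$records
  for (col in c("area", "length", "width", "outer_perimeter", "circularity")) {
    expect_lt(abs(rs[[col]] - base[[col]]) / base[[col]], 0.01)
    expect_lt(abs(rot[[col]] - base[[col]]) / base[[col]], 0.01)
  }
})

test_that("physical measurements are stable under pixel-size doubling", {
  fine <- measure_objects_2d(raster_disk(15, 0.2))$records
  coarse <- measure_objects_2d(raster_disk(15, 0.4))$records
  for (col in c("area", "length", "outer_perimeter"))
    expect_lt(abs(coarse[[col]] - fine[[col]]) / fine[[col]], 0.03)
})

test_that("ROI extraction clips border objects from per-object statistics", {
  px <- 0.5
  m <- matrix(0L, 400, 400)
  cent <- list(c(60, 60), c(100, 140), c(150, 80), c(199, 160))
  xs <- seq_len(400)
  for (k in seq_along(cent))
    m[outer(xs, xs, function(x, y)
      (x - cent[[k]][1])^2 + (y - cent[[k]][2])^2 <= 12^2)] <- k
  lab <- label_map(m, px)
  # 100 x 100 um ROI: object 4 straddles the right ROI edge at x = 100 um
  roi <- roi_spec(c(0, 0), c(100, 100))
  cut <- extract_roi(lab, roi)
  rec <- measure_objects_2d(cut, exclude_border = TRUE)$records
  expect_equal(nrow(rec), 3L)
  # whole-image ROI reproduces the full measurement
  whole <- extract_roi(lab, roi_spec(c(0, 0), c(200, 200)))
  expect_equal(measure_objects_2d(whole)$summary$number,
               measure_objects_2d(lab)$summary$number)
  expect_error(extract_roi(lab, roi_spec(c(150, 150), c(100, 100))), "bounds")
  # reference ROI arithmetic: 0.1 x 0.2 mm at 0.29 um/px
  big <- label_map(matrix(0L, 800, 800), 0.29)
  g <- extract_roi(big, roi_spec(c(2.9, 2.9), c(100, 200)))
  expect_equal(dim(g), c(345, 690))
})

test_that("porosity summary recovers the truth pore fraction", {
  sp <- small_spec(seed = 21, pore_params = list(radius = 14,
                                                 area_fraction = 0.05))
  res <- generate_section_2d(sp)
  ps <- porosity_summary(res$truth$masks$pores, res$truth$masks$bone)
  truth_frac <- res$truth$pore_area_um2 / res$truth$bone_area_um2
  expect_lt(abs(ps$porosity_ratio - truth_frac), 0.005)
  expect_equal(ps$number, nrow(res$truth$pores))
  # no pores -> zero ratio, zero number
  none <- porosity_summary(label_map(matrix(0L, 50, 50), 1),
                           matrix(TRUE, 50, 50))
  expect_equal(none$porosity_ratio, 0)
  expect_equal(none$number, 0L)
  expect_error(porosity_summary(res$truth$masks$pores,
                                matrix(FALSE, 400, 400)), "bone")
})

test_that("rough-margin pores score lower smoothness than smooth ones", {
  smooth <- generate_section_2d(small_spec(
    seed = 33, pore_params = list(radius = 14, roughness = 0.01,
                                  area_fraction = 0.05)))
  rough <- generate_section_2d(small_spec(
    seed = 33, pore_params = list(radius = 14, roughness = 0.22,
                                  area_fraction = 0.05)))
  ms <- measure_objects_2d(smooth$truth$masks$pores)$summary
  mr <- measure_objects_2d(rough$truth$masks$pores)$summary
  expect_gt(ms$mean_smoothness, mr$mean_smoothness)
  expect_gt(ms$mean_circularity, mr$mean_circularity)
})

test_that("an empty label map yields empty records and zero summary", {
  m <- measure_objects_2d(label_map(matrix(0L, 30, 30), 0.5))
  expect_equal(nrow(m$records), 0L)
  expect_equal(m$summary$number, 0L)
  expect_equal(m$summary$total_area, 0)
})
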