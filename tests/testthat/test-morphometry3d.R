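test_that("local-thickness separation splits a sphere from its tube", {
  vox <- 0.1
  m <- sphere_with_tubes(center = c(6, 6, 6), radius_um = 4,
                         dirs = matrix(c(1, 0, 0), 1),
                         lengths_um = 12, diameters_um = 0.5,
                         dims = c(240, 120, 120), vox_um = vox)
  sep <- separate_lacunae_canaliculi(m)
  expect_equal(n_objects(sep$lacunae), 1L)
  can_comps <- n_objects(label_components(sep$canaliculi, rep(vox, 3)))
  expect_equal(can_comps, 1L)
  # voxel bookkeeping: the three outputs partition the input foreground
  lac <- unclass(sep$lacunae) > 0
  expect_false(any(lac & sep$canaliculi))
  expect_false(any(lac & sep$discarded))
  expect_identical(lac | sep$canaliculi | sep$discarded,
                   unclass(m), ignore_attr = TRUE)
})

test_that("a bare sphere yields one lacuna and no canaliculi", {
  m <- raster_sphere(4, 0.1)
  sep <- separate_lacunae_canaliculi(m)
  expect_equal(n_objects(sep$lacunae), 1L)
  expect_equal(sum(sep$canaliculi), 0L)
  # idempotence: re-separating the lacuna output changes nothing
  lac_mask <- structure(unclass(sep$lacunae) > 0, pixel_size = rep(0.1, 3))
  sep2 <- separate_lacunae_canaliculi(lac_mask)
  expect_identical(unclass(sep2$lacunae) > 0, unclass(lac_mask),
                   ignore_attr = TRUE)
})

test_that("a 0.2 um tube (below the end point) is discarded from canaliculi", {
  vox <- 0.1
  # axis placed between voxel centers: the clean sub-resolution digitization
  m <- sphere_with_tubes(center = c(5, 5.05, 5.05), radius_um = 4,
                         dirs = matrix(c(1, 0, 0), 1),
                         lengths_um = 10, diameters_um = 0.2,
                         dims = c(200, 100, 100), vox_um = vox)
  sep <- separate_lacunae_canaliculi(m, d_start = 0.6, d_end = 0.3)
  expect_equal(sum(sep$canaliculi), 0L)
  expect_gt(sum(sep$discarded), 0L)
})

test_that("sphericity identities: sphere near 1, cube near (pi/6)^(1/3)", {
  sph <- measure_lacunae_3d(label_components(raster_sphere(4, 0.1)))
  expect_gte(sph$records$sphericity, 0.97)
  expect_lte(sph$records$sphericity, 1.02)
  cube <- measure_lacunae_3d(label_components(raster_cube(12, 0.1)))
  expect_lt(abs(cube$records$sphericity - (pi / 6)^(1 / 3)) / (pi / 6)^(1 / 3),
            0.02)
})

test_that("orientation is measured against the reference axis", {
  m <- raster_ellipsoid(c(6, 2.5, 2.5), 0.1)
  rec <- measure_lacunae_3d(label_components(m),
                            reference_axis = c(1, 0, 0))$records
  expect_lt(rec$orientation, 3)
  rec90 <- measure_lacunae_3d(label_components(m),
                              reference_axis = c(0, 0, 1))$records
  expect_gt(rec90$orientation, 87)
})

test_that("orientation SD matches a Monte-Carlo uniform-axis oracle", {
  expect_equal(orientation_sd(rep(12, 5)), 0)
  set.seed(41)
  # implementation input: acute angles of random axes against z
  v <- matrix(rnorm(3 * 4000), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  ang <- acos(abs(v[, 3])) * 180 / pi
  got <- orientation_sd(ang)
  # independent oracle: for uniform axes cos(theta) ~ U(0,1)
  oracle <- sd(acos(runif(1e5)) * 180 / pi)
  expect_lt(abs(got - oracle) / oracle, 0.05)
  # equivariance under a global rotation of axes and reference together
  rot <- function(v, a) cbind(v[, 1], cos(a) * v[, 2] - sin(a) * v[, 3],
                              sin(a) * v[, 2] + cos(a) * v[, 3])
  vr <- rot(v, 0.7); ref <- rot(matrix(c(0, 0, 1), 1), 0.7)
  angr <- acos(pmin(1, abs(vr %*% t(ref)))) * 180 / pi
  expect_lt(abs(orientation_sd(as.numeric(angr)) - got), 1e-6)
  expect_error(orientation_sd(5), "at least 2")
})

test_that("skeleton tracing recovers cylinder length and diameter", {
  vox <- 0.1
  m <- sphere_with_tubes(center = c(6, 8, 8), radius_um = 4,
                         dirs = matrix(c(1, 0, 0), 1),
                         lengths_um = 20, diameters_um = 0.5,
                         dims = c(320, 160, 160), vox_um = vox)
  sep <- separate_lacunae_canaliculi(m)
  sk <- skeletonize_and_measure_canaliculi(sep$canaliculi, sep$lacunae)
  expect_equal(nrow(sk$records), 1L)
  expect_lt(abs(sk$records$length - 20) / 20, 0.05)
  expect_lt(abs(sk$records$mean_diameter - 0.5), 0.15)
  expect_equal(sk$records$lacuna, 1L)
  # empty mask -> empty outputs
  e <- skeletonize_and_measure_canaliculi(
    structure(array(FALSE, c(10, 10, 10)), pixel_size = rep(vox, 3)), NULL)
  expect_equal(e$summary$number, 0L)
})

test_that("a branched tube yields one record per branch-free path", {
  vox <- 0.1
  base <- c(6, 10, 8)
  m <- sphere_with_tubes(center = base, radius_um = 4,
                         dirs = matrix(c(1, 0, 0), 1),
                         lengths_um = 10, diameters_um = 0.6,
                         dims = c(280, 200, 160), vox_um = vox)
  # add two arms forking from the tube's far end (a Y junction)
  fork <- base + c(14, 0, 0)
  m <- m | raster_tube(fork, fork + c(8, 6, 0) / sqrt(2), 0.6,
                       dim(m), vox)
  m <- m | raster_tube(fork, fork + c(8, -6, 0) / sqrt(2), 0.6,
                       dim(m), vox)
  m <- structure(m, pixel_size = rep(vox, 3))
  sep <- separate_lacunae_canaliculi(m)
  sk <- skeletonize_and_measure_canaliculi(sep$canaliculi, sep$lacunae)
  expect_equal(nrow(sk$records), 2L)
  # volume conservation across records
  expect_lt(abs(sum(sk$records$volume) - sum(sep$canaliculi) * vox^3) /
              (sum(sep$canaliculi) * vox^3), 0.01)
})

test_that("physical measurements are stable across voxel resolutions", {
  fine <- measure_lacunae_3d(label_components(raster_sphere(3, 0.05)))$records
  coarse <- measure_lacunae_3d(label_components(raster_sphere(3, 0.1)))$records
  expect_lt(abs(fine$volume - coarse$volume) / coarse$volume, 0.05)
  expect_lt(abs(fine$surface - coarse$surface) / coarse$surface, 0.05)
})

test_that("coarse anisotropic voxels trigger the degraded-mode warning", {
  m <- raster_sphere(4, 0.1)
  aniso <- structure(unclass(m), pixel_size = c(0.1, 0.1, 1.0))
  expect_warning(separate_lacunae_canaliculi(aniso), "under-resolved")
})

test_that("layer-resolved summaries aggregate per layer and flag empties", {
  rec <- data.frame(volume = c(100, 110, 150, 160),
                    layer = c("inner", "inner", "haversian", "haversian"),
                    specimen = "s1", group = "control")
  s <- layer_resolved_summary_3d(rec)
  expect_setequal(s$layer, c("inner", "haversian"))
  expect_equal(s$volume[s$layer == "inner"], 105)
  expect_equal(s$n[s$layer == "inner"], 2L)
  expect_error(layer_resolved_summary_3d(data.frame(volume = 1)), "layer")
})
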