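test_that("zero object densities give a bare noisy annulus with empty truth", {
  sp <- small_spec(seed = 3,
                   lacuna_params = list(density = 0),
                   canal_params = list(density = 0),
                   pore_params = list(density = 0),
                   calcein_params = list(p_class = c(Q = 1, E = 0, sL = 0,
                                                     dL = 0, mL = 0)))
  res <- generate_section_2d(sp)
  expect_null(res$truth$lacunae)
  expect_null(res$truth$canals)
  expect_null(res$truth$pores)
  expect_equal(n_objects(res$truth$masks$lacunae), 0L)
  expect_gt(sum(res$truth$masks$bone), 0)       # the annulus is there
  expect_gt(sd(as.numeric(res$image)), 0)       # and it is noisy
})

test_that("identical spec and seed give bit-identical images and truth", {
  sp <- small_spec(seed = 11)
  a <- generate_section_2d(sp)
  b <- generate_section_2d(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth$lacunae, b$truth$lacunae)
  expect_identical(unclass(a$truth$masks$pores), unclass(b$truth$masks$pores))
  sp3 <- phantom_spec_3d(image_shape = c(60, 60, 30), seed = 5,
                         lacuna_params = list(density = 3e5))
  s1 <- generate_stack_3d(sp3)
  s2 <- generate_stack_3d(sp3)
  expect_identical(unclass(s1$image), unclass(s2$image))
})

test_that("requested pore area fraction is hit within half a percentage point", {
  sp <- small_spec(seed = 21, pore_params = list(radius = 14,
                                                 area_fraction = 0.05))
  res <- generate_section_2d(sp)
  frac <- res$truth$pore_area_um2 / res$truth$bone_area_um2
  expect_lt(abs(frac - 0.05), 0.005)
})

test_that("truth masks conserve area: bone + marrow + background = image", {
  res <- generate_section_2d(small_spec(seed = 4))
  n_bone <- sum(res$truth$masks$bone)
  n_marrow <- sum(res$truth$masks$marrow)
  expect_false(any(res$truth$masks$bone & res$truth$masks$marrow))
  expect_equal(n_bone + n_marrow +
                 sum(!res$truth$masks$bone & !res$truth$masks$marrow),
               prod(dim(res$image)))
})

test_that("a rasterized 4 um sphere matches its closed-form volume within 2%", {
  sp <- phantom_spec_3d(
    image_shape = c(110, 110, 110), pixel_size = 0.1,
    lacuna_params = list(explicit = data.frame(cx = 5.5, cy = 5.5, cz = 5.5,
                                               a = 4, b = 4, c = 4)),
    canaliculi_params = list(per_lacuna = 0), seed = 2)
  st <- generate_stack_3d(sp)
  expect_equal(nrow(st$truth$lacunae), 1L)
  vox_vol <- sum(unclass(st$truth$masks$lacunae) > 0) * 0.1^3
  expect_lt(abs(vox_vol / (4 / 3 * pi * 4^3) - 1), 0.02)
})

test_that("explicit canaliculus truth reports its generative length and diameter", {
  sp <- phantom_spec_3d(
    image_shape = c(300, 100, 100), pixel_size = 0.1,
    lacuna_params = list(explicit = data.frame(cx = 6, cy = 5, cz = 5,
                                               a = 4, b = 4, c = 4)),
    canaliculi_params = list(explicit = data.frame(
      lacuna = 1, dx = 1, dy = 0, dz = 0, length = 20, diameter = 0.5)),
    seed = 8)
  st <- generate_stack_3d(sp)
  expect_equal(st$truth$canaliculi$length, 20)
  expect_equal(st$truth$canaliculi$diameter, 0.5)
  expect_equal(nrow(st$truth$lacunae), 1L)
})

test_that("impossible geometry (objects larger than their layer) is rejected", {
  sp <- small_spec(seed = 1,
                   lacuna_params = list(semiaxes_mean = c(30, 12)))
  expect_error(generate_section_2d(sp), "impossible geometry")
  expect_error(phantom_spec(layer_fractions = c(inner = 0.6, outer = 0.5)),
               "layer_fractions")
  expect_error(effect_profile(lacuna_volume = -1), "multipliers")
})

test_that("cohort generation is reproducible and carries group labels", {
  groups <- list(control = effect_profile(), tx = effect_profile())
  base <- phantom_spec_3d(image_shape = c(400, 400, 200), seed = 1)
  a <- generate_cohort(base, groups, n_per_group = 3, seed = 10, render = "none")
  b <- generate_cohort(base, groups, n_per_group = 3, seed = 10, render = "none")
  expect_identical(a$lacunae, b$lacunae)
  expect_equal(length(a$specimens), 6L)
  expect_setequal(unique(a$lacunae$group), c("control", "tx"))
})

test_that("an inner-layer 1.5x volume effect is recovered from cohort truth", {
  base <- phantom_spec_3d(image_shape = c(1500, 1500, 600))  # 150x150x60 um
  groups <- list(control = effect_profile(),
                 tx = effect_profile(lacuna_volume = c(inner = 1.5)))
  co <- generate_cohort(base, groups, n_per_group = 10, seed = 42,
                        render = "none")
  inner <- co$lacunae[co$lacunae$layer == "inner", ]
  ratio <- mean(inner$volume[inner$group == "tx"]) /
    mean(inner$volume[inner$group == "control"])
  expect_gt(ratio, 1.35)
  expect_lt(ratio, 1.65)
  # monotonicity: the multiplier strictly raises the group mean
  expect_gt(mean(inner$volume[inner$group == "tx"]),
            mean(inner$volume[inner$group == "control"]))
})

test_that("an all-ones effect is statistically indistinguishable from control", {
  base <- phantom_spec_3d(image_shape = c(800, 800, 300))
  groups <- list(control = effect_profile(), sham = effect_profile())
  rejections <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(base, groups, n_per_group = 4, seed = 9000 + r,
                          render = "none")
    pv <- t.test(volume ~ group, data = co$lacunae)$p.value
    rejections <- rejections + (pv < 0.01)
  }
  # nominal 1% test: allow up to 5/60 before calling it biased
  expect_lte(rejections, 5L)
})
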