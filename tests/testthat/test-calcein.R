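test_that("surface contours of an ideal annulus have the analytic lengths", {
  px <- 0.5
  bone <- annulus_mask(150, 100, px)
  ct <- extract_surface_contours(bone, pixel_size = px)
  expect_lt(abs(attr(ct$endosteal, "total_length") - 2 * pi * 100) /
              (2 * pi * 100), 0.01)
  expect_lt(abs(attr(ct$periosteal, "total_length") - 2 * pi * 150) /
              (2 * pi * 150), 0.01)
  # counterclockwise and deterministic
  expect_gt(osteomorph:::poly_signed_area(ct$endosteal / px), 0)
  expect_gt(osteomorph:::poly_signed_area(ct$periosteal / px), 0)
  ct2 <- extract_surface_contours(bone, pixel_size = px)
  expect_identical(unclass(ct$endosteal), unclass(ct2$endosteal))
})

test_that("an intracortical void belongs to neither surface contour", {
  px <- 0.5
  bone <- annulus_mask(150, 100, px)
  n <- dim(bone)[1]; cc <- n / 2 * px
  xs <- (seq_len(n) - 0.5) * px
  void <- outer(xs, xs, function(x, y) (x - cc - 125)^2 + (y - cc)^2 <= 10^2)
  bone2 <- structure(bone & !void, pixel_size = c(px, px))
  ct <- extract_surface_contours(bone2, pixel_size = px)
  for (s in ct) {
    d <- sqrt((s[, 1] - cc - 125)^2 + (s[, 2] - cc)^2)
    expect_gt(min(d), 10)   # contours never trace the void boundary
  }
})

test_that("band counting classifies single, double and absent labels", {
  px <- 0.5
  bone <- annulus_mask(150, 100, px)
  n <- dim(bone)[1]; cc <- n / 2 * px
  xs <- (seq_len(n) - 0.5) * px
  R <- sqrt(outer(xs, xs, function(x, y) (x - cc)^2 + (y - cc)^2))
  # two full circumferential bands 5 um apart (edge to edge), 2 um wide
  cal2 <- (R > 102 & R < 104) | (R > 109 & R < 111)
  ct <- extract_surface_contours(bone, pixel_size = px)
  pr <- classify_perimeter(ct$endosteal, label_map(cal2 + 0L, px),
                           probe_depth = 10, step = 2)
  expect_gt(mean(pr$class == "dL"), 0.95)
  # one band only -> sL
  cal1 <- (R > 102 & R < 104)
  pr1 <- classify_perimeter(ct$endosteal, label_map(cal1 + 0L, px))
  expect_gt(mean(pr1$class == "sL"), 0.95)
  # no label on a smooth circle -> quiescent
  pr0 <- classify_perimeter(ct$endosteal, label_map(matrix(0L, n, n), px))
  expect_gt(mean(pr0$class == "Q"), 0.95)
  # probe-depth monotonicity: band counts never drop as the probe deepens
  pr_deep <- classify_perimeter(ct$endosteal, label_map(cal2 + 0L, px),
                                probe_depth = 14, step = 2)
  expect_true(all(pr_deep$n_bands >= pr$n_bands))
})

test_that("perimeter class lengths sum exactly to the total perimeter", {
  res <- generate_section_2d(small_spec(seed = 2))
  seg <- segment_bone_marrow(res$truth$masks$bone, pixel_size = 0.64)
  calmap <- binarize_by_rule(res$image, reference_rules()$calcein)
  ct <- extract_surface_contours(seg)
  for (s in ct) {
    pr <- classify_perimeter(s, calmap)
    expect_equal(sum(attr(pr, "class_lengths")), attr(pr, "total_perimeter"))
  }
  expect_error(classify_perimeter(ct$endosteal, calmap, step = 1e6), "step")
})

test_that("surface classification matches the generator truth on phantoms", {
  agree <- c()
  for (s in c(2, 5)) {
    res <- generate_section_2d(small_spec(seed = s))
    seg <- segment_bone_marrow(res$truth$masks$bone, pixel_size = 0.64)
    calmap <- binarize_by_rule(res$image, reference_rules()$calcein)
    ct <- extract_surface_contours(seg)
    cc <- 400 * 0.64 / 2
    for (surf in c("endosteal", "periosteal")) {
      pr <- classify_perimeter(ct[[surf]], calmap)
      th <- atan2(pr$y - cc, pr$x - cc) %% (2 * pi)
      te <- res$truth$surfaces[res$truth$surfaces$surface == surf, ]
      sec <- findInterval(th, c(te$theta0, 2 * pi))
      truth_cls <- te$class[pmin(sec, nrow(te))]
      agree <- c(agree, mean(pr$class == truth_cls))
    }
  }
  expect_gte(mean(agree), 0.95)
})

test_that("multiple labels appear only under the frequent-dosing effect", {
  ml_len <- vapply(c(FALSE, TRUE), function(freq) {
    eff <- if (freq) effect_profile(multi_label_prob = 0.35) else effect_profile()
    res <- generate_section_2d(small_spec(seed = 14, effect = eff))
    seg <- segment_bone_marrow(res$truth$masks$bone, pixel_size = 0.64)
    calmap <- binarize_by_rule(res$image, reference_rules()$calcein)
    ct <- extract_surface_contours(seg)
    pr <- classify_perimeter(ct$endosteal, calmap)
    attr(pr, "class_lengths")[["mL"]]
  }, numeric(1))
  expect_equal(ml_len[1], 0)
  expect_gt(ml_len[2], 0)
})

test_that("labelled-length ratios track the labelled arc fraction", {
  px <- 0.5
  bone <- annulus_mask(150, 100, px)
  n <- dim(bone)[1]; cc <- n / 2 * px
  xs <- (seq_len(n) - 0.5) * px
  R <- sqrt(outer(xs, xs, function(x, y) (x - cc)^2 + (y - cc)^2))
  TH <- atan2(outer(xs, xs, function(x, y) y - cc),
              outer(xs, xs, function(x, y) x - cc)) %% (2 * pi)
  ct <- extract_surface_contours(bone, pixel_size = px)
  # full single band -> ratio ~ 1
  full <- (R > 102 & R < 104)
  pr <- classify_perimeter(ct$endosteal, label_map(full + 0L, px))
  r <- labeled_length_ratios(list(endosteal = pr))
  expect_lt(abs(r$calcein_ratio - 1), 0.05)
  # band over 40% of the circumference -> ratio 0.40 +- 0.03
  part <- full & (TH < 0.4 * 2 * pi)
  prp <- classify_perimeter(ct$endosteal, label_map(part + 0L, px))
  rp <- labeled_length_ratios(list(endosteal = prp))
  expect_lt(abs(rp$calcein_ratio - 0.40), 0.03)
  # no calcein -> 0
  pr0 <- classify_perimeter(ct$endosteal, label_map(matrix(0L, n, n), px))
  expect_equal(labeled_length_ratios(list(endosteal = pr0))$calcein_ratio, 0)
})

test_that("void surfaces split into labelled and eroded lengths", {
  px <- 0.5
  n <- 200; cc <- n / 2 * px
  xs <- (seq_len(n) - 0.5) * px
  R <- sqrt(outer(xs, xs, function(x, y) (x - cc)^2 + (y - cc)^2))
  void <- label_map((R <= 15) + 0L, px)
  rim <- label_map((R > 15 & R < 18) + 0L, px)
  res <- classify_void_surfaces(void, rim)
  expect_equal(nrow(res$voids), 1L)
  expect_lt(abs(res$voids$Vd.L.Pm - res$voids$perimeter_um), 2)
  expect_equal(res$voids$Vd.E.Pm, 0)
  # rough unlabelled void -> mostly eroded
  TH <- atan2(outer(xs, xs, function(x, y) y - cc),
              outer(xs, xs, function(x, y) x - cc))
  rough <- label_map((R <= 15 + 2 * abs(sin(8 * TH))) + 0L, px)
  none <- label_map(matrix(0L, n, n), px)
  rr <- classify_void_surfaces(rough, none)
  expect_gt(rr$voids$Vd.E.Pm / rr$voids$perimeter_um, 0.8)
  # labelled fraction invariant under rotation of the whole scene
  rot <- function(m) label_map(t(unclass(m))[rev(seq_len(n)), ], px)
  res_rot <- classify_void_surfaces(rot(void), rot(rim))
  f1 <- res$voids$Vd.L.Pm / res$voids$perimeter_um
  f2 <- res_rot$voids$Vd.L.Pm / res_rot$voids$perimeter_um
  expect_lt(abs(f1 - f2), 0.02)
})
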