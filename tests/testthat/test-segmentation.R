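test_that("binarization thresholds and size filters follow the reference rules", {
  px <- 0.64
  rule <- reference_rules()$porosity
  # uniform background below threshold -> empty map
  flat <- cal_image(matrix(5, 80, 80), px)
  expect_equal(n_objects(binarize_by_rule(flat, rule)), 0L)
  # two disks, equivalent diameters 100 and 50 um, both above threshold:
  # only the 100 um disk survives size > 90 um
  n <- 400
  img <- matrix(0, n, n)
  for (d in list(c(100, 100, 50), c(100, 280, 25))) {
    xs <- (seq_len(n) - 0.5) * px
    m <- outer(xs, xs, function(x, y)
      (x - d[1] * px)^2 + (y - d[2] * px)^2 <= d[3]^2)
    img[m] <- 30
  }
  lab <- binarize_by_rule(cal_image(img, px), rule)
  expect_equal(n_objects(lab), 1L)
  # the survivor is the big one: check its pixel-counted equivalent diameter
  area <- sum(unclass(lab) > 0) * px^2
  expect_gt(2 * sqrt(area / pi), 90)
  # uncalibrated input is rejected (size filter is physical)
  expect_error(binarize_by_rule(matrix(30, 10, 10), rule), "calibration")
})

test_that("the calcein rule keeps a band and rejects a small speckle", {
  px <- 0.64
  n <- 300
  img <- matrix(0, n, n)
  img[40:45, 20:280] <- 220      # band ~3.8 x 166 um, equiv diameter ~28 um
  img[200:207, 200:207] <- 220   # speckle ~5 um extent
  lab <- binarize_by_rule(cal_image(img, px), reference_rules()$calcein)
  expect_equal(n_objects(lab), 1L)
  expect_true(any(unclass(lab)[42, ] > 0))   # the band is the survivor
})

test_that("raising the threshold or the size filter never adds foreground", {
  set.seed(31)
  img <- cal_image(matrix(sample(0:255, 150 * 150, TRUE), 150, 150), 0.64)
  fg_px <- function(th) sum(unclass(binarize_by_rule(
    img, recognition_rule(th, 0))) > 0)
  counts <- vapply(c(20, 60, 120, 200), fg_px, numeric(1))
  expect_true(all(diff(counts) <= 0))
  n_obj <- function(ms) n_objects(binarize_by_rule(
    img, recognition_rule(100, ms)))
  objs <- vapply(c(0, 2, 5, 10), n_obj, numeric(1))
  expect_true(all(diff(objs) <= 0))
})

test_that("a classifier trained on a threshold-rule mask reproduces it", {
  pool <- phantom_pool(2, seed = 51)
  img <- pool[[1]]$image
  mask <- unclass(img) > 40          # the rule the classifier must learn
  mdl <- train_pixel_classifier(list(img), list(mask + 0L), n_train = 1,
                                seed = 1, num_trees = 50)
  pred <- predict_mask(mdl, img)
  tp <- sum(unclass(pred) > 0 & mask)
  f1 <- 2 * tp / (sum(unclass(pred) > 0) + sum(mask))
  expect_gte(f1, 0.95)
})

test_that("training and prediction are deterministic under a fixed seed", {
  pool <- phantom_pool(4, seed = 52)
  imgs <- lapply(pool, `[[`, "image")
  truths <- lapply(pool, function(p) p$truth$masks$lacunae)
  m1 <- train_pixel_classifier(imgs, truths, n_train = 3, seed = 7)
  m2 <- train_pixel_classifier(imgs, truths, n_train = 3, seed = 7)
  p1 <- predict_mask(m1, imgs[[4]])
  p2 <- predict_mask(m2, imgs[[4]])
  expect_identical(unclass(p1), unclass(p2))
  # blank image -> empty prediction
  blank <- cal_image(matrix(2, dim(imgs[[1]])[1], dim(imgs[[1]])[2]),
                     pixel_size(imgs[[1]]))
  expect_equal(n_objects(predict_mask(m1, blank)), 0L)
  expect_error(train_pixel_classifier(imgs, truths, n_train = 0), "n_train")
})

test_that("object success ratio implements one-to-one IoU matching", {
  px <- 0.5
  disks <- matrix(0L, 200, 200)
  cent <- list(c(40, 40), c(40, 150), c(150, 40), c(150, 150))
  for (k in seq_along(cent)) {
    xs <- seq_len(200)
    m <- outer(xs, xs, function(x, y)
      (x - cent[[k]][1])^2 + (y - cent[[k]][2])^2 <= 15^2)
    disks[m] <- k
  }
  truth <- label_map(disks, px)
  expect_equal(object_success_ratio(truth, truth)$ratio, 1)
  empty <- label_map(matrix(0L, 200, 200), px)
  expect_equal(object_success_ratio(empty, truth)$ratio, 0)
  expect_equal(object_success_ratio(empty, empty)$ratio, 1)
  # exactly two of four predicted -> 0.5
  two <- disks; two[two > 2L] <- 0L
  expect_equal(object_success_ratio(label_map(two, px), truth)$ratio, 0.5)
  # invariance to label permutation
  perm <- disks; perm[disks == 1L] <- 4L; perm[disks == 4L] <- 1L
  expect_equal(object_success_ratio(label_map(perm, px), truth)$ratio, 1)
  expect_error(object_success_ratio(label_map(matrix(0L, 10, 10), px), truth),
               "grid")
})

test_that("the training curve is reproducible and grows with the pool", {
  pool <- phantom_pool(10, seed = 61, image_shape = c(160, 160))
  evalset <- phantom_pool(4, seed = 62, image_shape = c(160, 160))
  imgs <- lapply(pool, `[[`, "image")
  truths <- lapply(pool, function(p) p$truth$masks$lacunae)
  eimgs <- lapply(evalset, `[[`, "image")
  etruths <- lapply(evalset, function(p) p$truth$masks$lacunae)
  cv1 <- training_curve(imgs, truths, eimgs, etruths, sizes = c(1, 8),
                        replicates = 2, seed = 5, num_trees = 40)
  cv2 <- training_curve(imgs, truths, eimgs, etruths, sizes = c(1, 8),
                        replicates = 2, seed = 5, num_trees = 40)
  expect_identical(cv1$results, cv2$results)
  s <- cv1$summary
  expect_gte(s$mean[s$group == "8"], s$mean[s$group == "1"])
  expect_error(training_curve(imgs, truths, imgs[1], truths[1],
                              sizes = c(1, 4), replicates = 1, seed = 1),
               "overlap")
})
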