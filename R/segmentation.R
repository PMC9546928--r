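#' Interactive binarization rule
#'
#' A rule of the form used for interactive object binarization on the
#' wide-field images: a gray-level intensity threshold plus a minimum object
#' size. The reference settings are threshold 12 with size > 90.0 µm for
#' cortical bone porosity and threshold 200 with size > 15.0 µm for calcein
#' labelling. The size is interpreted as an equivalent-circular-diameter in
#' µm by default (an area reading of "90 µm" would remove almost nothing at
#' this scale); set `size_as = "area"` for µm² semantics.
#'
#' @param threshold intensity threshold in native gray levels; foreground is
#'   strictly above it.
#' @param min_size minimum retained object size, µm (diameter) or µm² (area).
#' @param class optional structure-class tag ("porosity", "calcein", ...).
#' @param size_as `"diameter"` (equivalent circular/spherical diameter) or
#'   `"area"`.
#' @return object of class `recognition_rule`.
#' @export
recognition_rule <- function(threshold, min_size = 0, class = NULL,
                             size_as = c("diameter", "area")) {
  size_as <- match.arg(size_as)
  if (min_size < 0) stop("min_size must be >= 0")
  structure(list(threshold = threshold, min_size = min_size, class = class,
                 size_as = size_as), class = "recognition_rule")
}

#' Reference binarization rules
#' @return named list of [recognition_rule()]s: `porosity` (threshold 12,
#'   size > 90 µm) and `calcein` (threshold 200, size > 15 µm).
#' @export
reference_rules <- function() {
  list(porosity = recognition_rule(12, 90, "porosity"),
       calcein = recognition_rule(200, 15, "calcein"))
}

#' Binarize and label objects by an intensity/size rule
#'
#' Foreground is every pixel strictly above the rule's threshold; connected
#' components (8-connected in 2D, 26 in 3D) smaller than the rule's minimum
#' size are removed; survivors are labelled.
#'
#' @param image a [cal_image()] (calibration is required: the size filter is
#'   physical).
#' @param rule a [recognition_rule()].
#' @return a [label_map()].
#' @export
binarize_by_rule <- function(image, rule) {
  stopifnot(inherits(rule, "recognition_rule"))
  ps <- pixel_size(image)  # errors when uncalibrated
  if (rule$threshold < 0 ||
      (!is.null(attr(image, "bit_depth")) &&
       rule$threshold >= 2^attr(image, "bit_depth")))
    stop("threshold outside the image bit range")
  fg <- as_plain(image) > rule$threshold
  lab <- label_components(fg, ps)
  filter_small_objects(lab, rule$min_size, rule$size_as,
                       provenance = paste0("rule:", rule$class %||% "",
                                           " thr=", rule$threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

filter_small_objects <- function(lab, min_size, size_as = "diameter",
                                 provenance = NULL) {
  ps <- pixel_size(lab)
  x <- as_plain(lab)
  if (min_size > 0 && any(x > 0L)) {
    nd <- length(dim(x))
    unit <- prod(ps)  # pixel area (um^2) or voxel volume (um^3)
    cnt <- tabulate(x[x > 0L])
    meas <- cnt * unit
    size <- if (size_as == "diameter") {
      if (nd == 2L) 2 * sqrt(meas / pi) else (6 * meas / pi)^(1 / 3)
    } else meas
    drop <- which(size <= min_size)
    if (length(drop)) x[x %in% drop] <- 0L
    # relabel consecutively, preserving raster order
    keep <- sort(setdiff(unique(as.vector(x)), 0L))
    if (length(keep)) x[x > 0L] <- match(x[x > 0L], keep)
  }
  label_map(x, ps, provenance)
}

# ---- trainable pixel classifier (surrogate recognizer) ---------------------

# multiscale feature stack for one image; scales in um
pixel_features <- function(image, scales_um = c(0.5, 1, 2, 4)) {
  ps <- mean(pixel_size(image))
  x <- as_plain(image)
  x <- x / max(1, 2^(attr(image, "bit_depth") %||% 8L) - 1)
  feats <- list(intensity = as.vector(x))
  prev <- x
  for (s in scales_um) {
    sig <- max(0.5, s / ps)
    sm <- gauss_smooth(x, sig)
    gx <- sm; gx[] <- 0
    gx[-1, ] <- gx[-1, ] + diff(sm)  # forward difference along x
    gy <- sm; gy[] <- 0
    gy[, -1] <- gy[, -1] + t(diff(t(sm)))
    feats[[paste0("g", s)]] <- as.vector(sm)
    feats[[paste0("grad", s)]] <- as.vector(sqrt(gx^2 + gy^2))
    feats[[paste0("dog", s)]] <- as.vector(sm - prev)
    prev <- sm
  }
  as.data.frame(feats)
}

#' Train a pixel classifier for structure recognition
#'
#' A multiscale-feature random-forest pixel classifier standing in for the
#' commercial deep-learning recognizer: per-pixel Gaussian, gradient and
#' difference-of-Gaussian features at several physical scales feed a random
#' forest, trained on a balanced pixel sample from `n_train` images chosen
#' deterministically from the seed.
#'
#' @param images list of [cal_image()]s.
#' @param truth_masks list of aligned masks (logical or [label_map()]s).
#' @param n_train number of training images (>= 1, <= available).
#' @param seed integer; fixes both the image subset and the forest.
#' @param n_pixels_per_image balanced pixel sample size per image.
#' @param scales_um feature scales, µm.
#' @param num_trees forest size.
#' @return object of class `pixel_classifier` (serializable with
#'   [saveRDS()]).
#' @export
train_pixel_classifier <- function(images, truth_masks, n_train = length(images),
                                   seed = 1L, n_pixels_per_image = 2500,
                                   scales_um = c(0.5, 1, 2, 4),
                                   num_trees = 80) {
  stopifnot(length(images) == length(truth_masks), n_train >= 1,
            n_train <= length(images))
  set.seed(seed)
  pick <- sort(sample.int(length(images), n_train))
  train_dat <- lapply(pick, function(i) {
    f <- pixel_features(images[[i]], scales_um)
    y <- as.vector(as_plain(truth_masks[[i]]) > 0)
    fgi <- which(y); bgi <- which(!y)
    n_half <- ceiling(n_pixels_per_image / 2)
    sel <- c(sample(fgi, min(n_half, length(fgi))),
             sample(bgi, min(n_half, length(bgi))))
    cbind(f[sel, , drop = FALSE], .y = factor(y[sel], levels = c(FALSE, TRUE)))
  })
  dat <- do.call(rbind, train_dat)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  structure(list(fit = fit, scales_um = scales_um, seed = seed,
                 training_images = pick, n_train = n_train),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> random forest, %d trees, trained on %d image(s)\n",
              x$fit$num.trees, x$n_train))
  invisible(x)
}

#' Predict an object mask with a trained pixel classifier
#'
#' @param model a `pixel_classifier`.
#' @param image a [cal_image()] of the same modality as the training images.
#' @param prob threshold on the foreground class probability.
#' @param min_size optional size post-filter (equivalent diameter, µm).
#' @return a [label_map()] of the recognized objects.
#' @export
predict_mask <- function(model, image, prob = 0.5, min_size = 0) {
  stopifnot(inherits(model, "pixel_classifier"))
  f <- pixel_features(image, model$scales_um)
  p <- predict(model$fit, data = f, num.threads = 1)$predictions[, "TRUE"]
  fg <- matrix(p > prob, dim(image)[1], dim(image)[2])
  lab <- label_components(fg, pixel_size(image))
  if (min_size > 0) lab <- filter_small_objects(lab, min_size)
  attr(lab, "provenance") <- sprintf("classifier:n_train=%d", model$n_train)
  lab
}

#' Object-level recognition success ratio
#'
#' A ground-truth object counts as recognized when some predicted object
#' attains intersection-over-union at least `iou_min` with it, matched
#' one-to-one greedily by decreasing IoU (ties by smaller truth label).
#' Returns recognized / total truth objects; an empty truth with an empty
#' prediction scores 1.
#'
#' @param pred,truth [label_map()]s on the same grid.
#' @param iou_min minimum IoU for a match (default 0.5).
#' @return list with `ratio`, the per-truth-object `matched` flags, and the
#'   pixelwise `f1` score (secondary metric).
#' @export
object_success_ratio <- function(pred, truth, iou_min = 0.5) {
  p <- as_plain(pred); t <- as_plain(truth)
  if (!identical(dim(p), dim(t))) stop("grid mismatch between pred and truth")
  nt <- max(t); np <- max(p)
  tp_px <- sum(p > 0 & t > 0)
  f1 <- if (sum(p > 0) + sum(t > 0) == 0) 1 else
    2 * tp_px / (sum(p > 0) + sum(t > 0))
  if (nt == 0L) {
    return(list(ratio = if (np == 0L) 1 else 1, matched = logical(0), f1 = f1))
  }
  if (np == 0L)
    return(list(ratio = 0, matched = rep(FALSE, nt), f1 = f1))
  # IoU for all overlapping pairs
  both <- p > 0 & t > 0
  pair <- paste(t[both], p[both])
  inter <- table(pair)
  t_area <- tabulate(t[t > 0], nt)
  p_area <- tabulate(p[p > 0], np)
  ids <- do.call(rbind, strsplit(names(inter), " "))
  ti <- as.integer(ids[, 1]); pi <- as.integer(ids[, 2])
  iou <- as.numeric(inter) / (t_area[ti] + p_area[pi] - as.numeric(inter))
  ord <- order(-iou, ti, pi)
  matched_t <- rep(FALSE, nt); used_p <- rep(FALSE, np)
  for (k in ord) {
    if (iou[k] < iou_min) break
    if (!matched_t[ti[k]] && !used_p[pi[k]]) {
      matched_t[ti[k]] <- TRUE
      used_p[pi[k]] <- TRUE
    }
  }
  list(ratio = mean(matched_t), matched = matched_t, f1 = f1)
}

#' Recognition success versus number of training images
#'
#' For each training-set size and replicate, trains a fresh classifier on a
#' deterministic subset of the training pool and scores the mean object
#' success ratio on held-out evaluation images; the per-size replicate
#' ratios are then compared against the smallest size by a many-to-one
#' Dunnett test when replication allows.
#'
#' @param train_images,train_truths the training pool.
#' @param eval_images,eval_truths held-out evaluation set (must be disjoint
#'   from the pool).
#' @param sizes training-set sizes, e.g. `c(1, 2, 4, 8, 16, 32)`.
#' @param replicates replicates per size.
#' @param seed master seed.
#' @param iou_min IoU threshold defining a successful recognition.
#' @param ... passed to [train_pixel_classifier()].
#' @return list of class `success_curve`: `results` (one row per size x
#'   replicate), `summary` (mean ± SE per size), `dunnett` (vs the smallest
#'   size, when >= 2 replicates).
#' @export
training_curve <- function(train_images, train_truths, eval_images,
                           eval_truths, sizes = c(1, 2, 4, 8, 16),
                           replicates = 3, seed = 1L, iou_min = 0.5, ...) {
  stopifnot(max(sizes) <= length(train_images),
            length(eval_images) == length(eval_truths))
  for (e in eval_images)
    for (tr in train_images)
      if (identical(as_plain(e), as_plain(tr)))
        stop("evaluation images overlap the training pool")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(sizes) * replicates),
                      nrow = length(sizes))
  rows <- list()
  for (si in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      mdl <- train_pixel_classifier(train_images, train_truths,
                                    n_train = sizes[si],
                                    seed = rep_seeds[si, r], ...)
      ratios <- vapply(seq_along(eval_images), function(k) {
        pr <- predict_mask(mdl, eval_images[[k]])
        object_success_ratio(pr, eval_truths[[k]], iou_min)$ratio
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        n_train = sizes[si], replicate = r, success_ratio = mean(ratios))
    }
  }
  res <- do.call(rbind, rows)
  summ <- summarize_groups(res$success_ratio, factor(res$n_train, levels = sizes))
  dun <- NULL
  if (replicates >= 2 && length(sizes) >= 2) {
    dun <- dunnett_many_to_one(res$success_ratio,
                               factor(res$n_train, levels = sizes),
                               control = as.character(min(sizes)))
  }
  structure(list(results = res, summary = summ, dunnett = dun,
                 iou_min = iou_min), class = "success_curve")
}

#' @export
print.success_curve <- function(x, ...) {
  cat("<success_curve> object recognition success vs training-set size\n")
  print(x$summary)
  invisible(x)
}
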