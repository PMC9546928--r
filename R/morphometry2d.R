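# sub-pixel outer contour of a binary mask: iso-line at 0.5 of the lightly
# smoothed indicator. Returns closed polylines in pixel units (x = row
# coordinate, y = column coordinate), largest (outer) first.
mask_contours <- function(mask, smooth_sigma = 1) {
  d <- dim(mask)
  pad <- 3L
  m <- matrix(0, d[1] + 2L * pad, d[2] + 2L * pad)
  m[pad + seq_len(d[1]), pad + seq_len(d[2])] <- as.numeric(mask)
  if (smooth_sigma > 0) m <- gauss_smooth(m, smooth_sigma)
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                     levels = 0.5)
  if (!length(cl)) return(list())
  polys <- lapply(cl, function(ct) cbind(x = ct$x - pad, y = ct$y - pad))
  lens <- vapply(polys, function(p) poly_length(p), numeric(1))
  polys[order(-lens)]
}

poly_length <- function(p, scale = c(1, 1)) {
  x <- c(p[, 1], p[1, 1]) * scale[1]
  y <- c(p[, 2], p[1, 2]) * scale[2]
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p); j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2  # shoelace
}

hull_perimeter <- function(p, scale = c(1, 1)) {
  h <- chull(p[, 1] * scale[1], p[, 2] * scale[2])
  poly_length(cbind(p[h, 1], p[h, 2]), scale)
}

#' Rectangular region of interest in physical coordinates
#'
#' @param origin_um (x, y) of the ROI corner in µm.
#' @param size_um (width, height) in µm; the reference settings are
#'   0.1 x 0.2 mm for lacunae and 0.3 x 0.3 mm for Haversian canals.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(origin_um, size_um) {
  stopifnot(length(origin_um) == 2L, length(size_um) == 2L)
  if (any(size_um <= 0)) stop("roi extent must be positive")
  structure(list(origin = as.numeric(origin_um), size = as.numeric(size_um)),
            class = "roi_spec")
}

#' Extract a region of interest from a calibrated grid
#'
#' Crops a [cal_image()] or [label_map()] to a physical rectangle. For label
#' maps, objects clipped by the ROI border are recorded in the
#' `border_labels` attribute so that per-object statistics can exclude them
#' while total-area ratios keep their pixels.
#'
#' @param x a [cal_image()] or [label_map()].
#' @param roi a [roi_spec()].
#' @return the cropped object (same class as `x`).
#' @export
extract_roi <- function(x, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  ps <- pixel_size(x)
  d <- dim(x)
  i0 <- floor(roi$origin[1] / ps[1]) + 1L
  j0 <- floor(roi$origin[2] / ps[2]) + 1L
  i1 <- ceiling((roi$origin[1] + roi$size[1]) / ps[1])
  j1 <- ceiling((roi$origin[2] + roi$size[2]) / ps[2])
  if (i0 < 1L || j0 < 1L || i1 > d[1] || j1 > d[2])
    stop("roi outside image bounds")
  sub <- as_plain(x)[i0:i1, j0:j1]
  if (inherits(x, "label_map")) {
    out <- label_map(sub, ps, attr(x, "provenance"))
    edge <- unique(c(sub[1, ], sub[nrow(sub), ], sub[, 1], sub[, ncol(sub)]))
    attr(out, "border_labels") <- setdiff(edge, 0L)
    out
  } else {
    cal_image(sub, ps, attr(x, "bit_depth") %||% 8L)
  }
}

#' Per-object 2D shape descriptors
#'
#' Measures every labelled object: area (pixel count x pixel area), outer
#' perimeter (sub-pixel traced outer boundary; hole boundaries excluded),
#' length and width (major/minor axes of the second-moment best-fit
#' ellipse), circularity `4*pi*A/P^2`, smoothness (convex-hull perimeter /
#' outer perimeter, <= 1, lower for rough margins), centroid and
#' orientation.
#'
#' @param labels a [label_map()].
#' @param exclude_border drop objects touching the grid border (recommended
#'   after [extract_roi()], keeping shape statistics unbiased).
#' @param contour_sigma smoothing (pixels) for the sub-pixel boundary trace.
#' @return list with `records` (one row per object: id, area, length,
#'   width, outer_perimeter, circularity, smoothness, centroid_x/y,
#'   orientation, border) and `summary` (number, total_area, means).
#' @export
measure_objects_2d <- function(labels, exclude_border = FALSE,
                               contour_sigma = 1) {
  ps <- pixel_size(labels)
  x <- as_plain(labels)
  ids <- sort(setdiff(unique(as.vector(x)), 0L))
  px_area <- prod(ps)
  if (!length(ids)) {
    rec <- data.frame(id = integer(0), area = numeric(0), length = numeric(0),
                      width = numeric(0), outer_perimeter = numeric(0),
                      circularity = numeric(0), smoothness = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      orientation = numeric(0), border = logical(0))
    return(list(records = rec,
                summary = list(number = 0L, total_area = 0,
                               mean_area = NA_real_,
                               mean_circularity = NA_real_)))
  }
  d <- dim(x)
  border_ids <- setdiff(unique(c(x[1, ], x[d[1], ], x[, 1], x[, d[2]])), 0L)
  idx <- which(x > 0L)
  ii <- (idx - 1L) %% d[1] + 1L
  jj <- (idx - 1L) %/% d[1] + 1L
  lab <- x[idx]
  recs <- lapply(ids, function(id) {
    sel <- lab == id
    pi_ <- ii[sel]; pj_ <- jj[sel]
    npx <- length(pi_)
    area <- npx * px_area
    # physical coordinates of pixel centers
    cx <- (pi_ - 0.5) * ps[1]; cy <- (pj_ - 0.5) * ps[2]
    mx <- mean(cx); my <- mean(cy)
    # second-moment ellipse (+ pixel variance correction keeps 1-px objects sane)
    sxx <- mean((cx - mx)^2) + ps[1]^2 / 12
    syy <- mean((cy - my)^2) + ps[2]^2 / 12
    sxy <- mean((cx - mx) * (cy - my))
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE)
    len <- 4 * sqrt(max(ev$values[1], 0))
    wid <- 4 * sqrt(max(ev$values[2], 0))
    orient <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    # crop, trace outer boundary
    i0 <- min(pi_); i1 <- max(pi_); j0 <- min(pj_); j1 <- max(pj_)
    sub <- matrix(FALSE, i1 - i0 + 1L, j1 - j0 + 1L)
    sub[cbind(pi_ - i0 + 1L, pj_ - j0 + 1L)] <- TRUE
    ct <- mask_contours(sub, contour_sigma)
    if (length(ct)) {
      perim <- poly_length(ct[[1]], ps)
      hullp <- hull_perimeter(ct[[1]], ps)
      smooth <- min(1, hullp / perim)
    } else {
      perim <- NA_real_; smooth <- NA_real_
    }
    data.frame(id = id, area = area, length = len, width = wid,
               outer_perimeter = perim,
               circularity = 4 * pi * area / perim^2,
               smoothness = smooth,
               centroid_x = mx, centroid_y = my, orientation = orient,
               border = id %in% border_ids)
  })
  rec <- do.call(rbind, recs)
  total_area <- sum(rec$area)
  if (exclude_border) rec <- rec[!rec$border, , drop = FALSE]
  list(records = rec,
       summary = list(number = nrow(rec), total_area = total_area,
                      mean_area = mean(rec$area),
                      mean_length = mean(rec$length),
                      mean_width = mean(rec$width),
                      mean_perimeter = mean(rec$outer_perimeter),
                      mean_circularity = mean(rec$circularity),
                      mean_smoothness = mean(rec$smoothness)))
}

#' Cortical porosity summary
#'
#' Total porosity area over bone area plus per-pore shape statistics. Pores
#' lying outside the bone mask are excluded; pore pixels are intersected
#' with the bone compartment for the area ratio.
#'
#' @param pore_labels a [label_map()] of intracortical pores/voids.
#' @param bone_mask logical mask of the cortical bone compartment on the
#'   same grid.
#' @param min_overlap minimum fraction of a pore inside bone to keep it.
#' @return list: `porosity_ratio` (pore area / bone area), `number`,
#'   `mean_area`, `mean_circularity`, `mean_smoothness`, `records`.
#' @export
porosity_summary <- function(pore_labels, bone_mask, min_overlap = 0.5) {
  x <- as_plain(pore_labels)
  bm <- as_plain(bone_mask) > 0
  if (!identical(dim(x), dim(bm))) stop("masks on different grids")
  if (!any(bm)) stop("empty bone mask")
  ps <- pixel_size(pore_labels)
  ids <- sort(setdiff(unique(as.vector(x)), 0L))
  if (length(ids)) {
    inb <- tabulate(x[bm & x > 0L], max(ids))
    tot <- tabulate(x[x > 0L], max(ids))
    keep <- ids[inb[ids] / tot[ids] >= min_overlap]
    x2 <- x
    x2[!(x2 %in% keep)] <- 0L
  } else x2 <- x
  pore_area <- sum(x2 > 0L & bm) * prod(ps)
  bone_area <- sum(bm) * prod(ps)
  m <- measure_objects_2d(label_map(x2, ps))
  list(porosity_ratio = pore_area / bone_area,
       number = m$summary$number,
       mean_area = m$summary$mean_area,
       mean_circularity = m$summary$mean_circularity,
       mean_smoothness = m$summary$mean_smoothness,
       records = m$records)
}
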