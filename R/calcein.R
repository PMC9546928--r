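#' Extract endosteal and periosteal surface contours
#'
#' Traces the marrow-facing (endosteal) and outward-facing (periosteal)
#' boundaries of the cortical ring as closed, counterclockwise-ordered
#' polylines in µm. Boundaries of intracortical voids belong to neither
#' surface contour.
#'
#' @param bone logical bone mask or a [segment_bone_marrow()] result.
#' @param pixel_size µm per pixel when `bone` is a bare matrix.
#' @return list with `endosteal` and `periosteal`: two-column µm coordinate
#'   matrices of class `surface_contour`, carrying attributes
#'   `total_length` (µm) and `probe_side` (which side of the curve the bone
#'   lies on: `"exterior"` for the endosteal contour, `"interior"` for the
#'   periosteal one).
#' @export
extract_surface_contours <- function(bone, pixel_size = NULL) {
  marrow <- NULL
  if (is.list(bone) && !is.null(bone$bone)) {
    marrow <- bone$marrow; pixel_size <- bone$pixel_size; bone <- bone$bone
  }
  ps <- rep_len(as.numeric(pixel_size %||% attr(bone, "pixel_size") %||%
                             stop("calibration required")), 2L)
  dm <- dim(bone)
  bone <- as.logical(as_plain(bone)); dim(bone) <- dm
  if (is.null(marrow)) {
    solid <- as.matrix(EBImage::fillHull(EBImage::Image(bone + 0))) > 0
    cav <- label_components(solid & !bone, ps)
    if (n_objects(cav) == 0L) stop("ring not closed")
    sizes <- tabulate(as_plain(cav)[as_plain(cav) > 0L])
    marrow <- as_plain(cav) == which.max(sizes)
  }
  solid <- as.matrix(EBImage::fillHull(EBImage::Image((bone | marrow) + 0))) > 0
  mk <- function(mask, probe_side) {
    ct <- mask_contours(mask, smooth_sigma = 2)
    if (!length(ct)) stop("ring not closed")
    p <- ct[[1]]
    # CCW ordering (positive signed area)
    if (poly_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    um <- cbind(x = p[, 1] * ps[1], y = p[, 2] * ps[2])
    structure(um, total_length = poly_length(p, ps),
              probe_side = probe_side, class = c("surface_contour", "matrix"))
  }
  list(endosteal = mk(marrow, "exterior"),
       periosteal = mk(solid, "interior"))
}

# resample a closed polyline at n equal arc-length steps; returns points,
# unit tangents, and the exact step length (total / n)
resample_contour <- function(p, step_um) {
  x <- c(p[, 1], p[1, 1]); y <- c(p[, 2], p[1, 2])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  L <- sum(seg)
  n <- max(8L, floor(L / step_um))
  s_at <- (seq_len(n) - 1L) * L / n
  cs <- c(0, cumsum(seg))
  k <- findInterval(s_at, cs, rightmost.closed = TRUE)
  k[k >= length(x)] <- length(x) - 1L
  t <- (s_at - cs[k]) / pmax(seg[k], 1e-12)
  px <- x[k] + t * (x[k + 1L] - x[k])
  py <- y[k] + t * (y[k + 1L] - y[k])
  tx <- (x[k + 1L] - x[k]) / pmax(seg[k], 1e-12)
  ty <- (y[k + 1L] - y[k]) / pmax(seg[k], 1e-12)
  list(x = px, y = py, tx = tx, ty = ty, s = s_at, step = L / n,
       total = L, n = n)
}

# roughness profile: running standard deviation of the turning rate
# (signed curvature, 1/um) over a window of arc length
contour_roughness <- function(rs, window_um = 20) {
  ang <- atan2(rs$ty, rs$tx)
  dth <- diff(c(ang, ang[1]))
  dth <- ((dth + pi) %% (2 * pi)) - pi
  curv <- dth / rs$step
  half <- max(1L, round(window_um / (2 * rs$step)))
  n <- rs$n
  vapply(seq_len(n), function(i) {
    idx <- ((i - half):(i + half) - 1L) %% n + 1L
    sd(curv[idx])
  }, numeric(1))
}

#' Classify a bone surface contour by calcein labelling state
#'
#' Walks the contour at a fixed arc-length step; at each sample an inward
#' probe (a segment of length `probe_depth` along the bone-side normal)
#' counts the distinct calcein bands it crosses. Three or more bands give a
#' multiple-labelled sample (mL), two double (dL), one single (sL); an
#' unlabelled sample is eroded (E) when the local boundary roughness —
#' the standard deviation of signed curvature in a `roughness_window` —
#' exceeds `roughness_threshold`, quiescent (Q) otherwise. Per-class
#' lengths sum exactly to the total perimeter (classes are exhaustive and
#' exclusive per sample).
#'
#' @param contour a `surface_contour` from [extract_surface_contours()] (or
#'   a two-column µm matrix; then `probe_side` must be given).
#' @param calcein a [label_map()] or logical mask of calcein bands.
#' @param probe_depth probe length into bone, µm.
#' @param step arc-length sampling step, µm.
#' @param roughness_threshold curvature-SD threshold (1/µm) separating
#'   eroded from quiescent unlabelled surface.
#' @param roughness_window arc-length window for the roughness statistic, µm.
#' @param probe_side `"interior"` or `"exterior"`: which side of the CCW
#'   contour the bone lies on.
#' @return object of class `perimeter_profile`: data frame of samples
#'   (`s`, `x`, `y`, `n_bands`, `class`) with attributes `total_perimeter`,
#'   `step` and `class_lengths` (named µm lengths for mL/dL/sL/E/Q).
#' @export
classify_perimeter <- function(contour, calcein, probe_depth = 10, step = 2,
                               roughness_threshold = 0.055,
                               roughness_window = 20,
                               probe_side = attr(contour, "probe_side")) {
  if (is.null(probe_side)) stop("probe_side unknown; pass a surface_contour")
  ps <- pixel_size(calcein)
  cal <- as_plain(calcein) > 0
  if (step > attr(contour, "total_length") %||% Inf)
    stop("sampling step exceeds contour length")
  rs <- resample_contour(contour, step)
  # CCW contour: interior lies left of travel; left normal = (-ty, tx)
  sgn <- if (probe_side == "interior") 1 else -1
  nxv <- -rs$ty * sgn; nyv <- rs$tx * sgn
  probe_t <- seq(0.4, probe_depth, by = min(ps) / 2)
  d <- dim(cal)
  n_bands <- vapply(seq_len(rs$n), function(i) {
    qx <- rs$x[i] + probe_t * nxv[i]
    qy <- rs$y[i] + probe_t * nyv[i]
    ii <- round(qx / ps[1] + 0.5); jj <- round(qy / ps[2] + 0.5)
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    hit <- rep(FALSE, length(probe_t))
    hit[ok] <- cal[cbind(ii[ok], jj[ok])]
    # distinct bands = runs of consecutive hits along the probe
    r <- rle(hit)
    sum(r$values)
  }, numeric(1))
  rough <- contour_roughness(rs, roughness_window)
  cls <- ifelse(n_bands >= 3, "mL",
         ifelse(n_bands == 2, "dL",
         ifelse(n_bands == 1, "sL",
         ifelse(rough > roughness_threshold, "E", "Q"))))
  samples <- data.frame(s = rs$s, x = rs$x, y = rs$y,
                        n_bands = as.integer(n_bands), class = cls,
                        roughness = rough, stringsAsFactors = FALSE)
  class_lengths <- vapply(c("mL", "dL", "sL", "E", "Q"),
                          function(k) sum(cls == k) * rs$step, numeric(1))
  structure(samples, total_perimeter = rs$total, step = rs$step,
            class_lengths = class_lengths, probe_depth = probe_depth,
            class = c("perimeter_profile", "data.frame"))
}

#' Labelled-length ratios of a classified surface
#'
#' The total calcein length seen along a surface (bands crossed per sample,
#' integrated over arc length) divided by the surface perimeter; ranges in
#' `[0, max band count]`. Also reports the singly-counted labelled fraction
#' (arc fraction with at least one band).
#'
#' @param profile a `perimeter_profile` (or named list of them).
#' @return data frame with `surface`, `perimeter_um`, `calcein_ratio`,
#'   `labeled_fraction`.
#' @export
labeled_length_ratios <- function(profile) {
  if (inherits(profile, "perimeter_profile")) profile <- list(surface = profile)
  do.call(rbind, lapply(names(profile), function(nm) {
    p <- profile[[nm]]
    step <- attr(p, "step"); L <- attr(p, "total_perimeter")
    data.frame(surface = nm, perimeter_um = L,
               calcein_ratio = sum(p$n_bands) * step / L,
               labeled_fraction = mean(p$n_bands >= 1))
  }))
}

#' Classify intracortical void surfaces as labelled or eroded
#'
#' Each void's boundary is sampled by the same probing rules as the major
#' surfaces: samples with a calcein band within `probe_depth` are labelled
#' (Vd.L.Pm), unlabelled samples with high boundary roughness are eroded
#' (Vd.E.Pm), the rest quiescent. Labelled + eroded never exceeds the void
#' perimeter.
#'
#' @param void_labels a [label_map()] of intracortical voids.
#' @param calcein calcein band mask/label map on the same grid.
#' @param probe_depth probe length outward from the void, µm.
#' @param step sampling step, µm.
#' @param roughness_threshold,roughness_window as in [classify_perimeter()].
#' @return list: `voids` (per-void perimeter, Vd.L.Pm, Vd.E.Pm, Vd.Q.Pm)
#'   and `totals`.
#' @export
classify_void_surfaces <- function(void_labels, calcein, probe_depth = 5,
                                   step = 1, roughness_threshold = 0.055,
                                   roughness_window = 12) {
  x <- as_plain(void_labels)
  ps <- pixel_size(void_labels)
  ids <- sort(setdiff(unique(as.vector(x)), 0L))
  rows <- lapply(ids, function(id) {
    # void boundary, CCW; bone lies outside the void polygon
    idx <- which(x == id, arr.ind = TRUE)
    pad <- ceiling(probe_depth / min(ps)) + 4L
    i0 <- max(1L, min(idx[, 1]) - pad); i1 <- min(nrow(x), max(idx[, 1]) + pad)
    j0 <- max(1L, min(idx[, 2]) - pad); j1 <- min(ncol(x), max(idx[, 2]) + pad)
    sub <- x[i0:i1, j0:j1] == id
    ct <- mask_contours(sub, 2)
    if (!length(ct)) return(NULL)
    p <- ct[[1]]
    if (poly_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    um <- cbind((p[, 1] + i0 - 1L) * ps[1], (p[, 2] + j0 - 1L) * ps[2])
    um <- structure(um, total_length = poly_length(p, ps))
    prof <- classify_perimeter(um, calcein, probe_depth = probe_depth,
                               step = step,
                               roughness_threshold = roughness_threshold,
                               roughness_window = roughness_window,
                               probe_side = "exterior")
    cl <- attr(prof, "class_lengths")
    data.frame(void = id, perimeter_um = attr(prof, "total_perimeter"),
               Vd.L.Pm = cl[["mL"]] + cl[["dL"]] + cl[["sL"]],
               Vd.E.Pm = cl[["E"]], Vd.Q.Pm = cl[["Q"]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  voids <- if (length(rows)) do.call(rbind, rows) else
    data.frame(void = integer(0), perimeter_um = numeric(0),
               Vd.L.Pm = numeric(0), Vd.E.Pm = numeric(0),
               Vd.Q.Pm = numeric(0))
  list(voids = voids,
       totals = colSums(voids[, -1, drop = FALSE]))
}
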