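#' Segment the cortical ring into bone and marrow
#'
#' The marrow cavity is identified topologically as the largest cavity fully
#' enclosed by the cortical ring (robust to staining variation); the bone
#' compartment is the remaining annulus, intracortical voids included.
#'
#' @param x a [cal_image()] (thresholded at `threshold`) or a logical mask
#'   of the mineralized compartment.
#' @param threshold gray-level threshold separating tissue from background
#'   when `x` is an image.
#' @param pixel_size µm per pixel, taken from `x` when calibrated.
#' @return list: `bone`, `marrow` (logical masks), `bone_area_mm2`,
#'   `marrow_area_mm2`, `total_area_mm2`.
#' @export
segment_bone_marrow <- function(x, threshold = NULL, pixel_size = NULL) {
  ps <- pixel_size %||% attr(x, "pixel_size")
  if (is.null(ps)) stop("calibration required (areas are physical)")
  ps <- rep_len(as.numeric(ps), 2L)
  fg <- if (is.logical(x) || all(as_plain(x) %in% c(0, 1))) {
    as.logical(as_plain(x))
  } else {
    if (is.null(threshold)) threshold <- EBImage::otsu(
      EBImage::Image(as_plain(x) / max(as_plain(x)))) * max(as_plain(x))
    as_plain(x) > threshold
  }
  dim(fg) <- dim(x)
  # close small gaps so noise does not break the ring
  fg <- as.matrix(EBImage::closing(EBImage::Image(fg + 0),
                                   EBImage::makeBrush(3, "box"))) > 0
  solid <- as.matrix(EBImage::fillHull(EBImage::Image(fg + 0))) > 0
  cav <- label_components(solid & !fg, ps)
  if (n_objects(cav) == 0L) stop("no closed ring: no enclosed cavity found")
  sizes <- tabulate(as_plain(cav)[as_plain(cav) > 0L])
  marrow <- as_plain(cav) == which.max(sizes)
  # the marrow cavity must be a substantial central cavity, not a void
  if (max(sizes) * prod(ps) < 0.02 * sum(solid) * prod(ps))
    stop("no closed ring: largest cavity is not a marrow-scale cavity")
  bone <- solid & !marrow
  list(bone = bone, marrow = marrow,
       bone_area_mm2 = sum(bone) * prod(ps) / 1e6,
       marrow_area_mm2 = sum(marrow) * prod(ps) / 1e6,
       total_area_mm2 = sum(solid) * prod(ps) / 1e6,
       pixel_size = ps)
}

#' Partition the cortex into inner, Haversian and outer lamellae
#'
#' Assigns each bone pixel a normalized transmural coordinate
#' `u = d_endo / (d_endo + d_peri)` built from Euclidean distance
#' transforms to the marrow (endosteal, u = 0) and periosteal (u = 1)
#' boundaries, then cuts at the configured fractions: inner lamella
#' `u < f_in`, outer lamella `u > 1 - f_out`, Haversian lamella between.
#' The three layer masks partition the bone mask exactly.
#'
#' @param bone logical bone mask, or the list returned by
#'   [segment_bone_marrow()].
#' @param f_in,f_out endosteal and periosteal fractions of cortical
#'   thickness (defaults 0.25 / 0.25).
#' @param pixel_size µm per pixel when `bone` is a bare matrix.
#' @param marrow optional marrow mask (recomputed topologically otherwise).
#' @return object of class `cortical_partition`: masks (`bone`, `marrow`,
#'   `inner`, `haversian`, `outer`), the transmural coordinate `u`, layer
#'   areas (µm²) and relative portions.
#' @export
partition_cortex <- function(bone, f_in = 0.25, f_out = 0.25,
                             pixel_size = NULL, marrow = NULL) {
  if (is.list(bone) && !is.null(bone$bone)) {
    marrow <- bone$marrow
    pixel_size <- bone$pixel_size
    bone <- bone$bone
  }
  if (f_in <= 0 || f_out <= 0 || f_in + f_out >= 1)
    stop("need 0 < f_in, f_out and f_in + f_out < 1")
  ps <- pixel_size %||% attr(bone, "pixel_size")
  if (is.null(ps)) stop("calibration required")
  ps <- rep_len(as.numeric(ps), 2L)
  dm <- dim(bone)
  bone <- as.logical(as_plain(bone)); dim(bone) <- dm
  if (is.null(marrow)) {
    solid <- as.matrix(EBImage::fillHull(EBImage::Image(bone + 0))) > 0
    cav <- label_components(solid & !bone, ps)
    if (n_objects(cav) == 0L) stop("no enclosed cavity: cannot orient cortex")
    sizes <- tabulate(as_plain(cav)[as_plain(cav) > 0L])
    marrow <- as_plain(cav) == which.max(sizes)
  } else {
    marrow <- as.logical(as_plain(marrow)); dim(marrow) <- dim(bone)
    solid <- bone | marrow
  }
  outside <- !(as.matrix(EBImage::fillHull(EBImage::Image((bone | marrow) + 0))) > 0)
  if (!any(outside)) stop("cortex touches every border: cannot find periosteum")
  # distance of every pixel to marrow and to outside, in um
  d_endo <- distance_transform(!marrow, ps)
  d_peri <- distance_transform(!outside, ps)
  tot <- d_endo + d_peri
  if (any(tot[bone] <= 0)) stop("degenerate cortex: zero thickness")
  u <- array(NA_real_, dim(bone))
  u[bone] <- d_endo[bone] / tot[bone]
  inner <- bone & !is.na(u) & u < f_in
  outer <- bone & !is.na(u) & u > 1 - f_out
  hav <- bone & !inner & !outer
  px_area <- prod(ps)
  areas <- c(inner = sum(inner), haversian = sum(hav), outer = sum(outer)) * px_area
  structure(list(bone = bone, marrow = marrow,
                 inner = inner, haversian = hav, outer = outer,
                 u = u, f_in = f_in, f_out = f_out,
                 layer_areas_um2 = areas,
                 relative_portions = areas / sum(areas),
                 pixel_size = ps),
            class = "cortical_partition")
}

#' @export
print.cortical_partition <- function(x, ...) {
  cat("<cortical_partition>\n")
  print(round(rbind(area_um2 = x$layer_areas_um2,
                    portion = x$relative_portions), 4))
  invisible(x)
}

#' Assign objects to cortical layers by centroid
#'
#' @param partition a [partition_cortex()] result.
#' @param centroids two-column matrix/data.frame of µm coordinates.
#' @return character vector over `c("inner", "haversian", "outer")`;
#'   `"unassigned"` for centroids outside the bone mask.
#' @export
assign_layer <- function(partition, centroids) {
  stopifnot(inherits(partition, "cortical_partition"))
  centroids <- as.data.frame(centroids)
  ps <- partition$pixel_size
  i <- pmin(pmax(round(centroids[[1]] / ps[1] + 0.5), 1L), nrow(partition$bone))
  j <- pmin(pmax(round(centroids[[2]] / ps[2] + 0.5), 1L), ncol(partition$bone))
  idx <- cbind(i, j)
  out <- rep("unassigned", nrow(idx))
  out[partition$inner[idx]] <- "inner"
  out[partition$haversian[idx]] <- "haversian"
  out[partition$outer[idx]] <- "outer"
  out
}
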