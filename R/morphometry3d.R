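#' Separate lacunae from canaliculi by local thickness
#'
#' Splits a binarized lacuno-canalicular foreground into lacunar bodies and
#' canalicular tubes using two diameter set-points: voxels whose local
#' thickness (twice the Euclidean distance to background) exceeds `d_start`
#' seed lacuna cores, which are closed back to the true boundary by a
#' constrained dilation of `d_start / 2`; the connected thin remainder
#' forms the canalicular mask, and remainder components whose maximal local
#' thickness stays below `d_end` are discarded. The reference set-points
#' are 0.6 µm (start) and 0.3 µm (end).
#'
#' @param mask logical 3D array (or [cal_image()]/[label_map()]) of the
#'   binarized foreground.
#' @param d_start,d_end µm; `d_start > d_end > 0`. Structures whose local
#'   thickness reaches `d_start` become lacunar bodies by definition, so the
#'   set-points must bracket the canalicular diameters of interest.
#' @param min_volume µm³; remainder components smaller than this (junction
#'   crumbs of rasterization, far below any real canaliculus) are discarded.
#' @param pixel_size voxel size per axis, µm.
#' @return list: `lacunae` (a [label_map()]), `canaliculi` (logical mask),
#'   `discarded` (logical mask), `thickness` (local-thickness proxy 2*EDT).
#'   Lacunae, canaliculi and discarded voxels partition the input
#'   foreground.
#' @export
separate_lacunae_canaliculi <- function(mask, d_start = 0.6, d_end = 0.3,
                                        min_volume = 0.02,
                                        pixel_size = NULL) {
  stopifnot(d_start > d_end, d_end > 0)
  ps <- rep_len(as.numeric(pixel_size %||% attr(mask, "pixel_size") %||%
                             stop("calibration required")), 3L)
  fg <- as_plain(mask) > 0
  dim(fg) <- dim(as_plain(mask))
  stopifnot(length(dim(fg)) == 3L)
  if (d_end < max(ps))
    warning(sprintf(paste0("voxel size (%.2f um) coarser than d_end (%.2f um):",
                           " thin canaliculi are under-resolved"),
                    max(ps), d_end))
  dt <- distance_transform(fg, ps)
  core <- fg & (2 * dt > d_start)
  lac_vox <- array(FALSE, dim(fg))
  if (any(core)) {
    dist_to_core <- distance_transform(!core, ps)
    lac_vox <- fg & dist_to_core <= d_start / 2
  }
  remainder <- fg & !lac_vox
  can <- array(FALSE, dim(fg)); disc <- array(FALSE, dim(fg))
  if (any(remainder)) {
    rl <- label_components(remainder, ps)
    rx <- as_plain(rl)
    nid <- max(rx)
    keep <- logical(nid)
    # half-voxel guard: the thinnest digitizations of a just-passing tube
    # read up to h/2 below their true diameter depending on grid phase
    vox_vol <- prod(ps)
    for (id in seq_len(nid)) {
      sel <- rx == id
      keep[id] <- (2 * max(dt[sel]) + min(ps) / 2) >= d_end &&
        sum(sel) * vox_vol >= min_volume
    }
    can <- array(rx > 0L & keep[pmax(rx, 1L)], dim(fg))
    disc <- remainder & !can
  }
  list(lacunae = label_components(lac_vox, ps),
       canaliculi = structure(can, pixel_size = ps),
       discarded = structure(disc, pixel_size = ps),
       thickness = 2 * dt)
}

#' Measure 3D lacunar morphometry
#'
#' Per-lacuna volume (voxel count x voxel volume), surface (meshed boundary
#' area, see [surface_area_3d()]), sphericity
#' `pi^(1/3) (6V)^(2/3) / S` (1 for a perfect sphere), principal axis
#' (leading eigenvector of the voxel covariance) and orientation angle —
#' the acute angle, folded to `[0, 90]` degrees, between the principal axis
#' and `reference_axis`. Objects touching the stack border are flagged and
#' excluded from shape statistics.
#'
#' @param labels a 3D [label_map()] of lacunae.
#' @param reference_axis length-3 vector (default x, the long-bone axis).
#' @return list with `records` (id, volume, surface, sphericity,
#'   orientation, centroid, principal axis, border flag) and `summary`.
#' @export
measure_lacunae_3d <- function(labels, reference_axis = c(1, 0, 0)) {
  ps <- pixel_size(labels)
  x <- as_plain(labels)
  d <- dim(x)
  ids <- sort(setdiff(unique(as.vector(x)), 0L))
  ref <- reference_axis / sqrt(sum(reference_axis^2))
  vox_vol <- prod(ps)
  if (!length(ids))
    return(list(records = data.frame(), summary = list(number = 0L,
                                                       total_volume = 0)))
  idx <- which(x > 0L)
  ai <- arrayInd(idx, d)
  lab <- x[idx]
  recs <- lapply(ids, function(id) {
    sel <- lab == id
    vi <- ai[sel, , drop = FALSE]
    npx <- nrow(vi)
    vol <- npx * vox_vol
    border <- any(vi[, 1] %in% c(1L, d[1])) || any(vi[, 2] %in% c(1L, d[2])) ||
      any(vi[, 3] %in% c(1L, d[3]))
    # crop with margin for meshing
    lo <- pmax(apply(vi, 2, min) - 2L, 1L)
    hi <- pmin(apply(vi, 2, max) + 2L, d)
    sub <- array(FALSE, hi - lo + 1L)
    sub[vi - matrix(lo - 1L, npx, 3, byrow = TRUE)] <- TRUE
    surf <- surface_area_3d(sub, ps)
    # voxel covariance in physical coordinates (+ voxel variance)
    P <- sweep(vi, 2, c(0.5, 0.5, 0.5)) %*% diag(ps)
    cen <- colMeans(P)
    S <- cov(P) * (npx - 1) / npx + diag(ps^2) / 12
    ev <- eigen(S, symmetric = TRUE)
    axis <- ev$vectors[, 1]
    ang <- acos(pmin(1, abs(sum(axis * ref)))) * 180 / pi
    data.frame(id = id, volume = vol, surface = surf,
               sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / surf,
               orientation = ang,
               centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
               axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
               border = border)
  })
  rec <- do.call(rbind, recs)
  interior <- rec[!rec$border, , drop = FALSE]
  list(records = rec,
       summary = list(number = nrow(rec), total_volume = sum(rec$volume),
                      mean_volume = mean(rec$volume),
                      mean_surface = mean(interior$surface),
                      mean_sphericity = mean(interior$sphericity),
                      orientation_sd = if (nrow(interior) >= 2)
                        orientation_sd(interior) else NA_real_))
}

#' Standard deviation of lacunar orientation angles
#'
#' Axial angles are undirected and folded to `[0, 90]` degrees before the
#' standard deviation is taken; the statistic is invariant under a global
#' rotation applied to all axes together with the reference.
#'
#' @param records data frame with an `orientation` column (degrees), or a
#'   numeric vector of angles.
#' @return SD in degrees.
#' @export
orientation_sd <- function(records) {
  ang <- if (is.data.frame(records)) records$orientation else as.numeric(records)
  if (length(ang) < 2) stop("need at least 2 orientation angles")
  ang <- 90 - abs(90 - (ang %% 180))  # fold to [0, 90]
  sd(ang)
}

# sparse 26-connected voxel graph of a set of voxel indices (rows of arrayInd)
voxel_graph <- function(vi, ps) {
  n <- nrow(vi)
  key <- (vi[, 3] * 2048 + vi[, 2]) * 2048 + vi[, 1]  # unique numeric code
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    nbkey <- key + (offs[k, 3] * 2048 + offs[k, 2]) * 2048 + offs[k, 1]
    j <- match(nbkey, key)
    ok <- !is.na(j) & seq_len(n) < j      # each undirected edge once
    if (any(ok)) {
      from <- c(from, which(ok)); to <- c(to, j[ok])
      w <- c(w, rep(sqrt(sum((offs[k, ] * ps)^2)), sum(ok)))
    }
  }
  igraph::make_graph(rbind(from, to), n = n, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

# geodesic distance from a vertex set via a zero-weight virtual source;
# returns list(dist over all n vertices, path extractor to a target)
geo_from_set <- function(g, set, n) {
  gv <- igraph::add_vertices(g, 1)
  virt <- n + 1L
  gv <- igraph::add_edges(gv, rbind(rep(virt, length(set)), set),
                          attr = list(weight = rep(0, length(set))))
  dist <- as.numeric(igraph::distances(gv, v = virt))[seq_len(n)]
  list(dist = dist, graph = gv, virt = virt)
}

geo_path_to <- function(gs, target) {
  vp <- igraph::shortest_paths(gs$graph, from = gs$virt, to = target,
                               output = "vpath")$vpath[[1]]
  p <- as.integer(vp)
  p[p != gs$virt]
}

#' Trace and measure canaliculi from their binarized mask
#'
#' Builds a centerline skeleton of every canalicular component by iterative
#' geodesic farthest-point tracing on the 26-connected voxel graph (path
#' steps weighted toward medial, high-distance-transform voxels), splits
#' trees at branch points (each branch-free path is one canaliculus), and
#' measures: length (chord-resampled arc length of the centerline),
#' diameter (twice the mean distance-transform value along the path, with a
#' half-voxel boundary correction), and volume (component voxels
#' apportioned to their nearest path, so record volumes conserve the mask
#' volume exactly).
#'
#' @param canaliculi logical 3D mask from [separate_lacunae_canaliculi()].
#' @param lacuna_labels lacuna [label_map()] used to anchor paths (parent
#'   lacuna = label adjacent to the path seed); may be `NULL`.
#' @param pixel_size voxel size, µm.
#' @param min_branch_um branches shorter than this are absorbed, µm.
#' @param chord_um resampling interval for arc length, µm.
#' @return list: `records` (id, lacuna, length, mean_diameter, volume),
#'   `skeleton` (data frame of polyline points with path ids and local
#'   diameter), `summary` (number, means, total volume).
#' @export
skeletonize_and_measure_canaliculi <- function(canaliculi, lacuna_labels = NULL,
                                               pixel_size = NULL,
                                               min_branch_um = 2,
                                               chord_um = 0.5) {
  ps <- rep_len(as.numeric(pixel_size %||% attr(canaliculi, "pixel_size") %||%
                             stop("calibration required")), 3L)
  fg <- as_plain(canaliculi) > 0
  dim(fg) <- dim(as_plain(canaliculi))
  d <- dim(fg)
  vox_vol <- prod(ps)
  empty <- list(records = data.frame(), skeleton = data.frame(),
                summary = list(number = 0L, total_volume = 0))
  if (!any(fg)) return(empty)
  dt <- distance_transform(fg, ps)
  lac <- if (!is.null(lacuna_labels)) as_plain(lacuna_labels) else NULL
  comp <- as_plain(label_components(fg, ps))

  # voxel adjacent to which lacuna? (within one voxel of a lacuna label)
  lac_adj <- function(vi) {
    if (is.null(lac)) return(0L)
    for (k in seq_len(nrow(vi))) {
      lo <- pmax(vi[k, ] - 1L, 1L); hi <- pmin(vi[k, ] + 1L, d)
      nb <- lac[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      if (any(nb > 0L)) return(nb[nb > 0L][1])
    }
    0L
  }

  all_records <- list(); all_skel <- list(); path_id <- 0L
  for (cid in seq_len(max(comp))) {
    idx <- which(comp == cid)
    vi <- arrayInd(idx, d)
    n <- nrow(vi)
    pos <- (vi - 0.5) %*% diag(ps)    # physical voxel centers
    dtv <- dt[idx]
    if (n < 3) {            # degenerate speck: one record, no real path
      path_id <- path_id + 1L
      all_records[[path_id]] <- data.frame(
        id = path_id, lacuna = lac_adj(vi), length = max(ps) * n,
        mean_diameter = max(0, 2 * mean(dtv)), volume = n * vox_vol)
      next
    }
    g <- voxel_graph(vi, ps)
    # medial preference: shortest paths prefer high-dt voxels
    pen <- 1 / (dtv + 0.5 * min(ps))
    el <- igraph::ends(g, igraph::E(g), names = FALSE)
    igraph::E(g)$weight <- igraph::E(g)$weight *
      (pen[el[, 1]] + pen[el[, 2]]) / 2
    # seeds: voxels adjacent to a lacuna; fall back to the thickest voxel
    seed_mask <- rep(FALSE, n)
    parent_lac <- 0L
    if (!is.null(lac)) {
      for (k in seq_len(n)) {
        lo <- pmax(vi[k, ] - 1L, 1L); hi <- pmin(vi[k, ] + 1L, d)
        nb <- lac[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
        if (any(nb > 0L)) { seed_mask[k] <- TRUE
          if (parent_lac == 0L) parent_lac <- nb[nb > 0L][1] }
      }
    }
    seeds <- if (any(seed_mask)) {
      which(seed_mask)
    } else {
      # free-floating tube: start from a true endpoint (farthest voxel from
      # an arbitrary interior point, the tree-diameter double sweep)
      which.max(geo_from_set(g, which.max(dtv), n)$dist)
    }
    # iterative geodesic farthest-point path extraction (one Dijkstra from
    # the growing skeleton per branch, via a zero-weight virtual source)
    covered <- seeds
    paths <- list()
    repeat {
      gs <- geo_from_set(g, covered, n)
      far <- which.max(gs$dist)
      if (!is.finite(gs$dist[far]) || gs$dist[far] < 1e-9) break
      pvox <- geo_path_to(gs, far)
      bl <- chord_length(pos[pvox, , drop = FALSE], chord_um)
      if (length(paths) > 0 && bl < min_branch_um) break
      paths[[length(paths) + 1L]] <- pvox
      covered <- union(covered, pvox)
      if (length(covered) == n) break
    }
    if (!length(paths)) paths <- list(which.max(dtv))
    # apportion every voxel to its geodesically nearest path
    assign_path <- rep(1L, n)
    if (length(paths) > 1) {
      dists <- sapply(paths, function(pv) geo_from_set(g, pv, n)$dist)
      assign_path <- max.col(-dists, ties.method = "first")
    }
    for (pk in seq_along(paths)) {
      pvox <- paths[[pk]]
      path_id <- path_id + 1L
      plen <- chord_length(pos[pvox, , drop = FALSE], chord_um)
      # 2 x mean centerline EDT: near-axis voxels read slightly under the
      # radius, the lattice reads slightly over; the two nearly cancel
      dia <- 2 * mean(dtv[pvox])
      all_records[[path_id]] <- data.frame(
        id = path_id, lacuna = parent_lac, length = plen,
        mean_diameter = dia, volume = sum(assign_path == pk) * vox_vol)
      all_skel[[path_id]] <- data.frame(
        path = path_id, x = pos[pvox, 1], y = pos[pvox, 2], z = pos[pvox, 3],
        diameter = 2 * dtv[pvox])
    }
  }
  records <- do.call(rbind, all_records)
  skel <- if (length(all_skel)) do.call(rbind, all_skel) else data.frame()
  list(records = records, skeleton = skel,
       summary = list(number = nrow(records),
                      mean_diameter = mean(records$mean_diameter),
                      mean_length = mean(records$length),
                      total_volume = sum(records$volume)))
}

# polyline length after resampling at ~chord_um spacing (removes the
# zig-zag of voxel-to-voxel steps)
chord_length <- function(P, chord_um = 0.5) {
  if (nrow(P) < 2) return(0)
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= chord_um) return(sqrt(sum((P[nrow(P), ] - P[1, ])^2)))
  n <- max(2L, ceiling(L / chord_um))
  s_at <- seq(0, L, length.out = n + 1L)
  Q <- apply(P, 2, function(col) approx(s, col, xout = s_at)$y)
  sum(sqrt(rowSums(diff(Q)^2)))
}

#' Layer-resolved 3D morphometry summaries
#'
#' Aggregates per-object 3D records into per-layer summaries ready for
#' group statistics. Layers are taken from a `layer` column when present
#' (phantom truth carries it), otherwise assigned from a
#' [partition_cortex()] by object centroid.
#'
#' @param records data frame of per-object measurements with numeric
#'   parameter columns and optionally `layer`, `group`, `specimen`.
#' @param partition optional [partition_cortex()] for centroid assignment.
#' @param parameters which numeric columns to summarize (default: all).
#' @return data frame, one row per layer (x specimen/group when present)
#'   with `n` and the per-parameter means; centroids outside all layers
#'   land in layer `"unassigned"`.
#' @export
layer_resolved_summary_3d <- function(records, partition = NULL,
                                      parameters = NULL) {
  if (is.null(records$layer)) {
    if (is.null(partition)) stop("records carry no layer and no partition given")
    records$layer <- assign_layer(partition,
                                  records[, c("centroid_x", "centroid_y")])
  }
  keys <- intersect(c("group", "specimen", "layer"), names(records))
  if (is.null(parameters))
    parameters <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                          c("id", "lacuna", "centroid_x", "centroid_y",
                            "centroid_z", "axis_x", "axis_y", "axis_z"))
  agg <- aggregate(records[parameters], records[keys], mean)
  cnt <- aggregate(list(n = records[[parameters[1]]]), records[keys], length)
  merge(cnt, agg, by = keys)
}
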