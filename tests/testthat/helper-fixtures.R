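# Fixture builders and independent oracles used across the suite.
# All geometry is constructed in code; nothing is read from disk.

# rasterized disk as a calibrated label map (single object)
raster_disk <- function(radius_um, px_um, pad_um = 4, center_jitter = c(0.3, 0.1),
                        intensity = NULL) {
  n <- ceiling(2 * (radius_um + pad_um) / px_um)
  cx <- n / 2 * px_um + center_jitter[1]
  cy <- n / 2 * px_um + center_jitter[2]
  xs <- (seq_len(n) - 0.5) * px_um
  m <- outer(xs, xs, function(x, y) (x - cx)^2 + (y - cy)^2 <= radius_um^2)
  if (!is.null(intensity)) {
    cal_image(m * intensity, px_um)
  } else {
    label_map(m + 0L, px_um)
  }
}

raster_square <- function(side_um, px_um, pad_px = 10) {
  a <- round(side_um / px_um)
  n <- a + 2L * pad_px
  m <- matrix(0L, n, n)
  m[pad_px + seq_len(a), pad_px + seq_len(a)] <- 1L
  label_map(m, px_um)
}

# rasterized rotated ellipse + its analytic descriptors (the oracle)
raster_ellipse_oracle <- function(a_um, b_um, theta, px_um, pad_um = 3) {
  n <- ceiling(2 * (a_um + pad_um) / px_um)
  c0 <- n / 2 * px_um
  xs <- (seq_len(n) - 0.5) * px_um
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  xr <- (X - c0) * cos(theta) + (Y - c0) * sin(theta)
  yr <- -(X - c0) * sin(theta) + (Y - c0) * cos(theta)
  m <- (xr / a_um)^2 + (yr / b_um)^2 <= 1
  # Ramanujan II approximation: exact to ~1e-9 for these aspect ratios
  h <- ((a_um - b_um) / (a_um + b_um))^2
  perim <- pi * (a_um + b_um) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  list(labels = label_map(m + 0L, px_um),
       area = pi * a_um * b_um, length = 2 * a_um, width = 2 * b_um,
       perimeter = perim)
}

# digitized sphere / cube / axis-aligned ellipsoid as 3D logical arrays
raster_sphere <- function(radius_um, vox_um, pad_um = 1) {
  n <- ceiling(2 * (radius_um + pad_um) / vox_um)
  cc <- n / 2 * vox_um + 0.23 * vox_um
  xs <- (seq_len(n) - 0.5) * vox_um
  g <- expand.grid(x = xs, y = xs, z = xs)
  m <- array((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2 <= radius_um^2,
             c(n, n, n))
  structure(m, pixel_size = rep(vox_um, 3))
}

raster_cube <- function(side_um, vox_um, pad_vox = 8) {
  a <- round(side_um / vox_um)
  n <- a + 2L * pad_vox
  m <- array(FALSE, c(n, n, n))
  m[pad_vox + seq_len(a), pad_vox + seq_len(a), pad_vox + seq_len(a)] <- TRUE
  structure(m, pixel_size = rep(vox_um, 3))
}

raster_ellipsoid <- function(semi_um, vox_um, pad_um = 1) {
  n <- ceiling(2 * (max(semi_um) + pad_um) / vox_um)
  cc <- n / 2 * vox_um
  xs <- (seq_len(n) - 0.5) * vox_um
  g <- expand.grid(x = xs, y = xs, z = xs)
  m <- array(((g$x - cc) / semi_um[1])^2 + ((g$y - cc) / semi_um[2])^2 +
               ((g$z - cc) / semi_um[3])^2 <= 1, c(n, n, n))
  structure(m, pixel_size = rep(vox_um, 3))
}

# capsule mask: cylinder of given diameter between two points, in a box
raster_tube <- function(p0, p1, diameter_um, dims, vox_um) {
  xs <- (seq_len(dims[1]) - 0.5) * vox_um
  ys <- (seq_len(dims[2]) - 0.5) * vox_um
  zs <- (seq_len(dims[3]) - 0.5) * vox_um
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- p1 - p0; vv <- sum(v^2)
  t <- pmin(pmax(((g$x - p0[1]) * v[1] + (g$y - p0[2]) * v[2] +
                    (g$z - p0[3]) * v[3]) / vv, 0), 1)
  d2 <- (g$x - (p0[1] + t * v[1]))^2 + (g$y - (p0[2] + t * v[2]))^2 +
    (g$z - (p0[3] + t * v[3]))^2
  array(d2 <= (diameter_um / 2)^2, dims)
}

# sphere at `center` with tubes radiating along unit directions `dirs`
sphere_with_tubes <- function(center, radius_um, dirs, lengths_um,
                              diameters_um, dims, vox_um) {
  xs <- (seq_len(dims[1]) - 0.5) * vox_um
  ys <- (seq_len(dims[2]) - 0.5) * vox_um
  zs <- (seq_len(dims[3]) - 0.5) * vox_um
  g <- expand.grid(x = xs, y = ys, z = zs)
  sph <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <=
    radius_um^2
  m <- array(sph, dims)
  lac <- structure(array(as.integer(m), dims), pixel_size = rep(vox_um, 3))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ] / sqrt(sum(dirs[k, ]^2))
    p0 <- center + d * radius_um
    p1 <- p0 + d * lengths_um[k]
    m <- m | raster_tube(p0, p1, diameters_um[k], dims, vox_um)
  }
  structure(m, pixel_size = rep(vox_um, 3))
}

# ideal annulus mask (bone ring) in pixels
annulus_mask <- function(r_out, r_in, px, n = NULL) {
  if (is.null(n)) n <- ceiling(2.4 * r_out / px)
  cc <- n / 2 * px
  xs <- (seq_len(n) - 0.5) * px
  R2 <- outer(xs, xs, function(x, y) (x - cc)^2 + (y - cc)^2)
  structure((R2 <= r_out^2) & (R2 > r_in^2), pixel_size = c(px, px))
}

# quick small 2D phantom spec used in several tests: a thin annulus, so
# canals and calcein sectors are scaled down with it
small_spec <- function(seed = 1, ...) {
  args <- modifyList(
    list(canal_params = list(radius_mean = 5, radius_sd = 1),
         calcein_params = list(n_sectors = 8)),
    list(...))
  do.call(phantom_spec,
          c(list(image_shape = c(400, 400),
                 geometry = list(outer_radius = 110, inner_radius = 58,
                                 waviness_amp = 2),
                 seed = seed), args))
}
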