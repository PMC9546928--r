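#' Treatment-effect profile for phantom generation
#'
#' Multiplicative effects a dosing regimen exerts on the generated anatomy.
#' The control profile is the all-ones identity. Per-layer multipliers may be
#' given as a named vector over `c("inner", "haversian", "outer")`; scalars
#' are recycled to all layers.
#'
#' @param lacuna_volume multiplier on lacuna volume (2D: area), per layer.
#' @param canaliculus_diameter multiplier on canalicular diameter, per layer.
#' @param canal_area multiplier on Haversian canal cross-section area.
#' @param porosity_rate multiplier on cortical pore density / area fraction.
#' @param endosteal_band_width µm of naive new bone added at the endosteal
#'   surface (shifts the marrow boundary inward).
#' @param multi_label_prob probability that an endosteal surface sector is
#'   multiple-labelled (three calcein bands), emulating the phenotype seen
#'   only under daily dosing.
#' @return object of class `effect_profile`.
#' @export
effect_profile <- function(lacuna_volume = 1, canaliculus_diameter = 1,
                           canal_area = 1, porosity_rate = 1,
                           endosteal_band_width = 0, multi_label_prob = 0) {
  layer_vec <- function(x) {
    layers <- c("inner", "haversian", "outer")
    if (is.null(names(x))) return(setNames(rep_len(x, 3L), layers))
    out <- setNames(rep(1, 3), layers)
    out[names(x)] <- x
    out
  }
  p <- list(lacuna_volume = layer_vec(lacuna_volume),
            canaliculus_diameter = layer_vec(canaliculus_diameter),
            canal_area = canal_area,
            porosity_rate = porosity_rate,
            endosteal_band_width = endosteal_band_width,
            multi_label_prob = multi_label_prob)
  if (any(unlist(p[1:4]) <= 0)) stop("effect multipliers must be > 0")
  if (endosteal_band_width < 0 || multi_label_prob < 0 || multi_label_prob > 1)
    stop("invalid effect profile")
  structure(p, class = "effect_profile")
}

#' Parametric description of one synthetic bone section or stack
#'
#' Defines the full generative model of a Villanueva-type fluorescence
#' phantom: a cortical annulus (or an intracortical block) populated with
#' ellipse/ellipsoid lacunae, tubular canaliculi, clustered Haversian canals,
#' irregular cortical pores, and endosteal/periosteal calcein bands, rendered
#' over an autofluorescence background with blur and noise. The seed fixes
#' the image and its ground truth bit-exactly.
#'
#' Lacunar density and absolute size distributions are configurable
#' order-of-magnitude presets (cortical lacunar densities of several hundred
#' per mm² and ~9 x 4 µm section profiles are typical of lagomorph cortex);
#' every default can be overridden per study.
#'
#' @param image_shape pixels per axis; length 2 (section) or 3 (stack).
#' @param pixel_size µm per pixel per axis (recycled; anisotropy allowed).
#' @param bit_depth 8 (wide-field sections) or 12 (confocal stacks).
#' @param geometry list: `type` ("annulus" or "block"), `outer_radius`,
#'   `inner_radius` (µm), `waviness_amp` (µm), `waviness_modes`.
#' @param layer_fractions named fractions of cortical thickness assigned to
#'   the inner (endosteal) and outer (periosteal) lamellae; must sum < 1.
#' @param lacuna_params list: `density` (mm^-2 or mm^-3), `semiaxes_mean`,
#'   `semiaxes_sd` (µm), `orientation_kappa`, optional `explicit` data frame
#'   of fixed lacunae (columns cx, cy[, cz], a, b[, c][, theta | ax, ay, az]).
#' @param canaliculi_params list: `per_lacuna`, `diameter_mean`,
#'   `diameter_sd`, `length_mean`, `length_sd` (µm), `curvature`
#'   (rad per µm of direction wobble), optional `explicit` data frame
#'   (columns lacuna, dx, dy, dz, length, diameter).
#' @param canal_params list: `density` (mm^-2 of the Haversian band),
#'   `radius_mean`, `radius_sd` (µm), `clustering` in `[0,1]`.
#' @param pore_params list: `density` (mm^-2), `radius` (µm), `roughness`
#'   (relative boundary amplitude), optional `area_fraction` of bone area
#'   which overrides `density`.
#' @param calcein_params list: `band_offset`, `band_spacing`, `band_width`
#'   (µm), `p_class` named probabilities over Q/E/sL/dL/mL sectors,
#'   `n_sectors` per surface, `persistence` (probability a sector repeats its
#'   neighbour's class), `pore_label_prob` (calcein-rimmed voids).
#' @param noise_params list of rendering levels in native gray values:
#'   `background`, `bone_level`, `object_level`, `lacuna_level`,
#'   `calcein_level`, `noise_sd`, `blur_sigma` (µm), `gradient`.
#' @param effect an [effect_profile()].
#' @param seed integer seed fixing geometry and rendering.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(640, 640),
                         pixel_size = 0.64,
                         bit_depth = 8L,
                         geometry = list(),
                         layer_fractions = c(inner = 0.25, outer = 0.25),
                         lacuna_params = list(),
                         canaliculi_params = list(),
                         canal_params = list(),
                         pore_params = list(),
                         calcein_params = list(),
                         noise_params = list(),
                         effect = effect_profile(),
                         seed = 1L) {
  nd <- length(image_shape)
  stopifnot(nd %in% c(2L, 3L))
  merge_defaults <- function(x, d) { d[names(x)] <- x; d }
  geometry <- merge_defaults(geometry, list(
    type = "annulus", outer_radius = 180, inner_radius = 95,
    waviness_amp = 3, waviness_modes = 3))
  lacuna_params <- merge_defaults(lacuna_params, list(
    density = if (nd == 2L) 800 else 5e4,
    semiaxes_mean = if (nd == 2L) c(4.5, 2.1) else c(4.5, 2.2, 1.9),
    semiaxes_sd = if (nd == 2L) c(0.7, 0.35) else c(0.7, 0.35, 0.3),
    orientation_kappa = 8, explicit = NULL))
  canaliculi_params <- merge_defaults(canaliculi_params, list(
    per_lacuna = if (nd == 2L) 0 else 6,
    diameter_mean = 0.5, diameter_sd = 0.08,
    length_mean = 15, length_sd = 4, curvature = 0.05, explicit = NULL))
  canal_params <- merge_defaults(canal_params, list(
    density = 280, radius_mean = 11, radius_sd = 2.5, clustering = 0.5))
  pore_params <- merge_defaults(pore_params, list(
    density = 25, radius = 18, roughness = 0.12, area_fraction = NULL))
  calcein_params <- merge_defaults(calcein_params, list(
    band_offset = 2.0, band_spacing = 4.2, band_width = 3,
    p_class = c(Q = 0.40, E = 0.18, sL = 0.25, dL = 0.17, mL = 0),
    n_sectors = 12, persistence = 0.7, pore_label_prob = 0.3))
  noise_params <- merge_defaults(noise_params, list(
    background = if (nd == 2L) 3 else 150,
    bone_level = if (nd == 2L) 9 else 400,
    object_level = if (nd == 2L) 30 else 2200,
    lacuna_level = if (nd == 2L) 60 else 2500,
    calcein_level = 250,
    noise_sd = if (nd == 2L) 1.5 else 60,
    blur_sigma = if (nd == 2L) 0.5 else 0.12,
    gradient = if (nd == 2L) 1.5 else 0))

  f_in <- layer_fractions[["inner"]]; f_out <- layer_fractions[["outer"]]
  if (f_in <= 0 || f_out <= 0 || f_in + f_out >= 1)
    stop("layer_fractions must be positive and sum to < 1")
  pos <- c(lacuna_params$density, unlist(lacuna_params$semiaxes_mean),
           canaliculi_params$diameter_mean, canaliculi_params$length_mean,
           canal_params$density, canal_params$radius_mean,
           pore_params$density, pore_params$radius)
  if (any(pos < 0)) stop("densities and sizes must be non-negative")
  stopifnot(inherits(effect, "effect_profile"))

  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = rep_len(as.numeric(pixel_size), nd),
                 bit_depth = as.integer(bit_depth),
                 geometry = geometry,
                 layer_fractions = c(inner = f_in, outer = f_out),
                 lacuna_params = lacuna_params,
                 canaliculi_params = canaliculi_params,
                 canal_params = canal_params,
                 pore_params = pore_params,
                 calcein_params = calcein_params,
                 noise_params = noise_params,
                 effect = effect,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param ... overrides passed to [phantom_spec()].
#' @details `phantom_spec_3d()` supplies confocal-stack defaults: a
#'   0.1 x 0.1 x 0.1 µm voxel block of mineralized matrix populated with
#'   ellipsoid lacunae and tubular canaliculi at 12-bit depth.
#' @export
phantom_spec_3d <- function(image_shape = c(160, 160, 64), pixel_size = 0.1,
                            bit_depth = 12L, ...) {
  phantom_spec(image_shape = image_shape, pixel_size = pixel_size,
               bit_depth = bit_depth, geometry = list(type = "block"), ...)
}

# ---- internal geometry sampling -------------------------------------------

# wavy radius function r(theta) = r0 * (1 + sum a_k cos(k theta + phi_k))
sample_radius_fun <- function(r0, amp, modes) {
  if (amp <= 0 || modes < 1) {
    coef <- NULL
  } else {
    k <- seq_len(modes) + 1L   # start at mode 2: keeps the ring centred
    a <- runif(modes, 0.3, 1); a <- a / sum(a) * amp / r0
    phi <- runif(modes, 0, 2 * pi)
    coef <- list(k = k, a = a, phi = phi)
  }
  force(r0)
  function(theta) {
    r <- rep(r0, length(theta))
    if (!is.null(coef))
      for (i in seq_along(coef$k))
        r <- r + r0 * coef$a[i] * cos(coef$k[i] * theta + coef$phi[i])
    r
  }
}

# add a scalloped (eroded) local perturbation to a radius function within
# [t0, t1]; sign +1 pushes outward, -1 inward
scallop_fun <- function(rfun, t0, t1, amp, wavelength_um, r_ref, sign) {
  force(rfun); force(t0); force(t1); force(amp); force(sign)
  kw <- 2 * pi * r_ref / wavelength_um  # angular frequency of scallops
  phase <- runif(1, 0, 2 * pi)
  function(theta) {
    r <- rfun(theta)
    th <- theta %% (2 * pi)
    inside <- (th - t0) %% (2 * pi) < (t1 - t0) %% (2 * pi)
    if (any(inside)) {
      u <- ((th[inside] - t0) %% (2 * pi)) / ((t1 - t0) %% (2 * pi))
      win <- pmin(1, sin(pi * u) * 3)          # near-flat top, smooth onset
      r[inside] <- r[inside] +
        sign * amp * win * abs(sin(kw * th[inside] / 2 + phase))
    }
    r
  }
}

layer_names <- c("inner", "haversian", "outer")

# sample surface sector classes with spatial persistence; labelling fronts
# are contiguous, so isolated single-sector runs are absorbed into their
# left neighbour, and multiple-label promotion covers sector pairs
sample_sector_classes <- function(n, p_class, persistence, multi_prob = 0) {
  cls <- character(n)
  draw <- function() sample(names(p_class), 1L, prob = p_class)
  cls[1] <- draw()
  for (i in seq_len(n)[-1])
    cls[i] <- if (runif(1) < persistence) cls[i - 1] else draw()
  if (n >= 3) {
    r <- rle(cls)
    if (length(r$lengths) > 1) {
      singles <- which(r$lengths == 1)
      for (k in singles) r$values[k] <- r$values[if (k > 1) k - 1 else 2]
      cls <- inverse.rle(r)
    }
  }
  if (multi_prob > 0) {
    promote <- which(runif(n) < multi_prob)
    promote <- unique(c(promote, pmin(promote + 1L, n)))
    cls[promote] <- "mL"
  }
  cls
}

n_bands_of <- c(Q = 0L, E = 0L, sL = 1L, dL = 2L, mL = 3L)

sample_geometry_2d <- function(spec) {
  set.seed(spec$seed)
  g <- spec$geometry
  eff <- spec$effect
  shp <- spec$image_shape; px <- spec$pixel_size
  field <- shp * px
  if (g$type == "block") {
    geom <- list(type = "block", field = field)
  } else {
    r_out_f <- sample_radius_fun(g$outer_radius, g$waviness_amp, g$waviness_modes)
    r_in_f <- sample_radius_fun(g$inner_radius, g$waviness_amp, g$waviness_modes)
    # endosteal new-bone band: marrow boundary moves inward
    if (eff$endosteal_band_width > 0) {
      base_in <- r_in_f
      w <- eff$endosteal_band_width
      r_in_f <- function(theta) base_in(theta) - w
    }
    if (2 * (g$outer_radius + g$waviness_amp) > min(field))
      stop("annulus does not fit inside the image")
    geom <- list(type = "annulus", r_out_f = r_out_f, r_in_f = r_in_f,
                 center = field / 2)
  }
  thick <- if (g$type == "annulus") g$outer_radius - g$inner_radius else min(field)
  f_in <- spec$layer_fractions[["inner"]]
  f_out <- spec$layer_fractions[["outer"]]
  band_thick <- c(inner = f_in, haversian = 1 - f_in - f_out, outer = f_out) * thick
  lp <- spec$lacuna_params
  if (2 * (lp$semiaxes_mean[1] + 2 * lp$semiaxes_sd[1]) > min(band_thick) &&
      g$type == "annulus")
    stop("impossible geometry: lacuna size exceeds layer thickness")
  cp <- spec$canal_params
  if (2 * (cp$radius_mean + 2 * cp$radius_sd) > band_thick[["haversian"]] &&
      g$type == "annulus" && cp$density > 0)
    stop("impossible geometry: canal size exceeds layer thickness")

  # --- surface classes (sampled before masks: eroded sectors reshape the ring)
  surfaces <- NULL
  if (geom$type == "annulus") {
    csp <- spec$calcein_params
    ns <- csp$n_sectors
    mk_surface <- function(which_surface, multi_prob) {
      cls <- sample_sector_classes(ns, csp$p_class, csp$persistence, multi_prob)
      t0 <- seq(0, 2 * pi, length.out = ns + 1L)[-(ns + 1L)]
      data.frame(surface = which_surface, sector = seq_len(ns),
                 theta0 = t0, theta1 = t0 + 2 * pi / ns,
                 class = cls, n_bands = n_bands_of[cls],
                 stringsAsFactors = FALSE)
    }
    endo <- mk_surface("endosteal", eff$multi_label_prob)
    peri <- mk_surface("periosteal", 0)
    # scallop eroded sectors
    for (i in which(endo$class == "E"))
      geom$r_in_f <- scallop_fun(geom$r_in_f, endo$theta0[i], endo$theta1[i],
                                 amp = 2.5, wavelength_um = 14,
                                 r_ref = g$inner_radius, sign = +1)
    for (i in which(peri$class == "E"))
      geom$r_out_f <- scallop_fun(geom$r_out_f, peri$theta0[i], peri$theta1[i],
                                  amp = 2.5, wavelength_um = 14,
                                  r_ref = g$outer_radius, sign = -1)
    surfaces <- rbind(endo, peri)
  }

  # approximate bone area for densities (annulus: analytic; block: full field)
  bone_area_um2 <- if (geom$type == "annulus") {
    th <- seq(0, 2 * pi, length.out = 721L)[-721L]
    sum((geom$r_out_f(th)^2 - geom$r_in_f(th)^2) / 2) * (2 * pi / 720)
  } else prod(field)
  bone_area_mm2 <- bone_area_um2 / 1e6

  # helper: radial position -> xy, plus layer of a radial coordinate u
  u_of <- function(u) {
    brk <- c(0, f_in, 1 - f_out, 1)
    layer_names[findInterval(pmin(pmax(u, 0), 1 - 1e-9), brk,
                             rightmost.closed = TRUE)]
  }
  sample_in_cortex <- function(n, u_range = c(0, 1), margin_um = 0) {
    if (n == 0L) return(NULL)
    th <- runif(n, 0, 2 * pi)
    if (geom$type == "annulus") {
      rin <- geom$r_in_f(th); rout <- geom$r_out_f(th)
      lo <- pmax(u_range[1], margin_um / (rout - rin))
      hi <- pmin(u_range[2], 1 - margin_um / (rout - rin))
      u <- runif(n, lo, hi)
      r <- rin + u * (rout - rin)
      data.frame(cx = geom$center[1] + r * cos(th),
                 cy = geom$center[2] + r * sin(th),
                 u = u, layer = u_of(u), stringsAsFactors = FALSE)
    } else {
      data.frame(cx = runif(n, margin_um, field[1] - margin_um),
                 cy = runif(n, margin_um, field[2] - margin_um),
                 u = runif(n), layer = sample(layer_names, n, replace = TRUE,
                                              prob = c(f_in, 1 - f_in - f_out, f_out)),
                 stringsAsFactors = FALSE)
    }
  }

  # --- pores (irregular, mid-cortical) --------------------------------------
  pp <- spec$pore_params
  target_frac <- pp$area_fraction
  pore_rate <- eff$porosity_rate
  pores <- NULL
  if (!is.null(target_frac)) {
    target <- target_frac * pore_rate * bone_area_um2
    n_pore <- max(1L, round(target / (pi * pp$radius^2)))
    pore_r0 <- sqrt(target / (n_pore * pi))
  } else {
    n_pore <- rpois(1, pp$density * pore_rate * bone_area_mm2)
    pore_r0 <- pp$radius
  }
  if (n_pore > 0) {
    centers <- accept_centers(sample_in_cortex(6L * n_pore, c(0.15, 0.85),
                                               margin_um = pore_r0 * 1.15 + 2),
                              min_dist = 2.3 * pore_r0, n_keep = n_pore)
    if (!is.null(centers) && nrow(centers) > 0) {
      pores <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
        bf <- sample_boundary_fourier(pp$roughness)
        data.frame(id = i, cx = centers$cx[i], cy = centers$cy[i],
                   r0 = pore_r0, layer = centers$layer[i],
                   stringsAsFactors = FALSE)
      }))
      pores$shape <- lapply(seq_len(nrow(pores)),
                            function(i) sample_boundary_fourier(pp$roughness))
      # analytic polygon area of each pore boundary
      pores$area <- vapply(seq_len(nrow(pores)), function(i) {
        th <- seq(0, 2 * pi, length.out = 361L)[-361L]
        r <- pores$r0[i] * pores$shape[[i]](th)
        polygon_area(r * cos(th), r * sin(th))
      }, numeric(1))
    }
  }

  # --- Haversian canals (clustered, mid band) -------------------------------
  canals <- NULL
  if (cp$density > 0) {
    band_area_mm2 <- bone_area_mm2 * (1 - f_in - f_out)
    n_canal <- rpois(1, cp$density * band_area_mm2)
    if (n_canal > 0) {
      n_cl <- max(1L, round(n_canal * cp$clustering / 2))
      cl_centers <- sample_in_cortex(n_cl, c(0.3, 0.7), margin_um = 20)
      pick <- sample.int(n_cl, n_canal, replace = TRUE)
      cand <- data.frame(
        cx = cl_centers$cx[pick] + rnorm(n_canal, 0, 10),
        cy = cl_centers$cy[pick] + rnorm(n_canal, 0, 10))
      # keep those still inside the Haversian band, away from pores
      keep <- in_band(cand, geom, f_in, f_out, margin_u = 0.04)
      if (!is.null(pores) && nrow(pores) > 0)
        keep <- keep & apply(cand, 1, function(p)
          all(sqrt((p[1] - pores$cx)^2 + (p[2] - pores$cy)^2) >
                pores$r0 * 1.4 + cp$radius_mean))
      cand <- cand[keep, , drop = FALSE]
      cand <- accept_centers(cand, min_dist = 2.4 * cp$radius_mean)
      if (!is.null(cand) && nrow(cand) > 0) {
        r <- pmax(3, rnorm(nrow(cand), cp$radius_mean, cp$radius_sd)) *
          sqrt(eff$canal_area)
        canals <- data.frame(id = seq_len(nrow(cand)), cx = cand$cx,
                             cy = cand$cy, radius = r, area = pi * r^2,
                             layer = "haversian", stringsAsFactors = FALSE)
      }
    }
  }

  # --- lacunae --------------------------------------------------------------
  lacunae <- NULL
  if (!is.null(lp$explicit)) {
    lacunae <- lp$explicit
    lacunae$id <- seq_len(nrow(lacunae))
    if (is.null(lacunae$layer)) lacunae$layer <- "haversian"
    lacunae$area <- pi * lacunae$a * lacunae$b
  } else if (lp$density > 0) {
    n_lac <- rpois(1, lp$density * bone_area_mm2)
    if (n_lac > 0) {
      cand <- sample_in_cortex(3L * n_lac, margin_um = lp$semiaxes_mean[1] + 1)
      # keep clear of canals and pores
      if (!is.null(canals) && nrow(canals) > 0)
        cand <- cand[apply(cand[, c("cx", "cy")], 1, function(p)
          all(sqrt((p[1] - canals$cx)^2 + (p[2] - canals$cy)^2) >
                canals$radius + lp$semiaxes_mean[1] + 2)), , drop = FALSE]
      if (!is.null(pores) && nrow(pores) > 0)
        cand <- cand[apply(cand[, c("cx", "cy")], 1, function(p)
          all(sqrt((p[1] - pores$cx)^2 + (p[2] - pores$cy)^2) >
                pores$r0 * 1.4 + lp$semiaxes_mean[1] + 2)), , drop = FALSE]
      cand <- accept_centers(cand, min_dist = 2.6 * lp$semiaxes_mean[1],
                             n_keep = n_lac)
      if (!is.null(cand) && nrow(cand) > 0) {
        n <- nrow(cand)
        mult <- spec$effect$lacuna_volume[cand$layer]   # 2D: area multiplier
        a <- pmax(0.8, rnorm(n, lp$semiaxes_mean[1], lp$semiaxes_sd[1])) * sqrt(mult)
        b <- pmax(0.5, rnorm(n, lp$semiaxes_mean[2], lp$semiaxes_sd[2])) * sqrt(mult)
        # tangential preferred orientation with von Mises-like wobble
        th_c <- if (geom$type == "annulus")
          atan2(cand$cy - geom$center[2], cand$cx - geom$center[1]) + pi / 2
        else runif(n, 0, pi)
        theta <- th_c + rnorm(n, 0, 1 / sqrt(lp$orientation_kappa))
        lacunae <- data.frame(id = seq_len(n), cx = cand$cx, cy = cand$cy,
                              a = a, b = pmin(b, a), theta = theta,
                              layer = cand$layer, area = pi * a * pmin(b, a),
                              brightness = runif(n, 0.65, 1.35),
                              stringsAsFactors = FALSE)
      }
    }
  }

  # --- pore calcein rims ----------------------------------------------------
  if (!is.null(pores) && nrow(pores) > 0) {
    pores$labeled <- runif(nrow(pores)) < spec$calcein_params$pore_label_prob
  }

  list(geom = geom, surfaces = surfaces, lacunae = lacunae, canals = canals,
       pores = pores, bone_area_um2 = bone_area_um2,
       band_thick = band_thick)
}

# reject candidate centers closer than min_dist to an accepted one
accept_centers <- function(cand, min_dist, n_keep = Inf) {
  if (is.null(cand) || nrow(cand) == 0) return(cand)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= n_keep) break
    ok <- TRUE
    if (length(keep) > 0) {
      d <- sqrt((cand$cx[i] - cand$cx[keep])^2 + (cand$cy[i] - cand$cy[keep])^2)
      ok <- all(d >= min_dist)
    }
    if (ok) keep <- c(keep, i)
  }
  cand[keep, , drop = FALSE]
}

in_band <- function(pts, geom, f_in, f_out, margin_u = 0) {
  if (geom$type != "annulus") return(rep(TRUE, nrow(pts)))
  th <- atan2(pts$cy - geom$center[2], pts$cx - geom$center[1])
  r <- sqrt((pts$cx - geom$center[1])^2 + (pts$cy - geom$center[2])^2)
  u <- (r - geom$r_in_f(th)) / (geom$r_out_f(th) - geom$r_in_f(th))
  u > f_in + margin_u & u < 1 - f_out - margin_u
}

# normalized rough-boundary multiplier m(theta), mean ~1
sample_boundary_fourier <- function(roughness, modes = 4:9) {
  a <- runif(length(modes)) ; a <- a / sqrt(sum(a^2)) * roughness
  phi <- runif(length(modes), 0, 2 * pi)
  function(theta) {
    m <- rep(1, length(theta))
    for (i in seq_along(modes)) m <- m + a[i] * cos(modes[i] * theta + phi[i])
    m
  }
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# ---- internal 2D rendering -------------------------------------------------

render_section_2d <- function(geomtruth, spec) {
  shp <- spec$image_shape; px <- spec$pixel_size
  nx <- shp[1]; ny <- shp[2]
  xs <- (seq_len(nx) - 0.5) * px[1]
  ys <- (seq_len(ny) - 0.5) * px[2]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  geom <- geomtruth$geom

  if (geom$type == "annulus") {
    TH <- atan2(Y - geom$center[2], X - geom$center[1])
    R <- sqrt((X - geom$center[1])^2 + (Y - geom$center[2])^2)
    r_in <- geom$r_in_f(TH); r_out <- geom$r_out_f(TH)
    solid <- R <= r_out
    marrow <- R < r_in
    bone <- solid & !marrow
    u <- (R - r_in) / (r_out - r_in)
    f_in <- spec$layer_fractions[["inner"]]
    f_out <- spec$layer_fractions[["outer"]]
    layers <- array(0L, dim(bone))
    layers[bone & u < f_in] <- 1L
    layers[bone & u >= f_in & u <= 1 - f_out] <- 2L
    layers[bone & u > 1 - f_out] <- 3L
  } else {
    bone <- matrix(TRUE, nx, ny)
    marrow <- matrix(FALSE, nx, ny)
    layers <- matrix(2L, nx, ny)
    TH <- R <- NULL
  }

  lab0 <- function() array(0L, c(nx, ny))
  lac_lab <- lab0(); can_lab <- lab0(); pore_lab <- lab0()
  calcein <- matrix(FALSE, nx, ny)

  rast_ellipse <- function(cx, cy, a, b, theta) {
    i0 <- max(1L, floor((cx - a) / px[1])); i1 <- min(nx, ceiling((cx + a) / px[1]) + 1L)
    j0 <- max(1L, floor((cy - a) / px[2])); j1 <- min(ny, ceiling((cy + a) / px[2]) + 1L)
    if (i0 > i1 || j0 > j1) return(NULL)
    xi <- xs[i0:i1]; yj <- ys[j0:j1]
    dx <- outer(xi - cx, rep(1, length(yj)))
    dy <- outer(rep(1, length(xi)), yj - cy)
    xr <- dx * cos(theta) + dy * sin(theta)
    yr <- -dx * sin(theta) + dy * cos(theta)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    list(i = i0:i1, j = j0:j1, inside = inside)
  }

  if (!is.null(geomtruth$lacunae))
    for (k in seq_len(nrow(geomtruth$lacunae))) {
      L <- geomtruth$lacunae[k, ]
      e <- rast_ellipse(L$cx, L$cy, L$a, L$b, L$theta)
      if (!is.null(e)) {
        sub <- lac_lab[e$i, e$j]
        sub[e$inside & sub == 0L] <- L$id
        lac_lab[e$i, e$j] <- sub
      }
    }
  if (!is.null(geomtruth$canals))
    for (k in seq_len(nrow(geomtruth$canals))) {
      C <- geomtruth$canals[k, ]
      e <- rast_ellipse(C$cx, C$cy, C$radius, C$radius, 0)
      if (!is.null(e)) {
        sub <- can_lab[e$i, e$j]
        sub[e$inside & sub == 0L] <- C$id
        can_lab[e$i, e$j] <- sub
      }
    }
  if (!is.null(geomtruth$pores) && nrow(geomtruth$pores) > 0)
    for (k in seq_len(nrow(geomtruth$pores))) {
      P <- geomtruth$pores[k, ]
      rmax <- P$r0 * 1.4
      i0 <- max(1L, floor((P$cx - rmax) / px[1]))
      i1 <- min(nx, ceiling((P$cx + rmax) / px[1]) + 1L)
      j0 <- max(1L, floor((P$cy - rmax) / px[2]))
      j1 <- min(ny, ceiling((P$cy + rmax) / px[2]) + 1L)
      xi <- xs[i0:i1]; yj <- ys[j0:j1]
      dx <- outer(xi - P$cx, rep(1, length(yj)))
      dy <- outer(rep(1, length(xi)), yj - P$cy)
      th <- atan2(dy, dx)
      rr <- sqrt(dx^2 + dy^2)
      shape <- geomtruth$pores$shape[[k]]
      inside <- rr <= P$r0 * shape(as.vector(th))
      sub <- pore_lab[i0:i1, j0:j1]
      sub[inside & sub == 0L] <- P$id
      pore_lab[i0:i1, j0:j1] <- sub
    }

  # calcein bands parallel to surfaces, per labelled sector
  if (!is.null(geomtruth$surfaces) && geom$type == "annulus") {
    csp <- spec$calcein_params
    for (k in seq_len(nrow(geomtruth$surfaces))) {
      S <- geomtruth$surfaces[k, ]
      if (S$n_bands == 0L) next
      th <- TH %% (2 * pi)
      in_sector <- (th - S$theta0) %% (2 * pi) < (S$theta1 - S$theta0) %% (2 * pi)
      depth <- if (S$surface == "endosteal") R - geom$r_in_f(TH)
               else geom$r_out_f(TH) - R
      for (bnum in seq_len(S$n_bands)) {
        o <- csp$band_offset + (bnum - 1) * csp$band_spacing
        band <- bone & in_sector & depth >= o - csp$band_width / 2 &
          depth <= o + csp$band_width / 2
        calcein[band] <- TRUE
      }
    }
    # calcein rims on labelled pores
    if (!is.null(geomtruth$pores) && nrow(geomtruth$pores) > 0) {
      for (k in which(geomtruth$pores$labeled)) {
        P <- geomtruth$pores[k, ]
        rmax <- P$r0 * 1.5 + 3
        i0 <- max(1L, floor((P$cx - rmax) / px[1]))
        i1 <- min(nx, ceiling((P$cx + rmax) / px[1]) + 1L)
        j0 <- max(1L, floor((P$cy - rmax) / px[2]))
        j1 <- min(ny, ceiling((P$cy + rmax) / px[2]) + 1L)
        xi <- xs[i0:i1]; yj <- ys[j0:j1]
        dx <- outer(xi - P$cx, rep(1, length(yj)))
        dy <- outer(rep(1, length(xi)), yj - P$cy)
        th <- atan2(dy, dx); rr <- sqrt(dx^2 + dy^2)
        rb <- P$r0 * geomtruth$pores$shape[[k]](as.vector(th))
        rim <- rr > rb & rr <= rb + 1.8
        sub <- calcein[i0:i1, j0:j1]
        sub[rim & bone[i0:i1, j0:j1]] <- TRUE
        calcein[i0:i1, j0:j1] <- sub
      }
    }
  }

  # ---- intensity rendering -------------------------------------------------
  np <- spec$noise_params
  img <- matrix(np$background, nx, ny) +
    np$gradient * (X / max(xs) - 0.5)
  img[bone] <- img[bone] + (np$bone_level - np$background)
  img[pore_lab > 0L | can_lab > 0L] <- np$object_level
  if (any(lac_lab > 0L)) {
    bri <- geomtruth$lacunae$brightness %||% rep(1, max(lac_lab))
    sel <- lac_lab > 0L
    img[sel] <- np$lacuna_level * bri[lac_lab[sel]]
  }
  img[calcein] <- np$calcein_level
  sig_px <- np$blur_sigma / mean(px)
  if (sig_px > 0.05)
    img <- gauss_smooth(img, sig_px)
  set.seed(spec$seed + 7777L)
  img <- img + rnorm(length(img), 0, np$noise_sd)
  img <- round(pmin(pmax(img, 0), 2^spec$bit_depth - 1))

  list(image = cal_image(img, px, spec$bit_depth),
       masks = list(bone = bone, marrow = marrow, layers = layers,
                    lacunae = label_map(lac_lab, px, "truth:lacunae"),
                    canals = label_map(can_lab, px, "truth:canals"),
                    pores = label_map(pore_lab, px, "truth:pores"),
                    calcein = calcein))
}

#' Generate a synthetic 2D cortical bone section with ground truth
#'
#' Renders one wide-field-like section phantom from a [phantom_spec()]:
#' rasterized geometry, Gaussian blur, background plus gradient, additive
#' noise, clipped to the configured bit depth. The returned truth is
#' consistent with the rendered geometry before noise.
#'
#' @param spec a [phantom_spec()] with a 2D `image_shape`.
#' @return list with elements `image` (a [cal_image]), `truth` (label masks,
#'   object tables, per-sector surface classes, scalar summaries).
#' @export
generate_section_2d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$image_shape) == 2L)
  geomtruth <- sample_geometry_2d(spec)
  rend <- render_section_2d(geomtruth, spec)
  truth <- list(masks = rend$masks,
                lacunae = strip_shape(geomtruth$lacunae),
                canals = geomtruth$canals,
                pores = strip_shape(geomtruth$pores),
                surfaces = geomtruth$surfaces,
                bone_area_um2 = sum(rend$masks$bone) * prod(spec$pixel_size),
                pore_area_um2 = sum(as_plain(rend$masks$pores) > 0L) *
                  prod(spec$pixel_size),
                spec = spec)
  list(image = rend$image, truth = truth)
}

strip_shape <- function(df) {
  if (is.null(df)) return(NULL)
  df$shape <- NULL
  df
}

# ---- 3D --------------------------------------------------------------------

sample_geometry_3d <- function(spec) {
  set.seed(spec$seed)
  shp <- spec$image_shape; px <- spec$pixel_size
  field <- shp * px
  vol_mm3 <- prod(field) / 1e9
  lp <- spec$lacuna_params; cnp <- spec$canaliculi_params
  eff <- spec$effect
  f_in <- spec$layer_fractions[["inner"]]
  f_out <- spec$layer_fractions[["outer"]]

  if (!is.null(lp$explicit)) {
    lac <- lp$explicit
    lac$id <- seq_len(nrow(lac))
    if (is.null(lac$layer)) lac$layer <- "haversian"
    if (is.null(lac$ax)) { lac$ax <- 1; lac$ay <- 0; lac$az <- 0 }
  } else {
    n <- rpois(1, lp$density * vol_mm3)
    lac <- NULL
    if (n > 0) {
      amax <- lp$semiaxes_mean[1] + 2
      cand <- data.frame(cx = runif(3 * n, amax, field[1] - amax),
                         cy = runif(3 * n, amax, field[2] - amax),
                         cz = runif(3 * n, amax, field[3] - amax))
      keep <- integer(0)
      for (i in seq_len(nrow(cand))) {
        if (length(keep) >= n) break
        ok <- TRUE
        if (length(keep) > 0) {
          d <- sqrt((cand$cx[i] - cand$cx[keep])^2 +
                    (cand$cy[i] - cand$cy[keep])^2 +
                    (cand$cz[i] - cand$cz[keep])^2)
          ok <- all(d >= 2.4 * lp$semiaxes_mean[1])
        }
        if (ok) keep <- c(keep, i)
      }
      cand <- cand[keep, , drop = FALSE]
      n <- nrow(cand)
      if (n > 0) {
        layer <- sample(layer_names, n, replace = TRUE,
                        prob = c(f_in, 1 - f_in - f_out, f_out))
        mult <- eff$lacuna_volume[layer]^(1 / 3)
        a <- pmax(1.2, rnorm(n, lp$semiaxes_mean[1], lp$semiaxes_sd[1])) * mult
        b <- pmax(0.8, rnorm(n, lp$semiaxes_mean[2], lp$semiaxes_sd[2])) * mult
        c3 <- pmax(0.7, rnorm(n, lp$semiaxes_mean[3], lp$semiaxes_sd[3])) * mult
        # principal axis concentrated around x (the osteon/long-bone axis)
        kap <- lp$orientation_kappa
        ax <- cbind(1 + rnorm(n, 0, 1 / sqrt(kap)),
                    rnorm(n, 0, 1 / sqrt(kap)),
                    rnorm(n, 0, 1 / sqrt(kap)))
        ax <- ax / sqrt(rowSums(ax^2))
        lac <- data.frame(id = seq_len(n), cx = cand$cx, cy = cand$cy,
                          cz = cand$cz, a = a, b = pmin(b, a),
                          c = pmin(c3, b, a),
                          ax = ax[, 1], ay = ax[, 2], az = ax[, 3],
                          layer = layer, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(lac)) {
    lac$volume <- 4 / 3 * pi * lac$a * lac$b * lac$c
  }

  canaliculi <- NULL; paths <- list()
  if (!is.null(lac) && nrow(lac) > 0) {
    mk_path <- function(x0, dirv, len, curv) {
      step <- 1.0
      nstep <- max(2L, ceiling(len / step))
      pts <- matrix(NA_real_, nstep + 1L, 3L)
      pts[1, ] <- x0
      d <- dirv / sqrt(sum(dirv^2))
      for (s in seq_len(nstep)) {
        d <- d + rnorm(3, 0, curv)
        d <- d / sqrt(sum(d^2))
        pts[s + 1L, ] <- pts[s, ] + d * (len / nstep)
      }
      pts
    }
    recs <- list()
    if (!is.null(cnp$explicit)) {
      ex <- cnp$explicit
      for (k in seq_len(nrow(ex))) {
        L <- lac[ex$lacuna[k], ]
        d <- c(ex$dx[k], ex$dy[k], ex$dz[k]); d <- d / sqrt(sum(d^2))
        # anchor on the ellipsoid surface along d (axis-aligned approximation)
        tsurf <- 1 / sqrt((d[1] / L$a)^2 + (d[2] / L$b)^2 + (d[3] / L$c)^2)
        x0 <- c(L$cx, L$cy, L$cz) + d * tsurf
        pts <- rbind(x0, x0 + d * ex$length[k])
        paths[[length(paths) + 1L]] <- pts
        recs[[length(recs) + 1L]] <- data.frame(
          id = length(recs) + 1L, lacuna = ex$lacuna[k],
          length = ex$length[k], diameter = ex$diameter[k])
      }
    } else if (cnp$per_lacuna > 0) {
      for (i in seq_len(nrow(lac))) {
        L <- lac[i, ]
        nc <- rpois(1, cnp$per_lacuna)
        if (nc == 0) next
        mult <- eff$canaliculus_diameter[[L$layer]]
        for (k in seq_len(nc)) {
          d <- rnorm(3); d <- d / sqrt(sum(d^2))
          tsurf <- 1 / sqrt((d[1] / L$a)^2 + (d[2] / L$b)^2 + (d[3] / L$c)^2)
          x0 <- c(L$cx, L$cy, L$cz) + d * tsurf
          len <- max(2, rnorm(1, cnp$length_mean, cnp$length_sd))
          dia <- max(0.2, rnorm(1, cnp$diameter_mean, cnp$diameter_sd)) * mult
          pts <- mk_path(x0, d, len, cnp$curvature)
          paths[[length(paths) + 1L]] <- pts
          recs[[length(recs) + 1L]] <- data.frame(
            id = length(recs) + 1L, lacuna = L$id,
            length = sum(sqrt(rowSums(diff(pts)^2))), diameter = dia)
        }
      }
    }
    if (length(recs) > 0) {
      canaliculi <- do.call(rbind, recs)
      canaliculi$layer <- lac$layer[canaliculi$lacuna]
      canaliculi$volume <- pi * (canaliculi$diameter / 2)^2 * canaliculi$length
    }
  }
  list(lacunae = lac, canaliculi = canaliculi, paths = paths, field = field)
}

render_stack_3d <- function(geomtruth, spec) {
  shp <- spec$image_shape; px <- spec$pixel_size
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  lac_lab <- array(0L, shp); can_lab <- array(0L, shp)
  xs <- (seq_len(nx) - 0.5) * px[1]
  ys <- (seq_len(ny) - 0.5) * px[2]
  zs <- (seq_len(nz) - 0.5) * px[3]
  lac <- geomtruth$lacunae

  if (!is.null(lac))
    for (k in seq_len(nrow(lac))) {
      L <- lac[k, ]
      rad <- L$a
      i <- which(xs >= L$cx - rad & xs <= L$cx + rad)
      j <- which(ys >= L$cy - rad & ys <= L$cy + rad)
      l <- which(zs >= L$cz - rad & zs <= L$cz + rad)
      if (!length(i) || !length(j) || !length(l)) next
      # rotation: principal axis -> (ax,ay,az); build orthonormal frame
      e1 <- c(L$ax, L$ay, L$az)
      ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      g <- expand.grid(x = xs[i] - L$cx, y = ys[j] - L$cy, z = zs[l] - L$cz)
      p1 <- g$x * e1[1] + g$y * e1[2] + g$z * e1[3]
      p2 <- g$x * e2[1] + g$y * e2[2] + g$z * e2[3]
      p3 <- g$x * e3[1] + g$y * e3[2] + g$z * e3[3]
      inside <- (p1 / L$a)^2 + (p2 / L$b)^2 + (p3 / L$c)^2 <= 1
      sub <- lac_lab[i, j, l]
      sub[inside & sub == 0L] <- L$id
      lac_lab[i, j, l] <- sub
    }

  if (length(geomtruth$paths) > 0) {
    can <- geomtruth$canaliculi
    for (k in seq_along(geomtruth$paths)) {
      pts <- geomtruth$paths[[k]]
      rad <- can$diameter[k] / 2
      for (s in seq_len(nrow(pts) - 1L)) {
        p <- pts[s, ]; q <- pts[s + 1L, ]
        lo <- pmin(p, q) - rad; hi <- pmax(p, q) + rad
        i <- which(xs >= lo[1] & xs <= hi[1])
        j <- which(ys >= lo[2] & ys <= hi[2])
        l <- which(zs >= lo[3] & zs <= hi[3])
        if (!length(i) || !length(j) || !length(l)) next
        g <- expand.grid(x = xs[i], y = ys[j], z = zs[l])
        v <- q - p; vv <- sum(v^2)
        t <- ((g$x - p[1]) * v[1] + (g$y - p[2]) * v[2] + (g$z - p[3]) * v[3]) / vv
        t <- pmin(pmax(t, 0), 1)
        d2 <- (g$x - (p[1] + t * v[1]))^2 + (g$y - (p[2] + t * v[2]))^2 +
          (g$z - (p[3] + t * v[3]))^2
        inside <- d2 <= rad^2
        sub <- can_lab[i, j, l]
        sel <- inside & sub == 0L & lac_lab[i, j, l] == 0L
        sub[sel] <- can$id[k]
        can_lab[i, j, l] <- sub
      }
    }
  }

  np <- spec$noise_params
  img <- array(np$background, shp)
  img[can_lab > 0L] <- np$object_level
  img[lac_lab > 0L] <- np$lacuna_level
  sig_vox <- np$blur_sigma / px
  if (any(sig_vox > 0.05)) img <- gauss_smooth(img, pmax(sig_vox, 0))
  set.seed(spec$seed + 7777L)
  img <- img + rnorm(length(img), 0, np$noise_sd)
  img <- round(pmin(pmax(img, 0), 2^spec$bit_depth - 1))
  dim(img) <- shp

  list(image = cal_image(img, px, spec$bit_depth),
       masks = list(lacunae = label_map(lac_lab, px, "truth:lacunae"),
                    canaliculi = label_map(can_lab, px, "truth:canaliculi")))
}

#' Generate a synthetic 3D confocal stack with ground truth
#'
#' Renders ellipsoid lacunae with attached tubular canaliculi into a
#' calibrated 3D stack. Truth records each canaliculus path, length and
#' diameter (generative values, exact by construction).
#'
#' @param spec a [phantom_spec()] with a 3D `image_shape`
#'   (see [phantom_spec_3d()]).
#' @return list with `image` (a [cal_image]) and `truth` (label maps and
#'   object tables for lacunae and canaliculi, plus the sampled paths).
#' @export
generate_stack_3d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$image_shape) == 3L)
  geomtruth <- sample_geometry_3d(spec)
  rend <- render_stack_3d(geomtruth, spec)
  list(image = rend$image,
       truth = list(masks = rend$masks, lacunae = geomtruth$lacunae,
                    canaliculi = geomtruth$canaliculi,
                    paths = geomtruth$paths, spec = spec))
}

#' Generate a seeded multi-group phantom cohort
#'
#' Produces `n_per_group` independent specimens for each treatment-effect
#' profile, with per-specimen seeds derived deterministically from the master
#' seed. With `render = "none"` only the geometry (ground-truth object
#' tables) is sampled — the tables are identical to those of a rendered
#' specimen with the same seed — which makes large statistical simulations
#' on cohort truth cheap.
#'
#' @param base_spec a [phantom_spec()] (2D or 3D).
#' @param group_effects named list of [effect_profile()]s; names are group
#'   ids (include a control identity profile).
#' @param n_per_group specimens per group (>= 2).
#' @param seed master seed.
#' @param render `"image"` (full rendering) or `"none"` (truth tables only).
#' @return list with `specimens` (list of per-specimen results carrying
#'   `group` and `specimen` ids) and `lacunae` (combined truth lacuna table
#'   across the cohort, when lacunae exist).
#' @export
generate_cohort <- function(base_spec, group_effects, n_per_group, seed = 1L,
                            render = c("image", "none")) {
  render <- match.arg(render)
  stopifnot(inherits(base_spec, "phantom_spec"), n_per_group >= 2,
            length(group_effects) >= 1, !is.null(names(group_effects)))
  set.seed(seed)
  n_total <- length(group_effects) * n_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  specimens <- list(); idx <- 0L
  is3d <- length(base_spec$image_shape) == 3L
  for (g in names(group_effects)) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sp <- base_spec
      sp$effect <- group_effects[[g]]
      sp$seed <- seeds[idx]
      res <- if (render == "none") {
        gt <- if (is3d) sample_geometry_3d(sp) else sample_geometry_2d(sp)
        list(truth = list(lacunae = strip_shape(gt$lacunae),
                          canaliculi = gt$canaliculi,
                          canals = gt$canals, pores = strip_shape(gt$pores),
                          surfaces = gt$surfaces, spec = sp))
      } else {
        if (is3d) generate_stack_3d(sp) else generate_section_2d(sp)
      }
      res$group <- g
      res$specimen <- sprintf("%s_%02d", g, i)
      specimens[[idx]] <- res
    }
  }
  lac_tables <- lapply(specimens, function(s) {
    t <- s$truth$lacunae
    if (is.null(t) || nrow(t) == 0) return(NULL)
    t$group <- s$group; t$specimen <- s$specimen
    t
  })
  lac_tables <- lac_tables[!vapply(lac_tables, is.null, logical(1))]
  can_tables <- lapply(specimens, function(s) {
    t <- s$truth$canaliculi
    if (is.null(t) || nrow(t) == 0) return(NULL)
    t$group <- s$group; t$specimen <- s$specimen
    t
  })
  can_tables <- can_tables[!vapply(can_tables, is.null, logical(1))]
  list(specimens = specimens,
       lacunae = if (length(lac_tables)) do.call(rbind, lac_tables) else NULL,
       canaliculi = if (length(can_tables)) do.call(rbind, can_tables) else NULL)
}

#' Generate a pool of small region-of-interest phantoms for classifier work
#'
#' Emits `n` block-type lacuna phantoms whose rendering conditions
#' (background, autofluorescence level, lacuna brightness, blur, noise) vary
#' from image to image, emulating section-to-section staining and exposure
#' variability. This variability is what makes recognition quality depend on
#' the number of training images.
#'
#' @param n number of phantoms.
#' @param seed master seed.
#' @param image_shape,pixel_size grid of each phantom (0.29 µm/px ROI scale).
#' @param density lacunae per mm².
#' @return list of `list(image, truth)` as from [generate_section_2d()].
#' @export
phantom_pool <- function(n, seed = 1L, image_shape = c(224, 224),
                         pixel_size = 0.29, density = 1200) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  bone_level <- runif(n, 4, 34)
  lev <- data.frame(background = pmax(1, bone_level - runif(n, 2, 8)),
                    bone_level = bone_level,
                    lacuna_level = bone_level + runif(n, 6, 40),
                    noise_sd = runif(n, 1.5, 4),
                    blur = runif(n, 0.35, 0.9),
                    gradient = runif(n, 0, 4))
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(image_shape = image_shape, pixel_size = pixel_size,
                       geometry = list(type = "block"),
                       lacuna_params = list(density = density),
                       canal_params = list(density = 0),
                       pore_params = list(density = 0),
                       noise_params = list(background = lev$background[i],
                                           bone_level = lev$bone_level[i],
                                           lacuna_level = lev$lacuna_level[i],
                                           noise_sd = lev$noise_sd[i],
                                           blur_sigma = lev$blur[i],
                                           gradient = lev$gradient[i]),
                       seed = seeds[i])
    generate_section_2d(sp)
  })
}
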