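#' Specification for a single short-axis slice phantom
#'
#' Describes a synthetic bSSFP-like short-axis slice: a bright blood pool of
#' base radius `cavity_radius` whose endocardial border is radially perturbed
#' by a band-limited random field, surrounded by darker myocardium on a dark
#' background, with optional papillary-muscle disks inside the pool and
#' additive noise. The perturbed border is
#' `radius(theta) = R * (1 + sum_k a_k cos(k theta + phi_k))` with
#' `a_k = trabecular_amplitude * k^(-roughness_exponent/2)` for
#' `k = 2 .. trabecular_count` and phases drawn from the seed, giving a
#' seedable family from smooth (fractal dimension 1) to highly convoluted
#' borders.
#'
#' @param image_size side of the square image in pixels.
#' @param pixel_spacing mm per pixel.
#' @param cavity_radius base cavity radius in mm.
#' @param trabecular_amplitude dimensionless radial perturbation scale (>= 0).
#' @param trabecular_count highest angular harmonic (integer >= 0).
#' @param roughness_exponent spectral decay in (0, 2]; smaller = rougher.
#' @param papillary_count number of papillary-muscle disks (integer >= 0).
#' @param wall_thickness myocardial wall thickness in mm.
#' @param pool_intensity,myo_intensity,background_intensity intensities in
#'   arbitrary units; must be strictly ordered pool > myo > background.
#' @param noise_sigma additive noise standard deviation (same units).
#' @param noise_model "gaussian" (default) or "rician" (magnitude image).
#' @param seed integer RNG seed.
#' @return an object of class `slice_phantom_spec`.
#' @export
slice_phantom_spec <- function(image_size = 256L, pixel_spacing = 1.4,
                               cavity_radius = 22, trabecular_amplitude = 0.06,
                               trabecular_count = 96L, roughness_exponent = 1,
                               papillary_count = 2L, wall_thickness = 10,
                               pool_intensity = 200, myo_intensity = 80,
                               background_intensity = 20, noise_sigma = 0,
                               noise_model = c("gaussian", "rician"),
                               seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(image_size = as.integer(image_size),
               pixel_spacing = pixel_spacing, cavity_radius = cavity_radius,
               trabecular_amplitude = trabecular_amplitude,
               trabecular_count = as.integer(trabecular_count),
               roughness_exponent = roughness_exponent,
               papillary_count = as.integer(papillary_count),
               wall_thickness = wall_thickness,
               pool_intensity = pool_intensity, myo_intensity = myo_intensity,
               background_intensity = background_intensity,
               noise_sigma = noise_sigma, noise_model = noise_model,
               seed = as.integer(seed))
  class(spec) <- "slice_phantom_spec"
  validate_slice_phantom_spec(spec)
  spec
}

validate_slice_phantom_spec <- function(spec) {
  with(spec, {
    if (trabecular_amplitude < 0) stop("trabecular_amplitude must be >= 0")
    if (roughness_exponent <= 0 || roughness_exponent > 2)
      stop("roughness_exponent must lie in (0, 2]")
    if (!(pool_intensity > myo_intensity && myo_intensity > background_intensity))
      stop("intensities must be strictly ordered pool > myo > background")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    # outermost extent (perturbed cavity + wall) must leave a >= 10% margin
    amp_max <- trabecular_amplitude * perturbation_sd_factor(spec) * 3
    r_max_px <- (cavity_radius * (1 + amp_max) + wall_thickness) / pixel_spacing
    if (r_max_px > 0.45 * image_size)
      stop("cavity (plus wall) exceeds image bounds: reduce cavity_radius or ",
           "increase image_size")
  })
  invisible(spec)
}

# sd multiplier of the harmonic sum at unit amplitude (phases uniform)
perturbation_sd_factor <- function(spec) {
  k <- seq(2L, max(2L, spec$trabecular_count))
  if (spec$trabecular_count < 2L) return(0)
  sqrt(sum(k^(-spec$roughness_exponent)) / 2)
}

# radius(theta) in mm for the perturbed endocardial border
border_radius_fun <- function(spec) {
  if (spec$trabecular_count < 2L || spec$trabecular_amplitude == 0) {
    return(function(theta) rep(spec$cavity_radius, length(theta)))
  }
  k <- seq(2L, spec$trabecular_count)
  a <- spec$trabecular_amplitude * k^(-spec$roughness_exponent / 2)
  phi <- with_seed(spec$seed, runif(length(k), 0, 2 * pi))
  function(theta) {
    pert <- rowSums(vapply(seq_along(k),
                           function(i) a[i] * cos(k[i] * theta + phi[i]),
                           numeric(length(theta))))
    spec$cavity_radius * pmax(0.2, 1 + pert)
  }
}

#' Generate a single-slice phantom with ground truth
#'
#' Renders the slice described by a [slice_phantom_spec()]: bright pool,
#' darker myocardial annulus, background, optional papillary disks at
#' myocardial intensity inside the pool, plus noise. Identical spec and seed
#' give bit-identical images.
#'
#' @param spec a [slice_phantom_spec()].
#' @return list with `image` (numeric matrix), and `ground_truth`: a list with
#'   `border` (closed polyline of the true endocardial border, (row, col)),
#'   `pool_mask` (logical matrix, papillary disks excluded), and `spec`.
#' @export
generate_slice_phantom <- function(spec) {
  stopifnot(inherits(spec, "slice_phantom_spec"))
  validate_slice_phantom_spec(spec)
  n <- spec$image_size
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)          # row index
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  dr <- (rr - ctr) * spec$pixel_spacing
  dc <- (cc - ctr) * spec$pixel_spacing
  r_mm <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)

  rfun <- border_radius_fun(spec)
  r_border <- matrix(rfun(as.vector(theta)), n, n)
  pool <- r_mm <= r_border

  # partial-volume rendering: intensity ramps linearly across one pixel at
  # each interface, as in magnitude MR images, instead of a hard staircase
  ramp <- function(d_mm) pmin(pmax(d_mm / spec$pixel_spacing + 0.5, 0), 1)
  w_pool <- ramp(r_border - r_mm)
  w_in_wall <- ramp(r_border + spec$wall_thickness - r_mm)
  img <- spec$background_intensity +
    (spec$myo_intensity - spec$background_intensity) * w_in_wall +
    (spec$pool_intensity - spec$myo_intensity) * w_pool

  # papillary muscles: myocardial-intensity disks strictly inside the pool
  pap <- matrix(FALSE, n, n)
  if (spec$papillary_count > 0L) {
    r_min <- min(r_border[pool])
    ang <- with_seed(spec$seed + 1L,
                     runif(spec$papillary_count, 0, 2 * pi))
    pap_rad <- max(2 * spec$pixel_spacing, 0.12 * spec$cavity_radius)
    pap_pos <- min(0.45 * spec$cavity_radius, 0.8 * r_min - pap_rad)
    if (pap_pos > 0) {
      w_pap <- matrix(0, n, n)
      for (a in ang) {
        pdr <- dr - pap_pos * sin(a)
        pdc <- dc - pap_pos * cos(a)
        d <- sqrt(pdr^2 + pdc^2)
        w_pap <- pmax(w_pap, ramp(pap_rad - d))
        pap <- pap | (d <= pap_rad)
      }
      pap <- pap & pool
      w_pap[!pool] <- 0
      img <- img + (spec$myo_intensity - img) * w_pap
    }
  }

  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed + 2L, {
      if (spec$noise_model == "rician") {
        sqrt((img + rnorm(n * n, 0, spec$noise_sigma))^2 +
               rnorm(n * n, 0, spec$noise_sigma)^2)
      } else {
        img + matrix(rnorm(n * n, 0, spec$noise_sigma), n, n)
      }
    })
  }

  th <- seq(0, 2 * pi, length.out = 4L * n + 1L)[-(4L * n + 1L)]
  rb <- rfun(th)
  border <- cbind(row = ctr + rb * sin(th) / spec$pixel_spacing,
                  col = ctr + rb * cos(th) / spec$pixel_spacing)

  list(image = img,
       ground_truth = list(border = border, pool_mask = pool & !pap,
                           spec = spec))
}

#' Box-counting fractal dimension of a phantom's true border
#'
#' Rasterizes the ground-truth border polyline and estimates its box-counting
#' dimension; used to validate that generated borders span the intended
#' complexity range independent of the segmentation stage.
#'
#' @param gt ground-truth list from [generate_slice_phantom()].
#' @param upsample factor by which the border polyline is scaled before
#'   rasterization (matching the pipeline's sub-pixel upsampling).
#' @param sizes box sizes in pixels; default [default_box_sizes()] for the
#'   rasterized border's extent.
#' @return the fitted fractal dimension (numeric scalar).
#' @export
true_border_fd <- function(gt, upsample = 4L, sizes = NULL) {
  size <- gt$spec$image_size * upsample
  border <- (gt$border - 0.5) * upsample + 0.5
  edge <- rasterize_polyline(border, size)
  sizes <- sizes %||% default_box_sizes(edge_extent(edge))
  estimate_fd(box_count(edge, sizes))$fd
}

#' Specification for a short-axis stack phantom
#'
#' A stack of [slice_phantom_spec()]s ordered apex-first, with the cavity
#' radius tapering from a small apical cavity to a larger basal one and the
#' trabecular amplitude tapering apex to base (apical slices are typically the
#' most trabeculated). Slice thickness and section gap follow typical cine
#' protocols (8 mm slices, 3 mm gap, 8-13 slices).
#'
#' @param n_slices number of slices (>= 4; 8-13 typical).
#' @param cavity_radius_apex,cavity_radius_base cavity radius in mm at the
#'   two ends; intermediate slices are interpolated linearly.
#' @param amplitude_apex,amplitude_base trabecular amplitude at the two ends.
#' @param slice_thickness,section_gap geometry in mm.
#' @param papillary_slices integer indices (apex-first) of slices that carry
#'   papillary disks; defaults to the middle third.
#' @param seed integer seed; per-slice seeds are derived from it.
#' @param ... further arguments passed to every slice's
#'   [slice_phantom_spec()].
#' @return an object of class `stack_phantom_spec`.
#' @export
stack_phantom_spec <- function(n_slices = 10L, cavity_radius_apex = 9,
                               cavity_radius_base = 24,
                               amplitude_apex = 0.08, amplitude_base = 0.05,
                               slice_thickness = 8, section_gap = 3,
                               papillary_slices = NULL, seed = 1L, ...) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 4L)
    stop("n_slices must be >= 4 (apical/basal split undefined below this)")
  if (is.null(papillary_slices)) {
    papillary_slices <- seq.int(ceiling(n_slices / 3), ceiling(2 * n_slices / 3))
  }
  spec <- list(n_slices = n_slices,
               cavity_radius_apex = cavity_radius_apex,
               cavity_radius_base = cavity_radius_base,
               amplitude_apex = amplitude_apex,
               amplitude_base = amplitude_base,
               slice_thickness = slice_thickness, section_gap = section_gap,
               papillary_slices = as.integer(papillary_slices),
               seed = as.integer(seed), slice_args = list(...))
  class(spec) <- "stack_phantom_spec"
  spec
}

#' Generate a short-axis stack phantom
#'
#' @param spec a [stack_phantom_spec()].
#' @return a `slice_stack`: list with `slices` (list of image matrices,
#'   apex-first), `meta` (pixel spacing, slice thickness, section gap,
#'   `apex_first = TRUE`), and `ground_truth` (per-slice ground-truth lists).
#' @export
generate_stack_phantom <- function(spec) {
  stopifnot(inherits(spec, "stack_phantom_spec"))
  n <- spec$n_slices
  frac <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  radii <- spec$cavity_radius_apex +
    frac * (spec$cavity_radius_base - spec$cavity_radius_apex)
  amps <- spec$amplitude_apex +
    frac * (spec$amplitude_base - spec$amplitude_apex)
  slices <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    args <- c(list(cavity_radius = radii[i], trabecular_amplitude = amps[i],
                   papillary_count = if (i %in% spec$papillary_slices)
                     spec$slice_args$papillary_count %||% 2L else 0L,
                   seed = spec$seed * 101L + i),
              spec$slice_args[setdiff(names(spec$slice_args),
                                      c("papillary_count"))])
    sspec <- do.call(slice_phantom_spec, args)
    ph <- generate_slice_phantom(sspec)
    slices[[i]] <- ph$image
    gts[[i]] <- ph$ground_truth
  }
  structure(list(slices = slices,
                 meta = list(pixel_spacing_mm = gts[[1]]$spec$pixel_spacing,
                             slice_thickness_mm = spec$slice_thickness,
                             section_gap_mm = spec$section_gap,
                             apex_first = TRUE, n_slices = n,
                             seed = spec$seed),
                 ground_truth = gts),
            class = "slice_stack")
}

#' Vertices of a Koch-snowflake boundary
#'
#' Closed polyline of the Koch snowflake at the given subdivision level,
#' scaled to span `width` pixels. Its boundary has analytic fractal dimension
#' log(4)/log(3) (about 1.2619), making it a standard validation figure for
#' box-counting estimators.
#'
#' @param level subdivision level (>= 0); level 5 gives 3072 segments.
#' @param width target span in pixels.
#' @return two-column matrix of (row, col) vertices of the closed boundary.
#' @export
koch_snowflake_points <- function(level = 5L, width = 729) {
  # equilateral triangle, then each segment -> 4 segments with a /\ bump
  z <- complex(real = c(0, 1, 0.5), imaginary = c(0, 0, sqrt(3) / 2))
  for (l in seq_len(level)) {
    zn <- rbind(z, z[c(2:length(z), 1)])
    seg <- zn[2, ] - zn[1, ]
    a <- zn[1, ]
    b <- a + seg / 3
    c_ <- b + (seg / 3) * exp(complex(imaginary = -pi / 3))
    d <- a + 2 * seg / 3
    z <- as.vector(rbind(a, b, c_, d))
  }
  x <- Re(z); y <- Im(z)
  scale <- (width - 1) / max(diff(range(x)), diff(range(y)))
  cbind(row = (y - min(y)) * scale + 1, col = (x - min(x)) * scale + 1)
}
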