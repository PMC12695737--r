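#' Circular region of interest
#'
#' @param center (row, col) pixel coordinates of the circle center.
#' @param radius radius in pixels.
#' @return object of class `roi_circle`.
#' @export
roi_circle <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "roi_circle")
}

roi_mask <- function(roi, dims) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (rr - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2
}

check_roi <- function(roi, dims) {
  if (roi$center[1] - roi$radius < 1 || roi$center[1] + roi$radius > dims[1] ||
      roi$center[2] - roi$radius < 1 || roi$center[2] + roi$radius > dims[2])
    stop("ROI circle extends outside the image")
  invisible(roi)
}

#' Automatic ROI around the brightest central structure
#'
#' Two-class Otsu thresholding, then the largest bright connected component;
#' the ROI circle is centered on its centroid with radius 1.4 times its
#' equivalent-disk radius (clamped inside the image). The operator-drawn ROI
#' of clinical practice can always be supplied instead via [roi_circle()].
#'
#' @param img grayscale image matrix.
#' @return an `roi_circle`.
#' @export
auto_roi <- function(img) {
  thr <- otsu_thresholds(img, n_classes = 2L)
  bright <- img > thr
  lab <- EBImage::bwlabel(bright)
  if (max(lab) == 0) stop("no bright structure found for automatic ROI")
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  ctr <- colMeans(idx)
  rad <- 1.4 * sqrt(sizes[big] / pi)
  rad <- min(rad, ctr[1] - 1, ctr[2] - 1,
             nrow(img) - ctr[1] - 1, ncol(img) - ctr[2] - 1)
  roi_circle(ctr, rad)
}

#' Multi-level Otsu thresholds
#'
#' Exhaustive maximization of between-class variance over a 256-bin
#' histogram; with `n_classes = 3` returns the two thresholds separating
#' background, myocardium and blood pool.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_classes 2 or 3.
#' @return numeric thresholds (length `n_classes - 1`), on the intensity
#'   scale of `x`; values strictly above the last threshold belong to the
#'   brightest class.
#' @export
otsu_thresholds <- function(x, n_classes = 3L) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate intensity: constant image")
  nb <- 256L
  bin <- pmin(nb, pmax(1L, 1L + floor((x - rng[1]) / diff(rng) * nb)))
  h <- tabulate(bin, nb)
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  # between-class variance contribution of bin range (a, b]
  term <- function(a, b) { # a < b, a in 0:(nb-1)
    wa <- if (a == 0) 0 else w[a]; ma <- if (a == 0) 0 else mu[a]
    wk <- w[b] - wa
    if (wk <= 0) return(NA_real_)
    (mu[b] - ma)^2 / wk
  }
  if (n_classes == 2L) {
    vals <- vapply(1:(nb - 1), function(t) {
      v <- term(0, t) + term(t, nb); if (is.na(v)) -Inf else v
    }, numeric(1))
    t1 <- which.max(vals)
    return(rng[1] + t1 / nb * diff(rng))
  }
  stopifnot(n_classes == 3L)
  # vectorized search over all (t1, t2) pairs
  t1s <- 1:(nb - 2); t2s <- 2:(nb - 1)
  v1 <- vapply(t1s, function(t) term(0, t), numeric(1))
  v3 <- vapply(t2s, function(t) term(t, nb), numeric(1))
  w0 <- c(0, w); mu0 <- c(0, mu)
  num <- outer(mu0[t1s + 1], mu0[t2s + 1],
               function(a, b) (b - a)^2)
  den <- outer(w0[t1s + 1], w0[t2s + 1], function(a, b) b - a)
  v2 <- num / den
  v2[den <= 0] <- NA
  V <- outer(v1, v3, "+") + v2
  V[outer(t1s, t2s, ">=")] <- NA
  best <- arrayInd(which.max(V), dim(V))
  bt <- c(t1s[best[1]], t2s[best[2]])
  rng[1] + bt / nb * diff(rng)
}

# Chan-Vese-style two-phase region refinement restricted to a mask region.
# Piecewise-constant model: each pixel joins the region (pool / not-pool)
# whose mean intensity it is closer to; a Gaussian smoothing of the
# indicator followed by re-thresholding acts as the curvature penalty.
# Fixed iteration cap, convergence tolerance on the fraction of pixels
# changing per iteration. Fully deterministic.
chanvese_refine <- function(img, init, region, max_iter = 50L, tol = 1e-3,
                            sigma = 0.8) {
  phi <- init & region
  c1 <- NA_real_; c2 <- NA_real_; i <- 0L
  for (i in seq_len(max_iter)) {
    inside <- phi & region
    outside <- !phi & region
    if (!any(inside) || !any(outside)) break
    c1 <- mean(img[inside]); c2 <- mean(img[outside])
    assign_pool <- (img - c1)^2 < (img - c2)^2
    sm <- gauss_smooth(assign_pool * 1.0, sigma)
    new_phi <- (sm > 0.5) & region
    changed <- sum(xor(new_phi, phi)) / max(1, sum(region))
    phi <- new_phi
    if (changed < tol) break
  }
  list(mask = phi, iterations = i, c_pool = c1, c_myo = c2)
}

#' Binarize the blood pool within an ROI
#'
#' Implements the segmentation front end: 3-class multi-level Otsu
#' initialization inside the ROI (pool = brightest class), refined by a
#' Chan-Vese-style region evolution with a fixed iteration cap, then reduced
#' to the largest connected bright component; bright islands detached from
#' the pool are discarded. Papillary-muscle cross sections appear as holes in
#' the pool and are labeled as intracavity objects. Deterministic: no
#' stochastic step.
#'
#' @param img grayscale slice matrix.
#' @param roi an `roi_circle`, or `"auto"` for [auto_roi()].
#' @param upsample integer upsampling factor applied to the slice (bilinear)
#'   before thresholding; sub-pixel boundary detail matters for box
#'   counting. The ROI is scaled accordingly.
#' @param max_iter,tol,sigma refinement controls, see details.
#' @return object of class `blood_pool_mask`: list with `mask` (logical
#'   matrix, pool only, holes excluded), `filled` (holes filled),
#'   `intracavity` (labeled matrix of intracavity objects), `upsample`,
#'   `thresholds`, `iterations`, `roi`.
#' @export
binarize_blood_pool <- function(img, roi = "auto", upsample = 1L,
                                max_iter = 50L, tol = 1e-3, sigma = 0.8) {
  upsample <- as.integer(upsample)
  if (upsample > 1L) {
    img <- as.matrix(EBImage::resize(img, w = nrow(img) * upsample,
                                     h = ncol(img) * upsample,
                                     filter = "bilinear"))
  }
  if (identical(roi, "auto")) {
    roi <- auto_roi(img)
  } else if (upsample > 1L) {
    roi <- roi_circle(roi$center * upsample - (upsample - 1) / 2,
                      roi$radius * upsample)
  }
  check_roi(roi, dim(img))
  # crop to the ROI bounding box: everything outside can never be pool
  r0 <- max(1L, floor(roi$center[1] - roi$radius) - 2L)
  r1 <- min(nrow(img), ceiling(roi$center[1] + roi$radius) + 2L)
  c0 <- max(1L, floor(roi$center[2] - roi$radius) - 2L)
  c1 <- min(ncol(img), ceiling(roi$center[2] + roi$radius) + 2L)
  sub <- img[r0:r1, c0:c1]
  roi_sub <- roi_circle(roi$center - c(r0 - 1, c0 - 1), roi$radius)
  region <- roi_mask(roi_sub, dim(sub))
  vals <- sub[region]
  if (diff(range(vals)) == 0) stop("degenerate intensity inside ROI")
  thr <- otsu_thresholds(vals, n_classes = 3L)
  init <- sub > thr[2] & region
  if (!any(init)) stop("no blood pool detected inside ROI")
  ref <- chanvese_refine(sub, init, region, max_iter = max_iter, tol = tol,
                         sigma = sigma)
  pool_all <- ref$mask
  if (!any(pool_all)) stop("no blood pool detected after refinement")
  lab <- EBImage::bwlabel(pool_all)
  sizes <- tabulate(lab[lab > 0])
  pool_sub <- lab == which.max(sizes)      # detached bright islands discarded
  filled_sub <- EBImage::fillHull(pool_sub) > 0
  intr_sub <- EBImage::bwlabel(filled_sub & !pool_sub)
  embed <- function(s) {
    out <- matrix(if (is.logical(s)) FALSE else 0L, nrow(img), ncol(img))
    out[r0:r1, c0:c1] <- s
    out
  }
  pool <- embed(pool_sub)
  filled <- embed(filled_sub)
  intracavity <- embed(intr_sub)
  structure(list(mask = pool, filled = filled, intracavity = intracavity,
                 upsample = upsample, thresholds = thr,
                 iterations = ref$iterations, roi = roi),
            class = "blood_pool_mask")
}

# separable convolution via vectorized shift-and-add (zero boundary);
# much faster than FFT or filter() for the short kernels used here
shift_rows <- function(m, k) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  if (k >= 0) out[(1 + k):n, ] <- m[1:(n - k), ]
  else out[1:(n + k), ] <- m[(1 - k):n, ]
  out
}

conv_sep <- function(m, kv, kh) {
  rv <- (length(kv) - 1) / 2
  a <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(kv))
    if (kv[i] != 0) a <- a + kv[i] * shift_rows(m, i - 1 - rv)
  rh <- (length(kh) - 1) / 2
  at <- t(a)
  b <- matrix(0, nrow(at), ncol(at))
  for (i in seq_along(kh))
    if (kh[i] != 0) b <- b + kh[i] * shift_rows(at, i - 1 - rh)
  t(b)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_smooth <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  conv_sep(m, k, k)
}

sobel_magnitude <- function(m) {
  m <- m * 1.0
  gx <- conv_sep(m, c(1, 2, 1), c(-1, 0, 1))   # horizontal gradient
  gy <- conv_sep(m, c(-1, 0, 1), c(1, 2, 1))   # vertical gradient
  sqrt(gx^2 + gy^2)
}

#' Extract the trabeculated endocardial edge set
#'
#' Sobel gradient of the binarized pool, thresholded at any nonzero response
#' and thinned to the 1-pixel inner boundary, yielding the endocardial /
#' trabecular interface used for box counting. Borders of intracavity
#' objects (papillary-muscle cross sections) are included by default so that
#' the final edge image carries them, and can be excluded via
#' `include_papillary = FALSE`.
#'
#' @param bp a `blood_pool_mask` from [binarize_blood_pool()].
#' @param include_papillary include intracavity object borders (default TRUE).
#' @return object of class `edge_map`: list with `edge` (logical matrix),
#'   `upsample`, `n_edge_pixels`, `include_papillary`.
#' @export
extract_trabecular_edges <- function(bp, include_papillary = TRUE) {
  stopifnot(inherits(bp, "blood_pool_mask"))
  if (!any(bp$mask)) stop("empty blood-pool mask")
  # work on the mask bounding box only; embed the result back afterwards
  idx <- which(bp$filled, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(bp$filled), max(idx[, 1]) + 2L)
  c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(bp$filled), max(idx[, 2]) + 2L)
  boundary_of <- function(m) {
    g <- sobel_magnitude(m[r0:r1, c0:c1])
    # any genuine step in a 0/1 mask gives |g| >= 2; 0.5 rejects numerical
    # convolution noise
    (g > 0.5) & m[r0:r1, c0:c1]  # thinned: mask pixels adjacent to outside
  }
  edge_sub <- boundary_of(bp$filled)
  if (include_papillary && max(bp$intracavity) > 0) {
    edge_sub <- edge_sub | boundary_of(bp$intracavity > 0)
  }
  edge <- matrix(FALSE, nrow(bp$filled), ncol(bp$filled))
  edge[r0:r1, c0:c1] <- edge_sub
  if (!any(edge)) stop("no edge detected")
  structure(list(edge = edge, upsample = bp$upsample,
                 n_edge_pixels = sum(edge),
                 include_papillary = include_papillary),
            class = "edge_map")
}
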