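test_that("multi-level Otsu separates three well-defined intensity classes", {
  set.seed(3)
  x <- c(rnorm(500, 20, 3), rnorm(300, 80, 3), rnorm(200, 200, 3))
  thr <- otsu_thresholds(x, 3)
  expect_true(thr[1] > 25 && thr[1] < 75)   # background | myocardium
  expect_true(thr[2] > 85 && thr[2] < 195)  # myocardium | blood pool
  expect_error(otsu_thresholds(rep(5, 100)), "degenerate")
})

test_that("blood-pool masks recover ground truth on noiseless and noisy phantoms", {
  # noiseless: near-perfect overlap (trabecular wavelength kept above the
  # pixel scale so the target boundary is resolvable at native resolution)
  ph <- generate_slice_phantom(slice_phantom_spec(trabecular_count = 24L,
                                                  noise_sigma = 0, seed = 1))
  bp <- binarize_blood_pool(ph$image, roi = "auto", upsample = 1)
  expect_gte(dice(bp$mask, ph$ground_truth$pool_mask), 0.99)

  # noise at 10% of the pool-myocardium gap
  for (s in 1:3) {
    phn <- generate_slice_phantom(slice_phantom_spec(noise_sigma = 12,
                                                     seed = s))
    bpn <- binarize_blood_pool(phn$image, roi = "auto", upsample = 1)
    expect_gte(dice(bpn$mask, phn$ground_truth$pool_mask), 0.95)
  }

  # uniform image: degenerate intensity error
  expect_error(binarize_blood_pool(matrix(7, 64, 64),
                                   roi_circle(c(32, 32), 20)),
               "degenerate")
})

test_that("papillary borders enlarge the edge set; convolution enlarges it too", {
  ph <- generate_slice_phantom(slice_phantom_spec(seed = 2, noise_sigma = 0))
  bp <- binarize_blood_pool(ph$image, roi = "auto", upsample = 4)
  expect_gt(max(bp$intracavity), 0)   # papillary objects detected
  e_on <- extract_trabecular_edges(bp, include_papillary = TRUE)
  e_off <- extract_trabecular_edges(bp, include_papillary = FALSE)
  expect_gt(e_on$n_edge_pixels, e_off$n_edge_pixels)
  # papillary-on edges are a superset
  expect_true(all(e_off$edge[e_on$edge == FALSE] == FALSE))

  # convoluted border yields more edge pixels than a smooth one of equal radius
  smooth <- generate_slice_phantom(
    slice_phantom_spec(trabecular_amplitude = 0, papillary_count = 0,
                       noise_sigma = 0, seed = 2))
  rough <- generate_slice_phantom(
    slice_phantom_spec(trabecular_amplitude = 0.08, papillary_count = 0,
                       noise_sigma = 0, seed = 2))
  n_smooth <- extract_trabecular_edges(
    binarize_blood_pool(smooth$image, "auto", 4))$n_edge_pixels
  n_rough <- extract_trabecular_edges(
    binarize_blood_pool(rough$image, "auto", 4))$n_edge_pixels
  expect_gt(n_rough, n_smooth)
})

test_that("segmentation is translation-equivariant and idempotent", {
  ph <- generate_slice_phantom(slice_phantom_spec(papillary_count = 0,
                                                  noise_sigma = 0, seed = 4))
  img <- ph$image
  n <- nrow(img)
  shift <- 7L
  img_s <- matrix(min(img), n, n)
  img_s[(1 + shift):n, (1 + shift):n] <- img[1:(n - shift), 1:(n - shift)]
  roi0 <- roi_circle(c(128.5, 128.5), 80)
  roi1 <- roi_circle(c(128.5 + shift, 128.5 + shift), 80)
  e0 <- extract_trabecular_edges(binarize_blood_pool(img, roi0, 1))
  e1 <- extract_trabecular_edges(binarize_blood_pool(img_s, roi1, 1))
  want <- matrix(FALSE, n, n)
  want[(1 + shift):n, (1 + shift):n] <- e0$edge[1:(n - shift), 1:(n - shift)]
  expect_identical(want, e1$edge)

  # idempotence: identical inputs give bit-identical masks and edges
  b1 <- binarize_blood_pool(img, roi0, 2)
  b2 <- binarize_blood_pool(img, roi0, 2)
  expect_identical(b1$mask, b2$mask)
  expect_identical(extract_trabecular_edges(b1)$edge,
                   extract_trabecular_edges(b2)$edge)
})

test_that("downstream FD is robust to 90-degree rotation", {
  ph <- generate_slice_phantom(slice_phantom_spec(papillary_count = 0,
                                                  noise_sigma = 0, seed = 6))
  img <- ph$image
  img90 <- t(img)[, nrow(img):1]
  f0 <- process_slice(img, run_config(), 1L)$slice_fd$fd
  f90 <- process_slice(img90, run_config(), 1L)$slice_fd$fd
  expect_lt(abs(f0 - f90), 0.02)
})

test_that("a smooth circular pool yields a downstream FD near 1", {
  ph <- generate_slice_phantom(
    slice_phantom_spec(trabecular_amplitude = 0, papillary_count = 0,
                       noise_sigma = 0))
  r <- process_slice(ph$image, run_config(), 1L)
  expect_lt(abs(r$slice_fd$fd - 1), 0.05)
})
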