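test_that("box counts match the analytic values on canonical patterns", {
  # single pixel: one occupied box at every size
  single <- matrix(FALSE, 8, 8); single[3, 5] <- TRUE
  expect_equal(box_count(single, c(1, 2, 4))$counts, c(1, 1, 1))
  # fully occupied map: (n / size)^2 boxes
  expect_equal(box_count(matrix(TRUE, 8, 8), c(1, 2, 4, 8))$counts,
               c(64, 16, 4, 1))
  # horizontal line: n / size boxes
  line <- matrix(FALSE, 16, 16); line[9, ] <- TRUE
  expect_equal(box_count(line, c(1, 2, 4))$counts, c(16, 8, 4))
})

test_that("box_count validates its inputs", {
  expect_error(box_count(matrix(FALSE, 8, 8), c(1, 2)), "empty")
  expect_error(box_count(matrix(TRUE, 8, 8), c(2, 16)), "exceeds")
  expect_error(box_count(matrix(TRUE, 8, 8), c(4, 2)), "increasing")
})

test_that("box counts agree exactly with a brute-force double loop", {
  set.seed(101)
  sizes <- c(1L, 2L, 4L, 8L, 16L)
  for (i in 1:100) {
    edge <- matrix(runif(64 * 64) < runif(1, 0.005, 0.3), 64, 64)
    if (!any(edge)) edge[sample(4096, 1)] <- TRUE
    got <- box_count(edge, sizes)$counts
    want <- vapply(sizes, function(s) brute_box_count(edge, s), integer(1))
    expect_identical(got, as.numeric(want))
    expect_true(all(diff(got) <= 0))   # N(eps) nonincreasing
  }
})

test_that("log-log slope recovers exact dimensions for line and plane", {
  line <- structure(list(sizes = c(1L, 2L, 4L), counts = c(16, 8, 4),
                         grid_origin = "top-left"), class = "boxcount_curve")
  f1 <- estimate_fd(line, min_sizes = 3)
  expect_equal(f1$fd, 1.0)
  expect_equal(f1$fit_r2, 1.0)
  plane <- structure(list(sizes = c(1L, 2L, 4L, 8L), counts = c(64, 16, 4, 1),
                          grid_origin = "top-left"), class = "boxcount_curve")
  f2 <- estimate_fd(plane, min_sizes = 3)
  expect_equal(f2$fd, 2.0)
  expect_equal(f2$fit_r2, 1.0)
  # error contract: default minimum of five sizes
  expect_error(estimate_fd(line), "fewer than 5")
})

test_that("known-dimension suite: circle, Koch boundary, space-filling raster", {
  # circle: smooth curve, dimension 1
  th <- seq(0, 2 * pi, length.out = 8192)[-8192]
  circ <- rasterize_polyline(cbind(300 + 250 * sin(th), 300 + 250 * cos(th)),
                             600)
  fd_c <- estimate_fd(box_count(circ, default_box_sizes(edge_extent(circ))))
  expect_lt(abs(fd_c$fd - 1), 0.05)

  # level-5 Koch snowflake boundary: log 4 / log 3
  koch <- rasterize_polyline(koch_snowflake_points(5, 729), 729)
  fd_k <- estimate_fd(box_count(koch, default_box_sizes(edge_extent(koch))))
  expect_lt(abs(fd_k$fd - log(4) / log(3)), 0.05)

  # Hilbert-curve raster fills the plane: dimension pushed toward 2
  hp <- hilbert_points(6)                      # 64 x 64 cells
  poly <- hp * 2 + 1.5                         # cell centers, 2 px apart
  hil <- rasterize_polyline(poly, 130)
  fd_h <- estimate_fd(box_count(hil, c(2L, 4L, 8L, 16L, 32L)))
  expect_gte(fd_h$fd, 1.9)
})

test_that("estimated FD is stable under resolution doubling", {
  # trabecular wavelength kept above the coarser pixel scale so both
  # renderings carry the same boundary detail
  sp1 <- slice_phantom_spec(trabecular_count = 24L, papillary_count = 0,
                            noise_sigma = 0, seed = 5)
  sp2 <- slice_phantom_spec(image_size = 512L, pixel_spacing = 0.7,
                            trabecular_count = 24L, papillary_count = 0,
                            noise_sigma = 0, seed = 5)
  f1 <- process_slice(generate_slice_phantom(sp1)$image,
                      run_config(), 1L)$slice_fd$fd
  f2 <- process_slice(generate_slice_phantom(sp2)$image,
                      run_config(upsample = 2L), 1L)$slice_fd$fd
  expect_lt(abs(f1 - f2), 0.03)
})

test_that("regional summaries follow the apex-first split rules", {
  mk <- function(fd, i, valid = TRUE)
    structure(list(slice_index = i, fd = fd, fit_r2 = 0.99, n_sizes_used = 6,
                   valid = valid), class = "slice_fd")
  fds <- mapply(mk, c(1.30, 1.20, 1.25, 1.35), 1:4, SIMPLIFY = FALSE)
  s <- summarize_regional_fd(fds)
  expect_equal(s$fd_global, 1.275)
  expect_equal(s$fd_mean_apical, 1.25)
  expect_equal(s$fd_max_apical, 1.30)
  expect_equal(s$fd_mean_basal, 1.30)
  expect_equal(s$fd_max_basal, 1.35)

  # constant stack: every summary equals the common value
  same <- mapply(mk, rep(1.2, 6), 1:6, SIMPLIFY = FALSE)
  s2 <- summarize_regional_fd(same)
  expect_true(all(unlist(s2[1:5]) == 1.2))

  # invalid slices are excluded from all five summaries
  withinv <- mapply(mk, c(1.30, 1.99, 1.25, 1.35, 1.28), 1:5,
                    valid = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                    SIMPLIFY = FALSE)
  s3 <- summarize_regional_fd(withinv)
  expect_equal(s3$fd_global, mean(c(1.30, 1.25, 1.35, 1.28)))
  expect_identical(s3$n_valid_slices, 4L)

  # odd counts: middle slice goes basal by default, apical on request
  odd <- mapply(mk, c(1.1, 1.2, 1.3, 1.4, 1.5), 1:5, SIMPLIFY = FALSE)
  expect_identical(summarize_regional_fd(odd)$n_basal, 3L)
  expect_identical(summarize_regional_fd(odd,
                                         split_rule = "midpoint-apical")$n_apical, 3L)

  # max >= mean always
  expect_gte(s$fd_max_apical, s$fd_mean_apical)
  expect_gte(s$fd_max_basal, s$fd_mean_basal)

  expect_error(summarize_regional_fd(fds[1:3]), "insufficient")
  expect_error(summarize_regional_fd(fds, apex_first = FALSE), "ordering")
})
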