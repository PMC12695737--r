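test_that("slice phantoms are deterministic and respect parameter errors", {
  sp <- slice_phantom_spec(seed = 42)
  a <- generate_slice_phantom(sp)
  b <- generate_slice_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$ground_truth$pool_mask, b$ground_truth$pool_mask)

  # different seed changes the border
  c <- generate_slice_phantom(slice_phantom_spec(seed = 43))
  expect_false(identical(a$image, c$image))

  # cavity too large for the image -> parameter error
  expect_error(slice_phantom_spec(cavity_radius = 200), "exceeds image")
  # intensity ordering enforced
  expect_error(slice_phantom_spec(pool_intensity = 50, myo_intensity = 80),
               "ordered")
  expect_error(slice_phantom_spec(roughness_exponent = 3), "roughness")
})

test_that("amplitude-zero phantom border is a smooth closed curve (FD near 1)", {
  sp <- slice_phantom_spec(trabecular_amplitude = 0, papillary_count = 0,
                           noise_sigma = 0)
  ph <- generate_slice_phantom(sp)
  expect_lt(abs(true_border_fd(ph$ground_truth) - 1), 0.05)
  # border raster is a single closed curve: one component after bridging
  # diagonal (8-connected) steps with a 3x3 dilation
  edge <- rasterize_polyline((ph$ground_truth$border - 0.5) * 4 + 0.5,
                             sp$image_size * 4L)
  fat <- EBImage::dilate(edge * 1, EBImage::makeBrush(3, "box"))
  expect_equal(max(EBImage::bwlabel(fat)), 1)
})

test_that("true-border FD increases with trabecular amplitude across seeds", {
  amps <- c(0.02, 0.06, 0.10)
  grid <- expand.grid(seed = 1:5, amp = amps)
  fds <- mapply(function(s, a) {
    sp <- slice_phantom_spec(trabecular_amplitude = a, papillary_count = 0,
                             seed = s)
    true_border_fd(generate_slice_phantom(sp)$ground_truth)
  }, grid$seed, grid$amp)
  expect_gte(cor(grid$amp, fds, method = "spearman"), 0.9)
  # strict increase within each seed
  for (s in 1:5) {
    v <- fds[grid$seed == s]
    expect_true(all(diff(v) > 0))
  }
})

test_that("stack phantoms are apex-first with tapering cavity and size checks", {
  st <- generate_stack_phantom(stack_phantom_spec(n_slices = 8, seed = 2))
  expect_length(st$slices, 8)
  expect_true(st$meta$apex_first)
  expect_equal(st$meta$slice_thickness_mm, 8)
  expect_equal(st$meta$section_gap_mm, 3)
  # cavity tapers apex -> base: pool area grows monotonically
  areas <- vapply(st$ground_truth, function(g) sum(g$pool_mask), numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_error(stack_phantom_spec(n_slices = 3), "n_slices")
})

test_that("synthetic cohorts have the requested structure and hit group means", {
  spec <- cohort_sim_spec(seed = 7)
  tab <- generate_synthetic_cohort(spec)
  expect_identical(nrow(tab), 180L)
  expect_identical(as.integer(table(tab$group)), c(34L, 69L, 77L))
  expect_true(all(tab$fd_global >= 1 & tab$fd_global <= 2))

  # identical spec + seed -> identical table
  expect_identical(tab, generate_synthetic_cohort(spec))

  # group means of global FD within 3 standard errors of targets
  targets <- list(control = c(1.189, 0.038), HTN_nonHF = c(1.235, 0.040),
                  HTN_HF = c(1.258, 0.038))
  for (g in names(targets)) {
    v <- tab$fd_global[tab$group == g]
    se <- targets[[g]][2] / sqrt(length(v))
    expect_lt(abs(mean(v) - targets[[g]][1]), 3 * se)
  }

  # derived quantities respect their defining identities
  expect_equal(tab$bsa, sqrt(tab$height_cm * tab$weight_kg / 3600))
  expect_equal(tab$lvedvi, tab$lvedv / tab$bsa)
  expect_equal(tab$sv, tab$lvedv - tab$lvesv)
  expect_true(all(tab$sex %in% 0:1))
})

test_that("zero-SD cohort parameters yield a constant column with a warning", {
  gp <- default_group_params()
  for (g in names(gp)) gp[[g]]$age <- c(50, 0)
  expect_warning(tab <- generate_synthetic_cohort(cohort_sim_spec(gp, seed = 1)),
                 "constant column")
  expect_true(all(tab$age == 50))
})

test_that("Koch snowflake generator produces the closed analytic boundary", {
  k <- koch_snowflake_points(2, 100)
  expect_equal(nrow(k), 3 * 4^2)
  expect_true(all(k >= 1 & k <= 100))
})
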