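test_that("univariate logistic fits expose OR = exp(beta) with bracketing CI", {
  d <- sim_logistic(500, 0.8, seed = 1)
  f <- fit_logistic_univariate(d, "y", "x1")
  t <- f$terms[f$terms$term == "x1", ]
  expect_equal(t$or, exp(t$beta))
  expect_lt(t$ci_low, t$or)
  expect_gt(t$ci_high, t$or)
  expect_error(fit_logistic_univariate(data.frame(y = rep(1, 20),
                                                  x = rnorm(20)), "y", "x"),
               "both classes")
})

test_that("FD predictors enter per 0.01 unit so ORs land on the clinical scale", {
  set.seed(2)
  n <- 400
  fd <- rnorm(n, 1.24, 0.04)
  y <- rbinom(n, 1, plogis(30 * (fd - 1.24)))
  d <- data.frame(hf = y, fd_global = fd)
  f <- fit_logistic_univariate(d, "hf", "fd_global")
  beta <- f$terms$beta[f$terms$term == "fd_global"]
  # on the percent scale the slope is 100x smaller than on the raw FD scale
  raw <- glm(hf ~ fd_global, data = d, family = binomial())
  expect_equal(beta, unname(coef(raw)[2]) / 100)
  expect_match(f$fd_scale_note, "0.01")
})

test_that("logistic estimation is consistent and its CI has near-nominal coverage", {
  # point estimate at large n
  d <- sim_logistic(5000, 0.7, seed = 11)
  f <- fit_logistic_univariate(d, "y", "x1")
  expect_lt(abs(f$terms$beta[f$terms$term == "x1"] - 0.7), 0.1)

  # null coverage: CI for the OR covers 1 in >= 93% of 200 replicates
  covered <- 0L
  for (s in 1:200) {
    dn <- sim_logistic(5000, 0, seed = 1000 + s)
    fn <- fit_logistic_univariate(dn, "y", "x1")
    t <- fn$terms[fn$terms$term == "x1", ]
    if (t$ci_low <= 1 && t$ci_high >= 1) covered <- covered + 1L
  }
  expect_gte(covered / 200, 0.93)
})

test_that("VIFs equal 1/(1 - R^2) and flag exact collinearity", {
  # orthogonal design: all VIF exactly 1
  d <- data.frame(x1 = rep(c(1, 1, -1, -1), 5), x2 = rep(c(1, -1, 1, -1), 5),
                  x3 = rep(c(1, -1, -1, 1), 5))
  expect_equal(unname(compute_vif(d, c("x1", "x2", "x3"))), rep(1, 3))

  # duplicated predictor: infinite VIF
  d$x4 <- d$x1
  v <- compute_vif(d, c("x1", "x2", "x4"))
  expect_true(is.infinite(v["x1"]) && is.infinite(v["x4"]))

  # near-collinear: matches the definition computed independently
  set.seed(4)
  dd <- data.frame(a = rnorm(200), b = rnorm(200))
  dd$c <- dd$a + dd$b + rnorm(200, 0, 0.5)
  v2 <- compute_vif(dd, c("a", "b", "c"))
  r2 <- summary(lm(c ~ a + b, dd))$r.squared
  expect_equal(unname(v2["c"]), 1 / (1 - r2))
  # independent package cross-check
  if (requireNamespace("car", quietly = TRUE)) {
    dd$y <- rnorm(200)
    expect_equal(unname(v2), unname(car::vif(lm(y ~ a + b + c, dd))),
                 tolerance = 1e-8)
  }
})

test_that("screening, VIF gating and forward selection leave an audit trail", {
  set.seed(9)
  d <- sim_logistic(2000, c(0.8, 0.8, 0, 0, 0, 0), seed = 21)
  d$x7 <- d$x1                              # exact duplicate
  sel <- select_multivariable(d, "y", paste0("x", 1:7), rescale_fd = FALSE)
  # the duplicate is VIF-excluded before selection, with the reason recorded
  vif_rows <- sel$audit[sel$audit$step == "vif", ]
  expect_gte(nrow(vif_rows), 1)
  expect_true(any(grepl("VIF>5", vif_rows$detail)))
  expect_true(all(c("x1", "x2") %in% sel$selected) ||
                all(c("x7", "x2") %in% sel$selected))
  # audit records every screened candidate
  expect_identical(sort(unique(sel$audit$variable[sel$audit$step == "screen"])),
                   paste0("x", 1:7))

  # nothing passes the screen -> explained empty model
  dnull <- sim_logistic(300, c(0, 0), seed = 3)
  seln <- select_multivariable(dnull, "y", c("x1", "x2"),
                               rescale_fd = FALSE)
  if (length(seln$selected) == 0) {
    expect_null(seln$fit)
    expect_true(any(seln$audit$action == "empty-model"))
  }
})
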