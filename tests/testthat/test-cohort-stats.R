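test_that("Mosteller BSA and volume indexing follow their closed forms", {
  expect_equal(mosteller_bsa(180, 80), 2.0)
  expect_equal(mosteller_bsa(90, 40), 1.0)
  expect_equal(mosteller_bsa(170, 70), sqrt(170 * 70 / 3600))
  expect_error(mosteller_bsa(-1, 70), "positive")
  expect_equal(index_to_bsa(100, 2), 50)
  expect_equal(index_to_bsa(0, 1.5), 0)
  expect_equal(index_to_bsa(154.17, 1.82), 154.17 / 1.82)
  expect_error(index_to_bsa(100, 0), "positive")
})

test_that("symptom-class imbalance between HF groups reproduces the reported proportions", {
  # NYHA >= II: 65 of 77 HF vs 23 of 69 non-HF
  tab <- data.frame(
    group = factor(rep(c("HTN_nonHF", "HTN_HF"), times = c(69, 77))),
    nyha_ge2 = c(rep(1, 23), rep(0, 46), rep(1, 65), rep(0, 12)))
  p_hf <- 100 * mean(tab$nyha_ge2[tab$group == "HTN_HF"])
  p_nonhf <- 100 * mean(tab$nyha_ge2[tab$group == "HTN_nonHF"])
  expect_equal(round(p_hf, 2), 84.42)
  expect_equal(round(p_nonhf, 2), 33.33)
  gc <- compare_groups(tab, "nyha_ge2", categorical = TRUE)
  expect_identical(gc$test_used, "chi2")
  expect_lt(gc$p, 0.001)
})

test_that("chi-square statistic matches the textbook enumeration", {
  tab <- data.frame(group = factor(rep(c("a", "b"), each = 60)),
                    flag = c(rep(1, 35), rep(0, 25), rep(1, 18), rep(0, 42)))
  gc <- compare_groups(tab, "flag", categorical = TRUE)
  ct <- table(tab$flag, tab$group)
  expect_equal(unname(gc$statistic), chisq_brute(ct))
})

test_that("the normality gate selects the announced tests", {
  set.seed(20)
  norm3 <- data.frame(group = factor(rep(c("a", "b", "c"), each = 60)),
                      y = rnorm(180))
  expect_identical(compare_groups(norm3, "y")$test_used, "ANOVA")
  skew3 <- data.frame(group = factor(rep(c("a", "b", "c"), each = 60)),
                      y = rexp(180)^2)
  expect_identical(compare_groups(skew3, "y")$test_used, "KruskalWallis")
  norm2 <- data.frame(group = factor(rep(c("a", "b"), each = 60)),
                      y = rnorm(120))
  expect_identical(compare_groups(norm2, "y")$test_used, "t")
  skew2 <- data.frame(group = factor(rep(c("a", "b"), each = 60)),
                      y = rexp(120)^2)
  expect_identical(compare_groups(skew2, "y")$test_used, "MannWhitney")
  expect_error(compare_groups(data.frame(group = factor(rep(c("a", "b"),
                                                            each = 10)),
                                         y = rep(1, 20)), "y"),
               "degenerate")
})

test_that("the two-sample path keeps its nominal type-I error under the null", {
  set.seed(99)
  rejections <- 0L
  n_sim <- 1000L
  for (i in seq_len(n_sim)) {
    d <- data.frame(group = factor(rep(c("a", "b"), each = 50)),
                    y = rnorm(100))
    if (compare_groups(d, "y")$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("ANCOVA adds a covariate-adjusted group effect via partial F", {
  set.seed(5)
  d <- data.frame(group = factor(rep(c("a", "b", "c"), each = 50)),
                  age = rnorm(150, 50, 10), sex = rbinom(150, 1, 0.5))
  d$y <- 0.02 * d$age + 0.5 * (d$group == "c") + rnorm(150)
  gc <- compare_groups(d, "y", covariates = c("age", "sex"))
  # oracle: explicit model comparison
  f <- anova(lm(y ~ age + sex, d), lm(y ~ age + sex + group, d))$`Pr(>F)`[2]
  expect_equal(gc$ancova_p, f)
})

test_that("Spearman correlations honour monotone transforms and rank formula", {
  set.seed(8)
  x <- rnorm(30)
  d <- data.frame(x = x, up = exp(x), down = -x, const = 1)
  r <- spearman_correlations(d, "x", c("up", "down"))
  expect_equal(unname(r$rho["x", "up"]), 1)
  expect_equal(unname(r$rho["x", "down"]), -1)

  # fixed 6-point pair against the brute rank formula
  d6 <- data.frame(a = c(3.1, 0.2, 5.5, 2.2, 4.9, 1.0),
                   b = c(0.7, 0.3, 2.0, 2.5, 1.1, 0.4))
  r6 <- spearman_correlations(d6, "a", "b")
  expect_equal(unname(r6$rho["a", "b"]), spearman_brute(d6$a, d6$b))

  # constant column: flagged undefined, not zero
  rc <- spearman_correlations(d, "x", "const")
  expect_true(is.na(rc$rho["x", "const"]))
})
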