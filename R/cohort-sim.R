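#' Default per-group simulation parameters for a three-group cohort
#'
#' Gaussian mean/SD (or proportion) parameters for healthy controls,
#' hypertensives without heart failure (HTN_nonHF) and hypertensives with
#' heart failure (HTN_HF), matching the clinical baseline characteristics of
#' a typical 3 T hypertensive heart-failure cohort (variables reported as
#' median with IQR are converted to mean ~ median, SD ~ IQR/1.349). Height
#' and weight are chosen so that derived BMI and Mosteller BSA land on the
#' reported group values. Comorbidity prevalences for the healthy controls
#' are set to plausible check-up-population values.
#'
#' @return nested list `group -> variable -> c(mean, sd)` plus proportions.
#' @export
default_group_params <- function() {
  list(
    control = list(
      n = 34L, age = c(39.29, 16.99), sex_prop = 0.618,
      height = c(166, 8), weight = c(64, 11),
      sbp = c(121.65, 9.17), dbp = c(78.15, 5.57),
      lvef = c(62.23, 4.77), lvedv = c(109.50, 45.4), lvesv = c(40.0, 20.0),
      max_lvwt = c(8.5, 0.74),
      fd_global = c(1.189, 0.038), fd_mean_apical = c(1.173, 0.051),
      fd_max_apical = c(1.233, 0.052), fd_mean_basal = c(1.194, 0.035),
      fd_max_basal = c(1.282, 0.036),
      diabetes = 0.03, smoking = 0.25, alcohol = 0.25, dyslipidemia = 0.20,
      atrial_fibrillation = 0.0, nyha = c(1, 0, 0, 0)),
    HTN_nonHF = list(
      n = 69L, age = c(48.70, 14.11), sex_prop = 0.840,
      height = c(168, 8), weight = c(75, 12),
      sbp = c(156.59, 24.10), dbp = c(96.45, 20.12),
      lvef = c(60.87, 7.92), lvedv = c(130.57, 42.3), lvesv = c(53.09, 21.47),
      max_lvwt = c(13.0, 2.97),
      fd_global = c(1.235, 0.040), fd_mean_apical = c(1.222, 0.055),
      fd_max_apical = c(1.309, 0.047), fd_mean_basal = c(1.241, 0.042),
      fd_max_basal = c(1.339, 0.045),
      diabetes = 0.217, smoking = 0.406, alcohol = 0.348,
      dyslipidemia = 0.565, atrial_fibrillation = 0.043,
      nyha = c(46, 22, 1, 0) / 69),
    HTN_HF = list(
      n = 77L, age = c(53.13, 17.23), sex_prop = 0.753,
      height = c(168, 8), weight = c(74.8, 11),
      sbp = c(152.16, 27.28), dbp = c(93.78, 23.68),
      lvef = c(49.96, 14.91), lvedv = c(154.17, 50.7), lvesv = c(83.82, 48.44),
      max_lvwt = c(14.0, 2.22),
      fd_global = c(1.258, 0.038), fd_mean_apical = c(1.255, 0.053),
      fd_max_apical = c(1.322, 0.0615), fd_mean_basal = c(1.256, 0.043),
      fd_max_basal = c(1.345, 0.039),
      diabetes = 0.208, smoking = 0.390, alcohol = 0.299,
      dyslipidemia = 0.623, atrial_fibrillation = 0.065,
      nyha = c(12, 51, 12, 2) / 77))
}

#' Specification for a synthetic three-group cohort
#'
#' @param group_params nested parameter list as returned by
#'   [default_group_params()]; per-group sample sizes live in each group's
#'   `n` entry.
#' @param fd_wt_rho target Spearman correlation between each FD summary and
#'   maximal LV wall thickness, induced through a Gaussian copula (latent
#'   shared factor). 0 disables the coupling.
#' @param fd_factor_loading loading of the shared latent trabeculation factor
#'   on the five FD summaries (controls FD inter-correlation).
#' @param seed integer RNG seed.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(group_params = default_group_params(),
                            fd_wt_rho = 0.4, fd_factor_loading = 0.7,
                            seed = 1L) {
  for (g in names(group_params)) {
    gp <- group_params[[g]]
    if (gp$n < 2L) stop("group sample sizes must be >= 2")
    if (gp$sex_prop < 0 || gp$sex_prop > 1)
      stop("sex proportion must lie in [0, 1]")
    for (v in names(gp)) {
      p <- gp[[v]]
      if (is.numeric(p) && length(p) == 2 && p[2] < 0)
        stop("negative SD for ", v, " in group ", g)
    }
  }
  structure(list(group_params = group_params, fd_wt_rho = fd_wt_rho,
                 fd_factor_loading = fd_factor_loading,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

fd_cols <- c("fd_global", "fd_mean_apical", "fd_max_apical",
             "fd_mean_basal", "fd_max_basal")

#' Cohort CSV column schema
#' @return character vector of the fixed cohort column names.
#' @export
cohort_schema <- function() {
  c("subject_id", "group", "age", "sex", "bmi", "height_cm", "weight_kg",
    "bsa", "sbp", "dbp", "lvef", "lvedv", "lvesv", "sv", "max_lvwt",
    "lvedvi", "lvesvi", fd_cols,
    "diabetes", "smoking", "alcohol", "dyslipidemia", "atrial_fibrillation",
    "nyha")
}

draw_gauss <- function(n, p, what = "") {
  if (p[2] == 0 && n > 1) {
    warning("zero SD for ", what, ": constant column generated")
    return(rep(p[1], n))
  }
  rnorm(n, p[1], p[2])
}

#' Generate a synthetic three-group cohort table
#'
#' One row per subject. FD summaries are drawn per-group Gaussian (clipped to
#' \[1, 2\]) with a shared latent trabeculation factor; maximal LV wall
#' thickness shares that factor so that each FD attains the target Spearman
#' correlation with wall thickness. BMI and Mosteller BSA are derived from
#' simulated height and weight, stroke volume as LVEDV - LVESV (LVESV
#' truncated below LVEDV), and indexed volumes by dividing by BSA. Identical
#' spec and seed give identical tables.
#'
#' @param spec a [cohort_sim_spec()].
#' @return data.frame following [cohort_schema()], with `group` a factor
#'   (control, HTN_nonHF, HTN_HF) and binary columns coded 0/1.
#' @export
generate_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  # Spearman -> latent Pearson for bivariate Gaussian copula
  rho_latent <- 2 * sin(pi * spec$fd_wt_rho / 6)
  lam <- spec$fd_factor_loading
  rho_wt <- if (lam > 0) min(0.99, rho_latent / lam) else 0
  with_seed(spec$seed, {
    rows <- lapply(names(spec$group_params), function(g) {
      gp <- spec$group_params[[g]]
      n <- gp$n
      z <- rnorm(n)                       # shared trabeculation factor
      fd <- sapply(fd_cols, function(v) {
        lat <- lam * z + sqrt(1 - lam^2) * rnorm(n)
        pmin(2, pmax(1, gp[[v]][1] + gp[[v]][2] * lat))
      })
      wt_lat <- rho_wt * z + sqrt(max(0, 1 - rho_wt^2)) * rnorm(n)
      height <- pmax(140, draw_gauss(n, gp$height, "height"))
      weight <- pmax(35, draw_gauss(n, gp$weight, "weight"))
      bsa <- mosteller_bsa(height, weight)
      lvedv <- pmax(40, draw_gauss(n, gp$lvedv, "lvedv"))
      lvesv <- pmax(5, pmin(0.95 * lvedv, draw_gauss(n, gp$lvesv, "lvesv")))
      nyha_p <- gp$nyha / sum(gp$nyha)
      data.frame(
        subject_id = NA_character_, group = g,
        age = pmax(18, draw_gauss(n, gp$age, "age")),
        sex = as.integer(runif(n) < gp$sex_prop),
        bmi = weight / (height / 100)^2,
        height_cm = height, weight_kg = weight, bsa = bsa,
        sbp = pmax(80, draw_gauss(n, gp$sbp, "sbp")),
        dbp = pmax(40, draw_gauss(n, gp$dbp, "dbp")),
        lvef = pmin(90, pmax(10, draw_gauss(n, gp$lvef, "lvef"))),
        lvedv = lvedv, lvesv = lvesv, sv = lvedv - lvesv,
        max_lvwt = pmax(4, gp$max_lvwt[1] + gp$max_lvwt[2] * wt_lat),
        lvedvi = index_to_bsa(lvedv, bsa), lvesvi = index_to_bsa(lvesv, bsa),
        fd_global = fd[, "fd_global"],
        fd_mean_apical = fd[, "fd_mean_apical"],
        fd_max_apical = fd[, "fd_max_apical"],
        fd_mean_basal = fd[, "fd_mean_basal"],
        fd_max_basal = fd[, "fd_max_basal"],
        diabetes = as.integer(runif(n) < gp$diabetes),
        smoking = as.integer(runif(n) < gp$smoking),
        alcohol = as.integer(runif(n) < gp$alcohol),
        dyslipidemia = as.integer(runif(n) < gp$dyslipidemia),
        atrial_fibrillation = as.integer(runif(n) < gp$atrial_fibrillation),
        nyha = sample.int(4L, n, replace = TRUE, prob = nyha_p),
        stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$subject_id <- sprintf("S%04d", seq_len(nrow(tab)))
    tab$group <- factor(tab$group,
                        levels = names(spec$group_params))
    rownames(tab) <- NULL
    tab
  })
}
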