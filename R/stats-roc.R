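#' ROC area under the curve with DeLong confidence interval
#'
#' AUC equals the normalized Mann-Whitney U statistic (ties count one half);
#' the confidence interval uses the DeLong variance estimator.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary 0/1 (or two-level) outcome.
#' @param level confidence level.
#' @return object of class `roc_result`: list with `auc`, `ci` (length 2),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  labels <- as.integer(factor(labels)) - 1L
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (length(scores) != length(labels)) stop("length mismatch")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(as.numeric(pROC::ci.auc(r, conf.level = level,
                                         method = "delong"))[c(1, 3)],
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(auc = auc, ci = ci, n_pos = sum(labels == 1),
                 n_neg = sum(labels == 0), roc = r),
            class = "roc_result")
}

#' DeLong comparison of two correlated AUCs
#'
#' Two-sided test of the AUC difference between two score vectors for the
#' same subjects, using the DeLong covariance estimator for paired ROC
#' curves. Scores that are rank-identical (one a monotone transform of the
#' other) give difference 0 and p = 1.
#'
#' @param scores_a,scores_b paired prediction vectors.
#' @param labels binary outcome shared by both.
#' @return list with `auc_a`, `auc_b`, `diff`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores and labels must be paired (equal lengths)")
  labels <- as.integer(factor(labels)) - 1L
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  aa <- as.numeric(pROC::auc(ra)); ab <- as.numeric(pROC::auc(rb))
  # rank-identical scores: AUC difference is identically 0, variance 0
  if (identical(rank(scores_a), rank(scores_b)))
    return(list(auc_a = aa, auc_b = ab, diff = 0, z = 0, p = 1))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  z <- unname(tst$statistic)
  list(auc_a = aa, auc_b = ab, diff = aa - ab, z = z, p = tst$p.value)
}

#' Fit and compare a sequence of nested logistic diagnostic models
#'
#' Fits each model on the common complete-case rows, reports in-sample AUC
#' with DeLong CI, and compares each model with its predecessor by DeLong's
#' test on the fitted probabilities and by the -2 log-likelihood ratio test.
#' Predictor sets must be strictly nested.
#'
#' @param tab data.frame (typically restricted to the hypertensive groups).
#' @param outcome binary 0/1 column.
#' @param model_specs named list of predictor character vectors, in order;
#'   each must contain the previous one.
#' @param rescale_fd rescale FD columns to percent units first.
#' @return object of class `nested_model_set`: list with `models` (per model:
#'   `logistic_fit`, `roc_result`), `comparisons` (data.frame: model,
#'   auc, auc_ci_low, auc_ci_high, minus2ll, delong_p_vs_prev,
#'   lrt_p_vs_prev), `n`.
#' @export
build_nested_models <- function(tab, outcome, model_specs,
                                rescale_fd = TRUE) {
  stopifnot(length(model_specs) >= 1)
  for (i in seq_along(model_specs)[-1]) {
    if (!all(model_specs[[i - 1]] %in% model_specs[[i]]))
      stop("model specs must be nested: model ", i,
           " does not contain model ", i - 1)
  }
  if (rescale_fd) tab <- rescale_fd_percent(tab)
  allvars <- unique(unlist(model_specs))
  d <- tab[complete.cases(tab[, c(outcome, allvars)]), c(outcome, allvars)]
  y <- d[[outcome]]
  models <- vector("list", length(model_specs))
  names(models) <- names(model_specs) %||%
    paste0("model", seq_along(model_specs))
  rows <- NULL
  prev_probs <- NULL; prev_fit <- NULL
  for (i in seq_along(model_specs)) {
    f <- as.formula(paste(outcome, "~",
                          if (length(model_specs[[i]]))
                            paste(model_specs[[i]], collapse = " + ")
                          else "1"))
    g <- suppressWarnings(glm(f, data = d, family = binomial()))
    probs <- predict(g, type = "response")
    rr <- if (var(probs) == 0) {
      # intercept-only model: constant score, AUC 1/2 by the tie convention
      structure(list(auc = 0.5, ci = c(NA_real_, NA_real_),
                     n_pos = sum(y == 1), n_neg = sum(y == 0)),
                class = "roc_result")
    } else roc_auc(probs, y)
    dl_p <- NA_real_; lrt_p <- NA_real_
    if (i > 1) {
      dl_p <- if (var(probs) == 0 || var(prev_probs) == 0) NA_real_
      else delong_compare(probs, prev_probs, y)$p
      lrt <- prev_fit$deviance - g$deviance
      lrt_p <- pchisq(lrt, df = length(coef(g)) - length(coef(prev_fit)),
                      lower.tail = FALSE)
    }
    models[[i]] <- list(
      fit = structure(list(outcome = outcome, terms = logistic_ci(g),
                           n = nrow(d),
                           minus2ll = as.numeric(-2 * logLik(g)),
                           converged = g$converged,
                           separation = separation_flag(g),
                           fd_scale_note = NA_character_, fit = g),
                      class = "logistic_fit"),
      roc = rr)
    rows <- rbind(rows, data.frame(
      model = names(models)[i], n_predictors = length(model_specs[[i]]),
      auc = rr$auc, auc_ci_low = rr$ci[1], auc_ci_high = rr$ci[2],
      minus2ll = as.numeric(-2 * logLik(g)),
      delong_p_vs_prev = dl_p, lrt_p_vs_prev = lrt_p))
    prev_probs <- probs; prev_fit <- g
  }
  structure(list(models = models, comparisons = rows, n = nrow(d)),
            class = "nested_model_set")
}

#' Predictor sets of the four standard nested diagnostic models
#'
#' Model 1: clinical risk factors (age, male sex, BMI, diabetes,
#' dyslipidemia, SBP). Model 2 adds LV function (LVEF, LVEDV, LVESV, SV).
#' Model 3 adds maximal LV wall thickness. Model 4 adds the FD summaries
#' (global, mean apical, maximal apical, mean basal; maximal basal FD is
#' omitted, consistent with its lack of discrimination between the
#' hypertensive groups).
#'
#' @return named list of predictor vectors, nested in order.
#' @export
standard_model_specs <- function() {
  m1 <- c("age", "sex", "bmi", "diabetes", "dyslipidemia", "sbp")
  m2 <- c(m1, "lvef", "lvedv", "lvesv", "sv")
  m3 <- c(m2, "max_lvwt")
  m4 <- c(m3, "fd_global", "fd_mean_apical", "fd_max_apical",
          "fd_mean_basal")
  list(model1 = m1, model2 = m2, model3 = m3, model4 = m4)
}
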