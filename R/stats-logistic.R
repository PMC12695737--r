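#' Rescale fractal-dimension columns for regression
#'
#' FD summaries live on a narrow dimensionless scale (~1.2 +/- 0.05), so
#' odds ratios are reported per 0.01 FD unit ("per 1% increase"): FD columns
#' are multiplied by 100 before entering a model.
#'
#' @param tab data.frame.
#' @param cols FD column names present in `tab`.
#' @return `tab` with the FD columns rescaled.
#' @export
rescale_fd_percent <- function(tab, cols = intersect(fd_cols, names(tab))) {
  for (cl in cols) tab[[cl]] <- tab[[cl]] * 100
  tab
}

logistic_ci <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
             or = exp(sm[, 1]),
             ci_low = exp(sm[, 1] - z * sm[, 2]),
             ci_high = exp(sm[, 1] + z * sm[, 2]),
             p = sm[, 4], row.names = NULL)
}

# crude complete-separation flag: huge |beta| or blown-up SE
separation_flag <- function(fit) {
  sm <- summary(fit)$coefficients
  any(abs(sm[-1, 1]) > 15) || any(sm[-1, 2] > 100) || !fit$converged
}

#' Univariate logistic regression for a binary outcome
#'
#' Maximum-likelihood fit of `outcome ~ predictor` with odds ratio, Wald 95%
#' CI and p-value. Fractal-dimension predictors are rescaled to per-0.01-unit
#' (per "1%") before fitting unless already rescaled. Intended for the
#' hypertensive subgroups only (HF vs non-HF); subset the table first.
#'
#' @param tab data.frame.
#' @param outcome binary 0/1 column name.
#' @param predictor predictor column name.
#' @param rescale_fd rescale FD predictors to percent units (default TRUE).
#' @return object of class `logistic_fit`: list with `outcome`, `terms`
#'   (data.frame: term, beta, se, or, ci_low, ci_high, p), `n`,
#'   `minus2ll`, `converged`, `separation`, `fd_scale_note`.
#' @export
fit_logistic_univariate <- function(tab, outcome, predictor,
                                    rescale_fd = TRUE) {
  y <- tab[[outcome]]
  if (is.null(y)) stop("unknown outcome column: ", outcome)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome must have both classes present")
  is_fd <- rescale_fd && predictor %in% fd_cols
  if (is_fd) tab <- rescale_fd_percent(tab, predictor)
  d <- tab[complete.cases(tab[, c(outcome, predictor)]),
           c(outcome, predictor)]
  fit <- suppressWarnings(
    glm(as.formula(paste(outcome, "~", predictor)), data = d,
        family = binomial()))
  sep <- separation_flag(fit)
  terms <- logistic_ci(fit)
  if (sep) terms[terms$term != "(Intercept)", c("ci_low", "ci_high")] <- NA
  structure(list(outcome = outcome, terms = terms, n = nrow(d),
                 minus2ll = as.numeric(-2 * logLik(fit)),
                 converged = fit$converged, separation = sep,
                 fd_scale_note = if (is_fd)
                   "fractal dimension entered per 0.01 FD unit (per 1%)"
                 else NA_character_,
                 fit = fit),
            class = "logistic_fit")
}

#' Variance inflation factors from the definition
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the linear regression of
#' predictor j on all the others. Exact collinearity is flagged as `Inf`.
#'
#' @param tab data.frame.
#' @param predictors character vector (>= 2) of numeric predictor columns.
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(tab, predictors) {
  if (length(predictors) < 2) stop("need >= 2 predictors for VIF")
  d <- tab[complete.cases(tab[, predictors]), predictors]
  if (nrow(d) <= length(predictors)) stop("need n > number of predictors")
  vapply(predictors, function(pj) {
    f <- as.formula(paste(pj, "~", paste(setdiff(predictors, pj),
                                         collapse = " + ")))
    r2 <- summary(lm(f, data = d))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Multivariable logistic model by screening, VIF gating and forward selection
#'
#' Reproduces the standard clinical modelling chain: (i) univariate screen at
#' `p_screen` (default 0.1); (ii) iteratively drop the highest-VIF survivor
#' until all VIF <= `vif_max` (default 5); (iii) forward selection by
#' likelihood-ratio entry test at `alpha_entry` (default 0.05). Every
#' decision is recorded in an audit trail.
#'
#' @param tab data.frame.
#' @param outcome binary 0/1 column name.
#' @param candidates candidate predictor column names.
#' @param p_screen univariate screening threshold.
#' @param vif_max VIF exclusion threshold.
#' @param alpha_entry forward-selection entry significance level.
#' @param rescale_fd rescale FD candidates to percent units first.
#' @return object of class `logistic_selection`: list with `fit` (final
#'   `logistic_fit`, or NULL when nothing enters), `selected`, `audit`
#'   (data.frame: step, variable, action, detail).
#' @export
select_multivariable <- function(tab, outcome, candidates, p_screen = 0.1,
                                 vif_max = 5, alpha_entry = 0.05,
                                 rescale_fd = TRUE) {
  stopifnot(length(candidates) >= 1)
  if (rescale_fd) tab <- rescale_fd_percent(tab)
  audit <- data.frame(step = character(), variable = character(),
                      action = character(), detail = character())
  note <- function(step, var, action, detail) {
    audit <<- rbind(audit, data.frame(step = step, variable = var,
                                      action = action, detail = detail))
  }
  # (i) univariate screen
  kept <- character()
  for (v in candidates) {
    uf <- fit_logistic_univariate(tab, outcome, v, rescale_fd = FALSE)
    p <- uf$terms$p[uf$terms$term != "(Intercept)"][1]
    if (!is.na(p) && p < p_screen) {
      kept <- c(kept, v)
      note("screen", v, "kept", sprintf("univariate p = %.4g", p))
    } else {
      note("screen", v, "dropped", sprintf("univariate p = %.4g >= %.2g",
                                           p, p_screen))
    }
  }
  if (length(kept) == 0) {
    note("final", "", "empty-model", "no candidate passed the screen")
    return(structure(list(fit = NULL, selected = character(), audit = audit),
                     class = "logistic_selection"))
  }
  # (ii) VIF gate
  while (length(kept) >= 2) {
    v <- compute_vif(tab, kept)
    if (all(v <= vif_max)) break
    worst <- names(v)[which.max(v)]
    note("vif", worst, "excluded", sprintf("VIF>%g (VIF = %.3g)", vif_max,
                                           max(v)))
    kept <- setdiff(kept, worst)
  }
  # (iii) forward selection by likelihood-ratio entry test
  d <- tab[complete.cases(tab[, c(outcome, kept)]), c(outcome, kept)]
  selected <- character()
  repeat {
    remaining <- setdiff(kept, selected)
    if (length(remaining) == 0) break
    cur_f <- as.formula(paste(outcome, "~",
                              if (length(selected)) paste(selected,
                                                          collapse = " + ")
                              else "1"))
    cur <- suppressWarnings(glm(cur_f, data = d, family = binomial()))
    sc <- as.formula(paste("~ . +", paste(remaining, collapse = " + ")))
    a1 <- suppressWarnings(add1(cur, scope = sc, test = "LRT"))
    pvals <- a1[["Pr(>Chi)"]][-1]
    names(pvals) <- rownames(a1)[-1]
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= alpha_entry) {
      for (v in remaining)
        note("forward", v, "not entered",
             sprintf("LRT p = %.4g >= %.2g", pvals[v], alpha_entry))
      break
    }
    best <- names(pvals)[which.min(pvals)]
    selected <- c(selected, best)
    note("forward", best, "entered", sprintf("LRT p = %.4g", min(pvals,
                                                                 na.rm = TRUE)))
  }
  fit <- NULL
  if (length(selected)) {
    f <- as.formula(paste(outcome, "~", paste(selected, collapse = " + ")))
    g <- suppressWarnings(glm(f, data = d, family = binomial()))
    fit <- structure(list(outcome = outcome, terms = logistic_ci(g),
                          n = nrow(d), minus2ll = as.numeric(-2 * logLik(g)),
                          converged = g$converged,
                          separation = separation_flag(g),
                          fd_scale_note = if (rescale_fd)
                            "fractal dimension entered per 0.01 FD unit"
                          else NA_character_,
                          fit = g),
                     class = "logistic_fit")
  } else {
    note("final", "", "empty-model", "no variable passed forward selection")
  }
  structure(list(fit = fit, selected = selected, audit = audit),
            class = "logistic_selection")
}
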