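#' Body surface area by the Mosteller formula
#'
#' BSA (m^2) = sqrt(height\[cm\] * weight\[kg\] / 3600). Vectorized.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @return body surface area in m^2.
#' @export
mosteller_bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Index a volume to body surface area
#'
#' @param volume_ml volume in mL.
#' @param bsa_m2 body surface area in m^2 (> 0).
#' @return indexed volume in mL/m^2.
#' @export
index_to_bsa <- function(volume_ml, bsa_m2) {
  if (any(bsa_m2 <= 0)) stop("BSA must be positive")
  volume_ml / bsa_m2
}

#' Compare a variable across groups with normality-gated test selection
#'
#' Continuous variables: Shapiro-Wilk per group at `alpha_normal` decides the
#' parametric path (every group normal) versus the nonparametric one. Two
#' groups use t / Mann-Whitney, three or more use one-way ANOVA /
#' Kruskal-Wallis with unadjusted pairwise follow-ups. Categorical variables
#' use the chi-square test, or Fisher's exact test when any expected cell
#' count falls below 5. When covariates are supplied for a continuous
#' variable, an ANCOVA group-effect p-value is added (partial F for the group
#' factor in the additive linear model `variable ~ covariates + group`).
#'
#' @param tab data.frame containing `variable`, `group_col` and covariates.
#' @param variable column to compare.
#' @param group_col grouping column name (factor or character).
#' @param covariates optional character vector of covariate columns (ANCOVA).
#' @param categorical treat the variable as categorical; default guesses
#'   (non-numeric, or numeric with <= 4 distinct values coded 0/1/...).
#' @param alpha_normal Shapiro-Wilk significance level for the normality gate.
#' @param pairwise_adjust p.adjust method for pairwise follow-ups ("none"
#'   by default; pairwise flags are conventionally reported unadjusted).
#' @return object of class `group_comparison`: list with `variable`,
#'   `test_used`, `statistic`, `p`, `per_group` summaries, `pairwise`
#'   (data.frame of pairwise p-values), `normal` (per-group Shapiro p),
#'   `ancova_p` (or NA).
#' @export
compare_groups <- function(tab, variable, group_col = "group",
                           covariates = NULL, categorical = NULL,
                           alpha_normal = 0.05, pairwise_adjust = "none") {
  x <- tab[[variable]]
  g <- tab[[group_col]]
  if (is.null(x)) stop("unknown variable: ", variable)
  if (is.null(g)) stop("unknown group column: ", group_col)
  g <- droplevels(factor(g))
  lev <- levels(g)
  if (length(lev) < 2) stop("need >= 2 groups")
  if (is.null(categorical))
    categorical <- !is.numeric(x) || length(unique(x[!is.na(x)])) <= 4
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]

  if (categorical) {
    ct <- table(x, g)
    if (nrow(ct) < 2) stop("degenerate test: variable constant in all groups")
    expected <- outer(rowSums(ct), colSums(ct)) / sum(ct)
    use_fisher <- any(expected < 5)
    res <- if (use_fisher) fisher.test(ct) else
      suppressWarnings(chisq.test(ct, correct = FALSE))
    per_group <- lapply(lev, function(l) {
      n <- table(factor(x[g == l], levels = rownames(ct)))
      sprintf("%s: %d (%.1f%%)", rownames(ct), n, 100 * n / sum(n))
    })
    names(per_group) <- lev
    pw <- pairwise_categorical(ct, lev, pairwise_adjust)
    return(structure(list(variable = variable,
                          test_used = if (use_fisher) "Fisher" else "chi2",
                          statistic = unname(res$statistic %||% NA_real_),
                          p = res$p.value, per_group = per_group,
                          pairwise = pw, normal = NULL, ancova_p = NA_real_),
                     class = "group_comparison"))
  }

  ns <- table(g)
  if (any(ns < 2)) stop("each group needs n >= 2 for continuous tests")
  if (var(x) == 0)
    stop("degenerate test: variable constant in all groups")
  shp <- vapply(lev, function(l) {
    v <- x[g == l]
    if (length(v) < 3 || var(v) == 0) return(0)   # non-normal by convention
    shapiro.test(v)$p.value
  }, numeric(1))
  parametric <- all(shp > alpha_normal)

  if (length(lev) == 2) {
    res <- if (parametric) t.test(x ~ g) else
      suppressWarnings(wilcox.test(x ~ g))
    test_used <- if (parametric) "t" else "MannWhitney"
  } else {
    res <- if (parametric) summary(aov(x ~ g))[[1]] else kruskal.test(x, g)
    test_used <- if (parametric) "ANOVA" else "KruskalWallis"
  }
  if (test_used == "ANOVA") {
    statistic <- res[["F value"]][1]; p <- res[["Pr(>F)"]][1]
  } else {
    statistic <- unname(res$statistic); p <- res$p.value
  }
  per_group <- lapply(lev, function(l) {
    v <- x[g == l]
    if (parametric) sprintf("%.3f ± %.3f", mean(v), sd(v))
    else sprintf("%.3f (%.3f, %.3f)", median(v), quantile(v, .25),
                 quantile(v, .75))
  })
  names(per_group) <- lev
  pw <- NULL
  if (length(lev) > 2) {
    pairs <- utils::combn(lev, 2)
    pvals <- apply(pairs, 2, function(pr) {
      xi <- x[g %in% pr]; gi <- droplevels(g[g %in% pr])
      if (parametric) t.test(xi ~ gi)$p.value
      else suppressWarnings(wilcox.test(xi ~ gi))$p.value
    })
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p = stats::p.adjust(pvals, pairwise_adjust))
  }
  ancova_p <- NA_real_
  if (!is.null(covariates)) {
    d <- tab[keep, c(variable, group_col, covariates)]
    d <- d[complete.cases(d), ]
    f0 <- as.formula(paste(variable, "~",
                           paste(covariates, collapse = " + ")))
    f1 <- as.formula(paste(variable, "~",
                           paste(c(covariates, group_col), collapse = " + ")))
    ancova_p <- anova(lm(f0, data = d), lm(f1, data = d))$`Pr(>F)`[2]
  }
  structure(list(variable = variable, test_used = test_used,
                 statistic = statistic, p = p, per_group = per_group,
                 pairwise = pw, normal = shp, ancova_p = ancova_p),
            class = "group_comparison")
}

pairwise_categorical <- function(ct, lev, adjust) {
  if (length(lev) < 3) return(NULL)
  pairs <- utils::combn(lev, 2)
  pvals <- apply(pairs, 2, function(pr) {
    sub <- ct[, pr, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    if (nrow(sub) < 2) return(NA_real_)
    expected <- outer(rowSums(sub), colSums(sub)) / sum(sub)
    if (any(expected < 5)) fisher.test(sub)$p.value
    else suppressWarnings(chisq.test(sub, correct = FALSE))$p.value
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p = stats::p.adjust(pvals, adjust))
}

#' Spearman rank-correlation matrix with p-values
#'
#' @param tab data.frame.
#' @param row_vars,col_vars column-name vectors; one correlation per pair.
#' @return list with matrices `rho` and `p` of dimension
#'   `length(row_vars) x length(col_vars)`. Pairs involving a constant
#'   column are flagged `NA` (undefined), never silently 0.
#' @export
spearman_correlations <- function(tab, row_vars, col_vars) {
  rho <- matrix(NA_real_, length(row_vars), length(col_vars),
                dimnames = list(row_vars, col_vars))
  p <- rho
  for (rv in row_vars) for (cv in col_vars) {
    x <- tab[[rv]]; y <- tab[[cv]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 4) stop("need >= 4 complete pairs for ", rv, " vs ", cv)
    if (var(x[ok]) == 0 || var(y[ok]) == 0) next  # undefined, stays NA
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    rho[rv, cv] <- unname(ct$estimate)
    p[rv, cv] <- ct$p.value
  }
  list(rho = rho, p = p)
}
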