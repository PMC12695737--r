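#' Run configuration for the slice-to-FD pipeline
#'
#' @param roi `"auto"` or an [roi_circle()] applied to every slice.
#' @param upsample integer upsampling factor before edge extraction.
#' @param box_sizes `"auto"` (powers of two up to 45% of the upsampled side)
#'   or an explicit integer vector.
#' @param split_rule apical/basal split rule, see [summarize_regional_fd()].
#' @param include_papillary include papillary borders in the edge set.
#' @param min_valid_slices minimum valid slices per subject (below this the
#'   subject is flagged not computable).
#' @param r2_threshold per-slice fit validity threshold.
#' @param seed integer seed recorded in outputs (the pipeline itself is
#'   deterministic; the seed seeds any simulated inputs).
#' @return object of class `run_config`.
#' @export
run_config <- function(roi = "auto", upsample = 4L, box_sizes = "auto",
                       split_rule = "midpoint-basal",
                       include_papillary = TRUE, min_valid_slices = 4L,
                       r2_threshold = 0.95, seed = 1L) {
  structure(list(roi = roi, upsample = as.integer(upsample),
                 box_sizes = box_sizes, split_rule = split_rule,
                 include_papillary = include_papillary,
                 min_valid_slices = as.integer(min_valid_slices),
                 r2_threshold = r2_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Segment one slice and estimate its fractal dimension
#'
#' @param img grayscale slice matrix.
#' @param config a [run_config()].
#' @param slice_index apex-first index carried into the result.
#' @return list with `slice_fd` (a `slice_fd`, or NULL on failure),
#'   `edge_map` (or NULL), `log` (list of per-slice decisions).
#' @export
process_slice <- function(img, config, slice_index = NA_integer_) {
  log <- list(slice_index = slice_index)
  res <- tryCatch({
    bp <- binarize_blood_pool(img, roi = config$roi,
                              upsample = config$upsample)
    em <- extract_trabecular_edges(bp,
                                   include_papillary = config$include_papillary)
    sizes <- if (identical(config$box_sizes, "auto"))
      default_box_sizes(edge_extent(em$edge)) else
        as.integer(config$box_sizes)
    sfd <- estimate_fd(box_count(em$edge, sizes), slice_index = slice_index,
                       r2_threshold = config$r2_threshold)
    log$thresholds <- bp$thresholds
    log$iterations <- bp$iterations
    log$n_intracavity <- max(bp$intracavity)
    log$n_edge_pixels <- em$n_edge_pixels
    log$fd <- sfd$fd
    log$fit_r2 <- sfd$fit_r2
    log$valid <- sfd$valid
    if (!sfd$valid)
      log$exclusion_reason <- sprintf("fd %.3f or fit r2 %.3f outside validity bounds",
                                      sfd$fd, sfd$fit_r2)
    list(slice_fd = sfd, edge_map = em, log = log)
  }, error = function(e) {
    log$valid <- FALSE
    log$exclusion_reason <- conditionMessage(e)
    list(slice_fd = NULL, edge_map = NULL, log = log)
  })
  res
}

#' Run the full FD pipeline on one subject's slice stack
#'
#' Segments every slice, estimates per-slice FD, and aggregates the five
#' regional summaries. Slices failing segmentation or validity checks are
#' excluded from all summaries with a machine-readable reason; subjects with
#' fewer than `min_valid_slices` valid slices are flagged not computable
#' (the mechanical analogue of excluding poor-quality short-axis stacks).
#' Deterministic for a fixed stack and config.
#'
#' @param stack a `slice_stack` (list with `slices`, `meta`) as produced by
#'   [generate_stack_phantom()] or [read_stack_png()].
#' @param config a [run_config()].
#' @return object of class `subject_result`: list with `summary` (a
#'   `regional_fd`, or NULL when not computable), `slice_fds`, `manifest`
#'   (per-slice logs, config, config hash, status).
#' @export
run_subject <- function(stack, config = run_config()) {
  stopifnot(!is.null(stack$slices), length(stack$slices) >= 1)
  if (!isTRUE(stack$meta$apex_first)) stop("stack ordering must be apex-first")
  n <- length(stack$slices)
  results <- lapply(seq_len(n), function(i)
    process_slice(stack$slices[[i]], config, slice_index = i))
  slice_fds <- lapply(results, `[[`, "slice_fd")
  logs <- lapply(results, `[[`, "log")
  n_valid <- sum(vapply(slice_fds,
                        function(s) !is.null(s) && isTRUE(s$valid),
                        logical(1)))
  summary <- NULL
  status <- "ok"
  if (n_valid < config$min_valid_slices) {
    status <- sprintf("FD not computable: %d valid slices < %d", n_valid,
                      config$min_valid_slices)
  } else {
    summary <- summarize_regional_fd(
      slice_fds[!vapply(slice_fds, is.null, logical(1))],
      split_rule = config$split_rule,
      min_valid = config$min_valid_slices)
  }
  manifest <- list(slices = logs, config = unclass(config),
                   config_hash = config_hash(unclass(config)),
                   n_slices = n, n_valid = n_valid, status = status,
                   package_version = as.character(utils::packageVersion("trabfd")))
  structure(list(summary = summary, slice_fds = slice_fds,
                 manifest = manifest),
            class = "subject_result")
}

#' Per-slice FD table for a subject result
#'
#' @param res a `subject_result`.
#' @return data.frame with slice_index, fd, fit_r2, n_sizes, valid.
#' @export
slice_fd_table <- function(res) {
  do.call(rbind, lapply(res$manifest$slices, function(l) {
    data.frame(slice_index = l$slice_index,
               fd = l$fd %||% NA_real_, fit_r2 = l$fit_r2 %||% NA_real_,
               n_edge_pixels = l$n_edge_pixels %||% NA_integer_,
               valid = isTRUE(l$valid),
               reason = l$exclusion_reason %||% "")
  }))
}

#' Run the full statistics chain on a cohort table
#'
#' Reproduces the complete cohort analysis: three-group comparisons (with
#' ANCOVA adjustment for age and sex on the FD summaries), Spearman
#' correlations of FD against function and clinical covariates, univariate
#' logistic screening within the hypertensive groups, VIF-gated forward
#' multivariable selection, and the four nested diagnostic models with
#' DeLong and likelihood-ratio comparisons.
#'
#' @param tab cohort data.frame following [cohort_schema()].
#' @param hf_group,ref_group group labels defining the binary outcome among
#'   hypertensives.
#' @param fd_adjust covariates for the FD ANCOVA.
#' @param model_specs nested model predictor lists.
#' @return object of class `cohort_report`: list with `group_comparisons`
#'   (list of `group_comparison`), `correlations`, `univariate` (data.frame),
#'   `selection` (`logistic_selection`), `nested` (`nested_model_set`),
#'   `n_per_group`.
#' @export
run_cohort <- function(tab, hf_group = "HTN_HF", ref_group = "HTN_nonHF",
                       fd_adjust = c("age", "sex"),
                       model_specs = standard_model_specs()) {
  missing_cols <- setdiff(c("group", fd_cols), names(tab))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (length(unique(tab$group)) < 2) stop("need >= 2 groups present")

  cont_vars <- intersect(c("age", "bmi", "bsa", "sbp", "dbp", "lvef",
                           "lvedv", "lvesv", "sv", "max_lvwt", "lvedvi",
                           "lvesvi", fd_cols), names(tab))
  cat_vars <- intersect(c("sex", "diabetes", "smoking", "alcohol",
                          "dyslipidemia", "atrial_fibrillation"),
                        names(tab))
  group_comparisons <- c(
    lapply(cont_vars, function(v)
      compare_groups(tab, v,
                     covariates = if (v %in% fd_cols) fd_adjust else NULL)),
    lapply(cat_vars, function(v) compare_groups(tab, v, categorical = TRUE)))
  names(group_comparisons) <- c(cont_vars, cat_vars)

  corr_cols <- intersect(c("age", "bmi", "bsa", "sbp", "dbp", "lvef",
                           "lvedv", "lvesv", "sv", "max_lvwt", "lvedvi",
                           "lvesvi"), names(tab))
  correlations <- spearman_correlations(tab, fd_cols, corr_cols)

  htn <- droplevels(tab[tab$group %in% c(hf_group, ref_group), ])
  if (nrow(htn) == 0 || length(unique(htn$group)) < 2)
    stop("hypertensive subgroups not found for logistic analysis")
  htn$hf <- as.integer(htn$group == hf_group)
  candidates <- intersect(c("sex", "age", "bmi", "bsa", "sbp", "dbp",
                            "diabetes", "smoking", "alcohol", "dyslipidemia",
                            "atrial_fibrillation", "lvef", "lvedv", "lvesv",
                            "sv", "max_lvwt", "lvedvi", "lvesvi", fd_cols),
                          names(htn))
  univariate <- do.call(rbind, lapply(candidates, function(v) {
    uf <- fit_logistic_univariate(htn, "hf", v)
    t <- uf$terms[uf$terms$term != "(Intercept)", ][1, ]
    data.frame(predictor = v, or = t$or, ci_low = t$ci_low,
               ci_high = t$ci_high, p = t$p, n = uf$n)
  }))
  selection <- select_multivariable(htn, "hf", candidates)
  nested <- build_nested_models(htn, "hf", model_specs)

  structure(list(group_comparisons = group_comparisons,
                 correlations = correlations, univariate = univariate,
                 selection = selection, nested = nested,
                 n_per_group = table(tab$group)),
            class = "cohort_report")
}

#' Group-comparison results as a tidy table
#'
#' @param report a `cohort_report`.
#' @return data.frame with one row per compared variable.
#' @export
comparison_table <- function(report) {
  do.call(rbind, lapply(report$group_comparisons, function(gc) {
    pw <- NA_real_
    if (!is.null(gc$pairwise)) {
      hit <- gc$pairwise$p[(gc$pairwise$group1 == "HTN_nonHF" &
                              gc$pairwise$group2 == "HTN_HF") |
                             (gc$pairwise$group1 == "HTN_HF" &
                                gc$pairwise$group2 == "HTN_nonHF")]
      if (length(hit)) pw <- hit[1]
    }
    data.frame(variable = gc$variable, test = gc$test_used,
               statistic = gc$statistic %||% NA_real_, p = gc$p,
               ancova_p = gc$ancova_p, pairwise_hf_vs_nonhf = pw)
  }))
}

# ---- stack I/O -------------------------------------------------------------

#' Write a slice stack as zero-padded PNGs with a JSON sidecar
#'
#' Slices are written apex-first as `slice_000.png`, `slice_001.png`, ...
#' (intensities rescaled to \[0,1\] jointly across the stack) plus a
#' `stack.json` sidecar with the geometry metadata and intensity range.
#'
#' @param stack a `slice_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_png <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(unlist(lapply(stack$slices, range)))
  for (i in seq_along(stack$slices)) {
    img <- (stack$slices[[i]] - rng[1]) / max(rng[2] - rng[1], 1e-12)
    png::writePNG(img, file.path(dir, sprintf("slice_%03d.png", i - 1)))
  }
  meta <- stack$meta
  meta$intensity_range <- rng
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}

#' Read a slice stack written by [write_stack_png()]
#'
#' @param dir directory containing `slice_*.png` and `stack.json`.
#' @return a `slice_stack` (intensities restored to the original range).
#' @export
read_stack_png <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no slice PNGs found in ", dir)
  rng <- meta$intensity_range %||% c(0, 1)
  slices <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * (rng[2] - rng[1]) + rng[1]
  })
  structure(list(slices = slices, meta = meta, ground_truth = NULL),
            class = "slice_stack")
}
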