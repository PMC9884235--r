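# In-memory end-to-end study on synthetic scans: the desk-scale analog of
# evaluating a quality classifier and the choroid-localization of its
# explanations against ground truth.

#' Synthetic quality-assessment study
#'
#' Runs the complete protocol in memory on a synthetic dataset: generate
#' `n_good + n_bad` preset scans, cross-validate the classifier with
#' stratified K folds, compute a Grad-CAM saliency map for every scan with
#' the model of the fold that held it out, threshold the maps at `tau`, and
#' score OCC/CCVR against each scan's exact choroid mask. Alongside the
#' metrics report it returns the quantities that judge choroid-localized
#' attention: mean coverage among correctly classified scans per quality
#' class, against the mean choroid area fraction (the coverage a spatially
#' random explanation would achieve).
#'
#' By default the `"good"`-class logit is explained for every scan, so a
#' bad-quality scan's map shows which regions speak for (residual) choroid
#' quality; see the package vignette for the rationale.
#'
#' @param n_good,n_bad scans per quality class.
#' @param cohort_mix fraction of each class in the diseased cohort.
#' @param seed master seed for generation, folds and training.
#' @param config a [model_config()].
#' @param K cross-validation folds.
#' @param tau visibility threshold for coverage scoring.
#' @param explain_class class logit to explain (`"good"`, `"bad"` or
#'   `"predicted"`).
#' @param good_spec,bad_spec preset overrides (named lists).
#' @return list with `cv` (a [cross_validate()] report, models dropped),
#'   `scores` (per-image coverage rows with a `correct` flag),
#'   `summary` (the [group_summary()] table), `mean_ccvr_bad_correct`,
#'   `mean_occ_bad_correct`, `mean_ccvr_good_correct`,
#'   `mean_area_fraction`, and `agreement` between coverage at `tau` and
#'   at `min(tau + 0.1, 1)`.
#' @export
quality_assessment_study <- function(n_good = 200L, n_bad = 200L,
                                     cohort_mix = 0.5, seed = 1L,
                                     config = small_cnn_config(seed = seed),
                                     K = 5L, tau = 0.5,
                                     explain_class = "good",
                                     good_spec = list(),
                                     bad_spec = list()) {
  specs <- dataset_specs(n_good, n_bad, cohort_mix, seed,
                         good_spec, bad_spec)
  n <- length(specs)
  size <- config$input_size
  x4 <- array(0, c(size, size, 1L, n))
  masks <- vector("list", n)
  labels <- character(n)
  cohorts <- character(n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    sc <- generate_scan(specs[[i]])
    x4[, , 1L, i] <- resize_gray(sc$image, size, size)
    masks[[i]] <- sc$choroid_mask
    labels[i] <- sc$quality_label
    cohorts[i] <- sc$cohort_label
    area[i] <- mean(sc$choroid_mask)
  }

  cv <- cross_validate(x4, labels, config, K = K, seed = seed,
                       keep_models = TRUE)

  tau_b <- min(tau + 0.1, 1)
  rows <- vector("list", n)
  rows_b <- vector("list", n)
  for (i in seq_len(n)) {
    model <- cv$models[[cv$oof$fold[i]]]
    sal <- gradcam(model, x4[, , 1L, i], class = explain_class,
                   target_size = dim(masks[[i]]))
    rows[[i]] <- suppressWarnings(coverage_scores(
      unclass(sal), masks[[i]], tau = tau, image = sprintf("scan_%04d", i),
      quality_label = labels[i], cohort_label = cohorts[i]))
    rows_b[[i]] <- suppressWarnings(coverage_scores(
      unclass(sal), masks[[i]], tau = tau_b))
  }
  scores <- do.call(rbind, rows)
  scores$correct <- cv$oof$predicted == as_binary_labels(labels)
  scores_b <- do.call(rbind, rows_b)

  sel <- function(quality) scores$correct & scores$quality_label == quality
  out <- list(
    cv = cv[setdiff(names(cv), "models")],
    scores = scores,
    summary = suppressMessages(group_summary(scores)),
    mean_ccvr_bad_correct = mean(scores$ccvr[sel("bad")], na.rm = TRUE),
    mean_occ_bad_correct = mean(scores$occ[sel("bad")], na.rm = TRUE),
    mean_ccvr_good_correct = mean(scores$ccvr[sel("good")], na.rm = TRUE),
    mean_area_fraction = mean(area),
    agreement = agreement_report(scores, scores_b),
    n = n)
  class(out$cv) <- "metrics_report"
  out
}
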