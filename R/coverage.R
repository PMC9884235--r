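# Choroid-coverage explainability scores. T is the "visible" (transparent)
# region of a CTM — operationalized as the saliency pixels at or above a
# threshold tau — and C the ground-truth choroid region. OCC = |T∩C|/|C| is
# how much of the choroid the model makes visible; CCVR = |T∩C|/|T| is how
# much of what it makes visible is choroid.

#' Threshold a saliency map into a visible region
#'
#' @param saliency relevance map in `[0, 1]` (see [gradcam()]).
#' @param tau threshold in `(0, 1]`; a pixel is visible iff its relevance
#'   is `>= tau`. An all-zero saliency map yields an empty region.
#' @return object of class `visible_region`: list with logical `mask` and
#'   `tau`.
#' @export
visible_region <- function(saliency, tau = 0.5) {
  stopifnot(is.matrix(saliency), tau > 0, tau <= 1)
  structure(list(mask = unclass(saliency) >= tau, tau = tau),
            class = "visible_region")
}

as_region_mask <- function(x) {
  if (inherits(x, "visible_region")) return(x$mask)
  if (is.matrix(x)) return(x > 0)
  stop("expected a visible_region or a binary matrix")
}

#' Overall choroid coverage (OCC)
#'
#' `|T ∩ C| / |C|`: the fraction of the actual choroid region made visible
#' in the CTM.
#'
#' @param T visible region ([visible_region()] or binary matrix).
#' @param C choroid mask (binary matrix).
#' @return fraction in `[0, 1]`; `NaN` with a warning when the choroid mask
#'   is empty.
#' @export
occ <- function(T, C) {
  Tm <- as_region_mask(T); Cm <- as_region_mask(C)
  stopifnot(identical(dim(Tm), dim(Cm)))
  nc <- sum(Cm)
  if (nc == 0) {
    warning("OCC undefined: empty choroid mask")
    return(NaN)
  }
  sum(Tm & Cm) / nc
}

#' Choroid coverage within the visible region (CCVR)
#'
#' `|T ∩ C| / |T|`: the fraction of the visible region that lies in the
#' choroid.
#'
#' @inheritParams occ
#' @return fraction in `[0, 1]`; `NaN` with a warning when the visible
#'   region is empty (fully opaque CTM).
#' @export
ccvr <- function(T, C) {
  Tm <- as_region_mask(T); Cm <- as_region_mask(C)
  stopifnot(identical(dim(Tm), dim(Cm)))
  nt <- sum(Tm)
  if (nt == 0) {
    warning("CCVR undefined: empty visible region")
    return(NaN)
  }
  sum(Tm & Cm) / nt
}

#' Coverage scores for one image
#'
#' @param saliency relevance map in `[0, 1]`.
#' @param choroid_mask ground-truth choroid mask (binary matrix).
#' @param tau visibility threshold (see [visible_region()]).
#' @param image,quality_label,cohort_label metadata carried into the score
#'   row.
#' @return one-row `data.frame`: `image`, `occ`, `ccvr`, `abs_diff`,
#'   `quality_label`, `cohort_label`.
#' @export
coverage_scores <- function(saliency, choroid_mask, tau = 0.5,
                            image = NA_character_,
                            quality_label = NA_character_,
                            cohort_label = NA_character_) {
  Tr <- visible_region(saliency, tau)
  o <- occ(Tr, choroid_mask)
  c_ <- ccvr(Tr, choroid_mask)
  data.frame(image = image, occ = o, ccvr = c_, abs_diff = abs(o - c_),
             quality_label = quality_label, cohort_label = cohort_label,
             stringsAsFactors = FALSE)
}

#' Sub-group coverage summary
#'
#' Mean OCC, CCVR and |OCC − CCVR| (the mean of the per-image absolute
#' differences) per cohort x quality sub-group and overall, reported in
#' percent. Undefined (NaN) scores are excluded from the means; the number
#' excluded per group is reported and logged.
#'
#' @param scores `data.frame` of per-image rows as produced by
#'   [coverage_scores()] (columns `occ`, `ccvr`, `abs_diff`,
#'   `quality_label`, `cohort_label`).
#' @return `data.frame` with one row per sub-group plus `"Overall"`:
#'   columns `group`, `n`, `n_excluded`, `occ_pct`, `ccvr_pct`,
#'   `abs_diff_pct`.
#' @export
group_summary <- function(scores) {
  stopifnot(all(c("occ", "ccvr", "abs_diff") %in% names(scores)))
  groups <- list(
    "Healthy Good" = scores$cohort_label == "healthy" &
      scores$quality_label == "good",
    "Healthy Bad" = scores$cohort_label == "healthy" &
      scores$quality_label == "bad",
    "Diseased Good" = scores$cohort_label == "diseased" &
      scores$quality_label == "good",
    "Diseased Bad" = scores$cohort_label == "diseased" &
      scores$quality_label == "bad",
    "Overall" = rep(TRUE, nrow(scores)))
  rows <- lapply(names(groups), function(g) {
    sub <- scores[which(groups[[g]]), , drop = FALSE]
    ok <- stats::complete.cases(sub[, c("occ", "ccvr")]) &
      is.finite(sub$occ) & is.finite(sub$ccvr)
    n_excl <- nrow(sub) - sum(ok)
    sub <- sub[ok, , drop = FALSE]
    data.frame(group = g, n = nrow(sub), n_excluded = n_excl,
               occ_pct = 100 * mean(sub$occ),
               ccvr_pct = 100 * mean(sub$ccvr),
               abs_diff_pct = 100 * mean(sub$abs_diff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  excluded <- sum(out$n_excluded[out$group != "Overall"])
  if (excluded > 0)
    message(excluded, " image(s) with undefined coverage scores excluded ",
            "from sub-group means")
  out
}

#' Coverage as a function of the visibility threshold
#'
#' Convenience sweep of OCC and CCVR over a grid of thresholds, for
#' choosing or reporting sensitivity to `tau`.
#'
#' @param saliency relevance map.
#' @param choroid_mask ground-truth choroid mask.
#' @param taus thresholds to evaluate.
#' @return `data.frame` with columns `tau`, `occ`, `ccvr`.
#' @export
coverage_sweep <- function(saliency, choroid_mask,
                           taus = seq(0.1, 1, by = 0.1)) {
  rows <- lapply(taus, function(tau) {
    Tr <- visible_region(saliency, tau)
    data.frame(tau = tau,
               occ = suppressWarnings(occ(Tr, choroid_mask)),
               ccvr = suppressWarnings(ccvr(Tr, choroid_mask)))
  })
  do.call(rbind, rows)
}
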