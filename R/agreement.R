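# Inter-rater reliability between two score series (two graders, or an
# automated scorer against a reference).

#' Bland–Altman-style correlation between two score series
#'
#' The `"as-printed"` variant evaluates the reliability formula verbatim:
#' `sum(x * y) / sqrt(sum(x) * sum(y))`. Note that this expression is not
#' scale-invariant (doubling both series doubles it), so it is not bounded
#' by 1; it is provided for fidelity to the published definition. The
#' `"cosine"` variant computes cosine similarity,
#' `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`, which for non-negative series
#' lies in `[0, 1]` and equals 1 exactly when one series is a positive
#' multiple of the other. Both are symmetric in `x` and `y`.
#'
#' @param x,y equal-length numeric series of non-negative scores.
#' @param variant `"as-printed"` (default) or `"cosine"`.
#' @return scalar; `NaN` with a warning when a denominator vanishes.
#' @export
ba_correlation <- function(x, y, variant = c("as-printed", "cosine")) {
  variant <- match.arg(variant)
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (any(x < 0) || any(y < 0))
    stop("scores must be non-negative")
  denom <- if (variant == "as-printed") sqrt(sum(x) * sum(y))
           else sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) {
    warning("correlation undefined: zero denominator")
    return(NaN)
  }
  sum(x * y) / denom
}

#' Agreement report for OCC and CCVR score pairs
#'
#' Computes both correlation variants for the OCC and the CCVR series of
#' two raters. Inputs are either two-column lists/data frames with `occ`
#' and `ccvr` (per-image scores from each rater, as produced by
#' [coverage_scores()]) or explicit pairs.
#'
#' @param scores_a,scores_b per-rater score tables with columns `occ` and
#'   `ccvr`, row-aligned by image.
#' @return object of class `agreement_report`: list with `n` and, per
#'   metric, `as_printed` and `cosine` values (cosine also formatted as a
#'   percentage by the print method).
#' @export
agreement_report <- function(scores_a, scores_b) {
  stopifnot(all(c("occ", "ccvr") %in% names(scores_a)),
            all(c("occ", "ccvr") %in% names(scores_b)))
  if (length(scores_a$occ) != length(scores_b$occ))
    stop("score tables must be row-aligned")
  keep <- is.finite(scores_a$occ) & is.finite(scores_b$occ) &
    is.finite(scores_a$ccvr) & is.finite(scores_b$ccvr)
  a <- lapply(scores_a[c("occ", "ccvr")], function(v) v[keep])
  b <- lapply(scores_b[c("occ", "ccvr")], function(v) v[keep])
  res <- list(n = sum(keep))
  for (m in c("occ", "ccvr")) {
    res[[m]] <- list(
      as_printed = ba_correlation(a[[m]], b[[m]], "as-printed"),
      cosine = ba_correlation(a[[m]], b[[m]], "cosine"))
  }
  structure(res, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> N = %d image pairs\n", x$n))
  for (m in c("occ", "ccvr"))
    cat(sprintf("  %-5s cosine %6.2f%%   as-printed %.4f\n",
                toupper(m), 100 * x[[m]]$cosine, x[[m]]$as_printed))
  invisible(x)
}
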