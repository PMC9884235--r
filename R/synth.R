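# Synthetic B-scan simulator.
#
# A scan is a stack of horizontal tissue bands (vitreous / retina / choroid /
# sclera) separated by smooth boundary curves, with elliptical low-intensity
# vessel lumina inside the choroid, multiplicative speckle, and exponential
# depth attenuation. The four degradation axes mirror the determinants of
# choroidal image quality: luminal/stromal contrast, choroid/sclera contrast,
# speckle noise and signal attenuation.

#' Specification of a synthetic B-scan
#'
#' Collects the geometry, intensity, degradation and label parameters from
#' which [generate_scan()] builds one image. All intensity levels are mean
#' reflectivities in `[0, 1]`.
#'
#' @param height,width canvas size in pixels.
#' @param cib_curve,cob_curve optional functions mapping a column index
#'   vector to choroid inner/outer boundary row positions. When `NULL`
#'   (default) smooth random low-order sinusoid boundaries are drawn from
#'   `seed`; diseased cohorts get thinner, more irregular bands.
#' @param vessel_count number of luminal (vessel) blobs placed inside the
#'   choroid band.
#' @param vessel_radius_range length-2 vector, pixels: range of vessel
#'   vertical semi-axes.
#' @param luminal_level,stromal_level,retina_level,sclera_level,vitreous_level
#'   mean intensities of the tissue compartments, each in `[0, 1]`.
#' @param speckle_strength standard deviation of the mean-one multiplicative
#'   speckle field; `0` disables speckle.
#' @param attenuation_factor depth attenuation in `[0, 1]`: intensity is
#'   scaled by `exp(-4 * attenuation_factor * d)` where `d` is the depth
#'   below the inner retinal surface as a fraction of image height (the
#'   vitreous above the tissue is unattenuated).
#' @param retina_thickness thickness in pixels of the retina band above the
#'   choroid inner boundary.
#' @param quality_label `"good"` or `"bad"`.
#' @param cohort_label `"healthy"` or `"diseased"`.
#' @param seed integer seed; identical specs generate bit-identical scans.
#' @return an object of class `synthetic_spec`.
#' @seealso [good_quality_spec()], [bad_quality_spec()], [generate_scan()]
#' @export
synthetic_spec <- function(height = 496L, width = 768L,
                           cib_curve = NULL, cob_curve = NULL,
                           vessel_count = 12L,
                           vessel_radius_range = c(6, 16),
                           luminal_level = 0.15, stromal_level = 0.75,
                           retina_level = 0.55, sclera_level = 0.40,
                           vitreous_level = 0.05,
                           speckle_strength = 0.25,
                           attenuation_factor = 0.20,
                           retina_thickness = round(0.12 * height),
                           quality_label = c("good", "bad"),
                           cohort_label = c("healthy", "diseased"),
                           seed = 1L) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    cib_curve = cib_curve, cob_curve = cob_curve,
    vessel_count = as.integer(vessel_count),
    vessel_radius_range = as.numeric(vessel_radius_range),
    luminal_level = luminal_level, stromal_level = stromal_level,
    retina_level = retina_level, sclera_level = sclera_level,
    vitreous_level = vitreous_level,
    speckle_strength = speckle_strength,
    attenuation_factor = attenuation_factor,
    retina_thickness = as.integer(retina_thickness),
    quality_label = match.arg(quality_label),
    cohort_label = match.arg(cohort_label),
    seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  levels <- c(spec$luminal_level, spec$stromal_level, spec$retina_level,
              spec$sclera_level, spec$vitreous_level)
  if (any(levels < 0 | levels > 1))
    stop("all intensity levels must lie in [0, 1]")
  if (spec$speckle_strength < 0)
    stop("speckle_strength must be >= 0")
  if (spec$attenuation_factor < 0 || spec$attenuation_factor > 1)
    stop("attenuation_factor must lie in [0, 1]")
  if (spec$height < 16 || spec$width < 16)
    stop("canvas must be at least 16 x 16 pixels")
  if (spec$vessel_count < 0) stop("vessel_count must be >= 0")
  if (length(spec$vessel_radius_range) != 2 ||
      any(spec$vessel_radius_range <= 0))
    stop("vessel_radius_range must be two positive values")
  if (!is.null(spec$cib_curve) != !is.null(spec$cob_curve))
    stop("cib_curve and cob_curve must be given together")
  invisible(spec)
}

#' Good-quality preset
#'
#' High luminal/stromal and stroma/sclera contrast, light speckle and mild
#' attenuation — the profile an expert would grade as clinically usable.
#'
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
good_quality_spec <- function(...) {
  synthetic_spec(quality_label = "good", ...)
}

#' Bad-quality preset
#'
#' Collapsed luminal/stromal and stroma/sclera contrast gaps — the
#' choroid-local determinants an expert grades on — with moderately
#' elevated speckle and depth attenuation: the choroid is present but its
#' features are not gradable.
#'
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
bad_quality_spec <- function(...) {
  defaults <- list(luminal_level = 0.40, stromal_level = 0.50,
                   sclera_level = 0.40, retina_level = 0.55,
                   vitreous_level = 0.05,
                   speckle_strength = 0.35, attenuation_factor = 0.35,
                   quality_label = "bad")
  args <- modifyList(defaults, list(...))
  do.call(synthetic_spec, args)
}

# Smooth boundary curves: baseline + two random sinusoid harmonics. Diseased
# cohorts get a thinner band with larger undulation amplitude. Called inside
# the scan's seeded RNG scope.
draw_boundaries <- function(spec) {
  h <- spec$height; w <- spec$width
  x <- seq_len(w)
  diseased <- spec$cohort_label == "diseased"
  amp_scale <- if (diseased) 1.8 else 1
  thick_scale <- if (diseased) 0.7 else 1
  sinusoid <- function(amp) {
    f <- runif(2, 0.5, 2.5); ph <- runif(2, 0, 2 * pi)
    a <- runif(2, 0.3, 1) * amp
    a[1] * sin(2 * pi * f[1] * x / w + ph[1]) +
      a[2] * sin(2 * pi * f[2] * x / w + ph[2])
  }
  cib <- h * (0.42 + runif(1, -0.03, 0.03)) + sinusoid(0.025 * h * amp_scale)
  thickness <- h * 0.18 * thick_scale * (1 + runif(1, -0.1, 0.1)) +
    sinusoid(0.015 * h * amp_scale)
  thickness <- pmax(thickness, 0.05 * h)
  list(cib = round(cib), cob = round(cib + thickness))
}

#' Generate one synthetic B-scan
#'
#' Builds the layered image described by a [synthetic_spec()]: vitreous over
#' retina over the choroid band (stromal background with elliptical luminal
#' vessels) over sclera; then applies mean-one multiplicative speckle scaled
#' by `speckle_strength`, an exponential depth decay governed by
#' `attenuation_factor`, and clips to `[0, 1]`. The ground-truth choroid
#' mask and boundary vectors are returned exactly as constructed — noise
#' never alters them.
#'
#' The choroid mask uses the half-open band convention: pixel `(r, x)` is in
#' the choroid iff `cib[x] <= r < cob[x]` (rows 1-based, origin top-left).
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_scan`: list with `image` (matrix in
#'   `[0, 1]`), `choroid_mask` (logical matrix), `vessel_mask` (logical
#'   matrix), `cib`, `cob` (integer row vectors per column),
#'   `quality_label`, `cohort_label`, `spec`.
#' @export
generate_scan <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  withr::with_seed(spec$seed, generate_scan_impl(spec))
}

generate_scan_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  if (is.null(spec$cib_curve)) {
    b <- draw_boundaries(spec)
    cib <- b$cib; cob <- b$cob
  } else {
    x <- seq_len(w)
    cib <- round(spec$cib_curve(x)); cob <- round(spec$cob_curve(x))
    if (length(cib) != w || length(cob) != w)
      stop("boundary curves must return one row per column")
  }
  if (any(cib >= cob))
    stop("invalid boundaries: cib must lie strictly above cob in every column")
  ilm <- cib - spec$retina_thickness
  if (any(ilm < 2) || any(cob > h))
    stop("boundaries leave no room for the retina band or exceed the canvas")

  R <- matrix(seq_len(h), h, w)
  cibm <- matrix(cib, h, w, byrow = TRUE)
  cobm <- matrix(cob, h, w, byrow = TRUE)
  ilmm <- matrix(ilm, h, w, byrow = TRUE)

  img <- matrix(spec$vitreous_level, h, w)
  img[R >= ilmm] <- spec$retina_level
  choroid <- R >= cibm & R < cobm
  img[choroid] <- spec$stromal_level
  img[R >= cobm] <- spec$sclera_level

  vessel <- matrix(FALSE, h, w)
  if (spec$vessel_count > 0) {
    rr <- spec$vessel_radius_range
    for (v in seq_len(spec$vessel_count)) {
      ay <- runif(1, rr[1], rr[2])
      ax <- ay * runif(1, 1.2, 2.5)
      cx <- runif(1, 1 + ax, w - ax)
      col0 <- round(cx)
      top <- cib[col0] + ay + 1
      bot <- cob[col0] - ay - 1
      if (bot <= top) next    # band locally too thin for this vessel
      cy <- runif(1, top, bot)
      rows <- max(1L, floor(cy - ay)):min(h, ceiling(cy + ay))
      cols <- max(1L, floor(cx - ax)):min(w, ceiling(cx + ax))
      er <- outer(((rows - cy) / ay)^2, ((cols - cx) / ax)^2, "+") <= 1
      sub <- er & choroid[rows, cols, drop = FALSE]
      vessel[rows, cols][sub] <- TRUE
    }
    img[vessel] <- spec$luminal_level
  }

  # depth decay accumulates below the tissue entry (the inner retinal
  # surface), so vitreous stays unattenuated and a high attenuation_factor
  # washes out the choroid band and sclera under an intact-looking retina
  depth <- pmax(R - ilmm, 0) / h
  img <- img * exp(-4 * spec$attenuation_factor * depth)
  if (spec$speckle_strength > 0) {
    s2 <- spec$speckle_strength^2
    img <- img * matrix(rgamma(h * w, shape = 1 / s2, rate = 1 / s2), h, w)
  }
  img <- clip01(img)

  structure(list(image = img, choroid_mask = choroid, vessel_mask = vessel,
                 cib = as.integer(cib), cob = as.integer(cob),
                 quality_label = spec$quality_label,
                 cohort_label = spec$cohort_label, spec = spec),
            class = "synthetic_scan")
}

#' Reconstruct the choroid band mask from boundary vectors
#'
#' @param cib,cob integer row vectors (one entry per column).
#' @param height image height in pixels.
#' @return logical matrix: `TRUE` where `cib[x] <= r < cob[x]`.
#' @export
band_mask <- function(cib, cob, height) {
  stopifnot(length(cib) == length(cob))
  R <- matrix(seq_len(height), height, length(cib))
  R >= matrix(cib, height, length(cib), byrow = TRUE) &
    R < matrix(cob, height, length(cib), byrow = TRUE)
}

#' @export
print.synthetic_scan <- function(x, ...) {
  cat(sprintf("<synthetic_scan> %d x %d, quality=%s, cohort=%s, seed=%d\n",
              nrow(x$image), ncol(x$image), x$quality_label, x$cohort_label,
              x$spec$seed))
  cat(sprintf("  choroid band: %d px mean thickness, area fraction %.3f\n",
              round(mean(x$cob - x$cib)), mean(x$choroid_mask)))
  invisible(x)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_good + n_bad` scans as 8-bit grayscale PNGs with `{0, 255}`
#' choroid-mask PNGs and a JSON sidecar per scan (scan parameters, labels
#' and boundary arrays), plus a CSV manifest. Per-image seeds are derived
#' deterministically from the master seed, so the same call reproduces the
#' same dataset bit for bit.
#'
#' @param n_good,n_bad number of good- and bad-quality scans.
#' @param out_dir output directory (created if needed).
#' @param cohort_mix fraction of each quality class assigned to the
#'   `"diseased"` cohort (`round(cohort_mix * n)` scans per class).
#' @param seed master seed.
#' @param good_spec,bad_spec named lists of overrides applied to
#'   [good_quality_spec()] / [bad_quality_spec()].
#' @return the manifest `data.frame` (columns `image_path`, `mask_path`,
#'   `quality_label`, `cohort_label`, `seed`), invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_good, n_bad, out_dir, cohort_mix = 0.5,
                             seed = 1L, good_spec = list(),
                             bad_spec = list()) {
  stopifnot(n_good >= 0, n_bad >= 0, cohort_mix >= 0, cohort_mix <= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  specs <- dataset_specs(n_good, n_bad, cohort_mix, seed, good_spec, bad_spec)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    scan <- generate_scan(specs[[i]])
    stem <- sprintf("scan_%04d_%s_%s", i, scan$quality_label,
                    scan$cohort_label)
    image_path <- file.path(out_dir, paste0(stem, ".png"))
    mask_path <- file.path(out_dir, paste0(stem, ".mask.png"))
    write_gray_image(scan$image, image_path)
    write_mask_image(scan$choroid_mask, mask_path)
    side <- scan$spec[setdiff(names(scan$spec), c("cib_curve", "cob_curve"))]
    jsonlite::write_json(
      c(side, list(cib = scan$cib, cob = scan$cob)),
      file.path(out_dir, paste0(stem, ".json")), auto_unbox = TRUE)
    rows[[i]] <- data.frame(image_path = image_path, mask_path = mask_path,
                            quality_label = scan$quality_label,
                            cohort_label = scan$cohort_label,
                            seed = scan$spec$seed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Deterministic spec list for a dataset: per-image seeds drawn once from the
# master seed; within each quality class the first round(cohort_mix * n)
# scans (in a seed-shuffled order) are diseased.
dataset_specs <- function(n_good, n_bad, cohort_mix, seed,
                          good_overrides = list(), bad_overrides = list()) {
  n <- n_good + n_bad
  if (n == 0) return(list())
  withr::with_seed(as.integer(seed), {
    img_seeds <- sample.int(.Machine$integer.max - 1L, n)
    cohorts <- function(k) {
      n_dis <- round(cohort_mix * k)
      sample(c(rep("diseased", n_dis), rep("healthy", k - n_dis)))
    }
    coh <- c(if (n_good > 0) cohorts(n_good), if (n_bad > 0) cohorts(n_bad))
  })
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    args <- modifyList(
      list(seed = img_seeds[i], cohort_label = coh[i]),
      if (i <= n_good) good_overrides else bad_overrides)
    specs[[i]] <- do.call(
      if (i <= n_good) good_quality_spec else bad_quality_spec, args)
  }
  specs
}

#' Read a dataset manifest
#'
#' @param path a manifest CSV (columns `image_path`, `quality_label`, and
#'   optionally `mask_path`, `cohort_label`, `seed`).
#' @return `data.frame` with character columns.
#' @export
load_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_path", "quality_label")
  if (!all(required %in% names(m)))
    stop("manifest must contain columns: ", paste(required, collapse = ", "))
  m
}
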