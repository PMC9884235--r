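test_that("identical specs generate bit-identical scans", {
  s1 <- generate_scan(tiny_good(seed = 11))
  s2 <- generate_scan(tiny_good(seed = 11))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$choroid_mask, s2$choroid_mask)
  s3 <- generate_scan(tiny_good(seed = 12))
  expect_false(identical(s1$image, s3$image))
})

test_that("noise-free vessel-free scan is piecewise constant at the set levels", {
  s <- generate_scan(tiny_good(seed = 3, speckle_strength = 0,
                               attenuation_factor = 0, vessel_count = 0))
  expect_equal(mean(s$image[s$choroid_mask]), 0.75)
  expect_equal(unique(as.vector(s$image[s$choroid_mask])), 0.75)
  # below the band: sclera
  below <- band_mask(s$cob, rep(nrow(s$image) + 1L, length(s$cob)),
                     nrow(s$image))
  expect_equal(unique(as.vector(s$image[below])), 0.40)
})

test_that("choroid mask matches the half-open band implied by cib/cob", {
  for (seed in c(1, 9, 33)) {
    s <- generate_scan(tiny_bad(seed = seed))
    expect_identical(s$choroid_mask,
                     band_mask(s$cib, s$cob, nrow(s$image)))
    expect_true(all(s$cib < s$cob))
    # half-open convention: boundary rows themselves
    x <- 17L
    expect_true(s$choroid_mask[s$cib[x], x])
    expect_false(s$choroid_mask[s$cob[x], x])
  }
})

test_that("good spec has larger choroid/sclera contrast than bad spec", {
  for (seed in c(2, 5, 8)) {
    sg <- generate_scan(tiny_good(seed = seed))
    sb <- generate_scan(tiny_bad(seed = seed))
    contrast <- function(s) {
      below <- band_mask(pmin(s$cob + 1L, nrow(s$image)),
                         rep(nrow(s$image) + 1L, length(s$cob)),
                         nrow(s$image))
      abs(mean(s$image[s$choroid_mask]) - mean(s$image[below]))
    }
    expect_gt(contrast(sg), contrast(sb))
  }
})

test_that("explicit boundary curves are honored and invalid ordering rejected", {
  flat <- function(level) function(x) rep(level, length(x))
  s <- generate_scan(tiny_good(seed = 1, cib_curve = flat(40),
                               cob_curve = flat(60)))
  expect_identical(unique(s$cib), 40L)
  expect_identical(unique(s$cob), 60L)
  expect_equal(sum(s$choroid_mask), 20 * 128)
  expect_error(
    generate_scan(tiny_good(seed = 1, cib_curve = flat(60),
                            cob_curve = flat(40))),
    "cib must lie strictly above cob")
})

test_that("speckle does not increase the luminal/stromal contrast-to-noise ratio", {
  cnr <- function(s) {
    stroma <- s$choroid_mask & !s$vessel_mask
    abs(mean(s$image[s$vessel_mask]) - mean(s$image[stroma])) /
      sd(s$image[stroma])
  }
  values <- vapply(c(0, 0.15, 0.35, 0.6), function(sp)
    cnr(generate_scan(tiny_good(seed = 21, speckle_strength = sp))),
    numeric(1))
  expect_true(all(diff(values) < 1e-8))
})

test_that("in-band gradient energy separates the default presets", {
  n <- 100
  energy <- function(s) {
    g <- diff(s$image)                       # vertical first differences
    mean(g[s$choroid_mask[-1, ] & s$choroid_mask[-nrow(s$image), ]]^2)
  }
  e_good <- vapply(seq_len(n), function(i)
    energy(generate_scan(tiny_good(seed = 1000 + i))), numeric(1))
  e_bad <- vapply(seq_len(n), function(i)
    energy(generate_scan(tiny_bad(seed = 2000 + i))), numeric(1))
  # best threshold on the pooled sample, direction-agnostic
  all_e <- c(e_good, e_bad)
  y <- rep(c(1, 0), each = n)
  acc <- vapply(all_e, function(th)
    max(mean((all_e >= th) == (y == 1)), mean((all_e < th) == (y == 1))),
    numeric(1))
  expect_gte(max(acc), 0.95)
})

test_that("generate_dataset writes a consistent, reproducible manifest", {
  d1 <- withr::local_tempdir()
  man <- generate_dataset(2, 2, d1, cohort_mix = 0.5, seed = 5,
                          good_spec = list(height = 96L, width = 128L),
                          bad_spec = list(height = 96L, width = 128L))
  expect_equal(nrow(man), 4)
  expect_equal(sum(man$quality_label == "good"), 2)
  expect_equal(sum(man$quality_label == "bad"), 2)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))

  # round-trip: written mask equals regenerated ground truth
  sc <- generate_scan(good_quality_spec(height = 96L, width = 128L,
                                        seed = man$seed[man$quality_label == "good"][1],
                                        cohort_label = man$cohort_label[man$quality_label == "good"][1]))
  mask <- read_mask_image(man$mask_path[man$quality_label == "good"][1])
  expect_identical(mask, sc$choroid_mask)

  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(2, 2, d2, cohort_mix = 0.5, seed = 5,
                           good_spec = list(height = 96L, width = 128L),
                           bad_spec = list(height = 96L, width = 128L))
  expect_identical(man$seed, man2$seed)
  expect_identical(man$cohort_label, man2$cohort_label)
  expect_identical(read_gray_image(man$image_path[1]),
                   read_gray_image(man2$image_path[1]))
})

test_that("cohort mix is honored per quality class", {
  d <- withr::local_tempdir()
  man <- generate_dataset(8, 8, d, cohort_mix = 0.25, seed = 2,
                          good_spec = list(height = 96L, width = 128L),
                          bad_spec = list(height = 96L, width = 128L))
  for (q in c("good", "bad"))
    expect_equal(sum(man$cohort_label == "diseased" & man$quality_label == q),
                 round(0.25 * 8))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(luminal_level = 1.2), "intensity levels")
  expect_error(synthetic_spec(speckle_strength = -0.1), "speckle_strength")
  expect_error(synthetic_spec(attenuation_factor = 2), "attenuation_factor")
  expect_error(synthetic_spec(vessel_radius_range = c(0, 5)),
               "vessel_radius_range")
})
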