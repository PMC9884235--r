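# Small fixtures shared across tests: reduced-canvas synthetic specs and
# fixed-weight toy networks.

# a small canvas keeps the unit tests fast; geometry scales with height
tiny_good <- function(...) {
  args <- modifyList(list(height = 96L, width = 128L, vessel_count = 4L,
                          vessel_radius_range = c(3, 6)), list(...))
  do.call(good_quality_spec, args)
}
tiny_bad <- function(...) {
  args <- modifyList(list(height = 96L, width = 128L, vessel_count = 4L,
                          vessel_radius_range = c(3, 6)), list(...))
  do.call(bad_quality_spec, args)
}

# fixed-weight two-convolution network without pooling: every activation is
# differentiable almost everywhere and pool-tie artifacts cannot arise, so
# finite differences are a clean oracle
fixed_two_conv_net <- function(input_size = 12L, seed = 101L) {
  withr::with_seed(seed, {
    W1 <- matrix(rnorm(9 * 3, sd = 0.5), 9, 3)
    b1 <- runif(3, 0.05, 0.2)
    W2 <- matrix(rnorm(27 * 4, sd = 0.3), 27, 4)
    b2 <- runif(4, 0.05, 0.2)
    Wd <- matrix(rnorm(8), 4, 2)
  })
  qc_network(list(layer_conv(W1, b1), layer_relu(),
                  layer_conv(W2, b2), layer_relu(),
                  layer_gap(), layer_dense(Wd, c(0, 0))),
             input_size = input_size, hook = 4L)
}

# model whose class-2 logit is exactly the spatial mean of its single
# activation map: conv(1 filter) -> gap -> dense(identity into class 2)
single_map_mean_net <- function(input_size = 16L, seed = 7L) {
  W1 <- withr::with_seed(seed, matrix(rnorm(9), 9, 1))
  qc_network(list(layer_conv(W1, 0), layer_gap(),
                  layer_dense(matrix(c(0, 1), 1, 2), c(0, 0))),
             input_size = input_size, hook = 1L)
}

expect_all_in_range <- function(x, lo, hi) {
  expect_gte(min(x), lo)
  expect_lte(max(x), hi)
}
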