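test_that("normalize_map maps range to [0,1] and constants to zero", {
  expect_equal(as.vector(normalize_map(matrix(c(0, 1, 2), 1))),
               c(0, 0.5, 1))
  expect_equal(as.vector(normalize_map(matrix(5, 3, 3))), rep(0, 9))
  withr::with_seed(2, {
    for (i in 1:20) {
      m <- matrix(rnorm(30), 5, 6)
      nm <- normalize_map(m)
      expect_equal(min(nm), 0)
      expect_equal(max(nm), 1)
    }
  })
})

test_that("saliency of a spatial-mean-of-one-map model is the normalized map", {
  net <- single_map_mean_net(input_size = 16L)
  withr::with_seed(5, img <- matrix(runif(256), 16, 16))
  # closed form: gradients wrt the single map are constant 1/(h*w) > 0, so
  # w1 > 0 and the saliency is the min-max-normalized ReLU'd map
  fwd <- choroidqc:::net_forward(net, choroidqc:::as_input_batch(list(img), 16L))
  A1 <- fwd$acts[[1]][, , 1, 1]
  expected <- normalize_map(pmax(A1, 0))
  sal <- gradcam(net, img, class = 2, target_size = dim(A1))
  expect_equal(as.numeric(sal), as.numeric(expected), tolerance = 1e-12)
  expect_identical(dim(sal), dim(expected))
})

test_that("non-positive gradients yield an all-zero saliency map", {
  net <- single_map_mean_net(input_size = 16L)
  # explain class 1, whose logit is constant 0: gradients are all zero
  withr::with_seed(6, img <- matrix(runif(256), 16, 16))
  sal <- gradcam(net, img, class = 1)
  expect_equal(max(sal), 0)
  # non-negative (post-ReLU) activation maps with an everywhere-negative
  # gradient: the weighted sum is <= 0 and the ReLU extinguishes it
  W1 <- withr::with_seed(7, matrix(rnorm(9), 9, 1))
  net2 <- qc_network(list(layer_conv(W1, 0), layer_relu(), layer_gap(),
                          layer_dense(matrix(c(0, -1), 1, 2), c(0, 0))),
                     input_size = 16L, hook = 2L)
  sal <- gradcam(net2, img, class = 2)
  expect_equal(max(sal), 0)
})

test_that("backpropagated activation gradients match finite differences", {
  net <- fixed_two_conv_net(input_size = 12L)
  withr::with_seed(13, {
    max_rel <- 0
    for (r in 1:10) {
      x <- array(runif(144), c(12, 12, 1, 1))
      fwd <- choroidqc:::net_forward(net, x)
      bwd <- choroidqc:::net_backward(net, fwd, matrix(c(0, 1), 1),
                                      stop_at = net$hook,
                                      want_params = FALSE)
      A <- fwd$acts[[net$hook]]
      eps <- 1e-5
      # GAP importance weights against uniform-shift finite differences
      for (k in seq_len(dim(A)[3])) {
        Ap <- A; Ap[, , k, 1] <- Ap[, , k, 1] + eps
        Am <- A; Am[, , k, 1] <- Am[, , k, 1] - eps
        fd <- (network_logits_from(net, net$hook, Ap[, , , 1])[1, 2] -
               network_logits_from(net, net$hook, Am[, , , 1])[1, 2]) /
          (2 * eps)
        analytic <- mean(bwd$dx[, , k, 1]) * prod(dim(A)[1:2])
        max_rel <- max(max_rel, abs(fd - analytic) / max(abs(fd), 1e-8))
      }
      # spot-check individual cells
      for (t in 1:3) {
        i <- sample(length(A), 1)
        Ap <- A; Ap[i] <- Ap[i] + eps
        Am <- A; Am[i] <- Am[i] - eps
        fd <- (network_logits_from(net, net$hook, Ap[, , , 1])[1, 2] -
               network_logits_from(net, net$hook, Am[, , , 1])[1, 2]) /
          (2 * eps)
        max_rel <- max(max_rel, abs(fd - bwd$dx[i]) / max(abs(fd), 1e-8))
      }
    }
    expect_lt(max_rel, 1e-3)
  })
})

test_that("saliency is invariant to positive scaling of the head weights", {
  net <- fixed_two_conv_net(input_size = 12L)
  withr::with_seed(17, img <- matrix(runif(144), 12, 12))
  s1 <- gradcam(net, img, class = 2)
  net_scaled <- net
  net_scaled$layers[[6]]$W <- net$layers[[6]]$W * 7.5
  s2 <- gradcam(net_scaled, img, class = 2)
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-10)
})

test_that("saliency maps are bounded in [0,1] at the image resolution", {
  net <- fixed_two_conv_net(input_size = 12L)
  withr::with_seed(19, {
    for (r in 1:5) {
      img <- matrix(runif(31 * 57), 31, 57)   # arbitrary aspect ratio
      sal <- gradcam(net, img)
      expect_identical(dim(sal), dim(img))
      expect_all_in_range(sal, 0, 1)
    }
  })
})

test_that("the explained class resolves by name, index, and prediction", {
  net <- fixed_two_conv_net(input_size = 12L)
  withr::with_seed(23, img <- matrix(runif(144), 12, 12))
  s_name <- gradcam(net, img, class = "good")
  s_idx <- gradcam(net, img, class = 2)
  expect_identical(unclass(s_name), unclass(s_idx))
  expect_equal(attr(s_name, "class_name"), "good")
  expect_error(gradcam(net, img, class = "excellent"), "unknown class")
})
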