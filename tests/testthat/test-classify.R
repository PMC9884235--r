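test_that("stratified folds partition the samples and preserve class ratios", {
  labels <- rep(c("good", "bad"), each = 5)
  fs <- stratified_kfold(labels, K = 5, seed = 1)
  expect_s3_class(fs, "fold_split")
  for (k in 1:5) {
    idx <- which(fs$assignments == k)
    expect_length(idx, 2)
    expect_setequal(labels[idx], c("good", "bad"))
  }
  expect_setequal(unlist(lapply(1:5, function(k) which(fs$assignments == k))),
                  seq_along(labels))
})

test_that("fold class counts stay within one of the proportional split", {
  labels <- c(rep("good", 1593), rep("bad", 2581))
  for (seed in 1:3) {
    fs <- stratified_kfold(labels, K = 5, seed = seed)
    good_counts <- table(fs$assignments[labels == "good"])
    bad_counts <- table(fs$assignments[labels == "bad"])
    expect_true(all(good_counts %in% c(318, 319)))
    expect_true(all(bad_counts %in% c(516, 517)))
  }
  # property over odd sizes and several K
  for (case in list(c(37, 3), c(61, 4), c(101, 7))) {
    labels <- sample(rep(c("a", "b"), times = c(case[1], case[1] + 13)))
    fs <- stratified_kfold(labels, K = case[2], seed = 2)
    for (cl in c("a", "b")) {
      counts <- tabulate(fs$assignments[labels == cl], nbins = case[2])
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("a class smaller than K is rejected", {
  expect_error(stratified_kfold(c("good", rep("bad", 9)), K = 5),
               "at least K members")
})

test_that("confusion-matrix metrics match hand-computed values", {
  m <- compute_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))
  m <- compute_metrics(c(TP = 30, FP = 10, FN = 20, TN = 40))
  expect_equal(m[["accuracy"]], 0.70)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.60)
  expect_equal(m[["f1"]], 2 / 3)
})

test_that("the two F1 forms agree for random confusions with TP > 0", {
  withr::with_seed(4, {
    for (i in 1:200) {
      cm <- c(TP = sample(1:50, 1), TN = sample(0:50, 1),
              FP = sample(0:50, 1), FN = sample(0:50, 1))
      m <- suppressWarnings(compute_metrics(cm))
      harmonic <- 2 / (1 / m[["precision"]] + 1 / m[["recall"]])
      closed <- cm[["TP"]] / (cm[["TP"]] + 0.5 * (cm[["FP"]] + cm[["FN"]]))
      expect_equal(m[["f1"]], closed, tolerance = 1e-12)
      if (m[["precision"]] > 0 && m[["recall"]] > 0)
        expect_equal(m[["f1"]], unname(harmonic), tolerance = 1e-12)
    }
  })
})

test_that("undefined precision/recall are NaN with a warning", {
  expect_warning(m <- compute_metrics(c(TP = 0, TN = 5, FP = 0, FN = 3)),
                 "precision undefined")
  expect_true(is.nan(m[["precision"]]))
  expect_warning(m <- compute_metrics(c(TP = 0, TN = 5, FP = 3, FN = 0)),
                 "recall undefined")
  expect_true(is.nan(m[["recall"]]))
})

# independent AUC oracle: all positive/negative pairs, ties counted half
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

test_that("AUC matches examples and the pairwise brute-force oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
      expect_equal(roc_auc(scores, y), auc_bruteforce(scores, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("operating point maximizes accuracy with high-threshold tie-break", {
  th <- select_operating_point(c(0.9, 0.6, 0.55, 0.1), c(1, 1, 0, 0))
  expect_equal(mean((c(0.9, 0.6, 0.55, 0.1) >= th) == c(1, 1, 0, 0)), 1)
  # all-same scores: accuracy equals the majority-class fraction
  scores <- rep(0.4, 10); y <- c(rep(1, 7), rep(0, 3))
  th <- select_operating_point(scores, y)
  expect_equal(mean((scores >= th) == (y == 1)), 0.7)
  # optimality against every candidate threshold on random instances
  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(5:60, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
      th <- select_operating_point(scores, y)
      acc_at <- function(t) mean((scores >= t) == (y == 1))
      expect_true(all(acc_at(th) >= vapply(c(scores, Inf), acc_at,
                                           numeric(1))))
    }
  })
})

test_that("training learns a separable image task and is seed-reproducible", {
  withr::with_seed(31, {
    n <- 40
    imgs <- vector("list", n)
    y <- rep(c("good", "bad"), each = n / 2)
    for (i in seq_len(n)) {
      base <- matrix(runif(24 * 24, 0, 0.3), 24, 24)
      if (y[i] == "good") base[9:16, 9:16] <- base[9:16, 9:16] + 0.6
      imgs[[i]] <- pmin(base, 1)
    }
  })
  cfg <- small_cnn_config(input_size = 24L, epochs = 6L, seed = 3L)
  split <- c(1:15, 21:35)
  model <- train_classifier(imgs[split], y[split], cfg)
  heldout <- setdiff(seq_len(n), split)
  scores <- predict_scores(model, imgs[heldout])
  expect_gte(roc_auc(scores, y[heldout]), 0.95)
  expect_lt(tail(model$loss, 1), model$loss[1])

  model2 <- train_classifier(imgs[split], y[split], cfg)
  expect_identical(model$loss, model2$loss)
})

test_that("zero-epoch training still yields a scoring model", {
  imgs <- list(matrix(0.2, 24, 24), matrix(0.8, 24, 24))
  model <- train_classifier(imgs, c("bad", "good"),
                            small_cnn_config(input_size = 24L, epochs = 0L))
  s <- predict_scores(model, imgs)
  expect_length(s, 2)
  expect_all_in_range(s, 0, 1)
})

test_that("model_config defaults mirror the published protocol", {
  cfg <- model_config(backbone = "resnet18")
  expect_equal(cfg$input_size, 224L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$loss, "cross_entropy")
  expect_equal(model_config(backbone = "enet-b3")$input_size, 300L)
  expect_error(model_config(loss = "mse"), "cross_entropy")
  expect_error(train_classifier(list(matrix(0, 8, 8)), "good",
                                model_config(backbone = "resnet18")),
               "not bundled")
})

test_that("cross-validation reports coherent per-fold metrics", {
  withr::with_seed(41, {
    n <- 24
    imgs <- vector("list", n)
    y <- rep(c("good", "bad"), each = n / 2)
    for (i in seq_len(n)) {
      base <- matrix(runif(16 * 16, 0, 0.3), 16, 16)
      if (y[i] == "good") base[5:12, 5:12] <- base[5:12, 5:12] + 0.6
      imgs[[i]] <- pmin(base, 1)
    }
  })
  cfg <- small_cnn_config(input_size = 16L, epochs = 4L, seed = 1L)
  rep_ <- suppressWarnings(cross_validate(imgs, y, cfg, K = 2, seed = 9))
  expect_s3_class(rep_, "metrics_report")
  expect_equal(nrow(rep_$per_fold), 2)
  # every sample scored exactly once out-of-fold
  expect_false(anyNA(rep_$oof$score))
  # metric identities recomputable from the stored confusion counts
  for (k in 1:2) {
    row <- rep_$per_fold[k, ]
    m <- suppressWarnings(compute_metrics(
      c(TP = row$TP, TN = row$TN, FP = row$FP, FN = row$FN)))
    expect_equal(row$accuracy, m[["accuracy"]])
    expect_equal(row$f1, m[["f1"]])
  }
  expect_equal(unname(rep_$mean["accuracy"]),
               mean(rep_$per_fold$accuracy))
})
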