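# End-to-end pipeline: synthesize a labeled dataset, cross-validate the
# classifier, explain each held-out prediction with Grad-CAM, render CTMs,
# score choroid coverage against the ground-truth masks, and report
# agreement between two visibility thresholds. Stages communicate through
# files in the work directory and are individually toggleable.

#' Pipeline configuration
#'
#' @param out_dir work directory; every stage reads and writes here.
#' @param n_good,n_bad synthetic dataset composition.
#' @param cohort_mix fraction of each class in the diseased cohort.
#' @param seed master seed propagated to every stage.
#' @param good_spec,bad_spec overrides for the synthetic presets (named
#'   lists, see [synthetic_spec()]).
#' @param model a [model_config()].
#' @param K cross-validation folds.
#' @param tau visibility threshold for coverage scoring.
#' @param tau_b second threshold; the agreement stage compares coverage
#'   scored at `tau` versus `tau_b` (two automated "raters").
#' @param grid_spacing CTM grid period in pixels.
#' @param n_render number of explanation panels to render.
#' @param explain_class class logit to explain for every scan: `"good"`
#'   (default; see the vignette), `"bad"`, or `"predicted"`.
#' @param stages character vector of enabled stages, a subset of
#'   `c("synth", "train", "explain", "render", "score", "agree")`.
#' @param checkpoint optional path to a `train_result.rds` saved by a
#'   previous run; used when the `train` stage is disabled.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, n_good = 100L, n_bad = 100L,
                       cohort_mix = 0.5, seed = 1L,
                       good_spec = list(), bad_spec = list(),
                       model = small_cnn_config(), K = 5L,
                       tau = 0.5, tau_b = 0.6, grid_spacing = 50L,
                       n_render = 6L, explain_class = "good",
                       stages = c("synth", "train", "explain", "render",
                                  "score", "agree"),
                       checkpoint = NULL) {
  known <- c("synth", "train", "explain", "render", "score", "agree")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  stopifnot(inherits(model, "model_config"), tau > 0, tau <= 1,
            tau_b > 0, tau_b <= 1)
  structure(list(out_dir = out_dir, n_good = as.integer(n_good),
                 n_bad = as.integer(n_bad), cohort_mix = cohort_mix,
                 seed = as.integer(seed), good_spec = good_spec,
                 bad_spec = bad_spec, model = model, K = as.integer(K),
                 tau = tau, tau_b = tau_b,
                 grid_spacing = as.integer(grid_spacing),
                 n_render = as.integer(n_render),
                 explain_class = explain_class,
                 stages = stages, checkpoint = checkpoint),
            class = "run_config")
}

#' Run the pipeline
#'
#' Executes the enabled stages in order (synth, train, explain, render,
#' score, agree). Each stage consumes only its predecessors' on-disk
#' outputs, so a disabled stage can be backed by files from an earlier run
#' (e.g. `train` by a saved checkpoint). A failing stage aborts with the
#' stage named; outputs of completed stages are preserved.
#'
#' @param config a [run_config()].
#' @return consolidated run report (also written to `out_dir/report.json`):
#'   list with `metrics` (per-fold and aggregate), `coverage` (per-image
#'   scores and sub-group summary), `agreement`, and file pointers.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    log("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  manifest_path <- file.path(config$out_dir, "manifest.csv")
  stage("synth", {
    generate_dataset(config$n_good, config$n_bad, config$out_dir,
                     cohort_mix = config$cohort_mix, seed = config$seed,
                     good_spec = config$good_spec,
                     bad_spec = config$bad_spec)
    log("synth: wrote ", config$n_good + config$n_bad, " scans")
  })
  if (!file.exists(manifest_path))
    stop("no manifest at ", manifest_path,
         "; enable the synth stage or point out_dir at an existing dataset")
  manifest <- load_manifest(manifest_path)
  n <- nrow(manifest)

  train_path <- file.path(config$out_dir, "train_result.rds")
  cv <- NULL
  stage("train", {
    size <- config$model$input_size
    x4 <- array(0, c(size, size, 1L, n))
    for (i in seq_len(n))
      x4[, , 1L, i] <- resize_gray(read_gray_image(manifest$image_path[i]),
                                   size, size)
    cv <- cross_validate(x4, manifest$quality_label, config$model,
                          K = config$K, seed = config$seed,
                          keep_models = TRUE)
    saveRDS(cv, train_path)
    jsonlite::write_json(
      list(per_fold = cv$per_fold, mean = as.list(cv$mean),
           std = as.list(cv$std)),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(cv$per_fold, file.path(config$out_dir, "metrics.csv"),
              row.names = FALSE)
    log(sprintf("train: mean accuracy %.2f%%, mean AUC %.3f",
                100 * cv$mean[["accuracy"]], cv$mean[["auc"]]))
  })
  needs_cv <- any(c("explain", "score", "agree") %in% config$stages)
  if (is.null(cv) && needs_cv) {
    src <- if (!is.null(config$checkpoint)) config$checkpoint else train_path
    if (!file.exists(src))
      stop("train stage disabled and no checkpoint found at ", src)
    cv <- readRDS(src)
  }

  saliency_paths <- sub("\\.png$", ".gradcam.png", manifest$image_path)
  stage("explain", {
    if (is.null(cv$models))
      stop("checkpoint does not contain per-fold models")
    for (i in seq_len(n)) {
      img <- read_gray_image(manifest$image_path[i])
      model <- cv$models[[cv$oof$fold[i]]]
      sal <- gradcam(model, img, class = config$explain_class)
      write_gray_image(unclass(sal), saliency_paths[i])
    }
    log("explain: wrote ", n, " saliency maps")
  })

  stage("render", {
    idx <- head(seq_len(n), config$n_render)
    for (i in idx) {
      img <- read_gray_image(manifest$image_path[i])
      sal <- read_gray_image(saliency_paths[i])
      write_ctm_panel(img, sal,
                      sub("\\.png$", ".panel.png", manifest$image_path[i]),
                      grid_spacing = config$grid_spacing)
    }
    log("render: wrote ", length(idx), " explanation panels")
  })

  scores <- NULL
  scores_b <- NULL
  stage("score", {
    score_at <- function(tau) {
      rows <- lapply(seq_len(n), function(i) {
        sal <- read_gray_image(saliency_paths[i])
        mask <- read_mask_image(manifest$mask_path[i])
        suppressWarnings(coverage_scores(
          sal, mask, tau = tau,
          image = basename(manifest$image_path[i]),
          quality_label = manifest$quality_label[i],
          cohort_label = manifest$cohort_label[i]))
      })
      do.call(rbind, rows)
    }
    scores <- score_at(config$tau)
    scores$correct <- cv$oof$predicted ==
      as_binary_labels(manifest$quality_label)
    scores_b <- score_at(config$tau_b)
    write.csv(scores, file.path(config$out_dir, "coverage_scores.csv"),
              row.names = FALSE)
    summ <- group_summary(scores)
    write.csv(summ, file.path(config$out_dir, "coverage_summary.csv"),
              row.names = FALSE)
    log(sprintf("score: overall OCC %.1f%%, CCVR %.1f%% at tau=%.2f",
                summ$occ_pct[summ$group == "Overall"],
                summ$ccvr_pct[summ$group == "Overall"], config$tau))
  })

  agreement <- NULL
  stage("agree", {
    if (is.null(scores) || is.null(scores_b))
      stop("agree stage needs the score stage enabled in the same run")
    agreement <- agreement_report(scores, scores_b)
    jsonlite::write_json(unclass(agreement),
                         file.path(config$out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    log(sprintf("agree: OCC cosine %.2f%%, CCVR cosine %.2f%%",
                100 * agreement$occ$cosine, 100 * agreement$ccvr$cosine))
  })

  report <- list(
    config = config[c("n_good", "n_bad", "cohort_mix", "seed", "K", "tau",
                      "tau_b", "stages")],
    metrics = if (!is.null(cv))
      list(per_fold = cv$per_fold, mean = as.list(cv$mean),
           std = as.list(cv$std)),
    coverage = if (!is.null(scores))
      list(summary = group_summary(scores)),
    agreement = if (!is.null(agreement)) unclass(agreement),
    files = list(manifest = manifest_path, log = log_path))
  report_clean <- report
  report_clean$config$stages <- as.list(report$config$stages)
  jsonlite::write_json(report_clean,
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log("run complete")
  invisible(report)
}
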