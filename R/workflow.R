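#' Experiment configuration
#'
#' One experiment is one config and one output directory: simulate a
#' labelled dataset, digitize it, train the requested model kinds on the
#' same feature tensors, score and cross-validate each, and write every
#' artifact (plan JSONs, manifest, tensors, checkpoints, score and metric
#' tables, figures, run summary) under `output_dir`. Re-running the same
#' config reproduces all numeric artifacts.
#'
#' @param sim a [sim_config()].
#' @param resolution raster pixel pitch in mm (default: 1/5 of the target
#'   pixel pitch, i.e. 1.25 mm for a 400 mm field at 64x64).
#' @param target_shape network input size `c(M, N)`.
#' @param kinds model kinds to train (subset of multitask, vanilla,
#'   contractive, variational).
#' @param policy a [threshold_policy()].
#' @param epochs,latent_dim,channels,batch_size,lambda_weight shared model
#'   settings (see [ae_config()]).
#' @param n_folds cross-validation folds.
#' @param output_dir artifact directory (created; must not hold a previous
#'   run).
#' @param seed master seed; every stochastic stage derives from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              resolution = NULL,
                              target_shape = c(64L, 64L),
                              kinds = c("multitask", "vanilla",
                                        "contractive", "variational"),
                              policy = threshold_policy("oracle_fnr0"),
                              epochs = 3L, latent_dim = 32L,
                              channels = c(4L, 8L, 16L, 32L),
                              batch_size = 128L, lambda_weight = 1,
                              n_folds = 5L,
                              output_dir = "vmatqa_run", seed = 1L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  resolution <- resolution %||%
    (sim$machine$field_width / (5 * target_shape[1]))
  structure(list(sim = sim, resolution = resolution,
                 target_shape = as.integer(target_shape), kinds = kinds,
                 policy = policy, epochs = as.integer(epochs),
                 latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels),
                 batch_size = as.integer(batch_size),
                 lambda_weight = lambda_weight,
                 n_folds = as.integer(n_folds),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop("experiment stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

open_figure <- function(path_base, width = 6, height = 5) {
  opened <- tryCatch({
    grDevices::png(paste0(path_base, ".png"), width = width * 100,
                   height = height * 100)
    TRUE
  }, error = function(e) FALSE)
  if (!opened)
    grDevices::pdf(paste0(path_base, ".pdf"), width = width,
                   height = height)
  invisible(NULL)
}

#' Run a full simulate-train-evaluate experiment
#'
#' Executes the end-to-end workflow described in [experiment_config()] and
#' returns the output directory (invisibly) with:
#' \itemize{
#'   \item `plans/*.json`, `manifest.csv` — the simulated dataset;
#'   \item `features.rds` — the feature tensors;
#'   \item `models/<kind>.rds` — one checkpoint per kind, trained on all
#'     regular plans;
#'   \item `scores_<kind>.csv` — per-plan distances, threshold, predicted
#'     and true labels;
#'   \item `metrics.csv` — per-fold and mean cross-validated metrics for
#'     every model kind and distance metric (the multi-task model is
#'     evaluated under all three distances, the baselines under `d_I`);
#'   \item `roc_*`, `box_*` figures; `run_summary.yaml` (config hash,
#'     seeds, package version).
#' }
#'
#' @param config an [experiment_config()].
#' @return the output directory, invisibly.
#' @export
run_experiment <- function(config) {
  out <- config$output_dir
  if (dir.exists(out) && length(list.files(out)))
    stop("output_dir already holds a run; refusing to overwrite")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "plans"), showWarnings = FALSE)
  dir.create(file.path(out, "models"), showWarnings = FALSE)
  logf <- file.path(out, "run_summary.yaml")

  cfg_plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(list(config = cfg_plain), logf)
  cfg_hash <- unname(tools::md5sum(logf))

  plans <- stage("simulate", {
    sim <- config$sim; sim$seed <- config$seed
    make_dataset(sim)
  })
  stage("write-plans", {
    for (p in plans)
      write_plan_json(p, file.path(out, "plans",
                                   paste0(p$plan_id, ".json")))
    write.csv(dataset_manifest(plans), file.path(out, "manifest.csv"),
              row.names = FALSE)
  })
  tensors <- stage("featurize", {
    grid <- build_grid(config$sim$machine, config$resolution)
    tn <- featurize_dataset(plans, grid, config$target_shape)
    saveRDS(tn, file.path(out, "features.rds"))
    tn
  })
  labs <- vapply(plans, function(p) p$label, character(1))
  if (!any(labs == "anomalous"))
    stop("experiment stage 'evaluate' failed: no anomalies in the dataset",
         call. = FALSE)

  base_cfg <- function(kind) ae_config(
    kind = kind, input_shape = config$target_shape,
    latent_dim = config$latent_dim, channels = config$channels,
    lambda_weight = config$lambda_weight, epochs = config$epochs,
    batch_size = config$batch_size,
    seed = (config$seed * 977L) %% .Machine$integer.max)

  models <- stage("train", {
    reg <- tensors[labs == "regular"]
    ms <- lapply(config$kinds, function(k) {
      m <- vmat_ae(reg, config = base_cfg(k))
      save_vmat_ae(m, file.path(out, "models", paste0(k, ".rds")))
      m
    })
    names(ms) <- config$kinds
    ms
  })

  stage("score", {
    for (k in config$kinds) {
      sc <- predict(models[[k]], tensors, type = "scores")
      sc$true_label <- labs
      alpha <- if (config$policy$mode == "oracle_fnr0")
        calibrate_threshold(sc$d_I, labs, config$policy)
      else calibrate_threshold(sc$d_I[labs == "regular"],
                               policy = config$policy)
      sc$active_metric <- "d_I"
      sc$threshold <- alpha
      sc$predicted_label <- classify(sc$d_I, alpha)
      write.csv(sc, file.path(out, sprintf("scores_%s.csv", k)),
                row.names = FALSE)
    }
  })

  metrics <- stage("evaluate", {
    rows <- list()
    cvs <- list()
    for (k in config$kinds) {
      cv <- crossvalidate(plans, base_cfg(k), policy = config$policy,
                          seed = config$seed, tensors = tensors,
                          metric = "d_I", n_folds = config$n_folds)
      cvs[[k]] <- cv
      add <- function(cv, metric) {
        for (fd in cv$folds)
          rows[[length(rows) + 1L]] <<- data.frame(
            model = k, metric = metric, fold = fd$fold_index,
            as.data.frame(unclass(fd$metrics)))
        rows[[length(rows) + 1L]] <<- data.frame(
          model = k, metric = metric, fold = "mean",
          as.data.frame(cv$mean_metrics))
      }
      add(cv, "d_I")
      if (k == "multitask") { # distance-metric comparison on the same folds
        for (metric in c("d_A", "d_D")) {
          cvm <- rescore_cv(cv, metric, config$policy)
          cvs[[paste0(k, "_", metric)]] <- cvm
          add(cvm, metric)
        }
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out, "metrics.csv"), row.names = FALSE)
    list(tab = tab, cvs = cvs)
  })

  stage("figures", {
    for (nm in names(metrics$cvs)) {
      cv <- metrics$cvs[[nm]]
      s <- cv$scores[[cv$metric]]
      roc <- roc_auc(s, cv$scores$true_label)
      open_figure(file.path(out, paste0("roc_", nm)))
      plot(roc$curve$fpr, roc$curve$tpr, type = "l", xlab = "FPR",
           ylab = "TPR", main = sprintf("%s (AUC %.3f)", nm, roc$auc))
      graphics::abline(0, 1, lty = 3)
      grDevices::dev.off()
      open_figure(file.path(out, paste0("box_", nm)))
      graphics::boxplot(s ~ cv$scores$true_label, xlab = "class",
                        ylab = cv$metric, main = nm)
      grDevices::dev.off()
    }
  })

  stage("log", {
    summ <- list(config = cfg_plain, config_hash = cfg_hash,
                 package_version = as.character(packageVersion("vmatqa")),
                 seed = config$seed,
                 n_plans = length(plans),
                 n_anomalous = sum(labs == "anomalous"),
                 model_checksums = lapply(models, `[[`, "checksum"))
    yaml::write_yaml(summ, logf)
  })
  invisible(out)
}

# re-threshold an existing cv_report under a different distance metric
# (no retraining; the scores were computed by the same fold models)
rescore_cv <- function(cv, metric, policy) {
  folds <- cv$folds
  sc_all <- list()
  for (f in seq_along(folds)) {
    sc <- cv$scores[cv$scores$fold == f, , drop = FALSE]
    s <- sc[[metric]]
    alpha <- calibrate_threshold(s, sc$true_label,
                                 threshold_policy("oracle_fnr0"))
    sc$predicted_label <- classify(s, alpha)
    sc$active_metric <- metric
    sc$threshold <- alpha
    cnt <- confusion_counts(sc$true_label, sc$predicted_label)
    met <- metrics_from_confusion(cnt)
    met$auc <- roc_auc(s, sc$true_label)$auc
    folds[[f]]$alpha <- alpha
    folds[[f]]$counts <- cnt
    folds[[f]]$metrics <- met
    sc_all[[f]] <- sc
  }
  mnames <- c("auc", "accuracy", "precision", "recall", "fpr", "fnr", "f1")
  mm <- sapply(mnames, function(nm)
    mean(vapply(folds, function(fd)
      fd$metrics[[nm]] %||% NA_real_, numeric(1)), na.rm = TRUE))
  structure(list(folds = folds, mean_metrics = as.list(mm),
                 scores = do.call(rbind, sc_all), metric = metric,
                 policy = policy), class = "cv_report")
}
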