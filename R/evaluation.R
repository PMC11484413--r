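#' Confusion counts with the anomalous class as positive
#'
#' @param true_labels,predicted_labels equal-length vectors of
#'   `"regular"`/`"anomalous"`.
#' @return a `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(true_labels, predicted_labels) {
  if (!length(true_labels)) stop("no labels to tabulate")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  ok <- c("regular", "anomalous")
  if (!all(true_labels %in% ok) || !all(predicted_labels %in% ok))
    stop("labels must be 'regular' or 'anomalous'")
  structure(list(
    tp = sum(true_labels == "anomalous" & predicted_labels == "anomalous"),
    fp = sum(true_labels == "regular" & predicted_labels == "anomalous"),
    tn = sum(true_labels == "regular" & predicted_labels == "regular"),
    fn = sum(true_labels == "anomalous" & predicted_labels == "regular")),
    class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall
#' `tp/(tp+fn)`, FPR `fp/(fp+tn)`, FNR `fn/(fn+tp)` and F1
#' `2*precision*recall/(precision+recall)`. Ratios with a zero denominator
#' are reported as `NA`, not 0. AUC is left unset (it is threshold-free;
#' see [roc_auc()]).
#'
#' @param counts a [confusion_counts()].
#' @return a `metrics_report` list.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(auc = NA_real_, accuracy = (tp + tn) / total,
                 precision = precision, recall = recall,
                 fpr = ratio(fp, fp + tn), fnr = ratio(fn, fn + tp),
                 f1 = f1), class = "metrics_report")
}

#' ROC curve and tie-aware AUC
#'
#' AUC is computed as the Mann-Whitney statistic: the proportion of
#' (anomaly, regular) pairs in which the anomaly scores higher, counting
#' ties as 1/2. The returned curve is the full threshold sweep over the
#' observed scores; its trapezoidal integral equals the rank-based AUC.
#'
#' @param scores numeric scores (higher = more anomalous).
#' @param labels parallel `"regular"`/`"anomalous"` labels; both classes
#'   must be present.
#' @return list with `auc` and `curve` (data.frame of `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pos <- labels == "anomalous"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- rank(scores)
  na <- sum(pos); nr <- sum(!pos)
  auc <- (sum(r[pos]) - na * (na + 1) / 2) / (na * nr)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  tpr <- c(0, cumsum(p)[keep] / na)
  fpr <- c(0, cumsum(!p)[keep] / nr)
  curve <- data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr)
  list(auc = auc, curve = curve)
}

trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

#' Cross-validated detection benchmark
#'
#' Implements the evaluation protocol for a labelled plan set: the regular
#' plans are split into five folds (sizes differing by at most one); for
#' each fold the model is trained on the other four fifths of the regular
#' plans only, and tested on the held-out regular fifth together with ALL
#' anomalous plans (anomalies never enter training). The threshold is
#' calibrated per fold according to `policy`: `oracle_fnr0` on the labelled
#' test scores (zero false negatives by construction), `quantile` on the
#' training-set regular scores. Metrics are reported per fold and as the
#' across-fold mean.
#'
#' @param plans list of labelled [vmat_plan()] objects (both classes
#'   present), or a list of pre-built `feature_tensor`s via `tensors`.
#' @param model_config an [ae_config()].
#' @param policy a [threshold_policy()].
#' @param seed seed controlling fold assignment and training.
#' @param grid,target_shape digitization parameters (defaults: a raster at
#'   1/5 of the target pixel pitch for the first plan's machine).
#' @param metric which distance drives classification: `"d_I"`, `"d_A"` or
#'   `"d_D"`.
#' @param n_folds number of folds (default 5).
#' @param tensors optional pre-featurized tensors matching `plans`.
#' @return a `cv_report`: list with `folds` (per-fold list of `fold_index`,
#'   `train_ids`, `test_ids`, `alpha`, `counts`, `metrics`), `mean_metrics`
#'   and `scores` (per fold, per plan).
#' @export
crossvalidate <- function(plans, model_config, policy =
                            threshold_policy("oracle_fnr0"),
                          seed = 1L, grid = NULL, target_shape = NULL,
                          metric = "d_I", n_folds = 5L, tensors = NULL) {
  labs <- vapply(plans, function(p) p$label, character(1))
  if (!any(labs == "anomalous")) stop("no anomalies in the dataset")
  if (!any(labs == "regular")) stop("no regular plans in the dataset")
  reg <- which(labs == "regular"); anom <- which(labs == "anomalous")
  if (length(reg) < n_folds)
    stop("fewer than ", n_folds, " regular plans")
  target_shape <- target_shape %||% model_config$input_shape
  if (is.null(tensors)) {
    grid <- grid %||% build_grid(plans[[1]]$machine,
                                 plans[[1]]$machine$field_width /
                                   (5 * target_shape[1]))
    tensors <- featurize_dataset(plans, grid, target_shape)
  }
  fold_of <- with_seed(seed, sample(rep_len(seq_len(n_folds), length(reg))))
  folds <- vector("list", n_folds)
  all_scores <- list()
  for (f in seq_len(n_folds)) {
    tr <- reg[fold_of != f]; te <- c(reg[fold_of == f], anom)
    cfg <- model_config
    cfg$seed <- as.integer((seed * 131L + f) %% .Machine$integer.max)
    model <- vmat_ae(tensors[tr], config = cfg)
    sc_te <- do.call(rbind, lapply(tensors[te], score_plan, model = model))
    sc_te$true_label <- labs[te]
    s <- sc_te[[metric]]
    alpha <- if (policy$mode == "oracle_fnr0")
      calibrate_threshold(s, sc_te$true_label, policy)
    else {
      sc_tr <- vapply(tensors[tr], function(t)
        score_plan(model, t)[[metric]], numeric(1))
      calibrate_threshold(sc_tr, policy = policy)
    }
    sc_te$predicted_label <- classify(s, alpha)
    sc_te$active_metric <- metric
    sc_te$threshold <- alpha
    sc_te$fold <- f
    cnt <- confusion_counts(sc_te$true_label, sc_te$predicted_label)
    met <- metrics_from_confusion(cnt)
    met$auc <- roc_auc(s, sc_te$true_label)$auc
    folds[[f]] <- list(fold_index = f,
                       train_ids = vapply(tensors[tr], `[[`, "", "plan_id"),
                       test_ids = vapply(tensors[te], `[[`, "", "plan_id"),
                       alpha = alpha, counts = cnt, metrics = met)
    all_scores[[f]] <- sc_te
  }
  mnames <- c("auc", "accuracy", "precision", "recall", "fpr", "fnr", "f1")
  mm <- sapply(mnames, function(nm)
    mean(vapply(folds, function(fd)
      fd$metrics[[nm]] %||% NA_real_, numeric(1)), na.rm = TRUE))
  structure(list(folds = folds, mean_metrics = as.list(mm),
                 scores = do.call(rbind, all_scores), metric = metric,
                 policy = policy),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold detection benchmark (metric %s, policy %s)\n",
              length(x$folds), x$metric, x$policy$mode))
  mm <- x$mean_metrics
  cat(sprintf(
    "  mean: AUC %.3f, accuracy %.3f, precision %.3f, FPR %.3f, F1 %.3f\n",
    mm$auc, mm$accuracy, mm$precision, mm$fpr, mm$f1))
  invisible(x)
}
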