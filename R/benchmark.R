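#' Reference detection benchmark on synthetic plans
#'
#' The package's desk-scale study: simulate a labelled cohort (default 200
#' regular + 20 anomalous two-arc plans with gross injected faults),
#' digitize at 64x64, train the requested autoencoder on 80% of the
#' regular plans, and score the held-out 20% together with every anomalous
#' plan. Returns the threshold-free separability (AUC of the chosen
#' distance), a one-sided rank test that anomalous plans score higher than
#' held-out regular plans, and the zero-FNR confusion metrics.
#'
#' @param seed master seed for simulation, split and training.
#' @param n_regular,n_anomalous cohort composition.
#' @param kind model family (see [ae_config()]).
#' @param epochs training epochs.
#' @param metric distance driving detection (`"d_I"`, `"d_A"`, `"d_D"`).
#' @param target_shape network input size.
#' @param ... further [ae_config()] arguments.
#' @return list with `auc`, `rank_p` (one-sided Wilcoxon p-value),
#'   `alpha`, `metrics` (zero-FNR [metrics_from_confusion()] report),
#'   `scores` (per-plan data.frame), `model`, and timings (seconds).
#' @export
detection_benchmark <- function(seed = 1L, n_regular = 200L,
                                n_anomalous = 20L, kind = "multitask",
                                epochs = 2L, metric = "d_I",
                                target_shape = c(64L, 64L), ...) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- sim_config(n_regular = n_regular, n_anomalous = n_anomalous,
                    seed = seed)
  plans <- make_dataset(cfg)
  labs <- vapply(plans, function(p) p$label, character(1))
  grid <- build_grid(cfg$machine,
                     cfg$machine$field_width / (5 * target_shape[1]))
  tensors <- featurize_dataset(plans, grid, target_shape)
  t_feat <- proc.time()[["elapsed"]] - t0

  reg <- which(labs == "regular")
  split <- with_seed(seed + 1L, sample(reg))
  n_tr <- floor(0.8 * length(reg))
  tr <- split[seq_len(n_tr)]
  te <- c(split[-seq_len(n_tr)], which(labs == "anomalous"))

  t0 <- proc.time()[["elapsed"]]
  model <- vmat_ae(tensors[tr], kind = kind, input_shape = target_shape,
                   epochs = epochs, seed = seed, ...)
  t_train <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  sc <- predict(model, tensors[te], type = "scores")
  sc$true_label <- labs[te]
  sc$kind <- vapply(plans[te], function(p)
    if (is.null(p$anomaly_meta)) NA_character_ else p$anomaly_meta$kind,
    character(1))
  t_score <- proc.time()[["elapsed"]] - t0

  s <- sc[[metric]]
  auc <- roc_auc(s, sc$true_label)$auc
  rank_p <- stats::wilcox.test(s[sc$true_label == "anomalous"],
                               s[sc$true_label == "regular"],
                               alternative = "greater",
                               exact = FALSE)$p.value
  alpha <- calibrate_threshold(s, sc$true_label,
                               threshold_policy("oracle_fnr0"))
  met <- metrics_from_confusion(
    confusion_counts(sc$true_label, classify(s, alpha)))
  met$auc <- auc
  list(auc = auc, rank_p = rank_p, alpha = alpha, metrics = met,
       scores = sc, model = model,
       timings = c(featurize = t_feat, train = t_train, score = t_score))
}
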