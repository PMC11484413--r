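#' Intensity reconstruction distance
#'
#' Mean squared difference between two intensity stacks, normalized per
#' pixel: `(1/(K*M*N)) * sum (I - I')^2`. The per-pixel normalization makes
#' the distance comparable across input resolutions and consistent with the
#' aperture loss normalization.
#'
#' @param I,I_hat numeric stacks (arrays or matrices) of equal shape.
#' @return non-negative scalar; zero iff the stacks are equal.
#' @export
distance_I <- function(I, I_hat) {
  if (!identical(dim(I) %||% length(I), dim(I_hat) %||% length(I_hat)))
    stop("shape mismatch between I and I_hat")
  mean((I - I_hat)^2)
}

#' Plan-level reconstruction distances
#'
#' Computes the three anomaly scores of a plan from its feature tensor and
#' a reconstruction: `d_I` (per-pixel mean squared intensity error), `d_A`
#' (binary cross-entropy between the true apertures and the reconstructed
#' probabilities) and `d_D` (mean squared dose error, MU scale). For
#' baseline reconstructions without aperture/dose heads only `d_I` is
#' defined. Aperture probabilities enter `I'` continuously (no
#' binarization).
#'
#' @param tensor a `feature_tensor`.
#' @param recon a `vmat_reconstruction` for the same plan.
#' @return one-row data.frame with `plan_id`, `d_I`, `d_A`, `d_D`.
#' @export
plan_distances <- function(tensor, recon) {
  d_I <- distance_I(tensor$intensities, recon$intensity_hat)
  d_A <- if (!is.null(recon$aperture_prob))
    loss_aperture(tensor$apertures, recon$aperture_prob) else NA_real_
  d_D <- if (!is.null(recon$dose_hat) && length(recon$dose_hat))
    loss_dose(tensor$doses, recon$dose_hat) else NA_real_
  data.frame(plan_id = tensor$plan_id, d_I = d_I, d_A = d_A, d_D = d_D)
}

#' Score one plan with a fitted model
#'
#' @param model a fitted [vmat_ae()].
#' @param tensor a `feature_tensor`.
#' @return one-row data.frame of reconstruction distances (see
#'   [plan_distances()]).
#' @export
score_plan <- function(model, tensor) {
  plan_distances(tensor, reconstruct_tensor(model, tensor))
}

#' Threshold calibration policy
#'
#' `oracle_fnr0` selects, among the observed score values, the largest
#' threshold for which every labelled anomaly still scores above it (zero
#' false-negative rate under the strict `score > alpha` rule); when even
#' the smallest observed score fails this, the threshold falls back to just
#' below the smallest anomaly score. `quantile` needs no labels: the
#' threshold is the nearest-rank q-quantile of the regular scores.
#'
#' @param mode `"oracle_fnr0"` or `"quantile"`.
#' @param quantile_q quantile in (0, 1); required for `"quantile"`.
#' @return an object of class `threshold_policy`.
#' @export
threshold_policy <- function(mode = c("oracle_fnr0", "quantile"),
                             quantile_q = 0.99) {
  mode <- match.arg(mode)
  if (mode == "quantile" &&
      (!is.numeric(quantile_q) || quantile_q <= 0 || quantile_q >= 1))
    stop("quantile_q must lie in (0, 1)")
  structure(list(mode = mode, quantile_q = quantile_q),
            class = "threshold_policy")
}

#' Calibrate the detection threshold
#'
#' @param scores numeric vector of plan scores.
#' @param labels for `oracle_fnr0`: labels (`"regular"`/`"anomalous"`)
#'   parallel to `scores`, with at least one anomaly.
#' @param policy a [threshold_policy()].
#' @return the threshold alpha.
#' @export
calibrate_threshold <- function(scores, labels = NULL,
                                policy = threshold_policy("oracle_fnr0")) {
  if (!length(scores)) stop("no scores to calibrate on")
  if (policy$mode == "quantile") {
    x <- sort(scores)
    return(x[ceiling(policy$quantile_q * length(x))])
  }
  if (is.null(labels) || !any(labels == "anomalous"))
    stop("oracle_fnr0 calibration needs labelled anomalies")
  amin <- min(scores[labels == "anomalous"])
  cand <- scores[scores < amin]
  if (length(cand)) max(cand) else amin - 1e-12 * max(abs(scores), 1)
}

#' Classify scores against a threshold
#'
#' A plan is anomalous iff its score strictly exceeds the threshold; a
#' score equal to alpha is regular.
#'
#' @param score numeric score(s).
#' @param alpha threshold.
#' @return character vector of `"anomalous"`/`"regular"`.
#' @export
classify <- function(score, alpha) {
  if (any(!is.finite(score)) || !is.finite(alpha))
    stop("scores and threshold must be finite")
  ifelse(score > alpha, "anomalous", "regular")
}
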