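#' VMAT plan containers
#'
#' A VMAT plan is an ordered list of arcs; each arc is an ordered sequence of
#' control points (CPs). For efficiency an arc is stored columnwise: gantry
#' angles and doses as vectors of length `n_cp`, and the two leaf banks as
#' `n_leaf_pairs x n_cp` matrices of positions (mm along the travel axis).
#'
#' @param gantry_deg gantry angles in degrees, `[0, 360)`, monotone within
#'   the arc (either rotation direction).
#' @param left,right leaf bank position matrices (`n_leaf_pairs x n_cp`).
#' @param dose per-CP meterset (MU), non-negative. Doses are per-CP, not
#'   cumulative.
#' @return an object of class `vmat_arc`.
#' @export
vmat_arc <- function(gantry_deg, left, right, dose) {
  left <- as.matrix(left); right <- as.matrix(right)
  k <- length(gantry_deg)
  if (k < 1L) stop("an arc needs at least one control point")
  if (ncol(left) != k || ncol(right) != k)
    stop("left/right bank matrices must have one column per control point")
  if (nrow(left) != nrow(right))
    stop("left and right banks must have the same number of leaf pairs")
  if (length(dose) != k) stop("dose must have one value per control point")
  if (any(dose < 0)) stop("per-CP dose must be >= 0")
  if (any(gantry_deg < 0 | gantry_deg >= 360))
    stop("gantry_deg must lie in [0, 360)")
  if (k > 1L) {
    d <- diff(gantry_deg)
    if (!(all(d > 0) || all(d < 0)))
      stop("gantry angles must be monotone within an arc")
  }
  structure(list(gantry_deg = as.numeric(gantry_deg), left = left,
                 right = right, dose = as.numeric(dose)),
            class = "vmat_arc")
}

#' Assemble a VMAT plan
#'
#' @param plan_id character identifier.
#' @param arcs list of [vmat_arc()] objects (at least one CP in total).
#' @param machine the [machine_spec()] the plan is intended for.
#' @param label one of `"regular"`, `"anomalous"`, `"unknown"`.
#' @param anomaly_meta optional record of an injected fault (synthetic plans
#'   only): list with `kind`, `magnitude`, `cp_index`, `span`, `leaf_pair`.
#' @return an object of class `vmat_plan`.
#' @export
vmat_plan <- function(plan_id, arcs, machine,
                      label = c("unknown", "regular", "anomalous"),
                      anomaly_meta = NULL) {
  label <- match.arg(label)
  if (!inherits(machine, "machine_spec")) stop("machine must be a machine_spec")
  if (!length(arcs)) stop("a plan must contain at least one arc (K >= 1)")
  for (a in arcs) {
    if (!inherits(a, "vmat_arc")) stop("arcs must be vmat_arc objects")
    if (nrow(a$left) != machine$n_leaf_pairs)
      stop("bank length mismatch: arc has ", nrow(a$left),
           " leaf pairs, machine has ", machine$n_leaf_pairs)
  }
  structure(list(plan_id = as.character(plan_id), arcs = arcs,
                 machine = machine, label = label,
                 anomaly_meta = anomaly_meta),
            class = "vmat_plan")
}

#' Total number of control points in a plan
#' @param plan a [vmat_plan()].
#' @return integer K.
#' @export
n_cp <- function(plan) sum(vapply(plan$arcs, function(a)
  length(a$gantry_deg), integer(1)))

#' Extract one control point
#'
#' @param plan a [vmat_plan()].
#' @param k global CP index (1-based, counted across arcs in order).
#' @return list with `gantry_angle`, `left_positions`, `right_positions`,
#'   `dose`.
#' @export
control_point <- function(plan, k) {
  k <- as.integer(k)
  for (a in plan$arcs) {
    nk <- length(a$gantry_deg)
    if (k <= nk)
      return(list(gantry_angle = a$gantry_deg[k],
                  left_positions = a$left[, k],
                  right_positions = a$right[, k],
                  dose = a$dose[k]))
    k <- k - nk
  }
  stop("cp index out of range")
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("VMAT plan '%s': %d arc(s), K=%d control points, label=%s\n",
              x$plan_id, length(x$arcs), n_cp(x), x$label))
  if (!is.null(x$anomaly_meta))
    cat(sprintf("  injected fault: %s (magnitude %g, cp %d, span %d)\n",
                x$anomaly_meta$kind, x$anomaly_meta$magnitude,
                x$anomaly_meta$cp_index, x$anomaly_meta$span))
  invisible(x)
}

#' Check a plan against machine delivery constraints
#'
#' Reports every violation of the minimum leaf gap (`right - left <
#' min_gap`), the leaf travel range (a position outside
#' `[-field_height/2, field_height/2]`), and the leaf speed limit (a
#' between-CP displacement exceeding `max_leaf_speed * |delta gantry|`,
#' checked within each arc). One entry is reported per (CP, leaf pair,
#' kind); when both banks of a pair violate, the larger magnitude is kept.
#'
#' @param plan a [vmat_plan()].
#' @param machine a [machine_spec()]; defaults to the plan's own machine.
#' @return a `violation_report`: data.frame with columns `cp_index` (global),
#'   `leaf_pair`, `kind` (one of `"gap"`, `"travel"`, `"speed"`) and
#'   `magnitude` (mm of deficit/excess). Zero rows iff the plan conforms.
#' @export
validate_plan <- function(plan, machine = plan$machine) {
  if (machine$n_leaf_pairs != nrow(plan$arcs[[1]]$left))
    stop("leaf-pair count mismatch between plan and machine")
  half <- machine$field_height / 2
  rows <- list()
  off <- 0L
  for (a in plan$arcs) {
    k <- length(a$gantry_deg)
    gap <- a$right - a$left
    bad <- which(gap < machine$min_gap - 1e-9, arr.ind = TRUE)
    if (nrow(bad))
      rows[[length(rows) + 1L]] <- data.frame(
        cp_index = off + bad[, 2], leaf_pair = bad[, 1], kind = "gap",
        magnitude = machine$min_gap - gap[bad])
    ex <- pmax(abs(a$left), abs(a$right)) - half
    bad <- which(ex > 1e-9, arr.ind = TRUE)
    if (nrow(bad))
      rows[[length(rows) + 1L]] <- data.frame(
        cp_index = off + bad[, 2], leaf_pair = bad[, 1], kind = "travel",
        magnitude = ex[bad])
    if (k > 1L) {
      lim <- machine$max_leaf_speed * abs(diff(a$gantry_deg))
      for (bank in list(a$left, a$right)) {
        dm <- abs(bank[, -1, drop = FALSE] - bank[, -k, drop = FALSE])
        exs <- sweep(dm, 2, lim) # displacement minus limit
        bad <- which(exs > 1e-9, arr.ind = TRUE)
        if (nrow(bad))
          rows[[length(rows) + 1L]] <- data.frame(
            cp_index = off + bad[, 2] + 1L, leaf_pair = bad[, 1],
            kind = "speed", magnitude = exs[bad])
      }
    }
    off <- off + k
  }
  rep_ <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cp_index = integer(0), leaf_pair = integer(0),
               kind = character(0), magnitude = numeric(0))
  # merge duplicate (cp, pair, kind) entries keeping the largest magnitude
  if (nrow(rep_)) {
    key <- paste(rep_$cp_index, rep_$leaf_pair, rep_$kind)
    rep_ <- rep_[order(key, -rep_$magnitude), , drop = FALSE]
    key <- paste(rep_$cp_index, rep_$leaf_pair, rep_$kind)
    rep_ <- rep_[!duplicated(key), , drop = FALSE]
    rep_ <- rep_[order(rep_$cp_index, rep_$leaf_pair, rep_$kind), ]
    rownames(rep_) <- NULL
  }
  class(rep_) <- c("violation_report", "data.frame")
  rep_
}
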