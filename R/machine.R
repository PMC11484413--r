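#' Treatment machine description
#'
#' Defines the multi-leaf collimator (MLC) geometry and delivery limits used
#' for plan validation and aperture digitization. The default corresponds to
#' a linac with 40 leaf pairs of 1.0 cm width (a 400 mm extent along the
#' leaf-index axis) and a maximum leaf travel range of 400 mm.
#'
#' Coordinate convention: the position axis (leaf travel, "x") and the
#' leaf-index axis ("y") are both isocenter-centered, in mm. The left bank
#' must not pass the right bank in a valid plan; leaf pair 1 sits at the most
#' negative y.
#'
#' @param n_leaf_pairs number of opposed leaf pairs.
#' @param leaf_widths per-pair physical widths in mm along the leaf-index
#'   axis; must all be positive and sum to `field_width`.
#' @param field_width extent of the MLC along the leaf-index axis (mm);
#'   defaults to `sum(leaf_widths)`.
#' @param field_height maximum leaf-travel extent along the position axis
#'   (mm); leaf positions must lie in `[-field_height/2, field_height/2]`.
#' @param max_leaf_speed maximum leaf displacement per degree of gantry
#'   rotation (mm/deg). Gantry angle is the time proxy because delivery time
#'   is not part of the plan record.
#' @param min_gap minimum allowed separation between opposing leaves (mm).
#' @return an object of class `machine_spec`.
#' @export
machine_spec <- function(n_leaf_pairs = 40L,
                         leaf_widths = rep(10, n_leaf_pairs),
                         field_width = sum(leaf_widths),
                         field_height = 400,
                         max_leaf_speed = 5,
                         min_gap = 0) {
  n_leaf_pairs <- as.integer(n_leaf_pairs)
  stopifnot(n_leaf_pairs >= 1L, length(leaf_widths) == n_leaf_pairs)
  if (any(leaf_widths <= 0)) stop("all leaf widths must be > 0")
  if (abs(sum(leaf_widths) - field_width) > 1e-6)
    stop("sum(leaf_widths) must equal field_width (got ",
         sum(leaf_widths), " vs ", field_width, ")")
  if (max_leaf_speed <= 0) stop("max_leaf_speed must be > 0")
  if (field_height <= 0) stop("field_height must be > 0")
  if (min_gap < 0) stop("min_gap must be >= 0")
  structure(list(
    n_leaf_pairs = n_leaf_pairs,
    leaf_widths = as.numeric(leaf_widths),
    field_width = as.numeric(field_width),
    field_height = as.numeric(field_height),
    max_leaf_speed = as.numeric(max_leaf_speed),
    min_gap = as.numeric(min_gap)
  ), class = "machine_spec")
}

#' @export
print.machine_spec <- function(x, ...) {
  cat("MLC machine:", x$n_leaf_pairs, "leaf pairs,",
      x$field_width, "x", x$field_height, "mm field,",
      "max leaf speed", x$max_leaf_speed, "mm/deg, min gap",
      x$min_gap, "mm\n")
  invisible(x)
}

# y-coordinates of leaf-pair centers, isocenter-centered
pair_centers <- function(machine) {
  edges <- c(0, cumsum(machine$leaf_widths)) - machine$field_width / 2
  (edges[-1] + edges[-length(edges)]) / 2
}
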