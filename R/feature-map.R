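#' Build the digitization grid for aperture maps
#'
#' The MLC field is digitized on a uniform grid with `resolution` mm per
#' pixel on both axes. Rows index the leaf axis (`N_L = field_width /
#' resolution`), columns the travel axis (`N_P = field_height /
#' resolution`); e.g. a 300 mm field at 0.1 mm resolution gives
#' `N_L = 3000` and a 400 mm travel range gives `N_P = 4000`. Each leaf
#' pair is resampled to `round(leaf_width / resolution)` contiguous rows by
#' nearest-neighbour replication (no sub-row interpolation); the row ranges
#' must partition the leaf axis exactly, otherwise the resolution is
#' rejected as incompatible with the machine.
#'
#' @param machine a [machine_spec()].
#' @param resolution pixel size in mm (> 0); must divide the field extents
#'   within rounding tolerance.
#' @return an object of class `raster_grid` with fields `resolution`,
#'   `n_leaf_index`, `n_position_index`, `row_of_pair` (integer vector
#'   mapping each row to its leaf pair), `row_ranges` (2 x n_pairs matrix of
#'   first/last row) and `centers_x` (column-center x coordinates, mm).
#' @export
build_grid <- function(machine, resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a positive number (mm)")
  nl <- machine$field_width / resolution
  np <- machine$field_height / resolution
  if (abs(nl - round(nl)) > 1e-6 || abs(np - round(np)) > 1e-6)
    stop("resolution does not divide the field extents")
  nl <- as.integer(round(nl)); np <- as.integer(round(np))
  rows_per_pair <- as.integer(round(machine$leaf_widths / resolution))
  if (any(rows_per_pair < 1L) || sum(rows_per_pair) != nl)
    stop("per-pair row counts do not partition the leaf axis at this ",
         "resolution")
  row_of_pair <- rep.int(seq_len(machine$n_leaf_pairs), rows_per_pair)
  ends <- cumsum(rows_per_pair)
  row_ranges <- rbind(first = ends - rows_per_pair + 1L, last = ends)
  centers_x <- (seq_len(np) - 0.5) * resolution - machine$field_height / 2
  structure(list(resolution = resolution, n_leaf_index = nl,
                 n_position_index = np, row_of_pair = row_of_pair,
                 row_ranges = row_ranges, centers_x = centers_x,
                 machine = machine),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster grid: %.4g mm/pixel, %d x %d (leaf x position)\n",
              x$resolution, x$n_leaf_index, x$n_position_index))
  invisible(x)
}

#' Rasterize the aperture of one control point
#'
#' A pixel is open (1) iff its row belongs to leaf pair p and its column
#' center lies strictly inside the open interval `(left_p, right_p)`; a
#' closed pair (`left == right`) therefore contributes no open pixels.
#'
#' @param cp a control point as returned by [control_point()] (a list with
#'   `left_positions`, `right_positions`).
#' @param grid a [build_grid()] result.
#' @param cp_index optional CP index recorded on the result.
#' @return an `aperture_map`: list with `values` (binary
#'   `n_leaf_index x n_position_index` matrix) and `cp_index`.
#' @export
rasterize_aperture <- function(cp, grid, cp_index = NA_integer_) {
  np <- grid$machine$n_leaf_pairs
  if (length(cp$left_positions) != np || length(cp$right_positions) != np)
    stop("bank length does not match the grid's leaf-pair partition")
  v <- cpp_rasterize(cp$left_positions, cp$right_positions,
                     grid$row_of_pair, grid$centers_x)
  structure(list(values = v, cp_index = cp_index), class = "aperture_map")
}

#' Intensity map of an aperture
#'
#' The per-CP intensity (fluence) map is the binary aperture scaled by the
#' CP's meterset: `I = dose * A`, elementwise.
#'
#' @param aperture an `aperture_map` from [rasterize_aperture()].
#' @param dose per-CP meterset (MU), `>= 0`.
#' @return an `intensity_map`: list with `values` and `cp_index`.
#' @export
intensity_from_aperture <- function(aperture, dose) {
  if (!is.numeric(dose) || length(dose) != 1 || is.na(dose) || dose < 0)
    stop("dose must be a single non-negative number")
  structure(list(values = dose * aperture$values,
                 cp_index = aperture$cp_index),
            class = "intensity_map")
}

#' Digitize a whole plan into network-ready feature maps
#'
#' Every control point (in arc order) is rasterized on `grid`, the intensity
#' map is formed, and both maps are downsampled to `target_shape` by block
#' averaging: the aperture by its open-area fraction binarized at >= 0.5,
#' the intensity by the block mean (which equals `dose x` open-area
#' fraction). The grid dimensions must be integer multiples of the target.
#'
#' @param plan a [vmat_plan()].
#' @param grid a [build_grid()] result for the plan's machine.
#' @param target_shape integer `c(M, N)` network input size; defaults to the
#'   grid size itself (no downsampling).
#' @return a `feature_tensor`: list with `apertures` (`M x N x K` integer
#'   0/1 array), `intensities` (`M x N x K` array, MU-scaled), `doses`
#'   (length-K vector), `plan_id`, `label`, and grid metadata
#'   (`resolution`, `target_shape`).
#' @export
featurize_plan <- function(plan, grid,
                           target_shape = c(grid$n_leaf_index,
                                            grid$n_position_index)) {
  K <- n_cp(plan)
  if (K < 1L) stop("cannot featurize an empty plan")
  M <- as.integer(target_shape[1]); N <- as.integer(target_shape[2])
  if (M > grid$n_leaf_index || N > grid$n_position_index)
    stop("target_shape larger than the raster grid")
  fr <- grid$n_leaf_index / M; fc <- grid$n_position_index / N
  if (fr != round(fr) || fc != round(fc))
    stop("grid dimensions must be integer multiples of target_shape")
  fr <- as.integer(fr); fc <- as.integer(fc)
  apertures <- array(0L, c(M, N, K))
  intensities <- array(0, c(M, N, K))
  doses <- numeric(K)
  k <- 0L
  for (a in plan$arcs) {
    for (i in seq_along(a$gantry_deg)) {
      k <- k + 1L
      fine <- cpp_rasterize(a$left[, i], a$right[, i], grid$row_of_pair,
                            grid$centers_x)
      frac <- cpp_block_mean(fine, fr, fc)
      apertures[, , k] <- (frac >= 0.5) + 0L
      intensities[, , k] <- a$dose[i] * frac
      doses[k] <- a$dose[i]
    }
  }
  structure(list(apertures = apertures, intensities = intensities,
                 doses = doses, plan_id = plan$plan_id, label = plan$label,
                 resolution = grid$resolution, target_shape = c(M, N)),
            class = "feature_tensor")
}

#' Featurize a list of plans
#'
#' @param plans list of [vmat_plan()] objects.
#' @inheritParams featurize_plan
#' @return list of `feature_tensor` objects.
#' @export
featurize_dataset <- function(plans, grid, target_shape) {
  lapply(plans, featurize_plan, grid = grid, target_shape = target_shape)
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$apertures)
  cat(sprintf("feature tensor '%s': K=%d maps of %d x %d, label=%s\n",
              x$plan_id, d[3], d[1], d[2], x$label))
  invisible(x)
}
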