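# Shared fixtures and independent brute-force oracles.

# a small 4-pair machine for fast geometric tests
tiny_machine <- function() machine_spec(
  n_leaf_pairs = 4L, leaf_widths = rep(10, 4), field_height = 40,
  max_leaf_speed = 0.5, min_gap = 0)

tiny_sim_config <- function(n_regular = 6L, n_anomalous = 2L, ...) sim_config(
  n_regular = n_regular, n_anomalous = n_anomalous, arcs_per_plan = 2L,
  cps_per_arc = 10L, machine = tiny_machine(), dose_mean = 3,
  dose_cv = 0.3, smoothness = 3L, seed = 42L, ...)

# a hand-built one-arc plan on the tiny machine
tiny_plan <- function(left, right, gantry = NULL, dose = NULL,
                      label = "unknown") {
  left <- as.matrix(left); right <- as.matrix(right)
  k <- ncol(left)
  vmat_plan("tiny", list(vmat_arc(gantry %||% seq(0, by = 4,
                                                  length.out = k),
                                  left, right, dose %||% rep(1, k))),
            tiny_machine(), label = label)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# feature tensor built directly (simple rectangular aperture)
fake_tensor <- function(M = 16, N = 16, K = 3, dose = 3, label = "regular",
                        plan_id = "fake") {
  ap <- array(0L, c(M, N, K)); it <- array(0, c(M, N, K))
  for (k in seq_len(K)) {
    ap[3:(M - 4), 4:(N - 6), k] <- 1L
    it[, , k] <- dose * ap[, , k]
  }
  structure(list(apertures = ap, intensities = it, doses = rep(dose, K),
                 plan_id = plan_id, label = label, resolution = 1,
                 target_shape = c(M, N)), class = "feature_tensor")
}

# brute-force per-pixel rasterizer: loops every pixel independently
oracle_rasterize <- function(cp, grid) {
  m <- grid$machine
  A <- matrix(0, grid$n_leaf_index, grid$n_position_index)
  for (i in seq_len(grid$n_leaf_index)) {
    p <- grid$row_of_pair[i]
    for (j in seq_len(grid$n_position_index)) {
      x <- grid$centers_x[j]
      if (x > cp$left_positions[p] && x < cp$right_positions[p])
        A[i, j] <- 1
    }
  }
  A
}

# brute-force constraint checker enumerating every (arc, cp, pair) triple
oracle_validate <- function(plan, machine = plan$machine) {
  out <- list()
  half <- machine$field_height / 2
  off <- 0L
  for (a in plan$arcs) {
    k <- length(a$gantry_deg)
    for (ci in seq_len(k)) for (p in seq_len(machine$n_leaf_pairs)) {
      gap <- a$right[p, ci] - a$left[p, ci]
      if (gap < machine$min_gap - 1e-9)
        out[[length(out) + 1L]] <- data.frame(
          cp_index = off + ci, leaf_pair = p, kind = "gap",
          magnitude = machine$min_gap - gap)
      ex <- max(abs(a$left[p, ci]), abs(a$right[p, ci])) - half
      if (ex > 1e-9)
        out[[length(out) + 1L]] <- data.frame(
          cp_index = off + ci, leaf_pair = p, kind = "travel",
          magnitude = ex)
      if (ci > 1L) {
        lim <- machine$max_leaf_speed * abs(a$gantry_deg[ci] -
                                              a$gantry_deg[ci - 1L])
        exs <- max(abs(a$left[p, ci] - a$left[p, ci - 1L]),
                   abs(a$right[p, ci] - a$right[p, ci - 1L])) - lim
        if (exs > 1e-9)
          out[[length(out) + 1L]] <- data.frame(
            cp_index = off + ci, leaf_pair = p, kind = "speed",
            magnitude = exs)
      }
    }
    off <- off + k
  }
  if (!length(out))
    return(data.frame(cp_index = integer(0), leaf_pair = integer(0),
                      kind = character(0), magnitude = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$cp_index, df$leaf_pair, df$kind), ]
}

# O(n^2) pairwise Mann-Whitney AUC oracle
oracle_auc <- function(scores, labels) {
  a <- scores[labels == "anomalous"]; r <- scores[labels == "regular"]
  s <- 0
  for (x in a) for (y in r) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(r))
}

# exhaustive threshold sweep: largest observed candidate with zero FNR
oracle_fnr0_threshold <- function(scores, labels) {
  best <- NA_real_
  for (c in sort(unique(scores))) {
    fn <- sum(labels == "anomalous" & scores <= c)
    if (fn == 0 && (is.na(best) || c > best)) best <- c
  }
  best
}

expect_plans_equal <- function(p1, p2, tol = 1e-9) {
  expect_identical(p1$plan_id, p2$plan_id)
  expect_identical(p1$label, p2$label)
  expect_equal(length(p1$arcs), length(p2$arcs))
  for (i in seq_along(p1$arcs)) {
    expect_equal(p1$arcs[[i]]$gantry_deg, p2$arcs[[i]]$gantry_deg,
                 tolerance = tol)
    expect_equal(p1$arcs[[i]]$left, p2$arcs[[i]]$left, tolerance = tol)
    expect_equal(p1$arcs[[i]]$right, p2$arcs[[i]]$right, tolerance = tol)
    expect_equal(p1$arcs[[i]]$dose, p2$arcs[[i]]$dose, tolerance = tol)
  }
  expect_equal(p1$machine[1:6], p2$machine[1:6], tolerance = tol)
}
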