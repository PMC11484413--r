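#' Synthetic VMAT dataset configuration
#'
#' The simulator emulates the statistical structure the detector assumes:
#' two-arc plans with 90 CPs per arc, smooth leaf trajectories obeying the
#' machine's gap/travel/speed limits, per-CP metersets drawn from a
#' truncated normal, and a small anomalous minority produced by injecting
#' labelled mechanical or dosimetric faults into otherwise regular plans.
#'
#' @param n_regular,n_anomalous plan counts (the clinical-scale 652:25
#'   imbalance is reachable via these knobs; the desk-scale default is
#'   200:20).
#' @param arcs_per_plan,cps_per_arc plan structure; defaults 2 x 90.
#' @param machine a [machine_spec()].
#' @param dose_mean,dose_cv mean and coefficient of variation of the per-CP
#'   meterset (MU); doses are drawn from a normal truncated at 0.
#' @param smoothness moving-average window (in CPs) applied to the leaf
#'   trajectory noise; larger values give slower-varying apertures.
#' @param seed RNG seed; the dataset is a pure function of the config.
#' @param anomaly_mix named non-negative weights over fault kinds (see
#'   [anomaly_spec()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_regular = 200L, n_anomalous = 20L,
                       arcs_per_plan = 2L, cps_per_arc = 90L,
                       machine = machine_spec(),
                       dose_mean = 3, dose_cv = 0.3,
                       smoothness = 11L, seed = 1L,
                       anomaly_mix = c(leaf_jump = 1, crossed_leaves = 1,
                                       bank_swap = 1, dose_spike = 1,
                                       dose_dropout = 1,
                                       aperture_collapse = 1)) {
  if (n_regular < 0 || n_anomalous < 0) stop("plan counts must be >= 0")
  if (cps_per_arc < 2) stop("cps_per_arc must be >= 2")
  if (dose_mean <= 0) stop("dose_mean must be > 0")
  if (is.null(names(anomaly_mix)) ||
      !all(names(anomaly_mix) %in% anomaly_kinds()))
    stop("anomaly_mix must be named with known fault kinds")
  if (any(anomaly_mix < 0) || sum(anomaly_mix) <= 0)
    stop("anomaly_mix weights must be non-negative and not all zero")
  structure(list(n_regular = as.integer(n_regular),
                 n_anomalous = as.integer(n_anomalous),
                 arcs_per_plan = as.integer(arcs_per_plan),
                 cps_per_arc = as.integer(cps_per_arc),
                 machine = machine, dose_mean = dose_mean,
                 dose_cv = dose_cv, smoothness = as.integer(smoothness),
                 seed = as.integer(seed), anomaly_mix = anomaly_mix),
            class = "sim_config")
}

moving_average <- function(x, w) {
  w <- min(w, length(x))  # window cannot exceed the arc length
  if (w <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
}

rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Simulate one regular (fault-free) VMAT plan
#'
#' Leaf trajectories follow a slowly drifting, roughly elliptical aperture:
#' per-plan envelope parameters (aperture width, vertical extent, centre
#' drift) are drawn once, per-pair noise is a smoothed Gaussian random walk,
#' and the result is projected CP-by-CP onto the machine's travel, speed and
#' gap limits, so every simulated regular plan passes [validate_plan()] by
#' construction.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed for this plan (defaults to the config seed).
#' @param plan_id identifier for the plan.
#' @return a [vmat_plan()] with `label = "regular"`.
#' @export
simulate_regular_plan <- function(config, seed = config$seed,
                                  plan_id = "plan") {
  with_seed(seed, {
    m <- config$machine
    half <- m$field_height / 2
    yc <- pair_centers(m)
    karc <- config$cps_per_arc
    step <- 360 / karc
    gantry_fwd <- (seq_len(karc) - 1L) * step
    arcs <- vector("list", config$arcs_per_plan)
    # plan-level aperture envelope
    W0 <- runif(1, 30, 90)           # max aperture width (mm)
    Ry <- runif(1, 40, 150)          # vertical half-extent (mm)
    y0 <- runif(1, -40, 40)          # vertical centre (mm)
    x0b <- runif(1, -30, 30)         # mean horizontal centre (mm)
    xamp <- runif(1, 5, 35)          # horizontal drift amplitude (mm)
    phase <- runif(1, 0, 2 * pi)
    for (ai in seq_len(config$arcs_per_plan)) {
      g <- if (ai %% 2L == 1L) gantry_fwd else rev(gantry_fwd)
      kk <- seq_len(karc)
      x0 <- x0b + xamp * sin(2 * pi * kk / karc + phase + (ai - 1))
      env <- sqrt(pmax(0, 1 - ((yc - y0) / Ry)^2))
      left <- right <- matrix(0, m$n_leaf_pairs, karc)
      for (p in seq_len(m$n_leaf_pairs)) {
        wnoise <- moving_average(rnorm(karc, 0, 6), config$smoothness)
        cnoise <- moving_average(rnorm(karc, 0, 6), config$smoothness)
        w <- pmax(0, W0 * env[p] + wnoise * (env[p] > 0))
        ctr <- x0 + cnoise
        left[p, ] <- ctr - w / 2
        right[p, ] <- ctr + w / 2
      }
      # project onto machine limits, CP by CP (guarantees feasibility
      # because the previous CP's positions are always a feasible choice)
      smax <- m$max_leaf_speed * abs(diff(g))
      gmin <- m$min_gap
      for (k in kk) {
        l <- pmin(pmax(left[, k], -half), half)
        r <- pmin(pmax(right[, k], -half), half)
        if (k > 1L) {
          s <- smax[k - 1L]
          lp <- left[, k - 1L]; rp <- right[, k - 1L]
          l <- pmin(pmax(l, lp - s), lp + s)
          r <- pmin(pmax(r, rp - s), rp + s)
          short <- which(r - l < gmin)
          if (length(short)) {
            mid <- (l[short] + r[short]) / 2
            l2 <- pmin(pmax(mid - gmin / 2, lp[short] - s), lp[short] + s)
            r2 <- pmin(pmax(mid + gmin / 2, rp[short] - s), rp[short] + s)
            stuck <- which(r2 - l2 < gmin)
            if (length(stuck)) { # fall back to the previous CP's positions
              l2[stuck] <- lp[short][stuck]
              r2[stuck] <- rp[short][stuck]
            }
            l[short] <- l2; r[short] <- r2
          }
        } else {
          short <- which(r - l < gmin)
          if (length(short)) {
            mid <- (l[short] + r[short]) / 2
            l[short] <- pmax(mid - gmin / 2, -half)
            r[short] <- pmin(mid + gmin / 2, half)
          }
        }
        left[, k] <- l; right[, k] <- r
      }
      dose <- rtruncnorm0(karc, config$dose_mean,
                          config$dose_cv * config$dose_mean)
      arcs[[ai]] <- vmat_arc(g, left, right, dose)
    }
    vmat_plan(plan_id, arcs, m, label = "regular")
  })
}

#' Fault kinds known to the injector
#' @return character vector of kinds.
#' @export
anomaly_kinds <- function() c("leaf_jump", "crossed_leaves", "bank_swap",
                              "dose_spike", "dose_dropout",
                              "aperture_collapse")

#' Describe a fault to inject
#'
#' Defaults are deliberately gross, human-reviewable faults (several times
#' the machine's speed limit or the meterset spread), modelled as a
#' corrupted arc record: mechanical and dosimetric faults affect one whole
#' arc by default (`span` 90, capped at the arc length), the leaf jump
#' switches on mid-arc (default span 45, always leaving at least one
#' unaffected CP in the arc so the jump transition itself is part of the
#' record), and the dose spike is a single-meterset transcription error. A magnitude of zero is
#' always a no-op. `span` is the number of consecutive CPs affected; the
#' window never crosses an arc boundary.
#'
#' Kinds and their magnitude semantics:
#' \describe{
#'   \item{leaf_jump}{one leaf pair displaced by `magnitude` mm (default
#'     100) toward the field centre over `span` CPs.}
#'   \item{crossed_leaves}{one leaf pair's banks crossed by `magnitude` mm
#'     (default 20) about their centre over `span` CPs.}
#'   \item{bank_swap}{left/right banks exchanged over `span` CPs;
#'     magnitude acts as an on/off switch (default 1).}
#'   \item{dose_spike}{per-CP meterset multiplied by `magnitude` (default
#'     10) over `span` CPs (default 1).}
#'   \item{dose_dropout}{fraction `magnitude` (default 1) of the meterset
#'     removed over `span` CPs.}
#'   \item{aperture_collapse}{leaf gaps shrunk by a factor
#'     `1 + magnitude` (default 4) over `span` CPs.}
#' }
#'
#' @param kind one of [anomaly_kinds()].
#' @param magnitude kind-specific non-negative scalar; `NULL` for default.
#' @param cp_index global index of the first affected CP; `NULL` to draw at
#'   random (geometry faults prefer CPs with an open aperture).
#' @param span number of consecutive CPs affected; `NULL` for the kind's
#'   default.
#' @param leaf_pair target pair for single-pair faults; `NULL` to pick the
#'   widest-open pair.
#' @return an object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind, magnitude = NULL, cp_index = NULL,
                         span = NULL, leaf_pair = NULL) {
  kind <- match.arg(kind, anomaly_kinds())
  defaults <- list(
    leaf_jump = c(mag = 100, span = 45),
    crossed_leaves = c(mag = 20, span = 90),
    bank_swap = c(mag = 1, span = 90),
    dose_spike = c(mag = 10, span = 1),
    dose_dropout = c(mag = 1, span = 90),
    aperture_collapse = c(mag = 4, span = 90))[[kind]]
  magnitude <- magnitude %||% unname(defaults["mag"])
  span <- as.integer(span %||% defaults["span"])
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (span < 1L) stop("span must be >= 1")
  structure(list(kind = kind, magnitude = magnitude,
                 cp_index = cp_index, span = span, leaf_pair = leaf_pair),
            class = "anomaly_spec")
}

# locate (arc, local index) for a global cp index
locate_cp <- function(plan, k) {
  for (ai in seq_along(plan$arcs)) {
    nk <- length(plan$arcs[[ai]]$gantry_deg)
    if (k <= nk) return(c(arc = ai, idx = k))
    k <- k - nk
  }
  stop("cp index out of range")
}

#' Inject a labelled fault into a regular plan
#'
#' Returns a modified copy with `label = "anomalous"` and `anomaly_meta`
#' recording the fault; every CP outside the affected window is
#' bit-identical to the input. The window is confined to a single arc.
#'
#' @param plan a regular [vmat_plan()].
#' @param spec an [anomaly_spec()].
#' @param seed RNG seed used when the fault site is drawn at random.
#' @return the faulted [vmat_plan()].
#' @export
inject_anomaly <- function(plan, spec, seed = 1L) {
  if (!inherits(spec, "anomaly_spec")) stop("unknown anomaly specification")
  if (plan$label == "anomalous") stop("plan is already anomalous")
  with_seed(seed, {
    K <- n_cp(plan)
    min_arc <- min(vapply(plan$arcs, function(a)
      length(a$gantry_deg), integer(1)))
    span <- min(spec$span, min_arc)
    # a jump must switch on inside the arc, or no speed transition exists
    if (spec$kind == "leaf_jump") span <- max(1L, min(span, min_arc - 1L))
    geom <- spec$kind %in% c("leaf_jump", "crossed_leaves", "bank_swap",
                             "aperture_collapse")
    cp0 <- spec$cp_index
    if (is.null(cp0)) {
      draw_start <- function() {
        ai <- sample.int(length(plan$arcs), 1)
        nk <- length(plan$arcs[[ai]]$gantry_deg)
        off <- if (ai > 1)
          sum(vapply(plan$arcs[seq_len(ai - 1L)], function(a)
            length(a$gantry_deg), integer(1))) else 0L
        off + sample.int(nk - span + 1L, 1)
      }
      cp0 <- draw_start()
      if (geom) { # prefer a window where the aperture is actually open
        for (try in 1:20) {
          loc <- locate_cp(plan, cp0)
          a <- plan$arcs[[loc["arc"]]]
          win <- loc["idx"]:(loc["idx"] + span - 1L)
          if (max(a$right[, win] - a$left[, win]) > 5) break
          cp0 <- draw_start()
        }
      }
    }
    loc <- locate_cp(plan, cp0)
    a <- plan$arcs[[loc["arc"]]]
    nk <- length(a$gantry_deg)
    win <- loc["idx"]:min(nk, loc["idx"] + span - 1L)
    meta <- list(kind = spec$kind, magnitude = spec$magnitude,
                 cp_index = as.integer(cp0), span = length(win),
                 leaf_pair = NA_integer_)
    if (spec$magnitude > 0) {
      half <- plan$machine$field_height / 2
      if (spec$kind %in% c("leaf_jump", "crossed_leaves")) {
        p <- spec$leaf_pair %||%
          which.max(rowMeans(a$right[, win, drop = FALSE] -
                               a$left[, win, drop = FALSE]))
        meta$leaf_pair <- as.integer(p)
      }
      switch(spec$kind,
        leaf_jump = {
          dir <- -sign(mean(a$left[p, win] + a$right[p, win]))
          if (dir == 0) dir <- 1
          a$left[p, win] <- pmin(pmax(a$left[p, win] + dir * spec$magnitude,
                                      -half), half)
          a$right[p, win] <- pmin(pmax(a$right[p, win] + dir * spec$magnitude,
                                       -half), half)
        },
        crossed_leaves = {
          ctr <- (a$left[p, win] + a$right[p, win]) / 2
          a$left[p, win] <- ctr + spec$magnitude / 2
          a$right[p, win] <- ctr - spec$magnitude / 2
        },
        bank_swap = {
          tmp <- a$left[, win, drop = FALSE]
          a$left[, win] <- a$right[, win, drop = FALSE]
          a$right[, win] <- tmp
        },
        dose_spike = a$dose[win] <- a$dose[win] * spec$magnitude,
        dose_dropout = a$dose[win] <- a$dose[win] *
          (1 - min(spec$magnitude, 1)),
        aperture_collapse = {
          ctr <- (a$left[, win, drop = FALSE] +
                    a$right[, win, drop = FALSE]) / 2
          w <- (a$right[, win, drop = FALSE] -
                  a$left[, win, drop = FALSE]) / (1 + spec$magnitude)
          a$left[, win] <- ctr - w / 2
          a$right[, win] <- ctr + w / 2
        })
      plan$arcs[[loc["arc"]]] <- a
    }
    plan$label <- "anomalous"
    plan$anomaly_meta <- meta
    plan
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_regular` fault-free plans and `n_anomalous` plans with one
#' fault each, the kinds drawn from `anomaly_mix`. Deterministic given the
#' config (per-plan seeds are derived from `config$seed`).
#'
#' @param config a [sim_config()].
#' @return list of [vmat_plan()] objects (regular first).
#' @export
make_dataset <- function(config) {
  plan_seed <- function(i) (config$seed * 100003L + i * 7919L) %%
    .Machine$integer.max
  regs <- lapply(seq_len(config$n_regular), function(i)
    simulate_regular_plan(config, seed = plan_seed(i),
                          plan_id = sprintf("reg_%04d", i)))
  kinds <- names(config$anomaly_mix)[config$anomaly_mix > 0]
  wts <- config$anomaly_mix[config$anomaly_mix > 0]
  anoms <- lapply(seq_len(config$n_anomalous), function(j) {
    i <- config$n_regular + j
    base <- simulate_regular_plan(config, seed = plan_seed(i),
                                  plan_id = sprintf("anom_%04d", j))
    kind <- with_seed(plan_seed(i) + 1L,
                      sample(kinds, 1, prob = wts / sum(wts)))
    inject_anomaly(base, anomaly_spec(kind), seed = plan_seed(i) + 2L)
  })
  c(regs, anoms)
}

#' Manifest of a simulated dataset
#'
#' @param plans list of [vmat_plan()] objects.
#' @return data.frame with plan_id, label, fault kind/magnitude/site.
#' @export
dataset_manifest <- function(plans) {
  do.call(rbind, lapply(plans, function(p) {
    m <- p$anomaly_meta
    data.frame(plan_id = p$plan_id, label = p$label,
               kind = if (is.null(m)) NA_character_ else m$kind,
               magnitude = if (is.null(m)) NA_real_ else m$magnitude,
               cp_index = if (is.null(m)) NA_integer_ else m$cp_index,
               span = if (is.null(m)) NA_integer_ else m$span)
  }))
}
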