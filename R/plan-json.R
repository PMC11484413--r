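#' Read and write the plan interchange JSON
#'
#' Plans are exchanged as JSON with the layout:
#' \preformatted{
#' {plan_id, machine: {n_leaf_pairs, leaf_widths_mm, field_width_mm,
#'   field_height_mm, max_leaf_speed_mm_per_deg, min_gap_mm},
#'  arcs: [[{gantry_deg, left_mm: [...], right_mm: [...], dose}, ...], ...],
#'  label, anomaly_meta}
#' }
#' All bank arrays are ordered by leaf-pair index. Units are preserved
#' (mm / degrees / MU); the round trip `read_plan_json(write_plan_json(p))`
#' is lossless to full double precision.
#'
#' @param path file path.
#' @return `read_plan_json` returns a [vmat_plan()].
#' @export
read_plan_json <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("plan_id", "machine", "arcs", "label"))
    if (is.null(doc[[f]])) stop("plan JSON missing field \"", f, "\"")
  m <- doc$machine
  for (f in c("n_leaf_pairs", "leaf_widths_mm", "field_width_mm",
              "field_height_mm", "max_leaf_speed_mm_per_deg", "min_gap_mm"))
    if (is.null(m[[f]])) stop("plan JSON missing field \"machine.", f, "\"")
  machine <- machine_spec(
    n_leaf_pairs = m$n_leaf_pairs,
    leaf_widths = unlist(m$leaf_widths_mm),
    field_width = m$field_width_mm,
    field_height = m$field_height_mm,
    max_leaf_speed = m$max_leaf_speed_mm_per_deg,
    min_gap = m$min_gap_mm)
  np <- machine$n_leaf_pairs
  if (!length(doc$arcs)) stop("plan JSON field \"arcs\" is empty (K >= 1)")
  arcs <- lapply(doc$arcs, function(arc) {
    if (!length(arc)) stop("plan JSON contains an empty arc")
    g <- d <- numeric(length(arc))
    left <- right <- matrix(NA_real_, np, length(arc))
    for (i in seq_along(arc)) {
      cp <- arc[[i]]
      for (f in c("gantry_deg", "left_mm", "right_mm", "dose"))
        if (is.null(cp[[f]])) stop("control point missing field \"", f, "\"")
      l <- unlist(cp$left_mm); r <- unlist(cp$right_mm)
      if (length(l) != np)
        stop("bank length mismatch in field \"left_mm\" (left_positions): ",
             "got ", length(l), ", machine has ", np, " pairs")
      if (length(r) != np)
        stop("bank length mismatch in field \"right_mm\" (right_positions): ",
             "got ", length(r), ", machine has ", np, " pairs")
      g[i] <- cp$gantry_deg; d[i] <- cp$dose
      left[, i] <- l; right[, i] <- r
    }
    vmat_arc(g, left, right, d)
  })
  meta <- doc$anomaly_meta
  if (!is.null(meta)) meta <- lapply(meta, function(v)
    if (is.list(v)) unlist(v) else v)
  vmat_plan(doc$plan_id, arcs, machine, label = doc$label,
            anomaly_meta = meta)
}

#' @param plan a [vmat_plan()] whose invariants hold.
#' @rdname read_plan_json
#' @return `write_plan_json` invisibly returns `path`.
#' @export
write_plan_json <- function(plan, path) {
  if (!inherits(plan, "vmat_plan")) stop("plan must be a vmat_plan")
  if (!length(plan$arcs) || n_cp(plan) < 1L)
    stop("refusing to serialize a plan without control points (K >= 1)")
  m <- plan$machine
  doc <- list(
    plan_id = plan$plan_id,
    machine = list(
      n_leaf_pairs = m$n_leaf_pairs,
      leaf_widths_mm = m$leaf_widths,
      field_width_mm = m$field_width,
      field_height_mm = m$field_height,
      max_leaf_speed_mm_per_deg = m$max_leaf_speed,
      min_gap_mm = m$min_gap),
    arcs = lapply(plan$arcs, function(a)
      lapply(seq_along(a$gantry_deg), function(i)
        list(gantry_deg = a$gantry_deg[i],
             left_mm = a$left[, i],
             right_mm = a$right[, i],
             dose = a$dose[i]))),
    label = plan$label,
    anomaly_meta = plan$anomaly_meta)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null")
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) stop("cannot write plan to ", path,
                                          ": ", conditionMessage(e)))
  invisible(path)
}
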