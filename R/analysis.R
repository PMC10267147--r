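#' Map a cell index to the nearest grid node
#'
#' On a cell network this is the cell itself; on a finite-volume grid it is
#' the node whose center lies closest to the center of cell
#' `(cell_ix, cell_iy)`. Synthetic traces index nodes directly.
#'
#' @param net A `knm_network` (or the `net` element of a synthetic trace).
#' @param cell_ix,cell_iy 1-based cell indices.
#' @return A node index.
#' @export
cell_center_node <- function(net, cell_ix, cell_iy = 1) {
  if (identical(net$kind, "knm")) {
    if (cell_ix > net$n_x || cell_iy > net$n_y)
      stop("cell index outside the grid", call. = FALSE)
    return((cell_iy - 1L) * net$n_x + cell_ix)
  }
  if (identical(net$kind, "bd")) {
    cx <- (cell_ix - 0.5) * net$geom$length
    cy <- (cell_iy - 0.5) * net$geom$l_y
    return(which.min((net$pos[, 1] - cx)^2 + (net$pos[, 2] - cy)^2))
  }
  cell_ix
}

no_propagation <- function(msg) {
  stop(structure(class = c("knm_no_propagation", "error", "condition"),
                 list(message = msg, call = NULL)))
}

first_crossing_time <- function(trace, node, threshold, interpolate = FALSE) {
  if (!interpolate && isTRUE(all.equal(threshold, trace$threshold))) {
    a <- trace$activations[[node]]
    return(if (length(a)) a[1] else NA_real_)
  }
  if (is.null(trace$v))
    stop("snapshots were not recorded; re-simulate with the requested threshold",
         call. = FALSE)
  v <- trace$v[, node]
  idx <- which(v >= threshold)
  idx <- idx[idx > 1 & v[idx - 1] < threshold]   # upward crossings only
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (!interpolate) return(trace$times[i])
  t0 <- trace$times[i - 1]; t1 <- trace$times[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Conduction velocity between two cell centers
#'
#' The distance between the centers of cells `cell_a` and `cell_b` divided
#' by the difference of the times at which their membrane potentials first
#' reach the threshold (default -20 mV), in cm/s. By default the first
#' upward crossing is taken at full time-step resolution without temporal
#' interpolation (the literal reading of "reaches the threshold");
#' `interpolate = TRUE` instead interpolates linearly between recorded
#' snapshots, which matters at coarse snapshot cadences.
#'
#' @param trace A `knm_trace`.
#' @param cell_a,cell_b 1-based cell indices along the fibre (defaults 3 and
#'   13, the standard measurement cells on a 15-cell strand).
#' @param threshold Activation threshold, mV.
#' @param positions Optional overriding node-position matrix (um).
#' @param interpolate Interpolate the crossing time between snapshots.
#' @return Conduction velocity in cm/s.
#' @export
conduction_velocity <- function(trace, cell_a = 3, cell_b = 13,
                                threshold = -20, positions = NULL,
                                interpolate = FALSE) {
  net <- trace$net
  na <- cell_center_node(net, cell_a)
  nb <- cell_center_node(net, cell_b)
  pos <- if (is.null(positions)) net$pos else positions
  ta <- first_crossing_time(trace, na, threshold, interpolate)
  tb <- first_crossing_time(trace, nb, threshold, interpolate)
  if (is.na(ta) || is.na(tb))
    no_propagation(sprintf(
      "no threshold crossing at cell %s: the wave did not reach the measurement point",
      if (is.na(ta)) cell_a else cell_b))
  if (tb == ta)
    stop("identical activation times at the two measurement cells", call. = FALSE)
  d_um <- sqrt(sum((pos[nb, ] - pos[na, ])^2))
  # um/ms * 0.1 = cm/s
  0.1 * d_um / abs(tb - ta)
}

#' Detect reentrant (self-sustaining) activity after an S2 stimulus
#'
#' Operational reentry criterion: the tissue is classified as reentrant if
#' (a) at least one node activates twice or more after `t_s2 + guard`
#' (re-excitation beyond anything the S2 pulse itself can account for within
#' a refractory period), and (b) activity -- any node at or above the
#' activation threshold -- persists beyond `t_s2 + window`. A single decaying
#' wave fails (a); a captured but non-reentrant S2 response fails (b).
#'
#' @param trace A `knm_trace` extending at least `window` ms beyond `t_s2`.
#' @param t_s2 S2 onset time, ms.
#' @param guard Refractory guard after S2, ms.
#' @param window Persistence window after S2, ms.
#' @return A list: `reentrant` flag and `evidence` (number of re-activated
#'   cells, maximum re-activation count, last activity time, the windows).
#' @export
detect_reentry <- function(trace, t_s2, guard = 50, window = 300) {
  t_end <- max(trace$times)
  if (t_end < t_s2 + window)
    stop(sprintf("trace ends at %g ms but the persistence window extends to %g ms",
                 t_end, t_s2 + window), call. = FALSE)
  re_counts <- vapply(trace$activations,
                      function(a) sum(a > t_s2 + guard), integer(1))
  persistent <- is.finite(trace$last_active) && trace$last_active > t_s2 + window
  list(reentrant = any(re_counts >= 2) && persistent,
       evidence = list(n_reactivated = sum(re_counts >= 2),
                       max_reactivations = max(re_counts),
                       last_active = trace$last_active,
                       guard = guard, window = window))
}

#' Conduction velocity of a stimulated strand
#'
#' Builds a 1D strand (cell network or bidomain grid), stimulates its left
#' end, and measures the conduction velocity between two cell centers. The
#' simulation stops as soon as both measurement cells have activated.
#'
#' @param rg_multiplier Gap-junction resistance multiplier.
#' @param dt Time step, ms.
#' @param n_cells Strand length in cells.
#' @param model A [membrane_model()].
#' @param model_type `"knm"` (cell network) or `"bd"` (bidomain grid).
#' @param dx Bidomain grid spacing, um (ignored for `"knm"`).
#' @param geom,params Geometry and tissue parameters (the multiplier is
#'   applied on top of `params`).
#' @param duration Maximum simulated duration, ms.
#' @param cell_a,cell_b Measurement cells.
#' @param threshold Activation threshold, mV.
#' @param ... Passed to [simulate_knm()].
#' @return Conduction velocity in cm/s (or an error of class
#'   `knm_no_propagation` if the wave never arrives).
#' @export
strand_cv <- function(rg_multiplier = 1, dt = 0.01, n_cells = 15,
                      model = mitchell_schaeffer(), model_type = c("knm", "bd"),
                      dx = NULL, geom = cell_geometry(), params = tissue_params(),
                      duration = 400, cell_a = 3, cell_b = 13,
                      threshold = -20, ...) {
  model_type <- match.arg(model_type)
  params$rg_multiplier <- rg_multiplier
  net <- if (model_type == "knm") build_grid_network(n_cells, 1, geom, params)
         else bd_grid(n_cells, 1, dx = dx, geom = geom, params = params)
  tr <- simulate_knm(net, model, s1_protocol(net), dt = dt, duration = duration,
                     cadence = Inf, threshold = threshold,
                     record_snapshots = FALSE,
                     stop_after = c(cell_center_node(net, cell_a),
                                    cell_center_node(net, cell_b)), ...)
  conduction_velocity(tr, cell_a, cell_b, threshold)
}

#' Temporal convergence study of strand conduction velocity
#'
#' Recomputes the strand conduction velocity at a list of time steps and
#' reports, per gap-junction resistance multiplier, the percent difference
#' to the finest time step. Settings where the wave fails to propagate are
#' recorded with status `"block"` rather than raising an error.
#'
#' @param dts Time steps to evaluate, ms (coarse set).
#' @param rg_multipliers Gap-junction resistance multipliers.
#' @param dt_ref Reference (finest) time step, ms.
#' @param ... Passed to [strand_cv()] (`n_cells`, `model`, `model_type`, ...).
#' @return A data frame with columns `rg_multiplier`, `dt_ms`, `cv_cm_s`,
#'   `pct_diff_vs_finest`, `status`.
#' @export
convergence_study <- function(dts = c(0.1, 0.05, 0.02, 0.01, 0.005),
                              rg_multipliers = c(1, 50, 500),
                              dt_ref = 0.001, ...) {
  rows <- list()
  for (m in rg_multipliers) {
    cv_of <- function(dt) tryCatch(strand_cv(rg_multiplier = m, dt = dt, ...),
                                   knm_no_propagation = function(e) NA_real_)
    cv_ref <- cv_of(dt_ref)
    for (dt in sort(unique(c(dts, dt_ref)), decreasing = TRUE)) {
      cv <- if (dt == dt_ref) cv_ref else cv_of(dt)
      rows[[length(rows) + 1L]] <- data.frame(
        rg_multiplier = m, dt_ms = dt, cv_cm_s = cv,
        pct_diff_vs_finest =
          if (is.na(cv) || is.na(cv_ref)) NA_real_
          else 100 * abs(cv - cv_ref) / cv_ref,
        status = if (is.na(cv)) "block" else "ok")
    }
  }
  do.call(rbind, rows)
}

#' Conduction velocity versus gap-junction resistance
#'
#' Sweeps the gap-junction resistance multiplier on the 1D strand for the
#' cell network and/or the bidomain grid.
#'
#' @param multipliers Resistance multipliers to sweep.
#' @param models Which solvers to run.
#' @param dx_bd Bidomain grid spacing, um.
#' @param ... Passed to [strand_cv()].
#' @return A data frame with columns `model`, `rg_multiplier`, `cv_cm_s`.
#' @export
cv_rg_sweep <- function(multipliers = c(1, 10, 50, 100, 500),
                        models = c("knm", "bd"), dx_bd = 10, ...) {
  rows <- list()
  for (mod in models) for (m in multipliers) {
    cv <- tryCatch(
      strand_cv(rg_multiplier = m, model_type = mod,
                dx = if (mod == "bd") dx_bd else NULL, ...),
      knm_no_propagation = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(model = mod, rg_multiplier = m,
                                            cv_cm_s = cv)
  }
  do.call(rbind, rows)
}

#' S1-S2 reentry experiment on a 2D sheet
#'
#' Runs the S1-S2 protocol on a 2D tissue for each candidate S2 delay and
#' classifies the outcome with [detect_reentry()]. The delay set defaults to
#' a small sweep around 240 ms, since the vulnerable window depends on the
#' membrane model.
#'
#' @param model_type `"knm"` or `"bd"`.
#' @param rg_multiplier Gap-junction resistance multiplier (default 500,
#'   severely reduced coupling).
#' @param delays Candidate S2 delays, ms.
#' @param nx,ny Tissue extent in cells.
#' @param dt Time step, ms.
#' @param dx_bd,dy_bd Bidomain grid spacings, um.
#' @param model A [membrane_model()].
#' @param guard,window Reentry-detection windows, ms (see [detect_reentry()]).
#' @param margin Extra simulated time beyond `delay + window`, ms.
#' @param geom,params Geometry and tissue parameters.
#' @param ... Passed to [simulate_knm()].
#' @return A data frame with one row per delay: `model`, `s2_delay`,
#'   `reentrant`, `n_reactivated`, `max_reactivations`, `last_active`.
#' @export
reentry_experiment <- function(model_type = c("knm", "bd"),
                               rg_multiplier = 500,
                               delays = c(240, 200, 220, 260, 280),
                               nx = 20, ny = 20, dt = 0.02,
                               dx_bd = 20, dy_bd = NULL,
                               model = mitchell_schaeffer(),
                               guard = 50, window = 300, margin = 50,
                               geom = cell_geometry(), params = tissue_params(),
                               ...) {
  model_type <- match.arg(model_type)
  params$rg_multiplier <- rg_multiplier
  if (is.null(dy_bd)) dy_bd <- dx_bd
  net <- if (model_type == "knm") build_grid_network(nx, ny, geom, params)
         else bd_grid(nx, ny, dx = dx_bd, dy = dy_bd, geom = geom, params = params)
  rows <- list()
  for (d in delays) {
    tr <- simulate_knm(net, model, s1_s2_protocol(net, s2_delay = d),
                       dt = dt, duration = d + window + margin,
                       cadence = Inf, record_snapshots = FALSE, ...)
    res <- detect_reentry(tr, t_s2 = d, guard = guard, window = window)
    rows[[length(rows) + 1L]] <- data.frame(
      model = model_type, s2_delay = d, reentrant = res$reentrant,
      n_reactivated = res$evidence$n_reactivated,
      max_reactivations = res$evidence$max_reactivations,
      last_active = res$evidence$last_active)
  }
  do.call(rbind, rows)
}
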