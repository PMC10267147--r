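#' Assemble a synthetic trace from prescribed activation times
#'
#' Builds a minimal `knm_trace` from analytically placed activation times,
#' with no simulation involved. Used to exercise the analysis operations
#' ([conduction_velocity()], [detect_reentry()]) against known ground truth,
#' and as deterministic test fixtures.
#'
#' @param activations List of numeric activation-time vectors, one per node (ms).
#' @param positions Node-center matrix (um), one row per node.
#' @param duration Nominal trace duration, ms.
#' @param threshold Activation threshold the times refer to, mV.
#' @param last_active Last time any node was above threshold; defaults to the
#'   latest activation.
#' @return A `knm_trace` (synthetic: no snapshots, no solver diagnostics).
#' @export
synthetic_trace <- function(activations, positions, duration,
                            threshold = -20, last_active = NULL) {
  activations <- lapply(activations, sort)
  acts <- unlist(activations)
  if (is.null(last_active))
    last_active <- if (length(acts)) max(acts) else -Inf
  structure(
    list(times = c(0, duration), v = NULL, u_e = NULL,
         activations = activations, threshold = threshold,
         max_residual = 0, residual_bound = 0,
         last_active = last_active, dt = NA_real_,
         final_state = NULL,
         net = list(kind = "synthetic", n_nodes = nrow(positions),
                    pos = positions),
         config = list(synthetic = TRUE)),
    class = "knm_trace")
}

#' Synthetic planar-wave trace on a 1D strand
#'
#' Activation times placed analytically for a rightward planar wave of
#' exactly `cv` cm/s over a strand of cell centers spaced one cell length
#' apart; [conduction_velocity()] recovers `cv` exactly.
#'
#' @param n_cells Strand length in cells.
#' @param cv Wave speed, cm/s.
#' @param geom A [cell_geometry()] giving the cell spacing.
#' @param t0 Activation time of the first cell, ms.
#' @return A synthetic `knm_trace`.
#' @export
planar_wave_trace <- function(n_cells = 15, cv = 50, geom = cell_geometry(),
                              t0 = 1) {
  check_positive(cv = cv)
  x <- (seq_len(n_cells) - 0.5) * geom$length
  # t = t0 + distance / v;  um / (cm/s) = 0.1 um/(um/ms)
  times <- t0 + 0.1 * (x - x[1]) / cv
  synthetic_trace(as.list(times), cbind(x = x, y = 0.5 * geom$l_y),
                  duration = max(times) + 1)
}

#' Synthetic rotating-wave (reentry) trace on a 2D sheet
#'
#' Activation times assigned by a rotating phase map about the sheet center:
#' each node activates once per rotation period for `n_turns` turns starting
#' at `t_start`. A canonical positive fixture for [detect_reentry()].
#'
#' @param nx,ny Sheet extent in nodes.
#' @param period Rotation period, ms.
#' @param n_turns Number of completed rotations.
#' @param t_start First-activation reference time, ms.
#' @param geom A [cell_geometry()] giving node spacings.
#' @return A synthetic `knm_trace`.
#' @export
rotating_wave_trace <- function(nx = 20, ny = 20, period = 120, n_turns = 3,
                                t_start = 250, geom = cell_geometry()) {
  check_positive(period = period)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  pos <- cbind(x = (ix - 0.5) * geom$length, y = (iy - 0.5) * geom$l_y)
  phase <- atan2(iy - (ny + 1) / 2, ix - (nx + 1) / 2)   # (-pi, pi]
  first <- t_start + (phase + pi) / (2 * pi) * period
  acts <- lapply(first, function(t0) t0 + period * (seq_len(n_turns) - 1))
  synthetic_trace(acts, pos, duration = t_start + period * n_turns + 1)
}

#' Write deterministic analysis fixtures
#'
#' Writes plain-text fixtures to `dir`: the two-node passive network with
#' its matrix-exponential reference trajectory (CSV), the planar-wave
#' activation table (CSV), the rotating-wave activation table (CSV), and a
#' JSON manifest with the construction parameters. All outputs are
#' bit-identical across runs (fully deterministic, no randomness).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
generate_fixtures <- function(dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # 1) two-node passive strand: exact linear-DAE trajectory by matrix exponential
  net <- build_grid_network(2, 1)
  model <- passive_membrane()
  ref <- passive_reference_trajectory(net, model, v0 = c(-60, -80),
                                      times = seq(0, 2, by = 0.05))
  utils::write.csv(ref, file.path(dir, "passive_two_node_reference.csv"),
                   row.names = FALSE)

  # 2) planar wave at exactly 50 cm/s
  pw <- planar_wave_trace(15, cv = 50)
  utils::write.csv(
    data.frame(cell = seq_along(pw$activations),
               x_um = pw$net$pos[, 1],
               t_activation_ms = vapply(pw$activations, `[`, numeric(1), 1)),
    file.path(dir, "planar_wave_activations.csv"), row.names = FALSE)

  # 3) rotating-wave reentry fixture
  rw <- rotating_wave_trace(20, 20, period = 120, n_turns = 3, t_start = 250)
  utils::write.csv(
    data.frame(node = rep(seq_along(rw$activations), lengths(rw$activations)),
               t_activation_ms = unlist(rw$activations)),
    file.path(dir, "rotating_wave_activations.csv"), row.names = FALSE)

  manifest <- list(
    version = "1",
    passive_two_node = list(model = "passive", g_L = 0.1, E_L = -80,
                            v0 = c(-60, -80), dt_out = 0.05, t_end = 2),
    planar_wave = list(n_cells = 15, cv_cm_s = 50, t0_ms = 1),
    rotating_wave = list(nx = 20, ny = 20, period_ms = 120, n_turns = 3,
                         t_start_ms = 250),
    deterministic = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "fixtures_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Exact trajectory of a passive-membrane network
#'
#' For a passive (linear) membrane the whole coupled system is a linear
#' differential-algebraic system; eliminating the extracellular potentials
#' through the Kirchhoff constraint leaves a linear ODE in v, solved here in
#' closed form with the matrix exponential. This is an independent reference
#' for the operator-splitting integrator, not part of the solver itself.
#'
#' @param net A `knm_network`.
#' @param model A [passive_membrane()].
#' @param v0 Initial membrane potentials, mV (scalar or per node).
#' @param times Output times, ms.
#' @return A data frame: `t`, then `v1..vN`, then `ue1..ueN`.
#' @export
passive_reference_trajectory <- function(net, model, v0, times) {
  if (!identical(model$name, "passive"))
    stop("reference trajectory is defined for the passive model", call. = FALSE)
  n <- net$n_nodes
  lap <- network_laplacians(net)
  Li <- as.matrix(lap$L_i)
  Lie <- as.matrix(lap$L_i + lap$L_e)
  free <- !net$boundary
  if (!any(net$boundary)) stop("network has no grounded node", call. = FALSE)
  # constraint: Li v + Lie ue = 0 on free nodes, ue = 0 on grounded ones
  recover_ue <- function(v) {
    ue <- rep(0, n)
    if (any(free))
      ue[free] <- solve(Lie[free, free, drop = FALSE],
                        -(Li %*% v)[free])
    ue
  }
  # C_m A_m dv/dt = -[Li (v + ue)] - A_m g_L (v - E_L); ue = S v (linear)
  S <- matrix(0, n, n)
  for (k in seq_len(n)) S[, k] <- recover_ue(as.numeric(seq_len(n) == k))
  CmAm <- net$params$C_m * net$A_m
  g_L <- model$pars$g_L; E_L <- model$pars$E_L
  A <- -(Li %*% (diag(n) + S)) / CmAm - diag(g_L / net$params$C_m, n)
  b <- rep(g_L * E_L / net$params$C_m, n)
  v_inf <- solve(A, -b)
  v0 <- rep_len(v0, n)
  out <- matrix(NA_real_, length(times), 2 * n)
  for (i in seq_along(times)) {
    E <- as.matrix(Matrix::expm(A * times[i]))
    v <- as.numeric(v_inf + E %*% (v0 - v_inf))
    out[i, ] <- c(v, recover_ue(v))
  }
  out <- data.frame(t = times, out)
  names(out) <- c("t", paste0("v", seq_len(n)), paste0("ue", seq_len(n)))
  out
}
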