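#' Simulation state
#'
#' Snapshot of the coupled system at one time point: membrane potential `v`
#' and extracellular potential `u_e` per node (mV) and the membrane state
#' matrix `s` (nodes x state variables). The intracellular potential is the
#' derived quantity `u_i = v + u_e`.
#'
#' @param t Time, ms.
#' @param v,u_e Numeric vectors, one entry per node, mV.
#' @param s Membrane state matrix (nodes x state variables).
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(t, v, u_e, s) {
  stopifnot(length(v) == length(u_e))
  structure(list(t = t, v = v, u_e = u_e, s = s), class = "sim_state")
}

initial_state <- function(net, model, v0 = NULL, s0 = NULL) {
  n <- net$n_nodes
  v <- if (is.null(v0)) rep(model$v_rest, n) else rep_len(v0, n)
  s <- if (is.null(s0)) rest_state(model, n) else s0
  sim_state(0, v, rep(0, n), s)
}

#' Per-edge intracellular and extracellular currents
#'
#' For every stored edge (j, k) returns the intracellular current
#' `I_i = G_i * (u_i_j - u_i_k)` (with `u_i = v + u_e`) and the extracellular
#' current `I_e = G_e * (u_e_j - u_e_k)`, both in uA and positive when flowing
#' from j to k; the currents on the reversed edge are their negatives.
#'
#' @param state A [sim_state()].
#' @param net A `knm_network`.
#' @return A data frame with columns `from`, `to`, `I_i`, `I_e` (uA).
#' @export
edge_currents <- function(state, net) {
  if (length(state$v) != net$n_nodes)
    stop("state and network dimensions differ", call. = FALSE)
  if (is.null(net$edges) || nrow(net$edges) == 0)
    return(data.frame(from = integer(0), to = integer(0),
                      I_i = numeric(0), I_e = numeric(0)))
  a <- net$edges[, 1]; b <- net$edges[, 2]
  ui <- state$v + state$u_e
  data.frame(from = a, to = b,
             I_i = net$G_i * (ui[a] - ui[b]),
             I_e = net$G_e * (state$u_e[a] - state$u_e[b]))
}

#' Kirchhoff current-law residual
#'
#' Net current imbalance per node: the sum over neighbors of the
#' intracellular plus extracellular edge currents into each node (uA). After
#' a converged linear substep this is zero to solver tolerance at every
#' non-grounded node; at grounded (Dirichlet) boundary nodes the imbalance is
#' the current drained to ground. Diagnostic only.
#'
#' @param state A [sim_state()].
#' @param net A `knm_network`.
#' @return Numeric vector of residuals (uA) with attribute `boundary`, the
#'   logical grounded-node mask.
#' @export
kirchhoff_residual <- function(state, net) {
  lap <- network_laplacians(net)
  r <- -as.numeric(lap$L_i %*% (state$v + state$u_e) + lap$L_e %*% state$u_e)
  attr(r, "boundary") <- net$boundary
  r
}

#' Assemble the implicit network system
#'
#' Builds the backward-Euler operator for the linear substep of the
#' operator-splitting scheme. With the ionic term removed by splitting, one
#' implicit step solves, for the stacked unknowns (v, u_e) at the new time,
#'
#' \deqn{C_m A_m (v' - v*) / dt = -L_i (v' + u_e'),}
#' \deqn{0 = L_i v' + (L_i + L_e) u_e',}
#'
#' where `L_i`, `L_e` are the conductance-weighted graph Laplacians (mS), the
#' second line is Kirchhoff's current law for the extracellular compartments,
#' and `u_e' = 0` is imposed at grounded boundary nodes. After symmetric
#' elimination of the grounded rows and columns the operator is symmetric
#' positive definite and is Cholesky-factorized once; every step then reuses
#' the factorization. No-flux (Neumann) conditions on the intracellular side
#' are natural: no network edges leave the tissue.
#'
#' @param net A `knm_network`.
#' @param dt Time step, ms.
#' @param C_m Specific membrane capacitance, uF/cm^2. Defaults to the
#'   network's tissue parameters.
#' @param solver_tol Relative tolerance contract for the linear solve; the
#'   direct factorization used here achieves residuals far below it, and
#'   simulations verify the Kirchhoff residual against `10 * solver_tol`
#'   times the system's current scale.
#' @return An object of class `knm_system`.
#' @export
assemble_system <- function(net, dt, C_m = net$params$C_m, solver_tol = 1e-10) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  check_positive(C_m = C_m, solver_tol = solver_tol)
  if (!any(net$boundary))
    stop(paste("network has no grounded boundary node: the extracellular",
               "potential is determined only up to a constant and the system",
               "is singular"), call. = FALSE)
  n <- net$n_nodes
  lap <- network_laplacians(net)
  D <- C_m * net$A_m / dt                       # uF/ms = mS
  K <- rbind(cbind(Matrix::Diagonal(n, D) + lap$L_i, lap$L_i),
             cbind(lap$L_i, lap$L_i + lap$L_e))
  dir <- n + which(net$boundary)                # grounded u_e unknowns
  # symmetric elimination: u_e = 0 there, so zero rows/columns, unit diagonal
  keep <- rep(1, 2 * n); keep[dir] <- 0
  P <- Matrix::Diagonal(2 * n, keep)
  unit <- rep(0, 2 * n); unit[dir] <- 1
  K <- Matrix::forceSymmetric(P %*% K %*% P + Matrix::Diagonal(2 * n, unit))

  dense <- 2 * n <= 1200
  factor <- if (dense) chol(as.matrix(K)) else Matrix::Cholesky(K, LDL = FALSE)
  L_ie <- lap$L_i + lap$L_e
  structure(
    list(n = n, dt = dt, C_m = C_m, D = D, dir = dir,
         L_i = if (dense) as.matrix(lap$L_i) else as(lap$L_i, "generalMatrix"),
         L_ie = if (dense) as.matrix(L_ie) else as(L_ie, "generalMatrix"),
         dense = dense, factor = factor, K = K,
         solver_tol = solver_tol, boundary = net$boundary),
    class = "knm_system")
}

solve_system <- function(sys, b) {
  if (sys$dense)
    backsolve(sys$factor, backsolve(sys$factor, b, transpose = TRUE))
  else
    as.numeric(Matrix::solve(sys$factor, b))
}

#' Advance the coupled system by one operator-splitting step
#'
#' First-order (Godunov) splitting: (1) an explicit ionic substep per node --
#' Rush-Larsen update of the gates, forward Euler on non-gate states and on
#' `dv/dt = -(I_ion + I_stim) / C_m` with the network frozen; (2) the
#' implicit backward-Euler solve of the coupled linear (v, u_e) network
#' system from [assemble_system()]. The stimulus is evaluated at the midpoint
#' of the step interval, so a stimulus window [t_on, t_on + dur) is applied
#' on exactly those steps whose midpoints it contains, for any dt.
#'
#' @param state A [sim_state()].
#' @param sys A `knm_system` from [assemble_system()].
#' @param model A [membrane_model()].
#' @param stim `NULL`, or `function(t)` returning the applied membrane
#'   current density per node (uA/cm^2; negative = inward/depolarizing).
#' @param dt Time step, ms; must equal the step the system was assembled with.
#' @return The advanced [sim_state()].
#' @export
step_knm <- function(state, sys, model, stim = NULL, dt = sys$dt) {
  if (abs(dt - sys$dt) > 1e-12 * sys$dt)
    stop("dt differs from the assembled system's dt; reassemble", call. = FALSE)
  n <- sys$n
  I <- ionic_current(model, state$v, state$s)
  if (!is.null(stim)) I <- I + stim(state$t + dt / 2)
  v_star <- state$v - dt * I / sys$C_m
  s_new <- if (model$n_state > 0) rush_larsen_step(model, state$v, state$s, dt)
           else state$s
  b <- c(sys$D * v_star, rep(0, n))
  b[sys$dir] <- 0
  x <- solve_system(sys, b)
  sim_state(state$t + dt, x[seq_len(n)], x[n + seq_len(n)], s_new)
}

#' Run a tissue simulation
#'
#' Drives [step_knm()] from the resting initial condition (or a supplied
#' one), recording snapshots of `v` and `u_e` at the requested cadence,
#' per-node activation times (every upward crossing of `threshold`, detected
#' at full time-step resolution regardless of the snapshot cadence), the
#' running maximum of the Kirchhoff residual, and the last time any node was
#' at or above threshold.
#'
#' @param net A `knm_network` (from [build_grid_network()] or [bd_grid()]).
#' @param model A [membrane_model()].
#' @param protocol A [stimulus_protocol()], e.g. [s1_protocol()]; `NULL` for
#'   an unstimulated run.
#' @param dt Time step, ms.
#' @param duration Simulated duration, ms (rounded to a whole number of steps).
#' @param cadence Snapshot cadence, ms; `Inf` records only the initial and
#'   final states.
#' @param threshold Activation threshold, mV (upward crossings are recorded).
#' @param solver_tol Linear-solver tolerance contract, see [assemble_system()].
#' @param v0,s0 Optional initial membrane potential (scalar or per node) and
#'   state matrix; default rest.
#' @param record_snapshots Keep `v`/`u_e` snapshot matrices (set `FALSE` to
#'   save memory on long runs; activations are always recorded).
#' @param record_residual Track the Kirchhoff residual maximum each step.
#' @param stop_after Optional node indices: stop early once every one of
#'   them has activated at least once.
#' @return An object of class `knm_trace`: `times`, matrices `v` and `u_e`
#'   (snapshots x nodes), `activations` (list of crossing times per node),
#'   `threshold`, `max_residual` (uA), `residual_bound` (uA), `last_active`
#'   (ms), `final_state`, `net`, and a `config` echo.
#' @export
simulate_knm <- function(net, model = mitchell_schaeffer(),
                         protocol = NULL,
                         dt = 0.01, duration = 50, cadence = 1,
                         threshold = -20, solver_tol = 1e-10,
                         v0 = NULL, s0 = NULL,
                         record_snapshots = TRUE, record_residual = TRUE,
                         stop_after = NULL) {
  if (duration < 0) stop("duration must be non-negative", call. = FALSE)
  n <- net$n_nodes
  n_steps <- round(duration / dt)
  if (n_steps > 0) sys <- assemble_system(net, dt, solver_tol = solver_tol)
  stim <- if (is.null(protocol)) NULL else make_stimulus(protocol, net)
  state <- initial_state(net, model, v0, s0)

  snap_every <- if (!is.finite(cadence)) n_steps + 1L else max(1L, round(cadence / dt))
  n_snap_max <- if (n_steps == 0) 1L else floor(n_steps / snap_every) + 2L
  times <- numeric(n_snap_max)
  vs <- if (record_snapshots) matrix(NA_real_, n_snap_max, n) else NULL
  ues <- if (record_snapshots) matrix(NA_real_, n_snap_max, n) else NULL
  take <- function(k, st) {
    times[k] <<- st$t
    if (record_snapshots) { vs[k, ] <<- st$v; ues[k, ] <<- st$u_e }
  }
  take(1L, state)
  n_snap <- 1L

  activations <- vector("list", n)
  above <- state$v >= threshold
  last_active <- if (any(above)) 0 else -Inf
  max_res <- 0
  interior <- !net$boundary
  # residual scale: conductance scale x potential scale (100 mV), in uA
  res_scale <- if (is.null(net$edges) || nrow(net$edges) == 0) 1
               else 100 * max(net$G_i + net$G_e)

  step_i <- 0L
  while (step_i < n_steps) {
    step_i <- step_i + 1L
    state <- step_knm(state, sys, model, stim)
    if (record_residual && any(interior)) {
      r <- abs(as.numeric(sys$L_i %*% state$v + sys$L_ie %*% state$u_e))
      m <- max(r[interior])
      if (m > max_res) max_res <- m
    }
    now_above <- state$v >= threshold
    crossed <- now_above & !above
    if (any(crossed)) {
      for (k in which(crossed))
        activations[[k]] <- c(activations[[k]], state$t)
    }
    if (any(now_above)) last_active <- state$t
    above <- now_above
    if (step_i %% snap_every == 0L) {
      n_snap <- n_snap + 1L
      take(n_snap, state)
    }
    if (!is.null(stop_after) &&
        all(lengths(activations[stop_after]) > 0)) break
  }
  if (times[n_snap] < state$t - 1e-12) {   # ensure the final state is recorded
    n_snap <- n_snap + 1L
    take(n_snap, state)
  }

  structure(
    list(times = times[seq_len(n_snap)],
         v = if (record_snapshots) vs[seq_len(n_snap), , drop = FALSE] else NULL,
         u_e = if (record_snapshots) ues[seq_len(n_snap), , drop = FALSE] else NULL,
         activations = activations, threshold = threshold,
         max_residual = max_res,
         residual_bound = 10 * solver_tol * res_scale,
         last_active = last_active,
         n_steps_run = step_i, dt = dt,
         final_state = state, net = net,
         config = list(model = model$name, model_pars = model$pars,
                       dt = dt, duration = duration, cadence = cadence,
                       threshold = threshold, solver_tol = solver_tol,
                       protocol = if (is.null(protocol)) NULL
                                  else unclass(protocol))),
    class = "knm_trace")
}

#' @export
print.knm_trace <- function(x, ...) {
  n_act <- sum(lengths(x$activations) > 0)
  cat(sprintf(paste0(
    "<knm_trace> %d nodes, %d snapshots over %g ms (dt = %g ms)\n",
    "  %d node(s) activated (threshold %g mV); max Kirchhoff residual %.3g uA\n"),
    x$net$n_nodes, length(x$times), max(x$times), x$dt,
    n_act, x$threshold, x$max_residual))
  invisible(x)
}
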