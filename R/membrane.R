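#' Membrane model interface
#'
#' A membrane model supplies the transmembrane ionic current density
#' `I_ion(v, s)` (uA/cm^2, positive outward) and the dynamics of its state
#' variables. State variables are partitioned into *gates*, which obey
#' `ds/dt = (s_inf(v) - s) / tau(v)` and are advanced exactly for frozen
#' voltage by the Rush-Larsen exponential update, and *non-gates*, advanced
#' by forward Euler on `F(s, v)`.
#'
#' All functions are vectorized over nodes: `v` is a numeric vector and `s` a
#' matrix with one row per node and one column per state variable.
#'
#' @param name Model name.
#' @param v_rest Resting membrane potential, mV.
#' @param s_rest Resting state vector (length = number of state variables).
#' @param is_gate Logical vector marking which state variables are gates.
#' @param I_ion `function(v, s)` returning uA/cm^2 per node.
#' @param gate_inf `function(v)` returning a matrix (nodes x gates) of
#'   steady-state gate values, or `NULL` if the model has no gates.
#' @param gate_tau `function(v)` returning a matrix (nodes x gates) of gate
#'   time constants in ms, or `NULL`.
#' @param F_nongate `function(v, s)` returning a matrix (nodes x non-gates)
#'   of time derivatives, or `NULL` if the model has no non-gate states.
#' @param pars Named list of model parameters (kept for reporting).
#' @return An object of class `membrane_model`.
#' @seealso [passive_membrane()], [mitchell_schaeffer()], [rush_larsen_step()]
#' @export
membrane_model <- function(name, v_rest, s_rest, is_gate, I_ion,
                           gate_inf = NULL, gate_tau = NULL,
                           F_nongate = NULL, pars = list()) {
  stopifnot(is.function(I_ion), length(s_rest) == length(is_gate))
  if (any(is_gate) && (is.null(gate_inf) || is.null(gate_tau)))
    stop("models with gates must supply gate_inf and gate_tau", call. = FALSE)
  if (any(!is_gate) && is.null(F_nongate))
    stop("models with non-gate states must supply F_nongate", call. = FALSE)
  structure(
    list(name = name, v_rest = v_rest, s_rest = s_rest,
         n_state = length(s_rest), is_gate = is_gate,
         I_ion = I_ion, gate_inf = gate_inf, gate_tau = gate_tau,
         F_nongate = F_nongate, pars = pars),
    class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model> %s: %d state variable(s) (%d gate), v_rest = %g mV\n",
              x$name, x$n_state, sum(x$is_gate), x$v_rest))
  invisible(x)
}

#' Resting state matrix for a set of nodes
#' @keywords internal
rest_state <- function(model, n) {
  matrix(rep(model$s_rest, each = n), nrow = n, ncol = model$n_state)
}

#' Ionic current density
#'
#' Evaluates the model's transmembrane current density. Positive values are
#' outward currents (flow of positive ions out of the cell); depolarizing
#' currents are negative.
#'
#' @param model A [membrane_model()].
#' @param v Membrane potential(s), mV.
#' @param s State matrix (nodes x state variables), or a vector for one node.
#' @return Current density in uA/cm^2, one value per node.
#' @export
ionic_current <- function(model, v, s = NULL) {
  if (model$n_state > 0) {
    if (is.null(s)) stop("model requires a state argument", call. = FALSE)
    if (!is.matrix(s)) s <- matrix(s, nrow = length(v))
    if (ncol(s) != model$n_state)
      stop("state has wrong dimension for this model", call. = FALSE)
    if (any(!is.finite(s))) stop("non-finite state variable", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("non-finite membrane potential", call. = FALSE)
  as.numeric(model$I_ion(v, s))
}

#' Rush-Larsen / forward-Euler state update
#'
#' Advances the membrane state over one step of `dt` ms with the voltage
#' frozen: gate variables by the exponential closed form
#' `s' = s_inf + (s - s_inf) * exp(-dt / tau)` (exact for constant `v`, and
#' unconditionally keeping gates inside \[0, 1\]), non-gate variables by
#' forward Euler.
#'
#' @param model A [membrane_model()].
#' @param v Membrane potential(s), mV.
#' @param s State matrix (nodes x state variables).
#' @param dt Time step, ms.
#' @return Updated state matrix.
#' @export
rush_larsen_step <- function(model, v, s, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (model$n_state == 0) return(s)
  if (!is.matrix(s)) s <- matrix(s, nrow = length(v))
  g <- model$is_gate
  if (any(g)) {
    inf <- model$gate_inf(v)
    tau <- model$gate_tau(v)
    s[, g] <- inf + (s[, g, drop = FALSE] - inf) * exp(-dt / tau)
  }
  if (any(!g))
    s[, !g] <- s[, !g, drop = FALSE] + dt * model$F_nongate(v, s)
  s
}

#' Passive (leak) membrane model
#'
#' A linear, stateless membrane: `I_ion = g_L * (v - E_L)`. Its resting
#' potential is the leak reversal `E_L`, at which the current is exactly
#' zero. Used for analytically tractable reference problems, where the whole
#' tissue system becomes linear.
#'
#' @param g_L Leak conductance density, mS/cm^2.
#' @param E_L Leak reversal potential, mV.
#' @return A [membrane_model()].
#' @export
passive_membrane <- function(g_L = 0.1, E_L = -80) {
  check_positive(g_L = g_L)
  membrane_model(
    name = "passive", v_rest = E_L,
    s_rest = numeric(0), is_gate = logical(0),
    I_ion = function(v, s) g_L * (v - E_L),
    pars = list(g_L = g_L, E_L = E_L))
}

#' Minimal excitable membrane model (Mitchell-Schaeffer type)
#'
#' A two-current phenomenological cardiac model rescaled to physiological
#' units. With the normalized voltage `u = (v - v_rest) / v_amp`, the inward
#' (depolarizing) current is `h * u^2 * (1 - u) / tau_in` and the outward
#' (repolarizing) current `u / tau_out`; the single recovery gate `h` opens
#' with time constant `tau_open` below the threshold `v_gate` and closes
#' with `tau_close` above it, so it has the Hodgkin-Huxley gate form required
#' by the Rush-Larsen update (piecewise-constant `s_inf` and `tau`).
#'
#' The rest state `(v_rest, h = 1)` is an exact equilibrium. A 40 uA/cm^2,
#' 2 ms stimulus from rest triggers a full action potential (upstroke to
#' about `v_rest + v_amp`). Defaults are tuned so that a strand or sheet of
#' cells coupled at 500 times the default gap-junction resistance still
#' conducts (slowly), and so that an S2 stimulus a little over 200 ms after
#' S1 falls into the vulnerable window of partially recovered tissue; see the
#' package vignette for the parameter discussion.
#'
#' @param tau_in,tau_out Activation / repolarization time scales, ms.
#' @param tau_open,tau_close Gate recovery / inactivation time scales, ms.
#' @param v_gate Normalized threshold (fraction of `v_amp` above rest).
#' @param v_rest Resting potential, mV.
#' @param v_amp Action-potential amplitude, mV.
#' @return A [membrane_model()].
#' @export
mitchell_schaeffer <- function(tau_in = 0.15, tau_out = 6,
                               tau_open = 120, tau_close = 78,
                               v_gate = 0.10, v_rest = -80, v_amp = 100) {
  check_positive(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate, v_amp = v_amp)
  pars <- list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
               tau_close = tau_close, v_gate = v_gate,
               v_rest = v_rest, v_amp = v_amp)
  membrane_model(
    name = "mitchell_schaeffer",
    v_rest = v_rest, s_rest = 1, is_gate = TRUE,
    I_ion = function(v, s) {
      u <- (v - v_rest) / v_amp
      h <- s[, 1]
      # I_ion = -C dv/dt contribution, positive outward, assuming C_m = 1 uF/cm^2
      -v_amp * (h * u^2 * (1 - u) / tau_in - u / tau_out)
    },
    gate_inf = function(v) {
      u <- (v - v_rest) / v_amp
      matrix(as.numeric(u < v_gate), ncol = 1)
    },
    gate_tau = function(v) {
      u <- (v - v_rest) / v_amp
      matrix(ifelse(u < v_gate, tau_open, tau_close), ncol = 1)
    },
    pars = pars)
}

#' Look up a shipped membrane model by name
#'
#' @param name `"mitchell_schaeffer"` (alias `"ms"`, `"excitable"`) or
#'   `"passive"`.
#' @param overrides Named list of parameter overrides passed to the model
#'   constructor.
#' @return A [membrane_model()].
#' @export
get_membrane_model <- function(name, overrides = list()) {
  ctor <- switch(name,
    mitchell_schaeffer = , ms = , excitable = mitchell_schaeffer,
    passive = passive_membrane,
    stop(sprintf("unknown membrane model '%s'", name), call. = FALSE))
  bad <- setdiff(names(overrides), names(formals(ctor)))
  if (length(bad))
    stop("unknown membrane parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(ctor, overrides)
}
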