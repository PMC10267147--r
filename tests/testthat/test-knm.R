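# a stateless model with zero ionic current isolates the network substep
null_model <- function() {
  membrane_model(name = "null", v_rest = 0, s_rest = numeric(0),
                 is_gate = logical(0), I_ion = function(v, s) 0 * v)
}

test_that("edge currents follow the potential differences", {
  net <- build_grid_network(2, 1)
  net$G_i[] <- 2; net$G_e[] <- 2
  st <- sim_state(0, v = c(0, 0), u_e = c(1, 0), s = matrix(0, 2, 0))
  ec <- edge_currents(st, net)
  expect_equal(ec$I_i, 2)   # u_i = v + u_e = (1, 0)
  expect_equal(ec$I_e, 2)
  # uniform potentials carry no current
  st0 <- sim_state(0, v = c(3, 3), u_e = c(-2, -2), s = matrix(0, 2, 0))
  expect_equal(unlist(edge_currents(st0, net)[c("I_i", "I_e")]),
               c(I_i = 0, I_e = 0))
  # antisymmetry: reversing the potential pattern flips the sign
  st_r <- sim_state(0, v = c(0, 0), u_e = c(0, 1), s = matrix(0, 2, 0))
  expect_equal(edge_currents(st_r, net)$I_i, -ec$I_i)
})

test_that("Kirchhoff residual equals a dense graph-Laplacian product", {
  net <- build_grid_network(5, 1)
  set.seed(42)
  st <- sim_state(0, v = rnorm(5), u_e = rnorm(5), s = matrix(0, 5, 0))
  r <- kirchhoff_residual(st, net)
  # independent dense assembly from the edge list
  L <- function(w) {
    M <- matrix(0, 5, 5)
    for (e in seq_len(nrow(net$edges))) {
      a <- net$edges[e, 1]; b <- net$edges[e, 2]
      M[a, b] <- M[a, b] - w[e]; M[b, a] <- M[b, a] - w[e]
      M[a, a] <- M[a, a] + w[e]; M[b, b] <- M[b, b] + w[e]
    }
    M
  }
  expect_equal(as.numeric(r),
               as.numeric(-(L(net$G_i) %*% (st$v + st$u_e) + L(net$G_e) %*% st$u_e)),
               tolerance = 1e-12)
  # uniform potentials: exactly zero
  st0 <- sim_state(0, v = rep(1, 5), u_e = rep(2, 5), s = matrix(0, 5, 0))
  expect_equal(max(abs(kirchhoff_residual(st0, net))), 0)
})

test_that("assembly requires a grounded node and handles isolated cells", {
  net <- build_grid_network(3, 1)
  net$boundary[] <- FALSE
  expect_error(assemble_system(net, 0.01), "grounded")
  expect_error(assemble_system(build_grid_network(3, 1), -0.01), "positive")

  single <- build_grid_network(1, 1)
  sys <- assemble_system(single, 0.01)
  st <- sim_state(0, v = -37, u_e = 0, s = matrix(0, 1, 0))
  st1 <- step_knm(st, sys, null_model())
  expect_equal(st1$v, -37, tolerance = 1e-12)   # linear substep is the identity
  expect_equal(st1$u_e, 0)
})

test_that("the linear substep tends to the identity as dt -> 0", {
  net <- build_grid_network(4, 1)
  st <- sim_state(0, v = c(-80, -20, -60, -80), u_e = rep(0, 4),
                  s = matrix(0, 4, 0))
  dev <- vapply(c(1e-2, 1e-4, 1e-6), function(dt) {
    sys <- assemble_system(net, dt)
    max(abs(step_knm(st, sys, null_model())$v - st$v))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-3)
})

test_that("resting tissue is preserved exactly by the coupled step", {
  net <- build_grid_network(5, 1)
  tr <- simulate_knm(net, mitchell_schaeffer(), NULL, dt = 0.05, duration = 5)
  expect_lt(max(abs(tr$v - (-80))), 1e-9)
  expect_lt(max(abs(tr$u_e)), 1e-9)
})

test_that("a stimulated strand propagates with ordered activation times", {
  net <- build_grid_network(15, 1)
  tr <- simulate_knm(net, mitchell_schaeffer(), s1_protocol(net),
                     dt = 0.02, duration = 30)
  expect_true(all(lengths(tr$activations) == 1L))   # every cell fires once
  act <- vapply(tr$activations, `[`, numeric(1), 1)
  expect_true(all(diff(act) > 0))                   # rightward propagation
  expect_lte(tr$max_residual, tr$residual_bound)    # Kirchhoff conservation
})

test_that("deterministic reruns are bit-identical", {
  net <- build_grid_network(6, 1)
  run <- function() simulate_knm(net, mitchell_schaeffer(), s1_protocol(net),
                                 dt = 0.02, duration = 10)
  tr1 <- run(); tr2 <- run()
  expect_identical(tr1$v, tr2$v)
  expect_identical(tr1$activations, tr2$activations)
})

test_that("solutions respect the lattice reflection symmetries", {
  net <- build_grid_network(3, 3)
  stim <- stimulus_protocol(list(list(region = 5, amplitude = 40,
                                      onset = 0, duration = 2)))
  tr <- simulate_knm(net, mitchell_schaeffer(), stim, dt = 0.02, duration = 15,
                     cadence = 1)
  flip_x <- c(3, 2, 1, 6, 5, 4, 9, 8, 7)
  flip_y <- c(7, 8, 9, 4, 5, 6, 1, 2, 3)
  expect_lt(max(abs(tr$v - tr$v[, flip_x])), 1e-8)
  expect_lt(max(abs(tr$v - tr$v[, flip_y])), 1e-8)
})

test_that("middle-node current balance holds on a passive 3-cell strand", {
  net <- build_grid_network(3, 1)
  tr <- simulate_knm(net, passive_membrane(), NULL, dt = 0.01, duration = 1,
                     v0 = c(-60, -80, -80))
  st <- tr$final_state
  ec <- edge_currents(st, net)
  # Kirchhoff at the interior node: intracellular inflow returns extracellularly
  inflow_i <- ec$I_i[1] - ec$I_i[2]
  inflow_e <- ec$I_e[1] - ec$I_e[2]
  expect_lt(abs(inflow_i + inflow_e), tr$residual_bound)
})

test_that("passive trajectories match the matrix-exponential reference at first order", {
  net <- build_grid_network(3, 1)
  model <- passive_membrane()
  v0 <- c(-60, -75, -85)
  times <- seq(0, 2, by = 0.1)
  ref <- passive_reference_trajectory(net, model, v0, times)
  err <- vapply(c(0.02, 0.01, 0.005, 0.0025), function(dt) {
    tr <- simulate_knm(net, model, NULL, dt = dt, duration = 2, cadence = 0.1,
                       v0 = v0)
    max(abs(tr$v - as.matrix(ref[, c("v1", "v2", "v3")])))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  order <- coef(lm(log(err) ~ log(c(0.02, 0.01, 0.005, 0.0025))))[2]
  expect_gt(order, 0.8); expect_lt(order, 1.2)
})

test_that("the matrix-exponential reference itself agrees with a stiff ODE solve", {
  skip_if_not_installed("deSolve")
  net <- build_grid_network(2, 1)
  model <- passive_membrane()
  ref <- passive_reference_trajectory(net, model, c(-60, -80), seq(0, 2, 0.5))
  # independent reduction of the same DAE, integrated by lsoda
  lap <- knmsim:::network_laplacians(net)
  Li <- as.matrix(lap$L_i); Lie <- as.matrix(lap$L_i + lap$L_e)
  rhs <- function(t, v, parms) {
    ue <- rep(0, 2)           # both nodes grounded on a 2-cell strand
    dv <- (-(Li %*% (v + ue)) / net$A_m - 0.1 * (v + 80)) / 1
    list(as.numeric(dv))
  }
  ode <- deSolve::lsoda(c(-60, -80), seq(0, 2, 0.5), rhs,
                        rtol = 1e-11, atol = 1e-11)
  expect_equal(as.matrix(ref[, c("v1", "v2")]), unname(ode[, 2:3]),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("zero-duration runs return only the initial snapshot", {
  net <- build_grid_network(2, 1)
  tr <- simulate_knm(net, mitchell_schaeffer(), NULL, dt = 0.01, duration = 0)
  expect_equal(length(tr$times), 1L)
  expect_equal(tr$times, 0)
})
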