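# Geometry oracles: quadrature of the frustum profile and hand resistor
# arithmetic, independent of the closed forms used in the package.

quad_cell_volume <- function(geom) {
  h <- geom$length / 2
  r_of <- function(x) ifelse(x <= h,
                             geom$end_radius + (geom$center_radius - geom$end_radius) * x / h,
                             geom$center_radius - (geom$center_radius - geom$end_radius) * (x - h) / h)
  integrate(function(x) pi * r_of(x)^2, 0, geom$length,
            subdivisions = 2000, rel.tol = 1e-12)$value
}

test_that("volume fractions match a quadrature of the frustum profile", {
  geom <- cell_geometry()
  fr <- volume_fractions(geom)
  expect_equal(fr$delta_i,
               quad_cell_volume(geom) / (geom$length * geom$l_y * geom$l_z),
               tolerance = 1e-10)
  expect_equal(fr$delta_i, 0.410475583339407, tolerance = 1e-12)
  expect_equal(fr$delta_i + fr$delta_e, 1)
})

test_that("cylinder degenerate case and complementarity hold over geometries", {
  # equal radii: the double frustum is a cylinder
  g <- cell_geometry(length = 100, end_radius = 5, center_radius = 5, margin = 2)
  expect_equal(volume_fractions(g)$delta_i, pi * 25 / (14 * 14), tolerance = 1e-12)
  for (cr in c(5, 6.5, 8)) for (er in c(3, 5)) {
    g <- cell_geometry(length = 80, end_radius = er, center_radius = cr)
    fr <- volume_fractions(g)
    expect_gt(fr$delta_i, 0); expect_lt(fr$delta_i, 1)
    expect_equal(fr$delta_i + fr$delta_e, 1)
    expect_equal(fr$delta_i,
                 quad_cell_volume(g) / (g$length * g$l_y * g$l_z),
                 tolerance = 1e-9)
  }
})

test_that("geometry validation rejects impossible cells", {
  expect_error(cell_geometry(end_radius = 8, center_radius = 7), "end_radius")
  expect_error(cell_geometry(length = -1), "positive")
  expect_error(cell_geometry(l_y = 10), "fit")
  expect_error(cell_geometry(end_radius = 0), "positive")
})

test_that("membrane area matches a surface-of-revolution quadrature", {
  geom <- cell_geometry()
  h <- geom$length / 2
  slope <- (geom$center_radius - geom$end_radius) / h
  r_of <- function(x) geom$end_radius + slope * pmin(x, geom$length - x)
  quad <- integrate(function(x) 2 * pi * r_of(x) * sqrt(1 + slope^2),
                    0, geom$length, rel.tol = 1e-12)$value
  expect_equal(membrane_area(geom), quad / 1e8, tolerance = 1e-10)
  expect_equal(membrane_area(geom), 2 * pi * 13 * sqrt(60^2 + 1) / 1e8,
               tolerance = 1e-12)
})

test_that("membrane area: cylinder case and quadratic scaling", {
  g <- cell_geometry(length = 100, end_radius = 5, center_radius = 5)
  expect_equal(membrane_area(g), 2 * pi * 5 * 100 / 1e8, tolerance = 1e-12)
  g2 <- cell_geometry(length = 240, end_radius = 12, center_radius = 14, margin = 4)
  expect_equal(membrane_area(g2), 4 * membrane_area(cell_geometry()),
               tolerance = 1e-12)
})

test_that("disc area depends only on the end radius", {
  geom <- cell_geometry()
  expect_equal(disc_area(geom), pi * 36 / 1e8, tolerance = 1e-12)
  expect_equal(disc_area(geom), 1.131e-6, tolerance = 1e-3)
  g2 <- cell_geometry(center_radius = 8)   # wider waist, same disc
  expect_equal(disc_area(g2), disc_area(geom))
})

test_that("extracellular conductance follows the conductor formula", {
  # hand evaluation: 0.5 * 3.24e-6 cm2 * 20 mS/cm / 0.012 cm
  expect_equal(extracellular_conductance(0.5, 3.24e-6, 20, 0.012),
               2.7e-3, tolerance = 1e-12)
  expect_equal(extracellular_conductance(1, 2, 1, 2), 1)          # A = l, unit sigma
  g1 <- extracellular_conductance(0.6, 1e-6, 10, 0.01)
  expect_equal(extracellular_conductance(0.6, 1e-6, 20, 0.01), 2 * g1)
  expect_error(extracellular_conductance(-0.5, 1, 1, 1), "positive")
  expect_error(extracellular_conductance(0.5, 1, 0, 1), "positive")
})

test_that("intracellular conductance is bulk and junction resistance in series", {
  # independent two-resistor oracle
  R1 <- 0.012 / (0.41 * 3.24e-6 * 4)       # kOhm
  R2 <- 0.0015 / 1.131e-6                  # kOhm
  expect_equal(intracellular_conductance(0.41, 3.24e-6, 4, 0.012, 0.0015, 1.131e-6),
               1 / (R1 + R2), tolerance = 1e-12)
  # frozen default-parameter value (delta_i from the frustum quadrature)
  expect_equal(intracellular_conductance(0.410475583339407, 3.24e-6, 4, 0.012,
                                         0.0015, pi * 36e-8),
               2.79171265543e-4, tolerance = 1e-9)
  # vanishing junction resistance: pure bulk conductance
  expect_equal(intracellular_conductance(0.41, 3.24e-6, 4, 0.012, 1e-15, 1.131e-6),
               0.41 * 3.24e-6 * 4 / 0.012, tolerance = 1e-6)
})

test_that("conductance monotonicity over a parameter sweep", {
  rg <- c(0.0005, 0.0015, 0.015, 0.15, 0.75)
  gi <- vapply(rg, function(r)
    intracellular_conductance(0.41, 3.24e-6, 4, 0.012, r, 1.131e-6), numeric(1))
  expect_true(all(diff(gi) < 0))           # decreasing in R_g
  expect_lt(gi[length(gi)], 1e-5)          # uncoupling limit
  si <- c(1, 2, 4, 8)
  gs <- vapply(si, function(s)
    intracellular_conductance(0.41, 3.24e-6, s, 0.012, 0.0015, 1.131e-6), numeric(1))
  expect_true(all(diff(gs) > 0))           # increasing in sigma_i
  As <- c(1e-6, 2e-6, 4e-6)
  ga <- vapply(As, function(a)
    intracellular_conductance(0.41, a, 4, 0.012, 0.0015, 1.131e-6), numeric(1))
  expect_true(all(diff(ga) > 0))           # increasing in A
  ds <- c(0.2, 0.4, 0.6)
  gd <- vapply(ds, function(d)
    intracellular_conductance(d, 3.24e-6, 4, 0.012, 0.0015, 1.131e-6), numeric(1))
  expect_true(all(diff(gd) > 0))           # increasing in delta_i
})

test_that("unit round-trip: cm evaluation agrees with dimensionless reference", {
  # express everything in a self-consistent nondimensional system and rescale
  geom <- cell_geometry()
  fr <- volume_fractions(geom)
  A <- geom$l_y * geom$l_z / 1e8; l <- geom$length / 1e4
  ref <- fr$delta_e * (A / l) * 20          # dimensionless conductance x sigma
  expect_equal(extracellular_conductance(fr$delta_e, A, 20, l), ref,
               tolerance = 1e-14)
})

test_that("grid networks have the expected nodes, edges and flags", {
  strand <- build_grid_network(15, 1)
  expect_equal(strand$n_nodes, 15)
  expect_equal(nrow(strand$edges), 14)
  expect_equal(which(strand$boundary), c(1L, 15L))

  sheet <- build_grid_network(20, 20)
  expect_equal(sheet$n_nodes, 400)
  expect_equal(nrow(sheet$edges), 2 * 20 * 19)
  expect_equal(sum(sheet$boundary), 4 * 20 - 4)

  single <- build_grid_network(1, 1)
  expect_equal(single$n_nodes, 1)
  expect_equal(nrow(single$edges), 0)
  expect_error(build_grid_network(0, 1), "at least one")
})

test_that("grid conductances are symmetric and interior degree is 4", {
  net <- build_grid_network(5, 4)
  lap <- knmsim:::network_laplacians(net)
  expect_identical(as.matrix(lap$L_i), t(as.matrix(lap$L_i)))
  expect_identical(as.matrix(lap$L_e), t(as.matrix(lap$L_e)))
  deg <- tabulate(c(net$edges), nbins = net$n_nodes)
  interior <- !net$boundary
  expect_true(all(deg[interior] == 4))
  expect_true(all(net$G_i > 0) && all(net$G_e > 0))
  # no self-loops, each unordered pair appears once
  expect_true(all(net$edges[, 1] != net$edges[, 2]))
  keys <- paste(pmin(net$edges[, 1], net$edges[, 2]),
                pmax(net$edges[, 1], net$edges[, 2]))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("R_g multipliers scale every edge, with per-edge overrides", {
  base <- build_grid_network(4, 1)
  weak <- build_grid_network(4, 1, params = tissue_params(rg_multiplier = 500))
  expect_true(all(weak$G_i < base$G_i))
  geom <- cell_geometry(); fr <- volume_fractions(geom)
  expect_equal(weak$G_i[1],
               intracellular_conductance(fr$delta_i, 3.24e-6, 4, 0.012,
                                         500 * 0.0015, disc_area(geom)),
               tolerance = 1e-12)
  het <- build_grid_network(4, 1, edge_rg_multiplier = c(1, 500, 1))
  expect_equal(het$G_i[c(1, 3)], base$G_i[c(1, 3)])
  expect_equal(het$G_i[2], weak$G_i[2])
})

test_that("network JSON serialization round-trips the conductances", {
  net <- build_grid_network(3, 2)
  parsed <- jsonlite::fromJSON(network_to_json(net))
  expect_equal(parsed$n_nodes, 6)
  expect_equal(parsed$G_i_mS, net$G_i, tolerance = 1e-12)
  expect_equal(parsed$G_e_mS, net$G_e, tolerance = 1e-12)
})
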