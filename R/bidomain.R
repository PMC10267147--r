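#' Homogenized bidomain parameters from cell geometry
#'
#' Derives the parameters of the continuum bidomain description -- membrane
#' area-to-volume ratio `chi` and diagonal conductivity tensors `M_i`,
#' `M_e` -- from the cell geometry and tissue parameters, such that the
#' homogenized medium is exactly consistent with the cell network:
#'
#' * `chi = A_m / (l_x * l_y * l_z)` (cm^-1);
#' * `M_e = delta_e * sigma_e` in both directions (mS/cm);
#' * `M_i` in each direction is defined by requiring that the resistance of
#'   one cell span of homogenized medium equals the corresponding network
#'   edge resistance `1/G_i`, i.e. longitudinally
#'   `M_i = delta_i / (1/sigma_i + R_g * delta_i * A_cross / (A_g * l_x))`
#'   (bulk cytoplasm in series with the gap junction, distributed over the
#'   cell length), and analogously transversely with the transverse contact
#'   area and `l_y`.
#'
#' `R_g` includes the tissue `rg_multiplier`, so impaired coupling carries
#' over to the continuum model.
#'
#' @param geom A [cell_geometry()].
#' @param params A [tissue_params()].
#' @param transverse_area Transverse gap-junction contact area (cm^2),
#'   defaulting to the intercalated-disc area as in [build_grid_network()].
#' @return An object of class `bidomain_params`: `chi` (cm^-1), `M_i`,
#'   `M_e` (named vectors, mS/cm), `C_m` (uF/cm^2).
#' @export
homogenize <- function(geom, params = tissue_params(), transverse_area = NULL) {
  validate_cell_geometry(geom)
  fr <- volume_fractions(geom)
  A_g <- disc_area(geom)
  if (is.null(transverse_area)) transverse_area <- A_g
  Rg <- params$R_g * params$rg_multiplier

  l_x <- geom$length / UM_PER_CM
  l_y <- geom$l_y / UM_PER_CM
  A_x <- geom$l_y * geom$l_z / UM2_PER_CM2
  A_y <- geom$length * geom$l_z / UM2_PER_CM2

  chi <- membrane_area(geom) / (geom$length * geom$l_y * geom$l_z / UM_PER_CM^3)
  M_ix <- fr$delta_i / (1 / params$sigma_i + Rg * fr$delta_i * A_x / (A_g * l_x))
  M_iy <- fr$delta_i / (1 / params$sigma_i + Rg * fr$delta_i * A_y / (transverse_area * l_y))
  structure(
    list(chi = chi,
         M_i = c(x = M_ix, y = M_iy),
         M_e = c(x = fr$delta_e * params$sigma_e, y = fr$delta_e * params$sigma_e),
         C_m = params$C_m),
    class = "bidomain_params")
}

#' @export
print.bidomain_params <- function(x, ...) {
  cat(sprintf("<bidomain_params> chi = %.4g /cm, M_i = (%.4g, %.4g) mS/cm, M_e = %.4g mS/cm\n",
              x$chi, x$M_i["x"], x$M_i["y"], x$M_e["x"]))
  invisible(x)
}

#' Finite-volume grid for the bidomain model
#'
#' Discretizes the bidomain equations on a cell-centered finite-volume grid
#' over a tissue of `cells_x` x `cells_y` cells (domain
#' `cells_x * l_x` x `cells_y * l_y` um) with spacings `dx`, `dy` um. The
#' 3-point (1D) / 5-point (2D) flux stencil is algebraically a resistor
#' network, so the grid is returned in the same `knm_network` container and
#' simulated by the same engine ([simulate_knm()]): face conductances are
#' `M * A_face / h` and each node carries membrane area `chi * V_node`. With
#' `dx = l_x` and `dy = l_y` the grid nodes coincide with the cell centers
#' and the assembled operator is identical to the cell network's -- the cell
#' network is the coarsest consistent discretization of the continuum model.
#'
#' Boundary conditions match the cell network: extracellular potential
#' grounded on the domain ends (1D) or perimeter (2D), natural no-flux
#' elsewhere. `dx` must divide the domain length (and `dy` its width).
#'
#' @param cells_x,cells_y Tissue extent in cells.
#' @param dx,dy Grid spacings, um; default one cell per node.
#' @param geom,params,transverse_area As in [build_grid_network()].
#' @return A `knm_network` of kind `"bd"`, with `cells_x`, `cells_y`,
#'   `dx`, `dy` and the [homogenize()] result in `bd_params`.
#' @export
bd_grid <- function(cells_x, cells_y = 1, dx = NULL, dy = NULL,
                    geom = cell_geometry(), params = tissue_params(),
                    transverse_area = NULL) {
  if (cells_x < 1 || cells_y < 1) stop("grid must span at least one cell", call. = FALSE)
  if (is.null(dx)) dx <- geom$length
  if (is.null(dy)) dy <- geom$l_y
  check_positive(dx = dx, dy = dy)
  Lx <- cells_x * geom$length
  Ly <- cells_y * geom$l_y
  nx <- Lx / dx
  ny <- Ly / dy
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("dx (dy) must divide the domain length (width)", call. = FALSE)
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))

  hp <- homogenize(geom, params, transverse_area)
  l_z <- geom$l_z / UM_PER_CM
  dx_cm <- dx / UM_PER_CM; dy_cm <- dy / UM_PER_CM

  n <- nx * ny
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  pos <- cbind(x = (ix - 0.5) * dx, y = (iy - 0.5) * dy)
  node <- function(i, j) (j - 1L) * nx + i

  ex <- NULL; ey <- NULL
  if (nx > 1) {
    i <- rep(seq_len(nx - 1L), times = ny)
    j <- rep(seq_len(ny), each = nx - 1L)
    ex <- cbind(node(i, j), node(i + 1L, j))
  }
  if (ny > 1) {
    i <- rep(seq_len(nx), times = ny - 1L)
    j <- rep(seq_len(ny - 1L), each = nx)
    ey <- cbind(node(i, j), node(i, j + 1L))
  }
  edges <- rbind(ex, ey)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  n_ex <- if (is.null(ex)) 0L else nrow(ex)
  n_edges <- nrow(edges)
  is_x_edge <- seq_len(n_edges) <= n_ex

  G_i <- G_e <- numeric(n_edges)
  if (n_edges > 0) {
    # face conductance M * A_face / h, faces carry the slab thickness l_z
    G_i[is_x_edge] <- hp$M_i["x"] * (dy_cm * l_z) / dx_cm
    G_e[is_x_edge] <- hp$M_e["x"] * (dy_cm * l_z) / dx_cm
    if (any(!is_x_edge)) {
      G_i[!is_x_edge] <- hp$M_i["y"] * (dx_cm * l_z) / dy_cm
      G_e[!is_x_edge] <- hp$M_e["y"] * (dx_cm * l_z) / dy_cm
    }
  }
  A_m_node <- hp$chi * dx_cm * dy_cm * l_z
  boundary <- if (ny == 1L) ix == 1L | ix == nx
              else ix == 1L | ix == nx | iy == 1L | iy == ny

  structure(
    list(kind = "bd", n_nodes = n, n_x = nx, n_y = ny,
         pos = pos, ix = ix, iy = iy,
         edges = edges, is_x_edge = is_x_edge,
         G_i = G_i, G_e = G_e,
         A_m = rep(A_m_node, n), boundary = boundary,
         geom = geom, params = params, bd_params = hp,
         cells_x = as.integer(cells_x), cells_y = as.integer(cells_y),
         dx = dx, dy = dy,
         domain = c(x = Lx, y = Ly)),
    class = "knm_network")
}

#' Simulate the bidomain model
#'
#' Convenience wrapper: builds the finite-volume grid with [bd_grid()] and
#' runs the shared operator-splitting engine [simulate_knm()] on it.
#'
#' @param cells_x,cells_y Tissue extent in cells.
#' @param dx,dy Grid spacings, um.
#' @param geom,params As in [bd_grid()].
#' @param protocol A [stimulus_protocol()] built on the returned grid, or a
#'   function `function(net)` building one (e.g. `s1_protocol`); default S1.
#' @param ... Passed to [simulate_knm()] (`dt`, `duration`, `cadence`, ...).
#' @return A `knm_trace`.
#' @export
simulate_bd <- function(cells_x, cells_y = 1, dx = NULL, dy = NULL,
                        geom = cell_geometry(), params = tissue_params(),
                        protocol = s1_protocol, ...) {
  net <- bd_grid(cells_x, cells_y, dx, dy, geom, params)
  if (is.function(protocol)) protocol <- protocol(net)
  simulate_knm(net, protocol = protocol, ...)
}
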