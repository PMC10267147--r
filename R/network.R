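#' Build a rectangular myocyte network
#'
#' Lays out `n_x` x `n_y` cells on a regular lattice (spacing `length` um
#' along the fibre axis, `l_y` um transversely), connects nearest neighbors,
#' and computes each edge's intracellular and extracellular conductances.
#' Longitudinal (x) edges use the compartment face `l_y * l_z` as
#' cross-section and the cell length as distance; transverse (y) edges use
#' `length * l_z` and `l_y`. The intracellular path of every edge includes a
#' gap-junction resistance `R_g * rg_multiplier` over the contact area:
#' the intercalated-disc area for longitudinal edges and `transverse_area`
#' (defaulting to the same disc area) for transverse edges.
#'
#' Extracellular compartments on the tissue boundary (strand ends in 1D, the
#' full perimeter in 2D) are flagged as grounding nodes: the extracellular
#' potential is clamped to 0 mV there (homogeneous Dirichlet), while the
#' intracellular side everywhere satisfies the natural no-flux condition of
#' the network (no edges leave the tissue).
#'
#' @param n_x,n_y Number of cells along and across the fibre direction.
#' @param geom A [cell_geometry()].
#' @param params A [tissue_params()].
#' @param transverse_area Gap-junction contact area for transverse edges,
#'   cm^2. Defaults to the intercalated-disc area [disc_area()].
#' @param edge_rg_multiplier Optional numeric vector overriding the global
#'   `rg_multiplier` per edge (recycled; edge order is all x-edges in
#'   column-major node order, then all y-edges), for heterogeneous coupling.
#' @return An object of class `knm_network` with fields `n_nodes`, `pos`
#'   (node centers, um), `edges` (2-column index matrix), `G_i`, `G_e` (mS
#'   per edge), `A_m` (cm^2 per node), `boundary` (logical per node).
#' @examples
#' net <- build_grid_network(15, 1)
#' net$n_nodes
#' range(net$G_i)
#' @export
build_grid_network <- function(n_x, n_y = 1, geom = cell_geometry(),
                               params = tissue_params(),
                               transverse_area = NULL,
                               edge_rg_multiplier = NULL) {
  if (n_x < 1 || n_y < 1) stop("grid must contain at least one cell", call. = FALSE)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  validate_cell_geometry(geom)

  fr <- volume_fractions(geom)
  A_m <- membrane_area(geom)
  A_g <- disc_area(geom)
  if (is.null(transverse_area)) transverse_area <- A_g
  check_positive(transverse_area = transverse_area)

  n <- n_x * n_y
  ix <- rep(seq_len(n_x), times = n_y)
  iy <- rep(seq_len(n_y), each = n_x)
  # cell centers in um, cell (1,1) centered at (l_x/2, l_y/2)
  pos <- cbind(x = (ix - 0.5) * geom$length, y = (iy - 0.5) * geom$l_y)

  node <- function(i, j) (j - 1L) * n_x + i

  # x-edges, then y-edges, both in column-major node order
  ex <- NULL; ey <- NULL
  if (n_x > 1) {
    i <- rep(seq_len(n_x - 1L), times = n_y)
    j <- rep(seq_len(n_y), each = n_x - 1L)
    ex <- cbind(node(i, j), node(i + 1L, j))
  }
  if (n_y > 1) {
    i <- rep(seq_len(n_x), times = n_y - 1L)
    j <- rep(seq_len(n_y - 1L), each = n_x)
    ey <- cbind(node(i, j), node(i, j + 1L))
  }
  edges <- rbind(ex, ey)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  n_ex <- if (is.null(ex)) 0L else nrow(ex)
  n_edges <- nrow(edges)
  is_x_edge <- seq_len(n_edges) <= n_ex

  rg_mult <- rep_len(if (is.null(edge_rg_multiplier)) params$rg_multiplier
                     else edge_rg_multiplier, n_edges)
  if (n_edges > 0 && any(rg_mult <= 0))
    stop("edge R_g multipliers must be strictly positive", call. = FALSE)

  # geometric quantities in cm
  l_x_cm <- geom$length / UM_PER_CM
  l_y_cm <- geom$l_y / UM_PER_CM
  A_x <- geom$l_y * geom$l_z / UM2_PER_CM2   # face between longitudinal neighbors
  A_y <- geom$length * geom$l_z / UM2_PER_CM2

  G_i <- G_e <- numeric(n_edges)
  if (n_edges > 0) {
    Rg <- params$R_g * rg_mult
    G_i[is_x_edge] <- 1 / (l_x_cm / (fr$delta_i * A_x * params$sigma_i) +
                             Rg[is_x_edge] / A_g)
    G_e[is_x_edge] <- extracellular_conductance(fr$delta_e, A_x, params$sigma_e, l_x_cm)
    if (any(!is_x_edge)) {
      G_i[!is_x_edge] <- 1 / (l_y_cm / (fr$delta_i * A_y * params$sigma_i) +
                                Rg[!is_x_edge] / transverse_area)
      G_e[!is_x_edge] <- extracellular_conductance(fr$delta_e, A_y, params$sigma_e, l_y_cm)
    }
  }

  boundary <- if (n_y == 1L) ix == 1L | ix == n_x
              else ix == 1L | ix == n_x | iy == 1L | iy == n_y

  structure(
    list(kind = "knm", n_nodes = n, n_x = n_x, n_y = n_y,
         pos = pos, ix = ix, iy = iy,
         edges = edges, is_x_edge = is_x_edge,
         G_i = G_i, G_e = G_e,
         A_m = rep(A_m, n), boundary = boundary,
         geom = geom, params = params,
         domain = c(x = n_x * geom$length, y = n_y * geom$l_y)),
    class = "knm_network")
}

#' @export
print.knm_network <- function(x, ...) {
  ne <- if (is.null(x$edges)) 0L else nrow(x$edges)
  cat(sprintf("<%s network> %d x %d nodes (%d), %d edges, %d grounded boundary nodes\n",
              x$kind, x$n_x, x$n_y, x$n_nodes, ne, sum(x$boundary)))
  invisible(x)
}

#' Graph Laplacians of a network
#'
#' Weighted graph Laplacians of the intracellular and extracellular
#' conductance graphs, as sparse symmetric matrices in mS:
#' `(L x)_k = sum_j G_jk (x_k - x_j)`, so that the net current into node k
#' from its neighbors is `-(L x)_k` uA when x is in mV.
#'
#' @param net A `knm_network`.
#' @return A list with sparse matrices `L_i` and `L_e`.
#' @keywords internal
network_laplacians <- function(net) {
  lap <- function(w) {
    n <- net$n_nodes
    if (is.null(net$edges) || nrow(net$edges) == 0)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(n, n), symmetric = TRUE))
    a <- net$edges[, 1]; b <- net$edges[, 2]
    A <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w), dims = c(n, n))
    Matrix::Diagonal(n, Matrix::rowSums(A)) - A
  }
  list(L_i = lap(net$G_i), L_e = lap(net$G_e))
}

#' Serialize a network to JSON
#'
#' Writes (or returns) a plain JSON description of the network: node
#' positions, boundary flags, membrane areas, edges and per-edge
#' conductances. Intended for inspection and fixture reuse.
#'
#' @param net A `knm_network`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
network_to_json <- function(net, path = NULL) {
  obj <- list(
    kind = net$kind, n_x = net$n_x, n_y = net$n_y, n_nodes = net$n_nodes,
    pos_um = unname(net$pos), boundary = net$boundary,
    A_m_cm2 = net$A_m,
    edges = if (is.null(net$edges)) list() else unname(net$edges),
    G_i_mS = net$G_i, G_e_mS = net$G_e)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
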