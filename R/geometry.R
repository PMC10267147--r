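#' Myocyte and compartment geometry
#'
#' Describes a single cardiomyocyte as a solid of revolution of length
#' `length` whose radius varies linearly from `end_radius` at both cell ends
#' to `center_radius` at the cell center (two conical frusta joined base to
#' base), sitting inside a rectangular tissue compartment of cross-section
#' `l_y` x `l_z`. The compartment also contains the extracellular volume
#' associated with the cell; by default its cross-section is the tightest box
#' around the cell plus an extracellular margin on every side,
#' `l_y = l_z = 2 * (center_radius + margin)`.
#'
#' All lengths are in micrometres. Defaults describe a 120 um long myocyte
#' with radius tapering from 7 um at the center to 6 um at the ends, in a
#' compartment leaving a 2 um extracellular margin (18 x 18 um cross-section).
#'
#' @param length Cell (and compartment) length along the fibre axis, um.
#' @param end_radius Cell radius at both ends (the intercalated-disc radius), um.
#' @param center_radius Cell radius at the cell center, um.
#' @param margin Extracellular margin between cell and compartment boundary, um.
#' @param l_y,l_z Compartment cross-section, um. Default `2 * (center_radius + margin)`.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry()
#' volume_fractions(geom)
#' @export
cell_geometry <- function(length = 120, end_radius = 6, center_radius = 7,
                          margin = 2, l_y = NULL, l_z = NULL) {
  if (is.null(l_y)) l_y <- 2 * (center_radius + margin)
  if (is.null(l_z)) l_z <- 2 * (center_radius + margin)
  geom <- structure(
    list(length = length, end_radius = end_radius,
         center_radius = center_radius, margin = margin,
         l_y = l_y, l_z = l_z),
    class = "cell_geometry")
  validate_cell_geometry(geom)
  geom
}

validate_cell_geometry <- function(geom) {
  dims <- unlist(geom[c("length", "end_radius", "center_radius", "l_y", "l_z")])
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all cell dimensions must be strictly positive and finite", call. = FALSE)
  if (geom$margin < 0)
    stop("extracellular margin must be non-negative", call. = FALSE)
  if (geom$end_radius > geom$center_radius)
    stop("end_radius must not exceed center_radius", call. = FALSE)
  if (geom$l_y < 2 * (geom$center_radius + geom$margin) ||
      geom$l_z < 2 * (geom$center_radius + geom$margin))
    stop("cell (plus margin) does not fit inside its compartment: ",
         "l_y and l_z must be >= 2 * (center_radius + margin)", call. = FALSE)
  invisible(geom)
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<cell_geometry> %g um long, radius %g -> %g um, ",
    "compartment %g x %g um (margin %g um)\n"),
    x$length, x$end_radius, x$center_radius, x$l_y, x$l_z, x$margin))
  invisible(x)
}

#' Tissue-level electrical parameters
#'
#' Bulk conductivities, membrane capacitance and gap-junction resistance used
#' to derive network conductances. Defaults are the standard values for
#' cardiac tissue used throughout the package: `sigma_i = 4` mS/cm,
#' `sigma_e = 20` mS/cm, `C_m = 1` uF/cm^2, `R_g = 0.0015` kOhm cm^2.
#' `R_g` is a resistance *density*: the lumped gap-junction resistance of an
#' intercalated disc of area `A_g` (cm^2) is `R_g / A_g` kOhm. The
#' `rg_multiplier` scales `R_g` uniformly to emulate impaired cell-to-cell
#' coupling (e.g. 500 for severely reduced conduction).
#'
#' @param sigma_i Intracellular (cytoplasmic) conductivity, mS/cm.
#' @param sigma_e Extracellular conductivity, mS/cm.
#' @param C_m Specific membrane capacitance, uF/cm^2.
#' @param R_g Gap-junction resistance density, kOhm cm^2.
#' @param rg_multiplier Dimensionless multiplier applied to `R_g` on every edge.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(sigma_i = 4, sigma_e = 20, C_m = 1,
                          R_g = 0.0015, rg_multiplier = 1) {
  p <- structure(
    list(sigma_i = sigma_i, sigma_e = sigma_e, C_m = C_m,
         R_g = R_g, rg_multiplier = rg_multiplier),
    class = "tissue_params")
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all tissue parameters must be strictly positive and finite", call. = FALSE)
  p
}

UM2_PER_CM2 <- 1e8
UM_PER_CM <- 1e4

#' Intracellular and extracellular volume fractions of a compartment
#'
#' The intracellular fraction is the ratio of the cell volume (solid of
#' revolution: two conical frusta) to the compartment volume
#' `length * l_y * l_z`; the extracellular fraction is its complement. For a
#' compartment with uniformly sized cells these fractions are constant across
#' the tissue.
#'
#' @param geom A [cell_geometry()].
#' @return A list with components `delta_i` and `delta_e`, both in (0, 1).
#' @export
volume_fractions <- function(geom) {
  validate_cell_geometry(geom)
  h <- geom$length / 2
  R <- geom$center_radius
  r <- geom$end_radius
  # volume of one frustum: pi h/3 (R^2 + R r + r^2); the cell is two of them
  v_cell <- 2 * pi * h / 3 * (R^2 + R * r + r^2)
  v_comp <- geom$length * geom$l_y * geom$l_z
  delta_i <- v_cell / v_comp
  if (delta_i >= 1)
    stop("cell volume exceeds compartment volume", call. = FALSE)
  list(delta_i = delta_i, delta_e = 1 - delta_i)
}

#' Membrane area of one myocyte
#'
#' Lateral (slant-corrected) surface area of the double-frustum cell body, in
#' cm^2. The flat disc faces at the cell ends are intercalated discs carrying
#' gap-junction current, not ionic membrane current, and are excluded.
#'
#' @param geom A [cell_geometry()].
#' @return Membrane area A_m in cm^2.
#' @export
membrane_area <- function(geom) {
  validate_cell_geometry(geom)
  h <- geom$length / 2
  R <- geom$center_radius
  r <- geom$end_radius
  slant <- sqrt(h^2 + (R - r)^2)
  a_um2 <- 2 * pi * (R + r) * slant
  a_um2 / UM2_PER_CM2
}

#' Intercalated-disc area
#'
#' Area of the flat end face of the cell through which gap-junction current
#' flows to the longitudinal neighbor, `pi * end_radius^2`, in cm^2.
#'
#' @param geom A [cell_geometry()].
#' @return Disc area A_g in cm^2.
#' @export
disc_area <- function(geom) {
  validate_cell_geometry(geom)
  if (geom$end_radius <= 0)
    stop("degenerate intercalated disc: end_radius must be positive", call. = FALSE)
  pi * geom$end_radius^2 / UM2_PER_CM2
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (!is.finite(args[[nm]]) || args[[nm]] <= 0)
      stop(sprintf("'%s' must be strictly positive and finite", nm), call. = FALSE)
  invisible(TRUE)
}

#' Extracellular edge conductance
#'
#' Conductance of the extracellular path between two neighboring compartments
#' by the classical conductor formula: the extracellular fraction `delta_e` of
#' the shared cross-section `A` conducting over the center-to-center distance
#' `l` with conductivity `sigma_e`.
#'
#' @param delta_e Extracellular volume fraction, in (0, 1].
#' @param A Average cross-sectional area between the compartments, cm^2.
#' @param sigma_e Extracellular conductivity, mS/cm.
#' @param l Distance between compartment centers, cm.
#' @return Conductance G_e in mS.
#' @export
extracellular_conductance <- function(delta_e, A, sigma_e, l) {
  check_positive(delta_e = delta_e, A = A, sigma_e = sigma_e, l = l)
  delta_e * A * sigma_e / l
}

#' Intracellular edge conductance
#'
#' Conductance of the intracellular path between two neighboring cells: the
#' bulk cytoplasmic resistance `l / (delta_i * A * sigma_i)` in series with
#' the gap-junction resistance `R_g / A_g` of the connecting intercalated
#' disc. `R_g` in kOhm cm^2 divided by an area in cm^2 gives kOhm, whose
#' reciprocal is mS, so both series terms are in kOhm and the result in mS.
#'
#' @param delta_i Intracellular volume fraction, in (0, 1).
#' @param A Average cross-sectional area between the compartments, cm^2.
#' @param sigma_i Intracellular conductivity, mS/cm.
#' @param l Distance between cell centers, cm.
#' @param R_g Gap-junction resistance density, kOhm cm^2.
#' @param A_g Intercalated-disc area, cm^2.
#' @return Conductance G_i in mS.
#' @export
intracellular_conductance <- function(delta_i, A, sigma_i, l, R_g, A_g) {
  check_positive(delta_i = delta_i, A = A, sigma_i = sigma_i, l = l,
                 R_g = R_g, A_g = A_g)
  1 / (l / (delta_i * A * sigma_i) + R_g / A_g)
}
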