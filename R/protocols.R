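#' Stimulus protocol
#'
#' A list of stimulation items, each applying a membrane current density of
#' `amplitude` uA/cm^2 (delivered as an inward, depolarizing current) to a
#' set of nodes during `[onset, onset + duration)` ms.
#'
#' @param items A list of items, each a list with `region` (integer node
#'   indices), `amplitude` (uA/cm^2), `onset` (ms), `duration` (ms),
#'   and optionally `label`.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(items) {
  for (it in items) {
    if (length(it$region) == 0) stop("stimulus region is empty", call. = FALSE)
    if (it$duration <= 0) stop("stimulus duration must be positive", call. = FALSE)
    if (it$amplitude <= 0) stop("stimulus amplitude must be positive", call. = FALSE)
    if (it$onset < 0) stop("stimulus onset must be non-negative", call. = FALSE)
  }
  structure(list(items = items), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  for (it in x$items)
    cat(sprintf("  %s: %d node(s), %g uA/cm2, t in [%g, %g) ms\n",
                if (is.null(it$label)) "stim" else it$label,
                length(it$region), it$amplitude, it$onset,
                it$onset + it$duration))
  invisible(x)
}

# nodes whose centers lie in the leftmost cell-length of the domain
leftmost_region <- function(net) {
  which(net$pos[, 1] <= net$geom$length + 1e-9)
}

# lower-left quarter: cell indices <= floor(n/2) for cell networks, metric
# half-domain for finite-volume grids (odd cell counts round down)
lower_left_region <- function(net) {
  if (net$kind == "knm")
    which(net$ix <= net$n_x %/% 2 & net$iy <= net$n_y %/% 2)
  else {
    half_x <- (net$cells_x %/% 2) * net$geom$length
    half_y <- (net$cells_y %/% 2) * net$geom$l_y
    which(net$pos[, 1] <= half_x + 1e-9 & net$pos[, 2] <= half_y + 1e-9)
  }
}

#' S1 stimulus: excite the left edge of the tissue
#'
#' Stimulates the leftmost cell (1D strand) or the leftmost column of cells
#' (2D sheet) -- for finite-volume grids, all nodes whose centers lie within
#' the first cell length of the domain -- at time 0.
#'
#' @param net A `knm_network` or finite-volume grid from [bd_grid()].
#' @param amplitude Stimulus current density, uA/cm^2.
#' @param duration Stimulus duration, ms.
#' @return A [stimulus_protocol()].
#' @export
s1_protocol <- function(net, amplitude = 40, duration = 2) {
  stimulus_protocol(list(list(region = leftmost_region(net),
                              amplitude = amplitude, onset = 0,
                              duration = duration, label = "S1")))
}

#' S1-S2 stimulus: premature second stimulus in the lower-left quarter
#'
#' The S1 stimulus of [s1_protocol()] followed, after `s2_delay` ms, by an
#' identical stimulus applied to the lower-left quarter of the domain (cell
#' indices up to floor(n/2) on both axes). Used to provoke unidirectional
#' block and reentry. A zero delay (overlapping S1 and S2) is allowed but
#' flagged with a warning.
#'
#' @param net A 2D `knm_network` or [bd_grid()].
#' @param s2_delay S2 onset, ms after S1 onset.
#' @param amplitude Stimulus current density, uA/cm^2.
#' @param duration Stimulus duration of each pulse, ms.
#' @return A [stimulus_protocol()] with two items.
#' @export
s1_s2_protocol <- function(net, s2_delay = 240, amplitude = 40, duration = 2) {
  two_d <- if (net$kind == "knm") net$n_y > 1 else net$cells_y > 1
  if (!two_d)
    stop("S1-S2 protocol needs a 2D tissue: the lower-left quarter is undefined in 1D",
         call. = FALSE)
  if (s2_delay < 0) stop("s2_delay must be non-negative", call. = FALSE)
  if (s2_delay == 0) warning("S1 and S2 overlap (zero delay)")
  s1 <- s1_protocol(net, amplitude, duration)
  stimulus_protocol(c(s1$items,
                      list(list(region = lower_left_region(net),
                                amplitude = amplitude, onset = s2_delay,
                                duration = duration, label = "S2"))))
}

#' Stimulus evaluator for a protocol on a network
#'
#' Returns `function(t)` giving the applied membrane current density per
#' node at time t (uA/cm^2). Depolarizing stimuli are applied as negative
#' (inward) additions to the ionic current.
#'
#' @param protocol A [stimulus_protocol()].
#' @param net The network the protocol's regions refer to.
#' @return A function of time.
#' @export
make_stimulus <- function(protocol, net) {
  n <- net$n_nodes
  items <- protocol$items
  for (it in items)
    if (any(it$region < 1 | it$region > n))
      stop("stimulus region refers to nodes outside the network", call. = FALSE)
  function(t) {
    out <- rep(0, n)
    for (it in items)
      if (t >= it$onset && t < it$onset + it$duration)
        out[it$region] <- out[it$region] - it$amplitude
    out
  }
}
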