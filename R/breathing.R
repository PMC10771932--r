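# Breathing waveform and time-resolved geometry: sinusoidal tidal volume,
# inflation fraction, and interpolation of the airway tree between its FRC
# and TLC states over one cycle.

#' Breathing-cycle configuration
#'
#' Tidal volume and period default to the simulation boundary conditions
#' used throughout the package: a 1 L sinusoidal tidal volume over a 4 s
#' cycle. `frc_volume_L`/`tlc_volume_L` are the subject's lung air volumes
#' at the two imaged states; they define the inflation axis and the lung
#' volume entering the transpulmonary pressure.
#'
#' @param tidal_volume_L Tidal volume, liters (> 0).
#' @param period_s Breathing period, seconds (> 0).
#' @param steps_per_cycle Time steps per cycle (>= 4; default 40).
#' @param frc_volume_L,tlc_volume_L Lung air volumes at FRC and TLC,
#'   liters; must satisfy FRC + tidal <= TLC.
#' @param interp_method `"linear"` or `"akima"` smoothing of the inflation
#'   fraction time series (see [breathing_schedule()]).
#' @return An object of class `breath_config`.
#' @export
breath_config <- function(tidal_volume_L = 1.0, period_s = 4.0,
                          steps_per_cycle = 40L, frc_volume_L = 1.8,
                          tlc_volume_L = 5.0,
                          interp_method = c("akima", "linear")) {
  interp_method <- match.arg(interp_method)
  stopifnot(tidal_volume_L > 0, period_s > 0,
            frc_volume_L > 0, frc_volume_L + tidal_volume_L <= tlc_volume_L)
  if (steps_per_cycle < 4) stop("steps_per_cycle must be at least 4", call. = FALSE)
  structure(list(tidal_volume_L = tidal_volume_L, period_s = period_s,
                 steps_per_cycle = as.integer(steps_per_cycle),
                 frc_volume_L = frc_volume_L, tlc_volume_L = tlc_volume_L,
                 interp_method = interp_method),
            class = "breath_config")
}

#' Sinusoidal tidal volume above FRC
#'
#' V(t) = (V_tidal / 2) (1 - cos(2 pi t / T)): zero at the cycle start,
#' peaking at V_tidal at mid-cycle. Times outside the cycle wrap modulo T.
#'
#' @param t Time(s), seconds.
#' @param config A [breath_config()].
#' @return Volume above FRC, liters.
#' @export
volume_waveform <- function(t, config = breath_config()) {
  t <- t %% config$period_s
  config$tidal_volume_L / 2 * (1 - cos(2 * pi * t / config$period_s))
}

#' Inlet flow waveform
#'
#' Q(t) = dV/dt = (pi V_tidal / T) sin(2 pi t / T); positive during
#' inspiration.
#'
#' @inheritParams volume_waveform
#' @return Flow, L/s.
#' @export
flow_waveform <- function(t, config = breath_config()) {
  t <- t %% config$period_s
  pi * config$tidal_volume_L / config$period_s * sin(2 * pi * t / config$period_s)
}

#' Inflation fraction along the FRC-to-TLC axis
#'
#' lambda = V / (V_TLC - V_FRC) maps a volume above FRC onto the
#' single-parameter family of geometries between the two imaged states.
#'
#' @param v_above_frc Volume above FRC, liters.
#' @param config A [breath_config()].
#' @return Dimensionless fraction in [0, 1].
#' @export
inflation_fraction <- function(v_above_frc, config = breath_config()) {
  cap <- config$tlc_volume_L - config$frc_volume_L
  if (any(v_above_frc < -1e-12) || any(v_above_frc > cap + 1e-12)) {
    stop("volume above FRC must lie in [0, TLC - FRC]", call. = FALSE)
  }
  pmin(pmax(v_above_frc / cap, 0), 1)
}

#' Interpolate tree geometry between the FRC and TLC states
#'
#' Linearly blends node coordinates, branch diameters and branch lengths
#' between two topologically identical trees: lambda = 0 returns the FRC
#' tree exactly, lambda = 1 the TLC tree exactly.
#'
#' @param tree_frc,tree_tlc [airway_tree()] objects sharing branch and
#'   node ids.
#' @param lambda Inflation fraction in [0, 1].
#' @return An [airway_tree()] with state `"interpolated"` (or the exact
#'   endpoint tree at lambda 0/1).
#' @export
geometry_at <- function(tree_frc, tree_tlc, lambda) {
  stopifnot(length(lambda) == 1, lambda >= 0, lambda <= 1)
  bf <- tree_frc$branches; bt <- tree_tlc$branches
  if (nrow(bf) != nrow(bt) || !all(bf$id == bt$id) ||
      !identical(bf$parent, bt$parent)) {
    diff1 <- if (nrow(bf) != nrow(bt)) NA else bf$id[which(bf$parent != bt$parent)[1]]
    stop("trees differ in topology (first differing branch id: ", diff1, ")",
         call. = FALSE)
  }
  if (lambda == 0) return(tree_frc)
  if (lambda == 1) return(tree_tlc)
  out <- tree_frc
  out$state <- "interpolated"
  out$nodes$x <- (1 - lambda) * tree_frc$nodes$x + lambda * tree_tlc$nodes$x
  out$nodes$y <- (1 - lambda) * tree_frc$nodes$y + lambda * tree_tlc$nodes$y
  out$nodes$z <- (1 - lambda) * tree_frc$nodes$z + lambda * tree_tlc$nodes$z
  out$branches$diameter_mm <- (1 - lambda) * bf$diameter_mm + lambda * bt$diameter_mm
  out$branches$length_mm <- (1 - lambda) * bf$length_mm + lambda * bt$length_mm
  out
}

#' Build the breathing-cycle geometry schedule
#'
#' Lays a uniform time grid of `steps_per_cycle + 1` points over one cycle
#' (both endpoints included, so the cycle closure is explicit), computes
#' the inflation fraction lambda(t) from the tidal waveform, and exposes
#' the interpolated tree at any grid step. With `interp_method = "akima"`
#' the lambda(t) knot series is evaluated through an Akima spline (the
#' reconstruction used for discrete imaging time points); with two
#' geometric anchor states the geometry itself is linear in lambda either
#' way, so both methods are endpoint-exact.
#'
#' @param tree_frc,tree_tlc Topology-sharing [airway_tree()] objects.
#' @param config A [breath_config()].
#' @return An object of class `breathing_schedule` with elements `times`,
#'   `volume_L`, `flow_Ls`, `lambda`, and `tree_at(i)` returning the tree
#'   at grid index i.
#' @export
breathing_schedule <- function(tree_frc, tree_tlc, config = breath_config()) {
  geometry_at(tree_frc, tree_tlc, 0) # topology check
  times <- seq(0, config$period_s, length.out = config$steps_per_cycle + 1L)
  vol <- volume_waveform(times, config)
  vol[length(vol)] <- vol[1L] # close the cycle exactly despite t %% T
  lam <- inflation_fraction(vol, config)
  if (config$interp_method == "akima") {
    lam <- pracma::akimaInterp(times, lam, times)
    lam <- pmin(pmax(lam, 0), 1)
  }
  structure(list(times = times, volume_L = vol,
                 flow_Ls = flow_waveform(times, config), lambda = lam,
                 config = config,
                 tree_at = function(i) geometry_at(tree_frc, tree_tlc, lam[i])),
            class = "breathing_schedule")
}

#' Indices of peak inspiration and peak expiration on a schedule
#'
#' Peak inspiration (PI) and peak expiration (PE) are the peak-flow
#' instants t = T/4 and t = 3T/4; the alveolar pressure drop is largest in
#' magnitude (and opposite in sign) at peak flow, not at the zero-flow
#' turnaround. `definition = "end_volume"` selects the end-inspiration
#' (t = T/2) and cycle-start instants instead.
#'
#' @param schedule A [breathing_schedule()].
#' @param definition `"peak_flow"` (default) or `"end_volume"`.
#' @return Named integer vector with elements `PI` and `PE`.
#' @export
phase_indices <- function(schedule, definition = c("peak_flow", "end_volume")) {
  definition <- match.arg(definition)
  tt <- schedule$times; T <- schedule$config$period_s
  tgt <- if (definition == "peak_flow") c(PI = T / 4, PE = 3 * T / 4)
         else c(PI = T / 2, PE = 0)
  vapply(tgt, function(x) which.min(abs(tt - x)), integer(1))
}
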