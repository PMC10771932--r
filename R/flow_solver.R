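# Dynamic 1D airway-network solver: terminal flow apportionment, viscous
# branch pressure drops (Poiseuille with optional Pedley entrance-effect
# correction), path-summed node pressures, and the alveolar / pleural /
# transpulmonary decomposition over the breathing cycle.

#' Pascals per centimeter of water
#' @export
PA_PER_CMH2O <- 98.0665

#' Solver configuration
#'
#' Physical constants and model switches for the 1D pressure solve. The
#' global respiratory compliance defaults to 0.2 L/cmH2O and is shared by
#' all subjects; the resistance closure is Poiseuille, optionally
#' multiplied by the Pedley entrance-effect factor
#' gamma = max(1, (c / (4 sqrt(2))) sqrt(Re D / L)) with c = 1.85.
#'
#' @param viscosity_Pas Dynamic viscosity of air, Pa s.
#' @param density_kgm3 Density of air, kg/m^3.
#' @param compliance_LcmH2O Global lung compliance, L/cmH2O.
#' @param model Resistance model, `"pedley"` (default) or `"poiseuille"`.
#' @param pedley_coef Pedley coefficient c (dimensionless).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(viscosity_Pas = 1.81e-5, density_kgm3 = 1.20,
                          compliance_LcmH2O = 0.2,
                          model = c("pedley", "poiseuille"),
                          pedley_coef = 1.85) {
  model <- match.arg(model)
  stopifnot(viscosity_Pas > 0, density_kgm3 > 0, compliance_LcmH2O > 0,
            pedley_coef > 0)
  structure(list(viscosity_Pas = viscosity_Pas, density_kgm3 = density_kgm3,
                 compliance_LcmH2O = compliance_LcmH2O, model = model,
                 pedley_coef = pedley_coef),
            class = "solver_config")
}

#' Terminal flow weights from lobar volume change
#'
#' Apportionment of the inlet flow: each lobe receives a share
#' proportional to its air-volume change between TLC and FRC (the
#' registration-derived regional ventilation), split across the lobe's
#' terminal branches either uniformly or in proportion to each terminal
#' branch's viscous conductance D^4 / L. The conductance split represents
#' the redistribution a resistive network imposes — a stochastically
#' constricted terminal receives correspondingly less flow — while
#' leaving every lobar share untouched. With no volumes given, lobes
#' share by terminal count.
#'
#' @param tree A completed [airway_tree()].
#' @param lobar_delta_L Optional named vector of lobar TLC - FRC volume
#'   changes (liters), names in the lobe labels.
#' @param within_lobe `"uniform"` (default) or `"conductance"`.
#' @return Named vector of nonnegative fractions summing to 1, named by
#'   terminal branch id.
#' @export
terminal_weights <- function(tree, lobar_delta_L = NULL,
                             within_lobe = c("uniform", "conductance")) {
  within_lobe <- match.arg(within_lobe)
  term <- terminal_branches(tree)
  br <- tree$branches
  ti <- match(term, br$id)
  lobes <- br$lobe[ti]
  rel <- if (within_lobe == "uniform") rep(1, length(term))
         else br$diameter_mm[ti]^4 / br$length_mm[ti]
  if (is.null(lobar_delta_L)) {
    w <- rel / sum(rel)
  } else {
    stopifnot(all(lobes %in% names(lobar_delta_L)), all(lobar_delta_L >= 0))
    share <- lobar_delta_L / sum(lobar_delta_L)
    within <- rel / stats::ave(rel, lobes, FUN = sum)
    w <- as.numeric(share[lobes]) * within
  }
  names(w) <- term
  w
}

#' Distribute an inlet flow over the branch network
#'
#' Each terminal receives `weight x Q_total`; internal branch flows are
#' the sums of their subtended terminal flows, so junction conservation
#' holds by construction.
#'
#' @param tree A completed [airway_tree()].
#' @param q_total_Ls Inlet flow, L/s (positive toward the periphery).
#' @param weights Per-terminal fractions summing to 1 (default uniform),
#'   named by terminal branch id.
#' @return Numeric vector of branch flows (L/s) aligned with
#'   `tree$branches`.
#' @export
distribute_flow <- function(tree, q_total_Ls, weights = NULL) {
  br <- tree$branches
  if (is.null(weights)) weights <- terminal_weights(tree)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("terminal weights must sum to 1 within 1e-9", call. = FALSE)
  }
  if (any(weights < 0)) stop("terminal weights must be nonnegative", call. = FALSE)
  flow <- numeric(nrow(br))
  ti <- match(as.integer(names(weights)), br$id)
  if (anyNA(ti)) stop("weight names must be terminal branch ids", call. = FALSE)
  flow[ti] <- weights * q_total_Ls
  idx <- match(br$parent, br$id)
  for (g in sort(unique(br$generation), decreasing = TRUE)) {
    at <- which(br$generation == g & !is.na(idx))
    if (!length(at)) next
    add <- tapply(flow[at], idx[at], sum)
    tgt <- as.integer(names(add))
    flow[tgt] <- flow[tgt] + as.numeric(add)
  }
  flow
}

#' Viscous pressure drop along a branch
#'
#' Energy-balance closure for a 1D branch:
#' dP = gamma(Re) x 128 mu L Q / (pi D^4), with gamma = 1 for the
#' Poiseuille model and gamma = max(1, (c / (4 sqrt 2)) sqrt(Re D / L))
#' for the Pedley entrance-effect model, Re = 4 rho |Q| / (pi mu D). The
#' sign of dP follows the sign of Q.
#'
#' @param diameter_mm,length_mm Branch geometry, mm (positive).
#' @param flow_Ls Branch flow, L/s (signed).
#' @param config A [solver_config()].
#' @return Pressure drop(s) in Pa.
#' @export
branch_pressure_drop <- function(diameter_mm, length_mm, flow_Ls,
                                 config = solver_config()) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0) ||
      any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("diameter and length must be positive", call. = FALSE)
  }
  D <- diameter_mm * 1e-3
  L <- length_mm * 1e-3
  Q <- flow_Ls * 1e-3
  mu <- config$viscosity_Pas
  dp <- 128 * mu * L * Q / (pi * D^4)
  if (config$model == "pedley") {
    re <- 4 * config$density_kgm3 * abs(Q) / (pi * mu * D)
    gamma <- pmax(1, config$pedley_coef / (4 * sqrt(2)) * sqrt(re * D / L))
    dp <- gamma * dp
  }
  dp
}

#' Solve node pressures for one time step
#'
#' The tracheal inlet is the zero-pressure reference; every node's
#' pressure is minus the running sum of branch pressure drops along the
#' unique path from the inlet. The alveolar pressure P_alv is the
#' arithmetic mean of the pressures at the distal nodes of terminal
#' branches, i.e. the (negative of the) mean pressure drop from trachea
#' to terminal bronchioles.
#'
#' @param tree The tree at this time step.
#' @param flows Branch flows from [distribute_flow()] (junction-conserving).
#' @param config A [solver_config()].
#' @return List with `node_pressures_Pa` (named by node id) and
#'   `p_alv_Pa`.
#' @export
solve_timestep <- function(tree, flows, config = solver_config()) {
  br <- tree$branches
  dp <- branch_pressure_drop(br$diameter_mm, br$length_mm, flows, config)
  p <- rep(NA_real_, nrow(tree$nodes))
  names(p) <- tree$nodes$id
  root <- which(is.na(br$parent))
  p[as.character(br$prox_node[root])] <- 0
  for (g in sort(unique(br$generation))) {
    at <- which(br$generation == g)
    p[as.character(br$dist_node[at])] <-
      p[as.character(br$prox_node[at])] - dp[at]
  }
  if (anyNA(p)) stop("disconnected node(s): ",
                     paste(names(p)[is.na(p)][1], collapse = ", "), call. = FALSE)
  term <- terminal_branches(tree)
  p_alv <- mean(p[as.character(br$dist_node[match(term, br$id)])])
  list(node_pressures_Pa = p, p_alv_Pa = p_alv)
}

#' Pleural and transpulmonary pressure from the alveolar pressure
#'
#' With a fixed global compliance C, the elastic recoil load is
#' P_tp = V / C (converted to Pa), and the pleural pressure follows from
#' the identity P_tp = P_alv - P_pl, so P_pl = P_alv - P_tp. All
#' pressures are gauge relative to the tracheal inlet.
#'
#' @param p_alv_Pa Alveolar pressure, Pa.
#' @param lung_air_volume_L Current lung air volume, liters (>= 0).
#' @param config A [solver_config()].
#' @return List with `p_pl_Pa` and `p_tp_Pa`.
#' @export
pleural_decomposition <- function(p_alv_Pa, lung_air_volume_L,
                                  config = solver_config()) {
  if (any(lung_air_volume_L < 0)) stop("lung air volume must be nonnegative",
                                       call. = FALSE)
  p_tp <- lung_air_volume_L / config$compliance_LcmH2O * PA_PER_CMH2O
  list(p_pl_Pa = p_alv_Pa - p_tp, p_tp_Pa = p_tp)
}

#' Transpulmonary pressure from the decomposition identity
#'
#' P_tp = P_alv - P_pl: the elastic recoil pressure implied by a pair of
#' alveolar and pleural pressures.
#'
#' @param p_alv_Pa,p_pl_Pa Pressures in Pa.
#' @return P_tp in Pa.
#' @export
transpulmonary_pressure <- function(p_alv_Pa, p_pl_Pa) p_alv_Pa - p_pl_Pa

#' Simulate pressures over one breathing cycle
#'
#' Loops the breathing schedule, distributing the sinusoidal inlet flow,
#' solving branch pressure drops on the interpolated geometry, and
#' decomposing alveolar, pleural and transpulmonary pressures at every
#' step (lung air volume = FRC air volume + V(t)). Reports the three
#' pressures at peak inspiration and peak expiration, the resistive
#' workload per cycle |contour integral of P_pl dV| and the P_pl-volume
#' hysteresis loop.
#'
#' @param tree_frc,tree_tlc Completed, topology-sharing trees.
#' @param breath A [breath_config()].
#' @param solver A [solver_config()].
#' @param weights Terminal weights (default: lobar volume-change shares
#'   when `lobar_delta_L` is given, else uniform).
#' @param lobar_delta_L Optional named lobar TLC - FRC volume changes, L.
#' @param within_lobe Within-lobe apportionment passed to
#'   [terminal_weights()] when `weights` is not supplied.
#' @param phase_definition Passed to [phase_indices()].
#' @return An object of class `pressure_solution`: a list with the
#'   per-step `series` data.frame (time, volume, flow, P_alv, P_pl, P_tp),
#'   phase summaries `at_PI` / `at_PE`, `workload_J`, and the `hysteresis`
#'   data.frame (volume vs P_pl).
#' @export
simulate_breath <- function(tree_frc, tree_tlc, breath = breath_config(),
                            solver = solver_config(), weights = NULL,
                            lobar_delta_L = NULL, within_lobe = "uniform",
                            phase_definition = "peak_flow") {
  sched <- breathing_schedule(tree_frc, tree_tlc, breath)
  if (is.null(weights)) weights <- terminal_weights(tree_frc, lobar_delta_L,
                                                    within_lobe)
  n <- length(sched$times)
  p_alv <- p_pl <- p_tp <- numeric(n)
  for (i in seq_len(n)) {
    tr <- sched$tree_at(i)
    flows <- distribute_flow(tr, sched$flow_Ls[i], weights)
    sol <- solve_timestep(tr, flows, solver)
    dec <- pleural_decomposition(sol$p_alv_Pa,
                                 breath$frc_volume_L + sched$volume_L[i],
                                 solver)
    p_alv[i] <- sol$p_alv_Pa; p_pl[i] <- dec$p_pl_Pa; p_tp[i] <- dec$p_tp_Pa
  }
  series <- data.frame(time_s = sched$times, volume_L = sched$volume_L,
                       flow_Ls = sched$flow_Ls, p_alv_Pa = p_alv,
                       p_pl_Pa = p_pl, p_tp_Pa = p_tp)
  ph <- phase_indices(sched, phase_definition)
  # resistive work per cycle: loop integral of P_pl dV (volume in m^3)
  v_m3 <- sched$volume_L * 1e-3
  workload <- abs(sum((p_pl[-1] + p_pl[-n]) / 2 * diff(v_m3)))
  structure(list(series = series,
                 at_PI = series[ph["PI"], ], at_PE = series[ph["PE"], ],
                 workload_J = workload,
                 hysteresis = series[, c("volume_L", "p_pl_Pa")]),
            class = "pressure_solution")
}

#' @export
print.pressure_solution <- function(x, ...) {
  cat("pressure_solution over one breathing cycle\n")
  cat(sprintf("  PI: P_alv %8.2f  P_pl %9.2f  P_tp %9.2f  Pa\n",
              x$at_PI$p_alv_Pa, x$at_PI$p_pl_Pa, x$at_PI$p_tp_Pa))
  cat(sprintf("  PE: P_alv %8.2f  P_pl %9.2f  P_tp %9.2f  Pa\n",
              x$at_PE$p_alv_Pa, x$at_PE$p_pl_Pa, x$at_PE$p_tp_Pa))
  cat(sprintf("  workload: %.4g J/cycle\n", x$workload_J))
  invisible(x)
}
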