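# 1D network solver: flow apportionment, viscous pressure drops, path-sum
# pressures, pleural decomposition and whole-cycle simulation.

test_that("flow distribution conserves at junctions and honors weights", {
  sym <- make_symmetric_tree(levels = 4)
  fl <- distribute_flow(sym, 1.0)
  br <- sym$branches
  for (g in 1:4) expect_equal(unique(fl[br$generation == g]), 1 / 2^(g - 1))
  expect_equal(distribute_flow(sym, 0), rep(0, nrow(br)))
  # junction conservation on every internal branch
  idx <- match(br$parent, br$id)
  for (i in which(br$id %in% br$parent)) {
    expect_equal(fl[i], sum(fl[which(idx == i)]), tolerance = 1e-12)
  }
  star <- make_star_tree(k = 3)
  w <- setNames(c(0.5, 0.3, 0.2), terminal_branches(star))
  fs <- distribute_flow(star, 1.0, w)
  expect_equal(fs[1], 1.0, tolerance = 1e-12)
  expect_equal(unname(fs[2:4]), c(0.5, 0.3, 0.2))
  expect_error(distribute_flow(star, 1.0, w * 1.01), "sum to 1")
})

test_that("branch pressure drop matches the hand-evaluated closed form", {
  cfg <- solver_config(model = "poiseuille")
  expect_equal(branch_pressure_drop(2, 20, 0, cfg), 0)
  # D = 2 mm, L = 20 mm, Q = 1e-5 m^3/s: 128 mu L Q / (pi D^4) = 9.218 Pa
  expect_equal(branch_pressure_drop(2, 20, 0.01, cfg), 9.218225,
               tolerance = 1e-5)
  expect_equal(branch_pressure_drop(2, 20, -0.01, cfg), -9.218225,
               tolerance = 1e-5) # sign follows flow
  # quartic diameter dependence
  expect_equal(branch_pressure_drop(1, 20, 0.01, cfg) /
                 branch_pressure_drop(2, 20, 0.01, cfg), 16, tolerance = 1e-9)
  expect_error(branch_pressure_drop(0, 20, 0.01, cfg), "positive")
})

test_that("the Pedley correction lower-bounds at Poiseuille", {
  pois <- solver_config(model = "poiseuille")
  ped <- solver_config(model = "pedley")
  # tiny flow: Re D / L small, gamma formula < 1, exact Poiseuille value
  expect_identical(branch_pressure_drop(2, 40, 1e-6, ped),
                   branch_pressure_drop(2, 40, 1e-6, pois))
  # high flow in a short wide branch: entrance effects amplify the drop
  expect_gt(branch_pressure_drop(10, 15, 1.0, ped),
            branch_pressure_drop(10, 15, 1.0, pois))
  expect_gte(branch_pressure_drop(4, 25, 0.3, ped),
             branch_pressure_drop(4, 25, 0.3, pois))
})

test_that("node pressures are path sums from the tracheal reference", {
  sym <- make_symmetric_tree(levels = 3)
  cfg <- solver_config()
  zero <- solve_timestep(sym, rep(0, nrow(sym$branches)), cfg)
  expect_true(all(zero$node_pressures_Pa == 0))
  expect_equal(zero$p_alv_Pa, 0)
  # single tube: P_alv = -dP, negative on inspiration
  tube <- make_tube(diameter_mm = 3, length_mm = 30)
  fl <- distribute_flow(tube, 0.5)
  sol <- solve_timestep(tube, fl, cfg)
  expect_equal(sol$p_alv_Pa, -branch_pressure_drop(3, 30, 0.5, cfg))
  expect_lt(sol$p_alv_Pa, 0)
  # brute-force path enumeration agrees to 1e-12
  fl <- distribute_flow(sym, 0.8)
  sol <- solve_timestep(sym, fl, cfg)
  brute <- brute_force_pressures(sym, fl, cfg)
  expect_equal(sol$node_pressures_Pa, brute[names(sol$node_pressures_Pa)],
               tolerance = 1e-12)
  term <- terminal_branches(sym)
  dist <- sym$branches$dist_node[match(term, sym$branches$id)]
  expect_equal(sol$p_alv_Pa, mean(brute[as.character(dist)]), tolerance = 1e-12)
})

test_that("pleural decomposition reproduces unit conversion and identity", {
  cfg <- solver_config()
  dec <- pleural_decomposition(0, 1.6, cfg)
  expect_equal(dec$p_tp_Pa, 8 * 98.0665)  # 1.6 L / 0.2 L/cmH2O = 8 cmH2O
  expect_equal(dec$p_pl_Pa, -784.532, tolerance = 1e-3)
  for (pa in c(-53, 0, 70)) for (v in c(1.2, 1.8, 2.4)) {
    d <- pleural_decomposition(pa, v, cfg)
    expect_identical(transpulmonary_pressure(pa, d$p_pl_Pa), d$p_tp_Pa)
  }
  expect_error(pleural_decomposition(0, -1, cfg), "nonnegative")
})

breath_pair <- function(taper = 0.8) {
  frc <- make_symmetric_tree(levels = 4, diameter_mm = 5, taper = taper,
                             state = "FRC")
  tlc <- make_symmetric_tree(levels = 4, diameter_mm = 7, taper = taper,
                             state = "TLC")
  list(frc = frc, tlc = tlc,
       cfg = breath_config(frc_volume_L = 2, tlc_volume_L = 5))
}

test_that("a simulated cycle shows the expected pressure signs and
           identities", {
  p <- breath_pair()
  sim <- simulate_breath(p$frc, p$tlc, p$cfg)
  expect_lt(sim$at_PI$p_alv_Pa, 0)
  expect_gt(sim$at_PE$p_alv_Pa, 0)
  expect_lt(sim$at_PI$p_pl_Pa, 0)
  with(sim$series, expect_equal(p_tp_Pa, p_alv_Pa - p_pl_Pa, tolerance = 1e-14))
  expect_gt(sim$workload_J, 0)
  # hysteresis: the pleural path differs between inspiration and expiration
  n <- nrow(sim$series)
  expect_false(isTRUE(all.equal(sim$series$p_pl_Pa[2:20],
                                rev(sim$series$p_pl_Pa[22:40]))))
})

test_that("halving all diameters scales the alveolar drop sixteenfold under
           Poiseuille", {
  p <- breath_pair()
  pois <- solver_config(model = "poiseuille")
  base <- simulate_breath(p$frc, p$tlc, p$cfg, pois)
  half_frc <- p$frc; half_tlc <- p$tlc
  half_frc$branches$diameter_mm <- half_frc$branches$diameter_mm / 2
  half_tlc$branches$diameter_mm <- half_tlc$branches$diameter_mm / 2
  halved <- simulate_breath(half_frc, half_tlc, p$cfg, pois)
  expect_equal(halved$at_PI$p_alv_Pa / base$at_PI$p_alv_Pa, 16,
               tolerance = 1e-9)
  # any uniform shrink strictly deepens the inspiratory drop
  s_frc <- p$frc; s_tlc <- p$tlc
  s_frc$branches$diameter_mm <- s_frc$branches$diameter_mm * 0.9
  s_tlc$branches$diameter_mm <- s_tlc$branches$diameter_mm * 0.9
  shrunk <- simulate_breath(s_frc, s_tlc, p$cfg, pois)
  expect_gt(abs(shrunk$at_PI$p_alv_Pa), abs(base$at_PI$p_alv_Pa))
})

test_that("lobar volume-change weights drive the flow split", {
  star <- make_star_tree(k = 3)
  star$branches$lobe[2:4] <- c("LUL", "LLL", "RLL")
  w <- terminal_weights(star, c(LUL = 1.5, LLL = 1.0, RLL = 0.5))
  expect_equal(sum(w), 1)
  expect_equal(unname(w[as.character(2:4)]), c(0.5, 1 / 3, 1 / 6))
})
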