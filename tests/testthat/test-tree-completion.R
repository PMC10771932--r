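# Volume filling, Horsfield ordering and stochastic diameter assignment.

seed_for <- function(points, lobe = "LUL") {
  lobe_seed(lobe, points, tlc_volume_L = 1, frc_volume_L = 0.5)
}

test_that("a point cloud entirely within the length limit grows nothing", {
  tube <- make_tube(lobe = "LUL") # distal node at (0, 0, -20)
  pts <- cbind(runif(20, -1, 1), runif(20, -1, 1), -20 + runif(20, -1, 1))
  grown <- fill_lobe(tube, seed_for(pts))
  expect_equal(nrow(grown$branches), 1L)
})

test_that("two well-separated points give exactly two child branches, one
           toward each point", {
  tube <- make_tube(lobe = "LUL")
  pts <- rbind(c(-20, 0, -50), c(20, 0, -50))
  grown <- fill_lobe(tube, seed_for(pts), point_threshold = 1)
  expect_equal(nrow(grown$branches), 3L)
  kids <- grown$branches[!grown$branches$resolved, ]
  expect_equal(kids$generation, c(2L, 2L))
  tips <- grown$nodes[match(kids$dist_node, grown$nodes$id), c("x", "y", "z")]
  # children at branching_fraction = 0.4 of the way from (0,0,-20) to each point
  expect_equal(sort(tips$x), c(-8, 8))
  expect_equal(tips$z, c(-32, -32))
  expect_equal(kids$length_mm, rep(0.4 * sqrt(20^2 + 30^2), 2))
})

test_that("scattered clouds terminate with bounded terminal counts and are
           deterministic", {
  tube <- make_tube(diameter_mm = 6, length_mm = 20)
  set.seed(11)
  pts <- cbind(runif(256, -40, 40), runif(256, -40, 40), runif(256, -90, -30))
  g1 <- fill_lobe(tube, seed_for(pts), point_threshold = 1)
  g2 <- fill_lobe(tube, seed_for(pts), point_threshold = 1)
  expect_identical(g1$branches, g2$branches) # deterministic given the cloud
  term <- terminal_branches(g1)
  expect_lte(length(term), 256)
  expect_gt(length(term), 16)
  expect_no_error(validate_airway_tree(g1))
})

test_that("raising the point threshold never increases the terminal count", {
  tube <- make_tube(diameter_mm = 6, length_mm = 20)
  set.seed(12)
  pts <- cbind(runif(128, -40, 40), runif(128, -40, 40), runif(128, -90, -30))
  counts <- sapply(c(1, 2, 4, 8), function(th) {
    length(terminal_branches(fill_lobe(tube, seed_for(pts), point_threshold = th)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate point sets are rejected", {
  tube <- make_tube()
  expect_error(fill_lobe(tube, seed_for(matrix(5, 4, 3))), "degenerate")
  expect_error(seed_for(matrix(numeric(0), 0, 3)), ">= 2 rows")
  lll <- seed_for(rbind(c(0, 0, -40), c(5, 0, -45)), lobe = "LLL")
  expect_error(fill_lobe(tube, lll), "attachment")
})

test_that("Horsfield orders follow the bottom-up max-plus-one rule", {
  expect_equal(assign_horsfield_orders(make_tube())$branches$order, 1L)
  sym <- assign_horsfield_orders(make_symmetric_tree(levels = 2))
  expect_equal(sym$branches$order, c(2L, 1L, 1L))
  # asymmetric: root's children have orders {1, 2} -> root order 3
  deep <- make_symmetric_tree(levels = 3)
  pruned <- deep
  drop <- c(4L, 5L) # both grandchildren under child 2
  pruned$branches <- pruned$branches[!pruned$branches$id %in% drop, ]
  pruned <- assign_horsfield_orders(pruned)
  ord <- setNames(pruned$branches$order, pruned$branches$id)
  expect_equal(unname(ord["2"]), 1L) # now terminal
  expect_equal(unname(ord["3"]), 2L) # still carries two terminals
  expect_equal(unname(ord["1"]), 3L) # max(1, 2) + 1
})

test_that("the healthy-diameter power law is anchored and monotone", {
  expect_equal(healthy_diameter_from_order(6, 6, 4.5), 4.5)
  expect_equal(healthy_diameter_from_order(1, 6, 4.5, ratio = 1.5),
               4.5 * 1.5^-5, tolerance = 1e-9)
  expect_equal(4.5 * 1.5^-5, 0.5925926, tolerance = 1e-6)
  d <- healthy_diameter_from_order(1:10, 6, 4.5, ratio = 1.4)
  expect_true(all(diff(d) > 0))
  # near-unity ratio flattens the law
  d1 <- healthy_diameter_from_order(c(1, 10), 6, 4.5, ratio = 1 + 1e-9)
  expect_equal(d1[1], d1[2], tolerance = 1e-6)
  expect_error(healthy_diameter_from_order(1, 6, -1), "positive")
  expect_error(healthy_diameter_from_order(1, 6, 4.5, ratio = 0.9), "exceed 1")
})

grown_fixture <- function(npts = 64, seed = 13) {
  # wide attachment: the measured caliber exceeds every anchored healthy
  # child value, so the parent cap binds only between grown branches
  base <- make_attachment_tube(diameter_mm = 12, length_mm = 20)
  set.seed(seed)
  pts <- cbind(runif(npts, -40, 40), runif(npts, -40, 40),
               runif(npts, -110, -50))
  assign_horsfield_orders(fill_lobe(base, seed_for(pts)))
}

test_that("deterministic multiplier distributions scale unresolved branches
           exactly", {
  demo <- demographics(0, 1.70, 60)
  tree <- grown_fixture()
  un <- !tree$branches$resolved
  # with mean 1, SD 0: diameters equal the anchored healthy power law (capped)
  st1 <- data.frame(lobe = "LUL", mean = 1, sd = 0, n = 5, state = "FRC")
  t1 <- assign_unresolved_diameters(tree, demo, stats = st1, ratio = 1.4)
  st08 <- data.frame(lobe = "LUL", mean = 0.8, sd = 0, n = 5, state = "FRC")
  t08 <- assign_unresolved_diameters(tree, demo, stats = st08, ratio = 1.4)
  expect_equal(t08$branches$diameter_mm[un], 0.8 * t1$branches$diameter_mm[un],
               tolerance = 1e-12)
  # an uncapped unresolved branch sits exactly on the anchored power law
  br1 <- t1$branches
  anchor_pred <- predict_generation_diameter(demo, "LUL", 2)
  expected <- healthy_diameter_from_order(br1$order[un], br1$order[2],
                                          anchor_pred, 1.4)
  free <- br1$diameter_mm[un] < br1$diameter_mm[match(br1$parent, br1$id)][un] - 1e-12
  expect_true(any(free))
  expect_equal(br1$diameter_mm[un][free], expected[free], tolerance = 1e-12)
})

test_that("unresolved diameters respect parent caps and recover their
           generator mean", {
  demo <- demographics(0, 1.70, 60)
  tree <- grown_fixture()
  st <- data.frame(lobe = "LUL", mean = 0.85, sd = 0.13, n = 5, state = "FRC")
  set.seed(21)
  done <- assign_unresolved_diameters(tree, demo, stats = st, ratio = 1.4)
  br <- done$branches
  idx <- match(br$parent, br$id)
  kids <- which(!is.na(idx) & !br$resolved)
  expect_true(all(br$diameter_mm[kids] <= br$diameter_mm[idx[kids]] + 1e-12))
  expect_error(assign_unresolved_diameters(tree, demo,
                                           stats = st[0, ], ratio = 1.4),
               "missing constriction statistics")
  # Monte-Carlo: empirical multiplier mean near 0.85 over many branches
  big <- grown_fixture(npts = 600, seed = 22)
  set.seed(23)
  filled <- assign_unresolved_diameters(big, demo, stats = st, ratio = 1.4)
  un <- !big$branches$resolved
  # recompute implied multipliers from the healthy law (uncapped branches)
  healthy <- healthy_diameter_from_order(big$branches$order[un],
                                         big$branches$order[2],
                                         predict_generation_diameter(demo, "LUL", 2),
                                         1.4)
  mult <- filled$branches$diameter_mm[un] / healthy
  uncapped <- filled$branches$diameter_mm[un] <
    filled$branches$diameter_mm[match(filled$branches$parent,
                                      filled$branches$id)][un] - 1e-12
  expect_gt(sum(uncapped), 200)
  expect_equal(mean(mult[uncapped]), 0.85, tolerance = 0.03)
})

test_that("a completed default subject stays valid with plausible terminal
           calibers", {
  set.seed(31)
  s <- generate_subject("A", id = "T1")
  sc <- complete_subject(s)
  expect_no_error(validate_airway_tree(sc$tree_tlc))
  expect_no_error(validate_airway_tree(sc$tree_frc))
  br <- sc$tree_tlc$branches
  expect_gt(nrow(br), sum(br$resolved)) # completion added branches
  term <- terminal_branches(sc$tree_tlc)
  md <- mean(br$diameter_mm[match(term, br$id)])
  expect_gt(md, 0.3); expect_lt(md, 0.9)
  # every unresolved branch was grown into a lobe
  expect_true(all(br$lobe[!br$resolved] %in% c("LUL", "LLL", "RUL", "RML", "RLL")))
})
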