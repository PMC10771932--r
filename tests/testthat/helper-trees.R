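# In-code fixtures: minimal airway trees built by hand for solver and
# completion tests.

# a single straight tube along -z (terminal, lobe-labelled)
make_tube <- function(diameter_mm = 2, length_mm = 20, lobe = "LUL") {
  nodes <- data.frame(id = 1:2, x = 0, y = 0, z = c(0, -length_mm))
  branches <- data.frame(id = 1L, parent = NA_integer_, prox_node = 1L,
                         dist_node = 2L, lobe = lobe, generation = 1L,
                         order = 1L, diameter_mm = diameter_mm,
                         length_mm = length_mm, resolved = TRUE)
  airway_tree(nodes, branches, state = "FRC")
}

# central root plus one lobe-labelled attachment branch at generation 2
# (the shallowest generation with a tabulated healthy ratio)
make_attachment_tube <- function(diameter_mm = 8, length_mm = 20,
                                 lobe = "LUL") {
  nodes <- data.frame(id = 1:3, x = 0, y = 0, z = c(0, -length_mm,
                                                    -2 * length_mm))
  branches <- data.frame(id = 1:2, parent = c(NA_integer_, 1L),
                         prox_node = 1:2, dist_node = 2:3,
                         lobe = c("central", lobe), generation = 1:2,
                         order = NA_integer_,
                         diameter_mm = c(diameter_mm * 1.5, diameter_mm),
                         length_mm = length_mm, resolved = TRUE)
  airway_tree(nodes, branches, state = "FRC")
}

# full symmetric binary tree with `levels` generations, identical geometry
# within a generation
make_symmetric_tree <- function(levels = 3, diameter_mm = 4, length_mm = 15,
                                taper = 0.8, state = "FRC") {
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0)
  branches <- data.frame(id = 1L, parent = NA_integer_, prox_node = 1L,
                         dist_node = 2L, lobe = "central", generation = 1L,
                         order = NA_integer_, diameter_mm = diameter_mm,
                         length_mm = length_mm, resolved = TRUE)
  nodes <- rbind(nodes, data.frame(id = 2L, x = 0, y = 0, z = -length_mm))
  nid <- 2L; bid <- 1L
  frontier <- 1L
  for (g in seq_len(levels - 1)) {
    nxt <- integer(0)
    for (p in frontier) {
      prow <- branches[branches$id == p, ]
      for (k in 1:2) {
        nid <- nid + 1L; bid <- bid + 1L
        off <- (2 * k - 3) * length_mm / (g + 1)
        pn <- nodes[nodes$id == prow$dist_node, ]
        nodes <- rbind(nodes, data.frame(id = nid, x = pn$x + off, y = pn$y,
                                         z = pn$z - length_mm))
        branches <- rbind(branches, data.frame(
          id = bid, parent = p, prox_node = prow$dist_node, dist_node = nid,
          lobe = if (g == levels - 1) "LUL" else "central",
          generation = g + 1L, order = NA_integer_,
          diameter_mm = diameter_mm * taper^g, length_mm = length_mm,
          resolved = TRUE))
        nxt <- c(nxt, bid)
      }
    }
    frontier <- nxt
  }
  airway_tree(nodes, branches, state = state)
}

# root with k terminal children (for weighted-flow tests)
make_star_tree <- function(k = 3, diameter_mm = 4, length_mm = 15) {
  nodes <- data.frame(id = seq_len(k + 2),
                      x = c(0, 0, seq_len(k)), y = 0,
                      z = c(0, -length_mm, rep(-2 * length_mm, k)))
  branches <- rbind(
    data.frame(id = 1L, parent = NA_integer_, prox_node = 1L, dist_node = 2L,
               lobe = "central", generation = 1L, order = NA_integer_,
               diameter_mm = diameter_mm, length_mm = length_mm, resolved = TRUE),
    data.frame(id = 1L + seq_len(k), parent = 1L, prox_node = 2L,
               dist_node = 2L + seq_len(k), lobe = "LUL", generation = 2L,
               order = NA_integer_, diameter_mm = diameter_mm * 0.7,
               length_mm = length_mm, resolved = TRUE))
  airway_tree(nodes, branches, state = "FRC")
}

# brute-force node pressures: sum branch drops along each root-to-node path
brute_force_pressures <- function(tree, flows, config = solver_config()) {
  br <- tree$branches
  dp <- branch_pressure_drop(br$diameter_mm, br$length_mm, flows, config)
  p <- stats::setNames(rep(NA_real_, nrow(tree$nodes)), tree$nodes$id)
  root <- which(is.na(br$parent))
  p[as.character(br$prox_node[root])] <- 0
  for (i in seq_len(nrow(br))) {
    path <- i; j <- i
    while (!is.na(br$parent[j])) { j <- match(br$parent[j], br$id); path <- c(path, j) }
    p[as.character(br$dist_node[i])] <- -sum(dp[path])
  }
  p
}
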