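# Completion of the conducting tree beyond CT resolution: recursive
# volume filling of lobar point clouds, bottom-up Horsfield ordering, a
# power-law healthy diameter per order, and stochastic per-lobe
# constriction multipliers.

#' Lobe seed for volume filling
#'
#' A lobe label, a point cloud (mm) filling the lobar volume toward which
#' unresolved branches are grown, and the lobar air volumes at TLC and
#' FRC (liters).
#'
#' @param lobe Lobe label.
#' @param points Numeric matrix with columns x, y, z (>= 2 rows).
#' @param tlc_volume_L,frc_volume_L Lobar air volumes in liters
#'   (TLC > FRC > 0).
#' @return An object of class `lobe_seed`.
#' @export
lobe_seed <- function(lobe, points, tlc_volume_L, frc_volume_L) {
  points <- as.matrix(points)
  if (!lobe %in% LOBES) stop("unknown lobe: ", lobe, call. = FALSE)
  if (nrow(points) < 2 || ncol(points) != 3) {
    stop("lobe seed needs a point cloud with >= 2 rows and 3 columns", call. = FALSE)
  }
  if (!(tlc_volume_L > frc_volume_L && frc_volume_L > 0)) {
    stop("lobar volumes must satisfy TLC > FRC > 0", call. = FALSE)
  }
  structure(list(lobe = lobe, points = unname(points),
                 tlc_volume_L = tlc_volume_L, frc_volume_L = frc_volume_L),
            class = "lobe_seed")
}

# unit vector perpendicular to `dir`, deterministic
.perp_unit <- function(dir) {
  ref <- if (abs(dir[3]) < 0.9 * sqrt(sum(dir^2))) c(0, 0, 1) else c(1, 0, 0)
  n <- c(dir[2] * ref[3] - dir[3] * ref[2],
         dir[3] * ref[1] - dir[1] * ref[3],
         dir[1] * ref[2] - dir[2] * ref[1])
  n / sqrt(sum(n^2))
}

# normal of the splitting plane: the plane contains the branch direction
# and passes through the centroid, oriented along the dominant spread of
# the points perpendicular to the branch
.split_normal <- function(points, ctr, dir) {
  X <- sweep(points, 2, ctr)
  X <- X - outer(as.vector(X %*% dir), dir) # project out the branch axis
  if (max(abs(X)) < 1e-9) return(.perp_unit(dir))
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  v / sqrt(sum(v^2))
}

#' Grow unresolved branches into a lobe by recursive volume filling
#'
#' Tawhai-style recursive bisection: each growing branch owns a subset of
#' the lobar point cloud; the subset is split by the plane through its
#' centroid that contains the branch direction; a child branch is grown
#' from the parent's distal node a fraction of the way toward each half's
#' centroid; recursion continues into halves holding more than
#' `point_threshold` points while candidate branch lengths stay above
#' `length_limit`. The construction is deterministic given the point
#' cloud; grown branches are flagged unresolved, inherit the lobe label,
#' and carry a provisional diameter (the parent's) until
#' [assign_unresolved_diameters()] runs. Growth starts from every resolved
#' branch of the lobe that has no resolved child (its attachment
#' branches), with the points partitioned by nearest attachment.
#'
#' @param tree An [airway_tree()] containing resolved branches of
#'   `seed$lobe`.
#' @param seed A [lobe_seed()].
#' @param branching_fraction Fraction of the distance to the half-centroid
#'   used as child length (default 0.4).
#' @param length_limit Minimum candidate branch length in mm (default 1.2).
#' @param point_threshold Point count at or below which a branch is
#'   terminal (default 1).
#' @return The tree with the grown subtree appended.
#' @export
fill_lobe <- function(tree, seed, branching_fraction = 0.4,
                      length_limit = 1.2, point_threshold = 1) {
  stopifnot(inherits(seed, "lobe_seed"))
  pts <- seed$points
  if (nrow(pts) == 0) stop("empty point set for lobe ", seed$lobe, call. = FALSE)
  if (max(apply(pts, 2, function(v) diff(range(v)))) < 1e-9) {
    stop("degenerate (coincident) point set for lobe ", seed$lobe, call. = FALSE)
  }
  br <- tree$branches
  in_lobe <- br$resolved & br$lobe == seed$lobe
  if (!any(in_lobe)) {
    stop("tree has no resolved attachment branch for lobe ", seed$lobe, call. = FALSE)
  }
  has_res_child <- br$id %in% br$parent[br$resolved]
  attach <- br[in_lobe & !has_res_child, ]

  nodes <- tree$nodes
  node_xyz <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(node_xyz) <- nodes$id
  next_branch <- max(br$id) + 1L
  next_node <- max(nodes$id) + 1L
  acc_br <- list(); acc_nd <- list()

  grow <- function(parent_id, parent_gen, parent_diam, origin, dir, points) {
    if (nrow(points) <= point_threshold) return(invisible(NULL))
    ctr <- colMeans(points)
    nrm <- .split_normal(points, ctr, dir)
    s <- as.vector((points - matrix(ctr, nrow(points), 3, byrow = TRUE)) %*% nrm)
    for (half in list(points[s < 0, , drop = FALSE],
                      points[s >= 0, , drop = FALSE])) {
      if (nrow(half) < point_threshold || nrow(half) == nrow(points)) next
      hc <- colMeans(half)
      vec <- hc - origin
      len <- branching_fraction * sqrt(sum(vec^2))
      if (len < length_limit) next
      dist <- origin + branching_fraction * vec
      nid <- next_node; next_node <<- next_node + 1L
      bid <- next_branch; next_branch <<- next_branch + 1L
      acc_nd[[length(acc_nd) + 1L]] <<- c(id = nid, dist)
      acc_br[[length(acc_br) + 1L]] <<- list(
        id = bid, parent = parent_id, origin_node = NA_integer_, dist_node = nid,
        lobe = seed$lobe, generation = parent_gen + 1L,
        diameter_mm = parent_diam, length_mm = len)
      grow(bid, parent_gen + 1L, parent_diam, dist, vec / sqrt(sum(vec^2)), half)
    }
    invisible(NULL)
  }

  # partition the cloud by nearest attachment distal node
  att_xyz <- node_xyz[as.character(attach$dist_node), , drop = FALSE]
  d2 <- sapply(seq_len(nrow(attach)), function(i) {
    rowSums((pts - matrix(att_xyz[i, ], nrow(pts), 3, byrow = TRUE))^2)
  })
  owner <- max.col(-as.matrix(d2))
  for (i in seq_len(nrow(attach))) {
    sub <- pts[owner == i, , drop = FALSE]
    if (!nrow(sub)) next
    origin <- att_xyz[i, ]
    prox <- node_xyz[as.character(attach$prox_node[i]), ]
    dir <- origin - prox
    dir <- dir / sqrt(sum(dir^2))
    grow(attach$id[i], attach$generation[i], attach$diameter_mm[i],
         origin, dir, sub)
  }

  if (length(acc_br)) {
    new_nd <- as.data.frame(do.call(rbind, acc_nd))
    names(new_nd) <- c("id", "x", "y", "z")
    new_br <- do.call(rbind, lapply(acc_br, function(b) {
      data.frame(id = b$id, parent = b$parent, prox_node = NA_integer_,
                 dist_node = b$dist_node, lobe = b$lobe,
                 generation = b$generation, order = NA_integer_,
                 diameter_mm = b$diameter_mm, length_mm = b$length_mm,
                 resolved = FALSE, stringsAsFactors = FALSE)
    }))
    all_br <- rbind(br[, names(new_br)], new_br)
    # connect: each new branch starts at its parent's distal node
    all_br$prox_node <- all_br$dist_node[match(all_br$parent, all_br$id)]
    all_br$prox_node[is.na(all_br$parent)] <- br$prox_node[is.na(br$parent)]
    tree$nodes <- rbind(nodes, new_nd)
    tree$branches <- all_br
  }
  tree
}

#' Assign Horsfield orders bottom-up
#'
#' Terminal branches receive order 1; every parent receives
#' max(child orders) + 1. Deterministic on a valid tree.
#'
#' @param tree An [airway_tree()].
#' @return The tree with the `order` column filled.
#' @export
assign_horsfield_orders <- function(tree) {
  br <- tree$branches
  ord <- rep(NA_integer_, nrow(br))
  idx <- match(br$parent, br$id)
  for (g in sort(unique(br$generation), decreasing = TRUE)) {
    at <- which(br$generation == g)
    for (i in at) {
      kids <- which(idx == i)
      ord[i] <- if (length(kids)) max(ord[kids]) + 1L else 1L
    }
  }
  tree$branches$order <- ord
  tree
}

#' Healthy diameter from Horsfield order (power law)
#'
#' D(order) = anchor_diameter x ratio^(order - anchor_order): the
#' classical geometric progression of airway caliber down the ordered
#' tree, anchored at a branch of known order and healthy diameter.
#'
#' @param order Horsfield order(s) to evaluate at.
#' @param anchor_order Order of the anchor branch.
#' @param anchor_diameter_mm Healthy diameter of the anchor branch, mm.
#' @param ratio Per-order diameter ratio (> 1; default 1.4, the
#'   literature value for human conducting airways).
#' @return Diameter(s) in mm, strictly increasing in `order`.
#' @export
healthy_diameter_from_order <- function(order, anchor_order, anchor_diameter_mm,
                                        ratio = 1.4) {
  if (any(!is.finite(anchor_diameter_mm)) || any(anchor_diameter_mm <= 0)) {
    stop("anchor diameter must be positive", call. = FALSE)
  }
  if (!is.finite(ratio) || ratio <= 1) stop("ratio must exceed 1", call. = FALSE)
  anchor_diameter_mm * ratio^(order - anchor_order)
}

#' Assign stochastic diameters to unresolved branches
#'
#' For each lobe, the healthy caliber of every grown branch follows the
#' Horsfield power law anchored at the lobe's attachment branch *predicted*
#' healthy diameter (so constriction enters only through the multipliers),
#' and is then scaled by an independent per-branch draw from the lobe's
#' Dave* distribution. A child is finally capped at its parent's diameter
#' to rule out caliber inversions.
#'
#' @param tree Tree with Horsfield orders assigned.
#' @param demo A [demographics()] object.
#' @param table A [daver_table()].
#' @param stats `constriction_stats` covering every lobe that holds
#'   unresolved branches.
#' @param ratio Horsfield diameter ratio, see
#'   [healthy_diameter_from_order()].
#' @return The completed tree.
#' @export
assign_unresolved_diameters <- function(tree, demo, table = daver_table(),
                                        stats, ratio = 1.4) {
  br <- tree$branches
  if (any(is.na(br$order))) stop("assign Horsfield orders first", call. = FALSE)
  unres <- which(!br$resolved)
  if (!length(unres)) return(tree)
  need <- unique(br$lobe[unres])
  missing <- setdiff(need, stats$lobe)
  if (length(missing)) {
    stop("missing constriction statistics for lobe(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(br$parent, br$id)
  # anchor of an unresolved branch: first resolved ancestor
  anchor <- rep(NA_integer_, nrow(br))
  for (i in order(br$generation)) {
    if (br$resolved[i]) next
    p <- idx[i]
    anchor[i] <- if (br$resolved[p]) p else anchor[p]
  }
  dtr <- predict_trachea_diameter(demo)
  for (lb in need) {
    at <- unres[br$lobe[unres] == lb]
    a <- anchor[at]
    pred_anchor <- dtr * lookup_daver(br$lobe[a], br$generation[a], table)
    healthy <- healthy_diameter_from_order(br$order[at], br$order[a],
                                           pred_anchor, ratio)
    mult <- sample_constriction_multiplier(stats, lb, n = length(at))
    br$diameter_mm[at] <- healthy * mult
  }
  # child <= parent, top-down
  for (i in order(br$generation)) {
    if (br$resolved[i] || is.na(idx[i])) next
    br$diameter_mm[i] <- min(br$diameter_mm[i], br$diameter_mm[idx[i]])
  }
  tree$branches <- br
  validate_airway_tree(tree)
  tree
}

#' Complete a resolved tree into lobar volumes
#'
#' Convenience wrapper: volume-fills every lobe seed, assigns Horsfield
#' orders, computes per-lobe Dave* statistics from the resolved branches,
#' and assigns stochastic diameters to the grown branches.
#'
#' @param tree A resolved [airway_tree()].
#' @param seeds List of [lobe_seed()] objects.
#' @param demo A [demographics()] object.
#' @param table A [daver_table()].
#' @param stats Optional precomputed `constriction_stats`; defaults to
#'   statistics taken from the tree's own resolved branches.
#' @param ... Passed to [fill_lobe()] and [assign_unresolved_diameters()].
#' @inheritParams fill_lobe
#' @inheritParams healthy_diameter_from_order
#' @return The completed tree.
#' @export
complete_tree <- function(tree, seeds, demo, table = daver_table(),
                          stats = NULL, branching_fraction = 0.4,
                          length_limit = 1.2, point_threshold = 1,
                          ratio = 1.4) {
  for (seed in seeds) {
    tree <- fill_lobe(tree, seed, branching_fraction = branching_fraction,
                      length_limit = length_limit,
                      point_threshold = point_threshold)
  }
  tree <- assign_horsfield_orders(tree)
  if (is.null(stats)) stats <- lobar_constriction_stats(tree, demo, table)
  assign_unresolved_diameters(tree, demo, table, stats, ratio = ratio)
}
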