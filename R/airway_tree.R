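# Rooted airway-tree container: a node table (3D coordinates, mm) and a
# branch table (connectivity, lobe labels, generations, Horsfield orders,
# diameters, lengths, CT-resolved flags), plus a lung-volume state tag.

#' Construct an airway tree
#'
#' An airway tree couples a node table (`id, x, y, z`, coordinates in mm)
#' with a branch table (`id, parent, prox_node, dist_node, lobe,
#' generation, order, diameter_mm, length_mm, resolved`). Exactly one root
#' branch (the trachea) has `parent = NA`; every other branch starts at
#' its parent's distal node; generations increase by one from parent to
#' child. `lobe` is one of the five lobe labels or `"central"` for the
#' trachea and main/intermediate bronchi. `order` (Horsfield order) may be
#' `NA` until assigned.
#'
#' @param nodes data.frame with columns `id, x, y, z`.
#' @param branches data.frame with the columns listed above.
#' @param state Lung-volume state: `"TLC"`, `"FRC"` or `"interpolated"`.
#' @param validate Check the structural invariants (default `TRUE`).
#' @return An object of class `airway_tree`.
#' @export
airway_tree <- function(nodes, branches, state = c("TLC", "FRC", "interpolated"),
                        validate = TRUE) {
  state <- match.arg(state)
  if (!("order" %in% names(branches))) branches$order <- NA_integer_
  tree <- structure(list(nodes = as.data.frame(nodes),
                         branches = as.data.frame(branches),
                         state = state),
                    class = "airway_tree")
  rownames(tree$nodes) <- NULL
  rownames(tree$branches) <- NULL
  if (validate) validate_airway_tree(tree)
  tree
}

#' Validate the structural invariants of an airway tree
#'
#' Checks: a single root with no parent; connectivity and acyclicity;
#' child branches starting at the parent's distal node; positive diameters
#' and lengths; generation increments of one; lobe labels on every
#' terminal branch.
#'
#' @param tree An [airway_tree()].
#' @return The tree, invisibly; errors describe the first violation found.
#' @export
validate_airway_tree <- function(tree) {
  nodes <- tree$nodes; br <- tree$branches
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  req <- c("id", "parent", "prox_node", "dist_node", "lobe", "generation",
           "diameter_mm", "length_mm", "resolved")
  miss <- setdiff(req, names(br))
  if (length(miss)) stop("branch table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(br$id)) stop("duplicate branch ids", call. = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  root <- which(is.na(br$parent))
  if (length(root) != 1) stop("tree must have exactly one root branch", call. = FALSE)
  if (!all(br$parent[-root] %in% br$id)) {
    stop("branch parent ids must reference existing branches", call. = FALSE)
  }
  if (!all(c(br$prox_node, br$dist_node) %in% nodes$id)) {
    stop("branch endpoints must reference existing nodes", call. = FALSE)
  }
  bad <- which(!is.finite(br$diameter_mm) | br$diameter_mm <= 0 |
                 !is.finite(br$length_mm) | br$length_mm <= 0)
  if (length(bad)) stop("nonpositive diameter or length at branch id ",
                        br$id[bad[1]], call. = FALSE)
  idx <- match(br$parent, br$id)
  nonroot <- !is.na(idx)
  if (any(br$prox_node[nonroot] != br$dist_node[idx[nonroot]])) {
    first <- br$id[nonroot][which(br$prox_node[nonroot] != br$dist_node[idx[nonroot]])[1]]
    stop("branch ", first, " does not start at its parent's distal node", call. = FALSE)
  }
  if (any(br$generation[nonroot] != br$generation[idx[nonroot]] + 1)) {
    first <- br$id[nonroot][which(br$generation[nonroot] !=
                                    br$generation[idx[nonroot]] + 1)[1]]
    stop("branch ", first, " violates generation = parent generation + 1", call. = FALSE)
  }
  if (br$generation[root] != 1) stop("root branch must be generation 1", call. = FALSE)
  # acyclic: walking parents from every branch must reach the root
  depth <- rep(NA_integer_, nrow(br))
  depth[root] <- 0L
  remaining <- which(is.na(depth))
  for (pass in seq_len(nrow(br))) {
    if (!length(remaining)) break
    ready <- remaining[!is.na(depth[idx[remaining]])]
    if (!length(ready)) stop("tree is disconnected or cyclic", call. = FALSE)
    depth[ready] <- depth[idx[ready]] + 1L
    remaining <- setdiff(remaining, ready)
  }
  terminal <- !(br$id %in% br$parent)
  if (any(!br$lobe[terminal] %in% LOBES)) {
    stop("every terminal branch must carry a lobe label", call. = FALSE)
  }
  invisible(tree)
}

#' @export
print.airway_tree <- function(x, ...) {
  br <- x$branches
  cat(sprintf("airway_tree (%s): %d branches (%d resolved), %d terminal, %d nodes\n",
              x$state, nrow(br), sum(br$resolved),
              sum(!(br$id %in% br$parent)), nrow(x$nodes)))
  invisible(x)
}

#' Terminal branch ids of a tree
#'
#' A branch is terminal when no branch names it as parent.
#'
#' @param tree An [airway_tree()].
#' @return Integer vector of branch ids.
#' @export
terminal_branches <- function(tree) {
  br <- tree$branches
  br$id[!(br$id %in% br$parent)]
}

#' Write an airway tree to a directory
#'
#' Serializes `nodes.csv`, `branches.csv` and a `meta.json` header
#' (volume state, branch/node counts).
#'
#' @param tree An [airway_tree()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_airway_tree <- function(tree, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tree$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(tree$branches, file.path(dir, "branches.csv"), row.names = FALSE)
  meta <- list(state = tree$state, n_nodes = nrow(tree$nodes),
               n_branches = nrow(tree$branches))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an airway tree written by [write_airway_tree()]
#'
#' @param dir Directory containing `nodes.csv`, `branches.csv`, `meta.json`.
#' @return An [airway_tree()].
#' @export
read_airway_tree <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE)
  branches <- utils::read.csv(file.path(dir, "branches.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  airway_tree(nodes, branches, state = meta$state)
}
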