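# Bond environments: topological distances, spheres, cleavage ----------------

#' All-pairs topological distances
#'
#' Unweighted shortest-path bond counts between every pair of atoms; bond
#' orders never weight the edges.
#'
#' @param g A [mol_graph()].
#' @return Integer matrix, symmetric with zero diagonal.
#' @export
#' @examples
#' topological_distances(parse_structure("CC"))["1", "2"]
topological_distances <- function(g) {
  D <- igraph::distances(as_igraph(g))
  if (any(is.infinite(D))) {
    abort("graph is disconnected", class = "bondscope_structure_error")
  }
  storage.mode(D) <- "integer"
  dimnames(D) <- list(seq_len(nrow(D)), seq_len(nrow(D)))
  D
}

find_bond <- function(g, bond) {
  bond <- sort(as.integer(bond))
  idx <- which((pmin(g$bonds$from, g$bonds$to) == bond[1]) &
               (pmax(g$bonds$from, g$bonds$to) == bond[2]))
  if (!length(idx)) {
    abort(sprintf("no bond between atoms %d and %d", bond[1], bond[2]),
          class = "bondscope_structure_error")
  }
  idx[1]
}

#' Sphere assignment around a target bond
#'
#' Sphere 0 holds the two atoms of the target bond; sphere s holds the atoms
#' whose shortest-path distance to the nearer bond atom is s. The result does
#' not depend on the orientation in which the bond is given.
#'
#' @param g A [mol_graph()].
#' @param bond Length-2 vector of atom indices (unordered).
#' @param D Optional precomputed distance matrix from
#'   [topological_distances()].
#' @return A `bond_environment`: list with `graph`, `bond` (sorted pair),
#'   `sphere` (integer vector, one entry per atom), `D`, and for non-ring
#'   bonds `fragment` (1/2 membership labels, unordered sides).
#' @export
#' @examples
#' env <- assign_spheres(parse_structure("CCO"), c(1, 2))
#' table(env$sphere)
assign_spheres <- function(g, bond, D = NULL) {
  if (is.null(D)) D <- topological_distances(g)
  idx <- find_bond(g, bond)
  bond <- sort(as.integer(bond))
  sphere <- pmin(D[bond[1], ], D[bond[2], ])
  fragment <- NULL
  if (!g$bonds$in_ring[idx]) {
    ig <- igraph::delete_edges(as_igraph(g), idx)
    fragment <- igraph::components(ig)$membership
  }
  structure(
    list(graph = g, bond = bond, bond_index = idx,
         sphere = as.integer(sphere), D = D, fragment = fragment),
    class = "bond_environment"
  )
}

#' @export
print.bond_environment <- function(x, ...) {
  cat(sprintf("<bond_environment> target bond %d-%d, %d spheres\n",
              x$bond[1], x$bond[2], max(x$sphere) + 1L))
  print(table(sphere = x$sphere))
  invisible(x)
}

#' Cleave a non-ring bond into two fragments
#'
#' Homolytic cleavage of a bridge bond: the molecule falls into exactly two
#' connected fragments that keep their original atom ids. Within-fragment
#' shortest-path distances equal the parent-graph distances (bridge
#' property).
#'
#' @param g A [mol_graph()].
#' @param bond Length-2 atom-index vector; must not be in a ring.
#' @return List with `membership` (integer 1/2 per atom; sides unordered) and
#'   `fragments`, a list of two atom-index vectors.
#' @export
#' @examples
#' cleave_bond(parse_structure("CCO"), c(2, 3))$fragments
cleave_bond <- function(g, bond) {
  idx <- find_bond(g, bond)
  if (g$bonds$in_ring[idx]) {
    abort(sprintf("bond %d-%d is in a ring: cleavage would not give two fragments",
                  min(bond), max(bond)),
          class = "bondscope_cleavage_error")
  }
  ig <- igraph::delete_edges(as_igraph(g), idx)
  comp <- igraph::components(ig)
  stopifnot(comp$no == 2L)
  membership <- as.integer(comp$membership)
  list(
    membership = membership,
    fragments = list(which(membership == 1L), which(membership == 2L))
  )
}
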