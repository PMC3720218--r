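# Descriptor computation ------------------------------------------------------
#
# Strategy: per molecule, precompute distances, atom types, subset masks and
# the list of atom pairs up to the largest distance any definition needs;
# per bond, tabulate observed (sphere, distance, type...) keys and match them
# against the catalog's expected keys. All counts are non-negative integers
# and never depend on the orientation of the target bond.

subset_mask <- function(g, subset) {
  switch(subset,
    all = rep(TRUE, nrow(g$atoms)),
    ring = g$atoms$in_ring,
    aromatic = g$atoms$aromatic,
    pi = g$atoms$in_pi,
    abort(paste0("unknown atom subset: ", subset),
          class = "bondscope_catalog_error")
  )
}

pair_key_types <- function(t_i, t_j) {
  lo <- pmin(t_i, t_j)
  hi <- pmax(t_i, t_j)
  paste(lo, hi, sep = ".")
}

# molecule-level context shared by all bonds
molecule_context <- function(g, catalog) {
  D <- topological_distances(g)
  maxd <- suppressWarnings(
    max(catalog$distance[catalog$family %in% c("pair", "molecular_pair", "bbd")],
        na.rm = TRUE))
  pairs <- NULL
  if (is.finite(maxd)) {
    idx <- which(upper.tri(D) & D >= 1L & D <= maxd, arr.ind = TRUE)
    pairs <- list(i = idx[, 1], j = idx[, 2], d = D[idx])
  }
  types <- list(element = g$atoms$element, cn = g$atoms$cn)
  subsets <- list(all = subset_mask(g, "all"), ring = subset_mask(g, "ring"),
                  aromatic = subset_mask(g, "aromatic"),
                  pi = subset_mask(g, "pi"))
  list(g = g, D = D, pairs = pairs, types = types, subsets = subsets)
}

count_lookup <- function(keys) {
  if (!length(keys)) return(integer())
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

value_or_zero <- function(lookup, keys) {
  v <- lookup[keys]
  v[is.na(v)] <- 0L
  unname(v)
}

#' Point descriptors for one sphere
#'
#' Counts atoms of each type of the system lying in the given sphere,
#' restricted to an atom subset. The returned array always has one entry per
#' type label of the system.
#'
#' @param env A [assign_spheres()] environment.
#' @param type_system `"cn"` or `"element"`.
#' @param subset `"all"`, `"ring"`, `"aromatic"` or `"pi"`.
#' @param sphere Sphere index (0-based).
#' @return Named integer vector over the full type-label set.
#' @export
#' @examples
#' env <- assign_spheres(parse_structure("C"), c(1, 2))
#' point_descriptors(env, "cn", sphere = 0)[c("C4", "H1")]
point_descriptors <- function(env, type_system = "cn", subset = "all",
                              sphere = 0L) {
  g <- env$graph
  labs <- type_labels(type_system)
  mask <- subset_mask(g, subset) & env$sphere == sphere
  tys <- if (type_system == "element") g$atoms$element[mask] else g$atoms$cn[mask]
  tab <- count_lookup(tys)
  setNames(value_or_zero(tab, labs), labs)
}

#' Pair descriptors for one sphere and distance
#'
#' Counts unordered atom pairs whose outer atom lies in the given sphere (the
#' partner in the same or a lower sphere, i.e. max of the two sphere indices
#' equals `sphere`) at an exact shortest-path distance. With
#' `type_system = "none"` a single count over all such pairs is returned.
#'
#' @inheritParams point_descriptors
#' @param distance Shortest-path distance in bonds (>= 1).
#' @return Named integer vector over unordered type pairs (`"C.H"` style), or
#'   a single count for `"none"`.
#' @export
pair_descriptors <- function(env, type_system = "cn", sphere = 0L,
                             distance = 1L) {
  g <- env$graph
  D <- env$D
  idx <- which(upper.tri(D) & D == distance, arr.ind = TRUE)
  if (nrow(idx)) {
    smax <- pmax(env$sphere[idx[, 1]], env$sphere[idx[, 2]])
    idx <- idx[smax == sphere, , drop = FALSE]
  }
  if (type_system == "none") {
    return(c(count = nrow(idx)))
  }
  tys <- if (type_system == "element") g$atoms$element else g$atoms$cn
  keys <- pair_key_types(tys[idx[, 1]], tys[idx[, 2]])
  tp <- type_pairs(type_system)
  want <- paste(tp$type1, tp$type2, sep = ".")
  tab <- count_lookup(keys)
  setNames(value_or_zero(tab, want), want)
}

#' Bond-breaking difference pair descriptors
#'
#' The difference between whole-molecule pair counts before cleaving the
#' target bond and same-fragment pair counts after. Because a non-ring bond
#' is a bridge, within-fragment distances are unchanged by cleavage and the
#' difference equals the count of cross-fragment pairs at that distance -
#' hence always non-negative and orientation-free.
#'
#' @inheritParams pair_descriptors
#' @return Named integer vector as in [pair_descriptors()].
#' @export
bond_breaking_difference <- function(env, type_system = "cn", distance = 1L) {
  g <- env$graph
  if (is.null(env$fragment)) {
    abort("target bond is in a ring: no two-fragment cleavage",
          class = "bondscope_cleavage_error")
  }
  D <- env$D
  idx <- which(upper.tri(D) & D == distance, arr.ind = TRUE)
  if (nrow(idx)) {
    cross <- env$fragment[idx[, 1]] != env$fragment[idx[, 2]]
    idx <- idx[cross, , drop = FALSE]
  }
  if (type_system == "none") {
    return(c(count = nrow(idx)))
  }
  tys <- if (type_system == "element") g$atoms$element else g$atoms$cn
  keys <- pair_key_types(tys[idx[, 1]], tys[idx[, 2]])
  tp <- type_pairs(type_system)
  want <- paste(tp$type1, tp$type2, sep = ".")
  tab <- count_lookup(keys)
  setNames(value_or_zero(tab, want), want)
}

#' Fragment point descriptors
#'
#' Whole-fragment atom-type counts for the two fragments produced by cleaving
#' the target bond, sorted descending per type (rank 1 = larger value) so the
#' result does not depend on bond orientation.
#'
#' @inheritParams point_descriptors
#' @return Tibble with `type`, `rank` (1 = larger), `value`.
#' @export
fragment_point_descriptors <- function(env, type_system = "element",
                                       subset = "all") {
  g <- env$graph
  if (is.null(env$fragment)) {
    abort("target bond is in a ring: no two-fragment cleavage",
          class = "bondscope_cleavage_error")
  }
  labs <- type_labels(type_system)
  mask <- subset_mask(g, subset)
  tys <- if (type_system == "element") g$atoms$element else g$atoms$cn
  out <- tidyr::expand_grid(type = labs, rank = 1:2)
  v1 <- count_lookup(tys[mask & env$fragment == 1L])
  v2 <- count_lookup(tys[mask & env$fragment == 2L])
  a <- value_or_zero(v1, labs)
  b <- value_or_zero(v2, labs)
  out$value <- as.vector(rbind(pmax(a, b), pmin(a, b)))
  out
}

#' Molecular descriptors
#'
#' Atom-type or type-pair counts over the whole molecule, identical for every
#' bond of the molecule.
#'
#' @param g A [mol_graph()].
#' @param type_system `"cn"`, `"element"`, or `"none"` (pairs only).
#' @param subset Atom subset for point counts.
#' @param distance `NULL` for point counts; otherwise the pair distance.
#' @return Named integer vector.
#' @export
#' @examples
#' molecular_descriptors(parse_structure("C"), "element")[c("C", "H")]
molecular_descriptors <- function(g, type_system = "cn", subset = "all",
                                  distance = NULL) {
  if (is.null(distance)) {
    labs <- type_labels(type_system)
    mask <- subset_mask(g, subset)
    tys <- if (type_system == "element") g$atoms$element else g$atoms$cn
    tab <- count_lookup(tys[mask])
    return(setNames(value_or_zero(tab, labs), labs))
  }
  D <- topological_distances(g)
  idx <- which(upper.tri(D) & D == distance, arr.ind = TRUE)
  if (type_system == "none") {
    return(c(count = nrow(idx)))
  }
  tys <- if (type_system == "element") g$atoms$element else g$atoms$cn
  keys <- pair_key_types(tys[idx[, 1]], tys[idx[, 2]])
  tp <- type_pairs(type_system)
  want <- paste(tp$type1, tp$type2, sep = ".")
  tab <- count_lookup(keys)
  setNames(value_or_zero(tab, want), want)
}

# fast vector fill used by compute_vector / compute_descriptors
vector_from_context <- function(ctx, env, catalog, mol_cache) {
  g <- ctx$g
  vals <- numeric(nrow(catalog))
  fam <- catalog$family
  sphere <- env$sphere

  # --- point
  pi_ <- which(fam == "point")
  if (length(pi_)) {
    for (grp in split(pi_, paste(catalog$type_system[pi_], catalog$subset[pi_]))) {
      sys <- catalog$type_system[grp[1]]
      sub <- catalog$subset[grp[1]]
      mask <- ctx$subsets[[sub]]
      tys <- ctx$types[[sys]]
      keys <- paste(sphere[mask], tys[mask], sep = ".")
      tab <- count_lookup(keys)
      want <- paste(catalog$sphere[grp], catalog$type1[grp], sep = ".")
      vals[grp] <- value_or_zero(tab, want)
    }
  }

  # --- pair (sphere-scoped)
  pr <- which(fam == "pair")
  if (length(pr) && !is.null(ctx$pairs)) {
    p <- ctx$pairs
    smax <- pmax(sphere[p$i], sphere[p$j])
    for (grp in split(pr, catalog$type_system[pr])) {
      sys <- catalog$type_system[grp[1]]
      if (sys == "none") {
        keys <- paste(smax, p$d, sep = ".")
        want <- paste(catalog$sphere[grp], catalog$distance[grp], sep = ".")
      } else {
        tys <- ctx$types[[sys]]
        keys <- paste(smax, p$d, pair_key_types(tys[p$i], tys[p$j]), sep = ".")
        want <- paste(catalog$sphere[grp], catalog$distance[grp],
                      paste(catalog$type1[grp], catalog$type2[grp], sep = "."),
                      sep = ".")
      }
      tab <- count_lookup(keys)
      vals[grp] <- value_or_zero(tab, want)
    }
  }

  # --- bbd (cross-fragment pairs)
  bb <- which(fam == "bbd")
  if (length(bb)) {
    if (is.null(env$fragment)) {
      abort("catalog contains cleavage families but target bond is in a ring",
            class = "bondscope_cleavage_error")
    }
    p <- ctx$pairs
    cross <- env$fragment[p$i] != env$fragment[p$j]
    for (grp in split(bb, catalog$type_system[bb])) {
      sys <- catalog$type_system[grp[1]]
      if (sys == "none") {
        keys <- p$d[cross]
        want <- as.character(catalog$distance[grp])
      } else {
        tys <- ctx$types[[sys]]
        keys <- paste(p$d[cross],
                      pair_key_types(tys[p$i[cross]], tys[p$j[cross]]), sep = ".")
        want <- paste(catalog$distance[grp],
                      paste(catalog$type1[grp], catalog$type2[grp], sep = "."),
                      sep = ".")
      }
      tab <- count_lookup(as.character(keys))
      vals[grp] <- value_or_zero(tab, want)
    }
  }

  # --- fragment point
  fp <- which(fam == "fragment_point")
  if (length(fp)) {
    if (is.null(env$fragment)) {
      abort("catalog contains cleavage families but target bond is in a ring",
            class = "bondscope_cleavage_error")
    }
    for (grp in split(fp, paste(catalog$type_system[fp], catalog$subset[fp]))) {
      sys <- catalog$type_system[grp[1]]
      sub <- catalog$subset[grp[1]]
      mask <- ctx$subsets[[sub]]
      tys <- ctx$types[[sys]]
      t1 <- count_lookup(tys[mask & env$fragment == 1L])
      t2 <- count_lookup(tys[mask & env$fragment == 2L])
      a <- value_or_zero(t1, catalog$type1[grp])
      b <- value_or_zero(t2, catalog$type1[grp])
      vals[grp] <- ifelse(catalog$rank[grp] == 1L, pmax(a, b), pmin(a, b))
    }
  }

  # --- molecule-level families (cached per molecule)
  ml <- which(fam %in% c("molecular_point", "molecular_pair", "pi_total"))
  if (length(ml)) vals[ml] <- mol_cache[ml]

  setNames(vals, catalog$name)
}

molecular_values <- function(ctx, catalog) {
  vals <- numeric(nrow(catalog))
  fam <- catalog$family
  mp <- which(fam == "molecular_point")
  if (length(mp)) {
    for (grp in split(mp, paste(catalog$type_system[mp], catalog$subset[mp]))) {
      sys <- catalog$type_system[grp[1]]
      sub <- catalog$subset[grp[1]]
      tab <- count_lookup(ctx$types[[sys]][ctx$subsets[[sub]]])
      vals[grp] <- value_or_zero(tab, catalog$type1[grp])
    }
  }
  pt <- which(fam == "pi_total")
  if (length(pt)) {
    # sum of the two fragment values = whole-molecule count over the subset
    for (grp in split(pt, catalog$type_system[pt])) {
      sys <- catalog$type_system[grp[1]]
      tab <- count_lookup(ctx$types[[sys]][ctx$subsets$pi])
      vals[grp] <- value_or_zero(tab, catalog$type1[grp])
    }
  }
  mpr <- which(fam == "molecular_pair")
  if (length(mpr) && !is.null(ctx$pairs)) {
    p <- ctx$pairs
    for (grp in split(mpr, catalog$type_system[mpr])) {
      sys <- catalog$type_system[grp[1]]
      if (sys == "none") {
        tab <- count_lookup(as.character(p$d))
        want <- as.character(catalog$distance[grp])
      } else {
        tys <- ctx$types[[sys]]
        tab <- count_lookup(paste(p$d, pair_key_types(tys[p$i], tys[p$j]),
                                  sep = "."))
        want <- paste(catalog$distance[grp],
                      paste(catalog$type1[grp], catalog$type2[grp], sep = "."),
                      sep = ".")
      }
      vals[grp] <- value_or_zero(tab, want)
    }
  }
  vals
}

#' Compute the descriptor vector of one bond
#'
#' Values come back in catalog order; the result is identical for either
#' orientation of the bond and for any Kekule resolution of aromatic systems.
#'
#' @param g A [mol_graph()].
#' @param bond Length-2 atom-index vector.
#' @param catalog A [build_catalog()] result.
#' @return Named numeric vector of length `nrow(catalog)`.
#' @export
#' @examples
#' cat3 <- build_catalog("selection3")
#' v <- compute_vector(parse_structure("CCO"), c(2, 3), cat3)
#' length(v)
compute_vector <- function(g, bond, catalog) {
  ctx <- molecule_context(g, catalog)
  env <- assign_spheres(g, bond, D = ctx$D)
  mol_cache <- molecular_values(ctx, catalog)
  vector_from_context(ctx, env, catalog, mol_cache)
}

#' Compute descriptors for many bonds of many molecules
#'
#' @param mols A `mol_graph`, or a list of them (names become molecule ids).
#' @param catalog A [build_catalog()] result.
#' @param bonds Optional tibble with columns `molecule`, `from`, `to`
#'   selecting target bonds; by default every non-ring bond of every admitted
#'   molecule is used.
#' @return Tibble: `molecule`, `from`, `to`, `element_pair`, `order`, then one
#'   numeric column per catalog definition (in catalog order).
#' @export
compute_descriptors <- function(mols, catalog, bonds = NULL) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  ids <- names(mols)
  if (is.null(ids)) ids <- as.character(seq_along(mols))
  ids[ids == ""] <- as.character(which(ids == ""))
  rows <- vector("list", length(mols))
  for (m in seq_along(mols)) {
    g <- mols[[m]]
    ctx <- molecule_context(g, catalog)
    mol_cache <- molecular_values(ctx, catalog)
    if (is.null(bonds)) {
      bl <- enumerate_bonds(g)
    } else {
      bl <- bonds %>% filter(.data$molecule == ids[m]) %>%
        select("from", "to")
    }
    if (!nrow(bl)) next
    mat <- matrix(0, nrow(bl), nrow(catalog),
                  dimnames = list(NULL, catalog$name))
    ep <- character(nrow(bl)); ord <- integer(nrow(bl))
    for (k in seq_len(nrow(bl))) {
      b <- c(bl$from[k], bl$to[k])
      env <- assign_spheres(g, b, D = ctx$D)
      mat[k, ] <- vector_from_context(ctx, env, catalog, mol_cache)
      ep[k] <- element_pair(g, b[1], b[2])
      ord[k] <- g$bonds$order[env$bond_index]
    }
    rows[[m]] <- dplyr::bind_cols(
      tibble(molecule = ids[m], from = bl$from, to = bl$to,
             element_pair = ep, order = ord),
      as_tibble(mat)
    )
  }
  bind_rows(rows)
}

#' Names of the descriptor columns in a record tibble
#' @param records A tibble from [compute_descriptors()] or [build_records()].
#' @return Character vector of descriptor column names.
#' @export
descriptor_columns <- function(records) {
  setdiff(names(records),
          c("molecule", "from", "to", "element_pair", "order", "bde"))
}
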