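# Molecular graphs with explicit hydrogens -----------------------------------
#
# The descriptor engine works on a plain connection table: elements, formal
# charges, bonds with integer (Kekule) orders. Aromatic input is always
# resolved to one Kekule form before anything downstream runs, so that
# different mesomers of the same molecule cannot produce different
# descriptors.

ELEMENTS <- c("C", "H", "O", "N", "S")

#' The closed set of connection-number atom-type labels
#'
#' An atom's connection-number type is its element symbol followed by the
#' number of bonded neighbours (hydrogens included): the carbon of methane is
#' `C4`, an acetylenic carbon is `C2`, every hydrogen is `H1`. Fourteen labels
#' cover all valence-legal neutral-or-zwitterionic CHONS atoms; note there is
#' no `C1`.
#'
#' @return Character vector of the 14 labels.
#' @export
#' @examples
#' cn_type_labels()
cn_type_labels <- function() {
  c("C2", "C3", "C4", "H1",
    "N1", "N2", "N3", "N4",
    "O1", "O2",
    "S1", "S2", "S3", "S4")
}

#' Atom-type labels for a type system
#'
#' @param system `"element"` (5 labels) or `"cn"` (the 14 connection-number
#'   labels).
#' @return Character vector of labels defining descriptor array layout.
#' @export
type_labels <- function(system = c("cn", "element")) {
  system <- match.arg(system)
  if (system == "element") ELEMENTS else cn_type_labels()
}

default_valence <- function(element, charge = 0L) {
  base <- c(C = 4L, H = 1L, N = 3L, O = 2L, S = 2L)[element]
  adj <- ifelse(element %in% c("N", "O", "S"), charge,
         ifelse(element == "C", -abs(charge), 0L))
  pmax(unname(base) + as.integer(adj), 0L)
}

#' Construct a molecular graph
#'
#' Low-level constructor used by the parsers and the synthetic generator.
#' Atoms are numbered 1..n and hydrogens must already be explicit.
#'
#' @param atoms Tibble/data frame with columns `element` (one of C,H,O,N,S)
#'   and optionally `charge` (integer formal charge, default 0).
#' @param bonds Tibble/data frame with columns `from`, `to` (atom indices) and
#'   optionally `order` (1, 2 or 3; default 1).
#' @param name Optional molecule identifier.
#' @param perceive Compute ring/aromatic/pi flags now (default `TRUE`).
#' @return A `mol_graph` object: list with tibbles `atoms` (element, charge,
#'   degree, cn, in_ring, aromatic, in_pi) and `bonds` (from, to, order,
#'   in_ring), plus `name` and `charge` (net).
#' @export
#' @examples
#' methane <- mol_graph(
#'   atoms = tibble::tibble(element = c("C", "H", "H", "H", "H")),
#'   bonds = tibble::tibble(from = 1, to = 2:5)
#' )
#' methane
mol_graph <- function(atoms, bonds, name = NA_character_, perceive = TRUE) {
  atoms <- as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  bonds <- as_tibble(bonds)
  if (!"order" %in% names(bonds)) bonds$order <- 1L
  bonds <- tibble(from = as.integer(bonds$from), to = as.integer(bonds$to),
                  order = as.integer(bonds$order))
  n <- nrow(atoms)
  bad <- setdiff(atoms$element, ELEMENTS)
  if (length(bad)) {
    abort(paste0("unsupported element(s): ", paste(unique(bad), collapse = ", "),
                 " (only C, H, O, N, S are modelled)"),
          class = "bondscope_chemistry_error")
  }
  if (nrow(bonds) && (any(bonds$from < 1L | bonds$from > n) ||
                      any(bonds$to < 1L | bonds$to > n))) {
    abort("bond references a non-existent atom", class = "bondscope_format_error")
  }
  if (any(bonds$from == bonds$to)) {
    abort("self-bond in connection table", class = "bondscope_format_error")
  }
  if (!all(bonds$order %in% 1:3)) {
    abort("bond orders must be 1, 2 or 3 after kekulization",
          class = "bondscope_chemistry_error")
  }
  g <- structure(
    list(atoms = atoms, bonds = bonds, name = name,
         charge = sum(atoms$charge)),
    class = "mol_graph"
  )
  deg <- tabulate(c(bonds$from, bonds$to), nbins = n)
  g$atoms$degree <- deg
  g$atoms$cn <- paste0(atoms$element, deg)
  if (n > 1 && igraph::components(as_igraph(g))$no != 1L) {
    abort("molecular graph must be connected", class = "bondscope_format_error")
  }
  if (perceive) g <- perceive_features(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, net charge %+d\n",
              ifelse(is.na(x$name), "(unnamed)", x$name),
              nrow(x$atoms), nrow(x$bonds), x$charge))
  counts <- table(x$atoms$element)
  cat("  formula: ", paste0(names(counts), counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.mol_graph <- function(x, ...) x$atoms

as_igraph <- function(g) {
  igraph::graph_from_edgelist(cbind(g$bonds$from, g$bonds$to), directed = FALSE)
}

# -- parsing ------------------------------------------------------------------

#' Parse a molecule from SMILES or a V2000 molfile
#'
#' SMILES input is kekulized and hydrogens are made explicit (via Open
#' Babel). Molfile input keeps its atom numbering; missing hydrogens are
#' materialized from default valences and formal charges.
#'
#' @param text A SMILES string, or the text of a V2000 molfile record
#'   (anything containing a newline is treated as a molfile).
#' @param name Optional molecule identifier.
#' @return A [mol_graph()].
#' @export
#' @examples
#' parse_structure("C")            # methane: 5 atoms, 4 bonds
#' parse_structure("c1ccccc1")     # benzene, kekulized
parse_structure <- function(text, name = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("\n", text)) {
    parse_molfile(text, name = name)
  } else {
    parse_smiles(text, name = name)
  }
}

parse_smiles <- function(smiles, name = NA_character_) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\t", ifelse(is.na(name), "mol", name), "\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    )),
    error = function(e) "")
  if (!nzchar(out) || !grepl("V2000", out)) {
    abort(paste0("could not parse SMILES: ", smiles),
          class = "bondscope_format_error")
  }
  parse_molfile(out, name = name)
}

# Parse one V2000 record from raw text. Handles the counts line, atom block
# (element + old-style charge codes), bond block, and M CHG overrides.
parse_molfile <- function(text, name = NA_character_) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  cl <- grep("V2000", lines)[1]
  if (is.na(cl)) abort("not a V2000 molfile", class = "bondscope_format_error")
  counts <- lines[cl]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds) ||
      length(lines) < cl + n_atoms + n_bonds) {
    abort("malformed V2000 counts line", class = "bondscope_format_error")
  }
  atom_lines <- lines[(cl + 1):(cl + n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  bad <- setdiff(element, ELEMENTS)
  if (length(bad)) {
    abort(paste0("unsupported element(s): ", paste(unique(bad), collapse = ", "),
                 " (only C, H, O, N, S are modelled)"),
          class = "bondscope_chemistry_error")
  }
  charge_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge_code[is.na(charge_code)] <- 0L
  # old-style codes: 1..3 -> +3..+1, 5..7 -> -1..-3 (4 is a radical flag)
  charge <- dplyr::case_when(
    charge_code %in% 1:3 ~ 4L - charge_code,
    charge_code %in% 5:7 ~ 4L - charge_code,
    TRUE ~ 0L
  )
  if (n_bonds > 0) {
    bond_lines <- lines[(cl + n_atoms + 1):(cl + n_atoms + n_bonds)]
    from <- as.integer(substr(bond_lines, 1, 3))
    to <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    from <- to <- order <- integer()
  }
  # M CHG lines override the atom-block codes entirely
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (ln in chg_lines) {
      flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      k <- flds[1]
      idx <- flds[seq(2, by = 2, length.out = k)]
      val <- flds[seq(3, by = 2, length.out = k)]
      charge[idx] <- val
    }
  }
  if (any(order == 4L)) {
    ke <- kekulize_orders(n_atoms, from, to, order, element)
    order <- ke
  }
  g <- fill_hydrogens(
    tibble(element = element, charge = charge),
    tibble(from = from, to = to, order = order)
  )
  mol_graph(g$atoms, g$bonds, name = name)
}

# Resolve order-4 (aromatic) bonds to one canonical Kekule form: a maximum
# matching on the aromatic subgraph restricted to atoms that still need a
# double bond. Deterministic for a given atom ordering.
kekulize_orders <- function(n, from, to, order, element) {
  arom <- which(order == 4L)
  order[arom] <- 1L
  needs <- rep(FALSE, n)
  arom_atoms <- unique(c(from[arom], to[arom]))
  # atoms with a lone pair donate it and need no double bond
  deg <- tabulate(c(from, to), nbins = n)
  for (a in arom_atoms) {
    el <- element[a]
    needs[a] <- !(el %in% c("N", "O", "S") && deg[a] >= default_valence(el))
  }
  # greedy alternation: walk aromatic edges, assign a double bond when both
  # ends still lack one (two passes so ring closures written last still match)
  has_double <- order == 2L | order == 3L
  got <- rep(FALSE, n)
  got[from[has_double]] <- TRUE
  got[to[has_double]] <- TRUE
  for (e in c(arom, rev(arom))) {
    a <- from[e]; b <- to[e]
    if (needs[a] && needs[b] && !got[a] && !got[b]) {
      order[e] <- 2L
      got[a] <- TRUE
      got[b] <- TRUE
    }
  }
  order
}

# Add implicit hydrogens up to default valence (charge-adjusted).
fill_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  val_used <- rep(0L, n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      val_used[bonds$from[i]] <- val_used[bonds$from[i]] + bonds$order[i]
      val_used[bonds$to[i]] <- val_used[bonds$to[i]] + bonds$order[i]
    }
  }
  heavy <- which(atoms$element != "H")
  add_from <- integer(); n_new <- 0L
  for (a in heavy) {
    deficit <- default_valence(atoms$element[a], atoms$charge[a]) - val_used[a]
    if (deficit > 0) {
      add_from <- c(add_from, rep(a, deficit))
      n_new <- n_new + deficit
    }
  }
  if (n_new > 0) {
    atoms <- bind_rows(atoms, tibble(element = rep("H", n_new),
                                     charge = rep(0L, n_new)))
    bonds <- bind_rows(bonds, tibble(from = add_from,
                                     to = n + seq_len(n_new),
                                     order = 1L))
  }
  list(atoms = atoms, bonds = bonds)
}

# -- admission ----------------------------------------------------------------

#' Admission verdict for a molecule
#'
#' A molecule is admitted when its net charge is zero and all its elements
#' are among C, H, O, N, S. Zwitterions (non-zero formal charges summing to
#' zero) are admitted; globally charged species are not.
#'
#' @param g A [mol_graph()].
#' @return One-row tibble with `accepted` (logical) and `reason`
#'   (`"ok"`, `"net_charge"`, or `"element"`).
#' @export
#' @examples
#' validate_molecule(parse_structure("[NH3+]CC(=O)[O-]"))  # zwitterion: accepted
validate_molecule <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  if (!all(g$atoms$element %in% ELEMENTS)) {
    return(tibble(accepted = FALSE, reason = "element"))
  }
  if (g$charge != 0L) {
    return(tibble(accepted = FALSE, reason = "net_charge"))
  }
  tibble(accepted = TRUE, reason = "ok")
}

#' Atom type of one atom
#'
#' @param g A [mol_graph()].
#' @param atom Atom index.
#' @param system `"cn"` (element + neighbour count) or `"element"`.
#' @return Type label string.
#' @export
#' @examples
#' atom_type(parse_structure("C"), 1, "cn")  # "C4"
atom_type <- function(g, atom, system = c("cn", "element")) {
  system <- match.arg(system)
  lab <- if (system == "element") g$atoms$element[atom] else g$atoms$cn[atom]
  bad <- setdiff(lab, type_labels(system))
  if (length(bad)) {
    abort(paste0("atom type ", paste(bad, collapse = ", "),
                 " outside the closed label set"),
          class = "bondscope_typing_error")
  }
  lab
}

# -- feature perception -------------------------------------------------------

#' Perceive ring, aromatic and pi-system membership
#'
#' Ring membership comes from bridge detection (a bond is in a ring iff it is
#' not a bridge). Aromaticity is a pinned Hueckel model: for each smallest
#' ring through a ring bond, the ring is aromatic when every ring atom is
#' sp2-compatible (at most 3 neighbours and able to contribute 0, 1 or 2 pi
#' electrons) and the electron count is 4n+2. Pi-system membership covers
#' atoms incident to a double/triple bond or aromatic, plus lone-pair
#' heteroatoms (N, O, S, or negative C) directly attached to such an atom.
#' Exocyclic atoms attached to aromatic rings are not flagged aromatic.
#'
#' @param g A [mol_graph()].
#' @return `g` with logical atom columns `in_ring`, `aromatic`, `in_pi` and a
#'   logical bond column `in_ring` filled in.
#' @export
perceive_features <- function(g) {
  n <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  ig <- as_igraph(g)
  if (nb > 0) {
    br <- igraph::bridges(ig)
    bond_ring <- !(seq_len(nb) %in% as.integer(br))
  } else {
    bond_ring <- logical(0)
  }
  atom_ring <- rep(FALSE, n)
  atom_ring[c(g$bonds$from[bond_ring], g$bonds$to[bond_ring])] <- TRUE

  aromatic <- rep(FALSE, n)
  if (any(bond_ring)) {
    rings <- smallest_rings(g, ig, which(bond_ring))
    for (ring in rings) {
      if (ring_is_aromatic(g, ring)) aromatic[ring] <- TRUE
    }
  }

  multi <- g$bonds$order >= 2L
  in_pi <- rep(FALSE, n)
  in_pi[c(g$bonds$from[multi], g$bonds$to[multi])] <- TRUE
  in_pi <- in_pi | aromatic
  # lone-pair donors adjacent to the pi system
  adj <- adjacency_list(g)
  donors <- which(!in_pi &
                  (g$atoms$element %in% c("N", "O", "S") |
                   (g$atoms$element == "C" & g$atoms$charge < 0L)))
  for (a in donors) {
    if (any(in_pi[adj[[a]]])) in_pi[a] <- TRUE
  }

  g$atoms$in_ring <- atom_ring
  g$atoms$aromatic <- aromatic
  g$atoms$in_pi <- in_pi
  g$bonds$in_ring <- bond_ring
  g
}

adjacency_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[i]; b <- g$bonds$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# smallest cycle through each ring bond, deduplicated
smallest_rings <- function(g, ig, ring_bond_idx) {
  rings <- list()
  seen <- character()
  for (e in ring_bond_idx) {
    a <- g$bonds$from[e]; b <- g$bonds$to[e]
    g2 <- igraph::delete_edges(ig, e)
    p <- suppressWarnings(igraph::shortest_paths(g2, a, b)$vpath[[1]])
    if (length(p) < 3) next
    ring <- sort(as.integer(p))
    key <- paste(ring, collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- as.integer(p)
    }
  }
  rings
}

# Hueckel 4n+2 on one ring, using the Kekule orders
ring_is_aromatic <- function(g, ring) {
  electrons <- 0L
  ring_set <- ring
  for (a in ring) {
    if (g$atoms$degree[a] > 3L) return(FALSE)
    # bonds at this atom
    at <- which(g$bonds$from == a | g$bonds$to == a)
    partners <- ifelse(g$bonds$from[at] == a, g$bonds$to[at], g$bonds$from[at])
    orders <- g$bonds$order[at]
    multi_in <- any(orders >= 2L & partners %in% ring_set)
    multi_out <- any(orders >= 2L & !partners %in% ring_set)
    el <- g$atoms$element[a]
    if (multi_in) {
      electrons <- electrons + 1L
    } else if (multi_out) {
      electrons <- electrons + 0L
    } else if (el %in% c("N", "O", "S") ||
               (el == "C" && g$atoms$charge[a] < 0L)) {
      electrons <- electrons + 2L
    } else if (el == "C" && g$atoms$charge[a] > 0L) {
      electrons <- electrons + 0L
    } else {
      return(FALSE)
    }
  }
  electrons >= 2L && (electrons - 2L) %% 4L == 0L
}

# unordered element pair label, e.g. "C-H"
element_pair <- function(g, a, b) {
  paste(sort(c(g$atoms$element[a], g$atoms$element[b])), collapse = "-")
}
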