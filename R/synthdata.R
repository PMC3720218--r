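# Synthetic CHONS molecules and surrogate bond energies -----------------------
#
# The generator produces connected, valence-legal, net-neutral molecules with
# explicit hydrogens: a random tree over heavy atoms (respecting default
# valences), an optional ring-closing edge, random promotion of bonds to
# double/triple order where valence allows, then hydrogen fill. Surrogate
# energies are an additive model - a base value per (element pair, bond
# order) plus per-neighbour-type increments for spheres 1 and 2 - with
# homoscedastic Gaussian noise, so the noiseless part is a deterministic
# function of the bond's sphere-0..2 environment and is exactly learnable
# from the topological descriptors.

HEAVY_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L)

#' Generate random valence-legal CHONS molecules
#'
#' @param n Number of molecules.
#' @param max_heavy_atoms Maximum heavy-atom count per molecule (the count is
#'   drawn uniformly from 1..max).
#' @param element_weights Named sampling weights over C, N, O, S.
#' @param ring_prob Probability of attempting one ring closure per molecule.
#' @param double_prob,triple_prob Per-bond promotion probabilities (applied
#'   where both atoms have spare valence).
#' @param seed Integer seed (mandatory; generation is reproducible).
#' @return Named list of [mol_graph()] objects (`synth_1`, `synth_2`, ...).
#' @export
#' @examples
#' mols <- generate_molecules(3, max_heavy_atoms = 6, seed = 1)
#' length(mols)
generate_molecules <- function(n, max_heavy_atoms = 12,
                               element_weights = c(C = 0.72, N = 0.12,
                                                   O = 0.12, S = 0.04),
                               ring_prob = 0.35, double_prob = 0.15,
                               triple_prob = 0.03, seed) {
  stopifnot(n >= 1, max_heavy_atoms >= 1)
  missing_w <- setdiff(names(HEAVY_VALENCE), names(element_weights))
  if (length(missing_w)) element_weights[missing_w] <- 0
  element_weights <- element_weights[names(HEAVY_VALENCE)]
  if (all(element_weights == 0)) {
    abort("element weights are all zero", class = "bondscope_generation_error")
  }
  withr::with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- random_molecule(max_heavy_atoms, element_weights,
                                  ring_prob, double_prob, triple_prob,
                                  name = sprintf("synth_%d", i))
    }
    names(out) <- vapply(out, function(g) g$name, character(1))
    out
  })
}

random_molecule <- function(max_heavy, w, ring_prob, double_prob, triple_prob,
                            name) {
  for (attempt in 1:50) {
    k <- sample.int(max_heavy, 1)
    el <- sample(names(HEAVY_VALENCE), k, replace = TRUE, prob = w)
    # single heavy atoms of valence 0 make no molecule; methane etc. are fine
    cap <- unname(HEAVY_VALENCE[el])
    if (k > 1 && sum(cap) < 2 * (k - 1)) next
    free <- cap
    from <- integer(); to <- integer()
    ok <- TRUE
    for (a in seq_len(k)[-1]) {
      cand <- which(free[seq_len(a - 1)] > 0)
      if (!length(cand)) { ok <- FALSE; break }
      b <- if (length(cand) == 1) cand else sample(cand, 1)
      from <- c(from, b); to <- c(to, a)
      free[a] <- free[a] - 1L; free[b] <- free[b] - 1L
    }
    if (!ok) next
    order <- rep(1L, length(from))
    # one ring closure between non-adjacent atoms with spare valence
    if (k >= 3 && runif(1) < ring_prob) {
      cand <- which(free > 0)
      if (length(cand) >= 2) {
        pick <- sample(cand, 2)
        adjacent <- any((from == pick[1] & to == pick[2]) |
                        (from == pick[2] & to == pick[1]))
        if (!adjacent) {
          from <- c(from, pick[1]); to <- c(to, pick[2])
          order <- c(order, 1L)
          free[pick] <- free[pick] - 1L
        }
      }
    }
    # promote bond orders where valence allows; multiple bonds are kept
    # isolated (no atom carries two of them, no two are adjacent) so that a
    # bond's order is determined by the connection-number types of its atoms
    # - this is what makes the noiseless surrogate a function of the
    # topological descriptors
    has_multi <- rep(FALSE, k)
    for (e in seq_along(from)) {
      a <- from[e]; b <- to[e]
      if (has_multi[a] || has_multi[b]) next
      if (free[a] >= 2 && free[b] >= 2 && runif(1) < triple_prob) {
        order[e] <- 3L; free[a] <- free[a] - 2L; free[b] <- free[b] - 2L
        has_multi[a] <- has_multi[b] <- TRUE
      } else if (free[a] >= 1 && free[b] >= 1 && runif(1) < double_prob) {
        order[e] <- 2L; free[a] <- free[a] - 1L; free[b] <- free[b] - 1L
        has_multi[a] <- has_multi[b] <- TRUE
      }
    }
    filled <- fill_hydrogens(tibble(element = el, charge = 0L),
                             tibble(from = from, to = to, order = order))
    g <- tryCatch(mol_graph(filled$atoms, filled$bonds, name = name),
                  error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  abort("could not generate a valence-legal molecule under the constraints",
        class = "bondscope_generation_error")
}

# -- surrogate energies -------------------------------------------------------

default_base_table <- function() {
  # order-of-magnitude realistic single/double/triple base energies, kcal/mol
  singles <- c("C-C" = 83, "C-H" = 99, "C-N" = 73, "C-O" = 86, "C-S" = 65,
               "H-N" = 93, "H-O" = 111, "H-S" = 87, "N-N" = 39, "N-O" = 48,
               "N-S" = 55, "O-O" = 35, "O-S" = 87, "S-S" = 54, "H-H" = 104)
  pairs <- names(singles)
  tibble(element_pair = rep(pairs, times = 3),
         order = rep(1:3, each = length(pairs)),
         base = c(singles, singles + 63, singles + 117))
}

default_increments <- function() {
  labs <- cn_type_labels()
  inc1 <- setNames(c(3.5, 2.0, -1.5, 0.8, 4.0, 1.2, -0.6, -2.0, 5.0, -1.0,
                     2.0, -0.8, -1.5, -2.5), labs)
  inc2 <- setNames(c(-1.2, 0.9, 0.6, -0.3, 1.5, -0.7, 0.4, 1.0, -2.0, 0.5,
                     -0.9, 0.3, 0.7, -0.4), labs)
  list(sphere1 = inc1, sphere2 = inc2)
}

#' Surrogate-energy parameters
#'
#' @param sigma Gaussian noise standard deviation, kcal/mol (default 2).
#' @param base Base-energy table (tibble: element_pair, order, base); default
#'   covers every CHONS pair and order 1-3 with literature-magnitude values.
#' @param increments List with named vectors `sphere1`, `sphere2` of
#'   per-neighbour-type increments (kcal/mol) over the 14 CN labels.
#' @return A `surrogate_params` list.
#' @export
surrogate_params <- function(sigma = 2, base = default_base_table(),
                             increments = default_increments()) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, base = base, increments = increments),
            class = "surrogate_params")
}

#' Surrogate bond dissociation energy
#'
#' base(element pair, order) + sum of sphere-1 increments + sum of sphere-2
#' increments + N(0, sigma). The noiseless part depends only on the bond's
#' sphere-0..2 environment. Noise is drawn from the current RNG stream; seed
#' the caller (as [make_dataset()] does) for reproducibility.
#'
#' @param g A [mol_graph()].
#' @param bond Length-2 atom-index vector (non-ring bond).
#' @param params A [surrogate_params()].
#' @param env Optional precomputed [assign_spheres()] environment.
#' @return Energy in kcal/mol.
#' @export
surrogate_bde <- function(g, bond, params, env = NULL) {
  if (is.null(env)) env <- assign_spheres(g, bond)
  idx <- env$bond_index
  ep <- element_pair(g, env$bond[1], env$bond[2])
  ord <- g$bonds$order[idx]
  row <- params$base %>% filter(.data$element_pair == ep, .data$order == ord)
  if (!nrow(row)) {
    abort(sprintf("no base energy for class %s order %d", ep, ord),
          class = "bondscope_params_error")
  }
  s1 <- g$atoms$cn[env$sphere == 1L]
  s2 <- g$atoms$cn[env$sphere == 2L]
  val <- row$base[1] +
    sum(params$increments$sphere1[s1], 0) +
    sum(params$increments$sphere2[s2], 0)
  if (params$sigma > 0) val <- val + rnorm(1, 0, params$sigma)
  val
}

#' Generate an annotated synthetic dataset
#'
#' Generates molecules, enumerates their non-ring bonds, attaches surrogate
#' BDEs, and (optionally) writes a per-bond annotated SDF plus a YAML
#' manifest of seeds and parameters.
#'
#' @param n Number of molecules.
#' @param params A [surrogate_params()].
#' @param out_path Optional SDF output path (manifest goes to
#'   `<out_path>.manifest.yaml`).
#' @param seed Integer seed governing both generation and noise.
#' @param bde_tag SDF property tag (default `"BDE"`).
#' @param ... Passed to [generate_molecules()].
#' @return List with `molecules` and `bonds` (tibble: molecule, from, to,
#'   element_pair, order, bde), invisibly including the path when written.
#' @export
make_dataset <- function(n, params = surrogate_params(), out_path = NULL,
                         seed, bde_tag = "BDE", ...) {
  mols <- generate_molecules(n, seed = seed, ...)
  bonds <- withr::with_seed(seed + 1L, {
    purrr::imap(mols, function(g, id) {
      bl <- enumerate_bonds(g)
      if (!nrow(bl)) return(NULL)
      D <- topological_distances(g)
      bl$bde <- vapply(seq_len(nrow(bl)), function(k) {
        surrogate_bde(g, c(bl$from[k], bl$to[k]), params,
                      env = assign_spheres(g, c(bl$from[k], bl$to[k]), D = D))
      }, numeric(1))
      bl$molecule <- id
      bl
    }) %>% bind_rows() %>%
      select("molecule", "from", "to", "element_pair", "order", "bde")
  })
  if (!is.null(out_path)) {
    write_annotated_sdf(mols, out_path, bonds = bonds, bde_tag = bde_tag)
    yaml::write_yaml(
      list(n_molecules = n, seed = seed, sigma = params$sigma,
           bde_tag = bde_tag,
           increments = lapply(params$increments, as.list),
           generator = "bondscope synthetic CHONS"),
      paste0(out_path, ".manifest.yaml")
    )
  }
  invisible(list(molecules = mols, bonds = bonds, path = out_path))
}
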