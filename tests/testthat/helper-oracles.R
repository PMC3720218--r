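# Independent oracles: naive reimplementations used to cross-check the
# descriptor engine. Deliberately avoid igraph and the package's distance
# code - plain BFS over an adjacency list.

oracle_adj <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[i]; b <- g$bonds$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

oracle_bfs <- function(adj, start, blocked_edge = NULL) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.null(blocked_edge) &&
          ((v == blocked_edge[1] && w == blocked_edge[2]) ||
           (v == blocked_edge[2] && w == blocked_edge[1]))) next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

oracle_distances <- function(g, blocked_edge = NULL) {
  adj <- oracle_adj(g)
  n <- length(adj)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) D[s, ] <- oracle_bfs(adj, s, blocked_edge)
  D
}

oracle_spheres <- function(g, bond) {
  D <- oracle_distances(g)
  pmin(D[bond[1], ], D[bond[2], ])
}

oracle_type <- function(g, system) {
  if (system == "element") g$atoms$element else g$atoms$cn
}

# all unordered pairs at an exact distance, with outer atom in `sphere`
oracle_pair_count <- function(g, bond, system, sphere, distance,
                              t1 = NULL, t2 = NULL) {
  D <- oracle_distances(g)
  sph <- pmin(D[bond[1], ], D[bond[2], ])
  tys <- if (system == "none") NULL else oracle_type(g, system)
  n <- nrow(g$atoms)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] != distance) next
    if (max(sph[i], sph[j]) != sphere) next
    if (!is.null(tys)) {
      got <- sort(c(tys[i], tys[j]))
      if (!identical(got, sort(c(t1, t2)))) next
    }
    cnt <- cnt + 1L
  }
  cnt
}

# before-minus-after pair counts, recomputing distances inside each fragment
oracle_bbd_count <- function(g, bond, system, distance, t1 = NULL, t2 = NULL) {
  D0 <- oracle_distances(g)
  D1 <- oracle_distances(g, blocked_edge = bond)
  tys <- if (system == "none") NULL else oracle_type(g, system)
  n <- nrow(g$atoms)
  before <- 0L; after <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    type_ok <- is.null(tys) ||
      identical(sort(c(tys[i], tys[j])), sort(c(t1, t2)))
    if (!type_ok) next
    if (D0[i, j] == distance) before <- before + 1L
    if (!is.na(D1[i, j]) && D1[i, j] == distance) after <- after + 1L
  }
  before - after
}

oracle_fragment_counts <- function(g, bond, system, subset = "all") {
  memb <- oracle_bfs(oracle_adj(g), bond[1], blocked_edge = bond)
  side1 <- !is.na(memb)
  tys <- oracle_type(g, system)
  keep <- switch(subset,
    all = rep(TRUE, nrow(g$atoms)),
    aromatic = g$atoms$aromatic,
    ring = g$atoms$in_ring,
    pi = g$atoms$in_pi)
  list(side1 = table(tys[side1 & keep]), side2 = table(tys[!side1 & keep]))
}

# shared small corpus for property tests (built once per test run)
oracle_corpus <- function(n = 30, seed = 402, max_heavy = 8) {
  generate_molecules(n, max_heavy_atoms = max_heavy, seed = seed)
}

random_nonring_bond <- function(g, seed) {
  bl <- enumerate_bonds(g)
  if (!nrow(bl)) return(NULL)
  withr::with_seed(seed, {
    k <- sample.int(nrow(bl), 1)
  })
  c(bl$from[k], bl$to[k])
}
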