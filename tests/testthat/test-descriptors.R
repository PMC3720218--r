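test_that("point descriptors count atom types per sphere", {
  methane <- parse_structure("C")
  env <- assign_spheres(methane, c(1, 2))
  p0 <- point_descriptors(env, "cn", sphere = 0)
  expect_equal(unname(p0[c("C4", "H1")]), c(1L, 1L))
  expect_equal(sum(p0), 2L)
  p1 <- point_descriptors(env, "element", sphere = 1)
  expect_equal(unname(p1["H"]), 3L)
  expect_equal(sum(p1), 3L)

  benz <- parse_structure("c1ccccc1")
  ringbond <- benz$bonds[benz$bonds$in_ring, ][1, ]
  envb <- assign_spheres(benz, c(ringbond$from, ringbond$to))
  pa <- point_descriptors(envb, "element", subset = "aromatic", sphere = 1)
  expect_equal(unname(pa["C"]), 2L)
  expect_equal(unname(pa["H"]), 0L)
})

test_that("pair descriptors match the worked example, including which pairs", {
  g <- example_molecule()
  env <- assign_spheres(g, c(8, 9))
  pd <- pair_descriptors(env, "element", sphere = 2, distance = 2)
  expect_equal(unname(pd["C.C"]), 4L)
  # enumerate the contributing pairs explicitly
  D <- env$D
  n <- nrow(g$atoms)
  hits <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] == 2 && max(env$sphere[i], env$sphere[j]) == 2 &&
        g$atoms$element[i] == "C" && g$atoms$element[j] == "C") {
      hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  expect_equal(sort(vapply(hits, paste, character(1), collapse = "-")),
               c("4-6", "4-8", "6-8", "9-11"))

  # methane C-H bond, sphere 1, distance 2: the three sphere-1 hydrogens
  # pair with each other (3 pairs) and with the sphere-0 hydrogen (3 more),
  # since a pair only needs its outer atom in the sphere - the same rule
  # that makes pair 9-11 count in the worked example above
  methane <- parse_structure("C")
  envm <- assign_spheres(methane, c(1, 2))
  expect_equal(unname(pair_descriptors(envm, "element", 1, 2)["H.H"]), 6L)
  expect_equal(unname(pair_descriptors(envm, "element", 1, 2)["H.H"]),
               oracle_pair_count(methane, c(1, 2), "element", 1, 2, "H", "H"))
  expect_equal(unname(pair_descriptors(envm, "none", 0, 1)), 1L)
})

test_that("bond-breaking differences equal hand counts on ethane", {
  ethane <- parse_structure("CC")
  env <- assign_spheres(ethane, c(1, 2))
  expect_equal(unname(bond_breaking_difference(env, "element", 2)["C.H"]), 6L)
  expect_equal(unname(bond_breaking_difference(env, "element", 3)["H.H"]), 9L)
  expect_equal(unname(bond_breaking_difference(env, "element", 2)["H.H"]), 0L)
  chx <- parse_structure("C1CCCCC1")
  envr <- assign_spheres(chx, c(1, 2))
  expect_error(bond_breaking_difference(envr, "element", 2),
               class = "bondscope_cleavage_error")
})

test_that("fragment point descriptors are sorted and subset-aware", {
  ethane <- parse_structure("CC")
  env <- assign_spheres(ethane, c(1, 2))
  fp <- fragment_point_descriptors(env, "element")
  hs <- fp[fp$type == "H", ]
  expect_equal(hs$value[hs$rank == 1], 3L)
  expect_equal(hs$value[hs$rank == 2], 3L)

  etoh <- parse_structure("CCO")
  enve <- assign_spheres(etoh, c(2, 3))
  fpe <- fragment_point_descriptors(enve, "element")
  he <- fpe[fpe$type == "H", ]
  expect_equal(he$value[he$rank == 1], 5L)
  expect_equal(he$value[he$rank == 2], 1L)

  # toluene methyl C-H: all six aromatic carbons sit on the ring side
  tol <- parse_structure("Cc1ccccc1")
  ch <- enumerate_bonds(tol)
  ch <- ch[ch$from == 1 & tol$atoms$element[ch$to] == "H", ][1, ]
  envt <- assign_spheres(tol, c(ch$from, ch$to))
  fpt <- fragment_point_descriptors(envt, "element", subset = "aromatic")
  ct <- fpt[fpt$type == "C", ]
  expect_equal(ct$value[ct$rank == 1], 6L)
  expect_equal(ct$value[ct$rank == 2], 0L)
  # pi-total merges the two sides
  pit <- molecular_descriptors(tol, "element", subset = "pi")
  expect_equal(unname(pit["C"]), 6L)
})

test_that("molecular descriptors ignore the target bond", {
  methane <- parse_structure("C")
  mp <- molecular_descriptors(methane, "element")
  expect_equal(unname(mp[c("C", "H")]), c(1L, 4L))
  ethane <- parse_structure("CC")
  ep <- molecular_descriptors(ethane, "element", distance = 1)
  expect_equal(unname(ep[c("C.C", "C.H")]), c(1L, 6L))
  benz <- parse_structure("c1ccccc1")
  bp <- molecular_descriptors(benz, "cn")
  expect_equal(unname(bp[c("C3", "H1")]), c(6L, 6L))
})

test_that("descriptor vectors are orientation-invariant and catalog-ordered", {
  cat_full <- build_catalog("full", max_sphere = 4)
  for (g in oracle_corpus(8, seed = 51)) {
    bond <- random_nonring_bond(g, seed = 3)
    if (is.null(bond)) next
    v1 <- compute_vector(g, bond, cat_full)
    v2 <- compute_vector(g, rev(bond), cat_full)
    expect_identical(v1, v2)
    expect_equal(names(v1), cat_full$name)
    expect_true(all(v1 >= 0))
  }
})

test_that("no-type pairs roll up typed pairs; element rolls up CN; spheres conserve", {
  cat_full <- build_catalog("full", max_sphere = 4)
  for (g in oracle_corpus(6, seed = 61)) {
    bond <- random_nonring_bond(g, seed = 13)
    if (is.null(bond)) next
    env <- assign_spheres(g, bond)
    for (s in 0:3) {
      for (d in 1:4) {
        typed <- pair_descriptors(env, "cn", sphere = s, distance = d)
        untyped <- pair_descriptors(env, "none", sphere = s, distance = d)
        expect_equal(sum(typed), unname(untyped))
      }
      cn_pt <- point_descriptors(env, "cn", sphere = s)
      el_pt <- point_descriptors(env, "element", sphere = s)
      for (e in c("C", "H", "O", "N", "S")) {
        cn_of_e <- grep(paste0("^", e, "[0-9]+$"), names(cn_pt), value = TRUE)
        expect_equal(sum(cn_pt[cn_of_e]), unname(el_pt[e]))
      }
      expect_equal(sum(cn_pt), sum(env$sphere == s))
    }
  }
})

test_that("pair families agree with the naive all-pairs oracle", {
  mols <- oracle_corpus(12, seed = 71)
  for (g in mols) {
    bond <- random_nonring_bond(g, seed = 17)
    if (is.null(bond)) next
    env <- assign_spheres(g, bond)
    smax <- max(env$sphere)
    checks <- withr::with_seed(19, data.frame(
      s = sample(0:min(smax, 4), 4, replace = TRUE),
      d = sample(1:4, 4, replace = TRUE)
    ))
    for (r in seq_len(nrow(checks))) {
      s <- checks$s[r]; d <- checks$d[r]
      typed <- pair_descriptors(env, "element", sphere = s, distance = d)
      for (tp in names(typed)) {
        ts <- strsplit(tp, ".", fixed = TRUE)[[1]]
        expect_equal(unname(typed[tp]),
                     oracle_pair_count(g, bond, "element", s, d, ts[1], ts[2]))
      }
      expect_equal(unname(pair_descriptors(env, "none", s, d)),
                   oracle_pair_count(g, bond, "none", s, d))
    }
    # bond-breaking difference vs naive before/after recomputation
    for (d in 1:3) {
      expect_equal(unname(bond_breaking_difference(env, "none", d)),
                   oracle_bbd_count(g, bond, "none", d))
    }
    # fragment point counts vs naive side tallies
    fr <- oracle_fragment_counts(g, bond, "element")
    fp <- fragment_point_descriptors(env, "element")
    for (t in unique(fp$type)) {
      vals <- c(fr$side1[t], fr$side2[t])
      vals[is.na(vals)] <- 0L
      expect_equal(sort(fp$value[fp$type == t], decreasing = TRUE),
                   as.integer(sort(vals, decreasing = TRUE)),
                   ignore_attr = TRUE,
                   label = paste("fragment counts for", t))
    }
  }
})

test_that("an empty custom catalog yields an empty vector", {
  empty <- build_catalog("custom", definitions = bondscope:::new_definitions(
    family = character(), type_system = character(), subset = character()))
  v <- compute_vector(parse_structure("CC"), c(1, 2), empty)
  expect_length(v, 0)
})

test_that("topologically equivalent bonds get identical vectors", {
  # two N-H bonds of a symmetric diamine are indistinguishable by construction
  g <- parse_structure("NCCN")
  bl <- enumerate_bonds(g)
  nh <- bl[bl$element_pair == "H-N", ]
  cat3 <- build_catalog("selection3")
  vs <- lapply(seq_len(nrow(nh)), function(i) {
    compute_vector(g, c(nh$from[i], nh$to[i]), cat3)
  })
  for (i in seq_along(vs)[-1]) expect_identical(vs[[1]], vs[[i]])
})
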