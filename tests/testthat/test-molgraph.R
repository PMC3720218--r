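test_that("SMILES parsing materializes hydrogens and kekulizes", {
  m <- parse_structure("C")
  expect_equal(nrow(m$atoms), 5)
  expect_equal(nrow(m$bonds), 4)
  expect_equal(sum(m$atoms$element == "H"), 4)

  b <- parse_structure("c1ccccc1")
  expect_equal(nrow(b$atoms), 12)
  expect_true(all(b$bonds$order %in% 1:2))
  expect_equal(sum(b$bonds$order == 2), 3)
})

test_that("non-CHONS elements are rejected as chemistry errors", {
  molfile <- paste(
    c("phosphine", "  test", "",
      "  1  0  0  0  0  0  0  0  0  0999 V2000",
      "    0.0000    0.0000    0.0000 P   0  0  0  0  0  0  0  0  0  0  0  0",
      "M  END"), collapse = "\n")
  expect_error(parse_structure(molfile), class = "bondscope_chemistry_error")
  expect_error(parse_structure("garbage((("), class = "bondscope_format_error")
})

test_that("admission accepts neutral molecules and zwitterions, rejects ions", {
  expect_true(validate_molecule(parse_structure("C"))$accepted)
  zwit <- parse_structure("[NH3+]CC(=O)[O-]")
  expect_equal(zwit$charge, 0L)
  expect_true(validate_molecule(zwit)$accepted)
  v <- validate_molecule(parse_structure("[NH4+]"))
  expect_false(v$accepted)
  expect_equal(v$reason, "net_charge")
})

test_that("connection-number atom types follow the 14-label closed set", {
  expect_equal(atom_type(parse_structure("C"), 1, "cn"), "C4")
  ethyne <- parse_structure("C#C")
  expect_equal(atom_type(ethyne, 1, "cn"), "C2")
  h_idx <- which(ethyne$atoms$element == "H")[1]
  expect_equal(atom_type(ethyne, h_idx, "cn"), "H1")
  expect_equal(atom_type(ethyne, 1, "element"), "C")
  expect_length(cn_type_labels(), 14)
  expect_false("C1" %in% cn_type_labels())
})

test_that("element label equals the connection-number label minus its digit", {
  for (g in oracle_corpus(10, seed = 11)) {
    expect_equal(g$atoms$element, gsub("[0-9]+$", "", g$atoms$cn))
    expect_true(all(g$atoms$cn %in% cn_type_labels()))
  }
})

test_that("ring, aromatic and pi flags match the pinned models", {
  benz <- parse_structure("c1ccccc1")
  carb <- benz$atoms$element == "C"
  expect_true(all(benz$atoms$aromatic[carb]))
  expect_true(all(benz$atoms$in_ring[carb]))
  expect_true(all(benz$atoms$in_pi[carb]))
  expect_false(any(benz$atoms$aromatic[!carb]))

  ethane <- parse_structure("CC")
  expect_false(any(ethane$atoms$in_ring))
  expect_false(any(ethane$atoms$aromatic))
  expect_false(any(ethane$atoms$in_pi))

  buta <- parse_structure("C=CC=C")
  expect_equal(sum(buta$atoms$in_pi[buta$atoms$element == "C"]), 4)
  expect_false(any(buta$atoms$aromatic))
  expect_false(any(buta$atoms$in_ring))

  # heteroaromatics under the Hueckel count
  pyridine <- parse_structure("c1ccncc1")
  expect_equal(sum(pyridine$atoms$aromatic), 6)
  pyrrole <- parse_structure("c1cc[nH]c1")
  expect_equal(sum(pyrrole$atoms$aromatic), 5)
  # cyclohexane: ring but not aromatic
  chx <- parse_structure("C1CCCCC1")
  expect_equal(sum(chx$atoms$in_ring), 6)
  expect_false(any(chx$atoms$aromatic))
  # amide nitrogen joins the pi system as a lone-pair donor
  amide <- parse_structure("CC(=O)N")
  expect_true(amide$atoms$in_pi[which(amide$atoms$element == "N")])
})

test_that("the two Kekule resolutions of an aromatic ring give identical descriptors", {
  cat_full <- build_catalog("full", max_sphere = 4)
  for (pair in list(c("c1ccccc1", "C1=CC=CC=C1"),
                    c("Cc1ccccc1", "CC1=CC=CC=C1"),
                    c("c1ccc(O)cc1", "C1=CC=C(O)C=C1"))) {
    v1 <- compute_descriptors(parse_structure(pair[1]), cat_full)
    v2 <- compute_descriptors(parse_structure(pair[2]), cat_full)
    key <- function(v) {
      m <- as.matrix(v[descriptor_columns(v)])
      sort(apply(m, 1, paste, collapse = ","))
    }
    expect_equal(key(v1), key(v2))
  }
})

test_that("molfile atom numbering and formal charges survive parsing", {
  g <- example_molecule()
  expect_equal(g$atoms$element[14], "O")
  expect_equal(g$atoms$cn[8], "C2")
  txt <- paste(c(bondscope:::molfile_text(g, "rt"), "$$$$"), collapse = "\n")
  g2 <- parse_structure(txt)
  expect_equal(g2$atoms$element, g$atoms$element)
  expect_equal(g2$bonds$order, g$bonds$order)
})
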