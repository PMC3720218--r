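test_that("non-ring bond enumeration", {
  expect_equal(nrow(enumerate_bonds(parse_structure("C"))), 4)
  benz <- enumerate_bonds(parse_structure("c1ccccc1"))
  expect_equal(nrow(benz), 6)
  expect_true(all(benz$element_pair == "C-H"))
  expect_equal(nrow(enumerate_bonds(parse_structure("CC"))), 7)
})

test_that("deduplication keeps one record per identical descriptor vector", {
  cat3 <- build_catalog("selection3")
  methane <- compute_descriptors(parse_structure("C"), cat3)
  dd <- deduplicate(methane)
  expect_equal(nrow(dd$records), 1)
  expect_equal(dd$report$size, 4)

  ethane <- compute_descriptors(parse_structure("CC"), cat3)
  dd2 <- deduplicate(ethane)
  expect_equal(nrow(dd2$records), 2)
  expect_equal(sum(dd2$report$size), nrow(ethane))

  # idempotence
  dd3 <- deduplicate(dd2$records)
  expect_equal(nrow(dd3$records), nrow(dd2$records))
  expect_true(all(dd3$report$size == 1))
})

test_that("molecules identical up to the max sphere deduplicate across molecules", {
  # pentane vs 1-butanol-backbone: the difference (C vs O) sits 4 bonds from
  # the terminal C-H bond, outside a 4-layer point-only catalog
  cat4 <- build_catalog("cn-point-only", max_sphere = 4,
                        include_molecular = FALSE)
  g1 <- parse_structure("CCCCC")
  g2 <- parse_structure("CCCCO")
  b1 <- enumerate_bonds(g1)
  h_on_c1 <- b1[b1$from == 1 & g1$atoms$element[b1$to] == "H", ][1, ]
  recs <- dplyr::bind_rows(
    compute_descriptors(list(pentane = g1), cat4,
                        bonds = tibble::tibble(molecule = "pentane",
                                               from = h_on_c1$from, to = h_on_c1$to)),
    compute_descriptors(list(butanol = g2), cat4,
                        bonds = tibble::tibble(molecule = "butanol",
                                               from = h_on_c1$from, to = h_on_c1$to))
  )
  dd <- deduplicate(recs)
  expect_equal(nrow(dd$records), 1)
  expect_equal(dd$report$size, 2)
})

test_that("annotated SDF round trip preserves labels and skips bad records", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  ds <- make_dataset(5, surrogate_params(sigma = 1), out_path = tmp, seed = 11)
  ann <- read_annotated_sdf(tmp)
  expect_equal(length(ann$molecules), 5)
  expect_equal(nrow(ann$skipped), 0)

  # cross-check record segmentation and connection tables with ChemmineR
  sdf <- ChemmineR::read.SDFset(tmp)
  expect_equal(length(sdf), nrow(ds$bonds))
  bb <- ChemmineR::bondblock(sdf[[1]])
  g1 <- ann$molecules[[ChemmineR::sdfid(sdf[1])]]
  expect_equal(unname(bb[, 1:2]),
               unname(cbind(g1$bonds$from, g1$bonds$to)))
  joined <- dplyr::inner_join(ds$bonds, ann$labels,
                              by = c("molecule", "from", "to"))
  expect_equal(nrow(joined), nrow(ds$bonds))
  expect_true(all(abs(joined$bde.x - joined$bde.y) < 1e-6))

  # append a globally charged record: it must be skipped with a reason
  amm <- parse_structure("[NH4+]")
  con <- file(tmp, "a")
  writeLines(c(bondscope:::molfile_text(amm, "ammonium"),
               ">  <BDE>", "10.0", "", "$$$$"), con)
  close(con)
  ann2 <- read_annotated_sdf(tmp)
  expect_equal(nrow(ann2$skipped), 1)
  expect_equal(ann2$skipped$reason, "net_charge")
  expect_equal(length(ann2$molecules), 5)
})

test_that("missing BDE labels raise a labeling error listing records", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  g <- parse_structure("CC")
  con <- file(tmp, "w")
  writeLines(c(bondscope:::molfile_text(g, "m1"),
               ">  <BDE>", "90.0", "", "$$$$",
               bondscope:::molfile_text(g, "m2"), "$$$$"), con)
  close(con)
  expect_error(read_annotated_sdf(tmp), class = "bondscope_label_error")
})

test_that("empty SDF gives an empty result with a warning", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", tmp)
  expect_warning(out <- read_annotated_sdf(tmp), "empty")
  expect_length(out$molecules, 0)
})

test_that("molecule-level splits are reproducible and never straddle", {
  cat3 <- build_catalog("selection3")
  ds <- make_dataset(10, surrogate_params(sigma = 0), seed = 23)
  recs <- build_records(list(molecules = ds$molecules, labels = ds$bonds), cat3)
  s1 <- split_by_molecule(recs, 0.9, seed = 7)
  s2 <- split_by_molecule(recs, 0.9, seed = 7)
  expect_identical(s1$train, s2$train)
  expect_equal(length(unique(s1$train$molecule)), 9)
  expect_equal(length(unique(s1$test$molecule)), 1)
  for (seed in 1:100) {
    sp <- split_by_molecule(recs, 0.7, seed = seed)
    expect_length(intersect(unique(sp$train$molecule),
                            unique(sp$test$molecule)), 0)
  }
})

test_that("stratified sampling caps class sizes deterministically", {
  ds <- make_dataset(30, surrogate_params(sigma = 0), seed = 29)
  capped <- stratified_sample(ds$bonds, per_class = 5, seed = 1)
  sizes <- dplyr::count(capped, .data$element_pair, .data$order)
  expect_true(all(sizes$n <= 5))
  expect_identical(capped, stratified_sample(ds$bonds, per_class = 5, seed = 1))
})

test_that("bde_summary reports extremes, minimum positive and negative counts", {
  recs <- tibble::tibble(
    element_pair = c("C-H", "C-H", "C-N", "C-N", "N-N"),
    order = c(1, 1, 1, 1, 1),
    bde = c(99.5, 101.5, 80, 85.9, -3.2)
  )
  s <- bde_summary(recs)
  expect_equal(s$overall$max, 101.5)
  expect_equal(s$overall$min, -3.2)
  expect_equal(s$overall$min_positive, 80)
  expect_equal(s$overall$n_negative, 1)
  cn <- s$by_class[s$by_class$element_pair == "C-N", ]
  expect_equal(cn$mean_bde, 82.95)
})
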