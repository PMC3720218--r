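# Bond-level datasets ---------------------------------------------------------

#' Enumerate the non-ring bonds of a molecule
#'
#' Homolytic dissociation is modelled for bonds whose cleavage yields two
#' fragments, i.e. all covalent bonds not in any ring.
#'
#' @param g A [mol_graph()].
#' @return Tibble with `from`, `to` (from < to), `order`, `element_pair`.
#' @export
#' @examples
#' nrow(enumerate_bonds(parse_structure("C")))        # 4
#' nrow(enumerate_bonds(parse_structure("c1ccccc1"))) # 6 C-H bonds
enumerate_bonds <- function(g) {
  b <- g$bonds %>% filter(!.data$in_ring)
  if (!nrow(b)) {
    return(tibble(from = integer(), to = integer(), order = integer(),
                  element_pair = character()))
  }
  tibble(
    from = pmin(b$from, b$to),
    to = pmax(b$from, b$to),
    order = b$order,
    element_pair = purrr::map2_chr(b$from, b$to, ~element_pair(g, .x, .y))
  ) %>% arrange(.data$from, .data$to)
}

# -- SDF output ---------------------------------------------------------------

# Compact V2000 emitter: one record per annotated bond (coordinates are all
# zero - descriptors are purely topological). ChemmineR cannot conveniently
# assemble SDFset objects for graphs built in code, hence a direct writer.
molfile_text <- function(g, title = "") {
  n <- nrow(g$atoms); m <- nrow(g$bonds)
  lines <- c(title, "  bondscope", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, g$atoms$element)
  lines <- c(lines, atom_lines)
  if (m > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds$from, g$bonds$to, g$bonds$order))
  }
  chg <- which(g$atoms$charge != 0L)
  if (length(chg)) {
    for (start in seq(1, length(chg), by = 8)) {
      sl <- chg[start:min(start + 7, length(chg))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(sl)),
                               paste0(sprintf("%4d%4d", sl, g$atoms$charge[sl]),
                                      collapse = "")))
    }
  }
  c(lines, "M  END")
}

#' Write molecules (optionally one record per labelled bond) to SDF
#'
#' With `bonds` given, the molecule is emitted once per bond record and each
#' record carries the target-bond atoms and the BDE label as SDF properties,
#' so labels survive a round trip through [read_annotated_sdf()].
#'
#' @param mols Named list of [mol_graph()] objects.
#' @param path Output file.
#' @param bonds Optional tibble with `molecule`, `from`, `to`, `bde`.
#' @param bde_tag Property tag for the label (default `"BDE"`).
#' @return `path`, invisibly.
#' @export
write_annotated_sdf <- function(mols, path, bonds = NULL, bde_tag = "BDE") {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  ids <- names(mols) %||% as.character(seq_along(mols))
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(g, id, props) {
    writeLines(molfile_text(g, title = id), con)
    for (tag in names(props)) {
      writeLines(c(sprintf(">  <%s>", tag), props[[tag]], ""), con)
    }
    writeLines("$$$$", con)
  }
  if (is.null(bonds)) {
    for (m in seq_along(mols)) emit(mols[[m]], ids[m], list())
  } else {
    for (r in seq_len(nrow(bonds))) {
      id <- as.character(bonds$molecule[r])
      g <- mols[[id]]
      props <- list(BOND_ATOMS = sprintf("%d %d", bonds$from[r], bonds$to[r]))
      props[[bde_tag]] <- sprintf("%.6f", bonds$bde[r])
      emit(g, id, props)
    }
  }
  invisible(path)
}

# -- SDF input ----------------------------------------------------------------

split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) {
    return(if (any(grepl("V2000", lines))) list(lines) else list())
  }
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- purrr::map2(starts, ends - 1L, function(s, e) {
    if (e < s) character() else lines[s:e]
  })
  recs[vapply(recs, function(r) any(grepl("V2000", r)), logical(1))]
}

# "> <TAG>" blocks after M END: value lines up to the next blank line
record_properties <- function(lines) {
  tag_idx <- grep("^>.*<([^>]+)>", lines)
  if (!length(tag_idx)) return(character())
  tags <- sub("^>.*<([^>]+)>.*$", "\\1", lines[tag_idx])
  vals <- vapply(tag_idx, function(i) {
    j <- i + 1L
    out <- character()
    while (j <= length(lines) && nzchar(trimws(lines[j]))) {
      out <- c(out, lines[j])
      j <- j + 1L
    }
    paste(out, collapse = "\n")
  }, character(1))
  setNames(vals, tags)
}

#' Read a BDE-annotated SDF
#'
#' Reads a multi-record V2000 SDFile, parses each record into an
#' explicit-hydrogen [mol_graph()] (formal charges from `M CHG` lines
#' included), applies the admission rules ([validate_molecule()]), and
#' collects per-record labels stored under `property_key` (plus, when
#' present, a `BOND_ATOMS` "i j" property naming the target bond of the
#' record). Records are split on `$$$$` delimiters directly: SDF container
#' round trips through parsed-block representations drop `M CHG` lines, and
#' charge admission depends on them.
#'
#' @param path SDF file path.
#' @param property_key SDF property tag holding the BDE in kcal/mol
#'   (default `"BDE"`).
#' @param require_label Error if a record lacks the property (default `TRUE`
#'   when any record has it).
#' @return List with `molecules` (named list of unique mol_graphs), `labels`
#'   (tibble: molecule, from, to, bde - `from`/`to` are NA for molecule-level
#'   labels) and `skipped` (tibble of rejected records with reasons).
#' @export
read_annotated_sdf <- function(path, property_key = "BDE",
                               require_label = NULL) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !any(nzchar(txt))) {
    warn("empty SDF file")
    return(list(molecules = list(),
                labels = tibble(molecule = character(), from = integer(),
                                to = integer(), bde = numeric()),
                skipped = tibble(record = integer(), reason = character())))
  }
  records <- split_sdf_records(txt)
  n_rec <- length(records)
  mols <- list()
  labels <- list()
  skipped <- list()
  has_key <- logical(n_rec)
  for (r in seq_len(n_rec)) {
    lines <- records[[r]]
    rec_txt <- paste(lines, collapse = "\n")
    g <- tryCatch(parse_molfile(rec_txt), error = function(e) e)
    if (inherits(g, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble(record = r, reason = paste0("parse: ", conditionMessage(g)))
      next
    }
    verdict <- validate_molecule(g)
    if (!verdict$accepted) {
      skipped[[length(skipped) + 1L]] <- tibble(record = r, reason = verdict$reason)
      next
    }
    props <- record_properties(lines)
    prop_get <- function(key) {
      if (!is.null(names(props)) && key %in% names(props)) {
        unname(props[key])
      } else NULL
    }
    id <- lines[1]
    if (!nzchar(id)) id <- sprintf("record_%d", r)
    g$name <- id
    mols[[id]] <- g
    bde <- suppressWarnings(as.numeric(prop_get(property_key)))
    has_key[r] <- length(bde) == 1L && is.finite(bde)
    if (!has_key[r]) bde <- NA_real_
    ba <- prop_get("BOND_ATOMS")
    if (!is.null(ba) && length(ba)) {
      ft <- as.integer(strsplit(trimws(ba), "\\s+")[[1]])
    } else {
      ft <- c(NA_integer_, NA_integer_)
    }
    labels[[length(labels) + 1L]] <-
      tibble(record = r, molecule = id, from = min(ft), to = max(ft),
             bde = bde)
  }
  labels <- bind_rows(labels)
  if (is.null(require_label)) require_label <- any(has_key)
  if (require_label && nrow(labels) && any(is.na(labels$bde))) {
    abort(paste0("records missing/invalid '", property_key, "' label: ",
                 paste(labels$record[is.na(labels$bde)], collapse = ", ")),
          class = "bondscope_label_error")
  }
  skipped <- bind_rows(skipped)
  if (is.null(skipped) || !nrow(skipped)) {
    skipped <- tibble(record = integer(), reason = character())
  }
  list(molecules = mols,
       labels = labels %>% select(-"record"),
       skipped = skipped)
}

#' Build labelled bond records with descriptors
#'
#' Joins the output of [read_annotated_sdf()] (or any molecule list plus a
#' label tibble) with descriptor vectors computed under a reference catalog.
#'
#' @param annotated Result of [read_annotated_sdf()], or a list with
#'   `molecules` and `labels` of the same shape.
#' @param catalog A [build_catalog()] result.
#' @return Tibble: `molecule`, `from`, `to`, `element_pair`, `order`, `bde`,
#'   then descriptor columns. Carries the catalog in attribute `"catalog"`.
#' @export
build_records <- function(annotated, catalog) {
  mols <- annotated$molecules
  labels <- annotated$labels
  target_bonds <- NULL
  if (nrow(labels) && !all(is.na(labels$from))) {
    target_bonds <- labels %>% filter(!is.na(.data$from)) %>%
      select("molecule", "from", "to")
  }
  desc <- compute_descriptors(mols, catalog, bonds = target_bonds)
  lab <- labels %>% select(dplyr::any_of(c("molecule", "from", "to", "bde")))
  if (all(is.na(lab$from))) {
    lab <- lab %>% select("molecule", "bde") %>% distinct()
    out <- desc %>% left_join(lab, by = "molecule")
  } else {
    out <- desc %>% left_join(lab, by = c("molecule", "from", "to"))
  }
  out <- out %>% dplyr::relocate("bde", .after = "order")
  attr(out, "catalog") <- catalog
  out
}

# -- dedup / split ------------------------------------------------------------

#' Deduplicate identical bonds
#'
#' Two bonds are "identical" when their full descriptor vectors under the
#' reference catalog coincide; one representative per class is retained.
#'
#' @param records Tibble from [build_records()] / [compute_descriptors()].
#' @return List with `records` (one representative per class, first
#'   occurrence kept) and `report` (tibble: class id, size, representative
#'   molecule/bond).
#' @export
#' @examples
#' cat3 <- build_catalog("selection3")
#' recs <- compute_descriptors(parse_structure("C"), cat3)
#' deduplicate(recs)$report$size  # 4 equivalent C-H bonds -> one class
deduplicate <- function(records) {
  dcols <- descriptor_columns(records)
  if (!length(dcols)) {
    abort("records carry no descriptor columns", class = "bondscope_consistency_error")
  }
  key <- do.call(paste, c(records[dcols], sep = "\r"))
  cls <- match(key, unique(key))
  keep <- !duplicated(cls)
  report <- records %>%
    mutate(.class = cls) %>%
    group_by(.data$.class) %>%
    summarise(size = n(),
              molecule = dplyr::first(.data$molecule),
              from = dplyr::first(.data$from),
              to = dplyr::first(.data$to), .groups = "drop") %>%
    rename(class = ".class")
  out <- records[keep, , drop = FALSE]
  attr(out, "catalog") <- attr(records, "catalog")
  list(records = out, report = report)
}

#' Split records by molecule
#'
#' Molecule-level random partition: no molecule contributes bonds to both
#' sides.
#'
#' @param records Record tibble with a `molecule` column.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed (mandatory; the split is reproducible).
#' @return List with `train`, `test` (tibbles) and `seed`.
#' @export
split_by_molecule <- function(records, fraction = 0.9, seed) {
  stopifnot(fraction > 0, fraction < 1)
  mols <- unique(records$molecule)
  n_train <- max(1L, min(length(mols) - 1L, round(fraction * length(mols))))
  train_ids <- withr::with_seed(seed, sample(mols, n_train))
  list(
    train = records %>% filter(.data$molecule %in% train_ids),
    test = records %>% filter(!.data$molecule %in% train_ids),
    seed = seed
  )
}

#' Stratified sampling of bond records
#'
#' Utility for balancing synthetic corpora by bond class (element pair +
#' bond order), in the spirit of enriching underrepresented bond types.
#'
#' @param records Record tibble.
#' @param per_class Maximum records kept per (element pair, order) class.
#' @param seed Integer seed.
#' @return Subset tibble.
#' @export
stratified_sample <- function(records, per_class, seed) {
  withr::with_seed(seed, {
    records %>%
      group_by(.data$element_pair, .data$order) %>%
      dplyr::slice_sample(n = per_class) %>%
      ungroup()
  })
}

#' Summary statistics of a labelled bond set
#'
#' The descriptive numbers usually reported for a BDE training set: extremes,
#' the smallest positive label, how many labels are negative, and per-class
#' means.
#'
#' @param records Labelled record tibble (needs `bde`, `element_pair`,
#'   `order`).
#' @return List with `overall` (one-row tibble: n, min, max, min_positive,
#'   n_negative) and `by_class` (tibble of per-(element pair, order) means).
#' @export
bde_summary <- function(records) {
  stopifnot("bde" %in% names(records))
  b <- records$bde
  overall <- tibble(
    n = length(b),
    min = min(b), max = max(b),
    min_positive = if (any(b > 0)) min(b[b > 0]) else NA_real_,
    n_negative = sum(b < 0)
  )
  by_class <- records %>%
    group_by(.data$element_pair, .data$order) %>%
    summarise(n = n(), mean_bde = mean(.data$bde), sd_bde = sd(.data$bde),
              .groups = "drop")
  list(overall = overall, by_class = by_class)
}
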