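# Descriptor catalogs ---------------------------------------------------------
#
# A catalog is an ordered tibble of descriptor definitions; its order IS the
# vector layout, so enumeration must be deterministic. "N sphere layers"
# always means sphere indices 0..N-1.
#
# Families:
#   point           count of atoms of a type in one sphere (subset-restricted)
#   molecular_point same, whole molecule
#   pair            unordered atom pairs: outer atom in the sphere, partner in
#                   the same or a lower sphere, at an exact bond distance
#   molecular_pair  pairs counted over the whole molecule at a distance
#   bbd             bond-breaking difference: pairs before cleavage minus
#                   same-fragment pairs after (= cross-fragment pairs)
#   fragment_point  per-fragment counts after cleavage, value pair sorted
#                   descending (rank 1 = larger) for orientation freedom
#   pi_total        fragment_point over the pi subset with the two fragment
#                   values summed (= whole-molecule count of pi atoms by type)
#
# For pair families a (sphere s, distance d) cell is geometrically feasible
# only when d <= 2s+1 (path through the target bond); sphere 0 only admits
# d = 1 (the target bond itself). Infeasible cells are pruned from presets.

new_definitions <- function(family, type_system = "none", subset = "all",
                            sphere = NA_integer_, distance = NA_integer_,
                            type1 = NA_character_, type2 = NA_character_,
                            rank = NA_integer_) {
  tibble(family = family, type_system = type_system, subset = subset,
         sphere = as.integer(sphere), distance = as.integer(distance),
         type1 = type1, type2 = type2, rank = as.integer(rank))
}

type_pairs <- function(system) {
  labs <- type_labels(system)
  idx <- which(upper.tri(diag(length(labs)), diag = TRUE), arr.ind = TRUE)
  tibble(type1 = labs[idx[, "row"]], type2 = labs[idx[, "col"]]) %>%
    dplyr::rowwise() %>%
    mutate(t1 = min(.data$type1, .data$type2),
           t2 = max(.data$type1, .data$type2)) %>%
    ungroup() %>%
    dplyr::transmute(type1 = .data$t1, type2 = .data$t2) %>%
    distinct() %>%
    arrange(.data$type1, .data$type2)
}

enum_point <- function(system, subset, spheres) {
  grid <- tidyr::expand_grid(sphere = as.integer(spheres),
                             type1 = type_labels(system))
  new_definitions("point", system, subset, sphere = grid$sphere,
                  type1 = grid$type1)
}

enum_mol_point <- function(system, subset = "all") {
  new_definitions("molecular_point", system, subset,
                  type1 = type_labels(system))
}

feasible_sd <- function(spheres, distances) {
  grid <- tidyr::expand_grid(sphere = as.integer(spheres),
                             distance = as.integer(distances))
  grid %>% filter(.data$distance <= 2L * .data$sphere + 1L)
}

enum_pair <- function(system, spheres, distances) {
  sd <- feasible_sd(spheres, distances)
  if (system == "none") {
    return(new_definitions("pair", "none", sphere = sd$sphere,
                           distance = sd$distance))
  }
  tp <- type_pairs(system)
  grid <- tidyr::crossing(sd, tp)
  new_definitions("pair", system, sphere = grid$sphere,
                  distance = grid$distance, type1 = grid$type1,
                  type2 = grid$type2)
}

enum_mol_pair <- function(system, distances) {
  if (system == "none") {
    return(new_definitions("molecular_pair", "none",
                           distance = as.integer(distances)))
  }
  grid <- tidyr::crossing(distance = as.integer(distances), type_pairs(system))
  new_definitions("molecular_pair", system, distance = grid$distance,
                  type1 = grid$type1, type2 = grid$type2)
}

enum_bbd <- function(system, distances) {
  if (system == "none") {
    return(new_definitions("bbd", "none", distance = as.integer(distances)))
  }
  grid <- tidyr::crossing(distance = as.integer(distances), type_pairs(system))
  new_definitions("bbd", system, distance = grid$distance,
                  type1 = grid$type1, type2 = grid$type2)
}

enum_fragment_point <- function(system, subset) {
  grid <- tidyr::expand_grid(type1 = type_labels(system), rank = 1:2)
  new_definitions("fragment_point", system, subset, type1 = grid$type1,
                  rank = grid$rank)
}

enum_pi_total <- function(system = "element", types = c("C", "N", "O")) {
  new_definitions("pi_total", system, "pi", type1 = types)
}

definition_names <- function(defs) {
  nm <- character(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    nm[i] <- switch(
      d$family,
      point = sprintf("pnt.%s.%s.s%d.%s", d$type_system, d$subset, d$sphere, d$type1),
      molecular_point = sprintf("mol.pnt.%s.%s.%s", d$type_system, d$subset, d$type1),
      pair = if (d$type_system == "none") {
        sprintf("pair.none.s%d.d%d", d$sphere, d$distance)
      } else {
        sprintf("pair.%s.s%d.d%d.%s.%s", d$type_system, d$sphere, d$distance,
                d$type1, d$type2)
      },
      molecular_pair = if (d$type_system == "none") {
        sprintf("mol.pair.none.d%d", d$distance)
      } else {
        sprintf("mol.pair.%s.d%d.%s.%s", d$type_system, d$distance, d$type1, d$type2)
      },
      bbd = if (d$type_system == "none") {
        sprintf("bbd.none.d%d", d$distance)
      } else {
        sprintf("bbd.%s.d%d.%s.%s", d$type_system, d$distance, d$type1, d$type2)
      },
      fragment_point = sprintf("frg.%s.%s.r%d.%s", d$type_system, d$subset,
                               d$rank, d$type1),
      pi_total = sprintf("pit.%s.%s", d$type_system, d$type1)
    )
  }
  nm
}

#' Build a descriptor catalog
#'
#' Deterministically enumerates descriptor definitions for one of the named
#' presets. "N sphere layers" means sphere indices 0..N-1.
#'
#' Presets:
#' \describe{
#'   \item{`cn-point-only`}{Connection-number point descriptors for every
#'     sphere layer, plus (by default) the molecular point descriptors:
#'     14 x (N + 1) definitions, i.e. 112 at N = 7.}
#'   \item{`full`}{The extensive connection-number pool: point descriptors
#'     (with molecular), ring/pi/aromatic-restricted point descriptors, pair
#'     descriptors at distances 1-4, molecular pairs, and bond-breaking
#'     difference pairs.}
#'   \item{`selection1`}{The `full` layout with the 5-label element type
#'     system substituted throughout.}
#'   \item{`selection2`}{Connection-number points; element pairs at distance
#'     1; no-type pairs at distances 2-7; fragment points (plain CN, and
#'     element-typed aromatic/ring/pi); no-type bond-breaking differences;
#'     molecular element pairs.}
#'   \item{`selection3`}{The compact 4-layer set: CN points (56), element
#'     pairs at distance 1 for spheres 1-3 (45), aromatic element fragment
#'     points (10), no-type pairs for spheres 1-3 at feasible distances up to
#'     7 (15), and pi-total counts for C, N, O (3) - 129 definitions.}
#'   \item{`custom`}{Pass your own `definitions` tibble.}
#' }
#'
#' @param preset Preset name (see Details).
#' @param max_sphere Number of sphere layers N (indices 0..N-1). Defaults:
#'   7 for `cn-point-only`, `full`, `selection1`; 6 for `selection2`; 4 for
#'   `selection3`.
#' @param distances Pair distances for the `full`/`selection1` pools
#'   (default 1:4).
#' @param include_molecular For `cn-point-only`: append the molecular point
#'   block (default `TRUE`).
#' @param definitions For `preset = "custom"`: a definitions tibble as
#'   produced by the internal enumerators.
#' @return A `descriptor_catalog`: tibble of definitions with a unique `name`
#'   per row; attributes `preset` and `max_sphere`.
#' @export
#' @examples
#' nrow(build_catalog("cn-point-only", max_sphere = 7))          # 112
#' nrow(build_catalog("cn-point-only", 4, include_molecular = FALSE)) # 56
#' nrow(build_catalog("selection3"))                              # 129
build_catalog <- function(preset = c("selection3", "full", "selection1",
                                     "selection2", "cn-point-only", "custom"),
                          max_sphere = NULL, distances = 1:4,
                          include_molecular = TRUE, definitions = NULL) {
  preset <- match.arg(preset)
  if (preset != "custom" && !is.null(distances) &&
      preset %in% c("full", "selection1") &&
      (any(distances < 1L) || any(distances > 4L))) {
    abort("pair distances must lie in 1..4 for the full/selection1 pools",
          class = "bondscope_catalog_error")
  }
  defs <- switch(
    preset,
    "cn-point-only" = {
      if (is.null(max_sphere)) max_sphere <- 7L
      d <- enum_point("cn", "all", 0:(max_sphere - 1L))
      if (include_molecular) d <- bind_rows(d, enum_mol_point("cn"))
      d
    },
    "full" = build_pool("cn", max_sphere %||% 7L, distances),
    "selection1" = build_pool("element", max_sphere %||% 7L, distances),
    "selection2" = {
      N <- max_sphere %||% 6L
      ss <- seq_len(N - 1L)
      bind_rows(
        enum_point("cn", "all", 0:(N - 1L)),
        enum_pair("element", ss, 1L),
        enum_pair("none", ss, 2:7),
        enum_fragment_point("cn", "all"),
        enum_fragment_point("element", "aromatic"),
        enum_fragment_point("element", "ring"),
        enum_fragment_point("element", "pi"),
        enum_bbd("none", 2:7),
        enum_mol_pair("element", 1:2)
      )
    },
    "selection3" = {
      N <- max_sphere %||% 4L
      ss <- if (N > 1L) seq_len(N - 1L) else integer()
      bind_rows(
        enum_point("cn", "all", 0:(N - 1L)),
        if (length(ss)) enum_pair("element", ss, 1L),
        if (length(ss)) enum_pair("none", ss, 1:7),
        enum_fragment_point("element", "aromatic"),
        enum_pi_total()
      )
    },
    "custom" = {
      if (is.null(definitions)) {
        abort("custom preset needs a definitions tibble",
              class = "bondscope_catalog_error")
      }
      as_tibble(definitions)
    }
  )
  defs$name <- definition_names(defs)
  if (anyDuplicated(defs$name)) {
    abort("duplicate descriptor definitions in catalog",
          class = "bondscope_catalog_error")
  }
  structure(defs, class = c("descriptor_catalog", class(tibble())),
            preset = preset,
            max_sphere = if (is.null(max_sphere)) max(defs$sphere, 0L, na.rm = TRUE) + 1L
                         else as.integer(max_sphere))
}

build_pool <- function(system, max_sphere, distances) {
  spheres <- 0:(max_sphere - 1L)
  bind_rows(
    enum_point(system, "all", spheres),
    enum_mol_point(system),
    enum_point(system, "ring", spheres),
    enum_point(system, "pi", spheres),
    enum_point(system, "aromatic", spheres),
    enum_pair(system, spheres, distances),
    enum_mol_pair(system, distances),
    enum_bbd(system, distances)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group composition of a catalog
#'
#' @param catalog A [build_catalog()] result.
#' @return Tibble of definition counts per (family, type system, subset).
#' @export
catalog_summary <- function(catalog) {
  as_tibble(catalog) %>%
    count(.data$family, .data$type_system, .data$subset, name = "n_descriptors")
}

#' @export
print.descriptor_catalog <- function(x, ...) {
  cat(sprintf("<descriptor_catalog> preset '%s', %d sphere layer(s), %d definitions\n",
              attr(x, "preset"), attr(x, "max_sphere"), nrow(x)))
  print(catalog_summary(x))
  invisible(x)
}

#' Whether a catalog needs bond cleavage
#' @param catalog A descriptor catalog.
#' @return Logical: `TRUE` when any definition belongs to a cleavage-dependent
#'   family (bbd, fragment_point, pi_total).
#' @export
catalog_needs_cleavage <- function(catalog) {
  any(catalog$family %in% c("bbd", "fragment_point", "pi_total"))
}

#' Write / read a catalog as TSV
#'
#' The TSV carries the full vector layout (one definition per row, in order),
#' so a descriptor matrix can be reinterpreted later.
#'
#' @param catalog A descriptor catalog.
#' @param path File path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` a
#'   `descriptor_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  attr_line <- sprintf("# preset=%s max_sphere=%d",
                       attr(catalog, "preset"), attr(catalog, "max_sphere"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, regexec("preset=(\\S+) max_sphere=(\\d+)", hdr))[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          na.strings = "NA", stringsAsFactors = FALSE)
  df <- as_tibble(df)
  for (col in c("sphere", "distance", "rank")) df[[col]] <- as.integer(df[[col]])
  structure(df, class = c("descriptor_catalog", class(tibble())),
            preset = meta[2], max_sphere = as.integer(meta[3]))
}
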