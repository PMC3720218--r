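# End-to-end experiment workflows ---------------------------------------------
#
# Each workflow computes descriptors under one or more catalogs, trains a
# model with identical seeds across configurations, and reports OOB (or
# test-set) metrics as a tidy experiment table.

records_for_catalog <- function(mols, bonds, catalog, dedup = TRUE) {
  recs <- build_records(list(molecules = mols, labels = bonds), catalog)
  if (dedup) recs <- deduplicate(recs)$records
  recs
}

experiment_row <- function(label, catalog, recs, rf) {
  dplyr::bind_cols(
    tibble(label = label, n_descriptors = nrow(catalog), n_bonds = nrow(recs)),
    rf$oob_metrics
  )
}

#' Compare descriptor presets with a fixed RF configuration
#'
#' Trains one random forest per preset on the same labelled bonds (same seed
#' throughout) and reports OOB metrics, optionally ablating one descriptor
#' group at a time from a preset.
#'
#' @param mols Named list of [mol_graph()] objects.
#' @param bonds Label tibble (`molecule`, `from`, `to`, `bde`).
#' @param presets Character vector of [build_catalog()] preset names, or a
#'   named list of ready catalogs.
#' @param trees,seed RF configuration (shared across presets).
#' @param ablate_groups If `TRUE`, additionally retrain after removing each
#'   (family, type system, subset) group of the *first* preset in turn.
#' @param dedup Deduplicate identical bonds per catalog (default `TRUE`).
#' @return A `bde_experiment` tibble: label, n_descriptors, n_bonds, rmsd,
#'   mad, max_error, r2, n.
#' @export
run_selection_experiment <- function(mols, bonds, presets = c("selection3"),
                                     trees = 1000, seed = 1,
                                     ablate_groups = FALSE, dedup = TRUE) {
  if (!is.list(presets)) {
    presets <- setNames(lapply(presets, build_catalog), presets)
  }
  stopifnot(length(presets) >= 1)
  rows <- list()
  for (nm in names(presets)) {
    catalog <- presets[[nm]]
    recs <- records_for_catalog(mols, bonds, catalog, dedup)
    dcols <- descriptor_columns(recs)
    rf <- train_rf(recs[dcols], recs$bde, trees = trees, seed = seed)
    rows[[length(rows) + 1L]] <- experiment_row(nm, catalog, recs, rf)
  }
  if (ablate_groups) {
    catalog <- presets[[1]]
    groups <- catalog_summary(catalog)
    for (gi in seq_len(nrow(groups))) {
      keep <- !(catalog$family == groups$family[gi] &
                catalog$type_system == groups$type_system[gi] &
                catalog$subset == groups$subset[gi])
      sub <- build_catalog("custom",
                           definitions = as_tibble(catalog)[keep,
                             setdiff(names(catalog), "name")])
      recs <- records_for_catalog(mols, bonds, sub, dedup)
      dcols <- descriptor_columns(recs)
      rf <- train_rf(recs[dcols], recs$bde, trees = trees, seed = seed)
      lbl <- sprintf("%s - %s/%s/%s", names(presets)[1], groups$family[gi],
                     groups$type_system[gi], groups$subset[gi])
      rows[[length(rows) + 1L]] <- experiment_row(lbl, sub, recs, rf)
    }
  }
  structure(bind_rows(rows), class = c("bde_experiment", class(tibble())))
}

#' Sphere-truncation sweep
#'
#' Rebuilds a preset at different numbers of sphere layers and reports how
#' the OOB metrics and descriptor counts respond.
#'
#' @param mols,bonds As in [run_selection_experiment()].
#' @param max_list Sphere-layer counts to sweep (default 1:7).
#' @param preset Preset rebuilt per layer count (default `"selection3"`;
#'   `"cn-point-only"` gives the 14 x N closed form).
#' @param trees,seed RF configuration.
#' @param dedup Deduplicate per catalog (default `TRUE`).
#' @return A `bde_experiment` tibble with a numeric `n_spheres` column.
#' @export
run_sphere_sweep <- function(mols, bonds, max_list = 1:7,
                             preset = "selection3", trees = 1000, seed = 1,
                             dedup = TRUE) {
  stopifnot(all(max_list >= 1))
  rows <- list()
  for (N in max_list) {
    catalog <- build_catalog(preset, max_sphere = N,
                             include_molecular = FALSE)
    recs <- records_for_catalog(mols, bonds, catalog, dedup)
    dcols <- descriptor_columns(recs)
    rf <- train_rf(recs[dcols], recs$bde, trees = trees, seed = seed)
    rows[[length(rows) + 1L]] <-
      experiment_row(sprintf("%s@%d", preset, N), catalog, recs, rf) %>%
      mutate(n_spheres = N)
  }
  structure(bind_rows(rows), class = c("bde_experiment", class(tibble())))
}

#' Model versus fixed-value baseline, per bond class
#'
#' Trains the chosen model on the training side of a molecule-level split and
#' compares its test-set metrics against the per-(element pair, order) mean
#' baseline, class by class.
#'
#' @param train,test Labelled record tibbles (descriptor columns + `bde`).
#' @param model `"asnn"`, `"ensemble"` or `"rf"`.
#' @param seed Integer seed.
#' @param ... Passed to the model trainer ([train_ensemble()] or
#'   [train_rf()]).
#' @return List with `by_class` (tibble: element_pair, predictor, metrics,
#'   uses_fallback), `overall` (both predictors), and the fitted `model`.
#' @export
run_baseline_comparison <- function(train, test, model = c("asnn", "ensemble", "rf"),
                                    seed = 1, ...) {
  model <- match.arg(model)
  dcols <- descriptor_columns(train)
  fitted <- if (model == "rf") {
    train_rf(train[dcols], train$bde, seed = seed, ...)
  } else {
    train_ensemble(train[dcols], train$bde, seed = seed, ...)
  }
  pred_model <- if (model == "rf") {
    predict(fitted, test[dcols])
  } else {
    predict(fitted, test[dcols],
            type = ifelse(model == "asnn", "asnn", "ensemble"))
  }
  base <- baseline_fixed_values(train)
  pred_base <- suppressWarnings(predict(base, test))
  per_class <- function(pred, label, fallback = rep(FALSE, nrow(test))) {
    test %>%
      mutate(.pred = pred, .fb = fallback) %>%
      group_by(.data$element_pair) %>%
      dplyr::group_modify(~dplyr::bind_cols(
        suppressWarnings(evaluate(.x$.pred, .x$bde)),
        tibble(uses_fallback = any(.x$.fb))
      )) %>%
      ungroup() %>%
      mutate(predictor = label)
  }
  by_class <- bind_rows(
    per_class(pred_base$.pred, "fixed_values", pred_base$.fallback),
    per_class(pred_model, model)
  )
  overall <- bind_rows(
    evaluate(pred_base$.pred, test$bde) %>% mutate(predictor = "fixed_values"),
    evaluate(pred_model, test$bde) %>% mutate(predictor = model)
  )
  list(by_class = by_class, overall = overall, model = fitted)
}

#' @export
autoplot.bde_experiment <- function(object, ...) {
  if ("n_spheres" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$n_spheres, .data$rmsd)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "sphere layers", y = "OOB RMSD (kcal/mol)")
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(stats::reorder(.data$label, .data$rmsd),
                                 .data$rmsd)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "OOB RMSD (kcal/mol)")
  }
}
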