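# Random forest with out-of-bag validation ------------------------------------

#' Train a random forest BDE model
#'
#' Bootstrap-per-tree regression forest; each sample's out-of-bag prediction
#' comes only from trees whose bootstrap excluded it, and permutation
#' importances are reported. Defaults follow the reference configuration:
#' 1000 trees and floor(sqrt(p)) candidate variables per split.
#'
#' @param x Numeric matrix or data frame of descriptors (rows = bonds).
#' @param y Numeric vector of BDE labels (kcal/mol).
#' @param trees Number of trees (default 1000).
#' @param mtry Variables tried per split (default `floor(sqrt(ncol(x)))`).
#' @param seed Integer seed (mandatory).
#' @return A `bde_rf` object: list with `forest` (ranger object),
#'   `oob_predictions`, `oob_metrics` (tibble from [evaluate()]),
#'   `importance` (tibble, descending), `config`.
#' @export
train_rf <- function(x, y, trees = 1000, mtry = NULL, seed) {
  x <- as.data.frame(x)
  if (ncol(x) == 0) {
    abort("no descriptor columns to train on", class = "bondscope_config_error")
  }
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(
    x = x, y = y, num.trees = trees, mtry = mtry,
    importance = "permutation", seed = seed, num.threads = 1,
    oob.error = TRUE, verbose = FALSE
  )
  oob <- fit$predictions
  ok <- is.finite(oob)
  metrics <- evaluate(oob[ok], y[ok])
  imp <- tibble(descriptor = names(fit$variable.importance),
                importance = unname(fit$variable.importance)) %>%
    arrange(dplyr::desc(.data$importance))
  structure(
    list(forest = fit, oob_predictions = oob, oob_metrics = metrics,
         importance = imp,
         config = list(trees = trees, mtry = mtry, seed = seed, p = ncol(x)),
         y = y),
    class = "bde_rf"
  )
}

#' @export
print.bde_rf <- function(x, ...) {
  cat(sprintf("<bde_rf> %d trees, mtry %d, p = %d; OOB RMSD %.3f, R2 %.3f\n",
              x$config$trees, x$config$mtry, x$config$p,
              x$oob_metrics$rmsd, x$oob_metrics$r2))
  invisible(x)
}

#' @export
predict.bde_rf <- function(object, newdata, ...) {
  predict(object$forest, data = as.data.frame(newdata),
          num.threads = 1)$predictions
}

#' @export
tidy.bde_rf <- function(x, ...) x$importance

#' @export
glance.bde_rf <- function(x, ...) x$oob_metrics

#' @export
autoplot.bde_rf <- function(object, ...) {
  df <- tibble(observed = object$y, oob = object$oob_predictions)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$oob)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "BDE (kcal/mol)", y = "OOB prediction (kcal/mol)",
                  title = sprintf("Random forest OOB: RMSD %.2f kcal/mol",
                                  object$oob_metrics$rmsd))
}

#' Importance-based descriptor selection with correlation pruning
#'
#' Keeps the `k` most important descriptors, then walks them in importance
#' order and greedily drops any whose absolute Pearson correlation with an
#' already-retained descriptor exceeds the threshold.
#'
#' @param importance Tibble with `descriptor` and `importance` columns (as in
#'   `tidy(<bde_rf>)`), or a named numeric vector.
#' @param k How many descriptors to keep before pruning.
#' @param x Descriptor matrix/data frame (columns named as in `importance`)
#'   used for the correlation screen.
#' @param corr_threshold Drop when |r| exceeds this (default 0.95).
#' @return Character vector of retained descriptor names.
#' @export
select_descriptors <- function(importance, k, x, corr_threshold = 0.95) {
  if (!is.data.frame(importance)) {
    importance <- tibble(descriptor = names(importance),
                         importance = unname(importance))
  }
  importance <- importance %>% arrange(dplyr::desc(.data$importance))
  stopifnot(k <= nrow(importance))
  top <- head(importance$descriptor, k)
  xm <- as.matrix(as.data.frame(x)[, top, drop = FALSE])
  keep <- character()
  for (d in top) {
    if (!length(keep)) { keep <- d; next }
    v <- xm[, d]
    r <- suppressWarnings(abs(cor(v, xm[, keep, drop = FALSE])))
    # cor is NA when a constant column is involved: treat exact duplicates as
    # perfectly correlated, otherwise unrelated
    if (anyNA(r)) {
      for (w in which(is.na(r))) {
        r[w] <- if (all(v == xm[, keep[w]])) 1 else 0
      }
    }
    if (all(r <= corr_threshold)) keep <- c(keep, d)
  }
  keep
}
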