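# Fixed-value baseline --------------------------------------------------------

#' Per-bond-class mean baseline
#'
#' The "fixed values" predictor: the mean training-set BDE for bonds of a
#' given element pair and bond order is used as the prediction for every
#' test bond of that class. Classes unseen in training fall back to the
#' global training mean and are flagged.
#'
#' @param records Labelled record tibble (`element_pair`, `order`, `bde`).
#' @return A `bde_baseline`: list with `table` (tibble: element_pair, order,
#'   fixed, n) and `global_mean`.
#' @export
#' @examples
#' recs <- tibble::tibble(element_pair = "C-N", order = 1, bde = c(80, 90))
#' baseline_fixed_values(recs)$table$fixed  # 85
baseline_fixed_values <- function(records) {
  stopifnot(all(c("element_pair", "order", "bde") %in% names(records)))
  if (!nrow(records)) {
    abort("empty training set", class = "bondscope_config_error")
  }
  tab <- records %>%
    group_by(.data$element_pair, .data$order) %>%
    summarise(fixed = mean(.data$bde), n = n(), .groups = "drop")
  structure(list(table = tab, global_mean = mean(records$bde)),
            class = "bde_baseline")
}

#' @export
print.bde_baseline <- function(x, ...) {
  cat(sprintf("<bde_baseline> %d bond classes, global mean %.2f kcal/mol\n",
              nrow(x$table), x$global_mean))
  invisible(x)
}

#' @export
predict.bde_baseline <- function(object, newdata, ...) {
  joined <- newdata %>%
    select("element_pair", "order") %>%
    left_join(object$table, by = c("element_pair", "order"))
  fallback <- is.na(joined$fixed)
  if (any(fallback)) {
    warn(sprintf("%d bond(s) of unseen class: using the global training mean",
                 sum(fallback)))
  }
  tibble(.pred = ifelse(fallback, object$global_mean, joined$fixed),
         .fallback = fallback)
}

#' @export
tidy.bde_baseline <- function(x, ...) x$table
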