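# Prediction-quality metrics --------------------------------------------------

#' Evaluate predictions against reference values
#'
#' Root-mean-square deviation, mean absolute deviation, maximum absolute
#' deviation (all kcal/mol when the inputs are) and the coefficient of
#' determination R^2 = 1 - SS_res / SS_tot.
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @return One-row tibble: `rmsd`, `mad`, `max_error`, `r2`, `n`. With
#'   zero-variance truths R^2 is undefined and returned as `NA` with a
#'   warning.
#' @export
#' @examples
#' evaluate(c(0, 2), c(0, 0))  # rmsd sqrt(2), mad 1, max_error 2
evaluate <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) > 0)
  err <- predictions - truths
  ss_tot <- sum((truths - mean(truths))^2)
  if (ss_tot == 0) {
    warn("zero-variance reference values: R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / ss_tot
  }
  out <- tibble(
    rmsd = sqrt(mean(err^2)),
    mad = mean(abs(err)),
    max_error = max(abs(err)),
    r2 = r2,
    n = length(err)
  )
  # metric contract
  stopifnot(out$rmsd >= out$mad - 1e-12, out$max_error >= out$rmsd - 1e-12)
  out
}
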