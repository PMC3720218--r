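# FFNN ensemble with associative memory correction ----------------------------
#
# Each member is a fully connected single-hidden-layer network (logistic
# activations, bias units on the input and hidden layers) trained on its own
# random half of the training set with early stopping on the RMSD of the
# held-out half. Inputs and targets are linearly normalized to [0.1, 0.9]
# from the training data. The associative correction adds, to the ensemble
# mean, the mean residual of the k memory cases whose per-member output
# profiles are most similar (Spearman rank correlation) to the query's.

logistic <- function(z) 1 / (1 + exp(-z))

norm_bounds <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}
norm_apply <- function(x, b) {
  sweep(sweep(x, 2, b$lo, "-"), 2, b$rng, "/") * 0.8 + 0.1
}
norm_y <- function(y, b) 0.1 + 0.8 * (y - b$lo) / b$rng
denorm_y <- function(z, b) (z - 0.1) / 0.8 * b$rng + b$lo

decode_weights <- function(wts, p, h) {
  n1 <- (p + 1) * h
  list(W1 = matrix(wts[seq_len(n1)], nrow = p + 1),
       W2 = wts[(n1 + 1):(n1 + h + 1)])
}

member_forward <- function(wts, Xn, p, h) {
  w <- decode_weights(wts, p, h)
  Z <- logistic(cbind(1, Xn) %*% w$W1)
  as.vector(logistic(cbind(1, Z) %*% w$W2))
}

train_member <- function(Xn, yn, hidden, seed, chunk, patience, max_chunks) {
  n <- nrow(Xn); p <- ncol(Xn)
  withr::with_seed(seed, {
    val_idx <- sample(n, floor(n / 2))
    nw <- (p + 1) * hidden + hidden + 1
    w <- runif(nw, -0.5, 0.5)
  })
  Xtr <- Xn[-val_idx, , drop = FALSE]; ytr <- yn[-val_idx]
  Xva <- Xn[val_idx, , drop = FALSE]; yva <- yn[val_idx]
  best <- list(rmsd = Inf, wts = w)
  bad <- 0L
  for (it in seq_len(max_chunks)) {
    fit <- nnet::nnet(x = Xtr, y = ytr, size = hidden, Wts = w, maxit = chunk,
                      decay = 0, linout = FALSE, trace = FALSE,
                      MaxNWts = 10000)
    w <- fit$wts
    rmsd <- sqrt(mean((member_forward(w, Xva, p, hidden) - yva)^2))
    if (is.finite(rmsd) && rmsd < best$rmsd - 1e-9) {
      best <- list(rmsd = rmsd, wts = w)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  best
}

#' Train a feed-forward network ensemble with memory
#'
#' @param x Descriptor matrix/data frame (rows = bonds).
#' @param y BDE labels (kcal/mol).
#' @param members Ensemble size (reference configuration: 125; smaller values
#'   train much faster and are adequate for surrogate data).
#' @param hidden Hidden units per member (default 6).
#' @param seed Integer seed (mandatory; member initializations and half-splits
#'   derive from it deterministically).
#' @param chunk Optimizer iterations between validation checks (default 25).
#' @param patience Checks without held-half RMSD improvement before a member
#'   stops (default 4).
#' @param max_chunks Upper bound on checks per member (default 40).
#' @param retries Retraining attempts for a member that fails to produce a
#'   finite validation RMSD (default 3; logged via a warning).
#' @return A `bde_ensemble`: member weight vectors, normalization bounds,
#'   memory (training descriptors, labels, per-member outputs, residuals) and
#'   configuration.
#' @export
train_ensemble <- function(x, y, members = 25, hidden = 6, seed,
                           chunk = 25, patience = 4, max_chunks = 40,
                           retries = 3) {
  x <- as.matrix(as.data.frame(x))
  stopifnot(nrow(x) == length(y), members >= 1, !anyNA(x), !anyNA(y))
  bx <- norm_bounds(x)
  by <- list(lo = min(y), rng = max(max(y) - min(y), 1e-12))
  Xn <- norm_apply(x, bx)
  yn <- norm_y(y, by)
  fits <- vector("list", members)
  for (m in seq_len(members)) {
    s <- seed + 101L * m
    for (attempt in 0:retries) {
      fit <- train_member(Xn, yn, hidden, s + 7919L * attempt,
                          chunk, patience, max_chunks)
      if (is.finite(fit$rmsd)) break
      warn(sprintf("ensemble member %d retrained (attempt %d)", m, attempt + 1))
    }
    if (!is.finite(fit$rmsd)) {
      abort(sprintf("member %d failed to converge", m),
            class = "bondscope_training_error")
    }
    fits[[m]] <- fit$wts
  }
  obj <- structure(
    list(weights = fits, hidden = hidden, p = ncol(x),
         bounds = list(x = bx, y = by),
         config = list(members = members, hidden = hidden, seed = seed,
                       chunk = chunk, patience = patience,
                       max_chunks = max_chunks),
         memory = NULL),
    class = "bde_ensemble"
  )
  mo <- member_outputs(obj, x)
  obj$memory <- list(
    x = x, y = y, outputs = mo,
    residuals = y - rowMeans(mo)
  )
  obj
}

#' Per-member (denormalized) predictions
#' @param object A `bde_ensemble`.
#' @param x Descriptor matrix.
#' @return Numeric matrix, one column per member.
#' @export
member_outputs <- function(object, x) {
  x <- as.matrix(as.data.frame(x))
  Xn <- norm_apply(x, object$bounds$x)
  out <- vapply(object$weights,
                function(w) member_forward(w, Xn, object$p, object$hidden),
                numeric(nrow(Xn)))
  out <- matrix(out, nrow = nrow(Xn))
  denorm_y(out, object$bounds$y)
}

#' @export
print.bde_ensemble <- function(x, ...) {
  cat(sprintf("<bde_ensemble> %d members x %d hidden units, p = %d, memory n = %d\n",
              x$config$members, x$hidden, x$p,
              if (is.null(x$memory)) 0L else length(x$memory$y)))
  invisible(x)
}

#' Associative prediction with memory correction
#'
#' The plain ensemble output is the mean of the member predictions. The
#' associative correction ranks the memory cases by the Spearman correlation
#' between their per-member output profiles and the query's, and adds the
#' mean residual of the k most similar cases. Growing the memory requires no
#' retraining.
#'
#' @param model A [train_ensemble()] result.
#' @param x Descriptor matrix of query bonds.
#' @param k_neighbors Memory cases used per query (default 9).
#' @return Numeric vector of corrected predictions (kcal/mol).
#' @export
asnn_predict <- function(model, x, k_neighbors = 9) {
  x <- as.matrix(as.data.frame(x))
  q <- member_outputs(model, x)
  base <- rowMeans(q)
  mem <- model$memory
  if (is.null(mem) || !length(mem$y)) {
    warn("empty memory: falling back to the plain ensemble mean")
    return(base)
  }
  k <- min(k_neighbors, length(mem$y))
  stopifnot(k >= 1)
  if (ncol(q) < 3) {
    # rank correlation needs >= 3 member outputs; fall back to output distance
    sim <- -abs(outer(base, rowMeans(mem$outputs), "-"))
  } else {
    qr <- t(apply(q, 1, rank))
    mr <- t(apply(mem$outputs, 1, rank))
    sim <- suppressWarnings(cor(t(qr), t(mr)))
    sim[is.na(sim)] <- 0
  }
  corr <- vapply(seq_len(nrow(q)), function(i) {
    # rank correlation first; ties (common for small ensembles, where many
    # cases share a rank profile) break towards the nearest output profile
    d <- sqrt(colSums((t(mem$outputs) - q[i, ])^2))
    nb <- order(-sim[i, ], d, seq_along(mem$y))[seq_len(k)]
    mean(mem$residuals[nb])
  }, numeric(1))
  base + corr
}

#' @export
predict.bde_ensemble <- function(object, newdata,
                                 type = c("asnn", "ensemble"),
                                 k_neighbors = 9, ...) {
  type <- match.arg(type)
  if (type == "ensemble") {
    rowMeans(member_outputs(object, newdata))
  } else {
    asnn_predict(object, newdata, k_neighbors = k_neighbors)
  }
}

#' Add cases to the associative memory
#'
#' @param model A `bde_ensemble`.
#' @param x Descriptor matrix of new cases.
#' @param y Their labels.
#' @return The model with an enlarged memory (no retraining).
#' @export
add_to_memory <- function(model, x, y) {
  x <- as.matrix(as.data.frame(x))
  mo <- member_outputs(model, x)
  model$memory$x <- rbind(model$memory$x, x)
  model$memory$y <- c(model$memory$y, y)
  model$memory$outputs <- rbind(model$memory$outputs, mo)
  model$memory$residuals <- c(model$memory$residuals, y - rowMeans(mo))
  model
}

#' @export
glance.bde_ensemble <- function(x, ...) {
  mem <- x$memory
  evaluate(rowMeans(mem$outputs), mem$y) %>%
    mutate(members = x$config$members, hidden = x$hidden)
}

#' @export
tidy.bde_ensemble <- function(x, ...) {
  tibble(member = seq_along(x$weights),
         train_output_rmsd = vapply(seq_along(x$weights), function(m) {
           sqrt(mean((x$memory$outputs[, m] - x$memory$y)^2))
         }, numeric(1)))
}
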