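test_that("metric definitions and contract", {
  m <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m[c("rmsd", "mad", "max_error", "r2")]),
               c(rmsd = 0, mad = 0, max_error = 0, r2 = 1))
  expect_warning(m2 <- evaluate(c(0, 2), c(0, 0)), "zero-variance")
  expect_equal(m2$rmsd, sqrt(2))
  expect_equal(m2$mad, 1)
  expect_equal(m2$max_error, 2)
  truth <- c(1, 2, 3, 4)
  m3 <- evaluate(rep(mean(truth), 4), truth)
  expect_equal(m3$r2, 0)
  expect_warning(m4 <- evaluate(c(1, 2), c(5, 5)), "zero-variance")
  expect_true(is.na(m4$r2))
  # invariants on random data
  withr::with_seed(99, {
    for (i in 1:20) {
      p <- rnorm(50); t <- rnorm(50)
      mm <- evaluate(p, t)
      expect_gte(mm$rmsd, mm$mad)
      expect_gte(mm$max_error, mm$rmsd)
      expect_lte(mm$r2, 1)
    }
  })
})

test_that("random forest OOB behaves on degenerate and informative targets", {
  withr::with_seed(1, {
    X <- as.data.frame(matrix(rnorm(500 * 8), 500, 8))
  })
  expect_warning(rf0 <- train_rf(X, rep(5, 500), trees = 100, seed = 2),
                 "zero-variance")
  expect_lt(rf0$oob_metrics$rmsd, 1e-9)

  y <- X[[3]]
  rf1 <- train_rf(X, y, trees = 300, seed = 2)
  expect_gt(rf1$oob_metrics$r2, 0.9)
  expect_equal(tidy(rf1)$descriptor[1], "V3")

  expect_error(train_rf(X[, 0], y, seed = 1), class = "bondscope_config_error")

  # duplicated rows leave OOB metrics roughly unchanged
  rf2 <- train_rf(rbind(X, X), c(y, y), trees = 300, seed = 2)
  expect_lt(abs(rf2$oob_metrics$rmsd - rf1$oob_metrics$rmsd),
            3 * rf1$oob_metrics$rmsd)
})

test_that("descriptor selection honours k and the correlation screen", {
  withr::with_seed(5, {
    X <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  })
  imp <- setNames(10:1, names(X))
  expect_equal(select_descriptors(imp, k = 10, X, corr_threshold = 1.0),
               names(X))
  X2 <- X; X2$V11 <- X2$V1
  imp2 <- setNames(c(11, 10:1), c("V1", paste0("V", c(11, 2:10))))
  imp2 <- setNames(c(12, 11, 10:3), c("V1", "V11", paste0("V", 2:9)))
  kept <- select_descriptors(imp2, k = 10, X2, corr_threshold = 0.95)
  expect_true("V1" %in% kept)
  expect_false("V11" %in% kept)

  # five near-duplicates among the top 90 -> 85 survive
  withr::with_seed(6, {
    X90 <- as.data.frame(matrix(rnorm(300 * 90), 300, 90))
    for (i in 1:5) {
      X90[[i + 50]] <- X90[[i]] + rnorm(300, sd = 0.01)
    }
  })
  imp90 <- setNames(90:1, names(X90))
  kept90 <- select_descriptors(imp90, k = 90, X90, corr_threshold = 0.95)
  expect_length(kept90, 85)
})

test_that("ensemble members train reproducibly with early stopping", {
  withr::with_seed(8, {
    X <- matrix(runif(120 * 4), 120, 4)
    y <- 2 + 3 * X[, 1] - 2 * X[, 2] + 0.5 * X[, 3]
  })
  e1 <- train_ensemble(X, y, members = 3, seed = 31, chunk = 20,
                       max_chunks = 15)
  e2 <- train_ensemble(X, y, members = 3, seed = 31, chunk = 20,
                       max_chunks = 15)
  expect_identical(e1$weights, e2$weights)

  # noiseless linear target: held-out error well under the response spread
  withr::with_seed(9, {
    Xt <- matrix(runif(60 * 4), 60, 4)
    yt <- 2 + 3 * Xt[, 1] - 2 * Xt[, 2] + 0.5 * Xt[, 3]
  })
  pred <- predict(e1, Xt, type = "ensemble")
  expect_lt(sqrt(mean((pred - yt)^2)), 0.25 * sd(y))

  ec <- train_ensemble(X, rep(7, 120), members = 1, seed = 3, chunk = 10,
                       max_chunks = 5)
  expect_lt(max(abs(predict(ec, X, type = "ensemble") - 7)), 0.5)
})

test_that("the associative memory corrects predictions", {
  withr::with_seed(12, {
    X <- matrix(runif(80 * 3), 80, 3)
    y <- 10 * X[, 1] + rnorm(80, sd = 0.2)
  })
  ens <- train_ensemble(X, y, members = 5, seed = 21, chunk = 20,
                        max_chunks = 10)

  # exact recall: a query equal to a memory case returns its stored label
  pred <- asnn_predict(ens, X[17, , drop = FALSE], k_neighbors = 1)
  expect_equal(pred, y[17], tolerance = 1e-9)

  # zero residuals -> correction vanishes
  ens0 <- ens
  ens0$memory$residuals[] <- 0
  q <- matrix(runif(3), 1, 3)
  expect_equal(asnn_predict(ens0, q),
               predict(ens0, q, type = "ensemble"), tolerance = 1e-12)

  # k = memory size with zero-mean residuals degenerates to the plain mean
  ensz <- ens
  ensz$memory$residuals <- ensz$memory$residuals - mean(ensz$memory$residuals)
  expect_equal(asnn_predict(ensz, q, k_neighbors = length(ensz$memory$y)),
               predict(ensz, q, type = "ensemble"), tolerance = 1e-12)

  # three-case toy memory with hand-set residuals (+1, +1, -2), k = 2:
  # the two rank-identical cases are selected, correction is +1
  toy <- ens
  qo <- bondscope:::member_outputs(ens, q)
  toy$memory$x <- rbind(q, q, q)
  toy$memory$y <- c(0, 0, 0)
  toy$memory$outputs <- rbind(qo, qo + 5, qo[, ncol(qo):1, drop = FALSE])
  toy$memory$residuals <- c(1, 1, -2)
  expect_equal(asnn_predict(toy, q, k_neighbors = 2),
               predict(toy, q, type = "ensemble") + 1, tolerance = 1e-12)

  # growing the memory requires no retraining and enables new exact recalls
  withr::with_seed(13, xnew <- matrix(runif(3), 1, 3))
  ynew <- 42
  ens2 <- add_to_memory(ens, xnew, ynew)
  expect_equal(asnn_predict(ens2, xnew, k_neighbors = 1), ynew,
               tolerance = 1e-9)
  expect_identical(ens2$weights, ens$weights)

  # empty memory falls back to the ensemble mean with a warning
  ens3 <- ens
  ens3$memory <- NULL
  expect_warning(p3 <- asnn_predict(ens3, q), "memory")
  expect_equal(p3, predict(ens, q, type = "ensemble"))
})

test_that("fixed-value baseline averages classes and flags fallbacks", {
  recs <- tibble::tibble(element_pair = c("C-N", "C-N", "C-H"),
                         order = c(1L, 1L, 1L), bde = c(80, 90, 99))
  base <- baseline_fixed_values(recs)
  expect_equal(base$table$fixed[base$table$element_pair == "C-N"], 85)
  newdata <- tibble::tibble(element_pair = c("C-N", "O-S"), order = c(1L, 1L))
  expect_warning(p <- predict(base, newdata), "unseen")
  expect_equal(p$.pred[1], 85)
  expect_equal(p$.pred[2], mean(recs$bde))
  expect_true(p$.fallback[2])
  expect_error(baseline_fixed_values(recs[0, ]),
               class = "bondscope_config_error")
})
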