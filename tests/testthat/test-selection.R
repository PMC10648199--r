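test_that("a strong planted predictor is selected first with an oracle-exact F", {
  fx <- make_regression_fixture(n = 500, k_informative = 1, n_noise = 20,
                                effect_sizes = 3, sigma = 0.1, seed = 11)
  rep <- suppressWarnings(stepwise_select(fx$X, fx$y))
  expect_equal(rep$feature[rep$step == 1], "inf1")
  # entry F of the first feature against the nested-RSS oracle
  log <- attr(rep, "log")
  f_first <- unname(log$F[log$step == 1])
  f_oracle <- partial_f_oracle(scale(fx$X), fx$y - mean(fx$y), "inf1", character(0))
  expect_equal(f_first, f_oracle, tolerance = 1e-6)
  # final partial F of every kept feature matches the oracle on the kept model
  for (f in rep$feature) {
    expect_equal(rep$F[rep$feature == f],
                 partial_f_oracle(scale(fx$X), fx$y - mean(fx$y), f,
                                  setdiff(rep$feature, f)),
                 tolerance = 1e-6)
  }
})

test_that("pure-noise targets leave the final F>100 set empty", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      X <- matrix(rnorm(500 * 20), 500)
      colnames(X) <- paste0("x", 1:20)
      y <- rnorm(500)
    })
    rep <- suppressWarnings(stepwise_select(X, y))
    sum(rep$F >= 100)
  }, numeric(1))
  expect_true(mean(hits == 0) >= 0.95)
})

test_that("an exact linear relationship is recovered with near-zero residual", {
  withr::with_seed(5, {
    X <- matrix(rnorm(200 * 10), 200)
    colnames(X) <- paste0("x", 1:10)
    y <- X[, 2]
  })
  rep <- suppressWarnings(stepwise_select(X, y, selection_config(max_features = 3)))
  expect_equal(rep$feature[1], "x2")
  fit <- lm(y ~ X[, "x2"])
  expect_lt(sum(residuals(fit)^2), 1e-18)
})

test_that("constant columns are excluded with a warning", {
  withr::with_seed(6, {
    X <- cbind(const = 1, matrix(rnorm(300), 100))
    colnames(X)[-1] <- paste0("x", 1:3)
    y <- X[, "x1"] + rnorm(100, 0, 0.1)
  })
  expect_warning(rep <- stepwise_select(X, y), "constant")
  expect_false("const" %in% rep$feature)
})

test_that("collinear candidates are rejected rather than entered", {
  withr::with_seed(8, {
    X <- matrix(rnorm(200 * 4), 200)
    X <- cbind(X, X[, 1])  # exact duplicate of column 1
    colnames(X) <- c(paste0("x", 1:4), "dup1")
    y <- X[, 1] * 2 + rnorm(200, 0, 0.2)
  })
  rep <- suppressWarnings(stepwise_select(X, y))
  expect_false(all(c("x1", "dup1") %in% rep$feature))
})

test_that("bidirectional elimination removes features made redundant later", {
  # x3 is a noisy sum of x1 and x2; y = x1 + x2.  Stepwise enters x3 first
  # (best single predictor), then the true predictors; once both are in,
  # x3's partial F collapses and the removal phase must evict it.
  withr::with_seed(9, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    x3 <- x1 + x2 + rnorm(n, 0, 0.3)
    X <- cbind(x1 = x1, x2 = x2, x3 = x3)
    y <- x1 + x2 + rnorm(n, 0, 0.05)
  })
  rep <- suppressWarnings(stepwise_select(X, y))
  log <- attr(rep, "log")
  expect_equal(log$feature[1], "x3")
  expect_true("remove" %in% log$action)
  expect_setequal(rep$feature, c("x1", "x2"))
})

test_that("merge keeps the best-F member of correlated pairs and drops weak features", {
  withr::with_seed(12, {
    z <- rnorm(300)
    X <- cbind(a = z, b = z * 1 + rnorm(300, 0, 1e-8),   # r ~ 1 with a
               c = rnorm(300), d = rnorm(300))
  })
  reports <- list(
    t1 = tibble::tibble(feature = c("a", "c"), F = c(150, 120), step = 1:2),
    t2 = tibble::tibble(feature = c("b", "d"), F = c(120, 90), step = 1:2)
  )
  sel <- merge_and_dedup(reports, X, selection_config())
  expect_true("a" %in% sel$kept$feature)        # higher-F member of the pair
  expect_false("b" %in% sel$kept$feature)
  expect_equal(sel$dropped$feature, "b")
  expect_equal(sel$dropped$kept_competitor, "a")
  expect_false("d" %in% sel$kept$feature)       # F = 90 < 100
  expect_true("c" %in% sel$kept$feature)        # uncorrelated, F >= 100
  expect_equal(sel$kept$F, sort(sel$kept$F, decreasing = TRUE))
})

test_that("weakly correlated features are both kept", {
  withr::with_seed(13, {
    z <- rnorm(500)
    X <- cbind(a = z, e = 0.85 * z + sqrt(1 - 0.85^2) * rnorm(500))
  })
  expect_lt(abs(cor(X[, "a"], X[, "e"])), 0.9)
  reports <- list(t1 = tibble::tibble(feature = c("a", "e"),
                                      F = c(200, 150), step = 1:2))
  sel <- merge_and_dedup(reports, X, selection_config())
  expect_setequal(sel$kept$feature, c("a", "e"))
})

test_that("selection is deterministic for identical inputs", {
  fx <- make_regression_fixture(n = 400, k_informative = 3, n_noise = 30,
                                effect_sizes = rep(1, 3), sigma = 0.5, seed = 21)
  r1 <- suppressWarnings(stepwise_select(fx$X, fx$y))
  r2 <- suppressWarnings(stepwise_select(fx$X, fx$y))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("stepwise agrees with exhaustive best-subset search on small problems", {
  # on <= 8-column problems, enumerate every subset and apply the same
  # F-based filtering; the greedy path should land on the same model in
  # nearly all instances
  best_subset <- function(X, y, f_final = 100) {
    p <- ncol(X)
    best <- character(0)
    best_rss <- Inf
    for (size in 0:p) {
      for (sel in if (size == 0) list(integer(0)) else
           asplit(utils::combn(p, size), 2)) {
        sel <- as.integer(sel)
        A <- cbind(1, X[, sel, drop = FALSE])
        rss <- sum(qr.resid(qr(A), y)^2)
        if (size > 0) {
          pf <- pblocks:::refit_partial_f(scale(X), sel, y - mean(y))
          if (any(pf < f_final)) next
        }
        if (rss < best_rss - 1e-9) {
          best_rss <- rss
          best <- colnames(X)[sel]
        }
      }
    }
    best
  }
  agree <- vapply(1:25, function(s) {
    withr::with_seed(400 + s, {
      X <- matrix(rnorm(300 * 6), 300)
      colnames(X) <- paste0("x", 1:6)
      beta <- c(2, 1.5, 0, 0, 0, 0)
      y <- as.vector(X %*% beta) + rnorm(300)
    })
    cfg <- selection_config(f_enter = 100, f_remove = 99)
    rep <- suppressWarnings(stepwise_select(X, y, cfg))
    setequal(rep$feature, best_subset(X, y))
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
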