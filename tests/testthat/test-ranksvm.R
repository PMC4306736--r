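test_that("rank_dataset derives l, d, R and validates inputs", {
  X <- random_sparse_cols(16, 10)
  dat <- rank_dataset(X, rep(c(0L, 1L), 5))
  expect_equal(dat$l, 10)
  expect_equal(dat$R, 2)
  expect_equal(dat$d, length(X@x) / 10)
  expect_error(rank_dataset(X, 1:9), "one score per instance")
})

test_that("the objective matches hand-expanded values in closed form", {
  # two instances with unit-disjoint features, scores 1 > 0
  X <- tocs(Matrix::Matrix(diag(2), sparse = TRUE))
  dat <- rank_dataset(X, c(1L, 0L))
  # w = 0: hinge sits at the full margin, objective = C
  for (C in c(0.5, 1, 4)) {
    cfg <- train_config(C = C)
    expect_equal(rank_objective(numeric(2), dat, cfg), C)
  }
  # C = 0 is rejected, so evaluate the regularizer through a tiny C
  w <- c(3, -1)
  cfg0 <- train_config(C = 1e-12)
  expect_equal(rank_objective(w, dat, cfg0), 0.5 * sum(w^2),
               tolerance = 1e-9)
  # hand expansion: single pair, margin 1 - w'(x1 - x2) = 1 - 4 < 0
  expect_equal(rank_objective(w, dat, train_config(C = 2)),
               0.5 * 10 + 2 * 0)
  # three compounds, two features, scores (2,1,0): full symbolic expansion
  X3 <- tocs(Matrix::Matrix(matrix(c(1, 0, 1, 1, 0, 1), 2, 3),
                            sparse = TRUE))
  dat3 <- rank_dataset(X3, c(2L, 1L, 0L))
  w3 <- c(0.5, -0.25)
  f <- as.numeric(Matrix::crossprod(X3, w3))
  hand <- (max(0, 2 - (f[1] - f[3])) + max(0, 1 - (f[1] - f[2])) +
             max(0, 1 - (f[2] - f[3]))) / 4
  expect_equal(rank_objective(w3, dat3, train_config(C = 3)),
               0.5 * sum(w3^2) + 3 * hand)
})

test_that("fast weighted loss equals brute force for both variants", {
  set.seed(41)
  for (rep in 1:8) {
    l <- sample(20:80, 1)
    X <- random_sparse_cols(12, l, binary = FALSE)
    s <- sample(0:3, l, replace = TRUE)
    if (length(unique(s)) < 2) next
    dat <- rank_dataset(X, s)
    w <- rnorm(12)
    for (variant in c("margin_rescaled", "slack_rescaled")) {
      fast <- fast_weighted_loss(w, dat, variant)
      brute <- brute_weighted_loss(w, X, s, variant)
      expect_equal(fast$loss, brute$loss, tolerance = 1e-9)
      expect_equal(fast$coef, brute$coef, tolerance = 1e-9)
    }
  }
})

test_that("fast loss degenerate cases: R = 2 sweep and all-equal predictions", {
  set.seed(42)
  X <- random_sparse_cols(10, 30)
  s <- rep(c(1L, 0L), 15)
  dat <- rank_dataset(X, s)
  w <- rnorm(10)
  expect_equal(fast_weighted_loss(w, dat)$loss,
               brute_weighted_loss(w, X, s)$loss, tolerance = 1e-9)
  # all predictions equal (w = 0): every pair sits at its full margin
  # sdiff, so the normalized margin-rescaled loss is exactly 1
  s3 <- sample(0:3, 30, replace = TRUE)
  dat3 <- rank_dataset(X, s3)
  expect_equal(fast_weighted_loss(numeric(10), dat3)$loss, 1,
               tolerance = 1e-12)
  # and the slack-rescaled loss is likewise (1/W) * sum(sdiff * 1) = 1
  expect_equal(fast_weighted_loss(numeric(10), dat3,
                                  "slack_rescaled")$loss, 1,
               tolerance = 1e-12)
})

test_that("fitting separates a rank-separable toy problem", {
  # scores 3/2/1/0 increasing along a single feature
  X <- tocs(Matrix::Matrix(matrix(c(4, 3, 2, 1) / 4, 1, 4), sparse = TRUE))
  dat <- rank_dataset(X, c(3L, 2L, 1L, 0L))
  fit <- fit_ranksvm(dat, train_config(C = 100, tol = 1e-8))
  pred <- predict(fit, X)
  expect_equal(kpartite_error(pred, dat$scores), 0)
  expect_true(fit$diagnostics$converged)
})

test_that("fitted objective beats any scalar on a one-feature grid", {
  set.seed(43)
  X <- tocs(Matrix::Matrix(matrix(runif(20), 1, 20), sparse = TRUE))
  s <- sample(0:2, 20, replace = TRUE)
  dat <- rank_dataset(X, s)
  cfg <- train_config(C = 5, tol = 1e-8)
  fit <- fit_ranksvm(dat, cfg)
  obj_fit <- rank_objective(fit, dat, cfg)
  for (wv in seq(-10, 10, by = 0.05))
    expect_lte(obj_fit, rank_objective(wv, dat, cfg) + 1e-6)
})

test_that("duplicating every instance leaves the fit unchanged", {
  set.seed(44)
  X <- random_sparse_cols(10, 25)
  s <- sample(0:2, 25, replace = TRUE)
  cfg <- train_config(C = 2, tol = 1e-9, max_iter = 5000)
  w1 <- dense_w(fit_ranksvm(rank_dataset(X, s), cfg))
  w2 <- dense_w(fit_ranksvm(rank_dataset(cbind(X, X), c(s, s)), cfg))
  expect_equal(w1, w2, tolerance = 1e-4)
})

test_that("fits reproduce exactly under a fixed seed", {
  set.seed(45)
  X <- random_sparse_cols(15, 40)
  s <- sample(0:3, 40, replace = TRUE)
  cfg <- train_config(C = 1, seed = 99)
  f1 <- fit_ranksvm(rank_dataset(X, s), cfg)
  f2 <- fit_ranksvm(rank_dataset(X, s), cfg)
  expect_identical(dense_w(f1), dense_w(f2))
})

test_that("fit objective matches the generic QP solution on small instances", {
  set.seed(46)
  for (rep in 1:6) {
    l <- sample(8:20, 1)
    d <- sample(3:8, 1)
    X <- random_sparse_cols(d, l, density = 0.5)
    s <- sample(0:2, l, replace = TRUE)
    if (length(unique(s)) < 2) next
    for (variant in c("margin_rescaled", "slack_rescaled")) {
      cfg <- train_config(C = 1, tol = 1e-8, loss_variant = variant)
      fit <- fit_ranksvm(rank_dataset(X, s), cfg)
      obj <- rank_primal_objective(dense_w(fit), X, s, 1,
                                   variant)
      ref <- qp_rank_objective(X, s, 1, variant)
      expect_lte(obj, ref * (1 + 1e-4) + 1e-8)
      expect_gte(obj, ref * (1 - 1e-4) - 1e-8)
    }
  }
})

test_that("degenerate inputs are rejected or flagged", {
  X <- random_sparse_cols(8, 6)
  expect_error(fit_ranksvm(rank_dataset(X, rep(1L, 6))), "all rank scores")
  cfg <- train_config(C = 1e4, tol = 1e-12, max_iter = 2)
  set.seed(47)
  Xl <- random_sparse_cols(30, 40)
  sl <- sample(0:3, 40, replace = TRUE)
  expect_warning(fit <- fit_ranksvm(rank_dataset(Xl, sl), cfg),
                 "best iterate")
  expect_false(fit$diagnostics$converged)
})

test_that("prediction is linear, batched, and dimension-checked", {
  X <- random_sparse_cols(8, 5)
  w <- numeric(8); w[6] <- 2
  model <- multirank:::new_linear_model(w, 8)
  fp <- sparse_fp(5, 0.5, dim = 8)
  expect_equal(predict(model, list(fp)), 1)
  expect_equal(predict(multirank:::new_linear_model(numeric(8), 8), X),
               rep(0, 5))
  batch <- predict(model, X)
  single <- vapply(seq_len(5), function(k)
    predict(model, X[, k, drop = FALSE]), numeric(1))
  expect_identical(batch, single)
  expect_error(predict(model, random_sparse_cols(9, 2)), "dimension")
})

test_that("models serialize to JSON and back without loss", {
  set.seed(48)
  X <- random_sparse_cols(12, 20)
  s <- sample(0:2, 20, replace = TRUE)
  fit <- fit_ranksvm(rank_dataset(X, s), train_config(C = 1))
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  # JSON text serialization can shift the last ulp of a double
  expect_equal(dense_w(back), dense_w(fit), tolerance = 1e-14)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-14)
})
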