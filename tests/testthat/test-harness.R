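test_that("profile-balanced sampling draws half the smallest subset from
          each profile of the category", {
  groups <- list("100" = sprintf("a%d", 1:10), "010" = sprintf("b%d", 1:40),
                 "001" = sprintf("c%d", 1:60), "110" = sprintf("d%d", 1:8))
  sp <- profile_balanced_sample(groups, "single", seed = 1)
  expect_length(sp$train, 3 * 5)  # n = 10 %/% 2 from each single subset
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test),
                  unlist(groups[c("100", "010", "001")]))
  # each subset contributes exactly n
  expect_equal(sum(grepl("^a", sp$train)), 5)
  expect_equal(sum(grepl("^b", sp$train)), 5)
  expect_equal(sum(grepl("^c", sp$train)), 5)
})

test_that("equal subsets of eight give n = 4 and a train size of 12", {
  groups <- list("100" = sprintf("a%d", 1:8), "010" = sprintf("b%d", 1:8),
                 "001" = sprintf("c%d", 1:8))
  sp <- profile_balanced_sample(groups, "single", seed = 2)
  expect_length(sp$train, 12)
})

test_that("sampling is reproducible per seed and differs across seeds", {
  groups <- list("110" = sprintf("x%d", 1:30), "101" = sprintf("y%d", 1:20))
  s1 <- profile_balanced_sample(groups, "dual", seed = 5)
  s2 <- profile_balanced_sample(groups, "dual", seed = 5)
  s3 <- profile_balanced_sample(groups, "dual", seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1$train, s3$train))
  expect_error(profile_balanced_sample(groups, "triple"), "no profile")
  expect_error(profile_balanced_sample(list("100" = "only1"), "single"),
               "fewer than 2")
})

test_that("decoy addition samples without replacement and saturates", {
  pool <- sprintf("d%d", 1:5000)
  train <- sprintf("a%d", 1:30)
  got <- add_decoys(train, pool, k = 1000, seed = 3)
  expect_length(got, 1030)
  expect_equal(attr(got, "n_decoys"), 1000)
  expect_equal(anyDuplicated(got), 0)
  expect_length(intersect(got, train[1:30]), 30)
  small <- sprintf("d%d", 1:500)
  expect_warning(sat <- add_decoys(train, small, k = 1000), "using all")
  expect_length(sat, 530)
})

test_that("the default C grids match the published protocol", {
  expect_equal(default_C_grid("mtrank"), 10^seq(-6, -2))
  expect_equal(default_C_grid("srank"), 10^seq(-6, -2))
  expect_equal(default_C_grid("svc"), c(0.1, 1, 10, 100, 1000))
  expect_equal(default_C_grid("mcsvm"), c(0.1, 1, 10, 100, 1000))
})

test_that("grid search returns a singleton grid untouched and prefers
          smaller C on ties", {
  X <- random_sparse_cols(8, 20)
  s <- rep(c(1L, 0L), 10)
  expect_equal(grid_search_C("mtrank", X, s, grid = 0.5), 0.5)
  # perfectly separable single-feature data: all C values tie at zero
  # validation error, so the smallest must be returned
  X1 <- tocs(Matrix::Matrix(matrix(seq(0.1, 2, length.out = 20), 1, 20),
                            sparse = TRUE))
  s1 <- as.integer(seq(0.1, 2, length.out = 20) > 1)
  best <- grid_search_C("mtrank", X1, s1, grid = c(0.01, 1, 100),
                        seed = 4)
  expect_equal(as.numeric(best), 0.01)
  errs <- attr(best, "cv_errors")
  expect_length(errs, 3)
  expect_true(all(errs == errs[1]))
})

test_that("grid search fails after 10 attempts when a score level cannot
          reach every fold", {
  X <- random_sparse_cols(8, 11)
  s <- c(rep(0L, 10), 2L)  # singleton level can never be in both folds
  expect_error(grid_search_C("mtrank", X, s, grid = c(0.1, 1)),
               "10 attempts")
})

test_that("test-set labeling mirrors the training scheme", {
  scheme2 <- default_scheme_t2()
  profs <- rbind(c(1, 1, 0), c(0, 0, 0), c(1, 1, 1), c(1, 0, 0))
  lab <- label_test_sets(profs, scheme2)
  expect_equal(lab$binary, c(1L, 0L, 1L, 0L))
  expect_equal(lab$graded, c(3L, 0L, 1L, 2L))
  scheme1 <- default_scheme_t1()
  lab1 <- label_test_sets(rbind(c(1, 1, 0)), scheme1)
  expect_equal(lab1$binary, 1L)
  expect_equal(lab1$graded, 2L)
})

test_that("experiments are deterministic, leak-free and correctly shaped", {
  bench <- make_benchmark(synthetic_spec(
    overlap_design = c("100" = 20L, "010" = 20L, "001" = 20L,
                       "110" = 12L, "101" = 12L, "011" = 12L,
                       "111" = 10L, "000" = 80L),
    dim = 512, block_size = 12, seed = 71))
  cfg <- experiment_config(default_scheme_t2(),
                           methods = c("mtrank", "svc"),
                           repetitions = 3, decoys_per_train = 40,
                           C_grid = list(mtrank = 1e-3, svc = 1),
                           seed = 17)
  r1 <- run_experiment(cfg, bench)
  r2 <- run_experiment(cfg, bench)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 6)  # 3 repetitions x 2 methods
  expect_true(all(r1$method %in% c("mtrank", "svc")))
  expect_true(all(r1$kpartite_error_graded >= 0 &
                    r1$kpartite_error_graded <= 1))
  expect_true(all(r1$rank_error_binary >= 0 & r1$rank_error_binary <= 1))
  expect_true(all(r1$n_train + r1$n_test == 186))
  summ <- attr(r1, "summary")
  expect_setequal(summ$method, c("mtrank", "svc"))
  expect_true(all(c("sd_kpartite", "iqr_kpartite") %in% colnames(summ)))
})

test_that("srank and svm_lc run end to end on a single-main-target scheme", {
  bench <- make_benchmark(synthetic_spec(
    overlap_design = c("100" = 20L, "010" = 20L, "001" = 20L,
                       "110" = 12L, "101" = 12L, "011" = 12L,
                       "111" = 10L, "000" = 80L),
    dim = 512, block_size = 12, seed = 72))
  cfg <- experiment_config(default_scheme_t1(),
                           methods = c("srank", "svm_lc"),
                           repetitions = 2, decoys_per_train = 40,
                           C_grid = list(srank = 1e-3, svm_lc = c(1, 10)),
                           seed = 23)
  res <- run_experiment(cfg, bench)
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$kpartite_error_graded)))
})

test_that("alternative linear factors are honored by svm_lc", {
  bench <- make_benchmark(synthetic_spec(
    overlap_design = c("100" = 16L, "010" = 16L, "001" = 16L,
                       "000" = 60L),
    dim = 256, block_size = 10, seed = 73))
  base <- experiment_config(default_scheme_t1(), methods = "svm_lc",
                            repetitions = 1, decoys_per_train = 30,
                            C_grid = list(svm_lc = 1), seed = 3)
  flipped <- base
  flipped$lc_factors <- c(-2, 1, 1)  # penalize the main target instead
  r1 <- run_experiment(base, bench)
  r2 <- run_experiment(flipped, bench)
  expect_gt(r2$kpartite_error_graded, r1$kpartite_error_graded)
})

test_that("cutoff sweeps re-binarize and return one result per cutoff", {
  set.seed(81)
  n <- 120
  X <- random_sparse_cols(256, n)
  pk <- matrix(runif(n * 3, 4.5, 7.5), n, 3)
  colnames(pk) <- c("FXa", "Thr", "Try")
  cfg <- experiment_config(default_scheme_t1(), methods = "mtrank",
                           repetitions = 2,
                           C_grid = list(mtrank = 1e-3), seed = 7)
  sw <- suppressWarnings(cutoff_sweep(pk, c(5.6, 6.1, 6.6), cfg, X))
  expect_length(sw, 3)
  expect_named(sw, format(c(5.6, 6.1, 6.6)))
  for (res in sw) expect_equal(nrow(res), 2)
  expect_error(cutoff_sweep(pk, 99, cfg, X), "no active")
})

test_that("stratified splits preserve the label distribution", {
  scheme <- default_scheme_t1()
  bench <- make_benchmark(synthetic_spec(
    overlap_design = c("100" = 40L, "110" = 30L, "111" = 20L,
                       "000" = 50L),
    dim = 256, block_size = 10, seed = 74))
  cfg <- experiment_config(scheme, sampling = "stratified",
                           repetitions = 1, seed = 11)
  sp <- multirank:::split_indices(bench$profiles, bench$ids, cfg, 42)
  graded <- encode_profile(scheme, bench$profiles)
  tr_tab <- table(graded[sp$train])
  te_tab <- table(graded[sp$test])
  for (lev in names(tr_tab))
    expect_lte(abs(tr_tab[[lev]] - te_tab[[lev]]), 1)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("auc complements rank error on every tested prediction vector", {
  set.seed(82)
  for (rep in 1:50) {
    n <- sample(10:100, 1)
    lab <- sample(0:1, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    pred <- sample(round(rnorm(n), 1))
    expect_lt(abs(auc(pred, lab) + rank_error(pred, lab) - 1), 1e-12)
  }
})
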