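# Experiment harness reproducing the multi-target screening protocol:
# profile-balanced sampling (n = half of the smallest profile subset per
# single/dual/triple category, drawn from every subset of that category),
# decoy addition, 2-fold cross-validated grid search over the method's C
# grid, training, and evaluation of the test set under two labelings --
# binary (main-target activity only) and graded (the same rank-score
# scheme used for training). Splits are shared across methods within a
# repetition, so method comparisons are paired.

#' Experiment settings
#'
#' @param scheme the [build_scheme()] encoding defining main targets and
#'   rank scores.
#' @param methods character vector of methods to run on shared splits:
#'   any of `"mtrank"`, `"srank"`, `"svc"`, `"svm_lc"`, `"mcsvm"`.
#' @param repetitions number of independent sampling repetitions
#'   (default 20).
#' @param decoys_per_train decoys sampled (without replacement) into every
#'   training set (default 1000; if the pool is smaller, the whole pool is
#'   used with a warning).
#' @param cv_folds folds of the grid-search cross-validation (default 2).
#' @param C_grid optional named list method -> numeric grid; defaults to
#'   `10^(-6..-2)` for the ranking methods and `{0.1, 1, 10, 100, 1000}`
#'   for SVC, SVM LC and the MC-SVM.
#' @param seed master seed; every repetition derives its own sub-seeds
#'   from it and results are fully reproducible.
#' @param lc_factors optional numeric vector of per-target linear factors
#'   for SVM LC (default `+2` per main target, `-1` elsewhere).
#' @param sampling `"profile_balanced"` (default) or `"stratified"` (half
#'   split preserving the label distribution, the protocol used for the
#'   activity-cutoff sweep).
#' @param drop_promiscuous drop compounds active on all targets before
#'   sampling (default `FALSE`).
#' @param tol,max_iter solver settings used for every fit.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scheme, methods = "mtrank", repetitions = 20,
                              decoys_per_train = 1000, cv_folds = 2,
                              C_grid = NULL, seed = 1L, lc_factors = NULL,
                              sampling = c("profile_balanced",
                                           "stratified"),
                              drop_promiscuous = FALSE,
                              tol = 1e-5, max_iter = 400) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  sampling <- match.arg(sampling)
  methods <- match.arg(methods,
                       c("mtrank", "srank", "svc", "svm_lc", "mcsvm"),
                       several.ok = TRUE)
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (!is.null(C_grid)) {
    stopifnot(is.list(C_grid), all(methods %in% names(C_grid)),
              all(lengths(C_grid) >= 1))
  }
  structure(list(scheme = scheme, methods = methods,
                 repetitions = as.integer(repetitions),
                 decoys_per_train = as.integer(decoys_per_train),
                 cv_folds = as.integer(cv_folds), C_grid = C_grid,
                 seed = as.integer(seed), lc_factors = lc_factors,
                 sampling = sampling,
                 drop_promiscuous = isTRUE(drop_promiscuous),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "experiment_config")
}

#' Default regularization grids
#'
#' `10^(-6..-2)` for the ranking methods (mtrank, srank) and
#' `{0.1, 1, 10, 100, 1000}` for the classification methods (svc, svm_lc,
#' mcsvm).
#'
#' @param method method name.
#' @return Numeric grid.
#' @export
default_C_grid <- function(method) {
  if (method %in% c("mtrank", "srank")) 10^seq(-6, -2) else
    c(0.1, 1, 10, 100, 1000)
}

#' Profile-balanced train/test sampling
#'
#' For one profile category (single-, dual- or triple-target actives), `n`
#' compounds are drawn without replacement from **each** profile subset of
#' the category, where `n` is half the size of the smallest subset in that
#' category (rounded down). All remaining compounds are left for the test
#' set.
#'
#' @param groups named list: profile string -> character vector of
#'   compound ids.
#' @param category `"single"`, `"dual"` or `"triple"`.
#' @param seed sampling seed.
#' @return List with `train` and `test` id vectors.
#' @export
profile_balanced_sample <- function(groups,
                                    category = c("single", "dual",
                                                 "triple"),
                                    seed = 1L) {
  category <- match.arg(category)
  want <- c(single = 1L, dual = 2L, triple = 3L)[[category]]
  n_active <- vapply(names(groups), function(k)
    sum(strsplit(k, "")[[1]] == "1"), integer(1))
  groups <- groups[n_active == want]
  if (!length(groups))
    stop(sprintf("no profile subsets in category '%s'", category))
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop(sprintf("profile subset %s has fewer than 2 compounds",
                 names(groups)[sizes < 2][1]))
  n <- min(sizes) %/% 2L
  with_seed(seed, {
    train <- unlist(lapply(groups, function(idv) sample(idv, n)),
                    use.names = FALSE)
    list(train = train,
         test = setdiff(unlist(groups, use.names = FALSE), train))
  })
}

#' Add decoys to a training set
#'
#' Samples `k` decoys without replacement from the decoy pool (compounds
#' inactive on every target) and appends them; when the pool holds fewer
#' than `k`, the whole pool is used with a warning.
#'
#' @param train character vector of training compound ids.
#' @param decoy_pool character vector of decoy ids (disjoint from actives).
#' @param k decoys to add (default 1000).
#' @param seed sampling seed.
#' @return The augmented id vector, with attribute `n_decoys`.
#' @export
add_decoys <- function(train, decoy_pool, k = 1000, seed = 1L) {
  if (length(decoy_pool) < k) {
    warning(sprintf("decoy pool (%d) smaller than requested %d: using all",
                    length(decoy_pool), k))
    picked <- decoy_pool
  } else {
    picked <- with_seed(seed, sample(decoy_pool, k))
  }
  out <- c(train, picked)
  attr(out, "n_decoys") <- length(picked)
  out
}

# stratified fold assignment by score level; levels of size < folds make a
# valid assignment impossible for that level
assign_folds <- function(scores, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(scores))
    for (lev in unique(scores)) {
      idx <- which(scores == lev)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated grid search for C
#'
#' Stratified k-fold (default 2) cross-validation over the supplied grid.
#' Ranking methods (mtrank, srank, mcsvm) are selected by mean validation
#' [kpartite_error()] on the graded scores; the SVC by [rank_error()] on
#' its binary labels. Ties prefer the smaller C. If a fold misses a score
#' level the split is re-drawn (up to 10 times) before failing.
#'
#' @param method one of `"mtrank"`, `"srank"`, `"svc"`, `"svm_lc"`,
#'   `"mcsvm"` (`"svm_lc"` grids its per-target SVCs separately through
#'   `"svc"`).
#' @param x feature matrix (`dgCMatrix`, instances in columns).
#' @param scores graded rank scores (ranking methods) or binary labels
#'   (svc).
#' @param grid numeric candidate grid, non-empty.
#' @param folds number of folds.
#' @param seed split seed.
#' @param tol,max_iter solver settings.
#' @return Best C (numeric scalar) with attribute `cv_errors`.
#' @export
grid_search_C <- function(method, x, scores, grid, folds = 2, seed = 1L,
                          tol = 1e-5, max_iter = 400) {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  if (length(grid) == 1) return(grid)
  scores <- as.integer(scores)
  fold <- NULL
  for (try in seq_len(10)) {
    cand <- assign_folds(scores, folds, seed + (try - 1L) * 1000L)
    ok <- all(vapply(seq_len(folds), function(fd)
      length(unique(scores[cand == fd])) == length(unique(scores)),
      logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold))
    stop("could not build folds containing every score level (10 attempts)")
  errs <- vapply(grid, function(C) {
    fold_err <- vapply(seq_len(folds), function(fd) {
      tr <- fold != fd
      model <- fit_single(method, x[, tr, drop = FALSE], scores[tr], C,
                          tol, max_iter, seed)
      pred <- predict_single(method, model, x[, !tr, drop = FALSE])
      if (method == "svc") rank_error(pred, scores[!tr])
      else kpartite_error(pred, scores[!tr])
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  best <- grid[which.min(errs)]  # which.min takes the first = smallest C
  attr(best, "cv_errors") <- setNames(errs, format(grid))
  best
}

total_pair_weight <- function(scores) {
  cnt <- table(scores)
  vals <- as.numeric(names(cnt))
  n <- as.numeric(cnt)
  tot <- 0
  for (a in seq_along(vals)) for (b in seq_along(vals))
    if (vals[a] > vals[b]) tot <- tot + (vals[a] - vals[b]) * n[a] * n[b]
  tot
}

# One fit of one method on prepared scores/labels. The ranking C grid is
# quoted in per-pair (summed-slack) units -- the convention of the solvers
# the published grids were tuned for -- while the ranking objective here
# normalizes the loss by the total pair weight W; the grid value is
# therefore rescaled by W before fitting so both conventions agree.
fit_single <- function(method, X, scores, C, tol, max_iter, seed) {
  switch(method,
         mtrank = ,
         srank = fit_ranksvm(rank_dataset(X, scores),
                             train_config(C = C * total_pair_weight(scores),
                                          tol = tol,
                                          max_iter = max_iter,
                                          seed = seed)),
         svc = fit_svc(X, scores, C = C, tol = tol, max_iter = max_iter,
                       seed = seed),
         mcsvm = fit_mcsvm(X, scores, C = C, tol = tol,
                           max_iter = max_iter, seed = seed),
         stop(sprintf("unknown method '%s'", method)))
}

predict_single <- function(method, model, X) {
  if (method == "mcsvm") rank_by_mc(model, X) else predict(model, X)
}

# method-specific training scores/labels from profiles
method_scores <- function(method, profiles, scheme) {
  switch(method,
         mtrank = encode_profile(scheme, profiles),
         srank = {
           if (length(scheme$main_targets) != 1)
             stop("srank requires a single main target")
           srank_encode(profiles, scheme$main_targets)
         },
         svc = binary_labels(profiles, scheme$main_targets),
         mcsvm = encode_profile(scheme, profiles),
         stop(sprintf("unknown method '%s'", method)))
}

#' Label a test set in both evaluation modes
#'
#' Binary: activity on the main target(s) only. Graded: the same rank
#' score scheme that labeled the training sets.
#'
#' @param profiles binary profile matrix of the test compounds.
#' @param scheme the training [build_scheme()] scheme.
#' @return List with `binary` and `graded` integer vectors.
#' @export
label_test_sets <- function(profiles, scheme) {
  list(binary = binary_labels(profiles, scheme$main_targets),
       graded = encode_profile(scheme, profiles))
}

# one repetition's train/test index split
split_indices <- function(profiles, ids, cfg, seed) {
  n_active <- rowSums(profiles)
  if (cfg$sampling == "stratified") {
    graded <- encode_profile(cfg$scheme, profiles)
    train <- integer(0)
    with_seed(seed, {
      for (lev in sort(unique(graded))) {
        idx <- which(graded == lev)
        if (length(idx) < 2) {
          warning(sprintf("score level %d has < 2 compounds: left in test",
                          lev))
          next
        }
        train <- c(train, sample(idx, length(idx) %/% 2L))
      }
    })
    return(list(train = sort(train),
                test = setdiff(seq_len(nrow(profiles)), train)))
  }
  keys <- apply(profiles, 1, profile_key)
  active <- n_active > 0
  groups <- split(ids[active], keys[active])
  train_ids <- character(0)
  for (category in c("single", "dual", "triple")) {
    want <- c(single = 1L, dual = 2L, triple = 3L)[[category]]
    if (!any(n_active[active] %in% want)) next
    cat_n <- vapply(names(groups), function(k)
      sum(strsplit(k, "")[[1]] == "1"), integer(1))
    if (!any(cat_n == want)) next
    sp <- profile_balanced_sample(groups, category, seed = seed + want)
    train_ids <- c(train_ids, sp$train)
  }
  decoy_pool <- ids[n_active == 0]
  train_ids <- add_decoys(train_ids, decoy_pool, k = cfg$decoys_per_train,
                          seed = seed + 7L)
  train <- match(train_ids, ids)
  list(train = train, test = setdiff(seq_len(nrow(profiles)), train))
}

#' Run a multi-target screening experiment
#'
#' For every repetition: draw the train/test split (shared by all
#' methods), add decoys, grid-search C per method with stratified
#' cross-validation, fit, predict the test set, and record the binary
#' ranking error (`rank_error` on main-target labels, equal to 1 - AUC)
#' and the graded k-partite error. Fully reproducible from `cfg$seed`.
#'
#' @param cfg an [experiment_config()].
#' @param dataset an `mt_benchmark`, or any list with `x` (`dgCMatrix`,
#'   instances in columns), `profiles` (binary matrix) and `ids`.
#' @return An `experiment_result`: data.frame with one row per repetition
#'   and method (`repetition`, `method`, `C`, `rank_error_binary`,
#'   `kpartite_error_graded`, `n_train`, `n_test`) plus a `summary`
#'   attribute with per-method mean, SD and IQR.
#' @export
run_experiment <- function(cfg, dataset) {
  stopifnot(inherits(cfg, "experiment_config"))
  X <- as_feature_matrix(dataset$x)
  profiles <- dataset$profiles
  ids <- dataset$ids %||% sprintf("cpd%05d", seq_len(ncol(X)))
  if (cfg$drop_promiscuous) {
    keep <- filter_promiscuous(profiles)
    X <- X[, keep, drop = FALSE]
    profiles <- profiles[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  seeds <- derive_seeds(cfg$seed, cfg$repetitions)
  rows <- list()
  for (r in seq_len(cfg$repetitions)) {
    sp <- split_indices(profiles, ids, cfg, seeds[r])
    stopifnot(length(intersect(sp$train, sp$test)) == 0)
    Xtr <- X[, sp$train, drop = FALSE]
    Xte <- X[, sp$test, drop = FALSE]
    prof_tr <- profiles[sp$train, , drop = FALSE]
    labels_te <- label_test_sets(profiles[sp$test, , drop = FALSE],
                                 cfg$scheme)
    for (method in cfg$methods) {
      grid <- if (!is.null(cfg$C_grid)) cfg$C_grid[[method]] else
        default_C_grid(method)
      if (method == "svm_lc") {
        mains <- cfg$scheme$main_targets
        factors <- cfg$lc_factors %||%
          ifelse(seq_len(ncol(profiles)) %in% mains, 2, -1)
        per_target <- lapply(seq_len(ncol(profiles)), function(k) {
          lab_k <- prof_tr[, k]
          Ck <- grid_search_C("svc", Xtr, lab_k, grid,
                              folds = cfg$cv_folds, seed = seeds[r] + k,
                              tol = cfg$tol, max_iter = cfg$max_iter)
          fit_svc(Xtr, lab_k, C = Ck, tol = cfg$tol,
                  max_iter = cfg$max_iter, seed = seeds[r])
        })
        model <- combine_models(per_target, factors)
        bestC <- NA_real_
        pred <- predict(model, Xte)
      } else {
        sc_tr <- method_scores(method, prof_tr, cfg$scheme)
        bestC <- grid_search_C(method, Xtr, sc_tr, grid,
                               folds = cfg$cv_folds, seed = seeds[r],
                               tol = cfg$tol, max_iter = cfg$max_iter)
        model <- fit_single(method, Xtr, sc_tr, as.numeric(bestC),
                            cfg$tol, cfg$max_iter, seeds[r])
        pred <- predict_single(method, model, Xte)
      }
      reb <- if (length(unique(labels_te$binary)) < 2) NA_real_ else
        rank_error(pred, labels_te$binary)
      keg <- if (length(unique(labels_te$graded)) < 2) NA_real_ else
        kpartite_error(pred, labels_te$graded)
      rows[[length(rows) + 1L]] <-
        data.frame(repetition = r, method = method,
                   C = as.numeric(bestC), rank_error_binary = reb,
                   kpartite_error_graded = keg,
                   n_train = ncol(Xtr), n_test = ncol(Xte),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(res, res$method), function(d)
    data.frame(method = d$method[1],
               mean_rank_error_binary = mean(d$rank_error_binary),
               mean_kpartite_error_graded = mean(d$kpartite_error_graded),
               sd_kpartite = sd(d$kpartite_error_graded),
               iqr_kpartite = unname(diff(quantile(d$kpartite_error_graded,
                                                   c(0.25, 0.75)))),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  class(res) <- c("experiment_result", "data.frame")
  res
}

#' @exportS3Method base::print
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d repetitions x %d method(s)\n",
              max(x$repetition), length(unique(x$method))))
  print(attr(x, "summary"))
  invisible(x)
}

#' Write an experiment result table
#'
#' Deterministic TSV serialization (numbers at 15 significant digits):
#' identical results produce byte-identical files.
#'
#' @param res an `experiment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(res, path) {
  out <- as.data.frame(res)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v)
    formatC(v, digits = 15, format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Activity-cutoff robustness sweep
#'
#' Re-binarizes a real-valued (pK_i) activity matrix at each cutoff,
#' rebuilds the rank scores under the configured scheme, and runs the
#' experiment with stratified train/test splits (the label distribution
#' is preserved on both sides). Used to study how ranking performance
#' reacts to the chosen activity cutoff (the protease protocol sweeps
#' 5.6, 6.1 and 6.6).
#'
#' @param values numeric matrix of pK_i values (compounds x targets) or an
#'   `activity_table` read in `pki` mode.
#' @param cutoffs numeric vector of activity cutoffs.
#' @param cfg an [experiment_config()]; sampling is forced to
#'   `"stratified"`.
#' @param x feature matrix (`dgCMatrix`) aligned with `values` rows.
#' @param ids optional compound ids.
#' @return Named list (one `experiment_result` per cutoff), class
#'   `cutoff_sweep`.
#' @export
cutoff_sweep <- function(values, cutoffs, cfg, x, ids = NULL) {
  if (inherits(values, "activity_table")) {
    ids <- ids %||% values$ids
    values <- values$values
  }
  stopifnot(is.matrix(values), length(cutoffs) >= 1)
  X <- as_feature_matrix(x)
  out <- lapply(cutoffs, function(cut) {
    profiles <- (values >= cut) * 1L
    storage.mode(profiles) <- "integer"
    if (!any(profiles == 1L))
      stop(sprintf("cutoff %.2f leaves no active compounds", cut))
    cfg$sampling <- "stratified"
    run_experiment(cfg, list(x = X, profiles = profiles, ids = ids))
  })
  names(out) <- format(cutoffs)
  class(out) <- "cutoff_sweep"
  out
}

#' @exportS3Method base::print
print.cutoff_sweep <- function(x, ...) {
  for (k in seq_along(x)) {
    cat(sprintf("-- cutoff %s --\n", names(x)[k]))
    print(x[[k]])
  }
  invisible(x)
}
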