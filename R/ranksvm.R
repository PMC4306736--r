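# The multi-target ranking learner: a linear large-margin ranking function
# f(x) = w'x trained on (fingerprint, rank score) pairs with a k-partite
# pairwise hinge loss. Two convex surrogates are available:
#
#   margin-rescaled (default):
#     J(w) = 1/2 ||w||^2 + C/W * sum_P max(0, (s_i - s_j) - w'(x_i - x_j))
#   slack-rescaled:
#     J(w) = 1/2 ||w||^2 + C/W * sum_P (s_i - s_j) max(0, 1 - w'(x_i - x_j))
#
# where P = {(i,j) | s_i > s_j} and W = sum_P (s_i - s_j). Margin rescaling
# demands a separation proportional to the score difference, so ranking a
# score-0 decoy above a score-3 exact-profile compound costs more than
# swapping adjacent score levels. Dividing by W makes C comparable across
# data set sizes. There is no intercept: rankings are invariant to additive
# constants.

#' Ranking data set
#'
#' Bundles a sparse feature matrix with integer rank scores and the derived
#' statistics used throughout: `l` (instances), `d` (average non-zero
#' features per instance), `R` (number of distinct scores).
#'
#' @param x a `dgCMatrix` with one column per instance, or a list of
#'   [sparse_fp] with a common `dim`.
#' @param scores integer rank scores, one per instance.
#' @param ids optional character instance ids.
#' @return An object of class `rank_dataset`.
#' @export
rank_dataset <- function(x, scores, ids = NULL) {
  if (is.list(x) && !is(x, "Matrix")) x <- fps_to_matrix(x)
  if (!is(x, "dgCMatrix")) x <- as(as(as(x, "dMatrix"), "generalMatrix"),
                                   "CsparseMatrix")
  scores <- as.integer(scores)
  if (ncol(x) != length(scores))
    stop("need one score per instance (column of x)")
  if (!is.null(ids) && length(ids) != length(scores))
    stop("ids length mismatch")
  structure(list(x = x, scores = scores, ids = ids,
                 l = ncol(x), d = length(x@x) / max(1, ncol(x)),
                 R = length(unique(scores))),
            class = "rank_dataset")
}

#' @exportS3Method base::print
print.rank_dataset <- function(x, ...) {
  cat(sprintf("<rank_dataset> l=%d instances, d=%.1f avg features, R=%d scores\n",
              x$l, x$d, x$R))
  invisible(x)
}

#' Training settings for the ranking SVM
#'
#' @param C positive regularization constant; larger C weights the pairwise
#'   hinge loss more heavily against `||w||^2/2`. The cross-validation grid
#'   used for the ranking SVM in this package is `10^(-6..-2)`.
#' @param tol relative duality-gap tolerance certifying the returned
#'   weight vector's objective lies within `tol` (relative) of the optimum.
#' @param max_iter maximum coordinate-descent passes.
#' @param loss_variant `"margin_rescaled"` (default) or `"slack_rescaled"`.
#' @param seed integer seed for the solver's private shuffling stream; the
#'   fitted model is reproducible given (data, config, seed).
#' @return An object of class `train_config`.
#' @export
train_config <- function(C = 1e-2, tol = 1e-6, max_iter = 1000,
                         loss_variant = c("margin_rescaled",
                                          "slack_rescaled"),
                         seed = 1L) {
  loss_variant <- match.arg(loss_variant)
  stop_if_not_scalar_number(C, "C"); stop_if_not_scalar_number(tol, "tol")
  if (C <= 0) stop("C must be positive")
  if (tol <= 0) stop("tol must be positive")
  structure(list(C = C, tol = tol, max_iter = as.integer(max_iter),
                 loss_variant = loss_variant, seed = as.integer(seed)),
            class = "train_config")
}

model_weights <- function(model) {
  w <- numeric(model$dim)
  w[model$w_index] <- model$w_value
  w
}

new_linear_model <- function(w, dim, config = NULL, diagnostics = NULL,
                             class = character(0)) {
  idx <- which(w != 0)
  structure(list(w_index = idx, w_value = w[idx], dim = dim,
                 config = config, diagnostics = diagnostics),
            class = c(class, "mt_linear_model"))
}

#' @exportS3Method base::print
print.mt_linear_model <- function(x, ...) {
  cat(sprintf("<%s> %d non-zero weights / dim %s\n", class(x)[1],
              length(x$w_index), format(x$dim, scientific = FALSE)))
  invisible(x)
}

#' Predict ranking scores with a linear model
#'
#' `f(x) = w'x` per instance; output order matches input order.
#'
#' @param object a fitted linear model.
#' @param newdata a `dgCMatrix` (one column per instance), a list of
#'   [sparse_fp], or a [rank_dataset].
#' @param ... unused.
#' @return Numeric vector of real-valued ranking scores.
#' @export
predict.mt_linear_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (nrow(X) != object$dim) stop("feature dimension mismatch")
  as.numeric(Matrix::crossprod(X, model_weights(object)))
}

as_feature_matrix <- function(x) {
  if (inherits(x, "rank_dataset")) return(x$x)
  if (inherits(x, "sparse_fp")) return(fps_to_matrix(list(x)))
  if (is.list(x) && !is(x, "Matrix")) return(fps_to_matrix(x))
  if (!is(x, "dgCMatrix")) x <- as(as(as(x, "dMatrix"), "generalMatrix"),
                                   "CsparseMatrix")
  x
}

#' Ranking objective value
#'
#' Evaluates `J(w) = ||w||^2 / 2 + C * L(w)` for the configured loss
#' variant, using the fast sweep of [fast_weighted_loss()].
#'
#' @param w numeric weight vector (or a fitted model).
#' @param data a [rank_dataset].
#' @param cfg a [train_config].
#' @return A single numeric value.
#' @export
rank_objective <- function(w, data, cfg) {
  if (inherits(w, "mt_linear_model")) w <- model_weights(w)
  0.5 * sum(w^2) + cfg$C * fast_weighted_loss(w, data, cfg$loss_variant)$loss
}

#' Fast evaluation of the pairwise hinge loss
#'
#' Computes the normalized pairwise hinge loss `L(w)` (and the per-instance
#' coefficients of its subgradient) without materializing the ordered pair
#' set: the `l` prediction values are sorted once per score group and, for
#' each of the `R(R-1)/2` ordered score-group pairs, a merge sweep
#' accumulates hinge totals, giving `O(d l + R^2 l + l log l)` in place of
#' the brute-force `O(l^2)` pair expansion, with exact agreement up to
#' floating-point associativity.
#'
#' @param w numeric weight vector (or a fitted model).
#' @param data a [rank_dataset] with at least two distinct scores.
#' @param variant `"margin_rescaled"` or `"slack_rescaled"`.
#' @return List with `loss` (the value of `L(w)`) and `coef`
#'   (per-instance subgradient coefficients: `grad = X %*% coef`).
#' @export
fast_weighted_loss <- function(w, data,
                               variant = c("margin_rescaled",
                                           "slack_rescaled")) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "rank_dataset"))
  if (data$R < 2) stop("loss undefined: all scores equal (empty pair set)")
  if (inherits(w, "mt_linear_model")) w <- model_weights(w)
  f <- as.numeric(Matrix::crossprod(data$x, w))

  idx_groups <- split(seq_len(data$l), data$scores)
  idx_groups <- idx_groups[order(as.integer(names(idx_groups)),
                                 decreasing = TRUE)]
  vals <- as.integer(names(idx_groups))
  ng <- length(idx_groups)

  total <- 0
  coef <- numeric(data$l)
  Wtot <- 0
  for (a in seq_len(ng - 1)) {
    ia <- idx_groups[[a]]
    fa <- f[ia]
    for (b in seq(a + 1, ng)) {
      sd <- vals[a] - vals[b]
      Wtot <- Wtot + sd * length(ia) * length(idx_groups[[b]])
      ib <- idx_groups[[b]]
      ob <- order(f[ib])
      fb <- f[ib][ob]
      csum <- c(0, cumsum(fb))
      nb <- length(fb)
      m <- if (variant == "margin_rescaled") sd else 1
      mult <- if (variant == "margin_rescaled") 1 else sd
      # pair (i in a, j in b) contributes max(0, m - f_i + f_j):
      # active exactly when f_j > f_i - m
      v <- fa - m
      n_le <- findInterval(v, fb)          # f_j <= f_i - m
      cnt <- nb - n_le                     # active pairs per i
      s_gt <- csum[nb + 1] - csum[n_le + 1]
      total <- total + mult * sum(cnt * (m - fa) + s_gt)
      coef[ia] <- coef[ia] - mult * cnt
      # per j in b: number of i in a with f_i < f_j + m (strict, matching
      # the strict hinge activity f_j > f_i - m)
      fa_s <- sort(fa)
      cnt_j <- findInterval(fb + m, fa_s, left.open = TRUE)
      coef[ib][ob] <- coef[ib][ob] + mult * cnt_j
    }
  }
  list(loss = total / Wtot, coef = coef / Wtot, pair_weight_total = Wtot)
}

#' Fit the linear ranking SVM
#'
#' Minimizes the configured convex objective by dual coordinate descent
#' over the ordered pair set, stopping when the duality gap certifies a
#' relative accuracy of `cfg$tol`. If the iteration budget is exhausted
#' first, the best iterate is returned and flagged in the diagnostics
#' (`converged = FALSE`) with a warning.
#'
#' @param data a [rank_dataset] with `R >= 2` distinct scores.
#' @param cfg a [train_config].
#' @return An object of classes `mt_ranksvm` and `mt_linear_model`, with a
#'   `diagnostics` list (objective trace per pass, realized hinge loss,
#'   duality gap, iterations, convergence flag).
#' @export
fit_ranksvm <- function(data, cfg = train_config()) {
  stopifnot(inherits(data, "rank_dataset"), inherits(cfg, "train_config"))
  if (data$l < 2) stop("need at least two training instances")
  if (data$R < 2) stop("training impossible: all rank scores equal")
  variant <- if (cfg$loss_variant == "slack_rescaled") "slack" else "margin"
  res <- .ranksvm_dual_cd(data$x, data$scores, cfg$C, variant, cfg$tol,
                          cfg$max_iter, cfg$seed)
  if (!res$converged)
    warning(sprintf("ranking SVM did not reach tol %.1e in %d passes (gap %.2e); returning best iterate",
                    cfg$tol, cfg$max_iter, res$gap))
  diagnostics <- list(objective = res$objective, trace = res$trace,
                      hinge_loss = res$loss, gap = res$gap,
                      n_pairs = res$n_pairs,
                      pair_weight_total = res$pair_weight_total,
                      iterations = res$iterations,
                      converged = res$converged)
  new_linear_model(res$w, nrow(data$x), config = cfg,
                   diagnostics = diagnostics, class = "mt_ranksvm")
}

#' Serialize / restore a linear model as JSON
#'
#' Stores the sparse weights, dimension and training configuration; for
#' multi-class models, one weight vector per class. Round-trips through
#' [read_model()].
#'
#' @param model a fitted model.
#' @param path output path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "mt_mcsvm")) {
    obj <- list(type = "mt_mcsvm", dim = model$dim, classes = model$classes,
                W = lapply(seq_along(model$classes), function(k) {
                  wk <- model$W[, k]
                  idx <- which(wk != 0)
                  list(index = idx, value = wk[idx])
                }),
                config = unclass(model$config))
  } else {
    obj <- list(type = class(model)[1], dim = model$dim,
                index = model$w_index, value = model$w_value,
                config = unclass(model$config))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "mt_mcsvm")) {
    W <- matrix(0, obj$dim, length(obj$classes))
    for (k in seq_along(obj$classes)) {
      W[obj$W$index[[k]], k] <- obj$W$value[[k]]
    }
    return(structure(list(W = W, classes = as.integer(obj$classes),
                          dim = obj$dim, config = obj$config,
                          diagnostics = NULL),
                     class = c("mt_mcsvm")))
  }
  w <- numeric(obj$dim)
  w[obj$index] <- obj$value
  cls <- setdiff(obj$type, "mt_linear_model")
  new_linear_model(w, obj$dim, config = obj$config, class = cls)
}
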