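# Comparison methods: per-target soft-margin linear SVCs and their linear
# combination, and the Crammer-Singer multi-class SVM over rank-score
# classes. All are linear models without an intercept, trained by dual
# coordinate descent with duality-gap stopping (same machinery as the
# ranking SVM), so their optimization contracts can be checked against a
# generic QP solver.

#' Fit a soft-margin linear SVC
#'
#' Minimizes `||w||^2 / 2 + C * sum_i max(0, 1 - y_i w'x_i)` (L1 hinge, no
#' intercept). Labels may be given as `{0, 1}` or `{-1, +1}`; both classes
#' must be present.
#'
#' @param x feature matrix (`dgCMatrix`, one column per instance) or list
#'   of [sparse_fp].
#' @param labels binary class labels.
#' @param C positive regularization constant.
#' @param tol relative duality-gap tolerance.
#' @param max_iter maximum coordinate-descent passes.
#' @param seed solver shuffling seed.
#' @return An object of classes `mt_svc` and `mt_linear_model`.
#' @export
fit_svc <- function(x, labels, C = 1, tol = 1e-6, max_iter = 1000,
                    seed = 1L) {
  X <- as_feature_matrix(x)
  y <- as.numeric(labels)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be {0,1} or {-1,+1}")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) != ncol(X)) stop("need one label per instance")
  stop_if_not_scalar_number(C, "C")
  if (C <= 0) stop("C must be positive")
  res <- .svc_dual_cd(X, y, C, tol, as.integer(max_iter), as.integer(seed))
  if (!res$converged)
    warning(sprintf("SVC did not reach tol %.1e in %d passes (gap %.2e)",
                    tol, max_iter, res$gap))
  diagnostics <- list(objective = res$objective, trace = res$trace,
                      gap = res$gap, iterations = res$iterations,
                      converged = res$converged)
  new_linear_model(res$w, nrow(X), config = list(C = C, tol = tol,
                                                 seed = seed),
                   diagnostics = diagnostics, class = "mt_svc")
}

#' Linearly combine per-target models
#'
#' Forms `w_combined = sum_i c_i w_i` from per-target weight vectors, so
#' that `f_combined(x) = sum_i c_i f_i(x)` for every compound. Positive
#' factors favor desired targets, negative factors penalize undesired
#' ones; the convention used throughout this package is `+2` for each main
#' target's model and `-1` for each undesired target's model (an
#' alternative such as `+3/-2/-1` can be supplied explicitly).
#'
#' @param models list of fitted linear models with a common dimension.
#' @param factors numeric linear factors, one per model, not all zero.
#' @return An object of class `mt_svm_lc` / `mt_linear_model`.
#' @export
combine_models <- function(models, factors) {
  stopifnot(length(models) == length(factors), length(models) >= 1)
  if (all(factors == 0)) stop("at least one factor must be non-zero")
  dims <- vapply(models, `[[`, numeric(1), "dim")
  if (length(unique(dims)) != 1) stop("model dimensions differ")
  w <- numeric(dims[1])
  for (k in seq_along(models))
    w[models[[k]]$w_index] <- w[models[[k]]$w_index] +
      factors[k] * models[[k]]$w_value
  new_linear_model(w, dims[1], config = list(factors = factors),
                   class = "mt_svm_lc")
}

#' Fit a Crammer-Singer multi-class SVM
#'
#' Trains all class weight vectors in a single joint optimization
#' (multi-class hinge `max_k (w_k'x + 1 - [k = y]) - w_y'x`), interpreting
#' every distinct rank score as one class. Unlike one-vs-rest reductions,
#' a single problem couples the classes; unlike a ranking method, the
#' classes carry no order information.
#'
#' @param x feature matrix (`dgCMatrix`) or list of [sparse_fp].
#' @param scores integer class labels (rank scores); >= 2 distinct values.
#' @param C positive regularization constant.
#' @param tol relative duality-gap tolerance.
#' @param max_iter maximum passes.
#' @param seed solver shuffling seed.
#' @return An object of class `mt_mcsvm` with one weight vector per class
#'   (`W`, dimension x classes) and the sorted class values.
#' @export
fit_mcsvm <- function(x, scores, C = 1, tol = 1e-4, max_iter = 1000,
                      seed = 1L) {
  X <- as_feature_matrix(x)
  scores <- as.integer(scores)
  if (length(scores) != ncol(X)) stop("need one class per instance")
  classes <- sort(unique(scores))
  if (length(classes) < 2) stop("need at least two classes")
  stop_if_not_scalar_number(C, "C")
  if (C <= 0) stop("C must be positive")
  y0 <- match(scores, classes) - 1L
  res <- .mcsvm_dual_cd(X, y0, length(classes), C, tol,
                        as.integer(max_iter), as.integer(seed))
  if (!res$converged)
    warning(sprintf("MC-SVM did not reach tol %.1e in %d passes (gap %.2e)",
                    tol, max_iter, res$gap))
  structure(list(W = res$W, classes = classes, dim = nrow(X),
                 config = list(C = C, tol = tol, seed = seed),
                 diagnostics = list(objective = res$objective,
                                    trace = res$trace, gap = res$gap,
                                    iterations = res$iterations,
                                    converged = res$converged)),
            class = "mt_mcsvm")
}

#' @exportS3Method base::print
print.mt_mcsvm <- function(x, ...) {
  cat(sprintf("<mt_mcsvm> %d classes {%s}, dim %s\n", length(x$classes),
              paste(x$classes, collapse = ","),
              format(x$dim, scientific = FALSE)))
  invisible(x)
}

#' Predict classes with a multi-class SVM
#'
#' `argmax_k w_k'x`; exact ties are broken toward the lowest class value.
#'
#' @param model a fitted [fit_mcsvm()] model.
#' @param newdata feature matrix, list of [sparse_fp], or [rank_dataset].
#' @return Integer vector of predicted class values (rank scores).
#' @export
predict_mc <- function(model, newdata) {
  stopifnot(inherits(model, "mt_mcsvm"))
  X <- as_feature_matrix(newdata)
  if (nrow(X) != model$dim) stop("feature dimension mismatch")
  scores <- as.matrix(Matrix::crossprod(X, model$W))  # instances x classes
  model$classes[apply(scores, 1, which.max)]
}

#' Class values as coarse ranking scores
#'
#' A multi-class SVM outputs a class, not a gradual ordering; to evaluate
#' it with ranking metrics, the predicted class value itself is used as
#' the (heavily tied) prediction score.
#'
#' @inheritParams predict_mc
#' @return Numeric vector of predicted class values.
#' @export
rank_by_mc <- function(model, newdata) {
  as.numeric(predict_mc(model, newdata))
}
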