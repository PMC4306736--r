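# Pairwise ranking error and its k-partite, score-difference-weighted
# generalization, plus the Mann-Whitney AUC they reduce to on binary
# labels. All metrics share one group-based sweep that never materializes
# the ordered pair set, so evaluation is O(l log l + R^2 l) instead of
# O(l^2) in the number of instances l and distinct scores R.

#' Ordered pair set of a score vector
#'
#' All ordered index pairs `(i, j)` with `s_i > s_j`, each weighted by the
#' score difference `s_i - s_j`. These are the pairs a ranking function can
#' swap; an empty pair set (all scores equal) makes ranking training
#' impossible and yields a warning.
#'
#' @param scores integer rank scores, length >= 2.
#' @return An object of class `pair_set`: list with integer vectors `i`,
#'   `j` and `weight`.
#' @export
build_pair_set <- function(scores) {
  stopifnot(length(scores) >= 2)
  scores <- as.integer(scores)
  ord <- order(scores, decreasing = TRUE)
  ii <- jj <- integer(0)
  ww <- integer(0)
  groups <- split(seq_along(scores), scores)
  groups <- groups[order(as.integer(names(groups)), decreasing = TRUE)]
  vals <- as.integer(names(groups))
  ng <- length(groups)
  if (ng >= 2) {
    for (a in seq_len(ng - 1)) {
      for (b in seq((a + 1), ng)) {
        pairs <- expand.grid(i = groups[[a]], j = groups[[b]],
                             KEEP.OUT.ATTRS = FALSE)
        ii <- c(ii, pairs$i)
        jj <- c(jj, pairs$j)
        ww <- c(ww, rep.int(vals[a] - vals[b], nrow(pairs)))
      }
    }
  }
  if (!length(ii)) warning("all scores equal: empty pair set")
  structure(list(i = ii, j = jj, weight = ww), class = "pair_set")
}

#' @exportS3Method base::print
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d ordered pairs, total weight %d\n",
              length(x$i), sum(x$weight)))
  invisible(x)
}

#' Loss of one ordered pair
#'
#' For an ordered pair with `s_i > s_j`: 1 when the predictions invert the
#' pair (`f_i < f_j`), 1/2 when they tie exactly (`f_i == f_j`; sorting
#' tied values misorders the pair with probability one half), 0 otherwise.
#' The tie predicate is exact floating-point equality.
#'
#' @param fi,fj numeric predictions for the higher- and lower-scored
#'   instance (vectorized).
#' @return Values in `{0, 0.5, 1}`.
#' @export
pair_loss <- function(fi, fj) {
  ifelse(fi < fj, 1, ifelse(fi == fj, 0.5, 0))
}

# shared sweep: per ordered group pair count inverted and tied prediction
# pairs, weight them, and accumulate hinge-free totals
weighted_pair_error <- function(predictions, scores, weighted) {
  stopifnot(length(predictions) == length(scores))
  groups <- split(predictions, as.integer(scores))
  groups <- groups[order(as.integer(names(groups)), decreasing = TRUE)]
  vals <- as.integer(names(groups))
  ng <- length(groups)
  if (ng < 2) stop("rank error undefined: all scores equal (empty pair set)")
  num <- 0
  den <- 0
  for (a in seq_len(ng - 1)) {
    fa <- groups[[a]]
    for (b in seq(a + 1, ng)) {
      fb <- sort(groups[[b]])
      le <- findInterval(fa, fb)                    # f_j <= f_i
      lt <- findInterval(fa, fb, left.open = TRUE)  # f_j <  f_i
      inverted <- sum(length(fb) - le)
      tied <- sum(le - lt)
      w <- if (weighted) vals[a] - vals[b] else 1
      num <- num + w * (inverted + 0.5 * tied)
      den <- den + w * length(fa) * length(fb)
    }
  }
  num / den
}

#' Fraction of miss-ranked pairs
#'
#' The pairwise ranking error: the mean [pair_loss()] over the ordered pair
#' set. On binary scores this equals `1 - AUC`.
#'
#' @param predictions numeric ranking-function values.
#' @param scores integer rank scores of the same length.
#' @return A value in `[0, 1]`.
#' @export
rank_error <- function(predictions, scores) {
  weighted_pair_error(predictions, scores, weighted = FALSE)
}

#' k-partite ranking error
#'
#' Pairwise losses weighted by the score difference `s_i - s_j` and
#' normalized by the total weight, so that swapping instances whose scores
#' lie far apart is punished harder than swapping neighbors. With two
#' score levels `{1, 0}` it coincides with [rank_error()].
#'
#' @inheritParams rank_error
#' @return A value in `[0, 1]`.
#' @export
kpartite_error <- function(predictions, scores) {
  weighted_pair_error(predictions, scores, weighted = TRUE)
}

#' Mann-Whitney AUC
#'
#' Rank-based AUC with half credit for ties; on binary labels it satisfies
#' `auc + rank_error == 1`.
#'
#' @param predictions numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @return A value in `[0, 1]`.
#' @export
auc <- function(predictions, labels) {
  labels <- as.integer(labels)
  stopifnot(length(predictions) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("auc undefined: both classes must be present")
  r <- rank(predictions)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
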