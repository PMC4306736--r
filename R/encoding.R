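# Activity-profile rank-score encodings.
#
# A compound screened against m targets carries a binary activity profile
# (y_1, ..., y_m). The encoding collapses this profile into one integer
# rank score s >= 0: the desired profile gets the unique maximum, profiles
# deviating from it get graded lower scores, and decoys get 0. A ranking
# method trained on these scores learns the relative importance of the
# different activity profiles in a single model.

profile_key <- function(p) paste(as.integer(p), collapse = "")

all_profiles <- function(m) {
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))[, m:1, drop = FALSE]
  colnames(grid) <- NULL
  grid
}

#' Build an activity-profile encoding scheme
#'
#' Constructs the total map from binary activity profiles over `m` targets
#' to integer rank scores. The desired profile (active on every main
#' target, inactive elsewhere) receives the unique maximum score. Profiles
#' are first screened by hard decoy rules, then the survivors are graded by
#' how they deviate from the desired profile:
#'
#' * Decoy rules (score 0): inactive on every main target; active on an
#'   undesired target while missing a main target (a "wrong mix"); and,
#'   when `nonselective_as_decoy` is set, active on all `m` targets.
#' * Grading: survivors are ordered by (number of undesired-target
#'   activities, number of missed main targets), refined by the stated
#'   priorities -- an activity on a higher-priority avoid target, or a miss
#'   of a higher-priority main target, is more severe. Equally deviating
#'   profiles share one score, and scores are assigned as a contiguous
#'   descending integer range so that the full score set is `0..max`.
#'
#' For three targets the four canonical parameterizations (single or dual
#' main targets, with or without secondary/main prioritization and
#' non-selective decoys) reproduce the published example label tables
#' cell for cell; the same construction extends to any `m`.
#'
#' @param m number of targets.
#' @param main_targets integer indices of the main target(s), non-empty.
#' @param secondary_priority `"equal"` or an ordered integer vector of all
#'   secondary targets, most-important-to-avoid first.
#' @param main_priority `"equal"` or an ordered integer vector of all main
#'   targets, most important first.
#' @param nonselective_as_decoy logical; treat the all-active profile as a
#'   decoy (score 0).
#' @return An object of class `encoding_scheme` with the score `table`
#'   (named by profile strings such as `"101"`), `max_score`, and the
#'   parameters.
#' @export
build_scheme <- function(m, main_targets, secondary_priority = "equal",
                         main_priority = "equal",
                         nonselective_as_decoy = FALSE) {
  m <- as.integer(m)
  if (m < 1 || m > 16) stop("m must be between 1 and 16")
  main_targets <- sort(unique(as.integer(main_targets)))
  if (!length(main_targets)) stop("main_targets must be non-empty")
  if (any(main_targets < 1 | main_targets > m))
    stop("main_targets out of range")
  secondary <- setdiff(seq_len(m), main_targets)

  sec_w <- rep(1, m)   # severity weight per target when it is an extra
  if (!identical(secondary_priority, "equal")) {
    sp <- as.integer(secondary_priority)
    if (any(sp %in% main_targets))
      stop("secondary_priority names a main target")
    if (!setequal(sp, secondary))
      stop("secondary_priority must order all secondary targets")
    sec_w[sp] <- rev(seq_along(sp))  # avoid-first = largest weight
  }
  main_w <- rep(1, m)  # severity weight per main target when it is missed
  if (!identical(main_priority, "equal")) {
    mp <- as.integer(main_priority)
    if (!setequal(mp, main_targets))
      stop("main_priority must order all main targets")
    main_w[mp] <- rev(seq_along(mp))  # first listed = worst to miss
  }

  profs <- all_profiles(m)
  keys <- apply(profs, 1, profile_key)
  extras <- profs[, secondary, drop = FALSE] == 1L
  misses <- profs[, main_targets, drop = FALSE] == 0L
  n_extra <- rowSums(extras)
  n_miss <- rowSums(misses)
  w_extra <- as.numeric(extras %*% sec_w[secondary])
  w_miss <- as.numeric(misses %*% main_w[main_targets])

  decoy <- (n_miss == length(main_targets)) |        # inactive on all mains
    (n_extra > 0 & n_miss > 0)                       # wrong mix
  if (nonselective_as_decoy) decoy <- decoy | rowSums(profs) == m

  scores <- integer(nrow(profs))
  surv <- which(!decoy)
  sev <- data.frame(n_extra = n_extra[surv], n_miss = n_miss[surv],
                    w_extra = w_extra[surv], w_miss = w_miss[surv])
  sev_key <- do.call(paste, c(lapply(sev, function(v)
    formatC(v, width = 6, flag = "0")), sep = "|"))
  classes <- sort(unique(sev_key))
  scores[surv] <- length(classes) - match(sev_key, classes) + 1L

  table <- setNames(scores, keys)
  structure(list(m = m, main_targets = main_targets,
                 secondary_priority = secondary_priority,
                 main_priority = main_priority,
                 nonselective_as_decoy = nonselective_as_decoy,
                 table = table, max_score = max(scores)),
            class = "encoding_scheme")
}

#' @exportS3Method base::print
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme> m=%d, main={%s}, max score %d%s\n", x$m,
              paste(x$main_targets, collapse = ","), x$max_score,
              if (x$nonselective_as_decoy) ", non-selective = decoy" else ""))
  tab <- x$table[order(-x$table, names(x$table))]
  cat(paste(sprintf("  %s -> %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Map an activity profile to its rank score
#'
#' @param scheme an [build_scheme()] encoding scheme.
#' @param p binary activity profile of length `scheme$m` (a vector, or a
#'   matrix with one profile per row).
#' @return Integer rank score(s).
#' @export
encode_profile <- function(scheme, p) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  if (is.matrix(p)) {
    if (ncol(p) != scheme$m) stop("profile length does not match scheme$m")
    return(unname(scheme$table[apply(p, 1, profile_key)]))
  }
  if (length(p) != scheme$m) stop("profile length does not match scheme$m")
  unname(scheme$table[[profile_key(p)]])
}

#' Three-level selectivity labeling
#'
#' The selectivity-ranking labeling for a single main target: compounds
#' active on the main target only are labeled 1, decoys (inactive on the
#' main target) 0, and non-selective actives (active on the main target
#' and at least one other) -1, pushing non-selective compounds below the
#' decoys in the ranking.
#'
#' @param p binary activity profile (vector or matrix with one profile per
#'   row).
#' @param main single main-target index.
#' @return Integer label(s) in `{1, 0, -1}`.
#' @export
srank_encode <- function(p, main) {
  main <- as.integer(main)
  stopifnot(length(main) == 1)
  if (!is.matrix(p)) p <- matrix(as.integer(p), nrow = 1)
  if (main < 1 || main > ncol(p)) stop("main target index out of range")
  on_main <- p[, main] == 1L
  others <- rowSums(p[, -main, drop = FALSE]) > 0
  out <- ifelse(!on_main, 0L, ifelse(others, -1L, 1L))
  if (length(out) == 1) out[[1]] else out
}

#' Binary main-target labeling
#'
#' The labeling used for binary test sets: 1 iff the compound is active on
#' every main target, regardless of its activity elsewhere.
#'
#' @param p binary activity profile (vector or matrix with one profile per
#'   row).
#' @param main_targets non-empty integer index set.
#' @return Integer label(s) in `{0, 1}`.
#' @export
binary_labels <- function(p, main_targets) {
  main_targets <- as.integer(main_targets)
  if (!length(main_targets)) stop("main_targets must be non-empty")
  if (!is.matrix(p)) p <- matrix(as.integer(p), nrow = 1)
  out <- as.integer(rowSums(p[, main_targets, drop = FALSE] == 1L) ==
                      length(main_targets))
  if (length(out) == 1) out[[1]] else out
}

#' Drop highly promiscuous compounds
#'
#' Optional pre-filter removing compounds active on all `m` targets, for
#' data sets where such broad activity is suspected to stem from
#' non-specific events (aggregation, assay interference) rather than
#' genuine target engagement.
#'
#' @param profiles binary profile matrix (compounds x targets).
#' @return Logical vector: `TRUE` for compounds to keep.
#' @export
filter_promiscuous <- function(profiles) {
  rowSums(profiles) < ncol(profiles)
}
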