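# Synthetic multi-target screening benchmarks with known ground truth.
#
# Each target owns a disjoint block of "pharmacophore" features; a compound
# active on a target carries each feature of that target's block with
# probability `activation_prob`, and every feature position is additionally
# flipped with probability `background_noise` (XOR, so noise can both add
# spurious bits and erase signal bits). Because the signal is linear in the
# feature blocks, a linear ranker can in principle recover any profile
# ordering, and with `activation_prob = 1, background_noise = 0` the rank
# groups are exactly linearly separable -- the limit used to validate the
# whole train/evaluate loop.

#' Specification of a synthetic multi-target benchmark
#'
#' The default design emulates a three-target confirmatory-screening
#' collection of 800 compounds whose activity-profile composition covers
#' all single-, dual- and triple-target overlaps plus a decoy pool: 90
#' compounds per single-target profile, 60 per dual-target profile, 50
#' triple actives and 300 decoys, with a ~20-bit mean fingerprint density
#' in a 4096-dimensional hash space and moderate noise.
#'
#' @param m number of targets (default 3).
#' @param dim fingerprint dimension (default `2^12`; production
#'   fingerprints use `2^20`, but the smaller space keeps brute-force
#'   oracles cheap without changing the methods).
#' @param block_size features per target block (default 25).
#' @param target_feature_blocks optional list of `m` disjoint 0-based
#'   feature index vectors; by default the first `m * block_size` indices
#'   are split consecutively.
#' @param activation_prob probability that a target-active compound
#'   carries each feature of that target's block (default 0.9).
#' @param background_noise per-feature flip probability (default
#'   `bits_per_compound / dim`).
#' @param bits_per_compound mean background bits per compound (default 20);
#'   only used to derive the default `background_noise`.
#' @param overlap_design named integer vector: profile string (e.g.
#'   `"110"`) -> requested compound count. Must cover only profiles of
#'   length `m`. Default: the 800-compound design described above (m = 3
#'   only).
#' @param seed integer seed; the benchmark is bit-identical given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 3, dim = 2^12, block_size = 25,
                           target_feature_blocks = NULL,
                           activation_prob = 0.9,
                           background_noise = NULL,
                           bits_per_compound = 20,
                           overlap_design = NULL, seed = 1L) {
  m <- as.integer(m)
  if (is.null(overlap_design)) {
    if (m != 3)
      stop("a default overlap_design exists only for m = 3; supply one")
    overlap_design <- c("100" = 90L, "010" = 90L, "001" = 90L,
                        "110" = 60L, "101" = 60L, "011" = 60L,
                        "111" = 50L, "000" = 300L)
  }
  if (is.null(names(overlap_design)) ||
      any(nchar(names(overlap_design)) != m) ||
      !all(grepl("^[01]+$", names(overlap_design))))
    stop("overlap_design must be named by length-m profile strings")
  if (anyDuplicated(names(overlap_design)))
    stop("duplicate profile in overlap_design")
  if (any(overlap_design < 0)) stop("negative profile count")
  if (is.null(target_feature_blocks)) {
    if (m * block_size > dim) stop("feature blocks exceed dim")
    target_feature_blocks <- lapply(seq_len(m), function(k)
      seq.int((k - 1) * block_size, k * block_size - 1))
  }
  if (length(target_feature_blocks) != m)
    stop("need one feature block per target")
  if (anyDuplicated(unlist(target_feature_blocks)))
    stop("target feature blocks must be disjoint")
  if (any(unlist(target_feature_blocks) < 0) ||
      any(unlist(target_feature_blocks) >= dim))
    stop("block feature index out of range")
  if (is.null(background_noise)) background_noise <- bits_per_compound / dim
  if (activation_prob < 0 || activation_prob > 1 ||
      background_noise < 0 || background_noise > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(m = m, n_compounds = sum(overlap_design), dim = dim,
                 block_size = block_size,
                 target_feature_blocks = target_feature_blocks,
                 activation_prob = activation_prob,
                 background_noise = background_noise,
                 bits_per_compound = bits_per_compound,
                 overlap_design = overlap_design, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic benchmark
#'
#' Realizes the compound population of a [synthetic_spec()]: every
#' requested profile count is met exactly, fingerprints follow the planted
#' block model, and the per-target ground-truth weight vectors (indicator
#' of each target's feature block) are returned alongside.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `mt_benchmark`: list with `x` (sparse
#'   `dgCMatrix`, dim x n), `profiles` (n x m binary matrix), `ids`,
#'   `truth` (list with `weights`, a dim x m matrix, and the spec).
#' @export
make_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    profs <- do.call(rbind, lapply(names(spec$overlap_design), function(key) {
      cnt <- spec$overlap_design[[key]]
      matrix(as.integer(strsplit(key, "")[[1]]), nrow = cnt, ncol = spec$m,
             byrow = TRUE)
    }))
    n <- nrow(profs)
    ii <- vector("list", n)
    for (c_i in seq_len(n)) {
      on_bits <- integer(0)
      for (k in which(profs[c_i, ] == 1L)) {
        blk <- spec$target_feature_blocks[[k]]
        on_bits <- c(on_bits,
                     blk[runif(length(blk)) < spec$activation_prob])
      }
      n_flip <- rbinom(1, spec$dim, spec$background_noise)
      flips <- if (n_flip > 0) sample.int(spec$dim, n_flip) - 1L
      else integer(0)
      # XOR: flipped signal bits are erased, flipped silent bits are set
      bits <- union(setdiff(on_bits, flips), setdiff(flips, on_bits))
      ii[[c_i]] <- sort(bits)
    }
    weights <- matrix(0, spec$dim, spec$m)
    for (k in seq_len(spec$m))
      weights[spec$target_feature_blocks[[k]] + 1L, k] <- 1
    ids <- sprintf("cpd%05d", seq_len(n))
    X <- Matrix::sparseMatrix(
      i = unlist(ii) + 1L,
      j = rep(seq_len(n), lengths(ii)),
      x = 1, dims = c(spec$dim, n))
    structure(list(x = X, profiles = profs, ids = ids,
                   truth = list(weights = weights, spec = spec)),
              class = "mt_benchmark")
  })
}

#' @exportS3Method base::print
print.mt_benchmark <- function(x, ...) {
  cat(sprintf("<mt_benchmark> %d compounds x %d targets, dim %s\n",
              nrow(x$profiles), ncol(x$profiles),
              format(x$truth$spec$dim, scientific = FALSE)))
  print(profile_census(x))
  invisible(x)
}

#' Census of activity profiles
#'
#' Exact compound counts for every one of the `2^m` profiles (the overlap
#' composition of the collection).
#'
#' @param x an `mt_benchmark` or a binary profile matrix.
#' @return Named integer vector over all `2^m` profile strings.
#' @export
profile_census <- function(x) {
  profiles <- if (inherits(x, "mt_benchmark")) x$profiles else x
  if (is.null(dim(profiles))) stop("profiles must be a matrix")
  keys <- apply(all_profiles(ncol(profiles)), 1, profile_key)
  out <- setNames(integer(length(keys)), keys)
  if (nrow(profiles)) {
    got <- table(apply(profiles, 1, profile_key))
    out[names(got)] <- as.integer(got)
  }
  out
}

#' Write a benchmark to disk
#'
#' Emits the sparse fingerprint file (`fingerprints.svml`) and the binary
#' activity table (`activity.tsv`) in the formats the package readers
#' consume, so a written benchmark round-trips through
#' [read_sparse_fingerprints()] and [read_activity_table()].
#'
#' @param bench an `mt_benchmark`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "mt_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory %s", dir))
  X <- bench$x
  fps <- lapply(seq_len(ncol(X)), function(k) {
    col <- X[, k]
    idx <- which(col != 0)
    sparse_fp(idx - 1, col[idx], dim = nrow(X))
  })
  write_sparse_fingerprints(fps, file.path(dir, "fingerprints.svml"),
                            labels = rep(0, length(fps)), ids = bench$ids)
  tab <- data.frame(id = bench$ids, bench$profiles,
                    check.names = FALSE)
  colnames(tab) <- c("id", sprintf("T%d", seq_len(ncol(bench$profiles))))
  write.table(tab, file.path(dir, "activity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
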