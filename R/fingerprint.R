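#' Sparse non-negative fingerprint vector
#'
#' A sparse feature vector with 0-based indices into a hash space of
#' dimension `dim` (default `2^20`). Values are strictly positive; binary
#' fingerprints simply carry value 1 at every set position. A fingerprint
#' flagged as `normalized` has unit Euclidean norm, so the plain dot product
#' of two normalized fingerprints equals the cosine kernel
#' `k_cos(x_i, x_j) = x_i'x_j / (||x_i|| ||x_j||)`.
#'
#' @param indices integer vector of 0-based feature indices, strictly
#'   increasing, all in `[0, dim)`.
#' @param values positive numeric vector, one per index (default all 1).
#' @param dim hash-space dimension (default `2^20`).
#' @param normalized logical; assert that `values` already has unit norm.
#' @return An object of class `sparse_fp`.
#' @export
sparse_fp <- function(indices, values = rep(1, length(indices)),
                      dim = 2^20, normalized = FALSE) {
  indices <- as.numeric(indices)
  values <- as.numeric(values)
  if (length(indices) != length(values))
    stop("indices and values must have equal length")
  if (length(indices) && (any(indices < 0) || any(indices >= dim)))
    stop("fingerprint indices must lie in [0, dim)")
  if (length(indices) > 1 && any(diff(indices) <= 0))
    stop("fingerprint indices must be strictly increasing")
  if (any(values <= 0)) stop("fingerprint values must be positive")
  if (normalized && length(values)) {
    nrm <- sqrt(sum(values^2))
    if (abs(nrm - 1) >= 1e-9)
      stop("normalized fingerprint must have unit Euclidean norm")
  }
  structure(list(index = indices, value = values, dim = as.numeric(dim),
                 normalized = isTRUE(normalized)),
            class = "sparse_fp")
}

#' @exportS3Method base::print
print.sparse_fp <- function(x, ...) {
  cat(sprintf("<sparse_fp> %d/%s features%s\n", length(x$index),
              format(x$dim, scientific = FALSE),
              if (x$normalized) " (L2-normalized)" else ""))
  invisible(x)
}

#' Fingerprint generation settings
#'
#' Controls circular fingerprint generation: the bond diameter of the
#' largest atom environment (6 reaches three bonds out from each atom),
#' the hash-space size the substructure codes are folded into, and whether
#' duplicate environments increment counts or just set a bit.
#'
#' @param bond_diameter even non-negative integer bond diameter (default 6).
#' @param dim hash-space size, a power of two (default `2^20`).
#' @param counts logical; `FALSE` (default) gives binary presence
#'   fingerprints, `TRUE` counts duplicate environments.
#' @return An object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(bond_diameter = 6, dim = 2^20, counts = FALSE) {
  stop_if_not_scalar_number(bond_diameter, "bond_diameter")
  if (bond_diameter < 0 || bond_diameter %% 2 != 0)
    stop("bond_diameter must be a non-negative even integer")
  if (!is_power_of_two(dim)) stop("dim must be a power of two")
  structure(list(bond_diameter = as.integer(bond_diameter),
                 dim = as.numeric(dim), counts = isTRUE(counts)),
            class = "fingerprint_config")
}

#' Length-normalize a fingerprint for the cosine kernel
#'
#' Divides every value by the Euclidean norm so that `||x|| = 1`. After
#' normalization the sparse dot product of two fingerprints equals the
#' cosine kernel and lies in `[0, 1]` for non-negative inputs, removing the
#' dependence of the plain dot-product kernel on molecule size.
#'
#' @param fp a [sparse_fp] with at least one entry.
#' @return The normalized [sparse_fp] with the `normalized` flag set.
#' @export
cosine_normalize <- function(fp) {
  stopifnot(inherits(fp, "sparse_fp"))
  if (!length(fp$index)) stop("cannot normalize an empty fingerprint (norm 0)")
  sparse_fp(fp$index, fp$value / sqrt(sum(fp$value^2)), dim = fp$dim,
            normalized = TRUE)
}

#' Sparse dot product of two fingerprints
#'
#' Merge-join over the sorted index lists. On length-normalized
#' fingerprints of non-negative origin the result is the cosine kernel and
#' lies in `[0, 1]`.
#'
#' @param a,b [sparse_fp] objects with equal `dim`.
#' @return A single numeric value.
#' @export
fp_dot <- function(a, b) {
  stopifnot(inherits(a, "sparse_fp"), inherits(b, "sparse_fp"))
  if (a$dim != b$dim) stop("fingerprint dimensions differ")
  if (!length(a$index) || !length(b$index)) return(0)
  ka <- match(a$index, b$index)
  keep <- !is.na(ka)
  sum(a$value[keep] * b$value[ka[keep]])
}

#' Stack fingerprints into a sparse feature matrix
#'
#' @param fps list of [sparse_fp] with a common `dim`.
#' @return A `dgCMatrix` with `dim` rows and one column per fingerprint.
#' @export
fps_to_matrix <- function(fps) {
  stopifnot(length(fps) > 0)
  dims <- vapply(fps, function(f) f$dim, numeric(1))
  if (length(unique(dims)) != 1) stop("all fingerprints must share dim")
  nnz <- vapply(fps, function(f) length(f$index), integer(1))
  Matrix::sparseMatrix(
    i = unlist(lapply(fps, function(f) f$index)) + 1,
    j = rep(seq_along(fps), nnz),
    x = unlist(lapply(fps, function(f) f$value)),
    dims = c(dims[1], length(fps)))
}

# Stable 32-bit hash of an integer tuple (FNV-1a, implemented in C++).
# Accepts unsigned 32-bit values stored as doubles (previous-round codes)
# and maps them onto the signed 32-bit range before hashing.
hash_tuple <- function(v) {
  v <- as.numeric(v) %% 2^32
  v <- v - (v >= 2^31) * 2^32
  .fnv1a_hash(as.integer(v))
}

#' Initial per-atom invariant codes
#'
#' Assigns every atom a deterministic 32-bit hash of its local properties:
#' element, heavy-atom degree, attached hydrogen count, formal charge, and
#' ring membership. Atoms with identical local environments receive
#' identical codes, and the multiset of codes does not depend on atom input
#' order.
#'
#' @param mol a normalized [molecule].
#' @return Numeric vector of atom codes (unsigned 32-bit values).
#' @export
initial_atom_invariants <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  if (n == 0) return(numeric(0))
  deg <- integer(n)
  ring_atom <- rep(FALSE, n)
  if (nrow(mol$bonds)) {
    tab <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
    deg <- tab
    in_ring <- bonds_in_ring(mol)
    ring_atom[unique(c(mol$bonds$a1[in_ring], mol$bonds$a2[in_ring]))] <- TRUE
  }
  vapply(seq_len(n), function(a) {
    hash_tuple(c(utf8ToInt(mol$atoms$element[a]), deg[a],
                 mol$atoms$hcount[a], mol$atoms$charge[a],
                 as.integer(ring_atom[a])))
  }, numeric(1))
}

#' Hashed circular (ECFP-style) fingerprint
#'
#' Iterative neighborhood hashing: atoms start from
#' [initial_atom_invariants()]; in each of `bond_diameter / 2` rounds every
#' atom's code is re-hashed together with the sorted (bond order, neighbor
#' code) pairs of its neighbors, so a round-`r` code identifies the
#' substructure within bond radius `r`. Codes from every round (including
#' round 0) are folded modulo `dim` into the fingerprint. Hash collisions
#' in the folded space are accepted silently, as is usual for hashed
#' fingerprints. The result is independent of atom input order.
#'
#' @param mol a normalized [molecule].
#' @param cfg a [fingerprint_config].
#' @return A [sparse_fp]. An empty molecule yields an empty fingerprint
#'   with a warning.
#' @export
ecfp <- function(mol, cfg = fingerprint_config()) {
  stopifnot(inherits(mol, "molecule"), inherits(cfg, "fingerprint_config"))
  n <- nrow(mol$atoms)
  if (n == 0) {
    warning("empty molecule: returning empty fingerprint")
    return(sparse_fp(numeric(0), numeric(0), dim = cfg$dim))
  }
  nbr <- adjacency_list(mol)
  codes <- initial_atom_invariants(mol)
  all_codes <- codes
  rounds <- cfg$bond_diameter %/% 2L
  if (rounds > 0) {
    for (r in seq_len(rounds)) {
      codes <- vapply(seq_len(n), function(a) {
        nb <- nbr[[a]]
        if (!nrow(nb)) return(hash_tuple(c(r, codes[a])))
        env <- cbind(nb$order, codes[nb$atom])
        env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
        hash_tuple(c(r, codes[a], t(env)))
      }, numeric(1))
      all_codes <- c(all_codes, codes)
    }
  }
  idx <- all_codes %% cfg$dim
  if (cfg$counts) {
    cnt <- table(idx)
    ind <- as.numeric(names(cnt))
    o <- order(ind)
    sparse_fp(ind[o], as.numeric(cnt)[o], dim = cfg$dim)
  } else {
    sparse_fp(sort(unique(idx)), dim = cfg$dim)
  }
}
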