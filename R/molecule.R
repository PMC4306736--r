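#' Molecular graph
#'
#' A light hydrogen-suppressed molecular graph: atoms carry element symbol,
#' formal charge and attached-hydrogen count; bonds carry 1-based atom
#' indices and an order code (1, 2, 3, or 4 for aromatic, following the SDF
#' convention). Explicit hydrogen atoms are permitted on input and are
#' folded into `hcount` by [normalize_structure()].
#'
#' @param id compound identifier, unique within a file.
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer) and `hcount` (integer).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (1, 2, 3 or 4).
#' @param provenance source format tag, e.g. `"smiles"` or `"sdf"`.
#' @param meta optional named list of metadata (SDF property fields).
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds = empty_bonds(), provenance = "r",
                     meta = list()) {
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      hcount = as.integer(atoms$hcount),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                      order = as.integer(bonds$order))
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n))
      stop("bond refers to an invalid atom index")
    if (any(bonds$a1 == bonds$a2)) stop("self-bond not allowed")
    if (!all(bonds$order %in% 1:4)) stop("bond order must be 1, 2, 3 or 4")
    key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    if (anyDuplicated(key)) stop("duplicate bond between the same atoms")
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 provenance = provenance, meta = meta),
            class = "molecule")
}

empty_bonds <- function() data.frame(a1 = integer(0), a2 = integer(0),
                                     order = integer(0))

#' @exportS3Method base::print
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> %d atoms, %d bonds (%s)\n", x$id,
              nrow(x$atoms), nrow(x$bonds), x$provenance))
  invisible(x)
}

# neighbor table per atom: data.frame(atom, order)
adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  nbr <- rep(list(data.frame(atom = integer(0), order = integer(0))), n)
  b <- mol$bonds
  if (nrow(b)) {
    ends <- data.frame(from = c(b$a1, b$a2), atom = c(b$a2, b$a1),
                       order = c(b$order, b$order))
    sp <- split(ends[c("atom", "order")], ends$from)
    nbr[as.integer(names(sp))] <- sp
  }
  nbr
}

connected_components <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- integer(n)
  if (!n) return(comp)
  nbr <- adjacency_list(mol)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nx <- nbr[[a]]$atom
      nx <- nx[comp[nx] == 0L]
      comp[nx] <- cur
      queue <- c(queue, nx)
    }
  }
  comp
}

# a bond is in a ring iff its endpoints stay connected after removing it
bonds_in_ring <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(logical(0))
  nbr <- adjacency_list(mol)
  vapply(seq_len(nrow(b)), function(k) {
    src <- b$a1[k]; dst <- b$a2[k]
    seen <- rep(FALSE, nrow(mol$atoms))
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (t in seq_len(nrow(nbr[[a]]))) {
        nx <- nbr[[a]]$atom[t]
        if (a == src && nx == dst) next
        if (a == dst && nx == src) next
        if (!seen[nx]) { seen[nx] <- TRUE; queue <- c(queue, nx) }
      }
      if (seen[dst]) return(TRUE)
    }
    seen[dst]
  }, logical(1))
}

# all simple cycles with length <= maxlen, as vertex index vectors
simple_cycles <- function(mol, maxlen = 7L) {
  nbr <- adjacency_list(mol)
  n <- nrow(mol$atoms)
  found <- list()
  seen_keys <- character(0)
  path <- integer(0)
  walk <- function(start, a) {
    path <<- c(path, a)
    for (nx in nbr[[a]]$atom) {
      if (nx == start && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen_keys)) {
          seen_keys <<- c(seen_keys, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!(nx %in% path) && length(path) < maxlen && nx > start) {
        walk(start, nx)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) walk(s, s)
  found
}

bond_index_map <- function(mol) {
  if (!nrow(mol$bonds)) return(character(0))
  paste(pmin(mol$bonds$a1, mol$bonds$a2), pmax(mol$bonds$a1, mol$bonds$a2))
}

# Mark the bonds of simple aromatic rings with order 4: a ring qualifies if
# its bond orders alternate single/double around the cycle (benzene-like
# Kekule input) or are already all aromatic. Fused or exotic aromaticity is
# out of scope.
aromatize_simple_rings <- function(mol) {
  if (!nrow(mol$bonds)) return(mol)
  bmap <- bond_index_map(mol)
  for (cyc in simple_cycles(mol, maxlen = 7L)) {
    len <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    keys <- paste(pmin(cyc, nxt), pmax(cyc, nxt))
    bidx <- match(keys, bmap)
    if (anyNA(bidx)) next
    ords <- mol$bonds$order[bidx]
    alternating <- len %% 2 == 0 &&
      (all(ords == rep(c(1L, 2L), len / 2)) ||
         all(ords == rep(c(2L, 1L), len / 2)))
    if (all(ords == 4L) || alternating)
      mol$bonds$order[bidx] <- 4L
  }
  mol
}

# --- canonical atom ordering -------------------------------------------------
# Invariant refinement (iterated neighborhood hashing) followed by greedy
# individualization. Choices among refinement-tied atoms are resolved by
# comparing the resulting canonical strings, which depends only on graph
# structure, so the result is independent of atom input order for any
# molecule without unresolved hash collisions.

refine_codes <- function(mol, codes, nbr) {
  n <- length(codes)
  for (it in seq_len(max(n, 1L))) {
    new_codes <- vapply(seq_len(n), function(a) {
      nb <- nbr[[a]]
      if (!nrow(nb)) return(hash_tuple(codes[a]))
      env <- cbind(nb$order, codes[nb$atom])
      env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
      hash_tuple(c(codes[a], t(env)))
    }, numeric(1))
    # Morgan-style stop: the partition is stable once the class count
    # stops growing
    if (length(unique(new_codes)) == length(unique(codes)))
      return(new_codes)
    codes <- new_codes
  }
  codes
}

canonical_order <- function(mol) {
  n <- nrow(mol$atoms)
  if (n <= 1) return(seq_len(n))
  nbr <- adjacency_list(mol)
  base <- initial_atom_invariants(mol)

  order_from <- function(codes) order(codes, seq_along(codes))

  finish <- function(codes, depth) {
    codes <- refine_codes(mol, codes, nbr)
    if (!anyDuplicated(codes) || depth > n) return(order_from(codes))
    tied_code <- min(codes[duplicated(codes)])
    cand <- which(codes == tied_code)
    best <- NULL
    best_sig <- NULL
    for (a in cand) {
      trial <- codes
      trial[a] <- hash_tuple(c(trial[a], 1L))
      ord <- finish(trial, depth + 1L)
      sig <- signature_for_order(mol, ord)
      if (is.null(best_sig) || sig < best_sig) { best <- ord; best_sig <- sig }
    }
    best
  }
  finish(base, 1L)
}

signature_for_order <- function(mol, ord) {
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  at <- mol$atoms[ord, , drop = FALSE]
  arows <- sprintf("%s%+d H%d", at$element, at$charge, at$hcount)
  b <- mol$bonds
  if (nrow(b)) {
    r1 <- pmin(rank[b$a1], rank[b$a2])
    r2 <- pmax(rank[b$a1], rank[b$a2])
    o <- order(r1, r2)
    brows <- sprintf("%d-%d:%d", r1[o], r2[o], b$order[o])
  } else brows <- character(0)
  paste(c(arows, brows), collapse = ";")
}

#' Canonical signature string of a molecular graph
#'
#' Produces a deterministic text signature (atom rows followed by renumbered
#' bond rows under the canonical atom order) that is invariant to atom input
#' order. Used for tie-breaking between equal-size fragments and for
#' comparing molecules read from different formats.
#'
#' @param mol a [molecule].
#' @return A single string.
#' @export
canonical_signature <- function(mol) {
  signature_for_order(mol, canonical_order(mol))
}

#' Minimal structure normalization
#'
#' The preparation applied before fingerprinting: explicit hydrogens are
#' folded into the per-atom hydrogen count, only the largest connected
#' component (salt stripping) is kept, simple benzene-like rings are marked
#' aromatic, and atoms are renumbered canonically so that the output does
#' not depend on atom input order. This is a deliberately small
#' normalization: neutralization and tautomer canonicalization are not
#' attempted.
#'
#' When two components tie on heavy-atom count, the one with the
#' lexicographically smallest canonical signature is kept and the tie is
#' reported via [message()].
#'
#' @param mol a [molecule].
#' @return The normalized [molecule]. Idempotent.
#' @export
normalize_structure <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  if (n == 0) return(mol)

  # fold explicit hydrogens into neighbors
  is_h <- mol$atoms$element == "H" & mol$atoms$charge == 0L
  if (any(is_h) && !all(is_h)) {
    nbr <- adjacency_list(mol)
    hdeg <- vapply(seq_len(n), function(a) nrow(nbr[[a]]), integer(1))
    fold <- is_h & hdeg == 1L
    for (a in which(fold)) {
      parent <- nbr[[a]]$atom[1]
      if (!is_h[parent])
        mol$atoms$hcount[parent] <- mol$atoms$hcount[parent] + 1L
    }
    keep <- !fold
    remap <- cumsum(keep)
    b <- mol$bonds
    b <- b[keep[b$a1] & keep[b$a2], , drop = FALSE]
    b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
    mol <- molecule(mol$id, mol$atoms[keep, , drop = FALSE], b,
                    mol$provenance, mol$meta)
  }

  # keep the largest connected component
  comp <- connected_components(mol)
  if (max(comp) > 1) {
    sizes <- tabulate(comp)
    biggest <- which(sizes == max(sizes))
    if (length(biggest) > 1) {
      frags <- lapply(biggest, function(cc) extract_component(mol, comp, cc))
      sigs <- vapply(frags, canonical_signature, character(1))
      message(sprintf("molecule %s: %d equal-size fragments, keeping the %s",
                      mol$id, length(biggest),
                      "lexicographically smallest canonical form"))
      mol <- frags[[which(sigs == min(sigs))[1]]]
    } else {
      mol <- extract_component(mol, comp, biggest)
    }
  }

  mol <- aromatize_simple_rings(mol)

  ord <- canonical_order(mol)
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  b <- mol$bonds
  if (nrow(b)) {
    b1 <- pmin(rank[b$a1], rank[b$a2]); b2 <- pmax(rank[b$a1], rank[b$a2])
    o <- order(b1, b2)
    b <- data.frame(a1 = b1[o], a2 = b2[o], order = b$order[o])
  }
  molecule(mol$id, mol$atoms[ord, , drop = FALSE], b, mol$provenance, mol$meta)
}

extract_component <- function(mol, comp, cc) {
  keep <- comp == cc
  remap <- cumsum(keep)
  b <- mol$bonds[keep[mol$bonds$a1] & keep[mol$bonds$a2], , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  molecule(mol$id, mol$atoms[keep, , drop = FALSE], b, mol$provenance,
           mol$meta)
}
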