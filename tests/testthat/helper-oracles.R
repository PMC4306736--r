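# Shared fixtures and independent oracles. Oracles deliberately use the
# naive O(l^2) pair expansion or a generic QP solver (quadprog), never the
# package's fast paths, so each fast path is checked against a fully
# independent computation.

tocs <- function(M) {
  methods::as(methods::as(methods::as(M, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

random_sparse_cols <- function(d, l, density = 0.3, binary = TRUE) {
  M <- matrix(stats::rbinom(d * l, 1, density), d, l)
  if (!binary) M <- M * matrix(stats::runif(d * l, 0.5, 2), d, l)
  tocs(Matrix::Matrix(M, sparse = TRUE))
}

# brute-force pairwise ranking errors via explicit double loop
brute_rank_error <- function(pred, scores, weighted = FALSE) {
  num <- 0; den <- 0
  for (i in seq_along(scores)) for (j in seq_along(scores)) {
    if (scores[i] > scores[j]) {
      w <- if (weighted) scores[i] - scores[j] else 1
      loss <- if (pred[i] < pred[j]) 1 else if (pred[i] == pred[j]) 0.5 else 0
      num <- num + w * loss
      den <- den + w
    }
  }
  num / den
}

# brute-force normalized pairwise hinge loss and subgradient coefficients
brute_weighted_loss <- function(w, X, s, variant = "margin_rescaled") {
  f <- as.numeric(Matrix::crossprod(X, w))
  tot <- 0; W <- 0
  coef <- numeric(length(s))
  for (i in seq_along(s)) for (j in seq_along(s)) {
    if (s[i] > s[j]) {
      sdf <- s[i] - s[j]
      W <- W + sdf
      if (variant == "margin_rescaled") {
        h <- sdf - (f[i] - f[j])
        if (h > 0) { tot <- tot + h; coef[i] <- coef[i] - 1; coef[j] <- coef[j] + 1 }
      } else {
        h <- 1 - (f[i] - f[j])
        if (h > 0) {
          tot <- tot + sdf * h
          coef[i] <- coef[i] - sdf; coef[j] <- coef[j] + sdf
        }
      }
    }
  }
  list(loss = tot / W, coef = coef / W)
}

rank_primal_objective <- function(w, X, s, C, variant) {
  0.5 * sum(w^2) + C * brute_weighted_loss(w, X, s, variant)$loss
}

# Generic convex-QP solution of the fully expanded pairwise problem in its
# primal form: variables (w, xi_p), minimize 0.5||w||^2 + sum cap_p xi_p
# subject to xi_p >= 0 and xi_p >= mu_p - w'z_p. A vanishing ridge on the
# xi block makes the quadratic term positive definite for quadprog without
# measurably moving the optimum. Returns the exact primal objective of the
# recovered weight vector.
qp_rank_objective <- function(X, s, C, variant = "margin_rescaled") {
  Xd <- as.matrix(X)
  l <- ncol(Xd)
  d <- nrow(Xd)
  zl <- list(); mu <- c(); wt <- c()
  for (i in seq_len(l)) for (j in seq_len(l)) if (s[i] > s[j]) {
    zl[[length(zl) + 1]] <- Xd[, i] - Xd[, j]
    mu <- c(mu, if (variant == "margin_rescaled") s[i] - s[j] else 1)
    wt <- c(wt, s[i] - s[j])
  }
  Z <- do.call(cbind, zl)
  W <- sum(wt)
  cap <- if (variant == "margin_rescaled") rep(C / W, length(mu)) else
    C * wt / W
  P <- length(mu)
  D <- diag(c(rep(1, d), rep(1e-8, P)))
  dvec <- c(rep(0, d), -cap)
  # constraints: xi >= 0 and z_p'w + xi_p >= mu_p
  A <- cbind(rbind(matrix(0, d, P), diag(P)), rbind(Z, diag(P)))
  b0 <- c(rep(0, P), mu)
  sol <- quadprog::solve.QP(D, dvec, A, b0)
  w <- sol$solution[seq_len(d)]
  rank_primal_objective(w, X, s, C, variant)
}

qp_svc_objective <- function(X, y, C) {
  Xd <- as.matrix(X)
  l <- ncol(Xd)
  Z <- sweep(Xd, 2, y, "*")
  H <- crossprod(Z)
  H <- H + diag(1e-6 * max(diag(H)), l)
  A <- cbind(diag(l), -diag(l))
  sol <- quadprog::solve.QP(H, rep(1, l), A, c(rep(0, l), rep(-C, l)))
  w <- as.numeric(Z %*% sol$solution)
  f <- as.numeric(crossprod(Xd, w))
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * f))
}

cs_primal_objective <- function(W, X, y0, C) {
  K <- ncol(W)
  f <- as.matrix(Matrix::crossprod(X, W))
  xi <- vapply(seq_len(ncol(X)), function(i)
    max(f[i, ] + ifelse(seq_len(K) == y0[i] + 1, 0, 1)) - f[i, y0[i] + 1],
    numeric(1))
  0.5 * sum(W^2) + C * sum(xi)
}

# Crammer-Singer dual as an equality+box constrained QP via quadprog
qp_mcsvm_objective <- function(X, y0, K, C) {
  Xd <- as.matrix(X)
  l <- ncol(Xd)
  G <- crossprod(Xd)
  H <- matrix(0, l * K, l * K)
  for (k in seq_len(K)) {
    idx <- (k - 1) * l + seq_len(l)
    H[idx, idx] <- G
  }
  H <- H + diag(1e-6 * max(diag(H)), l * K)
  e <- as.numeric(vapply(seq_len(K), function(k)
    ifelse(y0 == k - 1, 0, 1), numeric(l)))
  Aeq <- matrix(0, l, l * K)
  for (i in seq_len(l)) for (k in seq_len(K)) Aeq[i, (k - 1) * l + i] <- 1
  A <- rbind(Aeq, -diag(l * K))
  caps <- as.numeric(vapply(seq_len(K), function(k)
    ifelse(y0 == k - 1, C, 0), numeric(l)))
  sol <- quadprog::solve.QP(H, -e, t(A), c(rep(0, l), -caps), meq = l)
  tau <- matrix(sol$solution, l, K)
  Wm <- Xd %*% tau
  cs_primal_objective(Wm, tocs(Matrix::Matrix(Xd, sparse = TRUE)), y0, C)
}

dense_w <- function(model) {
  w <- numeric(model$dim)
  w[model$w_index] <- model$w_value
  w
}

# tiny molecule fixtures built in code
smiles_fixture <- function(lines) {
  path <- tempfile(fileext = ".smi")
  writeLines(lines, path)
  path
}

# a small, valid single-record V2000 SDF (methane) written in code
methane_sdf_text <- function(id = "methane") {
  c(id,
    "  multirank",
    "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END",
    "> <origin>",
    "fixture",
    "",
    "$$$$")
}

# permute the atoms of a molecule (relabeling its bonds accordingly)
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  molecule(mol$id, mol$atoms[perm, , drop = FALSE],
           data.frame(a1 = inv[b$a1], a2 = inv[b$a2], order = b$order),
           mol$provenance, mol$meta)
}

default_scheme_t1 <- function() build_scheme(3, 1)
default_scheme_t2 <- function() build_scheme(3, c(1, 2))
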