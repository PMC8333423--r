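# deterministic start block without touching the caller's RNG stream
seeded_matrix <- function(n, p, seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  matrix(stats::rnorm(n * p), n, p)
}

#' Mass-normalize a vector
#'
#' Scales `v` so that `v' M v = 1` (the mass norm), with the sign convention
#' that the largest-magnitude entry is positive.
#'
#' @param v numeric vector (nonzero).
#' @param M mass matrix (sparse or dense), positive definite on the span.
#' @return the normalized vector.
#' @export
mass_normalize <- function(v, M) {
  v <- as.numeric(v)
  q <- as.numeric(t(v) %*% (M %*% v))
  if (!is.finite(q) || q <= 0) stop("cannot mass-normalize a zero vector")
  v <- v / sqrt(q)
  imax <- which.max(abs(v))
  if (v[imax] < 0) v <- -v
  v
}

#' Analytic rigid-body basis
#'
#' The six zero-strain motions of an unconstrained 3D body: three unit
#' translations and three linearized rotations about the node centroid,
#' M-orthonormalized (modified Gram-Schmidt in the M inner product,
#' translations first). Columns are full-DOF vectors.
#'
#' @param mesh a `tet_mesh`.
#' @param M full mass matrix (for the M-orthonormalization).
#' @return n_dofs x 6 matrix, M-orthonormal columns.
#' @export
rigid_body_basis <- function(mesh, M) {
  n <- nrow(mesh$nodes)
  ctr <- colMeans(mesh$nodes)
  X <- mesh$nodes[, 1] - ctr[1]
  Y <- mesh$nodes[, 2] - ctr[2]
  Z <- mesh$nodes[, 3] - ctr[3]
  zero <- numeric(n); one <- rep(1, n)
  interleave <- function(a, b, c) as.vector(rbind(a, b, c))
  R <- cbind(
    interleave(one, zero, zero),
    interleave(zero, one, zero),
    interleave(zero, zero, one),
    interleave(zero, -Z, Y),    # rotation about x
    interleave(Z, zero, -X),    # rotation about y
    interleave(-Y, X, zero))    # rotation about z
  for (j in 1:6) {
    v <- R[, j]
    if (j > 1) {
      prev <- R[, 1:(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, as.numeric(M %*% v))
    }
    R[, j] <- v / sqrt(as.numeric(t(v) %*% (M %*% v)))
  }
  R
}

# M-orthonormalize columns of X (dropping near-dependent directions),
# via the eigendecomposition of the small Gram matrix
m_orthonormalize <- function(X, M, drop_tol = 1e-12) {
  G <- crossprod(X, as.matrix(M %*% X))
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > drop_tol * max(eg$values)
  X %*% (eg$vectors[, keep, drop = FALSE] %*%
           diag(1 / sqrt(eg$values[keep]), sum(keep)))
}

#' Solve for the smallest deformable eigenpairs
#'
#' Computes the `n` smallest eigenpairs of the generalized problem
#' `K u = lambda M u` on the system's free DOFs by shift-invert block
#' subspace iteration with Rayleigh-Ritz extraction: the block is repeatedly
#' multiplied by `(K + sigma M)^{-1} M` (one sparse Cholesky factorization,
#' reused), M-orthonormalized, and rotated to Ritz vectors until every
#' requested pair satisfies `||K u - lambda M u|| <= tol * ||K u||`.
#'
#' For an unconstrained (FEMP-II) system the six analytic rigid-body
#' motions are deflated: the iteration block is kept M-orthogonal to the
#' rigid space every iteration, a small mass-proportional shift makes the
#' factorization definite, and the returned pairs are the smallest
#' deformable ones with `rigid_count = 6`. A returned "deformable" pair
#' with essentially zero strain energy signals a mechanism or disconnected
#' mesh and raises an error.
#'
#' Eigenvectors are returned back-expanded to full DOF numbering,
#' mass-normalized, M-orthogonal, sign-fixed (largest-magnitude entry
#' positive), with eigenvalues ascending. Deterministic for a given seed.
#'
#' @param system an `fe_system`.
#' @param n number of deformable eigenpairs requested (default 10).
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter maximum subspace iterations (default 500).
#' @param seed seed for the random start block (default 0).
#' @param block_extra extra block vectors beyond `n` to speed convergence.
#' @return object of class `eigen_pairs`: `lambdas` (rad^2/s^2, ascending),
#'   `vectors` (full-DOF columns, 1/sqrt(tonne)), `rigid_count`,
#'   `residuals`, `n_requested`, `solver_tol`, `seed`, `iterations`.
#' @export
solve_smallest_eigenpairs <- function(system, n = 10, tol = 1e-8,
                                      max_iter = 500, seed = 0,
                                      block_extra = max(8L, ceiling(n / 2))) {
  K <- system$K_red
  M <- system$M_red
  nf <- system$n_dofs_free
  free <- !length(system$constrained_dofs)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  rigid_dim <- if (free) 6L else 0L
  if (n + rigid_dim > nf)
    stop("requested ", n, " deformable pairs but the system has only ",
         nf - rigid_dim, " deformable DOFs")

  R <- NULL
  if (free) {
    Rfull <- rigid_body_basis(system$mesh, system$M)
    R <- Rfull[system$free_dofs, , drop = FALSE]
    # rigid motions must be strain-free; otherwise constraints are active
    kr <- max(apply(as.matrix(K %*% R), 2, function(x) sqrt(sum(x^2))))
    if (kr > 1e-6 * max(abs(K@x)))
      stop("analytic rigid modes are not in the stiffness null space; ",
           "is the system really unconstrained?")
  }
  deflate <- function(X) {
    if (is.null(R)) return(X)
    X - R %*% crossprod(R, as.matrix(M %*% X))
  }

  scale_ratio <- sum(Matrix::diag(K)) / sum(Matrix::diag(M))
  sigma <- if (free) 1e-8 * scale_ratio else 0
  A <- if (sigma > 0) K + sigma * M else K
  F <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
                error = function(e) NULL)
  if (is.null(F)) {
    # constrained system that is still semi-definite (partial constraints):
    # fall back to a small mass shift
    sigma <- 1e-8 * scale_ratio
    A <- K + sigma * M
    F <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  }

  p <- min(n + as.integer(block_extra), nf - rigid_dim)
  X <- deflate(seeded_matrix(nf, p, seed))
  X <- m_orthonormalize(X, M)
  lam <- rep(NA_real_, p)
  res <- rep(Inf, n)
  it <- 0L
  repeat {
    it <- it + 1L
    Y <- as.matrix(Matrix::solve(F, as.matrix(M %*% X), system = "A"))
    Y <- deflate(Y)
    Y <- m_orthonormalize(Y, M)
    if (ncol(Y) < p) {
      # rank loss: top up with fresh deflated random directions
      extra <- deflate(seeded_matrix(nf, p - ncol(Y), seed + it))
      Y <- m_orthonormalize(cbind(Y, extra), M)
    }
    Asm <- crossprod(Y, as.matrix(K %*% Y))
    Asm <- (Asm + t(Asm)) / 2
    eg <- eigen(Asm, symmetric = TRUE)
    ord <- order(eg$values)
    Z <- eg$vectors[, ord, drop = FALSE]
    lam <- eg$values[ord]
    X <- Y %*% Z
    if (free && lam[1] <= 1e-10 * scale_ratio)
      stop("near-zero deformable eigenvalue after rigid deflation: ",
           "mechanism or disconnected mesh")
    KX <- as.matrix(K %*% X[, 1:n, drop = FALSE])
    MX <- as.matrix(M %*% X[, 1:n, drop = FALSE])
    res <- vapply(1:n, function(i) {
      r <- KX[, i] - lam[i] * MX[, i]
      sqrt(sum(r^2)) / max(sqrt(sum(KX[, i]^2)), .Machine$double.xmin)
    }, numeric(1))
    if (all(res <= tol) || it >= max_iter) break
  }
  if (any(res > tol))
    stop("eigensolver did not converge in ", max_iter,
         " iterations; worst relative residual ",
         format(max(res), digits = 3))

  if (free && lam[1] <= 1e-10 * scale_ratio)
    stop("near-zero deformable eigenvalue after rigid deflation: ",
         "mechanism or disconnected mesh")

  vecs <- matrix(0, system$n_dofs_full, n)
  for (i in 1:n) {
    v <- expand_full(system, X[, i])
    vecs[, i] <- mass_normalize(v, system$M)
  }
  structure(
    list(lambdas = lam[1:n], vectors = vecs, rigid_count = rigid_dim,
         residuals = res, n_requested = n, solver_tol = tol, seed = seed,
         iterations = it, sigma = sigma, bc_mode = system$bc$mode),
    class = "eigen_pairs")
}

#' @export
print.eigen_pairs <- function(x, ...) {
  cat("eigen_pairs:", length(x$lambdas), "deformable pairs,",
      x$rigid_count, "rigid modes removed (", x$bc_mode, ")\n")
  cat("  lambda [rad^2/s^2]:",
      paste(format(x$lambdas, digits = 5), collapse = ", "), "\n")
  cat("  f [Hz]:",
      paste(format(sqrt(pmax(x$lambdas, 0)) / (2 * pi), digits = 5),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify rigid-body modes
#'
#' Tags each eigenpair of a free system as rigid or deformable. A mode is
#' a rigid *candidate* when its strain energy is essentially zero
#' (`lambda <= strain_tol * scale`, with `scale = tr(K)/tr(M)` a
#' Rayleigh-quotient upper bound); a candidate is *globally rigid* when the
#' M-norm of its projection onto the 6-dimensional analytic rigid space
#' exceeds `proj_tol` (scale-free criterion). Strain-free candidates
#' outside the global rigid space indicate a mechanism or disconnected
#' mesh and raise an error, as does any count above six.
#'
#' @param pairs an `eigen_pairs` (typically from a dense solve of a free
#'   system, rigid modes included).
#' @param system the `fe_system` the pairs belong to (provides `M`, mesh).
#' @param proj_tol rigid projection threshold (default 0.99).
#' @param strain_tol relative strain-energy threshold for rigid candidates
#'   (default 1e-7).
#' @return the `eigen_pairs` with rigid modes removed from
#'   `lambdas`/`vectors`, `rigid_count` set, a `rigid_info` data frame
#'   (`index`, `projection`, `subtype` = `"translation"`/`"rotation"`, the
#'   subtype by dominant projection — heuristic when the zero eigenvalue is
#'   degenerate), and `translation_dim`/`rotation_dim`: the exact split of
#'   the removed subspace into translational and rotational content (3 + 3
#'   for a connected free body, regardless of how individual vectors mix).
#' @export
classify_rigid_modes <- function(pairs, system, proj_tol = 0.99,
                                 strain_tol = 1e-7) {
  M <- system$M
  K <- system$K
  R <- rigid_body_basis(system$mesh, M)
  scale <- sum(Matrix::diag(K)) / sum(Matrix::diag(M))
  nmodes <- length(pairs$lambdas)
  proj <- numeric(nmodes)
  subtype <- character(nmodes)
  candidate <- logical(nmodes)
  for (i in seq_len(nmodes)) {
    v <- mass_normalize(pairs$vectors[, i], M)
    c6 <- crossprod(R, as.numeric(M %*% v))
    proj[i] <- sqrt(sum(c6^2))
    subtype[i] <- if (sum(c6[1:3]^2) >= sum(c6[4:6]^2)) "translation" else "rotation"
    candidate[i] <- pairs$lambdas[i] <= strain_tol * scale
  }
  # translational/rotational content: squared projections onto the
  # translation block (columns 1-3 of R span exactly the translations).
  # Individual zero-eigenvalue vectors mix freely inside the rigid
  # eigenspace, so per-mode subtype labels are heuristic; the summed
  # squared projections recover the 3 + 3 subspace split exactly.
  trans_sq <- numeric(nmodes)
  for (i in seq_len(nmodes)) {
    v <- mass_normalize(pairs$vectors[, i], M)
    trans_sq[i] <- sum(crossprod(R[, 1:3], as.numeric(M %*% v))^2)
  }
  rigid <- candidate & proj > proj_tol
  stray <- candidate & !rigid
  if (any(stray))
    stop("strain-free mode(s) outside the 6-dimensional rigid space ",
         "(indices ", paste(which(stray), collapse = ", "), "): ",
         "mechanism or disconnected mesh")
  if (sum(rigid) > 6L)
    stop("more than 6 rigid modes classified: mechanism or disconnected mesh")
  keep <- !rigid
  pairs$rigid_info <- data.frame(index = which(rigid),
                                 projection = proj[rigid],
                                 subtype = subtype[rigid])
  pairs$translation_dim <- sum(trans_sq[rigid])
  pairs$rotation_dim <- sum(proj[rigid]^2 - trans_sq[rigid])
  pairs$rigid_count <- sum(rigid)
  pairs$lambdas <- pairs$lambdas[keep]
  pairs$vectors <- pairs$vectors[, keep, drop = FALSE]
  pairs$residuals <- pairs$residuals[keep]
  pairs
}

#' Mesh-convergence check on eigenvalues
#'
#' Passes when every compared eigenvalue changes by at most `tol`
#' (relative to the fine value) between two mesh resolutions. By default
#' the first five deformable eigenvalues are compared.
#'
#' @param lambdas_coarse,lambdas_fine ascending eigenvalue vectors of the
#'   same model on a coarse and a fine mesh.
#' @param tol maximum allowed relative change (default 0.05).
#' @param n_compare how many leading eigenvalues to compare (default 5,
#'   capped at the common length).
#' @return list with `pass`, `rel_change` (per compared mode), and
#'   `failed_modes`.
#' @export
convergence_check <- function(lambdas_coarse, lambdas_fine, tol = 0.05,
                              n_compare = 5) {
  if (length(lambdas_coarse) != length(lambdas_fine))
    stop("eigenvalue lists have different lengths")
  n_compare <- min(n_compare, length(lambdas_fine))
  lc <- lambdas_coarse[seq_len(n_compare)]
  lf <- lambdas_fine[seq_len(n_compare)]
  if (any(lf <= 0)) stop("nonpositive fine-mesh eigenvalue")
  rel <- abs(lf - lc) / lf
  list(pass = all(rel <= tol), rel_change = rel,
       failed_modes = which(rel > tol))
}
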