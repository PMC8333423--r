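# Independent numerical oracles for the FE / spectral pipeline.
# These deliberately avoid the package's sparse assembly and iterative
# eigensolver paths: dense scatter-add, base-R eigen via Cholesky
# reduction, and closed-form beam theory.

# dense generalized symmetric eigensolver: M = R'R, standard problem on
# R^{-T} K R^{-1}; eigenvectors come out M-orthonormal
dense_geig <- function(K, M) {
  K <- as.matrix(K)
  M <- as.matrix(M)
  R <- chol(M)
  C <- t(solve(t(R), t(solve(t(R), K))))
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ord <- order(eg$values)
  list(values = eg$values[ord],
       vectors = backsolve(R, eg$vectors[, ord, drop = FALSE]))
}

# brute-force dense assembly: per-element 12x12 blocks scatter-added into
# dense global matrices with explicit double loops
dense_assemble <- function(mesh, material) {
  n_dofs <- 3L * nrow(mesh$nodes)
  K <- matrix(0, n_dofs, n_dofs)
  M <- matrix(0, n_dofs, n_dofs)
  for (e in seq_len(nrow(mesh$tets))) {
    conn <- mesh$tets[e, ]
    coords <- mesh$nodes[conn, , drop = FALSE]
    C <- elasticity_matrix(material$E[e], material$nu)
    Ke <- element_stiffness(coords, C)
    Me <- element_mass(coords, material$rho_eff[e] * 1e-9)
    edofs <- node_dofs(conn)
    for (a in 1:12) for (b in 1:12) {
      K[edofs[a], edofs[b]] <- K[edofs[a], edofs[b]] + Ke[a, b]
      M[edofs[a], edofs[b]] <- M[edofs[a], edofs[b]] + Me[a, b]
    }
  }
  list(K = K, M = M)
}

# Euler-Bernoulli tip stiffness of a cantilever with rectangular section
# (bending about the axis perpendicular to the load, load along height h)
beam_tip_stiffness <- function(E, L, b, h) 3 * E * (b * h^3 / 12) / L^3

# wrap dense-oracle eigenpairs (already M-orthonormal, full DOFs assumed)
# in the package's eigen_pairs shape for classify/metrics interop
as_eigen_pairs <- function(values, vectors, rigid_count = 0L) {
  structure(list(lambdas = values, vectors = vectors,
                 rigid_count = rigid_count,
                 residuals = rep(0, length(values)),
                 n_requested = length(values), solver_tol = 0, seed = NA,
                 bc_mode = NA_character_),
            class = "eigen_pairs")
}
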