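#' Isotropic elasticity matrix (Voigt, engineering strain)
#'
#' 6x6 material stiffness in the Voigt convention with engineering shear
#' strains, component order (xx, yy, zz, yz, xz, xy):
#' Lame form, `lambda * I (x) I + 2 mu` on symmetric tensors.
#'
#' @param E Young's modulus (MPa), > 0.
#' @param nu Poisson ratio, 0 <= nu < 0.5.
#' @return symmetric positive definite 6x6 matrix (MPa).
#' @export
elasticity_matrix <- function(E, nu) {
  if (!is.finite(E) || E <= 0) stop("Young's modulus must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson ratio must satisfy 0 <= nu < 0.5")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# Constant shape-function gradients of a P1 tet: 4x3 matrix G with row i =
# grad of barycentric coordinate L_i; plus the (signed) volume.
tet_gradients <- function(coords) {
  A <- cbind(1, coords)            # 4x4, rows = nodes
  V <- det(A) / 6
  if (!is.finite(V) || abs(V) < .Machine$double.eps)
    stop("degenerate tetrahedron (zero volume)")
  G <- t(solve(A)[2:4, , drop = FALSE])  # 4x3
  list(G = G, V = V)
}

# 6x12 strain-displacement matrix from P1 gradients (engineering shear),
# DOF order (n1x, n1y, n1z, n2x, ...), strain order (xx,yy,zz,yz,xz,xy)
strain_displacement <- function(G) {
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    gx <- G[a, 1]; gy <- G[a, 2]; gz <- G[a, 3]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- gx
    B[2, c0 + 2] <- gy
    B[3, c0 + 3] <- gz
    B[4, c0 + 2] <- gz; B[4, c0 + 3] <- gy   # gamma_yz
    B[5, c0 + 1] <- gz; B[5, c0 + 3] <- gx   # gamma_xz
    B[6, c0 + 1] <- gy; B[6, c0 + 2] <- gx   # gamma_xy
  }
  B
}

#' P1 tetrahedral element stiffness matrix
#'
#' One-point integration, exact for the constant-strain linear tetrahedron:
#' `Ke = V * B' C B`. Symmetric positive semidefinite of rank 6 (12 DOFs
#' minus 6 rigid motions).
#'
#' @param coords 4x3 matrix of node coordinates (mm), positive orientation.
#' @param C 6x6 elasticity matrix from [elasticity_matrix()].
#' @return 12x12 symmetric matrix (N/mm).
#' @export
element_stiffness <- function(coords, C) {
  g <- tet_gradients(coords)
  if (g$V <= 0) stop("negatively oriented or degenerate tetrahedron")
  B <- strain_displacement(g$G)
  Ke <- g$V * crossprod(B, C %*% B)
  (Ke + t(Ke)) / 2
}

#' P1 tetrahedral consistent mass matrix
#'
#' Closed-form consistent mass of the linear tetrahedron: per scalar
#' component `rho V / 20 * (2 on the diagonal, 1 off-diagonal)`,
#' block-repeated for the x, y, z axes.
#'
#' @param coords 4x3 matrix of node coordinates (mm).
#' @param rho mass density in tonne/mm^3, >= 0.
#' @return 12x12 symmetric matrix (tonne).
#' @export
element_mass <- function(coords, rho) {
  if (rho < 0) stop("negative density")
  g <- tet_gradients(coords)
  if (g$V <= 0) stop("negatively oriented or degenerate tetrahedron")
  Ms <- matrix(1, 4, 4)
  diag(Ms) <- 2
  Ms <- rho * g$V / 20 * Ms
  Me <- matrix(0, 12, 12)
  for (d in 1:3) {
    idx <- seq(d, 12, by = 3)
    Me[idx, idx] <- Ms
  }
  Me
}

#' Boundary condition specification
#'
#' `mode = "FEMP-I"` fixes the listed nodes (homogeneous zero displacement);
#' `mode = "FEMP-II"` is the fully free model with no kinematic constraints
#' (the fixed set must be empty). `fixed_sets` may name node sets stored on
#' the mesh; they are resolved and unioned with `fixed_nodes` at assembly.
#'
#' @param mode `"FEMP-I"` or `"FEMP-II"`.
#' @param fixed_nodes integer vector of 1-based node indices (FEMP-I).
#' @param fixed_sets character vector of mesh node-set names (FEMP-I).
#' @return object of class `bc_spec`.
#' @export
bc_spec <- function(mode = c("FEMP-I", "FEMP-II"), fixed_nodes = integer(0),
                    fixed_sets = character(0)) {
  mode <- match.arg(mode)
  fixed_nodes <- as.integer(fixed_nodes)
  if (mode == "FEMP-II" && (length(fixed_nodes) || length(fixed_sets)))
    stop("FEMP-II is the free model: no fixed nodes allowed")
  structure(list(mode = mode, fixed_nodes = fixed_nodes,
                 fixed_sets = as.character(fixed_sets)),
            class = "bc_spec")
}

resolve_fixed_nodes <- function(mesh, bc) {
  fixed <- bc$fixed_nodes
  for (nm in bc$fixed_sets) {
    s <- mesh$node_sets[[nm]]
    if (is.null(s)) stop("mesh has no node set '", nm, "'")
    fixed <- c(fixed, s)
  }
  fixed <- sort(unique(as.integer(fixed)))
  if (length(fixed) && (min(fixed) < 1L || max(fixed) > nrow(mesh$nodes)))
    stop("fixed node index out of range")
  fixed
}

#' DOF indices of a node
#'
#' Nodes carry 3 consecutive DOFs in (x, y, z) order: node `i` owns DOFs
#' `3i-2, 3i-1, 3i`.
#'
#' @param nodes integer node indices (1-based).
#' @return integer DOF indices.
#' @export
node_dofs <- function(nodes) {
  as.vector(t(cbind(3L * nodes - 2L, 3L * nodes - 1L, 3L * nodes)))
}

#' Assemble the global stiffness and mass matrices
#'
#' Scatter-adds P1 element stiffness and consistent mass matrices into
#' sparse symmetric global `K` (N/mm) and `M` (tonne). Material densities
#' are given in g/cm^3 and converted once to tonne/mm^3, so the consistent
#' unit system is mm-N-MPa-tonne-s: generalized eigenvalues come out in
#' rad^2/s^2 and stiffnesses in N/mm. Dirichlet constraints (FEMP-I) are
#' recorded and the reduced operators built by DOF elimination (see
#' [apply_dirichlet()]); for FEMP-II nothing is constrained.
#'
#' @param mesh a `tet_mesh`.
#' @param material a `material_field` with one entry per element.
#' @param bc a `bc_spec`; default free (FEMP-II).
#' @return object of class `fe_system` with full `K`, `M`, reduced
#'   `K_red`, `M_red`, `free_dofs`, `constrained_dofs`, `n_dofs_full`,
#'   `n_dofs_free`, and the originating mesh.
#' @export
assemble <- function(mesh, material, bc = bc_spec("FEMP-II")) {
  ne <- nrow(mesh$tets)
  if (length(material$E) != ne)
    stop("material has ", length(material$E), " entries for ", ne, " elements")
  n_nodes <- nrow(mesh$nodes)
  n_dofs <- 3L * n_nodes

  ii <- integer(144L * ne); jj <- integer(144L * ne)
  kk <- numeric(144L * ne); mm <- numeric(144L * ne)
  Ms0 <- matrix(1, 4, 4); diag(Ms0) <- 2
  Me_pattern <- matrix(0, 12, 12)
  for (d in 1:3) {
    idx <- seq(d, 12, by = 3)
    Me_pattern[idx, idx] <- Ms0 / 20
  }
  pos <- 0L
  for (e in seq_len(ne)) {
    conn <- mesh$tets[e, ]
    coords <- mesh$nodes[conn, , drop = FALSE]
    g <- tet_gradients(coords)
    B <- strain_displacement(g$G)
    C <- elasticity_matrix(material$E[e], material$nu)
    Ke <- g$V * crossprod(B, C %*% B)
    rho <- material$rho_eff[e] * GCM3_TO_TONNE_MM3
    Me <- rho * g$V * Me_pattern
    edofs <- node_dofs(conn)
    sl <- pos + 1:144
    ii[sl] <- rep(edofs, times = 12)
    jj[sl] <- rep(edofs, each = 12)
    kk[sl] <- as.vector(Ke)
    mm[sl] <- as.vector(Me)
    pos <- pos + 144L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(n_dofs, n_dofs))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(n_dofs, n_dofs))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)

  fixed <- resolve_fixed_nodes(mesh, bc)
  sys <- structure(
    list(K = K, M = M, mesh = mesh, bc = bc,
         n_nodes = n_nodes, n_dofs_full = n_dofs,
         constrained_dofs = integer(0), free_dofs = seq_len(n_dofs),
         n_dofs_free = n_dofs, K_red = K, M_red = M,
         total_mass = sum(material$rho_eff * GCM3_TO_TONNE_MM3 * tet_volumes(mesh))),
    class = "fe_system")
  if (length(fixed)) sys <- apply_dirichlet(sys, fixed)
  sys
}

#' @export
print.fe_system <- function(x, ...) {
  cat("fe_system:", x$n_nodes, "nodes,", x$n_dofs_full, "DOFs,",
      length(x$constrained_dofs), "constrained (", x$bc$mode, ")\n")
  cat(sprintf("  total mass %.6g tonne\n", x$total_mass))
  invisible(x)
}

#' Apply homogeneous Dirichlet constraints by DOF elimination
#'
#' Removes the rows and columns of the fixed nodes' DOFs from both `K` and
#' `M`. Elimination is spectrum-equivalent to the constrained eigenproblem
#' (unlike zeroing rows/columns with a unit diagonal in `K` only, which
#' plants spurious `1/M_ii` eigenvalues inside the spectrum). The
#' `free_dofs` map back-expands reduced vectors to full-mesh DOF numbering
#' with zeros at constrained DOFs, so downstream node indexing always
#' refers to the full mesh.
#'
#' @param system an `fe_system`.
#' @param fixed_nodes integer vector of node indices to fix (all 3 DOFs).
#' @return the `fe_system` with updated `K_red`, `M_red`, `free_dofs`,
#'   `constrained_dofs`, `n_dofs_free`.
#' @export
apply_dirichlet <- function(system, fixed_nodes) {
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  if (!length(fixed_nodes)) return(system)
  if (min(fixed_nodes) < 1L || max(fixed_nodes) > system$n_nodes)
    stop("fixed node index out of range")
  cdofs <- sort(unique(c(system$constrained_dofs, node_dofs(fixed_nodes))))
  if (length(cdofs) >= system$n_dofs_full)
    stop("all DOFs constrained: nothing left to solve")
  free <- setdiff(seq_len(system$n_dofs_full), cdofs)
  system$constrained_dofs <- cdofs
  system$free_dofs <- free
  system$n_dofs_free <- length(free)
  system$K_red <- system$K[free, free, drop = FALSE]
  system$M_red <- system$M[free, free, drop = FALSE]
  system
}

#' Back-expand a reduced vector to full DOF numbering
#'
#' @param system an `fe_system`.
#' @param v numeric vector (or matrix, columns = vectors) of length
#'   `n_dofs_free`.
#' @return vector/matrix of length `n_dofs_full` with zeros at constrained
#'   DOFs.
#' @export
expand_full <- function(system, v) {
  if (is.matrix(v) || inherits(v, "Matrix")) {
    out <- matrix(0, system$n_dofs_full, ncol(v))
    out[system$free_dofs, ] <- as.matrix(v)
  } else {
    out <- numeric(system$n_dofs_full)
    out[system$free_dofs] <- as.numeric(v)
  }
  out
}

#' Direct static solve at a point load
#'
#' Solves `K u = F` on the constrained system for a point force of given
#' magnitude at one node along a direction, and reports the direct static
#' stiffness `S_direct = magnitude / (u(k) . direction)` in N/mm. This is
#' the sparse-oracle counterpart of the modal-superposition stiffness.
#'
#' @param system a constrained (`FEMP-I`) `fe_system`.
#' @param node 1-based node index of the load point (must be unconstrained).
#' @param direction length-3 load direction (normalized internally).
#' @param magnitude force magnitude in N (default 1).
#' @return list with `u` (full-DOF displacement, mm), `deflection`
#'   (u(k).direction, mm), and `stiffness_direct` (N/mm).
#' @export
static_solve <- function(system, node, direction, magnitude = 1) {
  if (!length(system$constrained_dofs))
    stop("static solve is ill-posed for FEMP-II (free system): ",
         "the stiffness matrix is singular")
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero load direction")
  direction <- direction / nrm
  dofs <- node_dofs(node)
  if (any(dofs %in% system$constrained_dofs))
    stop("load node ", node, " is constrained")
  f <- numeric(system$n_dofs_full)
  f[dofs] <- magnitude * direction
  u_red <- Matrix::solve(system$K_red, f[system$free_dofs])
  u <- expand_full(system, u_red)
  defl <- sum(u[dofs] * direction)
  list(u = u, deflection = defl, stiffness_direct = magnitude / defl)
}

#' Direct pointwise compliance at a node
#'
#' Solves three unit point loads along the coordinate axes at one node and
#' returns the 3x3 nodal receptance block `H(k,k)` of `K^{-1}`, its trace
#' (the pointwise compliance that the full modal-superposition sum of
#' squared nodal norms reproduces exactly), and the directional compliance
#' along an optional direction.
#'
#' @param system a constrained `fe_system`.
#' @param node 1-based node index.
#' @param direction optional length-3 direction for a directional
#'   compliance `d' H d`.
#' @return list with `H` (3x3, mm/N), `trace_compliance` (mm/N),
#'   `stiffness_trace` (N/mm), and if `direction` given
#'   `directional_compliance` and `stiffness_directional`.
#' @export
static_compliance <- function(system, node, direction = NULL) {
  if (!length(system$constrained_dofs))
    stop("static solve is ill-posed for FEMP-II (free system)")
  dofs <- node_dofs(node)
  if (any(dofs %in% system$constrained_dofs))
    stop("node ", node, " is constrained")
  Fm <- matrix(0, system$n_dofs_full, 3)
  for (d in 1:3) Fm[dofs[d], d] <- 1
  U <- as.matrix(Matrix::solve(system$K_red, Fm[system$free_dofs, , drop = FALSE]))
  Uf <- expand_full(system, U)
  H <- Uf[dofs, , drop = FALSE]
  H <- (H + t(H)) / 2
  out <- list(H = H, trace_compliance = sum(diag(H)),
              stiffness_trace = 1 / sum(diag(H)))
  if (!is.null(direction)) {
    d <- direction / sqrt(sum(direction^2))
    out$directional_compliance <- as.numeric(t(d) %*% H %*% d)
    out$stiffness_directional <- 1 / out$directional_compliance
  }
  out
}
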