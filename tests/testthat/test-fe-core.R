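test_that("elasticity matrix matches the Lame closed form", {
  expect_equal(elasticity_matrix(1, 0), diag(c(1, 1, 1, 0.5, 0.5, 0.5)))
  C <- elasticity_matrix(2389, 0.3)
  expect_equal(C, t(C))
  expect_equal(C[1, 1], 2389 * (1 - 0.3) / ((1 + 0.3) * (1 - 2 * 0.3)))
  expect_equal(C[1, 1], 3215.9, tolerance = 1e-4)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(elasticity_matrix(2389, 0.5), "nu")
  expect_error(elasticity_matrix(-1, 0.3), "positive")
})

test_that("element stiffness annihilates rigid motions and has rank 6", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Ke <- element_stiffness(coords, elasticity_matrix(1000, 0.3))
  expect_equal(Ke, t(Ke))
  for (ax in 1:3) {
    tr <- numeric(12); tr[seq(ax, 12, by = 3)] <- 1
    expect_lt(max(abs(Ke %*% tr)), 1e-10 * max(abs(Ke)))
  }
  # linearized rotation about the centroid of the tet
  ctr <- colMeans(coords)
  rel <- sweep(coords, 2, ctr)
  rot <- as.vector(t(cbind(-rel[, 2], rel[, 1], 0)))  # about z
  expect_lt(max(abs(Ke %*% rot)), 1e-10 * max(abs(Ke)))
  expect_equal(qr(Ke)$rank, 6)
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))  # PSD
  expect_error(element_stiffness(rbind(coords[1:3, ], coords[1, ]),
                                 elasticity_matrix(1, 0.3)), "degenerate")
})

test_that("consistent mass matches the rho*V/20 pattern and conserves mass", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rho <- 2.5e-9
  Me <- element_mass(coords, rho)
  V <- 1 / 6
  ex <- numeric(12); ex[seq(1, 12, by = 3)] <- 1
  expect_equal(as.numeric(t(ex) %*% Me %*% ex), rho * V, tolerance = 1e-14)
  # the scalar-component pattern: 2 on the diagonal, 1 off, times rho*V/20
  for (a in 1:4) for (b in 1:4) {
    expect_equal(Me[3 * a - 2, 3 * b - 2],
                 rho * V / 20 * (if (a == b) 2 else 1))
    expect_equal(Me[3 * a - 2, 3 * b - 1], 0)  # no cross-axis coupling
  }
  expect_equal(element_mass(coords, 0), matrix(0, 12, 12))
})

test_that("sparse assembly equals the dense brute-force oracle", {
  for (mesh in list(two_tet_mesh(), generate_box_mesh(c(2, 1, 1), c(2, 1, 1)))) {
    mat <- build_material_field(mesh, seq(0.5, 1.5, length.out = nrow(mesh$tets)))
    sys <- assemble(mesh, mat)
    oracle <- dense_assemble(mesh, mat)
    expect_lt(max(abs(as.matrix(sys$K) - oracle$K)), 1e-10 * max(abs(oracle$K)))
    expect_lt(max(abs(as.matrix(sys$M) - oracle$M)), 1e-10 * max(abs(oracle$M)))
  }
})

test_that("assembled system conserves mass and annihilates rigid vectors", {
  mesh <- generate_box_mesh(c(3, 2, 1), c(2, 2, 1))
  mat <- build_material_field(mesh, 0.9)
  sys <- assemble(mesh, mat)
  # total mass recovered from M: sum over the 3 axis translations / 3
  tm <- 0
  for (ax in 1:3) {
    e <- numeric(sys$n_dofs_full); e[seq(ax, sys$n_dofs_full, by = 3)] <- 1
    tm <- tm + as.numeric(t(e) %*% (sys$M %*% e)) / 3
  }
  expect_equal(tm, sum(0.9e-9 * tet_volumes(mesh)), tolerance = 1e-12)
  R <- rigid_body_basis(mesh, sys$M)
  expect_lt(max(abs(sys$K %*% R)), 1e-8 * max(abs(sys$K)))
  # K symmetric PSD, M symmetric PD
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-12 * max(abs(sys$K)))
  evM <- eigen(as.matrix(sys$M), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(evM), 0)
  # rigid null space has dimension exactly 6
  evK <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(evK) < 1e-9 * max(evK)), 6)
})

test_that("Dirichlet elimination reduces dimensions and preserves spectrum", {
  mesh <- two_tet_mesh()
  mat <- build_material_field(mesh, 1.0)
  free_sys <- assemble(mesh, mat)
  sys <- apply_dirichlet(free_sys, 1:3)
  expect_equal(sys$n_dofs_free, 3 * (5 - 3))
  expect_equal(sys$constrained_dofs, node_dofs(1:3))
  # reduced spectrum equals the dense constrained oracle
  oracle <- dense_assemble(mesh, mat)
  keep <- setdiff(seq_len(15), node_dofs(1:3))
  ge <- dense_geig(oracle$K[keep, keep], oracle$M[keep, keep])
  ge2 <- dense_geig(sys$K_red, sys$M_red)
  expect_equal(ge2$values, ge$values, tolerance = 1e-10)
  # empty fixed set is the identity
  expect_identical(apply_dirichlet(free_sys, integer(0)), free_sys)
  expect_error(apply_dirichlet(free_sys, 1:5), "all DOFs")
})

test_that("static solve is linear and refuses the free system", {
  fx <- asym_cantilever_system(divisions = c(4, 1, 1))
  tipnode <- which(fx$mesh$nodes[, 1] == 60 & fx$mesh$nodes[, 2] == 0 &
                     fx$mesh$nodes[, 3] == 0)
  s1 <- static_solve(fx$system, tipnode, c(0, 1, 0), magnitude = 1)
  s2 <- static_solve(fx$system, tipnode, c(0, 1, 0), magnitude = 2)
  expect_equal(s2$deflection, 2 * s1$deflection, tolerance = 1e-12)
  expect_equal(s2$stiffness_direct, s1$stiffness_direct, tolerance = 1e-12)
  free_sys <- assemble(fx$mesh, fx$material)
  expect_error(static_solve(free_sys, tipnode, c(0, 1, 0)), "ill-posed")
  expect_error(static_solve(fx$system, 1, c(0, 1, 0)), "constrained")
  expect_error(static_solve(fx$system, tipnode, c(0, 0, 0)), "zero load")
})
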