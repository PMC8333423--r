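test_that("sparse eigensolver matches the dense oracle on a constrained mesh", {
  mesh <- two_tet_mesh()
  mat <- build_material_field(mesh, 0.8)
  sys <- assemble(mesh, mat, bc_spec("FEMP-I", fixed_sets = "base"))
  oracle <- dense_geig(sys$K_red, sys$M_red)
  pairs <- solve_smallest_eigenpairs(sys, n = 4, seed = 0)
  expect_equal(pairs$rigid_count, 0)
  expect_true(all(pairs$lambdas > 0))
  expect_equal(pairs$lambdas, oracle$values[1:4], tolerance = 1e-8)
  # subspace angle for simple eigenvalues: |v' M v_dense| = 1
  for (i in 1:4) {
    vd <- expand_full(sys, oracle$vectors[, i])
    cosang <- abs(as.numeric(t(pairs$vectors[, i]) %*% (sys$M %*% vd)))
    expect_equal(cosang, 1, tolerance = 1e-6)
  }
  # residual invariant of the returned pairs
  for (i in 1:4) {
    v <- pairs$vectors[sys$free_dofs, i]
    r <- sys$K_red %*% v - pairs$lambdas[i] * (sys$M_red %*% v)
    expect_lt(sqrt(sum(r^2)), 1e-7 * sqrt(sum((sys$K_red %*% v)^2)))
  }
})

test_that("free-system solver deflates 6 rigid modes and matches the oracle", {
  mesh <- generate_box_mesh(c(20, 20, 20), c(2, 2, 2))
  mat <- build_material_field(mesh, 0.8)
  sys <- assemble(mesh, mat, bc_spec("FEMP-II"))
  pairs <- solve_smallest_eigenpairs(sys, n = 8, seed = 1)
  expect_equal(pairs$rigid_count, 6)
  expect_gt(pairs$lambdas[1], 0)
  oracle <- dense_geig(sys$K_red, sys$M_red)
  expect_equal(pairs$lambdas, oracle$values[7:14], tolerance = 1e-8)
  # mass-normalization and pairwise M-orthogonality
  G <- crossprod(pairs$vectors, as.matrix(sys$M %*% pairs$vectors))
  expect_equal(diag(G), rep(1, 8), tolerance = 1e-8)
  expect_lt(max(abs(G - diag(8))), 1e-6)
})

test_that("solver is deterministic in the seed and validates n", {
  mesh <- two_tet_mesh()
  sys <- assemble(mesh, build_material_field(mesh, 1.0),
                  bc_spec("FEMP-I", fixed_sets = "base"))
  a <- solve_smallest_eigenpairs(sys, n = 3, seed = 7)
  b <- solve_smallest_eigenpairs(sys, n = 3, seed = 7)
  expect_equal(a$lambdas, b$lambdas, tolerance = 1e-12)
  expect_identical(a$vectors, b$vectors)
  expect_error(solve_smallest_eigenpairs(sys, n = 7), "only")
})

test_that("mass normalization scales, signs and handles the 1-DOF case", {
  M <- Matrix::Diagonal(x = c(2, 3, 4))
  v <- c(1, -2, 0.5)
  n1 <- mass_normalize(v, M)
  expect_equal(as.numeric(t(n1) %*% (M %*% n1)), 1)
  for (c_ in c(0.1, -3, 1e6))
    expect_equal(mass_normalize(c_ * v, M), n1)
  expect_gt(n1[which.max(abs(n1))], 0)
  # 1-DOF system M = [m]: normalized vector is 1/sqrt(m)
  expect_equal(mass_normalize(5, matrix(4)), 0.5)
  expect_error(mass_normalize(0, matrix(4)), "zero")
})

test_that("rigid classification finds 3 translations + 3 rotations on a free box", {
  mesh <- generate_box_mesh(c(10, 10, 10), c(1, 1, 1))
  mat <- build_material_field(mesh, 1.0)
  sys <- assemble(mesh, mat)
  ge <- dense_geig(sys$K_red, sys$M_red)
  pairs <- as_eigen_pairs(ge$values[1:10], ge$vectors[, 1:10])
  out <- classify_rigid_modes(pairs, sys)
  expect_equal(out$rigid_count, 6)
  # the removed subspace splits exactly into 3 translational and 3
  # rotational dimensions (individual vectors may mix inside the
  # degenerate zero eigenspace)
  expect_equal(out$translation_dim, 3, tolerance = 1e-6)
  expect_equal(out$rotation_dim, 3, tolerance = 1e-6)
  expect_true(all(out$rigid_info$projection > 0.99))
  expect_length(out$lambdas, 4)
  expect_true(all(out$lambdas > 0))
})

test_that("rigid classification is empty for a fixed system", {
  mesh <- two_tet_mesh()
  sys <- assemble(mesh, build_material_field(mesh, 1.0),
                  bc_spec("FEMP-I", fixed_sets = "base"))
  ge <- dense_geig(sys$K_red, sys$M_red)
  pairs <- as_eigen_pairs(ge$values, expand_full(sys, ge$vectors))
  out <- classify_rigid_modes(pairs, sys)
  expect_equal(out$rigid_count, 0)
  expect_length(out$lambdas, 6)
})

test_that("a disconnected mesh is rejected as a mechanism", {
  mesh <- disconnected_mesh()
  mat <- build_material_field(mesh, 1.0)
  sys <- assemble(mesh, mat)
  ge <- dense_geig(sys$K_red, sys$M_red)
  pairs <- as_eigen_pairs(ge$values[1:14], ge$vectors[, 1:14])
  expect_error(classify_rigid_modes(pairs, sys), "mechanism|disconnected")
  expect_error(solve_smallest_eigenpairs(sys, n = 4), "mechanism|disconnected")
})

test_that("adding Dirichlet constraints never decreases the first eigenvalue", {
  fx <- asym_cantilever_system(divisions = c(4, 1, 1))
  mesh <- fx$mesh
  sys1 <- fx$system  # xmin face fixed
  l_one <- solve_smallest_eigenpairs(sys1, n = 1, seed = 0)$lambdas[1]
  sys2 <- apply_dirichlet(sys1, mesh$node_sets$xmax)  # both end faces
  l_two <- solve_smallest_eigenpairs(sys2, n = 1, seed = 0)$lambdas[1]
  sys3 <- apply_dirichlet(sys2, mesh$node_sets$ymin)  # and the bottom face
  l_three <- solve_smallest_eigenpairs(sys3, n = 1, seed = 0)$lambdas[1]
  expect_lte(l_one, l_two * (1 + 1e-10))
  expect_lte(l_two, l_three * (1 + 1e-10))
})

test_that("first eigenvalue decreases monotonically under mesh refinement", {
  lams <- vapply(list(c(3, 1, 1), c(6, 2, 2), c(12, 4, 4)), function(dv) {
    fx <- asym_cantilever_system(divisions = dv)
    solve_smallest_eigenpairs(fx$system, n = 1, seed = 0)$lambdas[1]
  }, numeric(1))
  expect_true(all(diff(lams) < 0))  # P1 over-stiffens; refinement softens
})

test_that("convergence check compares leading eigenvalues at tolerance", {
  l <- c(1, 2, 3, 4, 5)
  same <- convergence_check(l, l)
  expect_true(same$pass)
  expect_equal(same$rel_change, rep(0, 5))
  expect_true(convergence_check(l, l, tol = 0)$pass)
  bumped <- l; bumped[3] <- l[3] * 1.1
  out <- convergence_check(bumped, l)
  expect_false(out$pass)
  expect_equal(out$failed_modes, 3L)
  expect_error(convergence_check(l, l[1:4]), "length")
  expect_error(convergence_check(l, -l), "nonpositive")
})
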