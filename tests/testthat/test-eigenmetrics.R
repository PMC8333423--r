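test_that("pointwise norm reshapes DOF triples into nodal magnitudes", {
  for (c_ in c(1, 0.25, 7)) {
    v <- c(3, 4, 0, 0, 0, 0) * c_
    expect_equal(pointwise_norm(v), c(5 * c_, 0))
  }
  expect_equal(pointwise_norm(numeric(9)), numeric(3))
  expect_length(pointwise_norm(rnorm(12)), 4)
  expect_error(pointwise_norm(rnorm(10)), "divisible by 3")
})

test_that("compliance argmax picks the first maximum and rejects zeros", {
  expect_equal(argmax_compliance(c(0, 1, 0.5)), 2L)
  expect_equal(argmax_compliance(c(1, 1)), 1L)  # tie -> smallest index
  expect_error(argmax_compliance(c(0, 0)), "all-zero")
  expect_error(argmax_compliance(numeric(0)), "empty")
})

test_that("modal stiffness recovers the 1-DOF spring constant exactly", {
  k_s <- 2.5; m <- 0.4
  lambda <- k_s / m
  u <- mass_normalize(1, matrix(m))     # 1/sqrt(m)
  expect_equal(modal_stiffness(lambda, abs(u), 1), k_s)
  # sign flip leaves it unchanged (squared magnitude)
  expect_equal(modal_stiffness(lambda, abs(-u), 1), k_s)
  expect_error(modal_stiffness(-1, abs(u), 1), "positive")
  expect_error(modal_stiffness(lambda, c(0), 1), "vibration node")
})

test_that("uniform density rescaling leaves s and S unchanged", {
  mesh <- two_tet_mesh()
  recs <- lapply(c(1, 3.7), function(c_) {
    mat <- build_material_field(mesh, rho_ash = 0.8, rho_eff = 0.8 * c_)
    sys <- assemble(mesh, mat, bc_spec("FEMP-I", fixed_sets = "base"))
    pairs <- solve_smallest_eigenpairs(sys, n = 4, seed = 0)
    compute_record(sys, pairs, n_hat = 4)
  })
  # lambda scales as 1/c, s and S are invariant
  expect_equal(recs[[1]]$lambdas / 3.7, recs[[2]]$lambdas, tolerance = 1e-8)
  expect_equal(recs[[1]]$s, recs[[2]]$s, tolerance = 1e-8)
  expect_equal(recs[[1]]$S, recs[[2]]$S, tolerance = 1e-8)
})

test_that("truncated static stiffness is exact in the full-spectrum limit", {
  mesh <- two_tet_mesh()
  mat <- build_material_field(mesh, 0.8)
  sys <- assemble(mesh, mat, bc_spec("FEMP-I", fixed_sets = "base"))
  pairs <- solve_smallest_eigenpairs(sys, n = 6, seed = 0)  # all free DOFs
  rec <- compute_record(sys, pairs, n_hat = 6)
  oracle <- static_compliance(sys, rec$k, rec$k_direction)
  # norm-form sum == trace of the nodal receptance block
  expect_equal(rec$S, oracle$stiffness_trace, tolerance = 1e-8)
  # directional sum == point-load solve along the mode-1 direction
  direct <- static_solve(sys, rec$k, rec$k_direction)
  expect_equal(rec$S_directional, direct$stiffness_direct, tolerance = 1e-8)
})

test_that("static stiffness is monotone in n_hat and bounded by s_1", {
  mesh <- two_tet_mesh()
  mat <- build_material_field(mesh, 0.8)
  sys <- assemble(mesh, mat, bc_spec("FEMP-I", fixed_sets = "base"))
  pairs <- solve_smallest_eigenpairs(sys, n = 6, seed = 0)
  nf <- pointwise_norm(pairs$vectors[, 1])
  k <- argmax_compliance(nf)
  S_by_n <- vapply(1:6, function(nh) static_stiffness(pairs, k, nh)$S,
                   numeric(1))
  expect_true(all(diff(S_by_n) <= 1e-12))        # non-increasing in n_hat
  s1 <- modal_stiffness(pairs$lambdas[1], nf, k)
  expect_equal(S_by_n[1], s1)                    # single term == Eq.-7 value
  expect_lte(S_by_n[6], s1)
  # 1/S reproduced from the stored per-mode compliances
  out <- static_stiffness(pairs, k, 6)
  expect_equal(1 / out$S, sum(out$compliances), tolerance = 1e-12)
  expect_warning(static_stiffness(pairs, k, 10), "exceeds")
})

test_that("natural frequency is the usual sqrt(lambda)/2pi map", {
  expect_equal(natural_frequency(4 * pi^2), 1)
  expect_equal(natural_frequency(0), 0)
  lam <- c(0, 1, 10, 1e6)
  f <- natural_frequency(lam)
  expect_equal(f, sqrt(lam) / (2 * pi), tolerance = 1e-12)
  expect_true(all(diff(f) > 0))
  expect_error(natural_frequency(-1), "negative")
})

test_that("cantilever compliance maximum lands on the free-end face", {
  fx <- asym_cantilever_system(divisions = c(6, 2, 2))
  pairs <- solve_smallest_eigenpairs(fx$system, n = 4, seed = 0)
  rec <- compute_record(fx$system, pairs, n_hat = 4)
  expect_equal(fx$mesh$nodes[rec$k, 1], 60)  # x = L: maximum bending sway
  expect_lte(rec$S, rec$s[1] * (1 + 1e-12))
  expect_equal(rec$f, sqrt(rec$lambdas) / (2 * pi), tolerance = 1e-12)
})

test_that("per-mode and first-mode policies differ on a gradient beam", {
  dirn <- withr::local_tempdir()
  fx <- make_fixture("gradient_beam", dir = dirn, divisions = c(8, 2, 3),
                     lengths = c(80, 8, 12))
  mat <- material_from_mesh(fx$mesh, "rho_ash_gcm3")
  sys <- assemble(fx$mesh, mat, fx$bc)
  pairs <- solve_smallest_eigenpairs(sys, n = 6, seed = 0)
  rec_first <- compute_record(sys, pairs, k_policy = "first_mode", n_hat = 6)
  rec_per <- compute_record(sys, pairs, k_policy = "per_mode", n_hat = 6)
  expect_identical(rec_first$policy, "first_mode")
  expect_identical(rec_per$policy, "per_mode")
  expect_false(isTRUE(all.equal(rec_first$s, rec_per$s)))
  expect_equal(rec_first$s[1], rec_per$s[1])  # mode 1 shares its own argmax
  # user_node policy pins k
  rec_user <- compute_record(sys, pairs, k_policy = "user_node", n_hat = 6,
                             user_k = rec_first$k)
  expect_equal(rec_user$S, rec_first$S)
})

test_that("rigid motion of the mesh leaves all eigenmetrics unchanged", {
  fx <- asym_cantilever_system(divisions = c(4, 2, 3))
  pairs <- solve_smallest_eigenpairs(fx$system, n = 4, seed = 0)
  rec <- compute_record(fx$system, pairs, n_hat = 4)

  th <- 0.7; ph <- 1.1
  Qz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Qx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  Q <- Qz %*% Qx
  mesh_r <- fx$mesh
  mesh_r$nodes <- fx$mesh$nodes %*% t(Q) + rep(1, nrow(fx$mesh$nodes)) %o% c(5, -3, 11)
  sys_r <- assemble(mesh_r, fx$material, bc_spec("FEMP-I", fixed_sets = "xmin"))
  pairs_r <- solve_smallest_eigenpairs(sys_r, n = 4, seed = 0)
  rec_r <- compute_record(sys_r, pairs_r, n_hat = 4)

  expect_equal(pairs_r$lambdas, pairs$lambdas, tolerance = 1e-8)
  expect_equal(rec_r$s, rec$s, tolerance = 1e-8)
  expect_equal(rec_r$S, rec$S, tolerance = 1e-8)
  expect_equal(rec_r$f, rec$f, tolerance = 1e-8)
  expect_equal(rec_r$k, rec$k)  # same node in the same (relabeled) geometry
})
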