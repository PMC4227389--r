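test_that("conjugate gradients solves a tiny SPD system exactly", {
  K <- Matrix::Matrix(diag(c(2, 3)), sparse = TRUE)
  sol <- pcg_solve(K, c(2, 3), rel_tol = 1e-12)
  expect_equal(sol$x, c(1, 1), tolerance = 1e-12)
  expect_lte(sol$iterations, 2L)
})

test_that("zero right-hand side returns the zero solution without iterating", {
  K <- Matrix::Matrix(diag(2), sparse = TRUE)
  sol <- pcg_solve(K, c(0, 0))
  expect_identical(sol$iterations, 0L)
  expect_identical(sol$x, c(0, 0))
})

test_that("indefinite matrices trigger a breakdown condition, not max-iter", {
  K <- Matrix::Matrix(diag(c(1, -1)), sparse = TRUE)
  expect_error(pcg_solve(K, c(1, 1)), class = "pcg_breakdown")
  n <- 50
  Kpd <- methods::as(Matrix::bandSparse(n, k = c(-1, 0, 1),
    diagonals = list(rep(-1, n - 1), rep(2.1, n), rep(-1, n - 1))),
    "generalMatrix")
  err <- tryCatch(pcg_solve(Kpd, rep(1, n), rel_tol = 1e-14, max_iters = 3L),
                  error = identity)
  expect_s3_class(err, "pcg_maxiter")
  expect_true(is.numeric(err$history))
})

test_that("relaxed ILU(0) is exact on matrices without fill", {
  # tridiagonal SPD: the ILU(0) pattern admits no fill, so the incomplete
  # factorization is the exact LU and the preconditioner a direct solve
  n <- 20
  K <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(rep(-1, n - 1), rep(2.5, n), rep(-1, n - 1)))
  K <- methods::as(K, "generalMatrix")
  for (omega in c(0, 0.5)) {
    fac <- tdcsbidomain:::rilu0(K, omega)
    y <- sin(seq_len(n))
    b <- as.numeric(K %*% y)
    z <- tdcsbidomain:::apply_block(fac, b)
    expect_equal(z, y, tolerance = 1e-12)
  }
})

test_that("block preconditioner is exact for diagonal blocks", {
  A <- methods::as(Matrix::Matrix(diag(c(2, 4, 8)), sparse = TRUE), "generalMatrix")
  C <- methods::as(Matrix::Matrix(diag(c(1, 3, 5, 7)), sparse = TRUE), "generalMatrix")
  sys <- list(A = A, C_constrained = C, vnodes = 1:3, n_nodes = 4L,
              has_bcs = TRUE)
  pc <- build_block_preconditioner(sys, 0.5)
  y <- c(0.1, 0.2, 0.3)
  b <- as.numeric(A %*% y)
  z <- tdcsbidomain:::apply_preconditioner(pc, c(b, numeric(4)))
  expect_equal(z[1:3], y, tolerance = 1e-14)
  expect_equal(z[4:7], numeric(4))
})

test_that("preconditioning reduces CG iterations on the phantom system", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  sys <- assemble_blocks(mesh, cond, dt = 1e-3)
  anode <- place_electrode(mesh, "ANODE", pi, 10, 1e-3)
  cathode <- place_electrode(mesh, "CATHODE", pi / 4, 10)
  sys <- apply_tdcs_bcs(sys, anode, cathode)
  rhs <- build_rhs(sys, rep(-0.07, length(sys$vnodes)))
  pc <- build_block_preconditioner(sys, 0.5)
  with_pc <- pcg_solve(sys$K, rhs, pc, rel_tol = 1e-8, max_iters = 5000)
  without <- pcg_solve(sys$K, rhs, NULL, rel_tol = 1e-8, max_iters = 5000)
  expect_lt(with_pc$iterations, without$iterations)
})

test_that("solutions match a dense direct solve on small meshes", {
  mesh <- oracle_phantom()
  expect_lte(nrow(mesh$elements), 500)
  cond <- build_conductivity(mesh)
  params <- fhn_params()

  # tDCS right-hand side
  sys <- assemble_blocks(mesh, cond, dt = 1e-3)
  anode <- place_electrode(mesh, "ANODE", pi, 15, 1e-3)
  cathode <- place_electrode(mesh, "CATHODE", pi / 4, 15)
  sys <- apply_tdcs_bcs(sys, anode, cathode)
  pc <- build_block_preconditioner(sys, 0.5)
  rhs <- build_rhs(sys, rep(params$v_rest, length(sys$vnodes)))
  x_cg <- pcg_solve(sys$K, rhs, pc, rel_tol = 1e-10, max_iters = 5000)$x
  x_dense <- solve(as.matrix(sys$K), rhs)
  expect_lt(sqrt(sum((x_cg - x_dense)^2) / sum(x_dense^2)), 1e-6)

  # AP right-hand side (no electrodes): compare in the zero-mean gauge of
  # the singular pure-Neumann problem; the dense oracle pins one node
  sys0 <- apply_tdcs_bcs(assemble_blocks(mesh, cond, dt = 1e-3), NULL, NULL)
  nb <- length(sys0$vnodes)
  nd <- mesh$nodes[sys0$vnodes, , drop = FALSE]
  bump <- params$v_rest + 0.1 * exp(-((nd[, 1])^2 + (nd[, 2] + 0.01)^2) / 1e-4)
  rhs0 <- build_rhs(sys0, bump)
  pc0 <- build_block_preconditioner(sys0, 0.5)
  x_cg0 <- pcg_solve(sys0$K, rhs0, pc0, rel_tol = 1e-10, max_iters = 5000)$x
  Kd <- as.matrix(sys0$K)
  pin <- nb + 1L
  Kd[pin, ] <- 0; Kd[, pin] <- 0; Kd[pin, pin] <- 1
  r0 <- rhs0; r0[pin] <- 0
  x_pin <- solve(Kd, r0)
  demean <- function(x) {
    x[-seq_len(nb)] <- x[-seq_len(nb)] - mean(x[-seq_len(nb)])
    x
  }
  a <- demean(x_cg0); b <- demean(x_pin)
  expect_lt(sqrt(sum((a - b)^2) / sum(b^2)), 1e-6)
})

test_that("Godunov stepping preserves the resting fixed point", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  params <- fhn_params()
  config <- solver_config(t_end = 0.1)
  sim <- run_simulation(mesh, cond, params = params, config = config)
  expect_equal(sim$state$step, 100L)
  expect_lt(max(abs(sim$state$v - params$v_rest)), 1e-6)
  expect_true(all(is.finite(sim$state$phi)))
})

test_that("t_end = 0 returns the initial state unmodified", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  sim <- run_simulation(mesh, config = solver_config(t_end = 0))
  expect_identical(sim$state$step, 0L)
  expect_true(all(sim$state$v == fhn_params()$v_rest))
  expect_true(all(sim$state$phi == 0))
})

test_that("identical configurations give bit-identical traces", {
  mesh <- build_annulus_phantom(target_element_count = 1000)
  probes <- data.frame(name = "c", x = 0, y = -0.02, quantity = "v")
  stim <- list(center = c(0, -0.025), radius = 0.005, t_on = 0, t_off = 0.01,
               amplitude = 100)
  cfg <- solver_config(t_end = 0.02)
  s1 <- run_simulation(mesh, probes = probes, stimulus = stim, config = cfg)
  s2 <- run_simulation(mesh, probes = probes, stimulus = stim, config = cfg)
  expect_identical(s1$traces$value, s2$traces$value)
})

test_that("halving the splitting step shows first-order self-convergence", {
  mesh <- fixture("phantom1k", function()
    build_annulus_phantom(target_element_count = 1000))
  stim <- list(center = c(0, -0.025), radius = 0.005, t_on = 0, t_off = 0.02,
               amplitude = 100)
  vv <- lapply(c(2e-3, 1e-3, 5e-4), function(dt) {
    cfg <- solver_config(dt_global = dt, dt_ode = dt, t_end = 0.02)
    run_simulation(mesh, stimulus = stim, config = cfg)$state$v
  })
  d1 <- sqrt(mean((vv[[1]] - vv[[2]])^2))
  d2 <- sqrt(mean((vv[[2]] - vv[[3]])^2))
  expect_gt(d1 / d2, 1.5)  # ~2 expected at order 1
})
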