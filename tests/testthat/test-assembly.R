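test_that("conductivity fields follow the tissue table", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  csf <- mesh$tissue == "CSF"
  expect_true(all(cond$M_e[csf, 1] == 1.654 & cond$M_e[csf, 3] == 1.654))
  skull <- mesh$tissue == "SKULL"
  expect_true(all(cond$M_i[skull, ] == 0))
  gm <- mesh$tissue == "GM"
  expect_true(all(cond$M_i[gm, 1] == 0.1))
  expect_error(build_conductivity(mesh, table = c(SKIN = 1, SKULL = 1)),
               "missing tissue")
})

test_that("supplied anisotropic tensors are used verbatim in the stiffness", {
  mesh <- unit_triangle_mesh()
  sig <- 0.3
  cond <- build_conductivity(mesh, M_e = cbind(2 * sig, 0, sig),
                             M_i = cbind(0.1, 0, 0.1))
  K <- tdcsbidomain:::p1_stiffness(mesh, cond$M_e)
  # hand integration: grad N = (-1,-1), (1,0), (0,1); area 1/2; M = diag(2s, s)
  K_hand <- sig * rbind(c(1.5, -1, -0.5),
                        c(-1,   1,  0),
                        c(-0.5, 0,  0.5))
  expect_equal(as.matrix(K), K_hand, tolerance = 1e-14, ignore_attr = TRUE)
  # non-SPD extracellular tensor is rejected
  expect_error(build_conductivity(mesh, M_e = cbind(1, 2, 1)),
               "positive definite")
})

test_that("unit-triangle stiffness equals the reference element matrix", {
  mesh <- unit_triangle_mesh()
  K <- tdcsbidomain:::p1_stiffness(mesh, cbind(1, 0, 1))
  expect_equal(as.matrix(K),
               0.5 * rbind(c(2, -1, -1), c(-1, 1, 0), c(-1, 0, 1)),
               tolerance = 1e-14, ignore_attr = TRUE)
  # constants lie in the null space of any stiffness matrix
  expect_equal(as.numeric(K %*% rep(1, 3)), rep(0, 3), tolerance = 1e-14)
})

test_that("block structure carries mass, scaling and the mass identity", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  sys <- assemble_blocks(mesh, cond, chi = 1.26e5, c_m = 1e-4, dt = 1e-3)
  brain_area <- sum(element_areas(mesh)[brain_elements(mesh)])
  # partition of unity: total mass = brain area
  expect_equal(sum(sys$mass_B), brain_area, tolerance = 1e-12)
  # A - mass and B share the intracellular stiffness; stiffness kills constants
  nb <- length(sys$vnodes)
  expect_equal(as.numeric((sys$A - sys$mass_B) %*% rep(1, nb)), rep(0, nb),
               tolerance = 1e-9)
  expect_equal(as.numeric(sys$C %*% rep(1, sys$n_nodes)), rep(0, sys$n_nodes),
               tolerance = 1e-9)
  # scaling consistency: the blocks depend on dt, chi, c_m only through
  # dt/(chi c_m)
  sys2 <- assemble_blocks(mesh, cond, chi = 1.26e5, c_m = 1e-4, dt = 0.5e-3)
  expect_equal(as.matrix(sys2$C), as.matrix(sys$C) / 2, tolerance = 1e-12)
  sys3 <- assemble_blocks(mesh, cond, chi = 2 * 1.26e5, c_m = 1e-4, dt = 2e-3)
  expect_lt(max(abs(sys3$B - sys$B)), 1e-15)
  expect_lt(max(abs(sys3$C - sys$C)), 1e-15)
  expect_lt(max(abs((sys3$A - sys3$mass_B) - (sys$A - sys$mass_B))), 1e-15)
})

test_that("anode load integrates to the injected current and keeps symmetry", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  sys <- assemble_blocks(mesh, cond, dt = 1e-3)
  anode <- place_electrode(mesh, "ANODE", pi, 10, 1e-3)
  cathode <- place_electrode(mesh, "CATHODE", pi / 4, 10)
  sys <- apply_tdcs_bcs(sys, anode, cathode)
  expect_equal(sum(sys$load_phi) / sys$scale, 1e-3, tolerance = 1e-12)
  expect_equal(max(abs(sys$K - Matrix::t(sys$K))), 0)
  # cathode rows reduced to the identity
  expect_true(all(sys$dirichlet %in% unique(as.vector(cathode$facets))))
})

test_that("without electrodes the potential block keeps its constant mode", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  sys <- assemble_blocks(mesh, build_conductivity(mesh), dt = 1e-3)
  sys <- apply_tdcs_bcs(sys, NULL, NULL)
  null_vec <- c(numeric(length(sys$vnodes)), rep(1, sys$n_nodes))
  expect_lt(max(abs(sys$K %*% null_vec)), 1e-9)
  # anode without cathode is rejected
  anode <- place_electrode(mesh, "ANODE", pi, 10, 1e-3)
  sys2 <- assemble_blocks(mesh, build_conductivity(mesh), dt = 1e-3)
  expect_error(apply_tdcs_bcs(sys2, anode, NULL), "singular")
})

test_that("no intracellular current escapes the brain boundary", {
  # with uniform v and M_e = 0 the intracellular flux through the brain
  # surface must vanish: rows of B sum to zero for interior and interface
  # nodes alike
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  sys <- assemble_blocks(mesh, cond, dt = 1e-3)
  flux <- as.numeric(sys$B %*% rep(1, sys$n_nodes))
  expect_lt(max(abs(flux)), 1e-12)
})

test_that("right-hand side assembles mass-weighted voltage plus anode load", {
  mesh <- fixture("phantom2k", function()
    build_annulus_phantom(target_element_count = 2000))
  cond <- build_conductivity(mesh)
  sys <- assemble_blocks(mesh, cond, dt = 1e-3)
  anode <- place_electrode(mesh, "ANODE", pi, 10, 1e-3)
  cathode <- place_electrode(mesh, "CATHODE", pi / 4, 10)
  sys_e <- apply_tdcs_bcs(sys, anode, cathode)
  sys_0 <- apply_tdcs_bcs(assemble_blocks(mesh, cond, dt = 1e-3), NULL, NULL)
  nb <- length(sys$vnodes)

  # zero voltage, no electrodes: zero vector
  expect_equal(build_rhs(sys_0, numeric(nb)), numeric(nb + sys$n_nodes))
  # uniform voltage 1: alpha sums to the brain area
  brain_area <- sum(element_areas(mesh)[brain_elements(mesh)])
  r1 <- build_rhs(sys_0, rep(1, nb))
  expect_equal(sum(r1[seq_len(nb)]), brain_area, tolerance = 1e-12)
  # superposition: v_rest with electrodes = v_rest * mass row sums + load
  vr <- -0.07
  r2 <- build_rhs(sys_e, rep(vr, nb))
  expect_equal(r2[seq_len(nb)], vr * r1[seq_len(nb)], tolerance = 1e-12)
  expect_equal(r2[-seq_len(nb)], sys_e$load_phi)
  expect_error(build_rhs(sys_e, numeric(nb - 1L)), "brain-node")
})
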