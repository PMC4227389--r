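test_that("P1 gradients of linear and constant fields are exact", {
  mesh <- fixture("phantom1k", function()
    build_annulus_phantom(target_element_count = 1000))
  phi <- mesh$nodes[, 1]   # phi = x
  E <- electric_field(mesh, phi)
  expect_equal(E[, 1], rep(-1, nrow(E)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(E[, 2], rep(0, nrow(E)), tolerance = 1e-12, ignore_attr = TRUE)
  E0 <- electric_field(mesh, rep(5, nrow(mesh$nodes)))
  expect_lt(max(abs(E0)), 1e-12)
  # affine field: exact on every element
  phi2 <- 3 * mesh$nodes[, 1] - 2 * mesh$nodes[, 2] + 1
  E2 <- electric_field(mesh, phi2)
  expect_lt(max(abs(E2[, 1] + 3)), 1e-10)
  expect_lt(max(abs(E2[, 2] - 2)), 1e-10)
})

test_that("current density applies the conductivity tensor", {
  E <- rbind(c(1, 0), c(0, 2))
  J <- current_density(E, rbind(c(2, 0, 2), c(1, 0.5, 3)))
  expect_equal(J, rbind(c(2, 0), c(1, 6)), ignore_attr = TRUE)
})

test_that("uniform strip carries |E| = dPhi/L and continuous normal J", {
  # one-tissue strip driven end to end
  mesh <- rectangle_mesh(L = 1, H = 0.2, nx = 30, ny = 6)
  sigma <- 0.5
  cond <- build_conductivity(mesh, table = c(SKIN = sigma, SKULL = sigma,
                                             CSF = sigma, GM = sigma, WM = sigma))
  I <- 1e-3
  anode <- edge_patch(mesh, "ANODE", function(x, y) x < 1e-9, total_current = I)
  cathode <- edge_patch(mesh, "CATHODE", function(x, y) x > 1 - 1e-9)
  sol <- solve_laplace(mesh, cond, anode, cathode, rel_tol = 1e-12)
  E <- electric_field(mesh, sol$phi)
  expect_equal(E[, 1], rep(I / (sigma * 0.2), nrow(E)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(abs(E[, 2])), 1e-8)

  # two layers: normal J continuous, E jumps by the conductivity ratio
  mesh2 <- rectangle_mesh(L = 1, H = 0.2, nx = 30, ny = 6,
                          tissue_fun = function(cx, cy) if (cx < 0.5) "SKIN" else "SKULL")
  cond2 <- build_conductivity(mesh2, table = c(SKIN = 0.4, SKULL = 0.1,
                                               CSF = 1, GM = 1, WM = 1))
  anode2 <- edge_patch(mesh2, "ANODE", function(x, y) x < 1e-9, total_current = I)
  cathode2 <- edge_patch(mesh2, "CATHODE", function(x, y) x > 1 - 1e-9)
  sol2 <- solve_laplace(mesh2, cond2, anode2, cathode2, rel_tol = 1e-12)
  E2 <- electric_field(mesh2, sol2$phi)
  J2 <- current_density(E2, cond2)
  left <- mesh2$tissue == "SKIN"; right <- mesh2$tissue == "SKULL"
  expect_equal(mean(J2[left, 1]), mean(J2[right, 1]), tolerance = 1e-6)
  expect_equal(mean(E2[right, 1]) / mean(E2[left, 1]), 0.4 / 0.1,
               tolerance = 1e-6)
})

test_that("AP sensitivity is the printed affine percentage", {
  p <- fhn_params()
  expect_equal(ap_sensitivity(-0.070, p), 0)
  expect_equal(ap_sensitivity(-0.0557, p), 100)
  expect_equal(ap_sensitivity(-0.06285, p), 50)
  # affine with slope -100 / (v_rest - v_th)
  v <- seq(-0.07, -0.05, by = 0.001)
  s <- ap_sensitivity(v, p)
  slopes <- diff(s) / diff(v)
  expect_equal(slopes, rep(-100 / (p$v_rest - threshold_voltage(p)),
                           length(slopes)),
               tolerance = 1e-9)
  expect_error(ap_sensitivity(-0.07, fhn_params(a = 0)), "division by zero")
})

synthetic_trace <- function(name, loc, cross_t, t = seq(0, 0.05, by = 1e-3)) {
  # ramp crossing the default threshold (-55.7 mV) at cross_t
  value <- -0.07 + (t - cross_t + 0.0143 / 2) * 2  # slope 2 V/s through vth
  structure(list(name = name, quantity = "v", location = loc,
                 node_location = loc, snap_distance = 0,
                 time = t, value = value),
            class = "probe_trace")
}

test_that("conduction velocity from constructed traces is exact arithmetic", {
  # crossings at 10 and 20 ms, 20 mm apart -> 2.0 m/s
  a <- synthetic_trace("a", c(0, -0.01), 0.010)
  b <- synthetic_trace("b", c(0, 0.01), 0.020)
  expect_equal(conduction_velocity(a, b), 2.0, tolerance = 1e-9)
  # invariant under a common time shift
  a2 <- a; b2 <- b
  a2$time <- a2$time + 0.007; b2$time <- b2$time + 0.007
  expect_equal(conduction_velocity(a2, b2), conduction_velocity(a, b),
               tolerance = 1e-12)
  # zero time difference is an error
  expect_error(conduction_velocity(a, a), "zero time difference")
  # a probe that never crosses is reported by name
  flat <- a
  flat$name <- "quiet"
  flat$value <- rep(-0.07, length(flat$time))
  expect_error(conduction_velocity(a, flat), "quiet")
})

test_that("VTK export round-trips mesh and fields", {
  mesh <- fixture("phantom1k", function()
    build_annulus_phantom(target_element_count = 1000))
  phi <- sin(10 * mesh$nodes[, 1]) * mesh$nodes[, 2]
  vbrain <- seq_along(brain_nodes(mesh)) / 1000
  E <- electric_field(mesh, phi)
  path <- withr::local_tempfile(fileext = ".vtk")
  export_vtk(mesh, path, point_data = list(phi = phi, v = vbrain),
             cell_data = list(E = E, Emag = sqrt(rowSums(E^2))))
  back <- read_vtk(path)
  expect_identical(back$mesh$nodes, mesh$nodes)
  expect_identical(back$mesh$elements, mesh$elements)
  expect_identical(as.character(back$mesh$tissue), as.character(mesh$tissue))
  expect_identical(back$point_data$phi, phi)
  expect_identical(back$cell_data$E, unname(E))
  # brain-only field padded with the NaN sentinel outside the brain
  v_full <- back$point_data$v
  bn <- brain_nodes(mesh)
  expect_identical(v_full[bn], vbrain)
  expect_true(all(is.nan(v_full[-bn])))
})

test_that("probe CSV export writes valid long format, even when empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_probes_csv(NULL, path)
  empty <- read.csv(path)
  expect_identical(names(empty), c("time", "name", "quantity", "value"))
  expect_identical(nrow(empty), 0L)

  tr <- data.frame(time = c(0, 1e-3), name = "p", quantity = "v",
                   value = c(-0.07, -0.069))
  export_probes_csv(tr, path)
  back <- read.csv(path)
  expect_equal(back$value, tr$value)
})
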