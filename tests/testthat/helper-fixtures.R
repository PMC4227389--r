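# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# single unit right triangle, brain tissue
unit_triangle_mesh <- function(tissue = "WM") {
  simplicial_mesh(nodes = rbind(c(0, 0), c(1, 0), c(0, 1)),
                  elements = rbind(c(1L, 2L, 3L)),
                  tissue = tissue)
}

# unit square split into four triangles around the center node
square_mesh <- function(tissue = c("WM", "GM", "CSF", "SKIN")) {
  simplicial_mesh(
    nodes = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)),
    elements = rbind(c(1L, 2L, 5L), c(2L, 3L, 5L), c(3L, 4L, 5L), c(4L, 1L, 5L)),
    tissue = tissue)
}

# structured rectangle [0,L]x[0,H]; tissue assigned by a centroid predicate
rectangle_mesh <- function(L = 1, H = 0.2, nx = 20, ny = 4,
                           tissue_fun = function(cx, cy) "WM") {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, H, length.out = ny + 1)
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  tris <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid(i, j); b <- nid(i + 1L, j); cc <- nid(i + 1L, j + 1L); d <- nid(i, j + 1L)
    tris[[length(tris) + 1L]] <- c(a, b, cc)
    tris[[length(tris) + 1L]] <- c(a, cc, d)
  }
  el <- do.call(rbind, tris)
  cen <- (nodes[el[, 1], ] + nodes[el[, 2], ] + nodes[el[, 3], ]) / 3
  tis <- mapply(tissue_fun, cen[, 1], cen[, 2])
  simplicial_mesh(nodes, el, tis)
}

# hand-built electrode on a straight mesh edge (for rectangle meshes)
edge_patch <- function(mesh, kind, predicate, total_current = 0) {
  bf <- mesh$boundary_facets
  mid <- (mesh$nodes[bf[, 1], , drop = FALSE] + mesh$nodes[bf[, 2], , drop = FALSE]) / 2
  sel <- which(predicate(mid[, 1], mid[, 2]))
  facets <- bf[sel, , drop = FALSE]
  len <- sqrt(rowSums((mesh$nodes[facets[, 1], , drop = FALSE] -
                       mesh$nodes[facets[, 2], , drop = FALSE])^2))
  structure(list(kind = kind, facets = facets, facet_lengths = len,
                 total_current = total_current),
            class = "electrode_patch")
}

# coarse five-tissue phantom small enough for dense-matrix oracles
oracle_phantom <- function() {
  fixture("oracle_phantom", function()
    build_annulus_phantom(radii = c(20, 40, 60, 80, 100), csf_strip_width = 0,
                          target_element_count = 450))
}

# reduced-scale packaged experiments shared by integration and acceptance tests
ap_run <- function() {
  fixture("ap_run", function()
    run_experiment(experiment_ap_conduction(target_element_count = 2500)))
}
tdcs_run <- function(cfg) {
  fixture(paste0("tdcs_run_", cfg), function()
    run_experiment(experiment_tdcs(cfg, target_element_count = 2500)))
}

# classical RK4 reference integrator for the membrane ODEs (independent of
# the Heun path under test)
rk4_fhn <- function(v, w, params, i_app, t_end, dt) {
  n <- round(t_end / dt)
  for (s in seq_len(n)) {
    k1 <- fhn_rhs(v, w, params, i_app)
    k2 <- fhn_rhs(v + dt / 2 * k1$dv, w + dt / 2 * k1$dw, params, i_app)
    k3 <- fhn_rhs(v + dt / 2 * k2$dv, w + dt / 2 * k2$dw, params, i_app)
    k4 <- fhn_rhs(v + dt * k3$dv, w + dt * k3$dw, params, i_app)
    v <- v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    w <- w + dt / 6 * (k1$dw + 2 * k2$dw + 2 * k3$dw + k4$dw)
  }
  list(v = v, w = w)
}

# P1 interpolation of a nodal field at arbitrary points (brute-force
# point-in-triangle search; test-sized meshes only)
interp_field <- function(mesh, values, points) {
  out <- rep(NA_real_, nrow(points))
  el <- mesh$elements
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    for (e in seq_len(nrow(el))) {
      tri <- el[e, ]
      a <- mesh$nodes[tri[1], ]; b <- mesh$nodes[tri[2], ]; cc <- mesh$nodes[tri[3], ]
      det <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
      l2 <- ((p[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (p[2] - a[2])) / det
      l3 <- ((b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])) / det
      l1 <- 1 - l2 - l3
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        out[k] <- l1 * values[tri[1]] + l2 * values[tri[2]] + l3 * values[tri[3]]
        break
      }
    }
  }
  out
}
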