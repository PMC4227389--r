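#' Laplace volume-conductor reference solution
#'
#' The classical tDCS forward model: a single stationary potential field
#' obeying `div(M grad Phi) = 0` over the whole head with the same
#' electrode boundary conditions as the multiscale model (anode Neumann
#' inward current, cathode grounded, insulated elsewhere). Uses the
#' extracellular conductivities only (there is no intracellular domain in
#' this model). Solved with the same P1 assembly, symmetric Dirichlet
#' elimination and RILU(0)-preconditioned conjugate gradients as the
#' coupled system.
#'
#' @param mesh a [simplicial_mesh()].
#' @param conductivity a [build_conductivity()] field; only `M_e` is used.
#' @param anode,cathode electrodes from [place_electrode()]; a cathode is
#'   required (otherwise the stationary problem is singular).
#' @param rel_tol,max_iters,omega linear-solver controls.
#' @return list with `phi` (nodal potential, V), `iterations`, and the
#'   stiffness matrix `K` (constrained).
#' @export
solve_laplace <- function(mesh, conductivity = build_conductivity(mesh),
                          anode, cathode, rel_tol = 1e-8,
                          max_iters = 5000L, omega = 0.5) {
  if (is.null(cathode)) stop("cathode required: pure-Neumann Laplace problem is singular")
  K <- p1_stiffness(mesh, conductivity$M_e)
  n <- nrow(mesh$nodes)
  load <- numeric(n)
  dens <- anode$total_current / sum(anode$facet_lengths)
  for (f in seq_len(nrow(anode$facets))) {
    nd <- anode$facets[f, ]
    load[nd] <- load[nd] + dens * anode$facet_lengths[f] / 2
  }
  dir_nodes <- sort(unique(as.vector(cathode$facets)))
  K[dir_nodes, ] <- 0
  K[, dir_nodes] <- 0
  diag(K)[dir_nodes] <- 1
  load[dir_nodes] <- 0
  K <- methods::as(Matrix::drop0(K), "generalMatrix")
  fac <- rilu0(K, omega)
  precond <- if (is.null(fac)) NULL else
    structure(list(v = fac, nv = n, nphi = 0L), class = "block_preconditioner")
  sol <- pcg_solve(K, load, precond, rel_tol, max_iters)
  list(phi = sol$x, iterations = sol$iterations, K = K)
}

#' Relative L2 difference between two potential fields
#'
#' `||a - b|| / ||b||` in the P1 mass-matrix inner product, either over a
#' set of elements (default: the whole domain) or along the outer (scalp)
#' boundary using facet-length weights.
#'
#' @param phi_a,phi_b nodal fields on the same mesh.
#' @param mesh the common [simplicial_mesh()].
#' @param region `"domain"`, `"boundary"`, or an integer vector of element
#'   indices.
#' @return nonnegative scalar; 0 for identical fields.
#' @export
compare_fields <- function(phi_a, phi_b, mesh, region = "domain") {
  if (length(phi_a) != nrow(mesh$nodes) || length(phi_b) != nrow(mesh$nodes))
    stop("fields must be nodal on the given mesh")
  if (identical(region, "boundary")) {
    bf <- mesh$boundary_facets
    len <- sqrt(rowSums((mesh$nodes[bf[, 1], , drop = FALSE] -
                         mesh$nodes[bf[, 2], , drop = FALSE])^2))
    w <- numeric(nrow(mesh$nodes))
    for (k in seq_len(nrow(bf))) w[bf[k, ]] <- w[bf[k, ]] + len[k] / 2
    d <- phi_a - phi_b
    denom <- sqrt(sum(w * phi_b^2))
    if (denom == 0) stop("reference field vanishes on the boundary")
    return(sqrt(sum(w * d^2)) / denom)
  }
  elems <- if (identical(region, "domain")) seq_len(nrow(mesh$elements)) else {
    if (length(region) == 0L) stop("empty region")
    as.integer(region)
  }
  M <- p1_mass(mesh, elems)
  d <- phi_a - phi_b
  denom <- sqrt(as.numeric(phi_b %*% (M %*% phi_b)))
  if (denom == 0) stop("reference field has zero L2 norm on the region")
  sqrt(as.numeric(d %*% (M %*% d))) / denom
}
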