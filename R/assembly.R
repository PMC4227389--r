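#' Default extracellular tissue conductivities (S/m)
#'
#' Isotropic extracellular conductivities: skin 0.465, skull 0.010,
#' CSF 1.654, grey matter 0.276, white matter 0.126.
#' @export
default_conductivities <- function() {
  c(SKIN = 0.465, SKULL = 0.010, CSF = 1.654, GM = 0.276, WM = 0.126)
}

#' Per-element conductivity tensor fields
#'
#' Builds the intracellular (`M_i`) and extracellular (`M_e`) conductivity
#' tensor fields on a mesh. Symmetric 2x2 tensors are stored row-wise as
#' `(m_xx, m_xy, m_yy)`. Isotropic tissues get `sigma * I`; the
#' intracellular tensor is `intra_sigma * I` on GM/WM elements and zero on
#' extracerebral elements (there is no intracellular space outside the
#' brain). Full per-element tensors may be supplied to override either
#' field, e.g. for anisotropic white matter.
#'
#' @param mesh a [simplicial_mesh()].
#' @param table named vector of extracellular conductivities covering all
#'   five tissues (S/m).
#' @param intra_sigma isotropic intracellular conductivity on GM/WM (S/m).
#' @param M_e,M_i optional full per-element tensor matrices
#'   (`n_elements x 3`, columns `m_xx, m_xy, m_yy`) overriding the
#'   table-derived fields.
#' @return object of class `conductivity_field` with matrices `M_e`, `M_i`.
#' @export
build_conductivity <- function(mesh, table = default_conductivities(),
                               intra_sigma = 0.1, M_e = NULL, M_i = NULL) {
  m <- nrow(mesh$elements)
  if (is.null(M_e)) {
    missing <- setdiff(levels(droplevels(mesh$tissue)), names(table))
    if (length(missing))
      stop("conductivity table is missing tissue(s): ", paste(missing, collapse = ", "))
    sig <- unname(table[as.character(mesh$tissue)])
    M_e <- cbind(m_xx = sig, m_xy = 0, m_yy = sig)
  }
  if (is.null(M_i)) {
    intra <- ifelse(mesh$tissue %in% BRAIN_TISSUES, intra_sigma, 0)
    M_i <- cbind(m_xx = intra, m_xy = 0, m_yy = intra)
  }
  M_e <- as.matrix(M_e); M_i <- as.matrix(M_i)
  if (nrow(M_e) != m || nrow(M_i) != m || ncol(M_e) != 3L || ncol(M_i) != 3L)
    stop("tensor fields must be n_elements x 3 matrices (m_xx, m_xy, m_yy)")
  check_spd <- function(M, name, strict) {
    det2 <- M[, 1] * M[, 3] - M[, 2]^2
    bad <- if (strict) which(M[, 1] <= 0 | det2 <= 0) else which(M[, 1] < 0 | det2 < -1e-300)
    if (length(bad))
      stop(name, " tensor not symmetric positive ",
           if (strict) "definite" else "semidefinite",
           " on element(s) ", paste(head(bad, 5L), collapse = ", "))
  }
  check_spd(M_e, "extracellular", strict = TRUE)
  check_spd(M_i, "intracellular", strict = FALSE)
  outside <- setdiff(seq_len(m), brain_elements(mesh))
  if (any(M_i[outside, ] != 0))
    stop("intracellular conductivity must vanish outside the brain (GM/WM)")
  structure(list(M_e = M_e, M_i = M_i), class = "conductivity_field")
}

# ---------------------------------------------------------------------------
# P1 element integrals. Gradients of P1 basis functions are constant per
# triangle; the stiffness integrand is exact. The mass matrix uses the
# exact order-2 quadrature A/12 * (1 + delta_ij).

# geometry: areas and basis gradients for a subset of elements
p1_geometry <- function(mesh, elems) {
  el <- mesh$elements[elems, , drop = FALSE]
  x1 <- mesh$nodes[el[, 1], 1]; y1 <- mesh$nodes[el[, 1], 2]
  x2 <- mesh$nodes[el[, 2], 1]; y2 <- mesh$nodes[el[, 2], 2]
  x3 <- mesh$nodes[el[, 3], 1]; y3 <- mesh$nodes[el[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(a2 <= 0))
    stop("degenerate element with non-positive area: element id ",
         elems[which(a2 <= 0)[1L]])
  # grad N_i = (b_i, c_i)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2
  list(el = el, area = a2 / 2, b = b, c = cc)
}

# sparse n x n stiffness matrix int M grad Nj . grad Ni over the given
# elements, with per-element symmetric tensor M (columns m_xx, m_xy, m_yy)
p1_stiffness <- function(mesh, tensor, elems = seq_len(nrow(mesh$elements))) {
  g <- p1_geometry(mesh, elems)
  mxx <- tensor[elems, 1]; mxy <- tensor[elems, 2]; myy <- tensor[elems, 3]
  n <- nrow(mesh$nodes)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    ii[[k]] <- g$el[, i]; jj[[k]] <- g$el[, j]
    vv[[k]] <- g$area * (g$b[, i] * (mxx * g$b[, j] + mxy * g$c[, j]) +
                         g$c[, i] * (mxy * g$b[, j] + myy * g$c[, j]))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, n), symmetric = FALSE)
}

# sparse n x n consistent mass matrix over the given elements
p1_mass <- function(mesh, elems = seq_len(nrow(mesh$elements))) {
  g <- p1_geometry(mesh, elems)
  n <- nrow(mesh$nodes)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    ii[[k]] <- g$el[, i]; jj[[k]] <- g$el[, j]
    vv[[k]] <- g$area / 12 * (1 + (i == j))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, n), symmetric = FALSE)
}

#' Assemble the coupled block system
#'
#' Discretizes the implicit-Euler step of the coupled transmembrane /
#' extracellular potential system with P1 finite elements, producing the
#' 2x2 block matrix
#' \deqn{\begin{pmatrix} A & B \\ B^T & C\end{pmatrix}
#'   \begin{pmatrix} v \\ \Phi \end{pmatrix} =
#'   \begin{pmatrix} \alpha \\ 0 \end{pmatrix}}
#' with
#' `A = mass(brain) + s * stiffness(M_i, brain)`,
#' `B = s * stiffness(M_i, brain)`,
#' `C = s * (stiffness(M_i + M_e, brain) + stiffness(M_e, extracerebral))`,
#' where `s = dt / (chi * c_m)`. Transmembrane degrees of freedom exist on
#' brain nodes only (including interface nodes); potential degrees of
#' freedom on all nodes. The confinement of intracellular current to the
#' brain is automatic: `A` and `B` integrate over brain elements with no
#' boundary terms.
#'
#' @param mesh a [simplicial_mesh()].
#' @param conductivity a [build_conductivity()] field.
#' @param chi membrane surface-to-volume ratio (1/m), default `1.26e5`.
#' @param c_m membrane capacitance per unit area (F/m^2), default `1e-4`.
#' @param dt implicit-Euler time step (s).
#' @return object of class `block_system`: blocks `A`, `B`, `C`, the brain
#'   mass matrix `mass_B` (for the right-hand side), the brain-node index
#'   map `vnodes`, scaling `scale = dt/(chi c_m)`, and (after
#'   [apply_tdcs_bcs()]) the constrained full matrix `K`, Dirichlet node
#'   set and anode load vector.
#' @export
assemble_blocks <- function(mesh, conductivity, chi = 1.26e5, c_m = 1e-4, dt) {
  if (dt <= 0 || chi <= 0 || c_m <= 0) stop("dt, chi and c_m must be positive")
  scale <- dt / (chi * c_m)
  belems <- brain_elements(mesh)
  if (length(belems) == 0L) stop("mesh has no brain (GM/WM) elements")
  bn <- brain_nodes(mesh)

  Ki <- p1_stiffness(mesh, conductivity$M_i, belems)   # intracellular, brain only
  Ke <- p1_stiffness(mesh, conductivity$M_e)           # extracellular, everywhere
  Mb <- p1_mass(mesh, belems)

  A <- Mb[bn, bn] + scale * Ki[bn, bn]
  B <- scale * Ki[bn, , drop = FALSE]
  C <- scale * (Ki + Ke)

  structure(list(A = A, B = B, C = C, mass_B = Mb[bn, bn],
                 vnodes = bn, n_nodes = nrow(mesh$nodes),
                 scale = scale, chi = chi, c_m = c_m, dt = dt,
                 K = NULL, dirichlet = integer(0),
                 load_phi = numeric(nrow(mesh$nodes)),
                 has_bcs = FALSE),
            class = "block_system")
}

#' @export
print.block_system <- function(x, ...) {
  cat("<block_system> v dofs: ", length(x$vnodes), ", phi dofs: ", x$n_nodes,
      if (x$has_bcs) paste0(", ", length(x$dirichlet), " Dirichlet (cathode) nodes"),
      "\n", sep = "")
  invisible(x)
}

#' Apply tDCS electrode boundary conditions
#'
#' Adds the anode Neumann boundary load (uniform inward current density
#' over the electrode, integrated against the facet basis functions and
#' scaled by `dt/(chi c_m)` consistently with the block scaling) and
#' constrains the cathode nodes to `Phi = 0` by symmetric row/column
#' elimination, which preserves the symmetry that the conjugate-gradient
#' solver relies on. All other boundary facets are natural (insulated).
#' With no electrodes at all the potential block keeps its constant null
#' space (pure Neumann); the time stepper then reports the zero-mean
#' gauge of `Phi`.
#'
#' @param system a [assemble_blocks()] result.
#' @param anode,cathode `electrode_patch` objects from [place_electrode()],
#'   or `NULL`.
#' @return the system with the constrained full sparse matrix `K` attached.
#' @export
apply_tdcs_bcs <- function(system, anode = NULL, cathode = NULL) {
  n <- system$n_nodes
  load <- numeric(n)
  if (!is.null(anode)) {
    if (is.null(cathode))
      stop("anode without cathode: system is singular up to constants; supply a cathode")
    # uniform line current density (A/m per unit depth) on the electrode
    dens <- anode$total_current / sum(anode$facet_lengths)
    for (f in seq_len(nrow(anode$facets))) {
      nd <- anode$facets[f, ]
      load[nd] <- load[nd] + dens * anode$facet_lengths[f] / 2
    }
    load <- system$scale * load
  }
  dir_nodes <- if (!is.null(cathode)) sort(unique(as.vector(cathode$facets))) else integer(0)
  if (!is.null(anode) && length(intersect(sort(unique(as.vector(anode$facets))), dir_nodes)))
    stop("anode and cathode facet sets overlap")

  C <- system$C
  B <- system$B
  if (length(dir_nodes)) {
    # symmetric elimination: prescribed value is zero, so no rhs correction
    C[dir_nodes, ] <- 0
    C[, dir_nodes] <- 0
    diag(C)[dir_nodes] <- 1
    load[dir_nodes] <- 0
    # B columns at cathode nodes are structurally zero already (cathode is
    # on the scalp, outside the brain), but eliminate defensively
    B[, dir_nodes] <- 0
  }
  K <- Matrix::rbind2(Matrix::cbind2(system$A, B),
                      Matrix::cbind2(Matrix::t(B), C))
  system$K <- methods::as(Matrix::drop0(K), "generalMatrix")
  system$C_constrained <- C
  system$dirichlet <- dir_nodes
  system$load_phi <- load
  system$has_bcs <- TRUE
  system
}

#' Right-hand side for one implicit-Euler step
#'
#' `alpha = mass(brain) %*% v_tilde` on the transmembrane block; the
#' potential block carries only the anode boundary load (zero at
#' constrained cathode nodes).
#'
#' @param system a `block_system` (see [assemble_blocks()]) with boundary conditions applied.
#' @param v_tilde partial (reaction-step) transmembrane voltage on the
#'   brain nodes, in the order of `system$vnodes`.
#' @return numeric right-hand-side vector of length
#'   `length(vnodes) + n_nodes`.
#' @export
build_rhs <- function(system, v_tilde) {
  if (!system$has_bcs)
    stop("apply_tdcs_bcs() must be called before build_rhs()")
  if (length(v_tilde) != length(system$vnodes))
    stop("v_tilde has length ", length(v_tilde), " but there are ",
         length(system$vnodes), " brain-node dofs")
  c(as.vector(system$mass_B %*% v_tilde), system$load_phi)
}
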