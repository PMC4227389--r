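#' Time-stepping and linear-solver configuration
#'
#' @param dt_global global (splitting/PDE) time step in seconds, default
#'   1 ms.
#' @param dt_ode membrane ODE substep in seconds, default 0.5 ms; must
#'   divide `dt_global`.
#' @param t_end total simulated time (s).
#' @param cg_rel_tol relative residual tolerance `||r_k||/||r_0||` of the
#'   preconditioned conjugate-gradient solver, default `1e-8`.
#' @param ilu_relaxation relaxation parameter `omega` of the relaxed
#'   ILU(0) preconditioner blocks, default 0.5 (0 = plain ILU(0),
#'   1 = modified ILU).
#' @param max_cg_iters iteration cap before the solver aborts.
#' @param warm_start use the previous step's solution as the CG initial
#'   guess (halves iterations in quasi-static tDCS runs); set `FALSE` for
#'   the strict zero-start residual definition.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt_global = 1e-3, dt_ode = 0.5e-3, t_end = 0.1,
                          cg_rel_tol = 1e-8, ilu_relaxation = 0.5,
                          max_cg_iters = 2000L, warm_start = TRUE) {
  if (dt_global <= 0 || dt_ode <= 0) stop("time steps must be positive")
  if (dt_ode > dt_global) stop("dt_ode must not exceed dt_global")
  if (cg_rel_tol <= 0) stop("cg_rel_tol must be positive")
  structure(list(dt_global = dt_global, dt_ode = dt_ode, t_end = t_end,
                 cg_rel_tol = cg_rel_tol, ilu_relaxation = ilu_relaxation,
                 max_cg_iters = as.integer(max_cg_iters),
                 warm_start = isTRUE(warm_start)),
            class = "solver_config")
}

# ---------------------------------------------------------------------------
# Relaxed ILU(0) factorization.
#
# Row-based IKJ incomplete factorization on the sparsity pattern of A; fill
# outside the pattern is not stored but subtracted from the diagonal scaled
# by omega (omega = 0: plain ILU(0); omega = 1: modified ILU preserving row
# sums). Returns unit-lower L and upper U as triangular sparse matrices so
# that applications use the C-level triangular solves of the Matrix
# package.

rilu0 <- function(A, omega = 0.5) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  n <- nrow(A)
  At <- Matrix::t(A)  # CSC of t(A) gives row-wise access to A
  rp <- At@p; rj <- At@i + 1L; rx <- At@x
  rows_j <- vector("list", n)
  rows_x <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- if (rp[i + 1L] > rp[i]) (rp[i] + 1L):rp[i + 1L] else integer(0)
    o <- order(rj[idx])
    rows_j[[i]] <- rj[idx][o]
    rows_x[[i]] <- rx[idx][o]
  }
  diag_val <- numeric(n)
  scale <- max(abs(rx))
  for (i in seq_len(n)) {
    jrow <- rows_j[[i]]; arow <- rows_x[[i]]
    dpos <- match(i, jrow)
    if (is.na(dpos)) return(NULL)  # structurally missing diagonal
    for (k in jrow[jrow < i]) {
      kpos <- match(k, jrow)
      lik <- arow[kpos] / diag_val[k]
      arow[kpos] <- lik
      if (lik == 0) next
      ujrow <- rows_j[[k]]; uxrow <- rows_x[[k]]
      upper <- which(ujrow > k)
      if (!length(upper)) next
      pos <- match(ujrow[upper], jrow)
      inpat <- !is.na(pos)
      if (any(inpat))
        arow[pos[inpat]] <- arow[pos[inpat]] - lik * uxrow[upper][inpat]
      if (omega != 0 && any(!inpat))
        arow[dpos] <- arow[dpos] - omega * lik * sum(uxrow[upper][!inpat])
    }
    if (!is.finite(arow[dpos]) || abs(arow[dpos]) < 1e-14 * scale)
      return(NULL)  # (near-)zero pivot: caller falls back to Jacobi
    diag_val[i] <- arow[dpos]
    rows_x[[i]] <- arow
  }
  ii <- rep.int(seq_len(n), lengths(rows_j))
  jj <- unlist(rows_j)
  xx <- unlist(rows_x)
  lower <- jj < ii
  L <- Matrix::sparseMatrix(i = ii[lower], j = jj[lower], x = xx[lower],
                            dims = c(n, n)) + Matrix::Diagonal(n)
  U <- Matrix::sparseMatrix(i = ii[!lower], j = jj[!lower], x = xx[!lower],
                            dims = c(n, n))
  list(L = methods::as(Matrix::tril(L), "triangularMatrix"),
       U = methods::as(Matrix::triu(U), "triangularMatrix"))
}

#' Block preconditioner for the coupled system
#'
#' Block-diagonal preconditioner: independent relaxed-ILU(0) approximate
#' inverses of the transmembrane block `A` and the (constrained) potential
#' block `C`. If an ILU factorization encounters a (near-)zero pivot that
#' block falls back to Jacobi (diagonal) preconditioning with a warning.
#'
#' @param system a `block_system` (see [assemble_blocks()]) with boundary conditions applied.
#' @param omega relaxation parameter in `[0, 1]`; 0 gives plain ILU(0).
#' @return a preconditioner object for [pcg_solve()].
#' @export
build_block_preconditioner <- function(system, omega = 0.5) {
  if (!system$has_bcs) stop("apply boundary conditions before preconditioning")
  mk <- function(M, label) {
    fac <- rilu0(M, omega)
    if (is.null(fac)) {
      warning("ILU(0) pivot breakdown in ", label,
              " block; falling back to Jacobi", call. = FALSE)
      list(jacobi = 1 / Matrix::diag(M))
    } else fac
  }
  structure(list(v = mk(system$A, "transmembrane"),
                 phi = mk(system$C_constrained, "potential"),
                 nv = length(system$vnodes), nphi = system$n_nodes),
            class = "block_preconditioner")
}

apply_block <- function(fac, r) {
  if (!is.null(fac$jacobi)) return(fac$jacobi * r)
  as.numeric(Matrix::solve(fac$U, Matrix::solve(fac$L, r)))
}

apply_preconditioner <- function(precond, r) {
  if (is.null(precond)) return(r)
  if (precond$nphi == 0L) return(apply_block(precond$v, r))
  iv <- seq_len(precond$nv)
  c(apply_block(precond$v, r[iv]), apply_block(precond$phi, r[-iv]))
}

#' Preconditioned conjugate gradients
#'
#' Standard PCG on a symmetric system with relative residual monitor
#' `||r_k|| / ||r_0||`. A breakdown (`p' K p <= 0`, i.e. the matrix is not
#' positive definite on the search space) is reported distinctly from
#' exceeding the iteration cap.
#'
#' @param K symmetric sparse matrix.
#' @param rhs right-hand side.
#' @param precond a [build_block_preconditioner()] object, or `NULL` for
#'   unpreconditioned CG.
#' @param rel_tol relative residual tolerance.
#' @param max_iters iteration cap.
#' @param x0 initial guess (default zero start).
#' @return list with `x`, `iterations`, `rel_residual`, and the residual
#'   `history`.
#' @export
pcg_solve <- function(K, rhs, precond = NULL, rel_tol = 1e-8,
                      max_iters = 2000L, x0 = NULL) {
  n <- length(rhs)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  if (sqrt(sum(rhs^2)) == 0 && is.null(x0))
    return(list(x = numeric(n), iterations = 0L, rel_residual = 0, history = numeric(0)))
  r <- rhs - as.numeric(K %*% x)
  r0n <- sqrt(sum(r^2))
  # absolute floor: with a warm start at the exact solution the initial
  # residual is pure roundoff and cannot be reduced by a further 10^8
  floor_n <- 100 * .Machine$double.eps * sqrt(sum(rhs^2))
  if (r0n <= floor_n)
    return(list(x = x, iterations = 0L, rel_residual = 0, history = numeric(0)))
  z <- apply_preconditioner(precond, r)
  p <- z
  rz <- sum(r * z)
  history <- numeric(0)
  for (it in seq_len(max_iters)) {
    Kp <- as.numeric(K %*% p)
    pKp <- sum(p * Kp)
    if (pKp <= 0) {
      # roundoff-level curvature once the residual sits at machine noise is
      # convergence, not indefiniteness
      if (sqrt(sum(r^2)) <= 10 * floor_n)
        return(list(x = x, iterations = it - 1L,
                    rel_residual = sqrt(sum(r^2)) / r0n, history = history))
      stop(structure(class = c("pcg_breakdown", "error", "condition"),
                     list(message = sprintf(
                       "conjugate-gradient breakdown at iteration %d: matrix not positive definite (p'Kp = %g)",
                       it, pKp), call = NULL)))
    }
    alpha <- rz / pKp
    x <- x + alpha * p
    r <- r - alpha * Kp
    rn <- sqrt(sum(r^2))
    rel <- rn / r0n
    history <- c(history, rel)
    if (rel <= rel_tol || rn <= floor_n)
      return(list(x = x, iterations = it, rel_residual = rel, history = history))
    z <- apply_preconditioner(precond, r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(structure(class = c("pcg_maxiter", "error", "condition"),
                 list(message = sprintf(
                   "conjugate gradients did not converge in %d iterations (relative residual %.3e); history attached",
                   max_iters, tail(history, 1)), call = NULL,
                   history = history)))
}

# ---------------------------------------------------------------------------
# Godunov splitting

new_simulation_state <- function(system, params) {
  nb <- length(system$vnodes)
  list(v = rep(params$v_rest, nb), w = numeric(nb),
       phi = numeric(system$n_nodes), t = 0, step = 0L,
       cg_iterations = integer(0))
}

#' One Godunov operator-splitting step
#'
#' Step (1): advance the membrane ODEs on the brain nodes by the global
#' step (Heun substeps), giving the partial solution `v_tilde`. Step (2):
#' solve the implicit-Euler finite-element system with `alpha` built from
#' `v_tilde`, yielding the end-of-step `v` and `Phi`. The recovery
#' variable `w` carries over unchanged through step (2).
#'
#' @param state simulation state (from an earlier step or created
#'   internally by [run_simulation()]).
#' @param system a `block_system` (see [assemble_blocks()]) with boundary conditions applied.
#' @param params an [fhn_params()].
#' @param config a [solver_config()].
#' @param precond preconditioner from [build_block_preconditioner()].
#' @param i_app applied current for the reaction step (V/s); scalar or
#'   per-brain-node vector (zero during plain tDCS runs).
#' @return updated state.
#' @export
godunov_step <- function(state, system, params, config, precond = NULL,
                         i_app = 0) {
  st <- ode_substep_loop(state$v, state$w, params, i_app,
                         config$dt_global, config$dt_ode)
  rhs <- build_rhs(system, st$v)
  x0 <- if (config$warm_start) c(state$v, state$phi) else NULL
  sol <- pcg_solve(system$K, rhs, precond,
                   rel_tol = config$cg_rel_tol,
                   max_iters = config$max_cg_iters, x0 = x0)
  nb <- length(system$vnodes)
  state$v <- sol$x[seq_len(nb)]
  state$phi <- sol$x[-seq_len(nb)]
  if (length(system$dirichlet) == 0L) {
    # pure Neumann: fix the free constant to the zero-mean gauge
    state$phi <- state$phi - mean(state$phi)
  }
  state$w <- st$w
  state$t <- state$t + config$dt_global
  state$step <- state$step + 1L
  state$cg_iterations <- c(state$cg_iterations, sol$iterations)
  state
}

resolve_probes <- function(probes, mesh, vnodes) {
  if (is.null(probes) || nrow(probes) == 0L) return(NULL)
  out <- vector("list", nrow(probes))
  for (k in seq_len(nrow(probes))) {
    loc <- c(probes$x[k], probes$y[k])
    cand <- if (probes$quantity[k] == "v") vnodes else seq_len(nrow(mesh$nodes))
    d2 <- (mesh$nodes[cand, 1] - loc[1])^2 + (mesh$nodes[cand, 2] - loc[2])^2
    best <- which.min(d2)
    out[[k]] <- list(name = probes$name[k], quantity = probes$quantity[k],
                     location = loc, node = cand[best],
                     node_location = mesh$nodes[cand[best], ],
                     snap_distance = sqrt(d2[best]))
  }
  out
}

#' Run a multiscale simulation
#'
#' Drives the Godunov splitting over `t_end / dt_global` steps, recording
#' probe time series every global step and full field snapshots at
#' requested times. An optional stimulus applies a uniform current `I_app`
#' inside a disc during the reaction substeps of the given time window
#' (used to initiate an action potential); during plain tDCS runs
#' `I_app = 0`.
#'
#' @param mesh a [simplicial_mesh()].
#' @param conductivity a [build_conductivity()] field (defaults to the
#'   standard table on this mesh).
#' @param anode,cathode electrodes from [place_electrode()], or `NULL`.
#' @param params an [fhn_params()].
#' @param config a [solver_config()].
#' @param probes data frame with columns `name`, `x`, `y` (meters),
#'   `quantity` (`"v"` or `"phi"`); each probe is snapped to the nearest
#'   (brain) node and the snap distance recorded.
#' @param stimulus optional list `(center, radius, t_on, t_off, amplitude)`
#'   with center/radius in meters, window in seconds, amplitude in V/s.
#' @param snapshot_times numeric times (s) at which to store full `v` and
#'   `Phi` fields; matched to the nearest completed step.
#' @param chi,c_m membrane surface-to-volume ratio (1/m) and capacitance
#'   (F/m^2).
#' @return object of class `tdcs_simulation`: final `state`, `traces`
#'   (long data frame: `time`, `name`, `quantity`, `value`), `snapshots`
#'   (list of `v`/`phi` fields), probe metadata, CG iteration log, and the
#'   assembled `system`.
#' @export
run_simulation <- function(mesh, conductivity = build_conductivity(mesh),
                           anode = NULL, cathode = NULL,
                           params = fhn_params(), config = solver_config(),
                           probes = NULL, stimulus = NULL,
                           snapshot_times = numeric(0),
                           chi = 1.26e5, c_m = 1e-4) {
  system <- assemble_blocks(mesh, conductivity, chi = chi, c_m = c_m,
                            dt = config$dt_global)
  system <- apply_tdcs_bcs(system, anode, cathode)
  precond <- build_block_preconditioner(system, config$ilu_relaxation)
  state <- new_simulation_state(system, params)

  n_steps <- round(config$t_end / config$dt_global)
  prb <- resolve_probes(probes, mesh, system$vnodes)
  vmap <- match(seq_len(nrow(mesh$nodes)), system$vnodes)

  stim_vec <- 0
  if (!is.null(stimulus)) {
    nd <- mesh$nodes[system$vnodes, , drop = FALSE]
    inside <- (nd[, 1] - stimulus$center[1])^2 + (nd[, 2] - stimulus$center[2])^2 <=
      stimulus$radius^2
    stim_vec <- ifelse(inside, stimulus$amplitude, 0)
    if (!any(inside))
      warning("stimulus disc contains no brain nodes", call. = FALSE)
  }

  probe_value <- function(state, p) {
    if (p$quantity == "v") state$v[vmap[p$node]] else state$phi[p$node]
  }
  trace_rows <- function(state) {
    if (is.null(prb)) return(NULL)
    data.frame(time = state$t,
               name = vapply(prb, `[[`, "", "name"),
               quantity = vapply(prb, `[[`, "", "quantity"),
               value = vapply(prb, probe_value, numeric(1), state = state))
  }

  traces <- list(trace_rows(state))
  snapshots <- list()
  snap_steps <- if (length(snapshot_times))
    pmax(1L, pmin(n_steps, round(snapshot_times / config$dt_global))) else integer(0)

  for (s in seq_len(n_steps)) {
    t_start <- state$t
    ia <- 0
    if (!is.null(stimulus) &&
        t_start >= stimulus$t_on - 1e-12 && t_start < stimulus$t_off - 1e-12)
      ia <- stim_vec
    state <- tryCatch(
      godunov_step(state, system, params, config, precond, ia),
      error = function(e) {
        stop("simulation failed at step ", s, " (t = ", t_start, " s): ",
             conditionMessage(e), call. = FALSE)
      })
    traces[[length(traces) + 1L]] <- trace_rows(state)
    if (s %in% snap_steps) {
      snapshots[[length(snapshots) + 1L]] <-
        list(time = state$t, v = state$v, phi = state$phi)
    }
  }

  structure(list(state = state,
                 traces = if (!is.null(prb)) do.call(rbind, traces) else NULL,
                 probes = prb, snapshots = snapshots,
                 cg_iterations = state$cg_iterations,
                 system = system, mesh = mesh, params = params,
                 config = config),
            class = "tdcs_simulation")
}

#' @export
print.tdcs_simulation <- function(x, ...) {
  cat("<tdcs_simulation> t = ", x$state$t, " s (", x$state$step, " steps), ",
      length(x$system$vnodes), " brain nodes / ", x$system$n_nodes,
      " nodes\n", sep = "")
  if (length(x$cg_iterations))
    cat("  CG iterations/step: median ", stats::median(x$cg_iterations),
        ", max ", max(x$cg_iterations), "\n", sep = "")
  invisible(x)
}

#' Extract one probe's time series
#'
#' @param sim a [run_simulation()] result.
#' @param name probe name.
#' @return a `probe_trace`: list with `name`, `quantity`, `location`,
#'   `snap_distance`, `time` and `value` vectors.
#' @export
probe_trace <- function(sim, name) {
  if (is.null(sim$traces)) stop("simulation was run without probes")
  rows <- sim$traces[sim$traces$name == name, ]
  if (nrow(rows) == 0L) stop("no probe named '", name, "'")
  meta <- sim$probes[[which(vapply(sim$probes, `[[`, "", "name") == name)]]
  structure(list(name = name, quantity = meta$quantity,
                 location = meta$location, node_location = meta$node_location,
                 snap_distance = meta$snap_distance,
                 time = rows$time, value = rows$value),
            class = "probe_trace")
}
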