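#' Electric field from a nodal potential
#'
#' `E = -grad(Phi)`, constant per P1 element (exact for the interpolant of
#' any globally linear field).
#'
#' @param mesh a [simplicial_mesh()].
#' @param phi nodal potential (V).
#' @return `n_elements x 2` matrix of field vectors (V/m).
#' @export
electric_field <- function(mesh, phi) {
  if (length(phi) != nrow(mesh$nodes)) stop("phi must be nodal on the mesh")
  g <- p1_geometry(mesh, seq_len(nrow(mesh$elements)))
  el <- g$el
  ex <- -(g$b[, 1] * phi[el[, 1]] + g$b[, 2] * phi[el[, 2]] + g$b[, 3] * phi[el[, 3]])
  ey <- -(g$c[, 1] * phi[el[, 1]] + g$c[, 2] * phi[el[, 2]] + g$c[, 3] * phi[el[, 3]])
  cbind(Ex = ex, Ey = ey)
}

#' Current density from an electric field
#'
#' `J = M_e E` per element, using the extracellular conductivity tensor.
#' Across tissue interfaces the normal component of `J` is continuous while
#' `E` jumps by the conductivity ratio.
#'
#' @param E `n_elements x 2` field matrix from [electric_field()].
#' @param conductivity a [build_conductivity()] field (its `M_e` is used),
#'   or an `n_elements x 3` tensor matrix.
#' @return `n_elements x 2` matrix of current density vectors (A/m^2).
#' @export
current_density <- function(E, conductivity) {
  M <- if (inherits(conductivity, "conductivity_field")) conductivity$M_e
       else as.matrix(conductivity)
  if (nrow(M) != nrow(E)) stop("conductivity and field are not congruent")
  cbind(Jx = M[, 1] * E[, 1] + M[, 2] * E[, 2],
        Jy = M[, 2] * E[, 1] + M[, 3] * E[, 2])
}

#' Action potential sensitivity (%)
#'
#' How far the membrane has depolarized from rest toward threshold,
#' as a percentage:
#' \deqn{\mathrm{AP\ sensitivity} = \frac{v_{rest} - v}{v_{rest} - v_{th}}
#'   \times 100\%.}
#' 0% at rest, 100% at threshold; affine in `v`.
#'
#' @param v transmembrane voltage (V), any shape.
#' @param params an [fhn_params()].
#' @return sensitivity values in percent, same shape as `v`.
#' @export
ap_sensitivity <- function(v, params) {
  vth <- threshold_voltage(params)
  if (params$v_rest == vth)
    stop("v_rest equals v_th: sensitivity undefined (division by zero)")
  (params$v_rest - v) / (params$v_rest - vth) * 100
}

# first upward crossing time of a threshold, linearly interpolated
first_upcrossing <- function(time, value, threshold) {
  below <- value < threshold
  idx <- which(below[-length(below)] & !below[-1L])
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  t0 <- time[i]; t1 <- time[i + 1L]
  v0 <- value[i]; v1 <- value[i + 1L]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Conduction velocity from two transmembrane voltage probes
#'
#' Distance between the probes divided by the difference of their first
#' upward threshold-crossing times, each linearly interpolated between the
#' bracketing samples. Invariant to a common time shift of both traces.
#'
#' @param trace_a,trace_b `probe_trace` objects (quantity `"v"`) from
#'   [probe_trace()], in propagation order (the wave reaches `trace_a`
#'   first).
#' @param params an [fhn_params()] supplying the threshold voltage.
#' @return conduction speed (m/s).
#' @export
conduction_velocity <- function(trace_a, trace_b, params = fhn_params()) {
  vth <- threshold_voltage(params)
  ta <- first_upcrossing(trace_a$time, trace_a$value, vth)
  tb <- first_upcrossing(trace_b$time, trace_b$value, vth)
  if (is.na(ta))
    stop("probe '", trace_a$name, "' never crossed the threshold voltage")
  if (is.na(tb))
    stop("probe '", trace_b$name, "' never crossed the threshold voltage")
  if (tb == ta)
    stop("probes crossed threshold simultaneously: zero time difference")
  # measure between the mesh nodes the probes snapped to, when known
  pa <- if (!is.null(trace_a$node_location)) trace_a$node_location else trace_a$location
  pb <- if (!is.null(trace_b$node_location)) trace_b$node_location else trace_b$location
  dist <- sqrt(sum((pa - pb)^2))
  dist / (tb - ta)
}
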