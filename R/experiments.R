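#' Packaged two-dimensional experiment specifications
#'
#' Config-driven reproductions of the simulator's two benchmark settings on
#' the five-tissue annulus phantom: action potential conduction without
#' electrodes, and direct-current stimulation with paired Laplace
#' validation. Specifications are plain serializable lists; nothing is
#' downloaded or read from disk.
#'
#' @name experiments
NULL

default_phi_probes <- function() {
  data.frame(name = c("center", "east", "west", "north", "south"),
             x = c(0, 0.1, -0.1, 0, 0),
             y = c(0, 0, 0, 0.1, -0.1),
             quantity = "phi", stringsAsFactors = FALSE)
}

#' Action-potential conduction experiment
#'
#' An action potential is initiated in a 2.5 mm radius disc centered at
#' (0, -25) mm by an applied current during the first 10 ms; total
#' simulated time 100 ms; no electrodes (the whole scalp is insulated,
#' homogeneous Neumann). Probes: two transmembrane-voltage probes on the
#' vertical axis below the CSF channel for conduction-velocity
#' measurement, and potential probes at the domain center and the four
#' points where the scalp meets the Cartesian axes.
#'
#' The stimulus amplitude is not a physiological constant of the model; the
#' default (200 V/s) is the smallest round amplitude for which the ignited
#' wave traverses both velocity probes at the reference resolution of
#' 10,000 triangles. (Much larger amplitudes destabilize the 0.5 ms Heun
#' substep and are not usable.)
#'
#' @param target_element_count phantom resolution (triangles).
#' @param t_end total simulated time (s).
#' @param stimulus_amplitude applied current in the initiation disc (V/s).
#' @return an `experiment_spec`.
#' @export
experiment_ap_conduction <- function(target_element_count = 10000,
                                     t_end = 0.1,
                                     stimulus_amplitude = 200) {
  probes <- rbind(
    data.frame(name = c("v_lower", "v_upper"),
               x = c(0, 0), y = c(-0.020, -0.015),
               quantity = "v", stringsAsFactors = FALSE),
    default_phi_probes())
  structure(list(
    name = "ap_conduction",
    mesh = list(radii = c(40, 50, 70, 90, 100), csf_strip_width = 10,
                target_element_count = target_element_count),
    electrodes = NULL,
    stimulus = list(center = c(0, -0.025), radius = 0.0025,
                    t_on = 0, t_off = 0.010, amplitude = stimulus_amplitude),
    solver = list(dt_global = 1e-3, dt_ode = 0.5e-3, t_end = t_end,
                  cg_rel_tol = 1e-8, ilu_relaxation = 0.5),
    cell = list(),        # fhn_params() defaults
    chi = 1.26e5, c_m = 1e-4,
    probes = probes,
    snapshot_every = 1e-3,
    compare_laplace = FALSE), class = "experiment_spec")
}

#' Direct-current stimulation experiments
#'
#' Two electrode configurations on the phantom, both with 10 mm
#' electrodes and 1.0 mA anode current, no applied membrane stimulus,
#' 100 ms duration. Configuration 1: anode at (-100, 0) (angle pi),
#' cathode at (70.7, 70.7) (angle pi/4). Configuration 2: anode at
#' (-70.7, 70.7) (angle 3pi/4), cathode at (0, -100) (angle 3pi/2). A
#' Laplace volume-conductor run with identical electrodes is paired for
#' comparison.
#'
#' @param config_id 1 or 2.
#' @param target_element_count phantom resolution (triangles).
#' @param t_end total simulated time (s).
#' @return an `experiment_spec`.
#' @export
experiment_tdcs <- function(config_id = 1, target_element_count = 10000,
                            t_end = 0.1) {
  if (!config_id %in% c(1, 2)) stop("config_id must be 1 or 2")
  ang <- if (config_id == 1) c(anode = pi, cathode = pi / 4)
         else c(anode = 3 * pi / 4, cathode = 3 * pi / 2)
  structure(list(
    name = paste0("tdcs_config", config_id),
    mesh = list(radii = c(40, 50, 70, 90, 100), csf_strip_width = 10,
                target_element_count = target_element_count),
    electrodes = list(
      anode = list(center_angle = unname(ang["anode"]), arc_length = 10,
                   total_current = 1e-3),
      cathode = list(center_angle = unname(ang["cathode"]), arc_length = 10)),
    stimulus = NULL,
    solver = list(dt_global = 1e-3, dt_ode = 0.5e-3, t_end = t_end,
                  cg_rel_tol = 1e-8, ilu_relaxation = 0.5),
    cell = list(),
    chi = 1.26e5, c_m = 1e-4,
    probes = default_phi_probes(),
    snapshot_every = 1e-3,
    compare_laplace = TRUE), class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("<experiment_spec> ", x$name, ": ", x$mesh$target_element_count,
      " target elements, t_end = ", x$solver$t_end, " s",
      if (!is.null(x$electrodes)) ", tDCS electrodes",
      if (!is.null(x$stimulus)) ", AP stimulus", "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize an experiment specification (YAML)
#'
#' @param spec an `experiment_spec`.
#' @param path file path.
#' @return `read_experiment()` returns the `experiment_spec`.
#' @export
write_experiment <- function(spec, path) {
  lst <- unclass(spec)
  lst$probes <- as.list(lst$probes)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$probes <- as.data.frame(lst$probes, stringsAsFactors = FALSE)
  if (!is.null(lst$stimulus$center)) lst$stimulus$center <- as.numeric(lst$stimulus$center)
  if (!is.null(lst$mesh$radii)) lst$mesh$radii <- as.numeric(lst$mesh$radii)
  structure(lst, class = "experiment_spec")
}

validate_experiment <- function(spec) {
  need <- c("name", "mesh", "solver", "chi", "c_m")
  missing <- need[!need %in% names(spec)]
  if (length(missing))
    stop("experiment spec is missing field(s): ", paste(missing, collapse = ", "))
  mneed <- c("radii", "csf_strip_width", "target_element_count")
  mmiss <- mneed[!mneed %in% names(spec$mesh)]
  if (length(mmiss))
    stop("experiment mesh parameters missing: ", paste(mmiss, collapse = ", "))
  invisible(spec)
}

#' Run a packaged experiment
#'
#' Builds the phantom, runs the multiscale simulation (and, for tDCS
#' specs, the paired Laplace reference), computes the experiment's summary
#' quantities, and optionally writes a deterministic artifact directory
#' (spec YAML, VTK snapshot, probe CSV, summary JSON).
#'
#' Summary fields: for the conduction experiment, the measured conduction
#' velocity (m/s), probe threshold-crossing times, and the maximum scalp
#' |Phi| over time; for tDCS, the multiscale-vs-Laplace relative L2
#' differences (domain and scalp boundary, at 1 ms and at the final
#' stabilized time), the quasi-static drift max_t |Phi(t) - Phi(1ms)| /
#' max|Phi|, and the maximum scalp |Phi|.
#'
#' @param spec an `experiment_spec`.
#' @param output_dir optional directory for artifacts.
#' @return list with `simulation`, `laplace` (or `NULL`), `summary`
#'   (named list of scalars), `mesh`.
#' @export
run_experiment <- function(spec, output_dir = NULL) {
  validate_experiment(spec)
  mesh <- build_annulus_phantom(radii = spec$mesh$radii,
                                csf_strip_width = spec$mesh$csf_strip_width,
                                target_element_count = spec$mesh$target_element_count)
  cond <- build_conductivity(mesh)
  params <- do.call(fhn_params, spec$cell)
  config <- do.call(solver_config, spec$solver)
  anode <- cathode <- NULL
  if (!is.null(spec$electrodes)) {
    anode <- place_electrode(mesh, "ANODE",
                             center_angle = spec$electrodes$anode$center_angle,
                             arc_length = spec$electrodes$anode$arc_length,
                             total_current = spec$electrodes$anode$total_current)
    cathode <- place_electrode(mesh, "CATHODE",
                               center_angle = spec$electrodes$cathode$center_angle,
                               arc_length = spec$electrodes$cathode$arc_length)
  }
  snap_times <- seq(spec$snapshot_every, config$t_end, by = spec$snapshot_every)
  sim <- run_simulation(mesh, cond, anode, cathode, params, config,
                        probes = spec$probes, stimulus = spec$stimulus,
                        snapshot_times = snap_times,
                        chi = spec$chi, c_m = spec$c_m)

  boundary_nodes <- sort(unique(as.vector(mesh$boundary_facets)))
  snap_t <- vapply(sim$snapshots, `[[`, numeric(1), "time")
  # scalp potential magnitude: with a grounded cathode the reference is
  # physical; without electrodes the potential is defined only up to a
  # constant, so scalp values are reported in the average-reference gauge
  # (the EEG convention)
  avg_ref <- is.null(spec$electrodes)
  scalp_abs_phi <- function(keep)
    max(vapply(sim$snapshots[keep], function(s) {
      b <- s$phi[boundary_nodes]
      if (avg_ref) b <- b - mean(b)
      max(abs(b))
    }, numeric(1)))

  summary <- list(name = spec$name, n_elements = nrow(mesh$elements),
                  max_scalp_abs_phi = scalp_abs_phi(seq_along(snap_t)),
                  median_cg_iterations = as.numeric(stats::median(sim$cg_iterations)))

  laplace <- NULL
  if (!is.null(spec$stimulus)) {
    tr_a <- probe_trace(sim, "v_lower")
    tr_b <- probe_trace(sim, "v_upper")
    cv <- tryCatch(conduction_velocity(tr_a, tr_b, params), error = function(e) NA_real_)
    vth <- threshold_voltage(params)
    summary$conduction_velocity <- cv
    summary$crossing_time_lower <- first_upcrossing(tr_a$time, tr_a$value, vth)
    summary$crossing_time_upper <- first_upcrossing(tr_b$time, tr_b$value, vth)
    # potential generated by the propagating wave itself, excluding the
    # artificial current-injection transient
    post <- which(snap_t > spec$stimulus$t_off + 1e-12)
    if (length(post)) summary$max_scalp_abs_phi_postdrive <- scalp_abs_phi(post)
  }
  if (isTRUE(spec$compare_laplace)) {
    laplace <- solve_laplace(mesh, cond, anode, cathode,
                             rel_tol = config$cg_rel_tol)
    at <- function(tt) sim$snapshots[[which.min(abs(snap_t - tt))]]$phi
    phi_1ms <- at(1e-3)
    phi_end <- sim$snapshots[[length(sim$snapshots)]]$phi
    summary$laplace_l2_domain_1ms <- compare_fields(phi_1ms, laplace$phi, mesh)
    if (config$t_end >= 25e-3)
      summary$laplace_l2_domain_25ms <- compare_fields(at(25e-3), laplace$phi, mesh)
    summary$laplace_l2_domain_end <- compare_fields(phi_end, laplace$phi, mesh)
    summary$laplace_l2_boundary_end <- compare_fields(phi_end, laplace$phi, mesh,
                                                      region = "boundary")
    phimax <- max(vapply(sim$snapshots, function(s) max(abs(s$phi)), numeric(1)))
    drift <- max(vapply(sim$snapshots, function(s) max(abs(s$phi - phi_1ms)),
                        numeric(1)))
    summary$quasistatic_drift <- drift / phimax
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_experiment(spec, file.path(output_dir, "experiment.yaml"))
    export_probes_csv(sim$traces, file.path(output_dir, "probes.csv"))
    last <- sim$snapshots[[length(sim$snapshots)]]
    E <- electric_field(mesh, last$phi)
    J <- current_density(E, cond)
    export_vtk(mesh, file.path(output_dir, "final_state.vtk"),
               point_data = list(phi = last$phi, v = last$v,
                                 sensitivity = ap_sensitivity(
                                   pad_brain_field(mesh, last$v), params)),
               cell_data = list(J = J, J_mag = sqrt(rowSums(J^2))))
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(simulation = sim, laplace = laplace, summary = summary, mesh = mesh)
}

#' Electrode montage templates for user-supplied head meshes
#'
#' Three standard scalp electrode montages, named by the international
#' 10-20 system, as inert configuration templates. Running them requires a
#' user-supplied tagged 3D head mesh and (for anisotropic brain tissue)
#' per-element conductivity tensors, neither of which this package
#' generates; the templates document the intended configurations and the
#' regions they target. The 2D phantom experiments are the package's
#' runnable surface.
#'
#' @return list of montage descriptions (anode, cathodes, target region,
#'   electrode area in cm^2, current in A).
#' @export
montage_templates <- function() {
  list(
    montage1 = list(anode = "C3", cathodes = "C4",
                    target = "motor cortex ipsilateral to anode",
                    electrode_area_cm2 = 25, total_current = 1e-3),
    montage2 = list(anode = "C3", cathodes = "Fp2",
                    target = "motor cortex ipsilateral to anode",
                    electrode_area_cm2 = 25, total_current = 1e-3),
    montage3 = list(anode = "forehead (symmetric)",
                    cathodes = c("left mastoid", "right mastoid"),
                    target = "motor cortex; subthalamic nucleus and substantia nigra",
                    electrode_area_cm2 = 25, total_current = 1e-3))
}

#' Pad a brain-node field to all mesh nodes
#'
#' Values outside the brain are set to the sentinel `NaN`.
#' @param mesh a [simplicial_mesh()].
#' @param values vector over [brain_nodes()].
#' @export
pad_brain_field <- function(mesh, values) {
  bn <- brain_nodes(mesh)
  if (length(values) != length(bn)) stop("values must match brain_nodes(mesh)")
  out <- rep(NaN, nrow(mesh$nodes))
  out[bn] <- values
  out
}
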