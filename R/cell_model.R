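#' FitzHugh-Nagumo membrane parameters
#'
#' Two-variable membrane kinetics: a cubic voltage nullcline plus a slow
#' linear recovery variable `w`. With the default constants (`a = 0.13`,
#' `b = 13` 1/s, `c1 = 260` 1/s, `c2 = 100` 1/s, `c3 = 1`) the model is the
#' classic dimensionless FitzHugh/Rogers-McCulloch parameter set with time
#' scaled to seconds and voltage mapped onto the physiological range
#' `v_rest = -70 mV` to `v_peak = +40 mV`.
#'
#' The voltage equation is
#' \deqn{dv/dt = c_1 v_{amp}^{-2} (v - v_{rest})(v - v_{th})(v_{peak} - v)
#'   - R(v, w) + I_{app}}
#' with threshold \eqn{v_{th} = v_{rest} + a\, v_{amp}},
#' \eqn{v_{amp} = v_{peak} - v_{rest}}, and recovery
#' \deqn{dw/dt = b (v - v_{rest} - c_3 w).}
#'
#' Two couplings of the recovery variable into the voltage equation are
#' supported. The default, `recovery = "rogers_mcculloch"`, uses
#' \eqn{R = c_2 (v - v_{rest}) w / v_{amp}}, the standard dimensionalization
#' of this parameter set; it supports sustained propagating action
#' potentials in tissue. `recovery = "linear"` uses the simpler
#' \eqn{R = c_2 w}, which yields a decremental (self-extinguishing) wave
#' under the same constants and is retained for comparison. Both have the
#' same resting fixed point `(v_rest, 0)` and identical voltage nullcline
#' structure at `w = 0`.
#'
#' @param a dimensionless threshold parameter in (0, 1).
#' @param b recovery rate (1/s).
#' @param c1 excitation rate constant (1/s; the cubic carries an explicit
#'   `1/v_amp^2` so `c1` keeps its dimensionless-model value).
#' @param c2 recovery coupling strength (1/s).
#' @param c3 dimensionless recovery self-decay coefficient.
#' @param v_rest,v_peak resting and peak transmembrane voltage (V).
#' @param recovery recovery coupling form, see Details.
#' @return object of class `fhn_params`.
#' @examples
#' p <- fhn_params()
#' threshold_voltage(p)  # -0.0557 V
#' @export
fhn_params <- function(a = 0.13, b = 13.0, c1 = 260.0, c2 = 100.0, c3 = 1.0,
                       v_rest = -0.07, v_peak = 0.04,
                       recovery = c("rogers_mcculloch", "linear")) {
  recovery <- match.arg(recovery)
  if (v_peak <= v_rest) stop("v_peak must exceed v_rest")
  if (a < 0 || a > 1) stop("a must lie in [0, 1]")
  structure(list(a = a, b = b, c1 = c1, c2 = c2, c3 = c3,
                 v_rest = v_rest, v_peak = v_peak, recovery = recovery),
            class = "fhn_params")
}

#' @export
print.fhn_params <- function(x, ...) {
  cat("<fhn_params> a=", x$a, " b=", x$b, " c1=", x$c1, " c2=", x$c2,
      " c3=", x$c3, "\n  v_rest=", x$v_rest, " V, v_peak=", x$v_peak,
      " V, v_th=", threshold_voltage(x), " V, recovery=", x$recovery,
      "\n", sep = "")
  invisible(x)
}

#' Peak-to-rest voltage amplitude (V)
#' @param params an [fhn_params()]
#' @export
v_amplitude <- function(params) params$v_peak - params$v_rest

#' Membrane threshold voltage (V)
#'
#' `v_th = v_rest + a * (v_peak - v_rest)`: the voltage above which the
#' cubic drives the membrane toward `v_peak` rather than back to rest.
#'
#' @param params an [fhn_params()]
#' @examples
#' threshold_voltage(fhn_params())  # -55.7 mV
#' @export
threshold_voltage <- function(params) {
  params$v_rest + params$a * v_amplitude(params)
}

#' FitzHugh-Nagumo right-hand side
#'
#' Vectorized over nodes: `v`, `w` and `i_app` may be vectors of equal
#' length (or `i_app` scalar).
#'
#' @param v transmembrane voltage (V).
#' @param w recovery variable (V).
#' @param params an [fhn_params()].
#' @param i_app applied current source term (V/s); scalar or per-node.
#' @return list with components `dv` and `dw` (V/s).
#' @export
fhn_rhs <- function(v, w, params, i_app = 0) {
  vr <- params$v_rest; vp <- params$v_peak
  vamp <- vp - vr
  vth <- vr + params$a * vamp
  cubic <- params$c1 / vamp^2 * (v - vr) * (v - vth) * (vp - v)
  rec <- if (params$recovery == "linear") params$c2 * w
         else params$c2 * (v - vr) / vamp * w
  list(dv = cubic - rec + i_app,
       dw = params$b * (v - vr - params$c3 * w))
}

#' One Heun (explicit trapezoidal) step of the membrane ODEs
#'
#' Predictor-corrector step applied nodewise:
#' `y* = y + dt f(y)`, `y_{n+1} = y + dt/2 (f(y) + f(y*))`.
#'
#' @param v,w state vectors (V).
#' @param params an [fhn_params()].
#' @param i_app applied current (V/s), held constant over the step.
#' @param dt step size (s), positive.
#' @return list with updated `v` and `w`.
#' @export
heun_step <- function(v, w, params, i_app = 0, dt) {
  if (dt <= 0) stop("dt must be positive")
  k1 <- fhn_rhs(v, w, params, i_app)
  vs <- v + dt * k1$dv
  ws <- w + dt * k1$dw
  k2 <- fhn_rhs(vs, ws, params, i_app)
  list(v = v + dt / 2 * (k1$dv + k2$dv),
       w = w + dt / 2 * (k1$dw + k2$dw))
}

#' Sub-stepped ODE integration over one global time step
#'
#' The reaction step of the operator splitting: advances the membrane state
#' by `dt_global` using Heun steps of size `dt_ode`. `dt_ode` must divide
#' `dt_global` (to within rounding); with the defaults of 1 ms and 0.5 ms
#' this is exactly two Heun substeps per global step.
#'
#' @inheritParams heun_step
#' @param dt_global global (PDE) time step (s).
#' @param dt_ode ODE substep (s), `<= dt_global`.
#' @return list with updated `v` and `w`.
#' @export
ode_substep_loop <- function(v, w, params, i_app = 0, dt_global, dt_ode = dt_global) {
  if (dt_ode > dt_global) stop("dt_ode must not exceed dt_global")
  nsub <- round(dt_global / dt_ode)
  if (abs(nsub * dt_ode - dt_global) > 1e-9 * dt_global)
    stop("dt_ode must divide dt_global")
  for (s in seq_len(nsub)) {
    st <- heun_step(v, w, params, i_app, dt_ode)
    v <- st$v; w <- st$w
  }
  list(v = v, w = w)
}
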