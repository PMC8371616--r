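#' Single-compartment lung model
#'
#' Defines the simulated patient as a linear one-compartment system: a single
#' compliance `C` filled and emptied through phase-dependent airway
#' resistances (`r_insp` during inflow, `r_exp` during outflow). Pressures
#' obey the equation of motion
#' \deqn{p_{aw}(t) = V(t)/C + PEEP + p_{mus}(t) + R(q)\,q(t)}
#' with volume `V` referenced to functional residual capacity (FRC), flow `q`
#' positive into the lung, and `p_mus` the (negative) spontaneous muscle
#' pressure.
#'
#' @param compliance lung compliance in mL/cmH2O (> 0).
#' @param r_insp inspiratory resistance in cmH2O/(L/s) (> 0). Endotracheal
#'   tube resistance is folded into this value, not modelled separately.
#' @param r_exp expiratory resistance in cmH2O/(L/s) (> 0).
#' @param label short name used in reports.
#' @return an object of class `lung_model`.
#' @seealso [lung_presets()] for the four bundled test-lung configurations.
#' @examples
#' normal <- lung_model(50, 6, 6, "NORMAL")
#' normal$compliance * 10   # volume stored per 10 cmH2O of driving pressure
#' @export
lung_model <- function(compliance, r_insp, r_exp, label = "custom") {
  if (!is.numeric(compliance) || length(compliance) != 1L || !is.finite(compliance) || compliance <= 0)
    stop("`compliance` must be a single positive number (mL/cmH2O)")
  if (!is.numeric(r_insp) || !is.finite(r_insp) || r_insp <= 0)
    stop("`r_insp` must be a single positive number (cmH2O/(L/s))")
  if (!is.numeric(r_exp) || !is.finite(r_exp) || r_exp <= 0)
    stop("`r_exp` must be a single positive number (cmH2O/(L/s))")
  structure(
    list(compliance = as.numeric(compliance), r_insp = as.numeric(r_insp),
         r_exp = as.numeric(r_exp), label = as.character(label)),
    class = "lung_model"
  )
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf("<lung_model> %s: C = %g mL/cmH2O, R_insp = %g, R_exp = %g cmH2O/(L/s)\n",
              x$label, x$compliance, x$r_insp, x$r_exp))
  invisible(x)
}

#' Bundled test-lung presets
#'
#' The four reference lung configurations used throughout the verification
#' suite: a normal adult lung and three ARDS severities of decreasing
#' compliance and increasing resistance.
#'
#' @param name optional preset name (`"NORMAL"`, `"ARDS1"`, `"ARDS2"`,
#'   `"ARDS3"`, case-insensitive). When omitted, the full named list is
#'   returned.
#' @return a `lung_model`, or a named list of all four.
#' @examples
#' lung_presets("ARDS3")
#' names(lung_presets())
#' @export
lung_presets <- function(name = NULL) {
  presets <- list(
    NORMAL = lung_model(50, 6, 6, "NORMAL"),
    ARDS1  = lung_model(30, 6, 6, "ARDS1"),
    ARDS2  = lung_model(30, 11, 16, "ARDS2"),
    ARDS3  = lung_model(10, 20, 20, "ARDS3")
  )
  if (is.null(name)) return(presets)
  key <- toupper(name)
  if (!key %in% names(presets))
    stop("unknown lung preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[key]]
}

#' Spontaneous muscle-effort pattern
#'
#' Describes periodic inspiratory muscle effort as a half-sinusoidal pressure
#' profile: within each cycle of length `60/rate` seconds the muscle pressure
#' falls sinusoidally from 0 to `-p_max` over the inspiratory fraction of the
#' cycle, then releases back to 0 along a quarter-cosine over the release
#' fraction, and stays at 0 for the remainder.
#'
#' @param rate patient respiratory rate, breaths per minute.
#' @param p_max magnitude of the maximal negative muscle pressure, cmH2O
#'   (>= 0).
#' @param insp_frac inspiratory fraction of the cycle (default 0.20).
#' @param release_frac expiratory release fraction of the cycle
#'   (default 0.15). `insp_frac + release_frac` must be < 1.
#' @param active logical; an inactive pattern produces zero pressure
#'   everywhere (a fully passive patient).
#' @return an object of class `muscle_pattern`.
#' @examples
#' spont <- muscle_pattern(rate = 30, p_max = 5)
#' muscle_pressure(0.4, spont)  # peak effort at end of the inspiratory ramp
#' @export
muscle_pattern <- function(rate = 15, p_max = 0, insp_frac = 0.20,
                           release_frac = 0.15, active = p_max > 0) {
  if (!is.numeric(p_max) || !is.finite(p_max) || p_max < 0)
    stop("`p_max` must be a non-negative number (cmH2O)")
  if (insp_frac <= 0 || release_frac <= 0 || insp_frac + release_frac >= 1)
    stop("configuration error: need insp_frac > 0, release_frac > 0 and insp_frac + release_frac < 1")
  if (active && (!is.finite(rate) || rate <= 0))
    stop("`rate` must be > 0 for an active pattern")
  structure(
    list(rate = as.numeric(rate), p_max = as.numeric(p_max),
         insp_frac = as.numeric(insp_frac), release_frac = as.numeric(release_frac),
         active = isTRUE(active)),
    class = "muscle_pattern"
  )
}

#' Passive patient shorthand
#' @return an inactive [muscle_pattern()] (zero muscle pressure).
#' @export
passive_patient <- function() muscle_pattern(rate = 15, p_max = 0, active = FALSE)

#' @export
print.muscle_pattern <- function(x, ...) {
  if (!x$active) cat("<muscle_pattern> passive (no spontaneous effort)\n")
  else cat(sprintf("<muscle_pattern> %g brpm, Pmus,max = -%g cmH2O, insp %g%% / release %g%% of cycle\n",
                   x$rate, x$p_max, 100 * x$insp_frac, 100 * x$release_frac))
  invisible(x)
}

#' Muscle pressure at a point in the breathing cycle
#'
#' Evaluates the half-sinusoidal effort profile. With `Ti = insp_frac * T` and
#' `Tr = release_frac * T` (cycle period `T = 60/rate`):
#' \itemize{
#'   \item `[0, Ti)`: `-p_max * sin(pi * t / (2 Ti))` (sinusoidal descent),
#'   \item `[Ti, Ti+Tr)`: `-p_max * cos(pi * (t - Ti) / (2 Tr))` (release),
#'   \item afterwards 0.
#' }
#' The profile is continuous everywhere and attains its minimum `-p_max`
#' exactly at `t = Ti`.
#'
#' @param t_in_cycle time since cycle start, seconds; vectorised. Values are
#'   wrapped into the cycle period.
#' @param pattern a [muscle_pattern()].
#' @return muscle pressure in cmH2O (<= 0).
#' @export
muscle_pressure <- function(t_in_cycle, pattern) {
  stopifnot(inherits(pattern, "muscle_pattern"))
  if (any(!is.finite(t_in_cycle))) stop("`t_in_cycle` must be finite")
  if (!pattern$active || pattern$p_max == 0) return(numeric(length(t_in_cycle)) + 0)
  period <- 60 / pattern$rate
  t <- t_in_cycle %% period
  ti <- pattern$insp_frac * period
  tr <- pattern$release_frac * period
  p <- numeric(length(t))
  rise <- t < ti
  rel <- !rise & t < ti + tr
  p[rise] <- -pattern$p_max * sin(pi * t[rise] / (2 * ti))
  p[rel] <- -pattern$p_max * cos(pi * (t[rel] - ti) / (2 * tr))
  p
}

#' Lung state
#'
#' Instantaneous state of the simulated lung: volume above FRC, alveolar
#' pressure, muscle pressure and simulation time.
#'
#' @param volume mL above FRC (>= 0).
#' @param p_alv alveolar pressure, cmH2O.
#' @param p_mus muscle pressure, cmH2O.
#' @param t time, seconds.
#' @return a `lung_state` list.
#' @export
lung_state <- function(volume = 0, p_alv = 0, p_mus = 0, t = 0) {
  structure(list(volume = volume, p_alv = p_alv, p_mus = p_mus, t = t,
                 clamped = FALSE),
            class = "lung_state")
}

#' Advance the lung by one integration step
#'
#' Explicit-Euler update of the single-compartment model over `dt`:
#' volume integrates the (signed) flow, muscle pressure is re-evaluated from
#' the effort pattern at the new time, and alveolar pressure follows the
#' quasi-static identity `p_alv = V/C + PEEP + p_mus`. A negative volume
#' (which the PEEP/check valves prevent in hardware) is clamped to 0 and
#' flagged in the returned state.
#'
#' @param state a [lung_state()].
#' @param q_in flow into the lung, L/s (signed, positive = inflation).
#' @param peep_applied applied PEEP baseline, cmH2O.
#' @param dt step, seconds; must satisfy `0 < dt <= 0.005`.
#' @param model a [lung_model()].
#' @param pattern a [muscle_pattern()] (default passive).
#' @return the updated `lung_state`.
#' @seealso [airway_pressure()] for the pressure at the airway opening.
#' @export
lung_step <- function(state, q_in, peep_applied, dt, model,
                      pattern = passive_patient()) {
  if (!is.finite(dt) || dt <= 0 || dt > 0.005)
    stop("`dt` must satisfy 0 < dt <= 0.005 s")
  if (!all(is.finite(c(state$volume, state$t, q_in, peep_applied))))
    stop("non-finite lung state or inputs")
  v <- state$volume + q_in * dt * 1000
  clamped <- v < 0
  if (clamped) v <- 0
  t <- state$t + dt
  p_mus <- if (pattern$active) muscle_pressure(t, pattern) else 0
  p_alv <- v / model$compliance + peep_applied + p_mus
  structure(list(volume = v, p_alv = p_alv, p_mus = p_mus, t = t,
                 clamped = clamped),
            class = "lung_state")
}

#' Pressure at the airway opening
#'
#' Adds the resistive drop across the airways to the alveolar pressure:
#' `p_aw = p_alv + R(q) * q`, with the inspiratory resistance used for inflow
#' (`q >= 0`) and the expiratory resistance for outflow.
#'
#' @param p_alv alveolar pressure, cmH2O.
#' @param q_in signed flow, L/s.
#' @param model a [lung_model()].
#' @return airway pressure in cmH2O; vectorised over `p_alv`/`q_in`.
#' @export
airway_pressure <- function(p_alv, q_in, model) {
  r <- ifelse(q_in >= 0, model$r_insp, model$r_exp)
  p_alv + r * q_in
}
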