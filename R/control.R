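#' Ventilator settings
#'
#' The controllable parameters of the ventilator: operating mode, mandatory
#' respiratory rate, inspiratory time, the volume limit (volume-controlled
#' mode), the software maximum-pressure guard, the assist trigger threshold
#' and the low-PEEP warning threshold.
#'
#' The trigger threshold is compared against the *absolute* airway pressure
#' gauge reading, not against PEEP.
#'
#' @param mode `"VC_AC"` (volume-controlled assist control) or `"PC_AC"`
#'   (pressure-controlled assist control).
#' @param rr_set mandatory respiratory rate, breaths/min (integer steps).
#' @param t_insp inspiratory time, seconds; must be < `60/rr_set`.
#' @param max_volume tidal-volume target/limit, mL (VC-AC setpoint; volume
#'   alarms reference it in both modes).
#' @param max_pressure software maximum-pressure guard, cmH2O; reaching it
#'   halts bag compression for the remainder of the cycle.
#' @param trigger_threshold absolute assist trigger threshold, cmH2O.
#' @param peep_min low-PEEP warning threshold, cmH2O.
#' @param run_enable master run flag; when `FALSE` the drive never moves and
#'   the device only monitors.
#' @return an object of class `vent_settings`.
#' @export
vent_settings <- function(mode = c("VC_AC", "PC_AC"), rr_set = 20,
                          t_insp = 1.0, max_volume = 400, max_pressure = 40,
                          trigger_threshold = 3, peep_min = 2,
                          run_enable = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(rr_set), rr_set > 0, is.numeric(t_insp), t_insp > 0,
            max_volume > 0, max_pressure > 0, trigger_threshold >= 0,
            peep_min >= 0)
  if (abs(rr_set - round(rr_set)) > 1e-9)
    warning("rr_set is set in increments of 1 brpm; got ", rr_set)
  if (t_insp >= 60 / rr_set)
    stop("t_insp (", t_insp, " s) must be shorter than the breath period ",
         60 / rr_set, " s")
  structure(
    list(mode = mode, rr_set = as.numeric(rr_set), t_insp = as.numeric(t_insp),
         max_volume = as.numeric(max_volume),
         max_pressure = as.numeric(max_pressure),
         trigger_threshold = as.numeric(trigger_threshold),
         peep_min = as.numeric(peep_min), run_enable = isTRUE(run_enable)),
    class = "vent_settings"
  )
}

#' @export
print.vent_settings <- function(x, ...) {
  cat(sprintf("<vent_settings> %s, RR %g brpm, Ti %g s, Vmax %g mL, Pmax %g cmH2O, trigger %g cmH2O%s\n",
              x$mode, x$rr_set, x$t_insp, x$max_volume, x$max_pressure,
              x$trigger_threshold, if (x$run_enable) "" else " [disabled]"))
  invisible(x)
}

# Refractory window after RELEASE begins during which the assist trigger is
# ignored, to avoid re-triggering on the exhalation transient.
TRIGGER_REFRACTORY_S <- 0.2

# shared zero-row event frame; controller_step runs at 100 Hz so avoid
# rebuilding it every tick
.empty_events <- data.frame(t = numeric(0), type = character(0),
                            detail = character(0), stringsAsFactors = FALSE)

#' Initial controller state
#'
#' @param settings a [vent_settings()].
#' @param t0 simulation time at initialisation.
#' @return a `controller_state` list. The adaptive volume setpoint starts at
#'   the set maximum volume.
#' @export
controller_init <- function(settings, t0 = 0) {
  structure(
    list(phase = "RELEASE", t_in_breath = 0, integrated_volume = 0,
         adaptive_setpoint = settings$max_volume,
         last_breath_start = -Inf, release_start = -Inf,
         halted_this_cycle = FALSE, breath_count = 0L,
         delivered_last = NA_real_, low_pressure_run = 0),
    class = "controller_state"
  )
}

#' Assist-trigger test
#'
#' A patient breath is triggered when, during RELEASE and outside the 200 ms
#' post-release refractory window, the airway pressure falls strictly below
#' the (absolute) trigger threshold. Efforts during COMPRESS or HOLD never
#' trigger.
#'
#' @param p_aw measured airway pressure, cmH2O.
#' @param settings a [vent_settings()].
#' @param state a controller state (uses `phase` and `release_start`).
#' @param t current time, seconds (defaults to a time safely past the
#'   refractory window for direct unit use).
#' @return logical.
#' @export
check_trigger <- function(p_aw, settings, state,
                          t = state$release_start + TRIGGER_REFRACTORY_S + 1) {
  state$phase == "RELEASE" &&
    (t - state$release_start) >= TRIGGER_REFRACTORY_S &&
    is.finite(p_aw) && p_aw < settings$trigger_threshold
}

#' Adaptive volume-setpoint update
#'
#' Breath-to-breath proportional correction of the internal volume setpoint:
#' `setpoint' = setpoint + gain * (target - delivered)`, clamped to
#' `[0, max_setpoint]`. With any fixed plant bias below 100% this map is a
#' contraction and converges geometrically to the setpoint that makes the
#' delivered volume equal the target.
#'
#' @param setpoint current internal setpoint, mL.
#' @param target set (desired) tidal volume, mL (> 0).
#' @param delivered measured delivered volume of the last breath, mL.
#' @param gain correction fraction in (0, 1]; default 0.5.
#' @param max_setpoint upper clamp, mL (bag capacity).
#' @return the updated setpoint, mL.
#' @export
update_volume_setpoint <- function(setpoint, target, delivered, gain = 0.5,
                                   max_setpoint = 750) {
  if (!is.numeric(gain) || gain <= 0 || gain > 1)
    stop("configuration error: `gain` must be in (0, 1]")
  if (target <= 0) stop("`target` must be > 0")
  min(max(setpoint + gain * (target - delivered), 0), max_setpoint)
}

#' One controller tick
#'
#' Advances the assist-control state machine by one 10 ms sensor sample.
#' Within a breath the phases run COMPRESS -> HOLD -> RELEASE:
#' \itemize{
#'   \item COMPRESS while the piston stroke window is open and, in VC-AC,
#'     the integrated (spirometer) volume is below the adaptive setpoint and
#'     the airway pressure is below the maximum-pressure guard;
#'   \item HOLD until the commanded inspiratory time elapses (the bag is held
#'     compressed -- the patient's inspiratory pause);
#'   \item RELEASE until the next mandatory (TIMED) breath falls due or a
#'     patient effort triggers early, which also resets the rate timer.
#' }
#' Reaching the maximum pressure during inspiration halts compression for the
#' remainder of the cycle and emits a `MAX_PRESSURE` event. Malformed
#' (non-finite) samples are ignored for triggering and integration.
#'
#' @param sample list with `t` (s), `p_aw` (cmH2O), `flow` (L/min) -- the
#'   calibrated sensor sample.
#' @param settings a [vent_settings()].
#' @param state the current controller state ([controller_init()]).
#' @param cfg a [circuit_config()] (stroke window, bag capacity).
#' @return list with elements `state` (updated), `phase` (commanded phase for
#'   the next 10 ms) and `events` (data.frame of breath/halt events, possibly
#'   empty: columns `t`, `type`, `detail`).
#' @export
controller_step <- function(sample, settings, state, cfg = circuit_config()) {
  dt_tick <- 0.01
  t <- sample$t
  p_aw <- sample$p_aw
  flow <- sample$flow
  if (!is.finite(p_aw)) p_aw <- NA_real_
  if (!is.finite(flow)) flow <- 0
  ev_t <- numeric(0); ev_type <- character(0); ev_detail <- character(0)

  if (!settings$run_enable) {
    state$phase <- "RELEASE"
    return(list(state = state, phase = "RELEASE", events = .empty_events))
  }

  period <- 60 / settings$rr_set

  # breath initiation: mandatory timer, or patient trigger during RELEASE
  if (state$phase == "RELEASE") {
    start <- NULL
    if (t - state$last_breath_start >= period - 1e-9) {
      start <- "TIMED"
    } else if (!is.na(p_aw) && check_trigger(p_aw, settings, state, t)) {
      start <- "PATIENT"
    }
    if (!is.null(start)) {
      state$phase <- "COMPRESS"
      state$last_breath_start <- t
      state$integrated_volume <- 0
      state$halted_this_cycle <- FALSE
      state$breath_count <- state$breath_count + 1L
      ev_t <- c(ev_t, t); ev_type <- c(ev_type, start)
      ev_detail <- c(ev_detail, sprintf("t_insp=%g", settings$t_insp))
    }
  }

  state$t_in_breath <- t - state$last_breath_start

  # volume integration from the calibrated spirometer flow (inspiration only)
  if (state$phase %in% c("COMPRESS", "HOLD"))
    state$integrated_volume <- state$integrated_volume +
      max(flow, 0) / 60 * dt_tick * 1000

  # software maximum-pressure guard
  if (state$phase %in% c("COMPRESS", "HOLD") && !state$halted_this_cycle &&
      !is.na(p_aw) && p_aw >= settings$max_pressure) {
    state$halted_this_cycle <- TRUE
    ev_t <- c(ev_t, t); ev_type <- c(ev_type, "MAX_PRESSURE_HALT")
    ev_detail <- c(ev_detail, sprintf("p_aw=%.1f", p_aw))
  }

  # phase transitions
  if (state$phase == "COMPRESS") {
    vol_reached <- settings$mode == "VC_AC" &&
      state$integrated_volume >= state$adaptive_setpoint
    if (state$halted_this_cycle || vol_reached ||
        state$t_in_breath >= cfg$stroke_time - 1e-9)
      state$phase <- "HOLD"
  }
  if (state$phase == "HOLD" && state$t_in_breath >= settings$t_insp - 1e-9) {
    state$phase <- "RELEASE"
    state$release_start <- t
    state$delivered_last <- state$integrated_volume
    if (settings$mode == "VC_AC")
      state$adaptive_setpoint <- update_volume_setpoint(
        state$adaptive_setpoint, settings$max_volume, state$delivered_last,
        gain = 0.5, max_setpoint = cfg$bag_capacity)
  }

  events <- if (length(ev_t) == 0L) .empty_events else
    data.frame(t = ev_t, type = ev_type, detail = ev_detail,
               stringsAsFactors = FALSE)
  list(state = state, phase = state$phase, events = events)
}
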