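#' Alarm codes and priorities
#'
#' Returns the priority (`"HIGH"` or `"MEDIUM"`) of an alarm code in a given
#' ventilator mode. `VOLUME_LOW` is a high-priority alarm in PC-AC mode
#' (tidal volume below an absolute floor) and a medium-priority alarm in
#' VC-AC (volume below 80% of the set maximum); all other codes have a fixed
#' priority.
#'
#' @param code one of `MAX_PRESSURE`, `PRESSURE_LOW`, `VOLUME_LOW`,
#'   `VOLUME_HIGH`, `POWER_LOST`, `BATTERY_LOW`, `CONTINUING_PRESSURE`.
#' @param mode `"VC_AC"` or `"PC_AC"`.
#' @return `"HIGH"` or `"MEDIUM"`.
#' @export
alarm_priority <- function(code, mode = "VC_AC") {
  switch(code,
    MAX_PRESSURE = "HIGH",
    PRESSURE_LOW = "HIGH",
    CONTINUING_PRESSURE = "HIGH",
    POWER_LOST = "HIGH",
    BATTERY_LOW = "MEDIUM",
    VOLUME_LOW = if (mode == "PC_AC") "HIGH" else "MEDIUM",
    VOLUME_HIGH = "MEDIUM",
    stop("unknown alarm code '", code, "'")
  )
}

#' Construct an alarm event
#'
#' @param code alarm code (see [alarm_priority()]).
#' @param t_onset onset time, seconds.
#' @param mode ventilator mode (decides `VOLUME_LOW` priority).
#' @param t_cleared clearing time, or `NA` while the condition persists
#'   (visual indications latch until the condition is no longer met).
#' @param message free-text description.
#' @return one-row data.frame with columns
#'   `t_onset, t_cleared, code, priority, message`.
#' @export
alarm_event <- function(code, t_onset, mode = "VC_AC", t_cleared = NA_real_,
                        message = "") {
  data.frame(t_onset = t_onset, t_cleared = t_cleared, code = code,
             priority = alarm_priority(code, mode), message = message,
             stringsAsFactors = FALSE)
}

.empty_alarms <- data.frame(t_onset = numeric(0), t_cleared = numeric(0),
                            code = character(0), priority = character(0),
                            message = character(0), stringsAsFactors = FALSE)

empty_alarms <- function() .empty_alarms

#' Per-breath alarm evaluation
#'
#' Evaluates the volume and end-expiratory-pressure alarm conditions on one
#' completed breath:
#' \itemize{
#'   \item PC-AC: tidal volume below 250 mL -> `VOLUME_LOW` (high priority);
#'   \item VC-AC: tidal volume below 80% of the set maximum ->
#'     `VOLUME_LOW` (medium), above 120% -> `VOLUME_HIGH` (medium);
#'   \item minimum breath pressure below the low-PEEP threshold ->
#'     `PRESSURE_LOW` (high).
#' }
#'
#' @param record one breath record: a list/one-row data.frame with at least
#'   `tidal_volume` (mL), `peep_min` (cmH2O) and `t_start` (s).
#' @param settings a [vent_settings()].
#' @return data.frame of alarm events (possibly zero rows).
#' @export
evaluate_breath_alarms <- function(record, settings) {
  out <- empty_alarms()
  tv <- record$tidal_volume
  t0 <- if (!is.null(record$t_start)) record$t_start else NA_real_
  if (settings$mode == "PC_AC") {
    if (is.finite(tv) && tv < 250)
      out <- rbind(out, alarm_event("VOLUME_LOW", t0, settings$mode,
                                    message = sprintf("tidal volume %.0f mL < 250 mL", tv)))
  } else {
    if (is.finite(tv) && tv < 0.80 * settings$max_volume)
      out <- rbind(out, alarm_event("VOLUME_LOW", t0, settings$mode,
                                    message = sprintf("tidal volume %.0f mL < 80%% of %g mL", tv, settings$max_volume)))
    if (is.finite(tv) && tv > 1.20 * settings$max_volume)
      out <- rbind(out, alarm_event("VOLUME_HIGH", t0, settings$mode,
                                    message = sprintf("tidal volume %.0f mL > 120%% of %g mL", tv, settings$max_volume)))
  }
  if (!is.null(record$peep_min) && is.finite(record$peep_min) &&
      record$peep_min < settings$peep_min)
    out <- rbind(out, alarm_event("PRESSURE_LOW", t0, settings$mode,
                                  message = sprintf("end-expiratory pressure %.1f < %g cmH2O", record$peep_min, settings$peep_min)))
  out
}

#' Per-sample alarm evaluation
#'
#' Sample-cadence conditions:
#' \itemize{
#'   \item airway pressure at or above the maximum-pressure guard ->
#'     `MAX_PRESSURE` (high; the controller halts compression in the same
#'     tick);
#'   \item airway pressure persistently below the low-PEEP threshold during
#'     RELEASE for more than one breath period -> `PRESSURE_LOW` (high;
#'     stopped ventilator or disconnected hose);
#'   \item airway pressure persistently above `PEEP + 5` cmH2O for two or
#'     more breath periods -> `CONTINUING_PRESSURE` (high).
#' }
#' The persistence counters live in the controller state
#' (`low_pressure_run`, `high_pressure_run`), updated here.
#'
#' @param sample list with `t`, `p_aw`.
#' @param settings a [vent_settings()].
#' @param state controller state; returned updated in the `state` element.
#' @param peep_applied the circuit PEEP setting, cmH2O (for the continuing
#'   pressure condition).
#' @return list with `alarms` (data.frame) and `state`.
#' @export
evaluate_sample_alarms <- function(sample, settings, state, peep_applied = 0) {
  dt_tick <- 0.01
  out <- empty_alarms()
  period <- 60 / settings$rr_set
  p_aw <- sample$p_aw
  if (is.finite(p_aw) && p_aw >= settings$max_pressure)
    out <- rbind(out, alarm_event("MAX_PRESSURE", sample$t, settings$mode,
                                  message = sprintf("airway pressure %.1f >= %g cmH2O", p_aw, settings$max_pressure)))
  # stuck-low pressure (stopped ventilator / disconnect)
  if (is.finite(p_aw) && state$phase == "RELEASE" && p_aw < settings$peep_min)
    state$low_pressure_run <- state$low_pressure_run + dt_tick
  else state$low_pressure_run <- 0
  if (state$low_pressure_run > period)
    out <- rbind(out, alarm_event("PRESSURE_LOW", sample$t, settings$mode,
                                  message = sprintf("airway pressure below %g cmH2O for > %g s", settings$peep_min, period)))
  # continuing airway pressure
  if (is.null(state$high_pressure_run)) state$high_pressure_run <- 0
  if (is.finite(p_aw) && p_aw > peep_applied + 5)
    state$high_pressure_run <- state$high_pressure_run + dt_tick
  else state$high_pressure_run <- 0
  if (state$high_pressure_run >= 2 * period)
    out <- rbind(out, alarm_event("CONTINUING_PRESSURE", sample$t, settings$mode,
                                  message = sprintf("airway pressure above PEEP + 5 cmH2O for >= %g s", 2 * period)))
  list(alarms = out, state = state)
}

#' Write an alarm log CSV
#'
#' Columns `t_onset, t_cleared, code, priority`.
#'
#' @param alarms alarm data.frame (as produced by the simulator).
#' @param path file path.
#' @export
write_alarm_csv <- function(alarms, path) {
  utils::write.csv(alarms[, c("t_onset", "t_cleared", "code", "priority")],
                   path, row.names = FALSE)
  invisible(path)
}
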