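#' Preset catalog
#'
#' The bundled configuration space: the four test-lung models, the
#' settings grid the verification campaign sweeps (volume- and
#' pressure-controlled assist-control ranges), and the named reference
#' scenarios used by the performance demonstrations.
#'
#' @return a list with elements `lungs` (named [lung_model()] list),
#'   `settings_grid` (data.frame of per-mode ranges) and
#'   `reference_scenarios` (character vector of preset names accepted by
#'   [load_scenario()]).
#' @export
preset_catalog <- function() {
  grid <- data.frame(
    mode = c("VC_AC", "PC_AC"),
    rr_brpm = c("10-30", "20-40"),
    set_tv_ml = c("250-600", NA),
    pip_cmh2o = c("15-35", "25-35"),
    t_insp_s = c("0.6-1.5", "1.0"),
    ie_ratio = c("1:1 to 1:4", "1:1 to 1:2"),
    trigger_rel_cmh2o = c("-2 to -5", NA),
    peep_cmh2o = c("5-20", "5-20"),
    stringsAsFactors = FALSE
  )
  list(lungs = lung_presets(), settings_grid = grid,
       reference_scenarios = c("normal_vcac_400", "ards3_pcac",
                               "spont_trigger", "monitor_spont"))
}

reference_scenario <- function(name, seed = 1L) {
  switch(name,
    # passive normal lung, the volume-controlled reference operating point
    normal_vcac_400 = scenario(
      lung = "NORMAL",
      settings = vent_settings("VC_AC", rr_set = 20, t_insp = 1.0,
                               max_volume = 400, trigger_threshold = 3),
      circuit = circuit_config(pip_setting = 35, peep_setting = 5),
      seed = seed, label = name),
    # severe ARDS under pressure control: the maximum-tidal-volume probe
    ards3_pcac = scenario(
      lung = "ARDS3",
      settings = vent_settings("PC_AC", rr_set = 20, t_insp = 1.0,
                               max_volume = 400, trigger_threshold = 8),
      circuit = circuit_config(pip_setting = 35, peep_setting = 10),
      seed = seed, label = name),
    # spontaneous patient (30 brpm, -5 cmH2O) against the VC-AC reference
    spont_trigger = scenario(
      lung = "NORMAL",
      muscle = muscle_pattern(rate = 30, p_max = 5),
      settings = vent_settings("VC_AC", rr_set = 20, t_insp = 1.0,
                               max_volume = 400, trigger_threshold = 3),
      circuit = circuit_config(pip_setting = 35, peep_setting = 5),
      seed = seed, label = name),
    # breathing through the disabled device (monitoring only)
    monitor_spont = scenario(
      lung = "NORMAL",
      muscle = muscle_pattern(rate = 15, p_max = 5),
      settings = vent_settings("VC_AC", rr_set = 20, t_insp = 1.0,
                               max_volume = 400, trigger_threshold = 3,
                               run_enable = FALSE),
      circuit = circuit_config(pip_setting = 35, peep_setting = 0),
      duration = 60, seed = seed, label = name),
    stop("unknown preset '", name, "'; available: ",
         paste(preset_catalog()$reference_scenarios, collapse = ", "))
  )
}

#' The bundled 29-scenario requirements suite
#'
#' The verification grid crossing the four test lungs with the
#' ventilator-settings ranges, anchored at the campaign's fixed points
#' (RR 20 brpm, I:E 1:2, PIP valve 35 cmH2O, PEEP 10 cmH2O for the ARDS
#' lungs, PEEP 5 for the normal lung):
#' \itemize{
#'   \item VC-AC, all 4 lungs x set TV 250/400/600 mL (12 scenarios);
#'   \item VC-AC, normal lung, RR 10/15/25/30 brpm at I:E 1:2 (4);
#'   \item VC-AC, normal lung, inspiratory time 0.6/0.75/1.5 s (3);
#'   \item PC-AC, all 4 lungs x PIP valve 25/35 cmH2O (8);
#'   \item spontaneous triggering, patient 30 brpm at -5 and -2 cmH2O
#'     effort vs the VC-AC reference (2).
#' }
#'
#' @param seed base RNG seed propagated to every scenario.
#' @return list of 29 [scenario()] objects.
#' @export
requirements_suite <- function(seed = 1L) {
  scns <- list()
  lungs <- c("NORMAL", "ARDS1", "ARDS2", "ARDS3")
  peep_for <- function(lung) if (lung == "NORMAL") 5 else 10
  trig_for <- function(peep) peep - 2  # relative -2 cmH2O, stored absolute

  for (lung in lungs) {
    peep <- peep_for(lung)
    for (tv in c(250, 400, 600)) {
      scns[[length(scns) + 1L]] <- scenario(
        lung = lung,
        settings = vent_settings("VC_AC", rr_set = 20, t_insp = 1.0,
                                 max_volume = tv,
                                 trigger_threshold = trig_for(peep)),
        circuit = circuit_config(pip_setting = 35, peep_setting = peep),
        seed = seed, label = sprintf("vcac_%s_tv%d", tolower(lung), tv))
    }
  }
  for (rr in c(10, 15, 25, 30)) {
    ti <- round((60 / rr) / 3, 1)  # keeps I:E at 1:2 on the 0.1 s input grid
    scns[[length(scns) + 1L]] <- scenario(
      lung = "NORMAL",
      settings = vent_settings("VC_AC", rr_set = rr, t_insp = ti,
                               max_volume = 400, trigger_threshold = 3),
      circuit = circuit_config(pip_setting = 35, peep_setting = 5),
      seed = seed, label = sprintf("vcac_normal_rr%d", rr))
  }
  for (ti in c(0.6, 0.75, 1.5)) {
    scns[[length(scns) + 1L]] <- scenario(
      lung = "NORMAL",
      settings = vent_settings("VC_AC", rr_set = 20, t_insp = ti,
                               max_volume = 400, trigger_threshold = 3),
      circuit = circuit_config(pip_setting = 35, peep_setting = 5),
      seed = seed, label = sprintf("vcac_normal_ti%g", ti))
  }
  for (lung in lungs) {
    peep <- peep_for(lung)
    for (pip in c(25, 35)) {
      scns[[length(scns) + 1L]] <- scenario(
        lung = lung,
        settings = vent_settings("PC_AC", rr_set = 20, t_insp = 1.0,
                                 max_volume = 400,
                                 trigger_threshold = trig_for(peep)),
        circuit = circuit_config(pip_setting = pip, peep_setting = peep),
        seed = seed, label = sprintf("pcac_%s_pip%d", tolower(lung), pip))
    }
  }
  for (pmax in c(5, 2)) {
    scns[[length(scns) + 1L]] <- scenario(
      lung = "NORMAL",
      muscle = muscle_pattern(rate = 30, p_max = pmax),
      settings = vent_settings("VC_AC", rr_set = 20, t_insp = 1.0,
                               max_volume = 400, trigger_threshold = 3),
      circuit = circuit_config(pip_setting = 35, peep_setting = 5),
      seed = seed, label = sprintf("spont_pmax%d", pmax))
  }
  scns
}

# recognised flat configuration keys (snake-cased control-panel names)
.scenario_keys <- c(
  "label", "lung_model", "compliance", "inspiratory_resistance",
  "expiratory_resistance", "run_enable", "control_mode", "respiration_rate",
  "inspiratory_time", "maximum_volume", "maximum_pressure",
  "trigger_threshold", "peep", "peep_minimum", "pip", "bag_capacity",
  "stroke_time", "patient_rate", "patient_p_max", "patient_insp_frac",
  "patient_release_frac", "duration", "dt_plant", "noise_sigma", "seed",
  "spirometer_k"
)

#' Load a scenario from a preset name or a configuration file
#'
#' A scenario source is either one of the named presets (see
#' [preset_catalog()]) or a flat key/value YAML file whose keys follow the
#' control-panel parameter names (snake-cased): `control_mode`
#' (`volume`/`pressure`), `respiration_rate`, `inspiratory_time`, `pip`,
#' `peep`, `peep_minimum`, `trigger_threshold`, `maximum_volume`,
#' `maximum_pressure`, `run_enable`, plus lung (`lung_model` preset name or
#' `compliance`/`inspiratory_resistance`/`expiratory_resistance`), patient
#' effort (`patient_rate`, `patient_p_max`, ...) and run parameters
#' (`duration`, `seed`, `noise_sigma`). Missing keys take the passive
#' normal-lung defaults; an empty file yields the all-defaults scenario.
#'
#' A negative `trigger_threshold` is interpreted as relative to PEEP and
#' converted to the absolute threshold the controller compares against
#' (e.g. PEEP 5 with trigger -2 becomes 3 cmH2O absolute).
#'
#' Values outside the recommended operating ranges (TV 250--600 mL,
#' RR 10--30 brpm, inspiratory pressure < 40 cmH2O) load with a warning,
#' not an error, since the device itself accepts them.
#'
#' @param source preset name or path to a YAML config file.
#' @param seed seed override for preset scenarios.
#' @return a [scenario()].
#' @export
load_scenario <- function(source, seed = 1L) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% preset_catalog()$reference_scenarios)
    return(reference_scenario(source, seed = seed))
  if (!file.exists(source))
    stop("unknown preset '", source, "' (available: ",
         paste(preset_catalog()$reference_scenarios, collapse = ", "),
         ") and no such file")
  cfg <- tryCatch(yaml::read_yaml(source), error = function(e)
    stop("malformed scenario file '", source, "': ", conditionMessage(e)))
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("scenario file '", source, "' must be a flat key/value mapping")
  unknown <- setdiff(names(cfg), .scenario_keys)
  if (length(unknown))
    warning("ignoring unknown configuration keys: ",
            paste(unknown, collapse = ", "))
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default

  lung <- if (!is.null(cfg$compliance)) {
    lung_model(cfg$compliance, pick("inspiratory_resistance", 6),
               pick("expiratory_resistance", 6), label = "custom")
  } else lung_presets(pick("lung_model", "NORMAL"))

  mode <- pick("control_mode", "volume")
  mode <- switch(tolower(mode), volume = , vc_ac = , vc = "VC_AC",
                 pressure = , pc_ac = , pc = "PC_AC",
                 stop("control_mode must be 'volume' or 'pressure', got '", mode, "'"))
  peep <- pick("peep", 5)
  trig <- pick("trigger_threshold", 3)
  if (trig < 0) trig <- peep + trig  # relative-to-PEEP convention

  rr <- pick("respiration_rate", 20)
  tv <- pick("maximum_volume", 400)
  pip <- pick("pip", 35)
  if (tv < 250 || tv > 600)
    warning("maximum_volume ", tv, " mL is outside the recommended 250-600 mL range")
  if (rr < 10 || rr > 30)
    warning("respiration_rate ", rr, " brpm is outside the required 10-30 brpm range")
  if (pip >= 40)
    warning("pip ", pip, " cmH2O is not below the required 40 cmH2O bound")

  settings <- vent_settings(
    mode = mode, rr_set = rr, t_insp = pick("inspiratory_time", 1.0),
    max_volume = tv, max_pressure = pick("maximum_pressure", 40),
    trigger_threshold = trig, peep_min = pick("peep_minimum", 2),
    run_enable = isTRUE(pick("run_enable", TRUE)))
  circuit <- circuit_config(
    pip_setting = pip, peep_setting = peep,
    bag_capacity = pick("bag_capacity", 750),
    stroke_time = pick("stroke_time", 0.5))
  p_max <- pick("patient_p_max", 0)
  muscle <- if (p_max > 0)
    muscle_pattern(rate = pick("patient_rate", 15), p_max = p_max,
                   insp_frac = pick("patient_insp_frac", 0.20),
                   release_frac = pick("patient_release_frac", 0.15))
  else passive_patient()

  scenario(lung = lung, muscle = muscle, settings = settings,
           circuit = circuit, cal = spirometer_cal(k = pick("spirometer_k", 45)),
           duration = cfg$duration, dt_plant = pick("dt_plant", 0.001),
           noise_sigma = pick("noise_sigma", 0),
           seed = as.integer(pick("seed", seed)),
           label = pick("label", sub("\\.[^.]*$", "", basename(source))))
}

#' Serialise a scenario to a flat YAML configuration
#'
#' Inverse of [load_scenario()]: the written file loads back to an
#' equivalent scenario (round-trip identity on every parameter).
#'
#' @param scn a [scenario()].
#' @param path output path.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "vent_scenario"))
  lung_names <- names(lung_presets())
  is_preset <- scn$lung$label %in% lung_names
  cfg <- list(label = scn$label)
  if (is_preset) cfg$lung_model <- scn$lung$label
  else {
    cfg$compliance <- scn$lung$compliance
    cfg$inspiratory_resistance <- scn$lung$r_insp
    cfg$expiratory_resistance <- scn$lung$r_exp
  }
  cfg <- c(cfg, list(
    run_enable = scn$settings$run_enable,
    control_mode = if (scn$settings$mode == "VC_AC") "volume" else "pressure",
    respiration_rate = scn$settings$rr_set,
    inspiratory_time = scn$settings$t_insp,
    maximum_volume = scn$settings$max_volume,
    maximum_pressure = scn$settings$max_pressure,
    trigger_threshold = scn$settings$trigger_threshold,
    peep = scn$circuit$peep_setting,
    peep_minimum = scn$settings$peep_min,
    pip = scn$circuit$pip_setting,
    bag_capacity = scn$circuit$bag_capacity,
    stroke_time = scn$circuit$stroke_time,
    patient_rate = scn$muscle$rate,
    patient_p_max = if (scn$muscle$active) scn$muscle$p_max else 0,
    patient_insp_frac = scn$muscle$insp_frac,
    patient_release_frac = scn$muscle$release_frac,
    duration = scn$duration,
    dt_plant = scn$dt_plant,
    noise_sigma = scn$noise_sigma,
    seed = scn$seed,
    spirometer_k = scn$cal$k))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
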