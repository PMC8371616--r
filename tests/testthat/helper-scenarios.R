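# Shared scenario builders for the test suite. Durations are kept short
# where the property under test allows it.

vcac_scenario <- function(tv = 400, rr = 20, ti = 1.0, peep = 5, pip = 35,
                          lung = "NORMAL", duration = NULL, label = NULL,
                          ...) {
  if (is.null(label)) label <- sprintf("vcac_%s_tv%g_rr%g", tolower(lung), tv, rr)
  suppressWarnings(scenario(  # short test durations trip the coverage warning
    lung = lung,
    settings = vent_settings("VC_AC", rr_set = rr, t_insp = ti,
                             max_volume = tv, trigger_threshold = peep - 2),
    circuit = circuit_config(pip_setting = pip, peep_setting = peep),
    duration = duration, label = label, ...))
}

pcac_scenario <- function(pip = 35, peep = 10, lung = "ARDS3", rr = 20,
                          ti = 1.0, duration = NULL, label = NULL, ...) {
  if (is.null(label)) label <- sprintf("pcac_%s_pip%g", tolower(lung), pip)
  suppressWarnings(scenario(
    lung = lung,
    settings = vent_settings("PC_AC", rr_set = rr, t_insp = ti,
                             max_volume = 400, trigger_threshold = peep - 2),
    circuit = circuit_config(pip_setting = pip, peep_setting = peep),
    duration = duration, label = label, ...))
}

steady_metrics <- function(scn) {
  wave <- run_simulation(scn)
  summarize_breaths(segment_breaths(wave), efforts = wave$efforts,
                    warmup = scn$warmup_breaths)
}
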