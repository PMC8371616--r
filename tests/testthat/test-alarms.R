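test_that("alarm priorities follow the device's condition table", {
  expect_equal(alarm_priority("MAX_PRESSURE"), "HIGH")
  expect_equal(alarm_priority("PRESSURE_LOW"), "HIGH")
  expect_equal(alarm_priority("POWER_LOST"), "HIGH")
  expect_equal(alarm_priority("BATTERY_LOW"), "MEDIUM")
  expect_equal(alarm_priority("VOLUME_LOW", "PC_AC"), "HIGH")
  expect_equal(alarm_priority("VOLUME_LOW", "VC_AC"), "MEDIUM")
  expect_equal(alarm_priority("VOLUME_HIGH", "VC_AC"), "MEDIUM")
  expect_error(alarm_priority("NO_SUCH"), "unknown alarm code")
})

test_that("breath alarms implement the volume and PEEP conditions per mode", {
  rec <- function(tv, peep = 5) list(tidal_volume = tv, peep_min = peep, t_start = 0)
  pc <- vent_settings("PC_AC", max_volume = 400, peep_min = 2)
  vc <- vent_settings("VC_AC", max_volume = 400, peep_min = 2)

  a <- evaluate_breath_alarms(rec(240), pc)
  expect_equal(a$code, "VOLUME_LOW"); expect_equal(a$priority, "HIGH")
  expect_equal(nrow(evaluate_breath_alarms(rec(260), pc)), 0L)

  a <- evaluate_breath_alarms(rec(319), vc)
  expect_equal(a$code, "VOLUME_LOW"); expect_equal(a$priority, "MEDIUM")
  expect_equal(nrow(evaluate_breath_alarms(rec(400), vc)), 0L)
  a <- evaluate_breath_alarms(rec(481), vc)
  expect_equal(a$code, "VOLUME_HIGH"); expect_equal(a$priority, "MEDIUM")

  a <- evaluate_breath_alarms(rec(400, peep = 1.5), vc)
  expect_equal(a$code, "PRESSURE_LOW"); expect_equal(a$priority, "HIGH")
})

test_that("raising the volume limit never creates new VOLUME_HIGH events", {
  set.seed(3)
  tvs <- stats::runif(50, 100, 900)
  for (mv in list(c(300, 400), c(400, 500))) {
    lo <- vent_settings("VC_AC", max_volume = mv[1])
    hi <- vent_settings("VC_AC", max_volume = mv[2])
    for (tv in tvs) {
      rec <- list(tidal_volume = tv, peep_min = 5, t_start = 0)
      high_lo <- "VOLUME_HIGH" %in% evaluate_breath_alarms(rec, lo)$code
      high_hi <- "VOLUME_HIGH" %in% evaluate_breath_alarms(rec, hi)$code
      expect_true(!high_hi || high_lo)
    }
  }
})

test_that("sample alarms flag overpressure immediately and stuck-low pressure after a breath period", {
  st <- vent_settings("VC_AC", max_pressure = 40, peep_min = 5, rr_set = 20)
  ctrl <- controller_init(st)
  out <- evaluate_sample_alarms(list(t = 0, p_aw = 41), st, ctrl)
  expect_true("MAX_PRESSURE" %in% out$alarms$code)
  out <- evaluate_sample_alarms(list(t = 0, p_aw = 39.9), st, ctrl)
  expect_false("MAX_PRESSURE" %in% out$alarms$code)

  # airway pressure stuck at 0 with PEEP 5: PRESSURE_LOW after > 3 s
  ctrl <- controller_init(st)  # phase RELEASE
  saw_low <- NA_real_
  for (k in 0:400) {
    out <- evaluate_sample_alarms(list(t = k * 0.01, p_aw = 0), st, ctrl)
    ctrl <- out$state
    if (is.na(saw_low) && "PRESSURE_LOW" %in% out$alarms$code) saw_low <- k * 0.01
  }
  expect_true(is.finite(saw_low))
  expect_gte(saw_low, 3)
  expect_lt(saw_low, 3.2)
})

test_that("the steady passive reference scenario raises no alarms", {
  wave <- run_simulation(vcac_scenario(tv = 400, duration = 45, label = "ref"))
  expect_equal(nrow(wave$alarms), 0L)
})

test_that("overpressure alarms coincide with controller halts in the same tick", {
  # software guard set below the PIP valve so the guard trips every breath
  scn <- suppressWarnings(scenario(
    lung = "NORMAL",
    settings = vent_settings("VC_AC", rr_set = 20, t_insp = 1.0,
                             max_volume = 600, max_pressure = 18,
                             trigger_threshold = 3),
    circuit = circuit_config(pip_setting = 35, peep_setting = 5),
    duration = 30, label = "overpressure"))
  wave <- run_simulation(scn)
  halts <- wave$events$t[wave$events$type == "MAX_PRESSURE_HALT"]
  onsets <- wave$alarms$t_onset[wave$alarms$code == "MAX_PRESSURE"]
  expect_gt(length(halts), 5)
  expect_true(all(onsets %in% halts))
  # every breath's peak stays at most one resistive step above the guard
  expect_lt(max(wave$data$p_aw), 35)
})

test_that("a disabled ventilator with a breathing patient raises the low-pressure alarm", {
  wave <- run_simulation(load_scenario("monitor_spont"))
  expect_true("PRESSURE_LOW" %in% wave$alarms$code)
  expect_equal(unique(wave$alarms$priority[wave$alarms$code == "PRESSURE_LOW"]),
               "HIGH")
})

test_that("externally injected power alarms carry their fixed priorities", {
  ev <- alarm_event("POWER_LOST", t_onset = 1)
  expect_equal(ev$priority, "HIGH")
  ev <- alarm_event("BATTERY_LOW", t_onset = 1)
  expect_equal(ev$priority, "MEDIUM")
})
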