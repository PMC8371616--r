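test_that("settings validation enforces the timing relation", {
  expect_error(vent_settings(rr_set = 20, t_insp = 3.0), "breath period")
  expect_warning(vent_settings(rr_set = 20.5), "increments")
  s <- vent_settings("PC_AC", rr_set = 20, t_insp = 1.0)
  expect_equal(s$mode, "PC_AC")
})

test_that("assist trigger fires strictly below threshold, only in RELEASE past the refractory window", {
  st <- vent_settings(trigger_threshold = 3)
  ctrl <- controller_init(st)
  ctrl$phase <- "RELEASE"; ctrl$release_start <- 10
  expect_true(check_trigger(2.9, st, ctrl, t = 11))
  expect_false(check_trigger(3.0, st, ctrl, t = 11))   # strict inequality
  expect_false(check_trigger(2.9, st, ctrl, t = 10.1)) # inside refractory
  ctrl$phase <- "HOLD"
  expect_false(check_trigger(2.0, st, ctrl, t = 11))
  ctrl$phase <- "COMPRESS"
  expect_false(check_trigger(2.0, st, ctrl, t = 11))
})

test_that("adaptive setpoint applies the proportional correction with clamping", {
  expect_equal(update_volume_setpoint(400, 400, 400, gain = 0.5), 400)
  expect_equal(update_volume_setpoint(400, 400, 380, gain = 0.5), 410)
  expect_equal(update_volume_setpoint(740, 400, 100, gain = 1, max_setpoint = 750), 750)
  expect_equal(update_volume_setpoint(10, 400, 900, gain = 1), 0)
  expect_error(update_volume_setpoint(400, 400, 380, gain = 0), "gain")
  expect_error(update_volume_setpoint(400, 400, 380, gain = 1.5), "gain")
  expect_error(update_volume_setpoint(400, -1, 380), "target")
})

test_that("setpoint iteration converges within 2% of target in at most 5 breaths under plant bias", {
  # breath-to-breath fixed-point oracle: the plant delivers bias * setpoint
  for (bias in c(0.8, 0.9, 1.0, 1.1, 1.2)) {
    sp <- 400  # initial setpoint = set volume
    delivered <- bias * sp
    n <- 0
    while (abs(delivered - 400) / 400 > 0.02 && n < 20) {
      sp <- update_volume_setpoint(sp, 400, delivered, gain = 0.5)
      delivered <- bias * sp
      n <- n + 1
    }
    expect_lte(n, 5)
    expect_lt(abs(delivered - 400) / 400, 0.02)
  }
})

run_ticks <- function(n, st, ctrl, cfg, sample_fn) {
  phases <- character(n); events <- list()
  for (k in seq_len(n)) {
    t <- (k - 1) * 0.01
    res <- controller_step(sample_fn(t, ctrl), st, ctrl, cfg)
    ctrl <- res$state
    phases[k] <- res$phase
    if (nrow(res$events)) events[[length(events) + 1L]] <- res$events
  }
  list(phases = phases, ctrl = ctrl,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(t = numeric(0), type = character(0), detail = character(0)))
}

test_that("VC-AC cycles COMPRESS -> HOLD at the volume setpoint -> RELEASE at t_insp", {
  st <- vent_settings("VC_AC", rr_set = 20, t_insp = 1.0, max_volume = 400)
  cfg <- circuit_config()
  # synthetic plant: 90 L/min whenever compressing, zero otherwise
  sample_fn <- function(t, ctrl) {
    list(t = t, p_aw = 20,
         flow = if (ctrl$phase == "COMPRESS") 90 else 0)
  }
  out <- run_ticks(700, st, controller_init(st), cfg, sample_fn)
  tt <- (seq_len(700) - 1) * 0.01
  # 90 L/min = 15 mL per tick -> setpoint 400 reached ~0.27 s in
  expect_true(all(out$phases[tt < 0.25] == "COMPRESS"))
  expect_true(all(out$phases[tt > 0.35 & tt < 0.99] == "HOLD"))
  expect_true(all(out$phases[tt > 1.01 & tt < 2.99] == "RELEASE"))
  # mandatory breaths exactly one period apart
  starts <- out$events$t[out$events$type == "TIMED"]
  expect_equal(diff(starts), rep(3, length(starts) - 1), tolerance = 1e-9)
  expect_true(all(out$events$type %in% c("TIMED")))
})

test_that("reaching maximum pressure halts compression for the cycle and emits the event", {
  st <- vent_settings("VC_AC", rr_set = 20, t_insp = 1.0, max_volume = 600,
                      max_pressure = 40)
  cfg <- circuit_config()
  sample_fn <- function(t, ctrl) {
    # pressure spikes over the guard shortly into the stroke
    list(t = t, p_aw = if (t > 0.1 && t < 1.0) 41 else 20, flow = 30)
  }
  out <- run_ticks(120, st, controller_init(st), cfg, sample_fn)
  halts <- out$events[out$events$type == "MAX_PRESSURE_HALT", ]
  expect_equal(nrow(halts), 1L)
  expect_equal(halts$t, 0.11, tolerance = 1e-9)
  tt <- (seq_len(120) - 1) * 0.01
  expect_true(all(out$phases[tt > 0.12 & tt < 0.99] == "HOLD"))
})

test_that("a patient effort during RELEASE triggers a breath and resets the rate timer", {
  st <- vent_settings("VC_AC", rr_set = 20, t_insp = 1.0, max_volume = 400,
                      trigger_threshold = 3)
  cfg <- circuit_config()
  dip_at <- 2.0  # during RELEASE, past the refractory window
  sample_fn <- function(t, ctrl) {
    p <- if (abs(t - dip_at) < 0.05) 2.5 else 5
    list(t = t, p_aw = p, flow = if (ctrl$phase == "COMPRESS") 90 else 0)
  }
  out <- run_ticks(600, st, controller_init(st), cfg, sample_fn)
  ev <- out$events[out$events$type %in% c("TIMED", "PATIENT"), ]
  expect_equal(ev$type[1:2], c("TIMED", "PATIENT"))
  expect_equal(ev$t[2], dip_at - 0.04, tolerance = 0.011)
  # rate timer reset: next mandatory breath one full period after the trigger
  expect_equal(ev$t[3] - ev$t[2], 3, tolerance = 1e-9)
  expect_equal(ev$type[3], "TIMED")
})

test_that("a disabled controller stays in RELEASE and emits nothing", {
  st <- vent_settings(run_enable = FALSE)
  out <- run_ticks(50, st, controller_init(st), circuit_config(),
                   function(t, ctrl) list(t = t, p_aw = 0, flow = 0))
  expect_true(all(out$phases == "RELEASE"))
  expect_equal(nrow(out$events), 0L)
})
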