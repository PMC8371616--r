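square_wave <- function(n_breaths = 6, amp = 30, t_on = 1, t_neg = 0.5,
                        t_off = 1.5, hz = 100) {
  period <- t_on + t_neg + t_off
  t <- seq(0, n_breaths * period, by = 1 / hz)
  ph <- t %% period
  flow <- ifelse(ph < t_on, amp, ifelse(ph < t_on + t_neg, -amp, 0))
  data.frame(t = t, flow_lpm = flow, p_aw = 5 + ifelse(ph < t_on, 10, 0))
}

test_that("segmentation integrates a square-wave flow to the analytic tidal volume", {
  d <- square_wave()       # 30 L/min for 1 s -> 0.5 L per breath
  br <- segment_breaths(d)
  expect_equal(nrow(br), 6L)
  # trapezoidal quadrature at 100 Hz clips half a sample at each edge of the
  # square pulse, so agreement is to 0.5%
  expect_equal(br$tidal_volume, rep(500, 6), tolerance = 0.01)
  expect_equal(br$duration, rep(3, 6), tolerance = 1e-9)
  expect_equal(br$t_insp_measured, rep(1, 6), tolerance = 0.011)
  expect_equal(br$pip, rep(15, 6))
  expect_equal(br$peep_min, rep(5, 6))
})

test_that("a zero-flow waveform yields no breaths, with a warning", {
  d <- data.frame(t = seq(0, 10, by = 0.01), flow_lpm = 0, p_aw = 5)
  expect_warning(br <- segment_breaths(d), "no breaths")
  expect_equal(nrow(br), 0L)
})

test_that("segmentation recovers the controller's breaths and integrated volumes", {
  scn <- vcac_scenario(tv = 400, duration = 45, label = "seg")
  wave <- run_simulation(scn)
  br <- segment_breaths(wave)
  # every controller breath after the first shows up exactly once
  expect_equal(nrow(br), nrow(wave$breaths) - 1L)
  expect_equal(br$t_start, wave$breaths$t_start[seq_len(nrow(br))],
               tolerance = 1e-9)
  expect_true(all(br$trigger == "TIMED"))
  # segmented TV agrees with the controller's integrator at hold entry
  deliv <- wave$breaths$delivered_ml[seq_len(nrow(br))]
  expect_true(all(abs(br$tidal_volume - deliv) / deliv < 0.02))
})

test_that("measured expiratory ratio tracks the commanded timing for passive breaths", {
  for (case in list(c(rr = 20, ti = 1.0), c(rr = 15, ti = 1.3))) {
    scn <- vcac_scenario(rr = case["rr"], ti = case["ti"], duration = 40,
                         label = "ie")
    s <- summarize_breaths(segment_breaths(run_simulation(scn)), warmup = 5)
    expect_lt(abs(s$ie_mean - (60 / case["rr"] - case["ti"]) / case["ti"]),
              0.15)
  }
})

test_that("summary statistics reduce identical breaths exactly", {
  br <- data.frame(
    t_start = seq(0, by = 3, length.out = 25), duration = 3,
    tidal_volume = 400, pip = 22, peep_min = 5, t_insp_measured = 1,
    ie_ratio = 2, trigger = "TIMED", stringsAsFactors = FALSE)
  s <- summarize_breaths(br, warmup = 5)
  expect_equal(s$n_breaths, 20L)
  expect_true(s$valid)
  expect_equal(s$rr_mean, 20)
  expect_equal(s$rr_sd, 0)
  expect_equal(s$tv_mean, 400); expect_equal(s$tv_sd, 0)
  s19 <- summarize_breaths(br[1:24, ], warmup = 5)
  expect_false(s19$valid)
})

test_that("missed-trigger fraction counts efforts without a matched patient breath", {
  # constructed fixture: efforts every 2 s; roughly every 10th unanswered
  efforts <- seq(1, by = 2, length.out = 40)
  answered <- efforts[!(seq_along(efforts) %in% c(5, 15, 25, 35))]
  br <- data.frame(
    t_start = answered + 0.15, duration = 2, tidal_volume = 400, pip = 20,
    peep_min = 5, t_insp_measured = 1, ie_ratio = 1, trigger = "PATIENT",
    stringsAsFactors = FALSE)
  s <- summarize_breaths(br, efforts = efforts, warmup = 0)
  # brute-force matching oracle over the same eligibility window
  eligible <- efforts[efforts >= min(br$t_start) - 0.3 &
                      efforts <= max(br$t_start) - 0.3]
  expected <- mean(!vapply(
    eligible, function(e) any(br$t_start >= e & br$t_start <= e + 0.3),
    logical(1)))
  expect_equal(s$missed_fraction, expected)
  expect_lt(abs(expected - 0.1), 0.01)
  # all efforts answered -> zero missed
  s0 <- summarize_breaths(br, efforts = answered, warmup = 0)
  expect_equal(s0$missed_fraction, 0)
  # no efforts supplied -> no missed fraction reported
  expect_null(summarize_breaths(br, warmup = 0)$missed_fraction)
})

test_that("metrics write out as a flat text table with breath records", {
  scn <- vcac_scenario(duration = 30, label = "wm")
  br <- segment_breaths(run_simulation(scn))
  s <- summarize_breaths(br, warmup = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_metrics(s, path, records = br)
  lines <- readLines(path)
  expect_true(any(grepl("^tv_mean = ", lines)))
  rp <- sub("\\.txt$", "_breaths.csv", path)
  expect_true(file.exists(rp))
  expect_equal(nrow(utils::read.csv(rp)), nrow(br))
})
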