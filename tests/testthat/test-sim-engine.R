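test_that("simulations are bit-identical for a fixed scenario and seed", {
  scn <- vcac_scenario(duration = 20, label = "det", noise_sigma = 0.2, seed = 42)
  w1 <- run_simulation(scn)
  w2 <- run_simulation(scn)
  expect_identical(w1$data, w2$data)
  expect_identical(w1$events, w2$events)
  scn2 <- vcac_scenario(duration = 20, label = "det", noise_sigma = 0.2, seed = 43)
  expect_false(identical(run_simulation(scn2)$data, w1$data))
})

test_that("measurement noise does not disturb the caller's RNG stream", {
  set.seed(99); before <- stats::runif(3)
  set.seed(99)
  invisible(run_simulation(vcac_scenario(duration = 10, label = "rng",
                                         noise_sigma = 0.2)))
  expect_identical(stats::runif(3), before)
})

test_that("halving the plant step changes delivered volume by under half a percent", {
  tv <- sapply(c(0.001, 0.0005), function(dt) {
    scn <- vcac_scenario(duration = 30, label = "conv", dt_plant = dt)
    s <- summarize_breaths(segment_breaths(run_simulation(scn)), warmup = 5)
    s$tv_mean
  })
  expect_lt(abs(tv[2] - tv[1]) / tv[1], 0.005)
})

test_that("passive mandatory breaths arrive exactly one period apart", {
  for (rr in c(12, 20)) {
    ti <- round(60 / rr / 3, 1)
    scn <- vcac_scenario(rr = rr, ti = ti, duration = 40,
                         label = paste0("period", rr))
    wave <- run_simulation(scn)
    gaps <- diff(wave$breaths$t_start)
    expect_true(all(abs(gaps - 60 / rr) <= 0.0100001))
  }
})

test_that("a disabled ventilator with a passive patient records a flat waveform at PEEP", {
  scn <- suppressWarnings(scenario(
    lung = "NORMAL",
    settings = vent_settings(run_enable = FALSE),
    circuit = circuit_config(pip_setting = 35, peep_setting = 5),
    duration = 10, label = "off"))
  wave <- run_simulation(scn)
  expect_true(all(wave$data$flow_lpm == 0))
  expect_true(all(wave$data$p_aw == 5))
  expect_equal(nrow(wave$breaths), 0L)
})

test_that("a disabled ventilator still lets an active patient breathe through the inlet valve", {
  wave <- run_simulation(load_scenario("monitor_spont"))
  d <- wave$data
  expect_gt(max(d$volume_ml), 50)      # air actually moves
  expect_gt(max(d$flow_lpm), 5)
  expect_lt(min(d$flow_lpm), -5)
  expect_true(all(d$p_aw <= 0 + 1e-9)) # inspiratory work pulls pressure down
})

test_that("stiffer lungs receive the same set volume at higher pressure", {
  s_norm <- steady_metrics(vcac_scenario(tv = 300, duration = 45, label = "n300"))
  s_ards <- steady_metrics(vcac_scenario(tv = 300, duration = 45, lung = "ARDS2",
                                         peep = 10, label = "a300"))
  expect_equal(s_ards$tv_mean, s_norm$tv_mean, tolerance = 0.02)
  expect_gt(s_ards$pip_mean, s_norm$pip_mean + 5)
})

test_that("the recorder pipeline is volume-consistent on smooth (spontaneous) flow", {
  wave <- run_simulation(load_scenario("monitor_spont"))
  d <- wave$data
  ct <- cumsum(c(0, (d$flow_lpm[-1] + d$flow_lpm[-nrow(d)]) / 2 / 60 *
                   diff(d$t) * 1000))
  expect_lt(max(abs(d$volume_ml - ct)), 0.005 * max(d$volume_ml))
})

test_that("waveforms survive a CSV round trip and resample cleanly to 64 Hz", {
  wave <- run_simulation(vcac_scenario(duration = 10, label = "io"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wave, path)
  d <- read_waveform_csv(path)
  expect_equal(d$flow_lpm, wave$data$flow_lpm, tolerance = 1e-9)
  expect_equal(d$volume_ml, wave$data$volume_ml, tolerance = 1e-9)
  r <- resample_waveform(wave, rate = 64)
  expect_equal(diff(r$t)[1], 1 / 64, tolerance = 1e-9)
  expect_lt(max(r$volume_ml), max(wave$data$volume_ml) + 1e-9)
  expect_equal(max(r$volume_ml), max(wave$data$volume_ml), tolerance = 0.05)
})

test_that("run_suite summarises per scenario, suffixes duplicate labels, tolerates failures", {
  scns <- list(vcac_scenario(duration = 25, label = "dup"),
               vcac_scenario(duration = 25, label = "dup"),
               vcac_scenario(duration = 25, label = "dup"))
  scns[[3]]$lung$compliance <- NA_real_  # poisoned scenario must not sink the batch
  rep <- run_suite(scns)
  expect_equal(rep$label, c("dup", "dup_2", "dup_3"))
  expect_true(is.na(rep$tv_mean[3]) && !is.na(rep$error[3]))
  expect_false(any(is.na(rep$tv_mean[1:2])))
  empty <- run_suite(list())
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0L)
})
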