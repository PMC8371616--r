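#' Simulation scenario
#'
#' Bundles a patient (lung model and muscle pattern), ventilator settings,
#' circuit configuration and run parameters into one reproducible scenario.
#' The default duration covers a warm-up (5 breaths for a passive patient,
#' 10 for a spontaneously breathing one) plus 20 steady-state breaths,
#' capped at 120 s of simulated time.
#'
#' @param lung a [lung_model()] or preset name.
#' @param muscle a [muscle_pattern()] (default passive).
#' @param settings a [vent_settings()].
#' @param circuit a [circuit_config()].
#' @param cal a [spirometer_cal()].
#' @param duration simulated seconds; `NULL` picks the default above.
#' @param dt_plant plant integration step, seconds (default 1 ms; controller
#'   ticks every 10 ms, so `0.01/dt_plant` must be a whole number).
#' @param noise_sigma zero-mean Gaussian measurement noise SD applied to the
#'   two pressure-sensor channels, cmH2O (default 0: deterministic).
#' @param seed RNG seed for the measurement noise.
#' @param label scenario name used in reports.
#' @return an object of class `vent_scenario`.
#' @export
scenario <- function(lung = "NORMAL", muscle = passive_patient(),
                     settings = vent_settings(), circuit = circuit_config(),
                     cal = spirometer_cal(), duration = NULL,
                     dt_plant = 0.001, noise_sigma = 0, seed = 1L,
                     label = "scenario") {
  if (is.character(lung)) lung <- lung_presets(lung)
  stopifnot(inherits(lung, "lung_model"), inherits(muscle, "muscle_pattern"),
            inherits(settings, "vent_settings"),
            inherits(circuit, "circuit_config"),
            inherits(cal, "spirometer_cal"))
  if (!is.finite(dt_plant) || dt_plant <= 0 || dt_plant > 0.005)
    stop("dt_plant must satisfy 0 < dt_plant <= 0.005 s")
  n_sub <- 0.01 / dt_plant
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("0.01 s controller tick must be a whole number of plant steps")
  warmup <- if (muscle$active) 10L else 5L
  period <- 60 / settings$rr_set
  duration_user <- !is.null(duration)
  if (!duration_user) duration <- min(120, ceiling((warmup + 21) * period))
  if (duration_user && settings$run_enable && duration < (warmup + 20) * period)
    warning(sprintf(
      "duration %g s covers fewer than %d breaths (warm-up %d + 20 steady-state) at RR %g",
      duration, warmup + 20L, warmup, settings$rr_set))
  if (settings$run_enable &&
      settings$trigger_threshold >= circuit$peep_setting)
    warning("trigger threshold >= applied PEEP: the ventilator will self-trigger continuously")
  structure(
    list(lung = lung, muscle = muscle, settings = settings,
         circuit = circuit, cal = cal, duration = as.numeric(duration),
         dt_plant = as.numeric(dt_plant), noise_sigma = as.numeric(noise_sigma),
         seed = as.integer(seed), warmup_breaths = warmup,
         label = as.character(label)),
    class = "vent_scenario"
  )
}

#' @export
print.vent_scenario <- function(x, ...) {
  cat(sprintf("<vent_scenario> '%s': %s lung, %s, %g s @ dt %g ms%s\n",
              x$label, x$lung$label, x$settings$mode, x$duration,
              1000 * x$dt_plant,
              if (x$muscle$active) sprintf(", patient %g brpm / -%g cmH2O",
                                           x$muscle$rate, x$muscle$p_max) else ", passive"))
  invisible(x)
}

PHASE_LEVELS <- c("COMPRESS", "HOLD", "RELEASE")

#' Run a closed-loop simulation
#'
#' Couples the continuous plant (lung + circuit, explicit Euler at
#' `dt_plant`) to the discrete controller (100 Hz) with zero-order-hold
#' phase commands. Each tick the controller sees the calibrated spirometer
#' flow and airway-pressure sample (optionally noisy), decides the phase,
#' and the plant integrates `0.01/dt_plant` substeps under that command.
#' The recorded sensor stream holds the instantaneous flow and airway
#' pressure at each sample instant (under the phase commanded at that
#' tick); the controller consumes each conversion one tick later, the
#' usual read-compute-actuate latency of a sampled controller.
#'
#' Flow routing per commanded phase:
#' \itemize{
#'   \item COMPRESS: piston drive flow, limited by the PIP relief valve and
#'     the remaining bag volume;
#'   \item HOLD: zero flow in VC-AC (piston parked at the volume setpoint);
#'     in PC-AC the compressed bag keeps acting as a pressure reservoir at
#'     the PIP setting until the inspiratory time ends;
#'   \item RELEASE: exhalation through the PEEP threshold valve; patient
#'     effort below ambient pressure draws air in through the bag inlet
#'     valve. A disabled ventilator (`run_enable = FALSE`) exposes only this
#'     path, which is what permits spontaneous breathing through the device.
#' }
#'
#' @param scn a [scenario()].
#' @return an object of class `vent_waveform`: a list with
#'   \describe{
#'     \item{data}{100 Hz data.frame: `t`, `flow_lpm`, `p_aw`, `p_alv`,
#'       `p_mus`, `volume_ml`, `phase` (factor).}
#'     \item{events}{controller events (`t`, `type` in
#'       TIMED/PATIENT/MAX_PRESSURE_HALT, `detail`).}
#'     \item{breaths}{breath starts (`t_start`, `trigger`,
#'       `t_insp_commanded`, `delivered_ml` -- the controller's integrated
#'       volume at hold entry).}
#'     \item{alarms}{latched alarm log (`t_onset`, `t_cleared`, `code`,
#'       `priority`, `message`).}
#'     \item{efforts}{patient effort onset times, seconds.}
#'     \item{scenario}{the input scenario.}
#'   }
#'   Runs are bit-identical for a fixed scenario and seed.
#' @export
run_simulation <- function(scn) {
  stopifnot(inherits(scn, "vent_scenario"))
  lung <- scn$lung; mus <- scn$muscle; st <- scn$settings
  cfg <- scn$circuit; cal <- scn$cal
  C <- lung$compliance; r_i <- lung$r_insp; r_e <- lung$r_exp
  pip <- cfg$pip_setting; peep <- cfg$peep_setting
  bag_cap <- cfg$bag_capacity; mech_max <- cfg$mechanical_max
  drive_rate <- bag_cap / 1000 / cfg$stroke_time
  k_cal <- cal$k; dp_rng <- cal$dp_range; paw_rng <- cal$paw_range
  run_en <- st$run_enable
  pc_mode <- st$mode == "PC_AC"
  dt <- scn$dt_plant
  n_sub <- as.integer(round(0.01 / dt))
  n_ticks <- as.integer(round(scn$duration * 100))
  m_active <- mus$active
  if (m_active) {
    m_period <- 60 / mus$rate
    m_ti <- mus$insp_frac * m_period
    m_titr <- m_ti + mus$release_frac * m_period
    m_tr <- mus$release_frac * m_period
    m_p <- mus$p_max
  }

  # measurement noise, reproducible and isolated from the caller's RNG
  if (scn$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(scn$seed)
    noise_dp <- stats::rnorm(n_ticks, 0, scn$noise_sigma)
    noise_paw <- stats::rnorm(n_ticks, 0, scn$noise_sigma)
  }

  t_v <- (seq_len(n_ticks) - 1L) * 0.01
  flow_v <- numeric(n_ticks); paw_v <- numeric(n_ticks)
  palv_v <- numeric(n_ticks); pmus_v <- numeric(n_ticks)
  vol_v <- numeric(n_ticks); phase_v <- integer(n_ticks)

  ctrl <- controller_init(st)
  V <- 0; p_alv <- peep; pm <- 0; q <- 0
  bag_used <- 0
  min_paw_breath <- Inf
  prev_breath <- NULL  # list(t_start, delivered) of the breath being closed
  deliv_v <- numeric(0)  # controller-integrated volume per breath

  ev_t <- numeric(0); ev_type <- character(0); ev_detail <- character(0)
  # latched alarm bookkeeping
  al_log <- list()
  active_codes <- character(0)
  active_onset <- numeric(0); active_pri <- character(0); active_msg <- character(0)
  latch <- function(codes_now, pri_now, msg_now, t) {
    opened <- !(codes_now %in% active_codes)
    for (i in which(opened)) {
      active_codes <<- c(active_codes, codes_now[i])
      active_onset <<- c(active_onset, t)
      active_pri <<- c(active_pri, pri_now[i])
      active_msg <<- c(active_msg, msg_now[i])
    }
  }
  release_latch <- function(codes_gone, t) {
    for (code in codes_gone) {
      i <- match(code, active_codes)
      al_log[[length(al_log) + 1L]] <<- data.frame(
        t_onset = active_onset[i], t_cleared = t, code = code,
        priority = active_pri[i], message = active_msg[i],
        stringsAsFactors = FALSE)
      active_codes <<- active_codes[-i]; active_onset <<- active_onset[-i]
      active_pri <<- active_pri[-i]; active_msg <<- active_msg[-i]
    }
  }
  sample_codes_prev <- character(0)
  breath_codes_prev <- character(0)

  # the controller reads the most recent sensor conversion: its sample at
  # tick k carries the measurement taken at tick k-1 (one-tick ADC latency)
  flow_meas_prev <- 0
  paw_meas_prev <- peep

  for (k in seq_len(n_ticks)) {
    t <- t_v[k]
    sample <- list(t = t, p_aw = paw_meas_prev, flow = flow_meas_prev)

    # --- controller tick ---
    res <- controller_step(sample, st, ctrl, cfg)
    ctrl <- res$state
    if (nrow(res$events) > 0L) {
      ev_t <- c(ev_t, res$events$t)
      ev_type <- c(ev_type, res$events$type)
      ev_detail <- c(ev_detail, res$events$detail)
      if (any(res$events$type %in% c("TIMED", "PATIENT"))) {
        # a new breath starts: close out the previous one for breath alarms
        if (!is.null(prev_breath)) {
          rec <- list(tidal_volume = prev_breath$delivered,
                      peep_min = min_paw_breath, t_start = prev_breath$t_start)
          ba <- evaluate_breath_alarms(rec, st)
          codes_now <- unique(ba$code)
          latch(codes_now, ba$priority[match(codes_now, ba$code)],
                ba$message[match(codes_now, ba$code)], t)
          release_latch(setdiff(breath_codes_prev, codes_now), t)
          breath_codes_prev <- codes_now
        }
        prev_breath <- list(t_start = t, delivered = NA_real_)
        bag_used <- 0
        min_paw_breath <- Inf
      }
    }
    if (!is.null(prev_breath) && is.na(prev_breath$delivered) &&
        ctrl$phase == "RELEASE" && !is.na(ctrl$delivered_last)) {
      prev_breath$delivered <- ctrl$delivered_last
      deliv_v[ctrl$breath_count] <- ctrl$delivered_last
    }

    # --- sample-cadence alarms (latched) ---
    sa <- evaluate_sample_alarms(sample, st, ctrl, peep_applied = peep)
    ctrl <- sa$state
    codes_now <- unique(sa$alarms$code)
    if (length(codes_now) || length(sample_codes_prev)) {
      latch(codes_now, sa$alarms$priority[match(codes_now, sa$alarms$code)],
            sa$alarms$message[match(codes_now, sa$alarms$code)], t)
      release_latch(setdiff(sample_codes_prev, codes_now), t)
      sample_codes_prev <- codes_now
    }

    phase <- res$phase
    phase_i <- if (phase == "COMPRESS") 1L else if (phase == "HOLD") 2L else 3L
    halted <- ctrl$halted_this_cycle

    p_alv_t <- p_alv; pm_t <- pm; V_t <- V

    # --- plant substeps under the held (zero-order-hold) phase command ---
    q_samp <- 0
    for (j in seq_len(n_sub)) {
      if (!run_en) {
        q <- 0
        if (p_alv < 0) q <- -p_alv / r_i
        if (p_alv > peep) q <- q - (p_alv - peep) / r_e
      } else if (phase_i == 3L) {
        q <- 0
        if (p_alv > peep) q <- -(p_alv - peep) / r_e
        if (p_alv < 0) q <- q - p_alv / r_i
      } else if (halted || bag_used >= bag_cap) {
        q <- 0
      } else if (phase_i == 1L || pc_mode) {
        h <- (pip - p_alv) / r_i
        q <- if (h < 0) 0 else if (h < drive_rate) h else drive_rate
      } else {
        q <- 0
      }
      if (j == 1L) q_samp <- q  # instantaneous flow at the sample instant
      V <- V + q * dt * 1000
      if (V < 0) V <- 0
      if (q > 0) bag_used <- bag_used + q * dt * 1000
      if (m_active) {
        tc <- (t + j * dt) %% m_period
        pm <- if (tc < m_ti) -m_p * sin(pi * tc / (2 * m_ti))
        else if (tc < m_titr) -m_p * cos(pi * (tc - m_ti) / (2 * m_tr))
        else 0
      }
      p_alv <- V / C + peep + pm
      if (!is.finite(p_alv))
        stop(sprintf("non-finite state at t = %.3f s; aborting", t + j * dt))
    }

    # --- sense and record at the sample instant t ---
    p_aw_true <- p_alv_t + (if (q_samp >= 0) r_i else r_e) * q_samp
    if (p_aw_true > mech_max) p_aw_true <- mech_max
    f60 <- q_samp * 60
    dp <- sign(f60) * (f60 / k_cal)^2
    if (scn$noise_sigma > 0) dp <- dp + noise_dp[k]
    if (dp > dp_rng) dp <- dp_rng else if (dp < -dp_rng) dp <- -dp_rng
    flow_meas <- sign(dp) * k_cal * sqrt(abs(dp))
    p_aw_meas <- p_aw_true
    if (scn$noise_sigma > 0) p_aw_meas <- p_aw_meas + noise_paw[k]
    if (p_aw_meas > paw_rng) p_aw_meas <- paw_rng
    else if (p_aw_meas < -paw_rng) p_aw_meas <- -paw_rng

    if (p_aw_true < min_paw_breath) min_paw_breath <- p_aw_true

    flow_v[k] <- flow_meas; paw_v[k] <- p_aw_meas
    palv_v[k] <- p_alv_t; pmus_v[k] <- pm_t; vol_v[k] <- V_t
    phase_v[k] <- phase_i

    flow_meas_prev <- flow_meas
    paw_meas_prev <- p_aw_meas
  }

  # flush still-active alarms with open clearing time
  for (i in seq_along(active_codes)) {
    al_log[[length(al_log) + 1L]] <- data.frame(
      t_onset = active_onset[i], t_cleared = NA_real_, code = active_codes[i],
      priority = active_pri[i], message = active_msg[i],
      stringsAsFactors = FALSE)
  }
  alarms <- if (length(al_log)) do.call(rbind, al_log) else empty_alarms()
  alarms <- alarms[order(alarms$t_onset), , drop = FALSE]
  rownames(alarms) <- NULL

  events <- data.frame(t = ev_t, type = ev_type, detail = ev_detail,
                       stringsAsFactors = FALSE)
  is_breath <- events$type %in% c("TIMED", "PATIENT")
  breaths <- data.frame(t_start = events$t[is_breath],
                        trigger = events$type[is_breath],
                        t_insp_commanded = rep(st$t_insp, sum(is_breath)),
                        stringsAsFactors = FALSE)
  # controller's integrated volume at hold entry, NA for a breath cut short
  # by the end of the recording
  breaths$delivered_ml <- rep(NA_real_, nrow(breaths))
  if (length(deliv_v) && nrow(breaths))
    breaths$delivered_ml[seq_along(deliv_v)] <- deliv_v
  efforts <- if (m_active) {
    on <- seq(0, scn$duration, by = 60 / mus$rate)
    on[on < scn$duration]
  } else numeric(0)

  structure(
    list(data = data.frame(t = t_v, flow_lpm = flow_v, p_aw = paw_v,
                           p_alv = palv_v, p_mus = pmus_v, volume_ml = vol_v,
                           phase = factor(PHASE_LEVELS[phase_v],
                                          levels = PHASE_LEVELS)),
         events = events, breaths = breaths, alarms = alarms,
         efforts = efforts, scenario = scn),
    class = "vent_waveform"
  )
}

#' @export
print.vent_waveform <- function(x, ...) {
  cat(sprintf("<vent_waveform> '%s': %g s @ 100 Hz, %d breaths, %d alarm events\n",
              x$scenario$label, x$scenario$duration, nrow(x$breaths),
              nrow(x$alarms)))
  invisible(x)
}

#' Resample a waveform onto a different uniform grid
#'
#' Linear interpolation of all continuous channels onto a new rate (the
#' bench analysis used 64 Hz); the phase channel takes the previous value.
#'
#' @param wave a `vent_waveform` or its `data` data.frame.
#' @param rate target rate, Hz.
#' @return a data.frame in the same column layout.
#' @export
resample_waveform <- function(wave, rate = 64) {
  d <- if (inherits(wave, "vent_waveform")) wave$data else wave
  tt <- seq(min(d$t), max(d$t), by = 1 / rate)
  out <- data.frame(t = tt)
  for (col in c("flow_lpm", "p_aw", "p_alv", "p_mus", "volume_ml"))
    out[[col]] <- stats::approx(d$t, d[[col]], xout = tt)$y
  ph <- stats::approx(d$t, as.integer(d$phase), xout = tt, method = "constant",
                      rule = 2)$y
  out$phase <- factor(PHASE_LEVELS[ph], levels = PHASE_LEVELS)
  out
}

#' Run a batch of scenarios and summarise each
#'
#' Runs every scenario, segments its waveform into breaths and reduces it to
#' one summary row. Failures in individual scenarios are caught and reported
#' in the `error` column without aborting the batch. Duplicate labels are
#' disambiguated with deterministic ordinal suffixes (`_2`, `_3`, ...).
#'
#' @param scenarios list of [scenario()] objects.
#' @return data.frame with one row per scenario: label, lung, mode, breath
#'   count, mean/SD of tidal volume, PIP, PEEP, RR and I:E, the per-breath
#'   PIP maximum, missed-trigger fraction (spontaneous scenarios), alarm
#'   count and error message (if any).
#' @export
run_suite <- function(scenarios) {
  stopifnot(is.list(scenarios))
  if (length(scenarios) == 0L)
    return(data.frame(
      label = character(0), lung = character(0), mode = character(0),
      n_breaths = integer(0), tv_mean = numeric(0), tv_sd = numeric(0),
      pip_mean = numeric(0), pip_sd = numeric(0), pip_max_breath = numeric(0),
      peep_mean = numeric(0), peep_sd = numeric(0), rr_mean = numeric(0),
      rr_sd = numeric(0), ie_mean = numeric(0), ie_sd = numeric(0),
      missed_fraction = numeric(0), n_alarms = integer(0),
      error = character(0), stringsAsFactors = FALSE))
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    for (lab in unique(labels[duplicated(labels)])) {
      idx <- which(labels == lab)
      labels[idx[-1]] <- paste0(lab, "_", seq_along(idx[-1]) + 1L)
    }
  }
  rows <- lapply(seq_along(scenarios), function(i) {
    scn <- scenarios[[i]]
    base <- data.frame(
      label = labels[i], lung = scn$lung$label, mode = scn$settings$mode,
      n_breaths = NA_integer_, tv_mean = NA_real_, tv_sd = NA_real_,
      pip_mean = NA_real_, pip_sd = NA_real_, pip_max_breath = NA_real_,
      peep_mean = NA_real_, peep_sd = NA_real_, rr_mean = NA_real_,
      rr_sd = NA_real_, ie_mean = NA_real_, ie_sd = NA_real_,
      missed_fraction = NA_real_, n_alarms = NA_integer_,
      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      wave <- run_simulation(scn)
      br <- segment_breaths(wave)
      ms <- summarize_breaths(br, efforts = wave$efforts,
                              warmup = scn$warmup_breaths)
      base$n_breaths <- ms$n_breaths
      base$tv_mean <- ms$tv_mean; base$tv_sd <- ms$tv_sd
      base$pip_mean <- ms$pip_mean; base$pip_sd <- ms$pip_sd
      base$pip_max_breath <- ms$pip_max
      base$peep_mean <- ms$peep_mean; base$peep_sd <- ms$peep_sd
      base$rr_mean <- ms$rr_mean; base$rr_sd <- ms$rr_sd
      base$ie_mean <- ms$ie_mean; base$ie_sd <- ms$ie_sd
      base$missed_fraction <- if (is.null(ms$missed_fraction)) NA_real_ else ms$missed_fraction
      base$n_alarms <- nrow(wave$alarms)
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a waveform to CSV
#'
#' Columns `t_s, flow_lpm, p_aw_cmh2o, p_alv_cmh2o, p_mus_cmh2o, volume_ml,
#' phase`.
#'
#' @param wave a `vent_waveform` or its `data` data.frame.
#' @param path output path.
#' @export
write_waveform_csv <- function(wave, path) {
  d <- if (inherits(wave, "vent_waveform")) wave$data else wave
  out <- data.frame(t_s = d$t, flow_lpm = d$flow_lpm, p_aw_cmh2o = d$p_aw,
                    p_alv_cmh2o = d$p_alv, p_mus_cmh2o = d$p_mus,
                    volume_ml = d$volume_ml, phase = as.character(d$phase))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform CSV back into the internal column layout
#'
#' Accepts the dialect of [write_waveform_csv()]; the pressure/phase columns
#' beyond time and flow are optional, so third-party recordings with only
#' `t_s, flow_lpm, p_aw_cmh2o` can be analysed.
#'
#' @param path CSV path.
#' @return data.frame with columns `t`, `flow_lpm`, `p_aw` (and any further
#'   recorded channels).
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_s", "flow_lpm") %in% names(d)))
    stop("waveform CSV must have at least columns t_s, flow_lpm")
  out <- data.frame(t = d$t_s, flow_lpm = d$flow_lpm)
  if ("p_aw_cmh2o" %in% names(d)) out$p_aw <- d$p_aw_cmh2o
  if ("p_alv_cmh2o" %in% names(d)) out$p_alv <- d$p_alv_cmh2o
  if ("p_mus_cmh2o" %in% names(d)) out$p_mus <- d$p_mus_cmh2o
  if ("volume_ml" %in% names(d)) out$volume_ml <- d$volume_ml
  if ("phase" %in% names(d)) out$phase <- factor(d$phase, levels = PHASE_LEVELS)
  out
}
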