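#' Patient-circuit configuration
#'
#' Parameters of the pneumatic drive and the mechanical valves: the
#' self-inflating bag (capacity and full-stroke compression time), the
#' peak-inspiratory-pressure (PIP) relief valve, the PEEP threshold valve,
#' and the absolute mechanical pressure ceiling that no state may exceed.
#'
#' @param pip_setting PIP relief-valve setting, cmH2O. The constructed valve
#'   covers roughly 20--40 cmH2O; values outside that band are accepted with
#'   a warning (the hardware knob can be forced past its markings).
#' @param peep_setting PEEP valve setting, cmH2O (>= 0).
#' @param bag_capacity deliverable bag volume per stroke, mL (default 750,
#'   within the 700--800 mL a typical adult resuscitator bag provides).
#' @param stroke_time full piston down-stroke time, seconds (default 0.5).
#' @param mechanical_max absolute relief ceiling, 60 cmH2O.
#' @return an object of class `circuit_config`.
#' @export
circuit_config <- function(pip_setting = 35, peep_setting = 5,
                           bag_capacity = 750, stroke_time = 0.5,
                           mechanical_max = 60) {
  stopifnot(is.numeric(pip_setting), is.finite(pip_setting),
            is.numeric(peep_setting), peep_setting >= 0,
            bag_capacity > 0, stroke_time > 0)
  if (pip_setting < 20 || pip_setting > 40)
    warning("pip_setting ", pip_setting,
            " cmH2O is outside the constructed PIP-valve range (20-40)")
  structure(
    list(pip_setting = as.numeric(pip_setting),
         peep_setting = as.numeric(peep_setting),
         bag_capacity = as.numeric(bag_capacity),
         stroke_time = as.numeric(stroke_time),
         mechanical_max = as.numeric(mechanical_max)),
    class = "circuit_config"
  )
}

#' @export
print.circuit_config <- function(x, ...) {
  cat(sprintf("<circuit_config> PIP %g, PEEP %g cmH2O; bag %g mL / %g s stroke\n",
              x$pip_setting, x$peep_setting, x$bag_capacity, x$stroke_time))
  invisible(x)
}

#' Spirometer calibration
#'
#' Differential-pressure spirometer model: flow across the orifice follows
#' `flow = sign(dp) * k * sqrt(|dp|)` (L/min for dp in cmH2O). The sensor
#' pair samples at 100 Hz; the differential channel saturates at `dp_range`
#' and the gauge (airway) channel at `paw_range`.
#'
#' @param k flow coefficient, (L/min) per sqrt(cmH2O). The hardware value is
#'   determined by calibration; the default 45 spans the drive's ~90 L/min
#'   peak flow within the 5 cmH2O differential range.
#' @param dp_range differential-sensor range, cmH2O (default 5).
#' @param paw_range airway-pressure sensor range, cmH2O (default 50).
#' @param sample_rate sensor sampling rate, Hz (default 100).
#' @return an object of class `spirometer_cal`.
#' @export
spirometer_cal <- function(k = 45, dp_range = 5, paw_range = 50,
                           sample_rate = 100) {
  stopifnot(is.numeric(k), is.finite(k), k > 0, dp_range > 0, paw_range > 0,
            sample_rate > 0)
  structure(list(k = as.numeric(k), dp_range = as.numeric(dp_range),
                 paw_range = as.numeric(paw_range),
                 sample_rate = as.numeric(sample_rate),
                 rms_residual = NA_real_, n_pairs = NA_integer_),
            class = "spirometer_cal")
}

#' @export
print.spirometer_cal <- function(x, ...) {
  cat(sprintf("<spirometer_cal> k = %.4g (L/min)/sqrt(cmH2O), dp range %g, paw range %g cmH2O @ %g Hz\n",
              x$k, x$dp_range, x$paw_range, x$sample_rate))
  if (is.finite(x$rms_residual))
    cat(sprintf("  fitted from %d pairs, residual RMS %.3g L/min\n", x$n_pairs, x$rms_residual))
  invisible(x)
}

#' Piston drive flow for a controller phase
#'
#' The pneumatic piston compresses the bag at a constant rate during
#' COMPRESS (`bag_capacity / stroke_time`); in HOLD it is held in place
#' (pressure maintained, no piston motion) and in RELEASE it is retracted,
#' so the drive itself contributes no flow in either.
#'
#' @param phase one of `"COMPRESS"`, `"HOLD"`, `"RELEASE"`.
#' @param cfg a [circuit_config()].
#' @param commanded logical run-enable flag; a disabled drive never flows.
#' @return drive flow in L/s.
#' @examples
#' drive_flow("COMPRESS", circuit_config())  # 0.75 L over 0.5 s = 1.5 L/s
#' @export
drive_flow <- function(phase, cfg, commanded = TRUE) {
  if (!phase %in% c("COMPRESS", "HOLD", "RELEASE"))
    stop("unknown controller phase '", phase, "'")
  if (!isTRUE(commanded) || phase != "COMPRESS") return(0)
  cfg$bag_capacity / 1000 / cfg$stroke_time
}

#' PIP relief-valve flow limit
#'
#' The relief valve vents any drive flow that would push the airway pressure
#' above the valve setting, so the delivered flow is
#' `min(q_drive, max(0, (pip_setting - p_alv) / r_insp))` and
#' `p_alv + r_insp * q` never exceeds `pip_setting`. Excess flow is vented,
#' not delivered.
#'
#' @param q_drive drive flow offered by the piston, L/s (>= 0).
#' @param p_alv current alveolar pressure, cmH2O.
#' @param r_insp inspiratory resistance, cmH2O/(L/s) (> 0).
#' @param cfg a [circuit_config()].
#' @return delivered flow in L/s; vectorised over `p_alv`.
#' @export
pip_limit <- function(q_drive, p_alv, r_insp, cfg) {
  if (!is.numeric(r_insp) || r_insp <= 0) stop("`r_insp` must be > 0")
  if (any(q_drive < 0)) stop("`q_drive` must be >= 0")
  pmin(q_drive, pmax(0, (cfg$pip_setting - p_alv) / r_insp))
}

#' Expiratory (PEEP-valve) flow
#'
#' During RELEASE the lung empties through the patient valve's exhaust port
#' into the PEEP threshold valve: flow is `-(p_alv - peep_setting)/r_exp`
#' when alveolar pressure exceeds the PEEP setting and zero otherwise, so
#' exhalation alone never pulls the airway below PEEP.
#'
#' @param p_alv alveolar pressure, cmH2O.
#' @param r_exp expiratory resistance, cmH2O/(L/s) (> 0).
#' @param cfg a [circuit_config()].
#' @return signed flow in L/s (<= 0); vectorised over `p_alv`.
#' @export
expiratory_flow <- function(p_alv, r_exp, cfg) {
  if (!is.numeric(r_exp) || r_exp <= 0) stop("`r_exp` must be > 0")
  -pmax(0, p_alv - cfg$peep_setting) / r_exp
}

#' Flow from spirometer differential pressure
#'
#' Square-root orifice law: `flow = sign(dp) * k * sqrt(|dp|)`. Readings
#' beyond the differential range are clipped to the range (the saturated
#' samples are flagged via the `"clipped"` attribute).
#'
#' @param dp differential pressure, cmH2O; vectorised.
#' @param cal a [spirometer_cal()].
#' @return flow in L/min, with attribute `clipped` (logical vector).
#' @export
flow_from_dp <- function(dp, cal = spirometer_cal()) {
  if (any(!is.finite(dp))) stop("`dp` must be finite")
  clipped <- abs(dp) > cal$dp_range
  dp <- pmin(pmax(dp, -cal$dp_range), cal$dp_range)
  structure(sign(dp) * cal$k * sqrt(abs(dp)), clipped = clipped)
}

#' Differential pressure from flow (inverse spirometer law)
#'
#' Exact inverse of [flow_from_dp()] for flows within the sensor range:
#' `dp = sign(flow) * (flow/k)^2`, clipped at the differential range.
#'
#' @param flow flow, L/min; vectorised.
#' @param cal a [spirometer_cal()].
#' @return differential pressure in cmH2O.
#' @export
dp_from_flow <- function(flow, cal = spirometer_cal()) {
  if (any(!is.finite(flow))) stop("`flow` must be finite")
  dp <- sign(flow) * (flow / cal$k)^2
  pmin(pmax(dp, -cal$dp_range), cal$dp_range)
}

#' Fit the spirometer coefficient from calibration pairs
#'
#' Least-squares fit of `flow` against `sqrt(dp)` through the origin, the
#' procedure used to calibrate the orifice spirometer against a reference
#' flowmeter. Pairs with `dp <= 0` are ignored.
#'
#' @param pairs a data.frame with columns `dp` (cmH2O) and `flow` (L/min),
#'   or a two-column matrix in that order.
#' @param ... passed to [spirometer_cal()] (e.g. `dp_range`).
#' @return a [spirometer_cal()] with the fitted `k` and the fit residual RMS
#'   in `rms_residual`.
#' @examples
#' calibrate_spirometer(data.frame(dp = c(1, 4), flow = c(60, 120)))
#' @export
calibrate_spirometer <- function(pairs, ...) {
  if (is.matrix(pairs)) pairs <- data.frame(dp = pairs[, 1], flow = pairs[, 2])
  if (is.null(pairs$dp) || is.null(pairs$flow))
    stop("`pairs` must have columns `dp` and `flow`")
  keep <- is.finite(pairs$dp) & is.finite(pairs$flow) & pairs$dp > 0
  if (!any(keep)) stop("degenerate fit: no calibration pair has dp > 0")
  x <- sqrt(pairs$dp[keep])
  y <- pairs$flow[keep]
  k <- sum(x * y) / sum(x * x)
  cal <- spirometer_cal(k = k, ...)
  cal$rms_residual <- sqrt(mean((y - k * x)^2))
  cal$n_pairs <- length(y)
  cal
}

#' Read spirometer calibration pairs from CSV
#'
#' Two-column CSV with header `dp_cmh2o, flow_lpm`.
#'
#' @param path file path.
#' @return data.frame with columns `dp`, `flow`.
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("dp_cmh2o", "flow_lpm") %in% names(d)))
    stop("calibration CSV must have columns dp_cmh2o, flow_lpm")
  data.frame(dp = d$dp_cmh2o, flow = d$flow_lpm)
}

#' Write spirometer calibration pairs to CSV
#' @param pairs data.frame with columns `dp`, `flow`.
#' @param path file path.
#' @export
write_calibration_csv <- function(pairs, path) {
  utils::write.csv(data.frame(dp_cmh2o = pairs$dp, flow_lpm = pairs$flow),
                   path, row.names = FALSE)
  invisible(path)
}
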