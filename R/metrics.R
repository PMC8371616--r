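#' Segment a waveform into breaths
#'
#' Flow-threshold breath detection, deliberately independent of the
#' controller's phase codes so recorded or third-party waveforms can be
#' analysed. A breath onset is an upward crossing of +1 L/min of the flow
#' signal, re-armed with 0.5 L/min hysteresis (flow must first fall below
#' 0.5 L/min). The inspiratory window runs from the onset to the first
#' expiratory crossing below -1 L/min; it therefore includes any zero-flow
#' inspiratory pause. Per breath:
#' \itemize{
#'   \item tidal volume: trapezoidal integral of positive flow over the
#'     inspiratory window, mL;
#'   \item PIP / PEEP: maximum / minimum airway pressure between consecutive
#'     onsets;
#'   \item I:E ratio reported as expiratory/inspiratory time,
#'     `(duration - t_insp)/t_insp`.
#' }
#' The final (incomplete) breath is dropped. When the waveform carries
#' controller breath events, each detected breath is tagged with the trigger
#' type (TIMED/PATIENT) of the nearest breath start within 100 ms.
#'
#' @param wave a `vent_waveform` from [run_simulation()], or a data.frame
#'   with columns `t`, `flow_lpm` and optionally `p_aw`.
#' @param threshold onset threshold, L/min (default 1).
#' @param hysteresis re-arm band below the threshold, L/min (default 0.5).
#' @return data.frame of breath records: `t_start`, `duration`,
#'   `tidal_volume`, `pip`, `peep_min`, `t_insp_measured`, `ie_ratio`,
#'   `trigger`. Zero rows (with a warning) when no breaths are found.
#' @export
segment_breaths <- function(wave, threshold = 1, hysteresis = 0.5) {
  breaths_df <- NULL
  if (inherits(wave, "vent_waveform")) {
    breaths_df <- wave$breaths
    d <- wave$data
  } else d <- wave
  stopifnot(is.data.frame(d), all(c("t", "flow_lpm") %in% names(d)))
  t <- d$t; flow <- d$flow_lpm
  p_aw <- if ("p_aw" %in% names(d)) d$p_aw else rep(NA_real_, length(t))
  n <- length(t)

  arm_lvl <- threshold - hysteresis
  onsets <- integer(0)
  armed <- TRUE
  for (i in seq_len(n)) {
    f <- flow[i]
    if (armed && f >= threshold) {
      onsets <- c(onsets, i)
      armed <- FALSE
    } else if (!armed && f < arm_lvl) armed <- TRUE
  }
  if (length(onsets) < 2L) {
    warning("no breaths found: fewer than two inspiratory onsets")
    return(data.frame(t_start = numeric(0), duration = numeric(0),
                      tidal_volume = numeric(0), pip = numeric(0),
                      peep_min = numeric(0), t_insp_measured = numeric(0),
                      ie_ratio = numeric(0), trigger = character(0),
                      stringsAsFactors = FALSE))
  }

  nb <- length(onsets) - 1L
  rec <- vector("list", nb)
  for (b in seq_len(nb)) {
    i0 <- onsets[b]; i1 <- onsets[b + 1L]
    win <- i0:(i1 - 1L)
    exp_rel <- which(flow[win] <= -threshold)
    if (length(exp_rel) == 0L) next  # no expiration found; skip fragment
    ie_end <- win[exp_rel[1L]]
    insp <- i0:ie_end
    fpos <- pmax(flow[insp], 0) / 60  # L/s
    tv <- sum((fpos[-1] + fpos[-length(fpos)]) / 2 * diff(t[insp])) * 1000
    ti <- t[ie_end] - t[i0]
    dur <- t[i1] - t[i0]
    rec[[b]] <- data.frame(
      t_start = t[i0], duration = dur, tidal_volume = tv,
      pip = max(p_aw[win]), peep_min = min(p_aw[win]),
      t_insp_measured = ti, ie_ratio = (dur - ti) / ti,
      trigger = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    warning("no complete breaths found")
    return(data.frame(t_start = numeric(0), duration = numeric(0),
                      tidal_volume = numeric(0), pip = numeric(0),
                      peep_min = numeric(0), t_insp_measured = numeric(0),
                      ie_ratio = numeric(0), trigger = character(0),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  if (!is.null(breaths_df) && nrow(breaths_df) > 0L) {
    for (b in seq_len(nrow(out))) {
      dtb <- out$t_start[b] - breaths_df$t_start
      j <- which(dtb >= -0.05 & dtb <= 0.1)
      if (length(j)) out$trigger[b] <- breaths_df$trigger[j[length(j)]]
    }
  }
  out
}

#' Summarise breath records
#'
#' Reduces a set of per-breath records to the derived-parameter summary:
#' mean and SD of tidal volume, PIP, minimum (end-expiratory) pressure,
#' respiratory rate and I:E ratio over the post-warm-up breaths. The
#' respiratory rate is `60 / mean(duration)`; its SD is that of the
#' per-breath rates. When patient effort onset times are supplied, the
#' missed-trigger fraction is the share of efforts not followed by a
#' PATIENT-triggered breath within the matching window.
#'
#' @param records breath data.frame from [segment_breaths()].
#' @param efforts optional numeric vector of patient effort onset times (s).
#' @param warmup number of initial breaths excluded from the summary
#'   (default 5; spontaneous scenarios conventionally use 10).
#' @param match_window effort-to-breath matching window, seconds
#'   (default 0.3, shorter than the shortest breath period tested).
#' @return an object of class `metrics_summary`: a list with `n_breaths`,
#'   `tv_mean`, `tv_sd`, `pip_mean`, `pip_sd`, `pip_max`, `peep_mean`,
#'   `peep_sd`, `rr_mean`, `rr_sd`, `ie_mean`, `ie_sd`, `missed_fraction`
#'   (NULL without efforts) and `valid` (TRUE when >= 20 breaths remain).
#' @export
summarize_breaths <- function(records, efforts = NULL, warmup = 5,
                              match_window = 0.3) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no breath records to summarise")
  n_drop <- min(warmup, nrow(records) - 1L)
  keep <- if (n_drop > 0) records[-seq_len(n_drop), , drop = FALSE] else records
  rr_each <- 60 / keep$duration
  out <- list(
    n_breaths = nrow(keep),
    tv_mean = mean(keep$tidal_volume), tv_sd = stats::sd(keep$tidal_volume),
    pip_mean = mean(keep$pip), pip_sd = stats::sd(keep$pip),
    pip_max = max(keep$pip),
    peep_mean = mean(keep$peep_min), peep_sd = stats::sd(keep$peep_min),
    rr_mean = 60 / mean(keep$duration), rr_sd = stats::sd(rr_each),
    ie_mean = mean(keep$ie_ratio), ie_sd = stats::sd(keep$ie_ratio),
    missed_fraction = NULL,
    valid = nrow(keep) >= 20L
  )
  if (!is.null(efforts) && length(efforts) > 0L) {
    # only efforts inside the analysed span, and early enough that a
    # response could still fall inside the recording
    t_lo <- min(keep$t_start) - match_window
    t_hi <- max(records$t_start)
    eff <- efforts[efforts >= t_lo & efforts <= t_hi - match_window]
    if (length(eff)) {
      pat <- records$t_start[!is.na(records$trigger) & records$trigger == "PATIENT"]
      matched <- vapply(eff, function(e)
        any(pat >= e & pat <= e + match_window), logical(1))
      out$missed_fraction <- mean(!matched)
      out$n_efforts <- length(eff)
    }
  }
  structure(out, class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary> %d breaths%s\n", x$n_breaths,
              if (x$valid) "" else " (fewer than 20: summary not valid)"))
  cat(sprintf("  TV   %7.1f (SD %5.2f) mL\n", x$tv_mean, x$tv_sd))
  cat(sprintf("  PIP  %7.1f (SD %5.2f) cmH2O, per-breath max %.1f\n",
              x$pip_mean, x$pip_sd, x$pip_max))
  cat(sprintf("  PEEP %7.1f (SD %5.2f) cmH2O\n", x$peep_mean, x$peep_sd))
  cat(sprintf("  RR   %7.2f (SD %5.2f) brpm\n", x$rr_mean, x$rr_sd))
  cat(sprintf("  I:E  1:%.2f (SD %.2f)\n", x$ie_mean, x$ie_sd))
  if (!is.null(x$missed_fraction))
    cat(sprintf("  missed triggers: %.1f%% of %d efforts\n",
                100 * x$missed_fraction, x$n_efforts))
  invisible(x)
}

#' Write a metrics summary to disk
#'
#' Writes a flat `key = value` text table (human-readable) and, optionally,
#' the per-breath records as CSV.
#'
#' @param summary a `metrics_summary`.
#' @param path output path for the text table.
#' @param records optional breath records data.frame; written next to
#'   `path` with suffix `_breaths.csv`.
#' @export
write_metrics <- function(summary, path, records = NULL) {
  keys <- c("n_breaths", "tv_mean", "tv_sd", "pip_mean", "pip_sd", "pip_max",
            "peep_mean", "peep_sd", "rr_mean", "rr_sd", "ie_mean", "ie_sd")
  lines <- vapply(keys, function(k) sprintf("%s = %.6g", k, summary[[k]]),
                  character(1))
  if (!is.null(summary$missed_fraction))
    lines <- c(lines, sprintf("missed_fraction = %.6g", summary$missed_fraction))
  writeLines(lines, path)
  if (!is.null(records)) {
    rp <- sub("(\\.[^.]*)?$", "_breaths.csv", path)
    utils::write.csv(records, rp, row.names = FALSE)
  }
  invisible(path)
}
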