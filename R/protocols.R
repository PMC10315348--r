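#' Sampling/replacement schedule for a release experiment
#'
#' An ordered table of sampling events. Each event records the day it
#' occurs, which phase is sampled, the aliquot volume withdrawn, whether the
#' whole medium is replaced (`"full"`, monophasic protocol) or only the
#' aliquot (`"partial"`, biphasic protocol), the vessel volume in effect over
#' the interval ending at the event, and the dilution factor applied before
#' HPLC injection.
#'
#' @param time Event times in days, strictly increasing within a phase.
#' @param phase Phase label per event: `"single"`, `"buffer"` or `"octanol"`.
#' @param sample_volume Aliquot volume withdrawn, mL (<= vessel volume).
#' @param replacement `"full"` or `"partial"` per event.
#' @param vessel_volume Vessel volume in effect for the interval ending at
#'   the event, mL.
#' @param dilution_factor Pre-injection dilution factor (>= 1).
#' @return A `sampling_protocol` data frame.
#' @export
sampling_protocol <- function(time, phase = "single", sample_volume,
                              replacement, vessel_volume,
                              dilution_factor = 1) {
  ev <- data.frame(time = time, phase = phase,
                   sample_volume = sample_volume,
                   replacement = replacement,
                   vessel_volume = vessel_volume,
                   dilution_factor = dilution_factor)
  for (ph in unique(ev$phase)) {
    tt <- ev$time[ev$phase == ph]
    if (any(diff(tt) <= 0)) {
      stop("event times must be strictly increasing within each phase",
           call. = FALSE)
    }
  }
  if (any(ev$sample_volume > ev$vessel_volume)) {
    stop("sample volume cannot exceed vessel volume", call. = FALSE)
  }
  if (any(ev$dilution_factor < 1)) {
    stop("dilution factors must be >= 1", call. = FALSE)
  }
  if (!all(ev$replacement %in% c("full", "partial"))) {
    stop("replacement must be 'full' or 'partial'", call. = FALSE)
  }
  structure(ev, class = c("sampling_protocol", "data.frame"))
}

#' Weekday/weekend monophasic protocol with full medium replacement
#'
#' Daily sampling with complete discard-and-refill of the medium, skipping
#' weekends: on Fridays the vessel is refilled with a double volume that
#' stays in place until the Monday sample (a 3-day interval). Day 0 is the
#' moment of ring immersion; with the default anchor, days congruent to 5 or
#' 6 modulo 7 are weekend days, so day 28 falls on a Monday-style sample.
#' The initial fill (interval ending on day 1) uses the weekend volume,
#' matching the common practice of a larger first fill.
#'
#' @param days Total duration, days (default 28).
#' @param weekday_volume Refill volume for 1-day intervals, mL (default 100).
#' @param weekend_volume Refill volume for the initial fill and for
#'   intervals spanning a weekend, mL (default 200).
#' @param sample_volume Aliquot taken for analysis, mL (default 1; the rest
#'   is discarded, so it does not enter the mass balance).
#' @param weekend_days Which residues of `time %% 7` are unsampled weekend
#'   days (default `c(5, 6)`).
#' @return A [sampling_protocol()].
#' @export
monophasic_protocol <- function(days = 28, weekday_volume = 100,
                                weekend_volume = 200, sample_volume = 1,
                                weekend_days = c(5, 6)) {
  tt <- seq_len(days)
  tt <- tt[!(tt %% 7) %in% weekend_days]
  dt <- diff(c(0, tt))
  vol <- ifelse(dt > 1 | tt == tt[1], weekend_volume, weekday_volume)
  sampling_protocol(time = tt, phase = "single",
                    sample_volume = sample_volume,
                    replacement = "full", vessel_volume = vol)
}

#' Biphasic buffer/octanol protocol with daily partial sampling
#'
#' Every day a fixed aliquot is withdrawn separately from the aqueous buffer
#' and the octanol overlay and replaced with the same volume of drug-free
#' medium, so each phase's volume is constant. Octanol samples are diluted
#' before injection.
#'
#' @param days Duration, days (default 28).
#' @param buffer_volume Aqueous phase volume, mL (default 100).
#' @param octanol_volume Octanol overlay volume, mL (default 20).
#' @param sample_volume Daily aliquot per phase, mL (default 1).
#' @param octanol_dilution Dilution factor for octanol samples (default 20).
#' @return A [sampling_protocol()] with interleaved buffer/octanol events.
#' @export
biphasic_protocol <- function(days = 28, buffer_volume = 100,
                              octanol_volume = 20, sample_volume = 1,
                              octanol_dilution = 20) {
  tt <- seq_len(days)
  rbind_protocol <- function(a, b) {
    structure(rbind(as.data.frame(a), as.data.frame(b)),
              class = c("sampling_protocol", "data.frame"))
  }
  rbind_protocol(
    sampling_protocol(tt, phase = "buffer", sample_volume = sample_volume,
                      replacement = "partial", vessel_volume = buffer_volume),
    sampling_protocol(tt, phase = "octanol", sample_volume = sample_volume,
                      replacement = "partial", vessel_volume = octanol_volume,
                      dilution_factor = octanol_dilution)
  )
}

protocol_phase <- function(protocol, phase) {
  ev <- protocol[protocol$phase == phase, , drop = FALSE]
  ev[order(ev$time), , drop = FALSE]
}

#' Measured concentration time series for one replicate and phase
#'
#' @param replicate_id Replicate (ring) identifier.
#' @param times Sampling days, strictly increasing.
#' @param concentrations Measured concentrations, ug/mL, already corrected
#'   for any pre-injection dilution. Must be non-negative.
#' @param phase `"single"`, `"buffer"` or `"octanol"`.
#' @return A `concentration_series` object.
#' @export
concentration_series <- function(replicate_id, times, concentrations,
                                 phase = "single") {
  stopifnot(length(times) == length(concentrations))
  ord <- order(times)
  times <- times[ord]; concentrations <- concentrations[ord]
  if (any(diff(times) <= 0)) {
    stop("sampling times must be distinct", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(replicate_id = replicate_id, phase = phase, times = times,
         concentrations = concentrations),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series: replicate %s, phase %s, %d samples (day %g-%g)\n",
              x$replicate_id, x$phase, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

new_release_profile <- function(replicate_id, times, interval_amounts,
                                interval_lengths, loading = NULL,
                                qc_decreasing = integer()) {
  cumulative <- cumsum(interval_amounts)
  df <- data.frame(
    time = times,
    interval_length = interval_lengths,
    interval_amount = interval_amounts,
    daily_rate = interval_amounts / interval_lengths,
    cumulative = cumulative
  )
  if (!is.null(loading)) df$fractional <- cumulative / loading
  structure(df, class = c("release_profile", "data.frame"),
            replicate_id = replicate_id, loading = loading,
            qc_decreasing = qc_decreasing)
}

#' @export
print.release_profile <- function(x, ...) {
  cat(sprintf("Release profile: replicate %s, %d intervals, cumulative %.4g ug at day %g\n",
              attr(x, "replicate_id"), nrow(x),
              x$cumulative[nrow(x)], x$time[nrow(x)]))
  qc <- attr(x, "qc_decreasing")
  if (length(qc)) {
    cat("  QC: cumulative decreases at day(s)", paste(qc, collapse = ", "), "\n")
  }
  NextMethod()
}
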