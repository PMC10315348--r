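#' Reconstruct release under full medium replacement
#'
#' With complete discard-and-refill at every sampling event, all drug found
#' in the vessel at event i was released during interval i, so the interval
#' amount is simply `C_i * V_i` (concentration times the vessel volume in
#' effect over that interval) and the cumulative release is the running sum.
#' Intervals spanning a weekend carry their true length, and the per-day
#' rate is `amount / interval length`.
#'
#' @param series A [concentration_series()].
#' @param protocol A [sampling_protocol()] whose events (for the series'
#'   phase) are all full-replacement and cover every sampling time.
#' @param loading Optional ring loading (ug) for fractional release.
#' @return A `release_profile` data frame with columns `time`,
#'   `interval_length`, `interval_amount`, `daily_rate`, `cumulative` and,
#'   when `loading` is given, `fractional`.
#' @export
reconstruct_monophasic <- function(series, protocol, loading = NULL) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(protocol, "sampling_protocol"))
  ev <- protocol_phase(protocol, series$phase)
  if (!all(ev$replacement == "full")) {
    stop("monophasic reconstruction requires full-replacement events",
         call. = FALSE)
  }
  idx <- match(series$times, ev$time)
  if (anyNA(idx)) {
    stop(sprintf("schedule mismatch: no protocol event at day(s) %s",
                 paste(series$times[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  V <- ev$vessel_volume[idx]
  amounts <- series$concentrations * V
  lens <- diff(c(0, series$times))
  new_release_profile(series$replicate_id, series$times, amounts, lens,
                      loading = loading)
}

#' Reconstruct release under partial sampling (biphasic phases)
#'
#' With a constant vessel volume `V` and a small aliquot `v_s` withdrawn and
#' replaced by drug-free medium at each event, the cumulative amount
#' attributable to the phase at event n is the drug currently present plus
#' everything previously removed by sampling:
#' `A_n = V * C_n + sum_(i<n) v_s * C_i`.
#' Measured noise can make `A_n` decrease between events; decreases are not
#' forced away but flagged in the profile's `qc_decreasing` attribute.
#'
#' @inheritParams reconstruct_monophasic
#' @return A `release_profile`; `interval_amount` holds the (possibly
#'   negative) first differences of `A_n`.
#' @export
reconstruct_biphasic <- function(series, protocol, loading = NULL) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(protocol, "sampling_protocol"))
  ev <- protocol_phase(protocol, series$phase)
  if (nrow(ev) == 0) {
    stop(sprintf("protocol has no events for phase '%s'", series$phase),
         call. = FALSE)
  }
  if (!all(ev$replacement == "partial")) {
    stop("biphasic reconstruction requires partial-replacement events",
         call. = FALSE)
  }
  if (length(unique(ev$vessel_volume)) != 1) {
    stop("biphasic reconstruction assumes a constant phase volume",
         call. = FALSE)
  }
  idx <- match(series$times, ev$time)
  if (anyNA(idx)) {
    stop(sprintf("schedule mismatch: no protocol event at day(s) %s",
                 paste(series$times[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  V <- ev$vessel_volume[1]
  vs <- ev$sample_volume[idx]
  C <- series$concentrations
  removed_before <- c(0, cumsum(vs * C)[-length(C)])
  A <- V * C + removed_before
  amounts <- diff(c(0, A))
  qc <- series$times[amounts < 0]
  lens <- diff(c(0, series$times))
  new_release_profile(series$replicate_id, series$times, amounts, lens,
                      loading = loading, qc_decreasing = qc)
}

#' Weighted linear HPLC calibration curve
#'
#' Fits `response = intercept + slope * concentration` by weighted least
#' squares. The default `1/x^2` weighting reflects concentration-
#' proportional assay variance, the usual convention for chromatographic
#' calibration over a wide range.
#'
#' @param nominal Nominal standard concentrations, ug/mL (>= 3, positive).
#' @param response Instrument responses at those standards.
#' @param weighting `"1/x2"` (default), `"1/x"`, or `"none"`.
#' @return A `calibration_curve` with `slope`, `intercept` and the
#'   calibrated concentration `range`.
#' @export
calibration_curve <- function(nominal, response,
                              weighting = c("1/x2", "1/x", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(length(nominal) == length(response))
  if (length(nominal) < 3) {
    stop("calibration requires at least 3 standards", call. = FALSE)
  }
  if (any(nominal <= 0)) stop("nominal concentrations must be positive",
                              call. = FALSE)
  w <- switch(weighting, "1/x2" = 1 / nominal^2, "1/x" = 1 / nominal,
              none = rep(1, length(nominal)))
  fit <- stats::lm(response ~ nominal, weights = w)
  co <- stats::coef(fit)
  if (co[2] <= 0) stop("calibration slope must be positive", call. = FALSE)
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]),
         range = range(nominal), weighting = weighting,
         n_points = length(nominal)),
    class = "calibration_curve"
  )
}

#' Back-calculate concentrations from instrument responses
#'
#' Inverts a [calibration_curve()] and applies the sample's pre-injection
#' dilution factor. Back-calculated values below zero are floored at zero,
#' and any response whose undiluted back-calculated concentration falls
#' below the calibrated range is flagged (not rejected).
#'
#' @param responses Instrument responses (>= 0).
#' @param curve A [calibration_curve()].
#' @param dilution_factor Dilution applied before injection (>= 1).
#' @return Numeric concentrations (ug/mL) with a logical
#'   `below_range` attribute.
#' @export
apply_calibration <- function(responses, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"), dilution_factor >= 1)
  raw <- (responses - curve$intercept) / curve$slope
  below <- raw < curve$range[1]
  if (any(below)) {
    warning(sprintf("%d response(s) below calibrated range; flagged",
                    sum(below)), call. = FALSE)
  }
  conc <- pmax(raw, 0) * dilution_factor
  attr(conc, "below_range") <- below
  conc
}

#' Pool replicate release profiles into a mean profile with SD
#'
#' @param profiles List of `release_profile`s sharing one time grid.
#' @return A `pooled_profile` data frame with per-time mean and sample SD
#'   (n-1 denominator; `NA` when a single replicate is supplied) of the
#'   interval amounts and cumulative release.
#' @export
pool_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "release_profile")))
  tt <- profiles[[1]]$time
  for (p in profiles[-1]) {
    if (length(p$time) != length(tt) || any(p$time != tt)) {
      stop("replicate profiles are not on a common time grid", call. = FALSE)
    }
  }
  cum <- vapply(profiles, function(p) p$cumulative, numeric(length(tt)))
  amt <- vapply(profiles, function(p) p$interval_amount, numeric(length(tt)))
  cum <- matrix(cum, nrow = length(tt))
  amt <- matrix(amt, nrow = length(tt))
  sd_or_na <- function(m) {
    if (ncol(m) < 2) return(rep(NA_real_, nrow(m)))
    apply(m, 1, stats::sd)
  }
  df <- data.frame(
    time = tt,
    interval_length = profiles[[1]]$interval_length,
    interval_amount = rowMeans(amt),
    interval_sd = sd_or_na(amt),
    cumulative = rowMeans(cum),
    cumulative_sd = sd_or_na(cum)
  )
  loading <- attr(profiles[[1]], "loading")
  if (!is.null(loading)) df$fractional <- df$cumulative / loading
  structure(df, class = c("pooled_profile", "release_profile", "data.frame"),
            replicate_id = "pooled", loading = loading,
            n_replicates = length(profiles))
}
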