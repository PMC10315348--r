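#' Release-medium specification
#'
#' @param label Medium label (e.g. `"30/70"` for 30% IPA in water).
#' @param solubility Saturation solubility of the drug in the medium, ug/mL.
#' @param cosolvent_percent Co-solvent content, % v/v (0-100).
#' @param pH Medium pH (aqueous media; `NA` for solvent mixtures).
#' @param volume Working vessel volume, mL.
#' @return A `medium_spec` object.
#' @export
medium_spec <- function(label, solubility, cosolvent_percent = 0,
                        pH = NA_real_, volume = 100) {
  stopifnot(solubility > 0,
            cosolvent_percent >= 0, cosolvent_percent <= 100)
  structure(
    list(label = label, solubility = solubility,
         cosolvent_percent = cosolvent_percent, pH = pH, volume = volume),
    class = "medium_spec"
  )
}

#' Assess sink conditions from daily sample concentrations
#'
#' Compares each measured concentration with the medium's saturation
#' solubility. Sink is declared strictly when every saturation ratio stays
#' below 10% of saturation, and in the relaxed sense below 30%. Ratios are
#' computed on the mean daily sample concentrations, not modelled
#' instantaneous peaks.
#'
#' @param series A [concentration_series()] (typically replicate-mean).
#' @param medium A [medium_spec()] giving the saturation solubility.
#' @param thresholds Two increasing fractions `c(strict, relaxed)`;
#'   defaults `c(0.10, 0.30)`.
#' @return A `sink_report`: per-time `ratio`, `strict_sink`,
#'   `relaxed_sink`, `max_ratio`, and `first_violation` (earliest day the
#'   relaxed threshold is exceeded, `NA` if never).
#' @export
assess_sink <- function(series, medium, thresholds = c(0.10, 0.30)) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(medium, "medium_spec"),
            length(thresholds) == 2, thresholds[1] < thresholds[2])
  ratio <- series$concentrations / medium$solubility
  strict <- all(ratio < thresholds[1])
  relaxed <- all(ratio < thresholds[2])
  viol <- series$times[ratio >= thresholds[2]]
  structure(
    list(times = series$times, ratio = ratio,
         strict_sink = strict, relaxed_sink = relaxed,
         thresholds = thresholds, max_ratio = max(ratio),
         first_violation = if (length(viol)) min(viol) else NA_real_,
         medium = medium$label),
    class = "sink_report"
  )
}

#' @export
print.sink_report <- function(x, ...) {
  cat(sprintf("Sink report (%s): max C/S = %.3g; strict (<%.0f%%): %s; relaxed (<%.0f%%): %s\n",
              x$medium, x$max_ratio, 100 * x$thresholds[1],
              ifelse(x$strict_sink, "yes", "no"), 100 * x$thresholds[2],
              ifelse(x$relaxed_sink, "yes", "no")))
  if (!is.na(x$first_violation)) {
    cat(sprintf("  relaxed threshold first exceeded on day %g\n",
                x$first_violation))
  }
  invisible(x)
}

#' Classify the release mechanism from model fits and sink status
#'
#' Deterministic rule grid. Without sink conditions (relaxed criterion),
#' release is labelled by the time basis: a better linear fit means
#' partition-controlled (solubility-limited) release, a better root-time
#' fit is reported as matrix-influenced but flagged because the Peppas
#' exponent is not interpretable off-sink. Under sink conditions the Peppas
#' exponent n is read against the Fickian reference (default 0.5,
#' tolerance `delta`): within tolerance is Fickian matrix diffusion, above
#' it (but < 1) anomalous transport, >= 1 case-II transport, below it
#' quasi-Fickian. If no Peppas fit is supplied, the winning time basis
#' decides.
#'
#' @param fit_zero,fit_hig Zero-order and Higuchi `model_fit`s.
#' @param fit_peppas Optional Peppas `model_fit`.
#' @param sink A `sink_report`.
#' @param delta Half-width of the Fickian band around `fickian_n`
#'   (default 0.05).
#' @param fickian_n Fickian reference exponent (default 0.5).
#' @return List with `label`, `basis`, `n` (or `NA`), `sink`, and a human-
#'   readable `rationale`.
#' @export
classify_mechanism <- function(fit_zero, fit_hig, fit_peppas = NULL,
                               sink, delta = 0.05, fickian_n = 0.5) {
  stopifnot(inherits(sink, "sink_report"))
  basis <- if (fit_zero$r_squared > fit_hig$r_squared + 1e-12)
    "zero_order" else "higuchi"
  n <- if (!is.null(fit_peppas)) fit_peppas$slope else NA_real_
  if (!sink$relaxed_sink) {
    if (!is.null(fit_peppas)) {
      warning("Peppas exponent suppressed: sink conditions not met, so n is not mechanistically interpretable",
              call. = FALSE)
    }
    if (basis == "zero_order") {
      label <- "partition-controlled"
      why <- "no sink conditions and cumulative release is linear in time: release is limited by drug solubility in the medium"
    } else {
      label <- "matrix-influenced (non-sink, interpret with caution)"
      why <- "root-time fit is better but sink conditions are absent, so the mechanism assignment is unreliable"
    }
    n <- NA_real_
  } else if (!is.na(n)) {
    if (abs(n - fickian_n) <= delta) {
      label <- "Fickian matrix diffusion"
      why <- sprintf("sink conditions hold and n = %.3f is within %.2f of the Fickian reference %.2f", n, delta, fickian_n)
    } else if (n > fickian_n + delta && n < 1) {
      label <- "anomalous transport"
      why <- sprintf("sink conditions hold and n = %.3f lies between the Fickian reference and 1", n)
    } else if (n >= 1) {
      label <- "case-II transport"
      why <- sprintf("sink conditions hold and n = %.3f >= 1", n)
    } else {
      label <- "quasi-Fickian diffusion"
      why <- sprintf("sink conditions hold and n = %.3f falls below the Fickian band", n)
    }
  } else if (basis == "higuchi") {
    label <- "Fickian matrix diffusion"
    why <- "sink conditions hold and cumulative release is linear in root time"
  } else {
    label <- "zero-order release"
    why <- "sink conditions hold and cumulative release is linear in time"
  }
  list(label = label, basis = basis, n = n,
       sink = list(strict = sink$strict_sink, relaxed = sink$relaxed_sink),
       rationale = why)
}

#' Summarise release rate and burst across a co-solvent ladder
#'
#' Assembles, per medium, the root-time release rate (the Higuchi slope is
#' used for every medium for cross-composition comparability, even where a
#' linear basis fits better) and the day-1 burst amount. Rows are ordered
#' by co-solvent percent; input count and order (after sorting) are
#' preserved.
#'
#' @param entries List of lists, each with `medium` (a [medium_spec()]),
#'   `fit_higuchi` (a `model_fit`), and `profile` (a `release_profile`
#'   whose first row is day 1).
#' @return Data frame with columns `label`, `cosolvent_percent`,
#'   `release_rate` (ug/day^0.5), `day1_burst` (ug), `r_squared`.
#' @export
composition_summary <- function(entries) {
  stopifnot(length(entries) >= 1)
  rows <- lapply(entries, function(e) {
    prof <- as.data.frame(e$profile)
    data.frame(label = e$medium$label,
               cosolvent_percent = e$medium$cosolvent_percent,
               release_rate = e$fit_higuchi$slope,
               day1_burst = prof$interval_amount[prof$time == min(prof$time)][1],
               r_squared = e$fit_higuchi$r_squared)
  })
  out <- do.call(rbind, rows)
  out[order(out$cosolvent_percent), , drop = FALSE]
}

#' Medium volume required to reach a target 28-day release
#'
#' Linear-scaling extrapolation: assuming cumulative release scales
#' proportionally with medium volume, the volume needed to release
#' `target` is `volume * target / release_28d`. This transparently
#' implements the linear assumption; it makes no claim that release
#' actually scales linearly far from the measured volume.
#'
#' @param release_28d Measured 28-day cumulative release, ug.
#' @param volume Volume at which it was measured, mL.
#' @param target Target 28-day release, ug.
#' @return Required volume, mL.
#' @export
scale_volume_for_target <- function(release_28d, volume, target) {
  stopifnot(release_28d > 0, volume > 0, target > 0)
  volume * target / release_28d
}
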