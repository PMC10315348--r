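#' Kinetic model curves
#'
#' Closed-form evaluation of the three release laws used for matrix rings:
#' Higuchi (`Q = a*sqrt(t) + b`, root-time diffusion out of a drug-loaded
#' matrix), zero order (`Q = a*t + b`, solubility/partition-limited release),
#' and Korsmeyer-Peppas (`Mt/Minf = k * t^n`, fractional power law whose
#' exponent diagnoses the transport mechanism).
#'
#' @param t Time, days. Non-negative for Higuchi/zero-order; strictly
#'   positive for Peppas (the log-log form is undefined at t = 0).
#' @param a Slope (ug/day^0.5 for Higuchi, ug/day for zero order).
#' @param b Intercept, ug. May be negative (burst/lag behaviour); values are
#'   reported as-is, not clamped.
#' @param k Peppas rate constant (fraction at t = 1 day).
#' @param n Peppas release exponent.
#' @param cap_at_one Cap the Peppas fraction at 1 for reporting
#'   (default TRUE).
#' @return Cumulative amount (ug) or released fraction.
#' @name release_laws
NULL

#' @rdname release_laws
#' @export
eval_higuchi <- function(t, a, b) {
  if (any(t < 0)) stop("Higuchi model requires t >= 0", call. = FALSE)
  a * sqrt(t) + b
}

#' @rdname release_laws
#' @export
eval_zero_order <- function(t, a, b) {
  if (any(t < 0)) stop("zero-order model requires t >= 0", call. = FALSE)
  a * t + b
}

#' @rdname release_laws
#' @export
eval_peppas <- function(t, k, n, cap_at_one = TRUE) {
  if (any(t <= 0)) stop("Peppas model requires t > 0", call. = FALSE)
  stopifnot(k > 0, n > 0)
  f <- k * t^n
  if (cap_at_one) f <- pmin(f, 1)
  f
}

#' Ordinary least-squares line with 95% confidence intervals
#'
#' The shared regression core of all three model fits: OLS slope and
#' intercept, Student-t 95% confidence intervals on n - 2 degrees of
#' freedom, and the coefficient of determination. A constant response is
#' given R^2 = 1 when residuals vanish (a perfect flat fit), 0 otherwise.
#'
#' @param x,y Numeric vectors (>= 3 points; `x` must vary).
#' @param model Label stored on the result.
#' @return A `model_fit` list: `model`, `slope`, `intercept`, `ci95_slope`,
#'   `ci95_intercept`, `r_squared`, `n_points`, `fit_window`, plus the
#'   regression data in `$data`.
#' @export
fit_linear <- function(x, y, model = "linear") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop("linear fit requires at least 3 points", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("singular fit: x values are all equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)
  structure(
    list(model = model, slope = unname(co[2]), intercept = unname(co[1]),
         ci95_slope = unname(ci[2, ]), ci95_intercept = unname(ci[1, ]),
         r_squared = max(0, min(1, r2)), n_points = length(x),
         fit_window = range(x), data = data.frame(x = x, y = y)),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: slope %.6g (%.6g, %.6g), intercept %.6g (%.6g, %.6g), R2 %.4f, n = %d\n",
              x$model, x$slope, x$ci95_slope[1], x$ci95_slope[2],
              x$intercept, x$ci95_intercept[1], x$ci95_intercept[2],
              x$r_squared, x$n_points))
  invisible(x)
}

profile_window <- function(profile, window) {
  df <- as.data.frame(profile)
  if (!is.null(window)) {
    df <- df[df$time >= window[1] & df$time <= window[2], , drop = FALSE]
  }
  df
}

#' Fit the Higuchi (root-time) model to a release profile
#'
#' Regresses cumulative release on the square root of time.
#'
#' @param profile A `release_profile` or `pooled_profile`.
#' @param window Optional `c(t_min, t_max)` restriction, days.
#' @return A `model_fit` with `model = "higuchi"`; slope in ug/day^0.5.
#' @export
fit_higuchi <- function(profile, window = NULL) {
  df <- profile_window(profile, window)
  fit <- fit_linear(sqrt(df$time), df$cumulative, model = "higuchi")
  fit$fit_window <- range(df$time)
  fit
}

#' Fit the zero-order (linear-time) model to a release profile
#'
#' @inheritParams fit_higuchi
#' @return A `model_fit` with `model = "zero_order"`; slope in ug/day.
#' @export
fit_zero_order <- function(profile, window = NULL) {
  df <- profile_window(profile, window)
  fit <- fit_linear(df$time, df$cumulative, model = "zero_order")
  fit$fit_window <- range(df$time)
  fit
}

#' Fit the Korsmeyer-Peppas power law on the log-log scale
#'
#' Regresses log10 fractional release on log10 time; the slope is the
#' release exponent `n` and the intercept is `log10 k`. Points with
#' non-positive fractional release are excluded with a warning. By default
#' all points with fraction in (0, 1] are used; `max_fraction = 0.6`
#' restricts to the textbook early-release window.
#'
#' @param profile A `release_profile`; its `fractional` column is used if
#'   present, otherwise computed from `loading`.
#' @param loading Ring loading, ug (required if the profile carries none).
#' @param window Optional time window `c(t_min, t_max)`, days.
#' @param max_fraction Optional upper fractional-release limit for the fit.
#' @return A `model_fit` with `model = "peppas"`, `slope` = n, `intercept`
#'   = log10 k, and convenience fields `n` and `k`.
#' @export
fit_peppas <- function(profile, loading = NULL, window = NULL,
                       max_fraction = NULL) {
  df <- profile_window(profile, window)
  if (is.null(loading)) loading <- attr(profile, "loading")
  if (is.null(df$fractional)) {
    if (is.null(loading)) {
      stop("`loading` is required to compute fractional release",
           call. = FALSE)
    }
    df$fractional <- df$cumulative / loading
  }
  keep <- df$time > 0 & df$fractional > 0
  if (!is.null(max_fraction)) keep <- keep & df$fractional <= max_fraction
  if (any(!keep)) {
    warning(sprintf("%d point(s) excluded from Peppas fit (non-positive or out-of-window fraction)",
                    sum(!keep)), call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 3) {
    stop("insufficient data: fewer than 3 usable points for Peppas fit",
         call. = FALSE)
  }
  fit <- fit_linear(log10(df$time), log10(df$fractional), model = "peppas")
  fit$fit_window <- range(df$time)
  fit$n <- fit$slope
  fit$k <- 10^fit$intercept
  fit
}

#' Choose between linear-time and root-time cumulative release
#'
#' Fits both the zero-order and Higuchi models and selects the basis with
#' the higher R^2. Ties (R^2 within 1e-12) resolve to Higuchi, the expected
#' mechanism for a matrix-type ring.
#'
#' @inheritParams fit_higuchi
#' @return List with `basis` (`"zero_order"` or `"higuchi"`), and both fits
#'   (`fit_zero`, `fit_higuchi`).
#' @export
select_time_basis <- function(profile, window = NULL) {
  fz <- fit_zero_order(profile, window)
  fh <- fit_higuchi(profile, window)
  basis <- if (fz$r_squared > fh$r_squared + 1e-12) "zero_order" else "higuchi"
  list(basis = basis, fit_zero = fz, fit_higuchi = fh)
}

model_predict <- function(fit, t) {
  switch(fit$model,
         higuchi = eval_higuchi(t, fit$slope, fit$intercept),
         zero_order = eval_zero_order(t, fit$slope, fit$intercept),
         peppas = eval_peppas(t, fit$k, fit$n, cap_at_one = FALSE),
         stop("unsupported model: ", fit$model, call. = FALSE))
}

#' Back-correct an anomalous interval using a fitted release model
#'
#' Replaces the measured interval amounts inside `interval` by the
#' model-predicted increments (e.g. to back-calculate expected release
#' across a dip caused by a medium-preparation error) and rebuilds the
#' cumulative profile. The returned `delta` is the change in cumulative
#' release at the final time point.
#'
#' @param profile A `release_profile`.
#' @param fit A `model_fit` (higuchi or zero_order).
#' @param interval `c(t_start, t_end)`, days; must lie within the profile's
#'   time range.
#' @return List with `profile` (corrected) and `delta` (ug, at the last
#'   time point).
#' @export
correct_interval_with_model <- function(profile, fit, interval) {
  stopifnot(inherits(fit, "model_fit"), length(interval) == 2)
  df <- as.data.frame(profile)
  if (interval[1] < min(df$time) - diff(c(0, min(df$time))) ||
      interval[2] > max(df$time)) {
    stop("correction interval lies outside the profile time range",
         call. = FALSE)
  }
  inside <- df$time >= interval[1] & df$time <= interval[2]
  if (!any(inside)) {
    stop("no profile points inside the correction interval", call. = FALSE)
  }
  t_prev <- c(0, df$time[-nrow(df)])
  pred_inc <- model_predict(fit, df$time) -
    ifelse(t_prev > 0, model_predict(fit, t_prev), fit$intercept)
  amounts <- df$interval_amount
  amounts[inside] <- pred_inc[inside]
  corrected <- new_release_profile(attr(profile, "replicate_id"), df$time,
                                   amounts, df$interval_length,
                                   loading = attr(profile, "loading"))
  delta <- corrected$cumulative[nrow(corrected)] -
    df$cumulative[nrow(df)]
  list(profile = corrected, delta = delta)
}

#' Refit after excluding replicates, with divergence flagging
#'
#' Pools the retained replicates, fits on the requested basis, and flags
#' any retained replicate whose cumulative-release residuals from the
#' pooled fit exceed 3 times a robust (MAD-based) residual SD — the
#' signature of e.g. accidental octanol contact driving one ring's
#' apparent release upward.
#'
#' @param profiles Named or indexed list of `release_profile`s on one grid.
#' @param exclude_ids Replicate ids to drop before refitting (default none).
#' @param basis `"higuchi"`, `"zero_order"`, or `"auto"` (R^2 selection).
#' @param window Optional time window.
#' @return List with `fit`, `basis`, `pooled`, `excluded`, and `flagged`
#'   (replicate ids whose max |residual| > 3 robust SD).
#' @export
exclude_replicates <- function(profiles, exclude_ids = NULL,
                               basis = c("auto", "higuchi", "zero_order"),
                               window = NULL) {
  basis <- match.arg(basis)
  ids <- vapply(profiles, function(p) as.character(attr(p, "replicate_id")),
                character(1))
  keep <- !(ids %in% as.character(exclude_ids))
  if (!any(keep)) stop("cannot exclude every replicate", call. = FALSE)
  retained <- profiles[keep]
  pooled <- pool_replicates(retained)
  if (basis == "auto") {
    sel <- select_time_basis(pooled, window)
    basis <- sel$basis
    fit <- if (basis == "higuchi") sel$fit_higuchi else sel$fit_zero
  } else {
    fit <- if (basis == "higuchi") fit_higuchi(pooled, window)
           else fit_zero_order(pooled, window)
  }
  resid <- lapply(retained, function(p) {
    df <- profile_window(p, window)
    df$cumulative - model_predict(fit, df$time)
  })
  all_res <- unlist(resid)
  sigma <- stats::mad(all_res)
  flagged <- character()
  if (sigma > 0) {
    worst <- vapply(resid, function(r) max(abs(r)), numeric(1))
    flagged <- ids[keep][worst > 3 * sigma]
  }
  list(fit = fit, basis = basis, pooled = pooled,
       excluded = as.character(exclude_ids), flagged = flagged)
}
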