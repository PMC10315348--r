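stop_schema <- function(fmt, ...) {
  stop(structure(class = c("ringrelease_schema_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

stop_empty <- function(fmt, ...) {
  stop(structure(class = c("ringrelease_empty_input", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Read concentration time series from CSV
#'
#' Expects the dialect `day, replicate, phase, concentration_ug_ml`
#' (header required, decimal point, UTF-8). Rows are split by
#' (replicate, phase) and sorted by day, so input row order is irrelevant.
#'
#' @param path CSV file path.
#' @return List of [concentration_series()], ordered by replicate then
#'   phase.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop_schema("input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("day", "replicate", "phase", "concentration_ug_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_schema("input CSV %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop_empty("input CSV %s contains no data rows", path)
  if (any(!is.finite(df$concentration_ug_ml)) ||
      any(df$concentration_ug_ml < 0)) {
    bad <- which(!is.finite(df$concentration_ug_ml) |
                   df$concentration_ug_ml < 0)
    stop_schema("negative or non-numeric concentration at data row(s) %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  keys <- unique(df[, c("replicate", "phase")])
  keys <- keys[order(keys$replicate, keys$phase), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$replicate == keys$replicate[i] & df$phase == keys$phase[i]
    concentration_series(keys$replicate[i], df$day[sel],
                         df$concentration_ug_ml[sel],
                         phase = keys$phase[i])
  })
}

#' Write concentration series to CSV
#'
#' Emits the same dialect [read_series_csv()] consumes, so a write/read
#' round trip is lossless on valid data.
#'
#' @param series List of [concentration_series()] (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "concentration_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(day = s$times, replicate = s$replicate_id, phase = s$phase,
               concentration_ug_ml = s$concentrations)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a release profile to CSV
#'
#' @param profile A `release_profile` (or pooled profile).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  df$replicate <- attr(profile, "replicate_id")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(model = fit$model, slope = fit$slope, intercept = fit$intercept,
       ci95_slope = fit$ci95_slope, ci95_intercept = fit$ci95_intercept,
       r_squared = fit$r_squared, n_points = fit$n_points,
       fit_window = fit$fit_window)
}

#' Serialize model fits to JSON and a summary-table CSV
#'
#' The CSV mirrors the conventional release-summary layout: one row per
#' medium with day-28 cumulative release (mg, 3 significant figures),
#' slope and intercept with 95% CI bounds, R^2, and the Peppas n and
#' log10 k where fitted.
#'
#' @param results Named list (by medium label) of lists with elements
#'   `basis_fit` (a `model_fit`), optional `peppas_fit`, and `day28_ug`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_fits <- function(results, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- lapply(results, function(r) {
      list(basis_fit = fit_to_list(r$basis_fit),
           peppas_fit = fit_to_list(r$peppas_fit),
           day28_ug = r$day28_ug)
    })
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    rows <- lapply(names(results), function(nm) {
      r <- results[[nm]]
      bf <- r$basis_fit; pf <- r$peppas_fit
      data.frame(
        medium = nm,
        day28_mg = signif(r$day28_ug / 1000, 3),
        basis = bf$model,
        slope = bf$slope, slope_lo = bf$ci95_slope[1],
        slope_hi = bf$ci95_slope[2],
        intercept = bf$intercept, intercept_lo = bf$ci95_intercept[1],
        intercept_hi = bf$ci95_intercept[2],
        r_squared = bf$r_squared,
        peppas_n = if (!is.null(pf)) pf$slope else NA_real_,
        peppas_log10k = if (!is.null(pf)) pf$intercept else NA_real_,
        peppas_r_squared = if (!is.null(pf)) pf$r_squared else NA_real_
      )
    })
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}

build_protocol <- function(pcfg) {
  type <- pcfg$type %||% "monophasic"
  if (type == "monophasic") {
    monophasic_protocol(
      days = pcfg$days %||% 28,
      weekday_volume = pcfg$volume_ml %||% 100,
      weekend_volume = pcfg$weekend_volume_ml %||% 200,
      sample_volume = pcfg$sample_ml %||% 1
    )
  } else if (type == "biphasic") {
    biphasic_protocol(
      days = pcfg$days %||% 28,
      buffer_volume = pcfg$volume_ml %||% 100,
      octanol_volume = pcfg$octanol_volume_ml %||% 20,
      sample_volume = pcfg$sample_ml %||% 1,
      octanol_dilution = pcfg$dilution_factor %||% 20
    )
  } else {
    stop_schema("unknown protocol type: %s", type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the release-analysis pipeline from a configuration
#'
#' Drives the stages `simulate -> reconstruct -> fit -> assess` from a
#' configuration list (or YAML file). `subcommand` selects how far to run:
#' `"simulate"` writes a series CSV; `"reconstruct"` additionally writes
#' per-replicate profiles and a pooled profile; `"fit"` adds model fits
#' (JSON + summary CSV); `"assess"`/`"report"` add the sink report,
#' mechanism classification and a Markdown summary. Each run writes a
#' `manifest.json` recording the configuration, seed and package version.
#'
#' Configuration keys: `subcommand`, `out_dir`, `seed`, `protocol`
#' (`type`, `days`, `volume_ml`, `sample_ml`, ...), `medium` (`label`,
#' `solubility_ug_ml`, `cosolvent_percent`), `simulate` (`a`, `b`, `phi`,
#' `noise_cv`, `n_replicates`), `series_csv` (input for `reconstruct`
#' when not simulating), `loading_ug`, `fit` (`basis` override,
#' `max_fraction`), `thresholds`.
#'
#' @param config Configuration list, or path to a YAML file.
#' @return Invisible list of stage outputs (series, profiles, fits,
#'   assessment, paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sub <- config$subcommand %||% "report"
  stages <- c("simulate", "reconstruct", "fit", "assess", "report")
  if (!sub %in% stages) stop_schema("unknown subcommand: %s", sub)
  depth <- match(sub, stages)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  protocol <- build_protocol(config$protocol %||% list())
  loading <- config$loading_ug %||% 24400
  paths <- list()
  out <- list()

  medium <- NULL
  if (!is.null(config$medium)) {
    medium <- medium_spec(
      label = config$medium$label %||% "medium",
      solubility = config$medium$solubility_ug_ml %||%
        stop_schema("medium requires `solubility_ug_ml`"),
      cosolvent_percent = config$medium$cosolvent_percent %||% 0,
      volume = config$protocol$volume_ml %||% 100
    )
  }

  # stage: obtain series
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    if (is.null(medium)) stop_schema("simulate requires a `medium` block")
    sim <- simulate_monophasic(
      protocol, a = sc$a %||% stop_schema("simulate requires `a`"),
      b = sc$b %||% 0, solubility = medium$solubility,
      phi = sc$phi %||% 0.5, loading = loading,
      noise_cv = sc$noise_cv %||% 0.03,
      n_replicates = sc$n_replicates %||% 4, seed = seed
    )
    series <- sim$series
    paths$series <- file.path(out_dir, "series.csv")
    write_series_csv(series, paths$series)
  } else if (!is.null(config$series_csv)) {
    series <- read_series_csv(config$series_csv)
  } else {
    stop_schema("configuration needs either a `simulate` block or `series_csv`")
  }
  out$series <- series
  if (depth >= 2) {
    biph <- any(vapply(series, function(s) s$phase != "single", logical(1)))
    profiles <- lapply(series, function(s) {
      if (biph) reconstruct_biphasic(s, protocol, loading = loading)
      else reconstruct_monophasic(s, protocol, loading = loading)
    })
    pooled_by_phase <- lapply(split(seq_along(series),
                                    vapply(series, `[[`, "", "phase")),
                              function(ix) pool_replicates(profiles[ix]))
    pooled <- pooled_by_phase[[if (biph) "octanol" else "single"]]
    paths$profile <- file.path(out_dir, "profile_pooled.csv")
    write_profile_csv(pooled, paths$profile)
    out$profiles <- profiles
    out$pooled <- pooled
  }
  if (depth >= 3) {
    fcfg <- config$fit %||% list()
    sel <- select_time_basis(out$pooled)
    basis <- fcfg$basis %||% sel$basis
    basis_fit <- if (basis == "higuchi") sel$fit_higuchi else sel$fit_zero
    peppas_fit <- tryCatch(
      suppressWarnings(fit_peppas(out$pooled, loading = loading,
                                  max_fraction = fcfg$max_fraction)),
      error = function(e) NULL
    )
    day28 <- out$pooled$cumulative[nrow(out$pooled)]
    label <- if (!is.null(medium)) medium$label else "medium"
    results <- stats::setNames(
      list(list(basis_fit = basis_fit, peppas_fit = peppas_fit,
                day28_ug = day28)), label)
    paths$fits_json <- file.path(out_dir, "fits.json")
    paths$fits_csv <- file.path(out_dir, "fits.csv")
    write_fits(results, paths$fits_json, paths$fits_csv)
    out$fit <- list(basis = basis, basis_fit = basis_fit,
                    peppas_fit = peppas_fit, selection = sel,
                    day28_ug = day28)
  }
  if (depth >= 4) {
    if (is.null(medium)) stop_schema("assessment requires a `medium` block")
    biph <- any(vapply(series, function(s) s$phase != "single", logical(1)))
    ev <- protocol_phase(protocol, if (biph) "octanol" else "single")
    V <- ev$vessel_volume[match(out$pooled$time, ev$time)]
    mean_conc <- concentration_series(
      "pooled", out$pooled$time,
      pmax(out$pooled$interval_amount, 0) / V,
      phase = "single")
    thresholds <- unlist(config$thresholds %||% c(0.10, 0.30))
    sink <- assess_sink(mean_conc, medium, thresholds)
    mech <- suppressWarnings(classify_mechanism(
      out$fit$selection$fit_zero, out$fit$selection$fit_higuchi,
      out$fit$peppas_fit, sink))
    out$assessment <- list(sink = sink, mechanism = mech)
    paths$report_json <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(medium = medium$label,
           day28_ug = out$fit$day28_ug,
           basis = out$fit$basis,
           basis_fit = fit_to_list(out$fit$basis_fit),
           peppas_fit = fit_to_list(out$fit$peppas_fit),
           sink = list(strict = sink$strict_sink,
                       relaxed = sink$relaxed_sink,
                       max_ratio = sink$max_ratio),
           mechanism = mech[c("label", "basis", "n", "rationale")]),
      paths$report_json, auto_unbox = TRUE, digits = NA, null = "null",
      pretty = TRUE)
    paths$report_md <- file.path(out_dir, "report.md")
    writeLines(render_report_md(medium, out, sink, mech), paths$report_md)
  }
  manifest <- list(package = "ringrelease",
                   version = as.character(utils::packageVersion("ringrelease")),
                   subcommand = sub, seed = seed,
                   config = config[setdiff(names(config), "out_dir")],
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$paths <- paths
  invisible(out)
}

render_report_md <- function(medium, out, sink, mech) {
  bf <- out$fit$basis_fit
  c(
    sprintf("# Release analysis: %s", medium$label),
    sprintf("_generated %s_", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "",
    sprintf("- Day-28 cumulative release: **%.3g mg**", out$fit$day28_ug / 1000),
    sprintf("- Time basis: **%s** (R2 %.4f)", out$fit$basis, bf$r_squared),
    sprintf("- Slope: %.4g (95%% CI %.4g, %.4g); intercept: %.4g (95%% CI %.4g, %.4g)",
            bf$slope, bf$ci95_slope[1], bf$ci95_slope[2],
            bf$intercept, bf$ci95_intercept[1], bf$ci95_intercept[2]),
    if (!is.null(out$fit$peppas_fit)) {
      pf <- out$fit$peppas_fit
      sprintf("- Peppas: n = %.4g (95%% CI %.4g, %.4g), log10 k = %.4g, R2 %.4f",
              pf$slope, pf$ci95_slope[1], pf$ci95_slope[2], pf$intercept,
              pf$r_squared)
    } else "- Peppas: not fitted",
    sprintf("- Sink: strict %s, relaxed %s (max C/S = %.3g)",
            ifelse(sink$strict_sink, "yes", "no"),
            ifelse(sink$relaxed_sink, "yes", "no"), sink$max_ratio),
    sprintf("- Mechanism: **%s** — %s", mech$label, mech$rationale)
  )
}
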