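#' Ionized (protonated) fraction of a monoprotic weak base
#'
#' Henderson-Hasselbalch partitioning of a monoprotic base between its
#' protonated (BH+) and neutral (B) forms. All logarithms are base 10,
#' following pharmacopoeial pKa/logP convention.
#'
#' @param pH Medium pH.
#' @param pKa Aqueous ionization constant of the conjugate acid.
#' @return Fraction of molecules in the protonated form, in \[0, 1\].
#'   Equals 0.5 exactly at `pH == pKa` and decreases monotonically with pH.
#' @examples
#' ionized_fraction(4.2, 5.30)  # predominately protonated at acidic pH
#' @export
ionized_fraction <- function(pH, pKa) {
  stopifnot(is.finite(pH), is.finite(pKa))
  1 / (1 + 10^(pH - pKa))
}

#' pH-dependent solubility of a weak base
#'
#' Total solubility of a monoprotic base whose neutral-species (intrinsic)
#' solubility is `S0`: `S(pH) = S0 * (1 + 10^(pKa - pH))`. The ionized form
#' is assumed fully soluble (no salt solubility limit), so S grows without
#' bound as pH falls below pKa.
#'
#' @param S0 Intrinsic (unionized) aqueous solubility, ug/mL. Must be > 0.
#' @param pKa Ionization constant.
#' @param pH Medium pH.
#' @return Total solubility in ug/mL; always >= `S0`.
#' @export
ph_dependent_solubility <- function(S0, pKa, pH) {
  if (!is.numeric(S0) || any(!is.finite(S0)) || any(S0 <= 0)) {
    stop("`S0` must be a positive finite solubility (ug/mL)", call. = FALSE)
  }
  S0 * (1 + 10^(pKa - pH))
}

#' pH-dependent octanol/water distribution coefficient (log D)
#'
#' `logD = logP - log10(1 + 10^(pKa - pH))` for a monoprotic base, under the
#' standard assumption that only the neutral species partitions into octanol
#' (ion-pair partitioning ignored). `logD -> logP` as pH rises far above pKa.
#'
#' @param logP Octanol/water partition coefficient of the neutral species.
#' @param pKa Ionization constant.
#' @param pH Aqueous-phase pH.
#' @return log10 distribution coefficient; always <= `logP`.
#' @export
distribution_coefficient <- function(logP, pKa, pH) {
  stopifnot(is.finite(logP), is.finite(pKa), is.finite(pH))
  logP - log10(1 + 10^(pKa - pH))
}

#' A set of co-solvent titration points for pKa extrapolation
#'
#' @param cosolvent_fraction Co-solvent content (% v/v or w/w) at which each
#'   apparent pKa was measured; in \[0, 100).
#' @param psKa Apparent (mixed-solvent) ionization constant at each fraction.
#' @param epsilon Dielectric constant of each solvent mixture (> 1).
#' @param log_water Base-10 log of the molar water concentration in each
#'   mixture. Defaults to the pure-water value minus a linear dilution in
#'   the co-solvent fraction if not supplied.
#' @return A `titration_points` data frame.
#' @export
titration_points <- function(cosolvent_fraction, psKa, epsilon,
                             log_water = NULL) {
  n <- length(cosolvent_fraction)
  stopifnot(length(psKa) == n, length(epsilon) == n)
  if (any(cosolvent_fraction < 0 | cosolvent_fraction >= 100)) {
    stop("co-solvent fractions must lie in [0, 100)", call. = FALSE)
  }
  if (any(epsilon <= 1)) stop("dielectric constants must exceed 1", call. = FALSE)
  if (is.null(log_water)) {
    log_water <- log10(55.5 * (1 - cosolvent_fraction / 100))
  }
  stopifnot(length(log_water) == n)
  structure(
    data.frame(cosolvent_fraction = cosolvent_fraction, psKa = psKa,
               epsilon = epsilon, log_water = log_water),
    class = c("titration_points", "data.frame")
  )
}

#' Extrapolate an aqueous pKa from mixed-solvent titrations
#'
#' Yasuda-Shedlovsky extrapolation: the quantity `psKa + log10[H2O]` is
#' regressed linearly on the reciprocal dielectric constant `1/eps` of the
#' solvent mixture, and the fit is evaluated at the pure-water point
#' (`1/eps_water`, subtracting the pure-water `log10[H2O]`). A plain linear
#' extrapolation of psKa against co-solvent percent is available via
#' `method = "fraction"` for instruments that report that variant.
#'
#' @param points A [titration_points()] data frame (>= 3 points with
#'   distinct abscissae).
#' @param method `"dielectric"` (Yasuda-Shedlovsky, default) or
#'   `"fraction"` (linear in co-solvent percent, evaluated at 0%).
#' @param eps_water Dielectric constant of pure water; default 78.3.
#' @param log_water_pure log10 molar water concentration of pure water;
#'   default `log10(55.5)`.
#' @return A list with `pKa` (extrapolated aqueous value), `r_squared`,
#'   `slope`, `intercept`, `method`, and `n_points`.
#' @export
yasuda_shedlovsky_extrapolate <- function(points,
                                          method = c("dielectric", "fraction"),
                                          eps_water = 78.3,
                                          log_water_pure = log10(55.5)) {
  method <- match.arg(method)
  if (!inherits(points, "data.frame") || nrow(points) < 3) {
    stop("insufficient data: need at least 3 titration points", call. = FALSE)
  }
  if (method == "dielectric") {
    x <- 1 / points$epsilon
    y <- points$psKa + points$log_water
    x_eval <- 1 / eps_water
    offset <- log_water_pure
  } else {
    x <- points$cosolvent_fraction
    y <- points$psKa
    x_eval <- 0
    offset <- 0
  }
  if (length(unique(signif(x, 12))) < 3) {
    stop("insufficient data: need at least 3 distinct abscissa values",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(
    pKa = unname(co[1] + co[2] * x_eval - offset),
    r_squared = r2,
    slope = unname(co[2]),
    intercept = unname(co[1]),
    method = method,
    n_points = nrow(points)
  )
}

#' Immutable physicochemical constants of the released drug
#'
#' @param molecular_weight g/mol.
#' @param pKa Ionization constant (monoprotic base), in (0, 14).
#' @param logP Octanol/water partition coefficient of the neutral species.
#' @param intrinsic_solubility Intrinsic (unionized) aqueous solubility,
#'   ug/mL.
#' @param medium_solubilities Named numeric vector: saturation solubility
#'   (ug/mL) per release-medium label.
#' @param ring_loading Drug content per ring, ug.
#' @return A `drug_properties` object.
#' @export
drug_properties <- function(molecular_weight, pKa, logP,
                            intrinsic_solubility,
                            medium_solubilities = numeric(),
                            ring_loading) {
  stopifnot(molecular_weight > 0, ring_loading > 0,
            intrinsic_solubility > 0)
  if (pKa <= 0 || pKa >= 14) stop("pKa must lie in (0, 14)", call. = FALSE)
  if (length(medium_solubilities) && any(medium_solubilities <= 0)) {
    stop("all medium solubilities must be positive", call. = FALSE)
  }
  structure(
    list(molecular_weight = molecular_weight, pKa = pKa, logP = logP,
         intrinsic_solubility = intrinsic_solubility,
         medium_solubilities = medium_solubilities,
         ring_loading = ring_loading),
    class = "drug_properties"
  )
}

#' @export
print.drug_properties <- function(x, ...) {
  cat("Drug properties\n")
  cat(sprintf("  MW: %.1f g/mol  pKa: %.2f  logP: %.2f\n",
              x$molecular_weight, x$pKa, x$logP))
  cat(sprintf("  intrinsic solubility: %.4g ug/mL  ring loading: %.4g ug\n",
              x$intrinsic_solubility, x$ring_loading))
  if (length(x$medium_solubilities)) {
    cat("  medium solubilities (ug/mL):\n")
    for (nm in names(x$medium_solubilities)) {
      cat(sprintf("    %-22s %.4g\n", nm, x$medium_solubilities[[nm]]))
    }
  }
  invisible(x)
}

#' Reference constants for the 25 mg dapivirine matrix ring
#'
#' Measured physicochemical constants of dapivirine (a weakly basic
#' diaminopyrimidine antiretroviral) and its saturation solubility in the
#' release media used for ring IVRT: isopropanol/water (IPA/water) ladders
#' and pH 7 / pH 4.2 buffers plus octanol. The intrinsic solubility is
#' back-calculated from the pH 7 phosphate-buffer measurement (0.018 ug/mL),
#' where the base is almost entirely neutral.
#'
#' @return A [drug_properties()] object (solubilities in ug/mL, loading in
#'   ug per ring).
#' @export
dapivirine_properties <- function() {
  pKa <- 5.30
  drug_properties(
    molecular_weight = 329.4,
    pKa = pKa,
    logP = 5.35,
    intrinsic_solubility = 0.018 / (1 + 10^(pKa - 7)),
    medium_solubilities = c(
      "0/100" = 0.084, "10/90" = 0.556, "20/80" = 2.76,
      "30/70" = 24.14, "40/60" = 178.6, "50/50" = 645.0,
      "phosphate_pH7" = 0.018, "acetate_pH4.2" = 0.499,
      "octanol" = 6058
    ),
    ring_loading = 24400
  )
}

#' Interpolate solubility across a co-solvent ladder
#'
#' Saturation solubility in water/co-solvent mixtures rises roughly
#' exponentially with co-solvent content (the dapivirine IPA/water ladder
#' spans four orders of magnitude from 0 to 50%), so interpolation between
#' tabulated levels is linear in log10 solubility against co-solvent
#' percent. Values outside the tabulated range are not extrapolated.
#'
#' @param percent Co-solvent content (% v/v) at which to interpolate.
#' @param percents,solubilities Tabulated ladder (same length, >= 2;
#'   solubilities in ug/mL). Defaults to the dapivirine IPA/water ladder.
#' @return Interpolated solubility, ug/mL.
#' @export
cosolvent_solubility <- function(percent,
                                 percents = c(0, 10, 20, 30, 40, 50),
                                 solubilities = c(0.084, 0.556, 2.76,
                                                  24.14, 178.6, 645.0)) {
  stopifnot(length(percents) == length(solubilities),
            length(percents) >= 2, all(solubilities > 0))
  if (any(percent < min(percents) | percent > max(percents))) {
    stop("co-solvent percent outside the tabulated ladder", call. = FALSE)
  }
  10^stats::approx(percents, log10(solubilities), xout = percent)$y
}
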