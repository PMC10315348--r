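#' Published release-kinetics parameters for the 25 mg dapivirine ring
#'
#' Reference cumulative-release fits reported for dapivirine ring IVRT in
#' isopropanol/water (IPA/water) media over 28 days: day-28 cumulative
#' release, the cumulative-release regression (zero order against time for
#' the solubility-limited 0% and 10% IPA media, Higuchi against root time
#' for >= 20% IPA) with 95% confidence bounds, and the Korsmeyer-Peppas
#' log-log fit (exponent n and log10 k) where sink conditions permit.
#' These serve as fixed inputs for parameter-recovery benchmarks and as
#' demonstration values; slopes are in ug/day (zero order) or ug/day^0.5
#' (Higuchi), intercepts in ug, day-28 amounts in mg.
#'
#' @return Data frame, one row per IPA/water medium.
#' @export
dapivirine_reference_fits <- function() {
  data.frame(
    medium = c("0/100", "10/90", "20/80", "30/70", "40/60", "50/50"),
    cosolvent_percent = c(0, 10, 20, 30, 40, 50),
    basis = c("zero_order", "zero_order", "higuchi", "higuchi",
              "higuchi", "higuchi"),
    day28_mg = c(0.218, 0.75, 3.49, 8.01, 9.54, 10.35),
    day28_sd_mg = c(0.004, 0.03, 0.31, 0.07, 0.20, 0.11),
    slope = c(7.55, 25.0, 766.1, 1693, 1904, 2022),
    slope_lo = c(7.41, 24.51, 723.8, 1685, 1879, 2004),
    slope_hi = c(7.69, 25.51, 808.4, 1702, 1929, 2040),
    intercept = c(14.24, 58.48, -723.4, -903, -430.5, -238.5),
    intercept_lo = c(11.9, 50.25, -883.4, -935.9, -524.9, -306.7),
    intercept_hi = c(16.58, 66.70, -563.5, -870, -336.2, -170.2),
    r_squared = c(0.9931, 0.9922, 0.9427, 0.9995, 0.9966, 0.9984),
    peppas_n = c(NA, NA, 0.817, 0.6638, 0.5622, 0.535),
    peppas_n_lo = c(NA, NA, 0.7751, 0.6505, 0.5547, 0.5294),
    peppas_n_hi = c(NA, NA, 0.8589, 0.6771, 0.5698, 0.5406),
    peppas_log10k = c(NA, NA, -2.044, -1.447, -1.235, -1.163),
    peppas_log10k_lo = c(NA, NA, -2.090, -1.462, -1.244, -1.169),
    peppas_log10k_hi = c(NA, NA, -1.998, -1.433, -1.227, -1.157),
    peppas_r_squared = c(NA, NA, 0.9507, 0.9922, 0.9965, 0.9978)
  )
}

#' Published octanol-accumulation parameters for biphasic dapivirine IVRT
#'
#' Reference zero-order fits of cumulative dapivirine accumulation in the
#' octanol phase of 100 mL buffer / 20 mL octanol biphasic systems at pH 7
#' and pH 4.2, both with all four rings and after excluding rings whose
#' release diverged anomalously (attributed to accidental ring-octanol
#' contact). Slopes in ug/day, intercepts in ug, day-28 amounts in mg.
#'
#' @return Data frame, one row per system/exclusion combination.
#' @export
dapivirine_reference_biphasic <- function() {
  data.frame(
    system = c("pH7_octanol", "pH4.2_octanol",
               "pH7_octanol_minus_ring4", "pH4.2_octanol_minus_ring5_8"),
    pH = c(7, 4.2, 7, 4.2),
    excluded = c("", "", "4", "5,8"),
    day28_mg = c(0.85, 1.58, 0.44, 0.98),
    day28_sd_mg = c(0.82, 0.72, 0.11, 0.14),
    slope = c(31.88, 68.81, 17.77, 40.94),
    slope_lo = c(22.89, 56.67, 14.81, 38.19),
    slope_hi = c(40.88, 80.95, 20.73, 43.69),
    intercept = c(-57.15, -89.70, 9.91, -26.24),
    intercept_lo = c(-205.2, -289.6, -38.84, -71.52),
    intercept_hi = c(90.91, 110.2, 58.66, 19.03),
    r_squared = c(0.3898, 0.6202, 0.7134, 0.9598)
  )
}
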