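ref <- dapivirine_reference_fits()

test_that("model curves evaluate their closed forms and guard their domains", {
  expect_equal(eval_higuchi(0, 1693, -903), -903)
  expect_equal(eval_higuchi(28, 1693, -903), 1693 * sqrt(28) - 903)
  expect_equal(eval_higuchi(28, 1693, -903), 8055.5, tolerance = 1e-4)
  expect_equal(eval_zero_order(28, 25.0, 58.48), 758.48)
  expect_equal(eval_zero_order(10, 7.55, 14.24), 89.74)
  expect_equal(eval_peppas(1, 0.2, 0.7), 0.2)
  expect_equal(eval_peppas(28, 10^-1.163, 0.535), 0.4086, tolerance = 1e-3)
  # fraction times ring loading gives the cumulative amount
  expect_equal(eval_peppas(28, 10^-1.163, 0.535) * 24400, 9969,
               tolerance = 1e-3)
  expect_error(eval_higuchi(-1, 1, 0), "t >= 0")
  expect_error(eval_peppas(0, 0.1, 0.5), "t > 0")
  expect_equal(eval_peppas(1e6, 0.1, 0.9), 1)  # reporting cap
})

test_that("OLS core matches the normal equations with t-based intervals", {
  # exactly collinear points: exact coefficients, R2 = 1, zero-width CI
  f <- fit_linear(1:5, 2 * (1:5) + 3)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 3, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(diff(f$ci95_slope), 0, tolerance = 1e-9)
  # hand oracle via normal equations: x = 1..4, y = (4,4,8,8),
  # Sxy/Sxx = 8/5 = 1.6, intercept = 6 - 1.6*2.5 = 2.0
  f2 <- fit_linear(1:4, c(4, 4, 8, 8))
  expect_equal(f2$slope, 1.6, tolerance = 1e-12)
  expect_equal(f2$intercept, 2.0, tolerance = 1e-12)
  # CI brackets the estimate; width matches qt(.975, n-2) * SE by hand
  se_slope <- sqrt(sum(residuals(lm(c(4, 4, 8, 8) ~ I(1:4)))^2) / 2 / 5)
  expect_equal(diff(f2$ci95_slope), 2 * qt(0.975, 2) * se_slope,
               tolerance = 1e-9)
  expect_error(fit_linear(1:2, 1:2), "at least 3")
  expect_error(fit_linear(rep(2, 4), 1:4), "singular")
})

test_that("noise-free profiles generated from reference parameters are refit exactly", {
  p <- daily_protocol()
  for (i in which(ref$basis == "higuchi")) {
    prof <- profile_from_law(function(t) eval_higuchi(t, ref$slope[i],
                                                      ref$intercept[i]), p)
    fit <- fit_higuchi(prof)
    expect_rel_equal(fit$slope, ref$slope[i], 1e-9)
    expect_rel_equal(fit$intercept, ref$intercept[i], 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  for (i in which(ref$basis == "zero_order")) {
    prof <- profile_from_law(function(t) eval_zero_order(t, ref$slope[i],
                                                         ref$intercept[i]), p)
    fit <- fit_zero_order(prof)
    expect_rel_equal(fit$slope, ref$slope[i], 1e-9)
    expect_rel_equal(fit$intercept, ref$intercept[i], 1e-9)
  }
})

test_that("time-basis discrimination and tie-breaking behave as specified", {
  p <- daily_protocol()
  hig <- profile_from_law(function(t) eval_higuchi(t, 2022, -238.5), p)
  lin <- profile_from_law(function(t) eval_zero_order(t, 25, 58.48), p)
  expect_equal(select_time_basis(hig)$basis, "higuchi")
  expect_equal(select_time_basis(lin)$basis, "zero_order")
  # root-time data fit worse on the time basis and vice versa
  sel <- select_time_basis(hig)
  expect_lt(sel$fit_zero$r_squared, sel$fit_higuchi$r_squared)
  # 3 collinear points fit both bases imperfectly but identically enough
  # to trigger the documented higuchi tie-break when R2 values coincide
  p3 <- daily_protocol(days = 3)
  flat <- profile_from_law(function(t) rep(500, length(t)), p3)
  expect_equal(select_time_basis(flat)$basis, "higuchi")
  expect_equal(fit_higuchi(flat)$slope, 0, tolerance = 1e-12)
})

test_that("log-log power-law fitting recovers parameters and excludes zeros", {
  p <- daily_protocol()
  prof <- profile_from_law(
    function(t) eval_peppas(t, 10^-1.235, 0.5622) * 24400, p)
  fit <- fit_peppas(prof, loading = 24400)
  expect_rel_equal(fit$slope, 0.5622, 1e-9)
  expect_rel_equal(fit$intercept, -1.235, 1e-9)
  # pure Higuchi data (zero intercept) has exponent 1/2 exactly
  prof_h <- profile_from_law(function(t) eval_higuchi(t, 1500, 0), p)
  fit_h <- fit_peppas(prof_h, loading = 24400)
  expect_equal(fit_h$slope, 0.5, tolerance = 1e-9)
  # a zero fraction at t = 1 is excluded with a warning and the fit proceeds
  prof_z <- profile_from_law(function(t) pmax(eval_higuchi(t, 1500, -1500), 0), p)
  expect_warning(fit_z <- fit_peppas(prof_z, loading = 24400), "excluded")
  expect_equal(fit_z$n_points, sum(prof_z$fractional > 0))
  # the optional early-release window restricts the fit
  fit_w <- suppressWarnings(fit_peppas(prof, loading = 24400,
                                       max_fraction = 0.2))
  expect_lt(fit_w$n_points, fit$n_points)
  expect_error(suppressWarnings(
    fit_peppas(profile_from_law(function(t) rep(0, length(t)), p),
               loading = 24400)), "insufficient")
})

test_that("R-squared is invariant under affine rescaling of the response", {
  set.seed(11)
  x <- 1:20; y <- 3 * x + rnorm(20)
  r2 <- fit_linear(x, y)$r_squared
  expect_equal(fit_linear(x, 5 * y - 40)$r_squared, r2, tolerance = 1e-12)
})

test_that("model-based interval correction recovers planted dips", {
  p <- daily_protocol()
  law <- function(t) eval_higuchi(t, 1693, -903)
  prof <- profile_from_law(law, p)
  fit <- fit_higuchi(prof)
  # increments already equal to the model prediction: zero delta
  noop <- correct_interval_with_model(prof, fit, c(14, 16))
  expect_equal(noop$delta, 0, tolerance = 1e-9)
  # subtract 60 ug/day over days 14-16 and recover 180 ug
  dipped <- as.data.frame(prof)
  dip_days <- dipped$time %in% 14:16
  s_dip <- invert_to_concentrations(
    cumsum(dipped$interval_amount - 60 * dip_days), p)
  prof_dip <- reconstruct_monophasic(s_dip, p)
  fixed <- correct_interval_with_model(prof_dip, fit, c(14, 16))
  expect_equal(fixed$delta, 180, tolerance = 1e-6)
  expect_error(correct_interval_with_model(prof, fit, c(20, 40)),
               "outside")
})

test_that("replicate exclusion refits and divergence flagging finds planted jumps", {
  p <- daily_protocol()
  law <- function(t) eval_higuchi(t, 2022, -238.5)
  mk <- function(id, extra = 0, from = Inf) {
    f <- function(t) law(t) + extra * (t >= from)
    reconstruct_monophasic(invert_to_concentrations(f, p), p)
  }
  clean <- lapply(1:4, function(i) {
    pr <- mk(i); attr(pr, "replicate_id") <- i; pr
  })
  # excluding nothing reproduces the pooled fit
  res <- exclude_replicates(clean, basis = "higuchi")
  expect_equal(res$fit$slope, 2022, tolerance = 1e-9)
  expect_length(res$flagged, 0)
  # a +500 ug jump from day 10 in one ring is flagged
  jumped <- clean
  jumped[[4]] <- mk(4, extra = 500, from = 10)
  attr(jumped[[4]], "replicate_id") <- 4
  res_j <- exclude_replicates(jumped, basis = "higuchi")
  expect_equal(res_j$flagged, "4")
  # excluding the flagged ring restores the clean fit
  res_x <- exclude_replicates(jumped, exclude_ids = 4, basis = "higuchi")
  expect_equal(res_x$fit$slope, 2022, tolerance = 1e-9)
  expect_equal(res_x$excluded, "4")
  expect_error(exclude_replicates(clean, exclude_ids = 1:4), "every")
})
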