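test_that("prediction error is achieved minus predicted refraction", {
  co <- suppressWarnings(generate_cohort(noise_free_params(n = 10), seed = 4))
  op <- operated(co)
  lc <- lens_constants(119.30)
  # self-consistent noise-free cohort: PE = 0 with the generating formula,
  # true constants and the pseudophakic reading
  for (i in seq_len(nrow(op))) {
    expect_equal(prediction_error(op[i, ], "srkt", lc, "Ps"), 0,
                 tolerance = 1e-9)
  }
  # additive in the achieved refraction
  rec <- op[1, ]
  rec$postop_se <- rec$postop_se + 0.25
  expect_equal(prediction_error(rec, "srkt", lc, "Ps"), 0.25,
               tolerance = 1e-9)
  # exact zero when the achieved refraction equals the prediction
  rec2 <- op[2, ]
  rec2$postop_se <- predict_refraction("srkt", rec2$al_post_aphakic,
                                       rec2$km_pre, lc, rec2$iol_power)
  expect_equal(prediction_error(rec2, "srkt", lc, "Ap"), 0, tolerance = 1e-12)
  # missing reading errors name the option
  rec3 <- op[3, ]
  rec3$al_post_aphakic <- NA_real_
  expect_error(prediction_error(rec3, "srkt", lc, "Ap"), "'Ap'")
  rec4 <- op[4, ]
  rec4$has_stable_refraction <- FALSE
  rec4$postop_se <- NA_real_
  expect_error(prediction_error(rec4, "srkt", lc, "Ps"), "stable")
})

test_that("PE summaries use the sample SD and median absolute error", {
  s <- summarize_pe(c(0.2, -0.2))
  expect_equal(s$me, 0)
  expect_equal(s$medae, 0.2)
  s2 <- summarize_pe(c(0.1, 0.3, -0.4))
  expect_equal(s2$me, 0)
  expect_equal(s2$medae, 0.3)
  s3 <- summarize_pe(rep(0, 5))
  expect_equal(c(s3$me, s3$sd, s3$medae), c(0, 0, 0))
  # even n: median of |PE| is the mean of the central pair
  expect_equal(summarize_pe(c(-0.1, 0.2, 0.3, -0.6))$medae, 0.25)
  expect_error(summarize_pe(0.3), "at least 2")
})

test_that("mean-error zeroing recovers the generating constant", {
  co <- suppressWarnings(generate_cohort(noise_free_params(n = 20), seed = 5))
  lc <- lens_constants(119.30)
  # refractions generated from the pseudophakic reading with A = 119.30
  opt <- zero_me_constant(co, "srkt", lc, "Ps")
  expect_equal(opt$a_constant, 119.30, tolerance = 1e-3)
  expect_identical(opt$source, "optimized")
  pe <- vapply(seq_len(sum(co$eye_role == "operated")), function(i) {
    prediction_error(operated(co)[i, ], "srkt", opt, "Ps")
  }, numeric(1))
  expect_lt(abs(mean(pe)), 1e-4)
  # with realistic refraction noise, the optimized constant leaves a mean
  # error so close to zero that the one-sample t cannot tell it apart
  con <- default_cohort(seed = 7, n_patients = 50)
  opt_n <- zero_me_constant(con, "srkt", lc, "Ps")
  el <- operated(con)[operated(con)$has_stable_refraction, ]
  pe_n <- vapply(seq_len(nrow(el)), function(i) {
    prediction_error(el[i, ], "srkt", opt_n, "Ps")
  }, numeric(1))
  expect_gt(one_sample_t(pe_n, 0)$p_value, 0.999)
})

test_that("zeroing is idempotent and monotone, with the bias-forced sign", {
  co <- default_cohort(seed = 6, n_patients = 60)
  lc <- lens_constants(119.30)
  for (f in formula_ids()) {
    opt <- zero_me_constant(co, f, lc, "Ps")
    opt2 <- zero_me_constant(co, f, opt, "Ps")
    get_c <- function(z) switch(f, srkt = , combo = z$a_constant,
                                hofferq = z$pacd, holladay1 = z$sf)
    expect_lt(abs(get_c(opt) - get_c(opt2)), 1e-6)
  }
  # +0.25 D hyperopic constant bias demands a larger A-constant
  expect_gt(zero_me_constant(co, "srkt", lc, "Ps")$a_constant, 119.30)
  # ME is strictly monotone (decreasing) in the A-constant over the bracket
  mes <- vapply(seq(116.5, 122, by = 0.5), function(a) {
    mean(vapply(which(operated(co)$has_stable_refraction), function(i) {
      prediction_error(operated(co)[i, ], "srkt", lens_constants(a), "Ps")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mes) < 0))
  # no sign change in a hopeless bracket reports both endpoint MEs
  expect_error(zero_me_constant(co, "srkt", lens_constants(117), "Ps",
                                bracket = 0.5),
               "no mean-error sign change")
})

test_that("ALc regression matches the normal-equations oracle", {
  al <- c(21.2, 22.5, 23.59, 24.8, 26.3)
  fit0 <- fit_al_correction(al, al)
  expect_equal(fit0$intercept, 0, tolerance = 1e-10)
  expect_equal(fit0$slope, 1, tolerance = 1e-12)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-12)
  shift <- fit_al_correction(al, al - 0.11)
  expect_equal(shift$intercept, -0.11, tolerance = 1e-10)
  expect_equal(shift$slope, 1, tolerance = 1e-12)
  # default cohort: slope near 1, implied correction near the offset,
  # and exact agreement with an independent normal-equations solve
  op <- operated(default_cohort(seed = 1))
  fit <- fit_al_correction(op$al_pre_phakic, op$al_post_pseudophakic)
  expect_true(fit$slope >= 0.99 && fit$slope <= 1.00)
  expect_equal(fit$intercept + fit$slope * mean(op$al_pre_phakic),
               mean(op$al_post_pseudophakic), tolerance = 1e-9)
  x <- op$al_pre_phakic; y <- op$al_post_pseudophakic
  slope_ne <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_ne <- mean(y) - slope_ne * mean(x)
  expect_lt(abs(fit$slope - slope_ne), 1e-10)
  expect_lt(abs(fit$intercept - intercept_ne), 1e-10)
  expect_error(fit_al_correction(rep(23, 5), rnorm(5, 23)), "zero variance")
  expect_error(fit_al_correction(1:5, 1:4), "equal length")
})

test_that("applying a correction is the fitted affine map", {
  paper_like <- al_correction(-0.017, 0.996)
  expect_equal(round(apply_al_correction(23.59, paper_like), 2), 23.48)
  expect_equal(apply_al_correction(26.00, paper_like), 25.879,
               tolerance = 1e-9)
  ident <- al_correction(0, 1)
  for (al in c(20.5, 23.59, 30)) {
    expect_equal(apply_al_correction(al, ident), al)
  }
})

test_that("option evaluation reproduces the expected mean-error pattern", {
  co <- default_cohort(seed = 2, n_patients = 80)
  lc <- lens_constants(119.30)
  tab <- evaluate_options(co, constants = lc)
  expect_equal(nrow(tab), length(formula_ids()) * 3)
  # all optimized rows have |ME| < 1e-4, i.e. 0.00 at 2 decimals
  expect_true(all(abs(tab$me_opt) < 1e-4))
  expect_true(all(sprintf("%.2f", tab$me_opt) %in% c("0.00", "-0.00")))
  # the +0.11 mm longer phakic reading makes predictions more myopic,
  # hence PE more positive, for every formula under biased constants
  for (f in formula_ids()) {
    me_ph <- tab$me[tab$formula == f & tab$al_option == "Ph"]
    me_ps <- tab$me[tab$formula == f & tab$al_option == "Ps"]
    expect_gt(me_ph, me_ps)
  }
  # noise-free self-consistent cohort: every MedAE is zero without
  # optimization under the generating constants
  co0 <- suppressWarnings(generate_cohort(noise_free_params(n = 12),
                                          seed = 9))
  tab0 <- evaluate_options(co0, formulas = "srkt", constants = lc,
                           options = "Ps", optimize = FALSE)
  expect_equal(tab0$medae, 0, tolerance = 1e-9)
  expect_equal(tab0$me, 0, tolerance = 1e-9)
})
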