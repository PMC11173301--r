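test_that("inner-filter correction applies the multiplicative factor", {
  tit <- quench_titration(c(0, 1e-6, 2e-6), c(100, 90, 80),
                          A_ex = c(0, 0.10, 0.10), A_em = c(0, 0.06, 0.06))
  cor <- inner_filter_correct(tit)
  expect_equal(cor$F[1], 100)                       # zero absorbance: unchanged
  expect_equal(cor$F[2], 90 * 10^0.08)              # 10^((0.10+0.06)/2)
  expect_true(cor$corrected)
  expect_error(inner_filter_correct(cor), "already")

  # with A_ex = A_em = A every F is multiplied by exactly 10^A
  for (A in c(0.02, 0.1, 0.3)) {
    t2 <- quench_titration(c(0, 1e-6), c(100, 90), A_ex = A, A_em = A)
    expect_equal(inner_filter_correct(t2)$F, c(100, 90) * 10^A)
  }

  # correction factor is monotone increasing in A_ex + A_em
  fac <- vapply(seq(0, 0.5, 0.05), function(A)
    inner_filter_correct(quench_titration(c(0, 1e-6), c(100, 90),
                                          A_ex = A))$F[2], numeric(1))
  expect_true(all(diff(fac) > 0))
})

test_that("Stern-Volmer fit recovers exact linear data and its identities", {
  tit <- exact_sv_titration(1e5)
  f <- stern_volmer_fit(tit)
  expect_equal(f$ksv, 1e5)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  # exact identities
  expect_equal(f$kq * tit$tau, f$ksv)
  expect_equal(f$kd * f$ksv, 1)

  # derived constants at the tabulated low-range value
  f2 <- stern_volmer_fit(exact_sv_titration(117050))
  expect_equal(f2$kq, 2.34e13, tolerance = 0.005)
  expect_equal(f2$kd * 1e6, 8.54, tolerance = 0.001)

  # uniform rescaling of all F leaves the fit untouched
  tit3 <- tit; tit3$F <- tit3$F * 37.5
  f3 <- stern_volmer_fit(tit3)
  expect_equal(f3$ksv, f$ksv)
  expect_equal(f3$intercept, f$intercept)

  expect_error(stern_volmer_fit(quench_titration(c(0, 1e-6, 2e-6),
                                                 c(100, 90, 80))),
               "at least 3")
  expect_error(stern_volmer_fit(quench_titration(c(1e-6, 2e-6, 3e-6, 4e-6),
                                                 c(90, 80, 70, 60))),
               "F0")
})

test_that("Stern-Volmer recovery is unbiased at 1% noise", {
  ksv <- vapply(1:200, function(s)
    stern_volmer_fit(gen_sv_titration(131160, noise_cv = 0.01, seed = s))$ksv,
    numeric(1))
  expect_lt(abs(median(ksv) / 131160 - 1), 0.02)
})

test_that("force_unit_intercept pins the intercept without biasing the slope", {
  f <- stern_volmer_fit(exact_sv_titration(1e5), force_unit_intercept = TRUE)
  expect_identical(f$intercept, 1)
  expect_equal(f$ksv, 1e5)
})

test_that("segmented fit flags purely linear data as unimodal", {
  f <- segmented_sv_fit(exact_sv_titration(1e5))
  expect_true(f$unimodal)
  expect_equal(f$low$ksv, 1e5, tolerance = 1e-6)
  expect_equal(f$high$ksv, 1e5, tolerance = 1e-6)
  expect_equal(f$single_slope, 1e5, tolerance = 1e-6)

  # stays unimodal under noise across seeds
  flags <- suppressWarnings(vapply(1:100, function(s)
    segmented_sv_fit(gen_sv_titration(1e5, noise_cv = 0.02, seed = s))$unimodal,
    logical(1)))
  expect_gte(mean(flags), 0.9)
})

test_that("segmented fit recovers construction slopes of piecewise data", {
  # piecewise-linear F0/F joined at 1 uM, built from the two tabulated slopes
  concs <- default_conc_grid()
  bp <- 1e-6
  ratio <- ifelse(concs <= bp, 1 + 117050 * concs,
                  (1 + 117050 * bp - 13780 * bp) + 13780 * concs)
  tit <- quench_titration(concs, 100 / ratio)
  f <- segmented_sv_fit(tit)
  expect_false(f$unimodal)
  expect_equal(f$low$ksv, 117050, tolerance = 1e-4)
  expect_equal(f$high$ksv, 13780, tolerance = 1e-4)
})

test_that("segmented fit locates the two-site slope change near 1:1", {
  f <- segmented_sv_fit(gen_two_site_titration(two_site_truth(noise_cv = 0)))
  expect_false(f$unimodal)
  expect_gt(f$breakpoint, 0.7e-6)
  expect_lt(f$breakpoint, 1.5e-6)
  # invariant: segments sit strictly on either side of the breakpoint
  expect_lt(f$low$conc_range[2], f$breakpoint)
  expect_gte(f$high$conc_range[1], f$breakpoint)
  expect_gte(f$low$n, 3)
  expect_gte(f$high$n, 3)
})

test_that("Lehrer fit reduces to Stern-Volmer at fa = 1", {
  tit <- gen_lehrer_titration(lehrer_truth(fa = 1, Ksv = 1e5, noise_cv = 0))
  lf <- lehrer_fit(tit)
  sv <- stern_volmer_fit(tit)
  expect_equal(lf$fa, 1, tolerance = 1e-6)
  expect_equal(lf$ksv, sv$ksv, tolerance = 1e-6)
})

test_that("Lehrer fit inverts the generator and both methods agree", {
  tit <- gen_lehrer_titration(lehrer_truth(fa = 0.44, Ksv = 117050,
                                           noise_cv = 0))
  d <- lehrer_fit(tit, method = "direct")
  l <- lehrer_fit(tit, method = "linearized")
  expect_equal(d$fa, 0.44, tolerance = 1e-6)
  expect_equal(d$ksv, 117050, tolerance = 1e-6)
  expect_equal(l$fa, d$fa, tolerance = 1e-6)
  expect_equal(l$ksv, d$ksv, tolerance = 1e-6)

  # closed form: at [Q] = 1/Ksv, F0/(F0-F) = 2/fa, i.e. F/F0 = 1 - fa/2
  q <- 1 / 117050
  Fq <- predict(d, q)
  expect_equal(d$F0 / (d$F0 - Fq), 2 / 0.44, tolerance = 1e-6)
  expect_equal(Fq / d$F0, 0.78, tolerance = 1e-6)
})

test_that("Lehrer fit excludes unquenched points with a warning", {
  tit <- quench_titration(c(0, 1e-7, 1e-6, 3e-6, 1e-5, 4e-5),
                          c(100, 101, 95, 85, 75, 62))
  expect_warning(f <- lehrer_fit(tit), "excluded")
  expect_equal(f$n, 4)
  tit2 <- quench_titration(c(0, 1e-6, 2e-6, 3e-6, 4e-6),
                           c(100, 101, 102, 103, 104))
  expect_error(suppressWarnings(lehrer_fit(tit2)), "at least 4")
})

test_that("mechanism classification uses strict exceedance of the limit", {
  expect_identical(mechanism_call(117050, 5e-9)$call, "static")
  expect_equal(mechanism_call(117050, 5e-9)$kq, 2.341e13)
  expect_identical(mechanism_call(10, 5e-9)$call, "dynamic-possible")
  # exactly at threshold: not static (strict inequality)
  expect_identical(mechanism_call(50, 5e-9, threshold = 1e10)$call,
                   "dynamic-possible")
  expect_error(mechanism_call(-1), "positive")
  expect_error(mechanism_call(100, 0), "positive")
})

test_that("dissociation constants are reciprocals of Ksv", {
  expect_equal(dissociation_constant(117050) * 1e6, 8.54, tolerance = 0.001)
  expect_equal(dissociation_constant(24690) * 1e6, 40.50, tolerance = 0.001)
  expect_equal(dissociation_constant(1e6), 1e-6)
  expect_error(dissociation_constant(0), "positive")
})
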