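test_that("generators are deterministic per seed and restore RNG state", {
  a <- gen_sv_titration(117050, seed = 42)
  b <- gen_sv_titration(117050, seed = 42)
  expect_identical(a$F, b$F)
  c <- gen_sv_titration(117050, seed = 43)
  expect_false(identical(a$F, c$F))

  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_sv_titration(117050, seed = 1))
  expect_identical(runif(1), before)

  m1 <- gen_melt(melt_truth(), seed = 7)
  m2 <- gen_melt(melt_truth(), seed = 7)
  expect_identical(m1$signal, m2$signal)
  s1 <- gen_cd_spectrum(cd_truth(), seed = 5)
  s2 <- gen_cd_spectrum(cd_truth(), seed = 5)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("ideal Stern-Volmer generation matches the closed form", {
  tit <- gen_sv_titration(131160, noise_cv = 0, seed = 1)
  F0 <- tit$F[1]
  F40 <- tit$F[length(tit$F)]            # the 40 uM point
  expect_equal(F40 / F0, 1 / (1 + 131160 * tit$ligand_conc[length(tit$F)]))
  expect_equal(F40 / F0, 0.160, tolerance = 1e-3)
})

test_that("tight-binding quadratic matches the bisection oracle", {
  # the worked point: P = 1 uM, Kd = 10 nM, L = 0.5 uM
  th <- tight_binding_occupancy(1e-6, 0.5e-6, 10e-9)
  expect_equal(th, bisect_occupancy(1e-6, 0.5e-6, 10e-9), tolerance = 1e-10)
  expect_equal(th, 0.49038, tolerance = 1e-4)  # frozen from the oracle

  set.seed(2024)
  for (i in 1:1000) {
    P <- 10^runif(1, -8, -4)
    L <- 10^runif(1, -9, -3)
    Kd <- 10^runif(1, -10, -3)
    th <- tight_binding_occupancy(P, L, Kd)
    expect_equal(th, bisect_occupancy(P, L, Kd), tolerance = 1e-10)
    expect_gte(th, 0)
    expect_lte(th, 1)
    expect_lte(th * P, min(P, L) * (1 + 1e-12))
  }
})

test_that("two-site generator degenerates to ideal SV when site 1 is off", {
  # Kd1 -> infinity and q2 = 0: site 1 never fills beyond the linear regime
  truth <- two_site_truth(kd1 = 10, kd2 = 20, q1 = 0.9, q2 = 0,
                          noise_cv = 0)
  tit <- gen_two_site_titration(truth)
  # in this regime theta1 ~ L/Kd1, so F ~ F0 (1 - q1 L / Kd1): a line with
  # effective Ksv ~ q1/Kd1 after the F0/F expansion
  f <- segmented_sv_fit(tit)
  expect_true(f$unimodal)
  sv <- stern_volmer_fit(tit)
  expect_equal(sv$ksv, truth$q1 / truth$kd1, tolerance = 1e-3)
})

test_that("two-site breakpoint recovery lands near the 1:1 point", {
  bp <- vapply(1:100, function(s)
    segmented_sv_fit(gen_two_site_titration(two_site_truth(), seed = s))$breakpoint,
    numeric(1))
  expect_gte(mean(bp >= 0.7e-6 & bp <= 1.5e-6), 0.6)
  expect_gt(median(bp), 0.7e-6)
  expect_lt(median(bp), 1.5e-6)
})

test_that("Lehrer generator asymptotes at the shielded fraction", {
  tit <- gen_lehrer_titration(lehrer_truth(fa = 0.5, Ksv = 1e6, noise_cv = 0),
                              concs = c(0, 10^seq(-6, -1, 1)))
  F0 <- tit$F[1]
  expect_equal(tit$F[length(tit$F)] / F0, 0.5, tolerance = 1e-4)
})

test_that("CD generator exercises the full mdeg pipeline", {
  truth <- cd_truth(0.59, 0.20, 0.21, noise_sd = 0)
  cd <- gen_cd_spectrum(truth, seed = 1)
  expect_identical(cd$units, "mdeg")
  fr <- estimate_secondary_structure(mdeg_to_mre(cd))
  expect_equal(unname(fr$fractions), unname(truth$fractions),
               tolerance = 1e-6)
  expect_error(cd_truth(0.7, 0.4, 0.2), "sum to 1")
})

test_that("melt generator uses the standard ramp and respects its range", {
  m <- gen_melt(melt_truth(tm = 53.84, noise_cv = 0), seed = 1)
  expect_length(m$temperature, 20)   # 15..72 C in 3 C steps
  expect_equal(m$temperature[1], 15)
  expect_equal(m$temperature[20], 72)
  expect_error(gen_melt(melt_truth(tm = 80), seed = 1), "outside")

  # noiseless inverse pair at a tabulated midpoint
  f <- fit_melt_two_state(m)
  expect_lt(abs(f$tm - 53.84), 0.01)
})

test_that("emission generator is linear in its band amplitudes", {
  s0 <- gen_emission_spectrum(trp_amp = 0, tyr_amp = 30, noise_cv = 0)
  expect_equal(s0$wavelength[which.max(s0$intensity)], 303)
  s1 <- gen_emission_spectrum(trp_amp = 50, tyr_amp = 0, noise_cv = 0)
  expect_equal(s1$wavelength[which.max(s1$intensity)], 345)

  # synchronous band tracks trp only, linearly
  y1 <- gen_emission_spectrum(50, 30, synchronous = TRUE, noise_cv = 0)
  y2 <- gen_emission_spectrum(25, 90, synchronous = TRUE, noise_cv = 0)
  expect_equal(y2$intensity, y1$intensity / 2)
  expect_error(gen_emission_spectrum(-1), "non-negative")
})

test_that("spectrum-level and titration-level generation agree", {
  # scale trp amplitude by a two-site truth and read F back off spectra
  truth <- two_site_truth(noise_cv = 0)
  tit <- gen_two_site_titration(truth)
  F_spec <- vapply(tit$F, function(f)
    band_intensity(gen_emission_spectrum(f, tyr_amp = 0, noise_cv = 0),
                   345, 10), numeric(1))
  expect_equal(F_spec, tit$F, tolerance = 1e-9)
  tit2 <- quench_titration(tit$ligand_conc, F_spec,
                           protein_conc = truth$protein_conc)
  f1 <- segmented_sv_fit(tit)
  f2 <- segmented_sv_fit(tit2)
  expect_equal(f2$breakpoint, f1$breakpoint)
  expect_equal(f2$low$ksv, f1$low$ksv)
})
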