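test_that("constructors enforce their invariants", {
  expect_error(spectrum(c(300, 300, 301), c(1, 2, 3)), "strictly increasing")
  expect_error(spectrum(301, 1), "at least 2")
  expect_error(quench_titration(c(0, 2e-6, 1e-6), c(100, 90, 95)),
               "strictly increasing")
  expect_error(quench_titration(c(0, 1e-6), c(100, -1)), "positive")
  expect_error(melt_curve(seq(15, 30, 3), rep(1, 6)), "at least 8")
  expect_error(cd_spectrum(200:240, rnorm(41), conc = -1), "positive")
})

test_that("CSV round-trips are lossless for every schema", {
  tmp <- withr::local_tempdir()
  set.seed(42)

  s <- spectrum(seq(300, 400, 1), runif(101, 1, 50), kind = "emission",
                meta = list(excitation_nm = 280))
  f <- file.path(tmp, "spec.csv")
  write_table(s, f)
  s2 <- read_table(f, "spectrum")
  expect_equal(s2$wavelength, s$wavelength, tolerance = 1e-12)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
  expect_identical(s2$kind, "emission")
  expect_equal(s2$meta$excitation_nm, 280)

  tit <- gen_sv_titration(117050, seed = 7)
  f <- file.path(tmp, "tit.csv")
  write_table(tit, f)
  t2 <- read_table(f, "titration")
  expect_equal(t2$ligand_conc, tit$ligand_conc, tolerance = 1e-12)
  expect_equal(t2$F, tit$F, tolerance = 1e-12)
  expect_equal(t2$protein_conc, 1e-6)
  expect_equal(t2$tau, 5e-9)

  m <- gen_melt(melt_truth(), seed = 3)
  f <- file.path(tmp, "melt.csv")
  write_table(m, f)
  m2 <- read_table(f, "melt")
  expect_equal(m2$signal, m$signal, tolerance = 1e-12)
  expect_equal(m2$wavelength, 210)

  cd <- gen_cd_spectrum(cd_truth(), seed = 5)
  f <- file.path(tmp, "cd.csv")
  write_table(cd, f)
  c2 <- read_table(f, "cd")
  expect_equal(c2$intensity, cd$intensity, tolerance = 1e-12)
  expect_identical(c2$units, "mdeg")
  expect_equal(c2$conc, cd$conc)
})

test_that("readers reject malformed tables with located errors", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "bad.csv")

  writeLines(c("wavelength_nm,wrongname", "300,1", "301,2"), f)
  expect_error(read_table(f, "spectrum"), "intensity")

  writeLines(c("ligand_conc_M,F", "2e-6,90", "1e-6,95"), f)
  expect_error(read_table(f, "titration"), "strictly increasing")

  writeLines(c("wavelength_nm,intensity", "300,1", "301,oops"), f)
  expect_error(read_table(f, "spectrum"), "row 2")

  writeLines(c("wavelength_nm,intensity", "300,1", "300,2"), f)
  expect_error(read_table(f, "spectrum"), "duplicated")
})

test_that("blank subtraction is exact pointwise inverse on matching grids", {
  wl <- seq(200, 240, 0.5)
  a <- spectrum(wl, sin(wl / 10), kind = "cd")
  b <- spectrum(wl, cos(wl / 7), kind = "cd")
  ab <- spectrum(wl, a$intensity + b$intensity, kind = "cd")
  expect_equal(subtract_blank(ab, b)$intensity, a$intensity)
  expect_equal(subtract_blank(a, a)$intensity, rep(0, length(wl)))
  expect_equal(subtract_blank(spectrum(1:2, c(5, 7)),
                              spectrum(1:2, c(1, 2)))$intensity, c(4, 5))
  shifted <- spectrum(wl + 0.1, b$intensity, kind = "cd")
  expect_error(subtract_blank(ab, shifted), "do not match")
})

test_that("mdeg to MRE follows the standard convention and scaling laws", {
  wl <- seq(200, 240, 1)
  cd <- cd_spectrum(wl, rep(10, length(wl)), units = "mdeg",
                    mrw = 117.53, conc = 1, path = 0.2)
  mre <- mdeg_to_mre(cd)
  # theta * MRW / (10 * l * c) = 10 * 117.53 / 2
  expect_equal(mre$intensity, rep(587.65, length(wl)))
  expect_identical(mre$units, "MRE")
  expect_error(mdeg_to_mre(mre), "twice")

  zero <- cd_spectrum(wl, rep(0, length(wl)), units = "mdeg", conc = 1)
  expect_equal(mdeg_to_mre(zero)$intensity, rep(0, length(wl)))

  cd2 <- cd_spectrum(wl, rep(10, length(wl)), units = "mdeg",
                     mrw = 117.53, conc = 2, path = 0.2)
  expect_equal(mdeg_to_mre(cd2)$intensity, mre$intensity / 2)

  # k-fold concentration scales MRE by 1/k exactly, any k
  for (k in c(0.5, 3, 10)) {
    cdk <- cd_spectrum(wl, rep(10, length(wl)), units = "mdeg",
                       mrw = 117.53, conc = k, path = 0.2)
    expect_equal(mdeg_to_mre(cdk)$intensity * k, mre$intensity)
  }
  expect_error(mdeg_to_mre(cd_spectrum(wl, rep(1, length(wl)),
                                       units = "mdeg", conc = NULL)), "conc")
})

test_that("band intensity reads peaks and interpolated points", {
  s <- gen_emission_spectrum(trp_amp = 50, tyr_amp = 0, noise_cv = 0)
  expect_equal(band_intensity(s, 345, 10), 50)
  expect_equal(band_intensity(s, 345, 0), 50)
  # halfwidth 0 at a grid point returns the exact stored value
  expect_equal(band_intensity(s, 330, 0), s$intensity[s$wavelength == 330])
  expect_error(band_intensity(s, 300, 10), "outside")

  # two-band spectrum: trp-band reading matches the generating amplitude
  # within 1% despite tyrosine overlap
  s2 <- gen_emission_spectrum(trp_amp = 50, tyr_amp = 30, noise_cv = 0)
  expect_equal(band_intensity(s2, 345, 10), 50, tolerance = 0.01)
})

test_that("minimal JCAMP-DX records are parsed with factors honoured", {
  tmp <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic emission",
    "##JCAMP-DX=4.24",
    "##XUNITS=NANOMETERS", "##YUNITS=ARBITRARY",
    "##XFACTOR=1", "##YFACTOR=0.5",
    "##FIRSTX=300", "##LASTX=304", "##NPOINTS=5",
    "##XYDATA=(X++(Y..Y))",
    "300 2 4 6", "303 8 10",
    "##END="), tmp)
  s <- read_jcamp(tmp)
  expect_equal(s$wavelength, 300:304)
  expect_equal(s$intensity, c(1, 2, 3, 4, 5))
  expect_identical(s$meta$xunits, "NANOMETERS")
})
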