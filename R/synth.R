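# Seeded mechanistic generators. Each generator is the documented inverse
# of an analysis operation: noiseless generation followed by analysis
# recovers the generating parameters to numerical precision, and noisy
# generation supports parameter-recovery experiments. Noise is
# multiplicative Gaussian (a coefficient of variation, detector shot-like)
# for fluorescence and melt signals, and additive (mdeg) for CD. All
# generators are deterministic given the seed and restore the caller's RNG
# state.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default titration concentration grid
#'
#' The ligand series used throughout: 0 (the F0 point) then 0.1, 0.3, 0.5,
#' 1, 3, 5, 10, 20, 40 uM, matching a typical 100 nM - 40 uM diterpene
#' titration against 1 uM protein.
#'
#' @param include_zero prepend the ligand-free point.
#' @return concentrations in mol/L.
#' @export
default_conc_grid <- function(include_zero = TRUE) {
  g <- c(0.1, 0.3, 0.5, 1, 3, 5, 10, 20, 40) * 1e-6
  if (include_zero) c(0, g) else g
}

apply_cv_noise <- function(F, noise_cv) {
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (noise_cv == 0) return(F)
  F * (1 + stats::rnorm(length(F), 0, noise_cv))
}

#' Generate an ideal Stern-Volmer titration
#'
#' F = F0 / (1 + Ksv [Q]) times multiplicative Gaussian noise; the exact
#' inverse of [stern_volmer_fit()] at zero noise.
#'
#' @param Ksv Stern-Volmer constant, L/mol.
#' @param F0 unquenched intensity.
#' @param concs ligand concentrations, mol/L (include 0 for the F0 point).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed (required when `noise_cv > 0`).
#' @param protein_conc,tau passed to [quench_titration()].
#' @return a [quench_titration()].
#' @export
gen_sv_titration <- function(Ksv, F0 = 100, concs = default_conc_grid(),
                             noise_cv = 0.01, seed = 1,
                             protein_conc = 1e-6, tau = 5e-9) {
  stopifnot(Ksv > 0, F0 > 0)
  F <- F0 / (1 + Ksv * concs)
  F <- with_seed(seed, apply_cv_noise(F, noise_cv))
  quench_titration(concs, F, protein_conc = protein_conc, tau = tau)
}

#' Two-site binding ground truth
#'
#' Parameter bundle for [gen_two_site_titration()]: a tight site that
#' titrates stoichiometrically at ligand:protein 1:1 and a weak site
#' occupied in the tens-of-micromolar range, each quenching a fraction of
#' the fluorescence multiplicatively. The defaults emulate a nuclear
#' receptor ligand-binding domain at 1 uM with a ~50 nM tight site and a
#' ~40 uM weak site.
#'
#' @param protein_conc mol/L.
#' @param kd1,kd2 site dissociation constants, mol/L; `kd1 < kd2`.
#' @param q1,q2 per-site quench efficiencies in `[0, 1]`.
#' @param F0 unquenched intensity.
#' @param noise_cv multiplicative noise CV.
#' @return An object of class `two_site_truth`.
#' @export
two_site_truth <- function(protein_conc = 1e-6, kd1 = 50e-9, kd2 = 40e-6,
                           q1 = 0.45, q2 = 0.5, F0 = 100, noise_cv = 0.01) {
  stopifnot(protein_conc > 0, kd1 > 0, kd2 > 0, kd1 < kd2,
            q1 >= 0, q1 <= 1, q2 >= 0, q2 <= 1, F0 > 0, noise_cv >= 0)
  structure(list(protein_conc = protein_conc, kd1 = kd1, kd2 = kd2,
                 q1 = q1, q2 = q2, F0 = F0, noise_cv = noise_cv),
            class = "two_site_truth")
}

#' Exact tight-binding site occupancy
#'
#' Fraction of protein with the tight site occupied, from the exact
#' mass-balance quadratic (no free-ligand approximation):
#' \deqn{\theta_1 = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2P}.}
#'
#' @param P total protein, mol/L. @param L total ligand, mol/L.
#' @param Kd site dissociation constant, mol/L.
#' @return occupancy in `[0, 1]` (vectorised over `L`).
#' @export
tight_binding_occupancy <- function(P, L, Kd) {
  stopifnot(P > 0, all(L >= 0), Kd > 0)
  s <- P + L + Kd
  disc <- s^2 - 4 * P * L
  if (any(disc < -1e-12 * s^2))
    stop("internal: negative discriminant in tight-binding quadratic")
  disc <- pmax(disc, 0)
  # conjugate form of the smaller root: 2L / (s + sqrt(disc)); avoids the
  # catastrophic cancellation of (s - sqrt(disc)) when 4PL << s^2
  pmin(pmax(2 * L / (s + sqrt(disc)), 0), 1)
}

#' Generate a two-site quenching titration
#'
#' Site-1 occupancy from [tight_binding_occupancy()]; site-2 occupancy
#' from the free-ligand isotherm theta2 = Lfree/(Lfree + Kd2) with
#' Lfree = L - theta1 P (floored at 0; site 2 is weak enough that its own
#' depletion is negligible). Sites are independent and quench
#' multiplicatively: F = F0 (1 - q1 theta1)(1 - q2 theta2). This produces
#' the bimodal Stern-Volmer plots with a slope change near the 1:1
#' ligand:protein point that [segmented_sv_fit()] resolves.
#'
#' @param truth a [two_site_truth()].
#' @param concs ligand concentrations, mol/L.
#' @param seed RNG seed.
#' @param tau fluorophore lifetime, s.
#' @return a [quench_titration()].
#' @export
gen_two_site_titration <- function(truth, concs = default_conc_grid(),
                                   seed = 1, tau = 5e-9) {
  stopifnot(inherits(truth, "two_site_truth"))
  P <- truth$protein_conc
  th1 <- tight_binding_occupancy(P, concs, truth$kd1)
  Lfree <- pmax(concs - th1 * P, 0)
  th2 <- Lfree / (Lfree + truth$kd2)
  F <- truth$F0 * (1 - truth$q1 * th1) * (1 - truth$q2 * th2)
  F <- with_seed(seed, apply_cv_noise(F, truth$noise_cv))
  quench_titration(concs, F, protein_conc = P, tau = tau)
}

#' Lehrer-model ground truth
#'
#' @param fa accessible fraction in (0, 1].
#' @param Ksv Stern-Volmer constant of the accessible population, L/mol.
#' @param F0 unquenched intensity. @param noise_cv multiplicative noise CV.
#' @return An object of class `lehrer_truth`.
#' @export
lehrer_truth <- function(fa = 0.44, Ksv = 117050, F0 = 100, noise_cv = 0.01) {
  stopifnot(fa > 0, fa <= 1, Ksv > 0, F0 > 0, noise_cv >= 0)
  structure(list(fa = fa, Ksv = Ksv, F0 = F0, noise_cv = noise_cv),
            class = "lehrer_truth")
}

#' Generate a Lehrer-model titration
#'
#' F = F0 (1 - fa Ksv [Q] / (1 + Ksv [Q])) times noise; the exact inverse
#' of [lehrer_fit()] at zero noise. As [Q] grows, F/F0 approaches 1 - fa,
#' the shielded residual fluorescence.
#'
#' @param truth a [lehrer_truth()].
#' @param concs ligand concentrations, mol/L.
#' @param seed RNG seed.
#' @param protein_conc,tau passed through to the titration.
#' @return a [quench_titration()].
#' @export
gen_lehrer_titration <- function(truth, concs = default_conc_grid(),
                                 seed = 1, protein_conc = 1e-6, tau = 5e-9) {
  stopifnot(inherits(truth, "lehrer_truth"))
  F <- truth$F0 * (1 - truth$fa * truth$Ksv * concs / (1 + truth$Ksv * concs))
  F <- with_seed(seed, apply_cv_noise(F, truth$noise_cv))
  quench_titration(concs, F, protein_conc = protein_conc, tau = tau)
}

#' CD composition ground truth
#'
#' @param f_helix,f_sheet,f_coil structure fractions summing to 1.
#' @param scale overall MRE scale factor.
#' @param noise_sd additive noise standard deviation in mdeg.
#' @param conc protein concentration, g/L (default 0.147, i.e. ~5 uM of a
#'   ~29 kDa domain). @param path cuvette path, cm.
#' @return An object of class `cd_truth`.
#' @export
cd_truth <- function(f_helix = 0.59, f_sheet = 0.20, f_coil = 0.21,
                     scale = 1, noise_sd = 0.2, conc = 0.147, path = 0.2) {
  f <- c(f_helix, f_sheet, f_coil)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  stopifnot(scale > 0, noise_sd >= 0, conc > 0, path > 0)
  structure(list(fractions = stats::setNames(f, c("helix", "sheet", "coil")),
                 scale = scale, noise_sd = noise_sd,
                 conc = conc, path = path),
            class = "cd_truth")
}

#' Generate a CD spectrum from a composition
#'
#' Builds the mixture of basis curves in MRE space, converts to instrument
#' millidegrees using the stated concentration and path length (so a full
#' analysis must run [mdeg_to_mre()] before unmixing, exercising the whole
#' pipeline), and adds Gaussian noise in mdeg.
#'
#' @param truth a [cd_truth()].
#' @param basis a [basis_set()].
#' @param seed RNG seed.
#' @return a [cd_spectrum()] in mdeg units.
#' @export
gen_cd_spectrum <- function(truth, basis = default_basis(), seed = 1) {
  stopifnot(inherits(truth, "cd_truth"), inherits(basis, "basis_set"))
  mre <- drop(basis$curves %*% truth$fractions) * truth$scale
  cd <- cd_spectrum(basis$wavelength, mre, units = "MRE",
                    conc = truth$conc, path = truth$path)
  cd <- mre_to_mdeg(cd)
  cd$intensity <- with_seed(seed,
    cd$intensity + stats::rnorm(length(cd$intensity), 0, truth$noise_sd))
  cd
}

#' Thermal-unfolding ground truth
#'
#' @param tm apparent melting midpoint, degrees C.
#' @param dh_app apparent van 't Hoff enthalpy, J/mol.
#' @param bn0,bn1 native baseline intercept/slope.
#' @param bu0,bu1 unfolded baseline intercept/slope.
#' @param noise_cv multiplicative noise CV.
#' @return An object of class `melt_truth`.
#' @export
melt_truth <- function(tm = 51.18, dh_app = 3e5, bn0 = 0, bn1 = 0,
                       bu0 = 1, bu1 = 0, noise_cv = 0.01) {
  stopifnot(dh_app > 0, noise_cv >= 0)
  structure(list(tm = tm, dh_app = dh_app, bn0 = bn0, bn1 = bn1,
                 bu0 = bu0, bu1 = bu1, noise_cv = noise_cv),
            class = "melt_truth")
}

#' Generate a two-state melt curve
#'
#' The two-state signal of [fit_melt_two_state()] evaluated on the
#' temperature grid (default 15-72 degrees C in 3-degree steps, the usual
#' CD denaturation protocol) with multiplicative noise.
#'
#' @param truth a [melt_truth()]; `tm` must lie inside `temps`.
#' @param temps temperature grid, degrees C.
#' @param seed RNG seed.
#' @param wavelength analysis wavelength recorded on the curve, nm.
#' @return a [melt_curve()].
#' @export
gen_melt <- function(truth, temps = seq(15, 72, by = 3), seed = 1,
                     wavelength = 210) {
  stopifnot(inherits(truth, "melt_truth"))
  if (truth$tm < min(temps) || truth$tm > max(temps))
    stop("generating Tm lies outside the temperature grid", call. = FALSE)
  s <- two_state_signal(temps, truth$tm, truth$dh_app,
                        truth$bn0, truth$bn1, truth$bu0, truth$bu1)
  s <- with_seed(seed, apply_cv_noise(s, truth$noise_cv))
  melt_curve(temps, s, wavelength = wavelength)
}

#' Generate a tryptophan/tyrosine emission or synchronous spectrum
#'
#' Emission mode: sum of two Gaussian bands on the 300-400 nm grid, a
#' tryptophan band at 345 nm and a tyrosine band at 303 nm (fixed widths).
#' Synchronous mode (delta-lambda = 60 nm, tryptophan-selective): a single
#' band on the 260-320 nm excitation grid whose amplitude tracks
#' `trp_amp` only, so tyrosine contributions cancel out of quenching
#' series read from synchronous spectra.
#'
#' @param trp_amp,tyr_amp non-negative band amplitudes.
#' @param seed RNG seed.
#' @param synchronous emit the synchronous analogue instead of emission.
#' @param noise_cv multiplicative noise CV.
#' @return a [spectrum()].
#' @export
gen_emission_spectrum <- function(trp_amp, tyr_amp = 0, seed = 1,
                                  synchronous = FALSE, noise_cv = 0) {
  if (trp_amp < 0 || tyr_amp < 0)
    stop("band amplitudes must be non-negative", call. = FALSE)
  if (synchronous) {
    wl <- seq(260, 320, by = 1)
    y <- trp_amp * exp(-0.5 * ((wl - 285) / 10)^2)
    kind <- "synchronous"
    meta <- list(delta_lambda_nm = 60)
  } else {
    wl <- seq(300, 400, by = 1)
    y <- trp_amp * exp(-0.5 * ((wl - 345) / 25)^2) +
         tyr_amp * exp(-0.5 * ((wl - 303) / 12)^2)
    kind <- "emission"
    meta <- list(excitation_nm = 280)
  }
  y <- with_seed(seed, apply_cv_noise(y, noise_cv))
  spectrum(wl, y, kind = kind, meta = meta)
}
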