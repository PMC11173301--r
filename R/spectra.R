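# Pointwise spectral arithmetic and unit conversion. Wavelength grids must
# match exactly: no resampling or interpolation is ever performed silently,
# so blank subtraction and unit conversion stay free of hidden smoothing.

#' Subtract a blank spectrum
#'
#' Pointwise subtraction on an exactly matching wavelength grid. The
#' sample's metadata are retained and a `blank` provenance note is added.
#'
#' @param sample,blank objects of class `spectrum` on identical grids.
#' @param blank_id optional identifier recorded in the result's metadata.
#' @return the blank-corrected `spectrum` (same class as `sample`).
#' @export
subtract_blank <- function(sample, blank, blank_id = NULL) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (length(sample$wavelength) != length(blank$wavelength) ||
      any(sample$wavelength != blank$wavelength))
    stop("wavelength grids do not match exactly; no interpolation is performed",
         call. = FALSE)
  out <- sample
  out$intensity <- sample$intensity - blank$intensity
  out$meta$blank <- if (is.null(blank_id)) "subtracted" else blank_id
  out
}

#' Convert CD millidegrees to mean residue ellipticity
#'
#' Applies the standard mean-residue-ellipticity convention
#' \deqn{[\Theta]_\lambda = \frac{\theta_{mdeg} \cdot MRW}{10 \; l \; c}}
#' with \eqn{l} the path length in cm and \eqn{c} the protein concentration
#' in g/L, giving deg cm^2 dmol^-1. The conversion is linear in the signal
#' and inverse-linear in concentration and path length; protein MRE
#' magnitudes come out in the conventional 10^3-10^4 range.
#'
#' @param cd a [cd_spectrum()] with `units = "mdeg"` and `conc`, `path`,
#'   `mrw` set. Converting an already-MRE spectrum is an error (no double
#'   conversion).
#' @return the same spectrum with `units = "MRE"`.
#' @export
mdeg_to_mre <- function(cd) {
  stopifnot(inherits(cd, "cd_spectrum"))
  if (identical(cd$units, "MRE"))
    stop("spectrum is already in MRE units; refusing to convert twice",
         call. = FALSE)
  if (is.null(cd$conc) || cd$conc <= 0)
    stop("conc (g/L) must be set and positive for MRE conversion", call. = FALSE)
  if (is.null(cd$path) || cd$path <= 0)
    stop("path (cm) must be set and positive for MRE conversion", call. = FALSE)
  out <- cd
  out$intensity <- cd$intensity * cd$mrw / (10 * cd$path * cd$conc)
  out$units <- "MRE"
  out
}

# Inverse of mdeg_to_mre; used by the CD generator so the full pipeline
# (generation in MRE space -> instrument mdeg -> conversion) is exercised.
mre_to_mdeg <- function(cd) {
  stopifnot(inherits(cd, "cd_spectrum"))
  if (identical(cd$units, "mdeg"))
    stop("spectrum is already in mdeg units", call. = FALSE)
  if (is.null(cd$conc) || cd$conc <= 0 || is.null(cd$path) || cd$path <= 0)
    stop("conc and path must be set and positive", call. = FALSE)
  out <- cd
  out$intensity <- cd$intensity * (10 * cd$path * cd$conc) / cd$mrw
  out$units <- "mdeg"
  out
}

#' Intensity at an emission band
#'
#' Reads the band intensity from a spectrum: the maximum of the signal
#' within `center +/- halfwidth` nm, or, with `halfwidth = 0`, the value
#' linearly interpolated at `center`. This is the reading used to extract
#' F at the tryptophan emission maximum (about 345 nm) from each spectrum
#' of a titration series.
#'
#' @param spec a `spectrum`.
#' @param center band centre, nm.
#' @param halfwidth half-window, nm; the whole window must lie inside the
#'   spectrum's wavelength range.
#' @return a single intensity value.
#' @export
band_intensity <- function(spec, center, halfwidth = 10) {
  stopifnot(inherits(spec, "spectrum"), halfwidth >= 0)
  lo <- center - halfwidth; hi <- center + halfwidth
  rng <- range(spec$wavelength)
  if (lo < rng[1L] || hi > rng[2L])
    stop(sprintf("window [%.6g, %.6g] nm outside spectrum range [%.6g, %.6g] nm",
                 lo, hi, rng[1L], rng[2L]), call. = FALSE)
  if (halfwidth == 0)
    return(stats::approx(spec$wavelength, spec$intensity, xout = center)$y)
  keep <- spec$wavelength >= lo & spec$wavelength <= hi
  max(spec$intensity[keep])
}
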