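#' @keywords internal
"_PACKAGE"

SPECTRUM_KINDS <- c("emission", "synchronous", "cd")

#' Construct a spectrum
#'
#' A spectrum is a wavelength/intensity pair with a kind tag and free-form
#' metadata. Wavelengths must be strictly increasing; fluorescence spectra
#' carry arbitrary intensity units, CD spectra carry millidegrees (use
#' [cd_spectrum()] for CD so unit bookkeeping is explicit).
#'
#' @param wavelength numeric vector, nm, strictly increasing, length >= 2.
#' @param intensity numeric vector, same length as `wavelength`.
#' @param kind one of `"emission"`, `"synchronous"`, `"cd"`.
#' @param meta named list of free-form metadata (excitation wavelength nm,
#'   delta-lambda nm, temperature C, slit nm, path length cm, ...).
#' @return An object of class `spectrum` (a list with elements `wavelength`,
#'   `intensity`, `kind`, `meta`).
#' @examples
#' s <- spectrum(300:400, dnorm(300:400, 345, 12), kind = "emission")
#' s
#' @export
spectrum <- function(wavelength, intensity, kind = "emission", meta = list()) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) < 2L)
    stop("spectrum needs at least 2 points", call. = FALSE)
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity must have equal length", call. = FALSE)
  if (anyNA(wavelength) || anyNA(intensity))
    stop("wavelength and intensity must be finite (no NA)", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelength must be strictly increasing (no duplicates or reordering)",
         call. = FALSE)
  structure(list(wavelength = wavelength, intensity = intensity,
                 kind = kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<%s spectrum> %d points, %.6g-%.6g nm\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelength)

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, intensity = x$intensity)
}

#' Construct a circular dichroism spectrum
#'
#' A CD spectrum extends [spectrum()] with explicit units (raw instrument
#' millidegrees or mean residue ellipticity), the mean residue weight, the
#' protein mass concentration, and the cuvette path length needed for the
#' mdeg to MRE conversion.
#'
#' @param wavelength nm, strictly increasing.
#' @param signal millidegrees if `units = "mdeg"`, deg cm^2 dmol^-1 if
#'   `units = "MRE"`.
#' @param units `"mdeg"` or `"MRE"`.
#' @param mrw mean residue weight in g/mol; default 117.53, the value for
#'   the FXR ligand-binding domain construct the defaults emulate.
#' @param conc protein concentration in g/L (required to convert to MRE).
#' @param path cuvette path length in cm (default 0.2).
#' @param meta free-form metadata list.
#' @return An object of classes `cd_spectrum` and `spectrum`.
#' @seealso [mdeg_to_mre()]
#' @export
cd_spectrum <- function(wavelength, signal, units = c("mdeg", "MRE"),
                        mrw = 117.53, conc = NULL, path = 0.2,
                        meta = list()) {
  units <- match.arg(units)
  s <- spectrum(wavelength, signal, kind = "cd", meta = meta)
  if (!is.null(conc) && (!is.numeric(conc) || conc <= 0))
    stop("conc must be a positive concentration in g/L", call. = FALSE)
  if (!is.null(path) && (!is.numeric(path) || path <= 0))
    stop("path must be a positive length in cm", call. = FALSE)
  if (!is.numeric(mrw) || mrw <= 0)
    stop("mrw must be positive", call. = FALSE)
  s$units <- units
  s$mrw <- mrw
  s$conc <- conc
  s$path <- path
  class(s) <- c("cd_spectrum", "spectrum")
  s
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<CD spectrum> %d points, %.6g-%.6g nm, units %s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$units))
  cat(sprintf("  mrw %.5g g/mol, conc %s g/L, path %s cm\n", x$mrw,
              if (is.null(x$conc)) "?" else format(x$conc),
              if (is.null(x$path)) "?" else format(x$path)))
  invisible(x)
}

#' Construct a fluorescence quenching titration
#'
#' Holds an ordered ligand-concentration series with the fluorescence
#' intensity read at the analysis band, optional absorbances at the
#' excitation and emission wavelengths for inner-filter correction, the
#' protein concentration, and the fluorophore lifetime used to derive the
#' bimolecular quenching rate.
#'
#' The first point may have `ligand_conc = 0`; its intensity defines F0.
#' If no zero point is present F0 must be supplied explicitly to the
#' fitting functions.
#'
#' @param ligand_conc mol/L, non-negative, strictly increasing.
#' @param F fluorescence intensity at the analysis band, all > 0.
#' @param A_ex,A_em absorbances at the excitation / emission wavelength
#'   (dimensionless), recycled; default 0.
#' @param protein_conc protein concentration, mol/L, > 0. Default 1e-6
#'   (the 1 uM used in the titrations the defaults emulate).
#' @param tau fluorophore excited-state lifetime in seconds; default 5e-9
#'   (5 ns, the conventional tryptophan value).
#' @param corrected logical; has the inner-filter correction already been
#'   applied? Guards against double correction.
#' @return An object of class `quench_titration`.
#' @export
quench_titration <- function(ligand_conc, F, A_ex = 0, A_em = 0,
                             protein_conc = 1e-6, tau = 5e-9,
                             corrected = FALSE) {
  ligand_conc <- as.numeric(ligand_conc)
  F <- as.numeric(F)
  n <- length(ligand_conc)
  if (n < 2L) stop("titration needs at least 2 points", call. = FALSE)
  if (length(F) != n) stop("ligand_conc and F must match in length", call. = FALSE)
  if (anyNA(ligand_conc) || anyNA(F))
    stop("ligand_conc and F must be finite", call. = FALSE)
  if (any(ligand_conc < 0))
    stop("ligand_conc must be non-negative", call. = FALSE)
  if (any(diff(ligand_conc) <= 0))
    stop("ligand_conc must be strictly increasing", call. = FALSE)
  if (any(F <= 0)) stop("all F must be positive", call. = FALSE)
  A_ex <- rep_len(as.numeric(A_ex), n)
  A_em <- rep_len(as.numeric(A_em), n)
  if (any(A_ex < 0) || any(A_em < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  if (!is.numeric(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be positive (mol/L)", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0)
    stop("tau must be positive (seconds)", call. = FALSE)
  structure(list(ligand_conc = ligand_conc, F = F,
                 A_ex = A_ex, A_em = A_em,
                 protein_conc = protein_conc, tau = tau,
                 corrected = isTRUE(corrected)),
            class = "quench_titration")
}

#' @export
print.quench_titration <- function(x, ...) {
  cat(sprintf("<quench titration> %d points, [L] %.3g-%.3g mol/L\n",
              length(x$ligand_conc), min(x$ligand_conc), max(x$ligand_conc)))
  cat(sprintf("  protein %.3g mol/L, tau %.3g s, inner-filter corrected: %s\n",
              x$protein_conc, x$tau, x$corrected))
  invisible(x)
}

#' @export
as.data.frame.quench_titration <- function(x, ...) {
  data.frame(ligand_conc_M = x$ligand_conc, F = x$F,
             A_ex = x$A_ex, A_em = x$A_em)
}

# F0 of a titration: the zero-ligand point.
titration_F0 <- function(tit) {
  i <- which(tit$ligand_conc == 0)
  if (length(i) == 0L)
    stop("titration has no ligand_conc = 0 point: F0 undefined", call. = FALSE)
  tit$F[i[1L]]
}

#' Construct a thermal denaturation curve
#'
#' Signal (CD, in mdeg or mean residue ellipticity) followed at a single
#' fixed wavelength while temperature is ramped.
#'
#' @param temperature degrees C, strictly increasing, at least 8 points.
#' @param signal ellipticity at `wavelength` for each temperature.
#' @param wavelength analysis wavelength, nm (210 and 225 nm are the usual
#'   choices for following helix loss).
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, signal, wavelength = 210) {
  temperature <- as.numeric(temperature)
  signal <- as.numeric(signal)
  if (length(temperature) < 8L)
    stop("melt curve needs at least 8 points", call. = FALSE)
  if (length(signal) != length(temperature))
    stop("temperature and signal must match in length", call. = FALSE)
  if (anyNA(temperature) || anyNA(signal))
    stop("temperature and signal must be finite", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing", call. = FALSE)
  structure(list(temperature = temperature, signal = signal,
                 wavelength = as.numeric(wavelength)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt curve> %d points, %.4g-%.4g C at %g nm\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$wavelength))
  invisible(x)
}

#' @export
as.data.frame.melt_curve <- function(x, ...) {
  data.frame(temperature_C = x$temperature, signal = x$signal,
             wavelength_nm = x$wavelength)
}
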