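# Secondary-structure estimation from far-UV CD. A measured MRE spectrum
# is decomposed as a convex combination of three reference curves (helix,
# sheet, coil): non-negative least squares under a sum-to-one constraint.
# With three components the convex QP is solved exactly by enumerating
# active sets, so no iterative solver or external reference database is
# needed. The default basis is a versioned parametric fixture shipped with
# the package (synthetic reference curves with conventional band positions
# and magnitudes), and any BasisSet with the same layout can be plugged in.

#' Construct a CD basis set
#'
#' Three reference mean-residue-ellipticity curves (helix, sheet, coil) on
#' a shared wavelength grid, used by [estimate_secondary_structure()].
#'
#' @param wavelength nm, strictly increasing, covering at least the range
#'   of the spectra to be analysed.
#' @param helix,sheet,coil reference MRE curves, deg cm^2 dmol^-1.
#' @param provenance free-text label recording where the curves come from.
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(wavelength, helix, sheet, coil,
                      provenance = "user-supplied") {
  wavelength <- as.numeric(wavelength)
  stopifnot(length(wavelength) >= 2L, all(diff(wavelength) > 0))
  m <- cbind(helix = as.numeric(helix), sheet = as.numeric(sheet),
             coil = as.numeric(coil))
  if (nrow(m) != length(wavelength))
    stop("basis curves must match the wavelength grid", call. = FALSE)
  if (!all(is.finite(m))) stop("basis curves must be finite", call. = FALSE)
  structure(list(wavelength = wavelength, curves = m,
                 provenance = provenance),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<CD basis set> %d points, %.4g-%.4g nm (%s)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$provenance))
  invisible(x)
}

#' Default reference basis
#'
#' Loads the parametric helix/sheet/coil reference curves shipped with the
#' package (200-240 nm, 0.5 nm step; synthetic curves built from Gaussian
#' bands at the conventional far-UV positions: helix minima near 208 and
#' 222 nm, sheet minimum near 217 nm, coil minimum near 198 nm).
#'
#' @return A [basis_set()].
#' @export
default_basis <- function() {
  f <- system.file("extdata", "cd_basis_synthetic_v1.csv",
                   package = "bindspec", mustWork = TRUE)
  parsed <- read_csv_with_comments(f)
  df <- parsed$df
  basis_set(df$wavelength_nm, df$helix, df$sheet, df$coil,
            provenance = "bindspec synthetic parametric basis v1")
}

# Interpolate basis curves once onto a target grid; error on coverage gap.
align_basis <- function(basis, wavelength) {
  rng <- range(basis$wavelength)
  if (min(wavelength) < rng[1L] || max(wavelength) > rng[2L])
    stop(sprintf(
      "spectrum grid %.4g-%.4g nm not covered by basis %.4g-%.4g nm",
      min(wavelength), max(wavelength), rng[1L], rng[2L]), call. = FALSE)
  if (length(wavelength) == length(basis$wavelength) &&
      all(wavelength == basis$wavelength))
    return(basis$curves)
  apply(basis$curves, 2L, function(col)
    stats::approx(basis$wavelength, col, xout = wavelength)$y)
}

# Exact simplex-constrained least squares for k columns: min ||y - A f||^2
# with sum(f) = 1, f >= 0, by enumerating active sets of the convex QP.
simplex_lsq <- function(A, y) {
  k <- ncol(A)
  best <- NULL
  for (sz in seq_len(k)) {
    for (S in utils::combn(k, sz, simplify = FALSE)) {
      f <- numeric(k)
      if (sz == 1L) {
        f[S] <- 1
      } else {
        # substitute the last support component: f_last = 1 - sum(others)
        last <- S[sz]; rest <- S[-sz]
        B <- A[, rest, drop = FALSE] - A[, last]
        z <- y - A[, last]
        fit <- stats::lm.fit(B, z)
        f[rest] <- fit$coefficients
        f[last] <- 1 - sum(fit$coefficients)
      }
      if (any(!is.finite(f)) || any(f < -1e-12)) next
      f <- pmax(f, 0); f <- f / sum(f)
      rss <- sum((y - drop(A %*% f))^2)
      if (is.null(best) || rss < best$rss - 1e-12 * max(best$rss, 1))
        best <- list(f = f, rss = rss)
    }
  }
  if (is.null(best)) stop("constrained fit failed (degenerate basis)",
                          call. = FALSE)
  best
}

#' Estimate secondary-structure fractions from an MRE spectrum
#'
#' Decomposes a far-UV CD spectrum (in mean residue ellipticity units)
#' into helix, sheet, and coil fractions by least squares onto the basis
#' curves, under the physical constraints that fractions are non-negative
#' and sum to one. The fit is scale-sensitive by design: the MRE scale
#' carries the structural information, so multiplying the spectrum by a
#' constant changes the residual, not a normalisation.
#'
#' @param spec a [cd_spectrum()] in MRE units ([mdeg_to_mre()] first if
#'   needed; an mdeg spectrum is an error, never silently converted).
#' @param basis a [basis_set()]; default [default_basis()]. Interpolated
#'   once onto the spectrum grid; a coverage gap is an error.
#' @return An object of class `structure_fractions`: `fractions` (named
#'   helix/sheet/coil, in [0,1], summing to 1), `residual_norm`, `rss`,
#'   `method`.
#' @export
estimate_secondary_structure <- function(spec, basis = default_basis()) {
  stopifnot(inherits(spec, "cd_spectrum"), inherits(basis, "basis_set"))
  if (!identical(spec$units, "MRE"))
    stop("spectrum must be in MRE units; run mdeg_to_mre() first",
         call. = FALSE)
  A <- align_basis(basis, spec$wavelength)
  sol <- simplex_lsq(A, spec$intensity)
  fr <- sol$f; names(fr) <- colnames(basis$curves)
  structure(list(fractions = fr,
                 residual_norm = sqrt(sol$rss), rss = sol$rss,
                 method = "simplex-constrained least squares",
                 basis_provenance = basis$provenance),
            class = "structure_fractions")
}

#' @export
print.structure_fractions <- function(x, ...) {
  cat("Secondary-structure fractions (", x$method, ")\n", sep = "")
  cat(sprintf("  helix %.3f  sheet %.3f  coil %.3f  (residual norm %.4g)\n",
              x$fractions[["helix"]], x$fractions[["sheet"]],
              x$fractions[["coil"]], x$residual_norm))
  invisible(x)
}

#' @export
coef.structure_fractions <- function(object, ...) object$fractions
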