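# Two-state thermal denaturation. The observed signal is modelled as
#   S(T) = [N(T) + U(T) K(T)] / [1 + K(T)],
#   K(T) = exp[-(dH_app/R) (1/T - 1/Tm)]   (T in kelvin)
# with linear native and unfolded baselines N, U in degrees C. Because the
# unfolding followed here is irreversible, dH_app is a purely apparent
# van 't Hoff width parameter and Tm an apparent midpoint; neither is
# interpreted thermodynamically.

R_GAS <- 8.314462618  # J mol^-1 K^-1

two_state_signal <- function(temp_C, tm_C, dh, bn0, bn1, bu0, bu1) {
  TK <- temp_C + 273.15
  K <- exp(-(dh / R_GAS) * (1 / TK - 1 / (tm_C + 273.15)))
  N <- bn0 + bn1 * temp_C
  U <- bu0 + bu1 * temp_C
  (N + U * K) / (1 + K)
}

#' Melting midpoint by the derivative method
#'
#' Model-free cross-check for [fit_melt_two_state()]: the signal is boxcar
#' smoothed, central differences are taken, and the temperature of the
#' extremal derivative is refined by parabolic interpolation of the three
#' points around the extremum. Data whose extremal derivative does not
#' stand out from the background (flat or purely linear signal) are
#' flagged as having no transition.
#'
#' @param melt a [melt_curve()] with at least 8 points.
#' @param smooth_halfwidth boxcar half-width in points (0 = no smoothing).
#' @return A list with `tm` (degrees C, `NA` if flagged), `no_transition`,
#'   and `derivative` (the central-difference curve).
#' @export
tm_by_derivative <- function(melt, smooth_halfwidth = 1) {
  stopifnot(inherits(melt, "melt_curve"), smooth_halfwidth >= 0)
  temp <- melt$temperature; s <- melt$signal
  n <- length(s)
  h <- as.integer(smooth_halfwidth)
  if (h > 0) {
    sm <- vapply(seq_len(n), function(i)
      mean(s[max(1L, i - h):min(n, i + h)]), numeric(1))
  } else sm <- s
  i <- 2:(n - 1L)
  d <- (sm[i + 1L] - sm[i - 1L]) / (temp[i + 1L] - temp[i - 1L])
  td <- temp[i]
  span <- diff(range(s))
  ad <- abs(d)
  flat_tol <- 1e-12 + 1e-9 * max(abs(s))
  # a transition needs an interior derivative peak that dominates both
  # ends of the ramp; flat or monotone-linear signals (constant
  # derivative) and transitions truncated at the range boundary fail this
  j <- which.max(ad)
  edge_dom <- max(ad[1L], ad[length(ad)]) >= 0.7 * max(ad) - flat_tol
  if (span <= flat_tol || edge_dom || j == 1L || j == length(ad))
    return(list(tm = NA_real_, no_transition = TRUE,
                derivative = data.frame(temperature_C = td, dS_dT = d)))
  tm <- td[j]
  if (j > 1L && j < length(d)) {
    # parabolic vertex through the three points around the extremum
    y1 <- ad[j - 1L]; y2 <- ad[j]; y3 <- ad[j + 1L]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 0) {
      delta <- 0.5 * (y1 - y3) / denom
      delta <- max(min(delta, 1), -1)
      # assumes locally uniform spacing
      tm <- td[j] + delta * (td[j + 1L] - td[j - 1L]) / 2
    }
  }
  list(tm = tm, no_transition = FALSE,
       derivative = data.frame(temperature_C = td, dS_dT = d))
}

#' Two-state fit of a thermal denaturation curve
#'
#' Nonlinear least squares of the two-state unfolding model with linear
#' native and unfolded baselines, returning the apparent melting midpoint
#' Tm (degrees C) and the apparent van 't Hoff enthalpy governing the
#' transition width. Starting values are deterministic: Tm from
#' [tm_by_derivative()], baselines from OLS on the first and last three
#' points, dH_app = 300 kJ/mol. Curves with no detectable transition
#' (derivative pre-check, or a fit pinned to the temperature boundary) are
#' returned flagged rather than fitted blindly.
#'
#' @param melt a [melt_curve()] with at least 8 points spanning both
#'   baselines.
#' @param dh_start starting apparent enthalpy, J/mol.
#' @return An object of class `melt_fit`: `tm`, `se_tm` (degrees C),
#'   `dh_app` (J/mol), `baseline_native` and `baseline_unfolded`
#'   (intercept, slope), `no_transition`, `method`, `wavelength`, plus the
#'   underlying `nls` object.
#' @export
fit_melt_two_state <- function(melt, dh_start = 3e5) {
  stopifnot(inherits(melt, "melt_curve"))
  temp <- melt$temperature; s <- melt$signal
  rng <- range(temp)
  pre <- tm_by_derivative(melt)
  if (pre$no_transition)
    return(structure(list(tm = NA_real_, se_tm = NA_real_, dh_app = NA_real_,
                          baseline_native = c(intercept = NA, slope = NA),
                          baseline_unfolded = c(intercept = NA, slope = NA),
                          no_transition = TRUE, method = "two-state",
                          wavelength = melt$wavelength, fit = NULL,
                          data = as.data.frame(melt)),
                     class = "melt_fit"))

  head_fit <- stats::lm(s[1:3] ~ temp[1:3])
  tail_fit <- stats::lm(s[(length(s) - 2):length(s)] ~
                          temp[(length(temp) - 2):length(temp)])
  start <- list(tm = pre$tm, dh = dh_start,
                bn0 = unname(stats::coef(head_fit)[1L]),
                bn1 = unname(stats::coef(head_fit)[2L]),
                bu0 = unname(stats::coef(tail_fit)[1L]),
                bu1 = unname(stats::coef(tail_fit)[2L]))
  df <- data.frame(temp = temp, s = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ two_state_signal(temp, tm, dh, bn0, bn1, bu0, bu1),
      data = df, start = start,
      lower = c(tm = rng[1L], dh = 1e3, bn0 = -Inf, bn1 = -Inf,
                bu0 = -Inf, bu1 = -Inf),
      upper = c(tm = rng[2L], dh = 1e8, bn0 = Inf, bn1 = Inf,
                bu0 = Inf, bu1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("two-state melt fit did not converge: ", conditionMessage(e),
           "\n  starting values: tm=", signif(pre$tm, 5),
           ", dh=", signif(dh_start, 3), call. = FALSE))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tm <- unname(co[["tm"]])
  pinned <- (tm - rng[1L]) < 1e-6 * diff(rng) ||
            (rng[2L] - tm) < 1e-6 * diff(rng)
  structure(list(tm = tm, se_tm = unname(se[["tm"]]),
                 dh_app = unname(co[["dh"]]),
                 baseline_native = c(intercept = unname(co[["bn0"]]),
                                     slope = unname(co[["bn1"]])),
                 baseline_unfolded = c(intercept = unname(co[["bu0"]]),
                                       slope = unname(co[["bu1"]])),
                 no_transition = pinned, method = "two-state",
                 wavelength = melt$wavelength, fit = fit,
                 data = df),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (x$no_transition) {
    cat("Two-state melt fit: NO TRANSITION detected in range\n")
  } else {
    cat(sprintf("Two-state melt fit at %g nm: Tm = %.2f +/- %.2f C, dH_app = %.3g kJ/mol\n",
                x$wavelength, x$tm, x$se_tm, x$dh_app / 1e3))
  }
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, dh_app = object$dh_app,
    bn0 = object$baseline_native[["intercept"]],
    bn1 = object$baseline_native[["slope"]],
    bu0 = object$baseline_unfolded[["intercept"]],
    bu1 = object$baseline_unfolded[["slope"]])
}

#' @export
predict.melt_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$data$temp
  co <- coef(object)
  two_state_signal(temperature, co[["tm"]], co[["dh_app"]],
                   co[["bn0"]], co[["bn1"]], co[["bu0"]], co[["bu1"]])
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$data$s - predict(object)
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$data$temp, x$data$s, xlab = "temperature (C)",
                 ylab = "signal", main = "Thermal denaturation", ...)
  if (!x$no_transition) {
    tt <- seq(min(x$data$temp), max(x$data$temp), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = 2)
    graphics::abline(v = x$tm, lty = 2)
  }
  invisible(x)
}

#' Ligand-induced melting-temperature shift
#'
#' Difference of apparent melting midpoints between a ligand-bound (holo)
#' and a ligand-free (apo) fit at the same analysis wavelength. Positive
#' values indicate stabilisation by the ligand.
#'
#' @param apo,holo [fit_melt_two_state()] results at the same wavelength.
#' @return delta-Tm = holo Tm - apo Tm, degrees C.
#' @export
delta_tm <- function(apo, holo) {
  stopifnot(inherits(apo, "melt_fit"), inherits(holo, "melt_fit"))
  if (apo$no_transition || holo$no_transition)
    stop("both fits must have a detected transition", call. = FALSE)
  if (!isTRUE(all.equal(apo$wavelength, holo$wavelength)))
    stop(sprintf("wavelength mismatch: apo %g nm vs holo %g nm",
                 apo$wavelength, holo$wavelength), call. = FALSE)
  holo$tm - apo$tm
}
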