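# Fluorescence-quenching analysis. The Stern-Volmer relation
#   F0/F = 1 + Ksv [Q]
# is fitted by OLS; under a static (complex-formation) mechanism Ksv equals
# the association constant, so Kd = 1/Ksv, and the apparent bimolecular
# rate Kq = Ksv/tau discriminates static from collisional quenching against
# the diffusion limit (~1e10 L mol^-1 s^-1). Titrations showing two linear
# regimes are handled by an exhaustive-search segmented fit; partially
# shielded fluorophores by the Lehrer accessible-fraction model
#   F0/(F0-F) = 1/([Q] Ksv fa) + 1/fa.

#' Inner-filter correction of a quenching titration
#'
#' Corrects each observed intensity for attenuation of the excitation and
#' emission beams by the absorbing ligand:
#' \deqn{F_{corr} = F_{obs} \times 10^{(A_{ex}+A_{em})/2}.}
#' The returned titration is flagged `corrected`; correcting twice is an
#' error.
#'
#' @param tit a [quench_titration()] with per-point absorbances `A_ex`,
#'   `A_em` (default 0, i.e. no correction).
#' @return the corrected [quench_titration()].
#' @export
inner_filter_correct <- function(tit) {
  stopifnot(inherits(tit, "quench_titration"))
  if (isTRUE(tit$corrected))
    stop("titration is already inner-filter corrected", call. = FALSE)
  if (any(tit$A_ex < 0) || any(tit$A_em < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  out <- tit
  out$F <- tit$F * 10^((tit$A_ex + tit$A_em) / 2)
  out$corrected <- TRUE
  out
}

#' Classical Stern-Volmer fit
#'
#' Ordinary least squares of F0/F against ligand concentration. The slope
#' is the Stern-Volmer constant Ksv (L/mol); the intercept is reported, not
#' forced to its theoretical value of 1, unless `force_unit_intercept`.
#' Derived quantities obey the exact identities Kq = Ksv/tau and
#' Kd = 1/Ksv.
#'
#' @param tit a [quench_titration()] containing a ligand_conc = 0 point
#'   (defines F0) unless `F0` is given.
#' @param range optional `c(min, max)` in mol/L restricting which nonzero
#'   concentrations enter the fit (used to fit the low and high regimes of
#'   a bimodal plot separately).
#' @param F0 unquenched intensity; defaults to the zero-ligand point.
#' @param force_unit_intercept fit `F0/F - 1 ~ 0 + [Q]` instead, pinning
#'   the intercept at 1.
#' @return An object of class `sv_fit` with elements `ksv`, `se_ksv`,
#'   `intercept`, `se_intercept`, `kq`, `kd`, `r2`, `n`, `conc_range`,
#'   `tau`, and the underlying `lm` fit.
#' @examples
#' tit <- gen_sv_titration(Ksv = 1e5, F0 = 100, noise_cv = 0, seed = 1)
#' fit <- stern_volmer_fit(tit)
#' coef(fit)
#' @export
stern_volmer_fit <- function(tit, range = NULL, F0 = NULL,
                             force_unit_intercept = FALSE) {
  stopifnot(inherits(tit, "quench_titration"))
  if (is.null(F0)) F0 <- titration_F0(tit)
  if (!is.numeric(F0) || F0 <= 0) stop("F0 must be positive", call. = FALSE)
  keep <- tit$ligand_conc > 0
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1L] <= range[2L])
    keep <- keep & tit$ligand_conc >= range[1L] & tit$ligand_conc <= range[2L]
  }
  q <- tit$ligand_conc[keep]
  F <- tit$F[keep]
  if (length(q) < 3L)
    stop("need at least 3 points with ligand_conc > 0 in range", call. = FALSE)
  if (any(F <= 0)) stop("all F must be positive", call. = FALSE)
  y <- F0 / F
  # suppressWarnings: summary.lm warns on "essentially perfect" noiseless fits
  if (force_unit_intercept) {
    fit <- stats::lm(I(y - 1) ~ 0 + q)
    ksv <- unname(stats::coef(fit)[["q"]])
    se_ksv <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit))))[["q"]])
    intercept <- 1; se_int <- 0
  } else {
    fit <- stats::lm(y ~ q)
    co <- stats::coef(fit)
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    ksv <- unname(co[["q"]]); se_ksv <- unname(se[["q"]])
    intercept <- unname(co[["(Intercept)"]]); se_int <- unname(se[["(Intercept)"]])
  }
  if (!is.finite(ksv) || ksv <= 0)
    warning("non-positive Stern-Volmer slope: data show no net quenching")
  r2 <- 1 - sum(stats::residuals(fit)^2) / max(sum((y - mean(y))^2),
                                               .Machine$double.xmin)
  structure(list(ksv = ksv, se_ksv = se_ksv,
                 intercept = intercept, se_intercept = se_int,
                 kq = ksv / tit$tau, kd = 1 / ksv,
                 r2 = r2, n = length(q),
                 conc_range = range(q), tau = tit$tau, F0 = F0,
                 data = data.frame(q = q, ratio = y),
                 lm = fit),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Stern-Volmer fit\n")
  cat(sprintf("  Ksv = %.6g +/- %.3g L/mol (intercept %.4g, r2 %.5f, n = %d)\n",
              x$ksv, x$se_ksv, x$intercept, x$r2, x$n))
  cat(sprintf("  Kq  = %.4g L/mol/s (tau = %.3g s)\n", x$kq, x$tau))
  cat(sprintf("  Kd  = %.4g mol/L (%.4g uM)\n", x$kd, x$kd * 1e6))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(ksv = object$ksv, intercept = object$intercept,
    kq = object$kq, kd = object$kd)
}

#' @export
summary.sv_fit <- function(object, ...) {
  out <- list(fit = object, lm_summary = summary(object$lm))
  class(out) <- "summary.sv_fit"
  out
}

#' @export
print.summary.sv_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying regression of F0/F on [Q]:\n")
  print(stats::coef(x$lm_summary))
  invisible(x)
}

#' @export
predict.sv_fit <- function(object, ligand_conc, ...) {
  # predicted F0/F at the given concentrations
  object$intercept + object$ksv * ligand_conc
}

#' @export
residuals.sv_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(x$data$q, x$data$ratio, xlab = "[Q] (mol/L)",
                 ylab = "F0/F", main = "Stern-Volmer plot", ...)
  graphics::abline(x$intercept, x$ksv, col = 2)
  invisible(x)
}

sv_fit_to_list <- function(f) {
  list(ksv = f$ksv, se_ksv = f$se_ksv, intercept = f$intercept,
       kq = f$kq, kd = f$kd, r2 = f$r2, n = f$n,
       range = as.list(f$conc_range),
       units = list(ksv = "L/mol", kq = "L/mol/s", kd = "mol/L",
                    range = "mol/L"))
}

#' Segmented (two-regime) Stern-Volmer fit
#'
#' Detects and fits the bimodal Stern-Volmer plots seen when a tight
#' binding site saturates at a 1:1 ligand:protein ratio and a weaker site
#' takes over at higher concentration: two independent OLS lines on F0/F
#' vs [Q], with the split point chosen by exhaustive search over all
#' admissible gaps between consecutive concentrations, minimising the
#' pooled residual sum of squares (ties broken toward the lower
#' concentration). The reported breakpoint is the concentration where the
#' two fitted lines intersect, clamped into the gap between the segments.
#'
#' Two guards protect against over-segmentation of genuinely linear data:
#' a two-segment vs single-line F-test (2 extra parameters,
#' Bonferroni-corrected for the searched split grid) and a t-test that the
#' two slopes actually differ (conservative min-segment residual df, which
#' is robust to the heteroscedasticity of F0/F noise at high [Q]). If
#' either fails at `alpha` the result is flagged `unimodal`, and the two
#' segment slopes then both essentially equal the global slope.
#'
#' @param tit a [quench_titration()].
#' @param min_points_per_segment at least 3.
#' @param alpha significance level of the segmentation F-test.
#' @param F0 optional explicit unquenched intensity.
#' @return An object of class `segmented_sv_fit`: elements `low` and
#'   `high` (both [stern_volmer_fit()] results), `breakpoint` (mol/L),
#'   `pooled_rss`, `single_rss`, `f_stat`, `p_value`, `unimodal`,
#'   `breakpoint_grid` (candidate split concentrations searched).
#' @export
segmented_sv_fit <- function(tit, min_points_per_segment = 3, alpha = 0.05,
                             F0 = NULL) {
  stopifnot(inherits(tit, "quench_titration"), min_points_per_segment >= 3)
  if (is.null(F0)) F0 <- titration_F0(tit)
  q <- tit$ligand_conc[tit$ligand_conc > 0]
  F <- tit$F[tit$ligand_conc > 0]
  n <- length(q)
  m <- min_points_per_segment
  if (n < 2L * m)
    stop(sprintf("need at least %d points with ligand_conc > 0", 2L * m),
         call. = FALSE)
  y <- F0 / F

  rss_line <- function(idx) {
    fit <- stats::lm(y[idx] ~ q[idx])
    sum(stats::residuals(fit)^2)
  }
  splits <- m:(n - m)           # low segment = 1..k, high = (k+1)..n
  pooled <- vapply(splits, function(k)
    rss_line(1:k) + rss_line((k + 1):n), numeric(1))
  best <- splits[which.min(pooled)]   # which.min takes the first (lowest conc) tie
  single <- stats::lm(y ~ q)
  rss1 <- sum(stats::residuals(single)^2)
  rss2 <- min(pooled)
  tss <- sum((y - mean(y))^2)

  # F-test: 2 extra parameters (second slope + intercept), n - 4 residual
  # df; the p-value is Bonferroni-corrected for the searched split grid.
  df2 <- n - 4
  unimodal <- FALSE
  # a single line leaving < 1e-8 of the variance unexplained is unimodal
  # outright (degenerate noiseless case; avoids zero-residual F statistics)
  if (rss1 <= 1e-8 * tss || df2 <= 0) {
    unimodal <- TRUE
    f_stat <- NA_real_; p_val <- NA_real_
  } else {
    f_stat <- ((rss1 - rss2) / 2) / (rss2 / df2)
    p_val <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
    if (!is.finite(f_stat) && rss2 < rss1) { f_stat <- Inf; p_val <- 0 }
    p_val <- min(p_val * length(splits), 1)
    unimodal <- !is.na(p_val) && p_val > alpha
  }

  # slope-sign warnings are deferred: a flat/negative segment slope is
  # routine while probing splits of unimodal data
  low <- suppressWarnings(
    stern_volmer_fit(tit, range = c(min(q), q[best]), F0 = F0))
  high <- suppressWarnings(
    stern_volmer_fit(tit, range = c(q[best + 1L], max(q)), F0 = F0))

  # two linear regimes also require genuinely different slopes: t-test on
  # the slope difference with the conservative min-segment residual df
  # (guards the F-test against heteroscedastic F0/F noise at high [Q])
  if (!unimodal && !is.na(p_val)) {
    se_d <- sqrt(low$se_ksv^2 + high$se_ksv^2)
    if (is.finite(se_d) && se_d > 0) {
      t_sl <- abs(low$ksv - high$ksv) / se_d
      p_sl <- 2 * stats::pt(t_sl, min(low$n, high$n) - 2, lower.tail = FALSE)
      unimodal <- p_sl > alpha
    }
  }

  if (!unimodal && (low$ksv <= 0 || high$ksv <= 0))
    warning("a segment of the two-regime fit has a non-positive slope")

  # breakpoint: intersection of the two lines, clamped into the split gap
  gap <- c(q[best], q[best + 1L])
  dslope <- low$ksv - high$ksv
  bp <- if (abs(dslope) < .Machine$double.eps * max(abs(low$ksv), 1))
    sqrt(prod(gap))
  else (high$intercept - low$intercept) / dslope
  eps <- .Machine$double.eps * 64
  bp <- min(max(bp, gap[1L] * (1 + eps)), gap[2L])

  structure(list(low = low, high = high,
                 breakpoint = bp, split_gap = gap,
                 pooled_rss = rss2, single_rss = rss1,
                 f_stat = f_stat, p_value = p_val, unimodal = unimodal,
                 breakpoint_grid = q[splits],
                 single_slope = unname(stats::coef(single)[["q"]])),
            class = "segmented_sv_fit")
}

#' @export
print.segmented_sv_fit <- function(x, ...) {
  if (x$unimodal) {
    cat("Segmented Stern-Volmer fit: UNIMODAL (single line adequate)\n")
    cat(sprintf("  global slope %.6g L/mol\n", x$single_slope))
  } else {
    cat(sprintf("Segmented Stern-Volmer fit: breakpoint %.4g mol/L (%.3g uM)\n",
                x$breakpoint, x$breakpoint * 1e6))
  }
  cat("Low range:\n"); print(x$low)
  cat("High range:\n"); print(x$high)
  invisible(x)
}

#' @export
coef.segmented_sv_fit <- function(object, ...) {
  c(ksv_low = object$low$ksv, ksv_high = object$high$ksv,
    breakpoint = object$breakpoint)
}

#' Lehrer (accessible-fraction) quenching fit
#'
#' Fits the modified Stern-Volmer model for a fluorophore population of
#' which only a fraction `fa` is accessible to the quencher:
#' \deqn{\frac{F_0}{F_0-F} = \frac{1}{[Q]\,K_{SV}\,f_a} + \frac{1}{f_a}}
#' equivalently \eqn{F = F_0 (1 - f_a K_{SV} [Q] / (1 + K_{SV} [Q]))}.
#'
#' `method = "direct"` (default) fits the untransformed F vs [Q] curve by
#' Levenberg-Marquardt nonlinear least squares; the double-reciprocal
#' `"linearized"` form (OLS of F0/(F0-F) on 1/[Q]) mirrors the classical
#' plot but inflates noise at low quenching. Points with F >= F0 at
#' nonzero ligand (no quenching) are excluded with a warning.
#'
#' @param tit a [quench_titration()].
#' @param method `"direct"` or `"linearized"`.
#' @param F0 optional explicit unquenched intensity.
#' @return An object of class `lehrer_fit`: `fa`, `ksv`, `se_fa`,
#'   `se_ksv`, `method`, `n`, plus the underlying fit object.
#' @export
lehrer_fit <- function(tit, method = c("direct", "linearized"), F0 = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(tit, "quench_titration"))
  if (is.null(F0)) F0 <- titration_F0(tit)
  q <- tit$ligand_conc[tit$ligand_conc > 0]
  F <- tit$F[tit$ligand_conc > 0]
  bad <- F >= F0
  if (any(bad)) {
    warning(sprintf("%d point(s) with F >= F0 (no quenching) excluded", sum(bad)))
    q <- q[!bad]; F <- F[!bad]
  }
  if (length(q) < 4L)
    stop("need at least 4 points with measurable quenching (F < F0)",
         call. = FALSE)

  # linearized start values in all cases
  ylin <- F0 / (F0 - F)
  xlin <- 1 / q
  lfit <- stats::lm(ylin ~ xlin)
  co <- stats::coef(lfit)
  fa0 <- 1 / unname(co[["(Intercept)"]])
  ksv0 <- unname(co[["(Intercept)"]]) / unname(co[["xlin"]])
  if (!is.finite(fa0) || fa0 <= 0) fa0 <- 0.5
  if (!is.finite(ksv0) || ksv0 <= 0) ksv0 <- 1 / stats::median(q)
  fa0 <- min(fa0, 1)

  if (method == "linearized") {
    V <- suppressWarnings(stats::vcov(lfit))
    a <- unname(co[["(Intercept)"]]); b <- unname(co[["xlin"]])
    fa <- 1 / a; ksv <- a / b
    # delta-method standard errors
    se_fa <- sqrt(V[1, 1]) / a^2
    g <- c(1 / b, -a / b^2)   # d(a/b)/d(a,b)
    se_ksv <- sqrt(drop(t(g) %*% V %*% g))
    obj <- lfit
  } else {
    df <- data.frame(q = q, F = F)
    obj <- minpack.lm::nlsLM(
      F ~ F0 * (1 - fa * ksv * q / (1 + ksv * q)),
      data = df, start = list(fa = fa0, ksv = ksv0),
      lower = c(fa = 1e-8, ksv = 0),
      upper = c(fa = 1, ksv = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co2 <- stats::coef(obj); se <- sqrt(diag(stats::vcov(obj)))
    fa <- unname(co2[["fa"]]); ksv <- unname(co2[["ksv"]])
    se_fa <- unname(se[["fa"]]); se_ksv <- unname(se[["ksv"]])
  }
  if (fa <= 0 || fa > 1 + 1e-9)
    warning(sprintf("fitted fa = %.4g outside (0, 1]", fa))
  structure(list(fa = fa, ksv = ksv, se_fa = se_fa, se_ksv = se_ksv,
                 method = method, n = length(q), F0 = F0, fit = obj),
            class = "lehrer_fit")
}

#' @export
print.lehrer_fit <- function(x, ...) {
  cat(sprintf("Lehrer fit (%s): fa = %.4g +/- %.3g, Ksv = %.6g +/- %.3g L/mol (n = %d)\n",
              x$method, x$fa, x$se_fa, x$ksv, x$se_ksv, x$n))
  invisible(x)
}

#' @export
coef.lehrer_fit <- function(object, ...) c(fa = object$fa, ksv = object$ksv)

#' @export
predict.lehrer_fit <- function(object, ligand_conc, ...) {
  object$F0 * (1 - object$fa * object$ksv * ligand_conc /
                 (1 + object$ksv * ligand_conc))
}

#' Classify the quenching mechanism from the bimolecular rate
#'
#' Computes Kq = Ksv / tau and compares it with the diffusion-limited
#' collisional rate: Kq strictly above the threshold (default 1e10
#' L mol^-1 s^-1) is only compatible with static (complex-formation)
#' quenching; at or below it, dynamic quenching cannot be excluded.
#'
#' @param ksv Stern-Volmer constant, L/mol, > 0.
#' @param tau fluorophore lifetime, s, > 0 (default 5e-9).
#' @param threshold diffusion-limit rate, L mol^-1 s^-1.
#' @return An object of class `mechanism_call` with `kq`, `threshold`, and
#'   `call` (`"static"` or `"dynamic-possible"`).
#' @export
mechanism_call <- function(ksv, tau = 5e-9, threshold = 1e10) {
  if (!is.numeric(ksv) || ksv <= 0) stop("ksv must be positive", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  kq <- ksv / tau
  structure(list(kq = kq, threshold = threshold,
                 call = if (kq > threshold) "static" else "dynamic-possible"),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Kq = %.4g L/mol/s (threshold %.3g): %s\n",
              x$kq, x$threshold, x$call))
  invisible(x)
}

#' Dissociation constant from a static-quenching Stern-Volmer constant
#'
#' Under a static mechanism the Stern-Volmer constant equals the
#' association constant of the complex, so the dissociation constant is
#' its reciprocal: Kd = 1/Ksv.
#'
#' @param ksv Stern-Volmer constant, L/mol, > 0.
#' @return Kd in mol/L.
#' @examples
#' dissociation_constant(117050) * 1e6   # 8.54 uM
#' @export
dissociation_constant <- function(ksv) {
  if (!is.numeric(ksv) || any(ksv <= 0))
    stop("ksv must be positive", call. = FALSE)
  1 / ksv
}
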