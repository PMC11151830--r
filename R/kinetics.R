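#' Fit a single-exponential dark-recovery trace
#'
#' Nonlinear least squares of `A(t) = A0 + A1 exp(-k t)` to a dark trace
#' (absorbance at 450 nm, or mean residue ellipticity at 208 nm for
#' CD-monitored recovery). Initial guesses come from endpoint heuristics:
#' `A0` is the mean of the last decile, `A1` the first point minus `A0`,
#' and the rate the reciprocal of the time at which the amplitude has
#' decayed to 1/e. A warning is issued when the trace spans less than one
#' fitted half-life.
#'
#' @param trace A dark [kinetic_trace()] with at least 6 points.
#' @return Object of class `lov_kinetic_fit` with fields `model`, `A0`,
#'   `A1`, `rate_observed` (s^-1), standard errors, and residual RMS.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "lov_trace"))
  if (trace$illumination_intensity != 0) {
    stop_validation("recovery requires a dark trace (illumination_intensity 0)")
  }
  fit <- fit_single_exponential(trace$times, trace$signal)
  if (diff(range(trace$times)) < log(2) / fit$rate) {
    warning("trace spans less than one half-life; rate poorly constrained")
  }
  structure(
    list(model = "recovery", A0 = fit$A0, A1 = fit$A1,
         rate_observed = fit$rate, k_rec = fit$rate, k1 = NA_real_,
         se = fit$se, residual_rms = fit$residual_rms,
         temperature = trace$temperature),
    class = "lov_kinetic_fit"
  )
}

#' Fit a photoactivation trace under constant illumination
#'
#' Under illumination the two-state photocycle decays with observed rate
#' `k_obs = k1 + k_rec` toward the photostationary plateau. The observed
#' exponential is fitted as in [fit_recovery()] and the photoactivation
#' rate obtained by subtracting the independently determined recovery rate:
#' `k1 = k_obs - k_rec`. `k1` is defined at the fixed illumination
#' condition of the trace (the reference condition is 3 mW cm^-2 of blue
#' light).
#'
#' @param trace An illuminated [kinetic_trace()].
#' @param k_rec Independently determined dark-recovery rate (s^-1), >= 0.
#' @return A `lov_kinetic_fit` with `k1`, `k_rec` and
#'   `rate_observed = k1 + k_rec`.
#' @export
fit_photoactivation <- function(trace, k_rec) {
  stopifnot(inherits(trace, "lov_trace"))
  if (k_rec < 0) stop_validation("k_rec must be >= 0")
  if (trace$illumination_intensity <= 0) {
    stop_validation("photoactivation requires an illuminated trace")
  }
  fit <- fit_single_exponential(trace$times, trace$signal)
  if (fit$rate <= k_rec) {
    stop_validation("photoactivation slower than recovery -- check intensity/units")
  }
  structure(
    list(model = "photoactivation", A0 = fit$A0, A1 = fit$A1,
         rate_observed = fit$rate, k1 = fit$rate - k_rec, k_rec = k_rec,
         se = fit$se, residual_rms = fit$residual_rms,
         temperature = trace$temperature,
         illumination_intensity = trace$illumination_intensity),
    class = "lov_kinetic_fit"
  )
}

#' @export
print.lov_kinetic_fit <- function(x, ...) {
  cat(sprintf("<lov_kinetic_fit> %s: observed rate %.4g s-1", x$model,
              x$rate_observed))
  if (x$model == "photoactivation") {
    cat(sprintf(" (k1 %.4g, k_rec %.4g)", x$k1, x$k_rec))
  }
  cat(sprintf(", A0 %.4g, A1 %.4g\n", x$A0, x$A1))
  invisible(x)
}

# Shared single-exponential engine: A(t) = A0 + A1 exp(-k t).
fit_single_exponential <- function(times, signal) {
  if (length(times) < 6) {
    stop_validation("need >= 6 points for an exponential fit")
  }
  n <- length(signal)
  A0g <- mean(signal[times >= stats::quantile(times, 0.9)])
  A1g <- signal[1] - A0g
  if (abs(A1g) < 1e-12 ||
      abs(A1g) < 1e-6 * max(abs(signal), .Machine$double.eps)) {
    stop_validation("no decay detected: trace is constant")
  }
  # time at which the amplitude has fallen to 1/e
  target <- A0g + A1g / exp(1)
  crossed <- if (A1g > 0) which(signal <= target) else which(signal >= target)
  t_e <- if (length(crossed)) times[crossed[1]] else max(times)
  kg <- 1 / max(t_e, diff(range(times)) / n)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ A0 + A1 * exp(-k * times),
      start = list(A0 = A0g, A1 = A1g, k = kg),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_validation(paste("exponential fit did not converge:",
                            conditionMessage(e)))
    })
  est <- stats::coef(fit)
  if (est[["k"]] <= 0) {
    stop_validation("fitted rate is non-positive; model inappropriate for this trace")
  }
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     c("A0", "A1", "k")))
  list(A0 = est[["A0"]], A1 = est[["A1"]], rate = est[["k"]], se = se,
       residual_rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Fit the Arrhenius temperature dependence of a rate constant
#'
#' Ordinary least squares of `ln k` against `1/T` per
#' `k = A exp(-EA / RT)`; the activation energy is `-slope * R`, reported
#' in kJ mol^-1. Two distinct temperatures determine the line exactly (no
#' standard errors); at least three are needed for uncertainty estimates.
#'
#' @param points data.frame with columns `temperature` (K) and `k`
#'   (s^-1, all > 0), or a list of `(T, k)` pairs.
#' @return Object of class `lov_arrhenius_fit`: `EA_kj_mol`, `lnA`,
#'   standard errors (NA for two-point input), residuals.
#' @export
fit_arrhenius <- function(points) {
  if (!is.data.frame(points)) {
    points <- as.data.frame(do.call(rbind, points))
    names(points) <- c("temperature", "k")
  }
  if (!all(c("temperature", "k") %in% names(points))) {
    stop_validation("points needs columns temperature and k")
  }
  if (any(points$k <= 0)) stop_validation("all rate constants must be positive")
  n_temp <- length(unique(points$temperature))
  if (n_temp < 2) {
    stop_validation("need at least 2 distinct temperatures")
  }
  fit <- stats::lm(log(k) ~ I(1 / temperature), data = points)
  co <- stats::coef(fit)
  EA <- -unname(co[2]) * GAS_CONSTANT / 1000
  ses <- if (nrow(points) > 2) {
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  } else c(NA_real_, NA_real_)
  structure(
    list(EA_kj_mol = EA, lnA = unname(co[1]),
         EA_se_kj_mol = unname(ses[2]) * GAS_CONSTANT / 1000,
         lnA_se = unname(ses[1]),
         residuals = stats::residuals(fit), n_temperatures = n_temp),
    class = "lov_arrhenius_fit"
  )
}

#' @export
print.lov_arrhenius_fit <- function(x, ...) {
  cat(sprintf("<lov_arrhenius_fit> EA = %.1f kJ mol-1 (lnA = %.2f), %d temperatures\n",
              x$EA_kj_mol, x$lnA, x$n_temperatures))
  invisible(x)
}

#' Photostationary-state dark fraction of the two-state photocycle
#'
#' At steady state under constant illumination, activation and recovery
#' fluxes balance and the dark-adapted fraction is `k_rec / (k1 + k_rec)`.
#' Optionally `k1` is rescaled linearly with illumination intensity before
#' evaluation (`k1` is proportional to photon flux); this is an
#' extrapolation beyond the calibrated reference intensity, not a measured
#' quantity.
#'
#' @param k1 Photoactivation rate (s^-1) at the reference intensity, >= 0.
#' @param k_rec Dark-recovery rate (s^-1), >= 0. Not both rates may be 0.
#' @param intensity,intensity_ref Optional illumination rescaling:
#'   `k1 * intensity / intensity_ref` is used when `intensity` is given.
#' @return Dark-state fraction in \[0, 1\].
#' @export
#' @examples
#' pss_dark_fraction(0.048, 0.013)
pss_dark_fraction <- function(k1, k_rec, intensity = NULL,
                              intensity_ref = 3) {
  if (k1 < 0 || k_rec < 0) stop_validation("rates must be >= 0")
  if (!is.null(intensity)) {
    if (intensity < 0 || intensity_ref <= 0) {
      stop_validation("intensities must be positive")
    }
    k1 <- k1 * intensity / intensity_ref
  }
  if (k1 == 0 && k_rec == 0) {
    stop_validation("k1 and k_rec cannot both be 0")
  }
  k_rec / (k1 + k_rec)
}
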