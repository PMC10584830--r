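# Hybridization kinetics.  Both the duplex-formation and strand-displacement
# reactions are bimolecular with reactants mixed at equal concentration C0,
# so unreacted concentration follows [S](t) = C0 / (1 + k*C0*t) and a plot of
# 1/[S] against time is linear with slope k (M^-1 s^-1).

kB_J_PER_K <- 1.380649e-23 # Boltzmann constant, J/K

# coefficient of determination without summary.lm's perfect-fit warning
r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(1)
  max(0, min(1, 1 - sum(resid(fit)^2) / sst))
}

#' Simulate a second-order fluorescence trace
#'
#' Equal-concentration bimolecular decay `[S](t) = C0/(1 + k C0 t)` mapped
#' through an affine signal calibration (identity by default, i.e. the
#' signal is the unreacted concentration), with optional Gaussian noise.
#' A synthetic stand-in for a dye/quencher hybridization assay.
#'
#' @param k Rate constant (M^-1 s^-1, > 0).
#' @param times Sampling times in seconds (strictly increasing).
#' @param C0 Initial reactant concentration in M (default 1e-8, i.e. 10 nM).
#' @param noise_sd Gaussian noise s.d. on the signal (same units as the
#'   signal; default 0).
#' @param calibration List `(slope, intercept)` mapping concentration to
#'   signal.
#' @param temperature Temperature in degrees C (metadata).
#' @param reaction `"formation"` or `"displacement"` (metadata).
#' @param seed Optional integer seed.
#' @return A `fluorescence_trace`: data.frame (time, signal) with attributes
#'   `C0`, `calibration`, `temperature`, `reaction`.
#' @export
simulate_second_order <- function(k, times, C0 = 1e-8, noise_sd = 0,
                                  calibration = list(slope = 1,
                                                     intercept = 0),
                                  temperature = 25,
                                  reaction = c("formation", "displacement"),
                                  seed = NULL) {
  stopifnot(k > 0, C0 > 0, all(diff(times) > 0))
  reaction <- match.arg(reaction)
  if (!is.null(seed)) set.seed(seed)
  conc <- C0 / (1 + k * C0 * times)
  signal <- calibration$slope * conc + calibration$intercept
  if (noise_sd > 0) signal <- signal + rnorm(length(times), 0, noise_sd)
  structure(data.frame(time = times, signal = signal),
            C0 = C0, calibration = calibration, temperature = temperature,
            reaction = reaction,
            class = c("fluorescence_trace", "data.frame"))
}

#' Extract a rate constant from a trace
#'
#' Converts the signal back to concentration via the trace's calibration,
#' then fits `1/[S] ~ time` by least squares on each candidate initial
#' window; the window with the largest coefficient of determination wins and
#' its slope is the rate constant.
#'
#' @param trace A `fluorescence_trace`, or a data.frame with `time` and
#'   `signal` columns (then `C0`/`calibration` must be supplied).
#' @param windows Candidate window lengths in seconds.
#' @param C0,calibration Overrides for plain data.frames.
#' @return Object of class `rate_fit`: `k` (M^-1 s^-1), `window` (s), `r2`.
#' @export
fit_rate <- function(trace, windows = c(5, 10, 20, 50, 100, 200, 500),
                     C0 = NULL, calibration = NULL) {
  if (is.null(calibration)) calibration <- attr(trace, "calibration")
  if (is.null(calibration)) calibration <- list(slope = 1, intercept = 0)
  conc <- (trace$signal - calibration$intercept) / calibration$slope
  # noise can push late, nearly exhausted points at or below zero, where
  # 1/[S] is undefined; such points are excluded from every window
  usable <- conc > 0
  if (sum(usable) < 2L) {
    stop("fewer than 2 points with positive calibrated concentration",
         call. = FALSE)
  }
  inv <- 1 / conc
  best <- NULL
  for (w in sort(windows)) {
    keep <- usable & trace$time <= w
    if (sum(keep) < 2L) next
    f <- lm(inv[keep] ~ trace$time[keep])
    r2 <- r_squared(f, inv[keep])
    if (is.null(best) || r2 > best$r2) {
      best <- list(k = unname(coef(f)[2]), window = w, r2 = r2)
    }
  }
  if (is.null(best)) {
    stop("no candidate window contains at least 2 points", call. = FALSE)
  }
  structure(best, class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Second-order rate fit: k = %.4g M^-1 s^-1 (window %g s, R2 = %.4f)\n",
              x$k, x$window, x$r2))
  invisible(x)
}

#' Arrhenius fit of rate constants against temperature
#'
#' Linear fit of `ln(k)` against `1/T` (T in kelvin, conversion offset
#' 273.15): the slope is `-Ea/kB` and the intercept `ln(A)`, with the
#' Boltzmann constant `kB = 1.380649e-23` J/K, so activation energies are in
#' joules per molecule.
#'
#' @param ks Rate constants (M^-1 s^-1, > 0).
#' @param temps_c Matching temperatures in degrees C (>= 2 distinct).
#' @return Object of class `arrhenius_fit`: `A` (M^-1 s^-1), `Ea` (J), `r2`.
#' @export
arrhenius_fit <- function(ks, temps_c) {
  stopifnot(length(ks) == length(temps_c), all(ks > 0))
  if (length(unique(temps_c)) < 2L) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  invT <- 1 / (temps_c + 273.15)
  f <- lm(log(ks) ~ invT)
  structure(list(A = exp(unname(coef(f)[1])),
                 Ea = -unname(coef(f)[2]) * kB_J_PER_K,
                 r2 = r_squared(f, log(ks))),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: A = %.4g M^-1 s^-1, Ea = %.4g J (R2 = %.4f)\n",
              x$A, x$Ea, x$r2))
  invisible(x)
}

#' Compensation fit between pre-exponential factor and activation energy
#'
#' Across a family of similar reactions, `ln(A)` is empirically linear in
#' `Ea`: `ln(A) = C1 + C2 * Ea`. The derived constants are the maximum rate
#' `C3 = exp(C1)` (M^-1 s^-1) and the critical temperature
#' `Tc = 1/(kB * C2)` (K) at which all reactions on the compensation line
#' share the rate `C3` regardless of activation energy.
#'
#' @param As Pre-exponential factors (M^-1 s^-1, > 0).
#' @param Eas Activation energies (J).
#' @return Object of class `compensation_fit`: `C1` (log M^-1 s^-1), `C2`
#'   (1/J), `C3`, `Tc`, `r2`.
#' @export
compensation_fit <- function(As, Eas) {
  stopifnot(length(As) == length(Eas), all(As > 0), length(As) >= 2L)
  f <- lm(log(As) ~ Eas)
  C1 <- unname(coef(f)[1])
  C2 <- unname(coef(f)[2])
  out <- c(list(C1 = C1, C2 = C2), derived_constants(C1, C2))
  out$r2 <- r_squared(f, log(As))
  structure(out, class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf("Compensation fit: ln(A) = %.3f + %.4g * Ea\n", x$C1, x$C2))
  cat(sprintf("  C3 = %.4g M^-1 s^-1, Tc = %.1f K (R2 = %.4f)\n",
              x$C3, x$Tc, if (is.null(x$r2)) NA else x$r2))
  invisible(x)
}

#' Derived compensation constants
#'
#' @param C1 Intercept of the compensation line (log M^-1 s^-1).
#' @param C2 Slope of the compensation line (1/J).
#' @return List with `C3 = exp(C1)` and `Tc = 1/(kB*C2)`.
#' @examples
#' derived_constants(19.1, 20.6e19) # C3 ~ 1.97e8 M^-1 s^-1, Tc ~ 352 K
#' @export
derived_constants <- function(C1, C2) {
  list(C3 = exp(C1), Tc = 1 / (kB_J_PER_K * C2))
}

#' Rate constant from the compensation model
#'
#' `k = C3 * exp((Ea/kB) * (1/Tc - 1/T))`: equivalent to the Arrhenius form
#' when `(A, Ea)` lies exactly on the compensation line, and equal to `C3`
#' for every `Ea` at `T = Tc`.
#'
#' @param Ea Activation energy (J).
#' @param temp_K Absolute temperature (K).
#' @param C3 Maximum rate (M^-1 s^-1).
#' @param Tc Critical temperature (K).
#' @return Rate constant (M^-1 s^-1).
#' @export
rate_from_compensation <- function(Ea, temp_K, C3, Tc) {
  C3 * exp((Ea / kB_J_PER_K) * (1 / Tc - 1 / temp_K))
}

#' Half-completion time of an equal-concentration bimolecular reaction
#'
#' @param k Rate constant (M^-1 s^-1).
#' @param C0 Initial concentration (M).
#' @return Time in seconds: `1/(k*C0)`.
#' @examples
#' half_completion(1e6, 1e-8) # 100 s
#' @export
half_completion <- function(k, C0) {
  stopifnot(k > 0, C0 > 0)
  1 / (k * C0)
}
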