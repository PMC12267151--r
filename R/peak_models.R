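# Peak model families for oral-bolus enrichment/concentration curves.
# Each family provides: value(t), analytic Tmax/Emax where available, and an
# AUC over a finite window (closed form where one exists).

#' Bateman (one-compartment absorption-elimination) curve
#'
#' `E(t) = A (exp(-ke (t - t0)) - exp(-ka (t - t0)))` for `t > t0`, 0
#' otherwise, with absorption rate `ka` > elimination rate `ke` > 0 and lag
#' `t0 >= 0`. As `ka -> ke` the family degenerates to the limit form
#' `A' s exp(-k s)`; evaluation switches to a series expansion near the
#' degeneracy so the value is continuous.
#'
#' @param t time (min).
#' @param A amplitude (curve units).
#' @param ka,ke absorption and elimination rate constants (1/min).
#' @param t0 lag time (min).
#' @return curve value at `t`.
#' @export
bateman_value <- function(t, A, ka, ke, t0 = 0) {
  stopifnot(ka > 0, ke > 0, t0 >= 0)
  s <- pmax(t - t0, 0)
  d <- ka - ke
  if (abs(d) < 1e-10 * ke) {
    # limit form: A (ka - ke) s exp(-ke s) to first order
    v <- A * d * s * exp(-ke * s)
  } else {
    v <- A * (exp(-ke * s) - exp(-ka * s))
  }
  v[t <= t0] <- 0
  v
}

#' @describeIn bateman_value degenerate (ka = ke) limit form `A s exp(-k s)`.
#' @param k rate constant of the limit form (1/min).
#' @export
bateman_limit_value <- function(t, A, k, t0 = 0) {
  s <- pmax(t - t0, 0)
  v <- A * s * exp(-k * s)
  v[t <= t0] <- 0
  v
}

#' Analytic time of peak for a Bateman curve
#' @inheritParams bateman_value
#' @return `Tmax = t0 + log(ka/ke)/(ka - ke)` (min).
#' @export
bateman_tmax <- function(ka, ke, t0 = 0) {
  stopifnot(ka > 0, ke > 0)
  d <- ka - ke
  if (abs(d) < 1e-10 * ke) return(t0 + 1 / ke)   # limit of log(ka/ke)/(ka-ke)
  t0 + log(ka / ke) / d
}

#' Analytic peak value (Emax) of a Bateman curve
#' @inheritParams bateman_value
#' @export
bateman_emax <- function(A, ka, ke, t0 = 0) {
  bateman_value(bateman_tmax(ka, ke, t0), A, ka, ke, t0)
}

#' Closed-form Bateman AUC over a finite window
#'
#' Integral of the Bateman curve over `window` (min); the curve is zero for
#' `t <= t0`.
#' @inheritParams bateman_value
#' @param window integration limits in min, default `c(0, 300)`.
#' @export
bateman_auc <- function(A, ka, ke, t0 = 0, window = c(0, 300)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  # cumulative integral from t0 to T
  Fcum <- function(T) {
    s <- max(T - t0, 0)
    A * ((1 - exp(-ke * s)) / ke - (1 - exp(-ka * s)) / ka)
  }
  Fcum(window[2]) - Fcum(window[1])
}

#' Solve Bateman parameters from a target peak
#'
#' Given a target `(Emax, Tmax)` and a fixed absorption/elimination rate
#' ratio `rho = ka/ke`, returns the unique Bateman parameter set with that
#' peak. With `t0` fixed, `ke (Tmax - t0) = log(rho)/(rho - 1)` determines
#' the rates and the amplitude is scaled to hit `Emax`.
#'
#' @param emax,tmax target peak value and time (min).
#' @param rho ka/ke ratio (> 1), default 10.
#' @param t0 lag (min).
#' @return named list `A`, `ka`, `ke`, `t0`.
#' @export
bateman_from_peak <- function(emax, tmax, rho = 10, t0 = 0) {
  stopifnot(emax > 0, tmax > t0, rho > 1)
  ke <- log(rho) / ((tmax - t0) * (rho - 1))
  ka <- rho * ke
  A <- emax / (exp(-ke * (tmax - t0)) - exp(-ka * (tmax - t0)))
  list(A = A, ka = ka, ke = ke, t0 = t0)
}

#' Solve Bateman parameters from a target AUC and peak time
#'
#' Same shape constraint as [bateman_from_peak()] but the amplitude is scaled
#' so the windowed AUC matches `auc`.
#' @param auc target AUC (curve units x min) over `window`.
#' @inheritParams bateman_from_peak
#' @param window AUC window (min).
#' @return named list `A`, `ka`, `ke`, `t0`.
#' @export
bateman_from_auc <- function(auc, tmax, rho = 10, t0 = 0, window = c(0, 300)) {
  stopifnot(auc > 0, tmax > t0, rho > 1)
  ke <- log(rho) / ((tmax - t0) * (rho - 1))
  ka <- rho * ke
  A1 <- bateman_auc(1, ka, ke, t0, window)
  list(A = auc / A1, ka = ka, ke = ke, t0 = t0)
}

#' Log-normal peak curve
#'
#' `E(t) = A exp(-(log(t) - log(Tm))^2 / (2 sigma^2))` for `t > 0`: peaks at
#' `t = Tm` with value `A`; right-skewed like oral-bolus curves.
#' @param t time (min), > 0 for nonzero values.
#' @param A peak value.
#' @param Tm peak time (min).
#' @param sigma log-scale width.
#' @export
lognormal_peak_value <- function(t, A, Tm, sigma) {
  stopifnot(A > 0, Tm > 0, sigma > 0)
  v <- ifelse(t > 0, A * exp(-(log(t / Tm))^2 / (2 * sigma^2)), 0)
  v
}

#' Closed-form log-normal peak AUC over a finite window
#'
#' With `mu = log(Tm)`, the integral of the log-normal peak from 0 to T is
#' `A sigma sqrt(2 pi) exp(mu + sigma^2/2) Phi((log T - mu - sigma^2)/sigma)`.
#' @inheritParams lognormal_peak_value
#' @param window integration limits (min).
#' @export
lognormal_peak_auc <- function(A, Tm, sigma, window = c(0, 300)) {
  mu <- log(Tm)
  Fcum <- function(T) {
    if (T <= 0) return(0)
    A * sigma * sqrt(2 * pi) * exp(mu + sigma^2 / 2) *
      stats::pnorm((log(T) - mu - sigma^2) / sigma)
  }
  Fcum(window[2]) - Fcum(window[1])
}

#' Gamma-variate peak curve
#'
#' `E(t) = A (t - t0)^alpha exp(-(t - t0)/beta)` for `t > t0`; peaks at
#' `t0 + alpha beta`.
#' @param t time (min).
#' @param A amplitude.
#' @param alpha shape (> 0).
#' @param beta scale (min, > 0).
#' @param t0 lag (min).
#' @export
gamma_variate_value <- function(t, A, alpha, beta, t0 = 0) {
  stopifnot(A > 0, alpha > 0, beta > 0, t0 >= 0)
  s <- pmax(t - t0, 0)
  v <- A * s^alpha * exp(-s / beta)
  v[t <= t0] <- 0
  v
}

#' Closed-form gamma-variate AUC over a finite window
#'
#' Uses the regularized incomplete gamma function:
#' integral of `s^alpha exp(-s/beta)` from 0 to S equals
#' `beta^(alpha+1) Gamma(alpha+1) P(alpha+1, S/beta)`.
#' @inheritParams gamma_variate_value
#' @param window integration limits (min).
#' @export
gamma_variate_auc <- function(A, alpha, beta, t0 = 0, window = c(0, 300)) {
  Fcum <- function(T) {
    s <- max(T - t0, 0)
    A * beta^(alpha + 1) * gamma(alpha + 1) *
      stats::pgamma(s, shape = alpha + 1, scale = beta)
  }
  Fcum(window[2]) - Fcum(window[1])
}

# Family registry used by fit_peak_model(); order encodes the tie-break
# preference (fewer-parameter/simpler families first).
peak_families <- function() {
  list(
    bateman = list(
      npar = 4L,
      value = function(t, p) bateman_value(t, p[["A"]], p[["ka"]], p[["ke"]], p[["t0"]]),
      tmax = function(p) bateman_tmax(p[["ka"]], p[["ke"]], p[["t0"]]),
      emax = function(p) bateman_emax(p[["A"]], p[["ka"]], p[["ke"]], p[["t0"]]),
      auc  = function(p, window) bateman_auc(p[["A"]], p[["ka"]], p[["ke"]], p[["t0"]], window)
    ),
    lognormal_peak = list(
      npar = 3L,
      value = function(t, p) lognormal_peak_value(t, p[["A"]], p[["Tm"]], p[["sigma"]]),
      tmax = function(p) p[["Tm"]],
      emax = function(p) p[["A"]],
      auc  = function(p, window) lognormal_peak_auc(p[["A"]], p[["Tm"]], p[["sigma"]], window)
    ),
    gamma_variate = list(
      npar = 4L,
      value = function(t, p) gamma_variate_value(t, p[["A"]], p[["alpha"]], p[["beta"]], p[["t0"]]),
      tmax = function(p) p[["t0"]] + p[["alpha"]] * p[["beta"]],
      emax = function(p) gamma_variate_value(p[["t0"]] + p[["alpha"]] * p[["beta"]],
                                             p[["A"]], p[["alpha"]], p[["beta"]], p[["t0"]]),
      auc  = function(p, window) gamma_variate_auc(p[["A"]], p[["alpha"]], p[["beta"]], p[["t0"]], window)
    )
  )
}
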