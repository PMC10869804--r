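## Gas constant, kJ mol^-1 K^-1
.Rgas <- 0.0083144626

#' Fit a fluorescence-polarization binding isotherm
#'
#' Fits a 1:1 binding function assuming each peptide binds each protomer of
#' the dimer independently, so concentrations are protomer-denominated. The
#' `hyperbolic` model treats the titrant as non-depleted:
#' `P(T) = p_free + (p_bound - p_free) * T / (Kd + T)`;
#' the `quadratic_depletion` model uses the exact bound fraction of the
#' fluorescent tracer at its stated concentration. Kd is fitted on a log
#' scale so that the least-squares trajectory cannot cross zero; asymptotic
#' (Jacobian-based) standard errors are reported.
#'
#' @param conc protein concentration, micromolar, protomer units.
#' @param polarization measured polarization, mP.
#' @param model `"hyperbolic"` or `"quadratic_depletion"`.
#' @param tracer_conc fluorescent tracer concentration in micromolar
#'   (default 0.01, i.e. 10 nM), used by the depletion model.
#' @return list of class `binding_fit`: `kd` (micromolar), `kd_se`,
#'   `p_free`, `p_bound` and their SEs, `model`, `residual_sd`, `fitted`,
#'   `data`.
#' @export
fit_fp_binding <- function(conc, polarization,
                           model = c("hyperbolic", "quadratic_depletion"),
                           tracer_conc = 0.01) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(polarization), all(conc >= 0))
  o <- order(conc)
  conc <- conc[o]
  polarization <- polarization[o]
  if (length(conc) < 5L) warning("fewer than 5 titration points; fit may be unstable")
  span <- diff(range(polarization))
  half <- polarization[1] + span / 2 * sign(polarization[length(polarization)] - polarization[1])
  kd0 <- stats::approx(polarization, conc, xout = half, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
  bound_frac <- function(t, kd) {
    if (model == "hyperbolic") t / (kd + t)
    else {
      s <- kd + tracer_conc + t
      (s - sqrt(s^2 - 4 * tracer_conc * t)) / (2 * tracer_conc)
    }
  }
  df <- data.frame(t = conc, p = polarization)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ pf + (pb - pf) * bound_frac(t, exp(lkd)), data = df,
                      start = list(pf = polarization[1],
                                   pb = polarization[length(polarization)],
                                   lkd = log(kd0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("binding fit did not converge: ", conditionMessage(e),
                             call. = FALSE))
  cf <- summary(fit)$coefficients
  kd <- exp(cf["lkd", "Estimate"])
  out <- list(kd = kd,
              kd_se = kd * cf["lkd", "Std. Error"],   # delta method on log Kd
              p_free = cf["pf", "Estimate"], p_free_se = cf["pf", "Std. Error"],
              p_bound = cf["pb", "Estimate"], p_bound_se = cf["pb", "Std. Error"],
              model = model, tracer_conc = tracer_conc,
              residual_sd = summary(fit)$sigma,
              fitted = stats::fitted(fit),
              data = df)
  class(out) <- "binding_fit"
  out
}

#' Confidence interval for a fitted dissociation constant
#'
#' t-based interval computed on the log-Kd scale (the fitting scale), which
#' respects the positivity of Kd and is more accurate than a symmetric
#' interval at small n.
#'
#' @param object a [fit_fp_binding()] result.
#' @param parm ignored (only Kd is intervalled).
#' @param level confidence level.
#' @param ... unused.
#' @return named vector `c(lower, upper)` in micromolar.
#' @export
confint.binding_fit <- function(object, parm = "kd", level = 0.95, ...) {
  df <- nrow(object$data) - 3L
  q <- stats::qt(1 - (1 - level) / 2, df = max(df, 1L))
  se_log <- object$kd_se / object$kd
  c(lower = object$kd * exp(-q * se_log), upper = object$kd * exp(q * se_log))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit (%s): Kd = %.3g +/- %.2g uM, P %.1f -> %.1f mP>\n",
              x$model, x$kd, x$kd_se, x$p_free, x$p_bound))
  invisible(x)
}

two_state_fraction_thermal <- function(T_K, tm_K, dh) {
  1 / (1 + exp(dh / .Rgas * (1 / T_K - 1 / tm_K)))
}

two_state_fraction_chemical <- function(u, dg0, m, T_K = 298.15) {
  1 / (1 + exp(-(dg0 - m * u) / (.Rgas * T_K)))
}

thermal_model <- function(T_K, tm, dh, af, bf, au, bu) {
  f <- two_state_fraction_thermal(T_K, tm, dh)
  (1 - f) * (af + bf * T_K) + f * (au + bu * T_K)
}

chemical_model <- function(u, dg0, m, af, bf, au, bu, T_K) {
  f <- two_state_fraction_chemical(u, dg0, m, T_K)
  (1 - f) * (af + bf * u) + f * (au + bu * u)
}

check_transition <- function(fit, midpoint, xr, amp_at_mid) {
  rmse <- summary(fit)$sigma
  if (!is.finite(midpoint) || midpoint < xr[1] || midpoint > xr[2] ||
      abs(amp_at_mid) <= max(4 * rmse, 1e-12)) {
    stop(structure(class = c("dimerlab_no_transition", "error", "condition"),
                   list(message = "no transition detected within the data range",
                        call = NULL)))
  }
}

#' Fit a two-state thermal denaturation curve
#'
#' Minimal two-state model with linear folded/unfolded baselines and a van't
#' Hoff transition (delta-Cp fixed at 0, not estimable from a single melt):
#' `f(T) = 1 / (1 + exp(dH/R * (1/T - 1/Tm)))` with T in Kelvin, and
#' `signal = (1 - f) * (af + bf*T) + f * (au + bu*T)`. Temperatures are
#' supplied in Celsius and converted internally; `Tm` is returned in
#' Celsius. Traces without a resolvable transition in the scanned range (a
#' flat or baseline-only signal, as an unfolded variant would give) raise a
#' "no transition detected" error rather than returning a spurious midpoint.
#'
#' @param temperature Celsius, strictly increasing.
#' @param signal CD signal (e.g. ellipticity at 222 nm), arbitrary units.
#' @return list of class `two_state_fit`: `midpoint` (Tm, Celsius),
#'   `midpoint_se`, `dh` (van't Hoff enthalpy, kJ/mol), `dh_se`, baselines,
#'   `residual_sd`, `fitted`, `data`, `kind = "thermal"`.
#' @export
fit_two_state_thermal <- function(temperature, signal) {
  stopifnot(length(temperature) == length(signal),
            all(diff(temperature) > 0))
  if (length(temperature) < 10L) stop("need at least 10 points across the melt")
  T_K <- temperature + 273.15
  ## midpoint guess from the steepest slope of a lightly smoothed trace
  sm <- stats::lowess(T_K, signal, f = 1 / 4)
  slope <- diff(sm$y) / diff(sm$x)
  tm0 <- sm$x[which.max(abs(slope))]
  df <- data.frame(T_K = T_K, y = signal)
  n <- length(signal)
  lo <- stats::lm(y ~ T_K, data = df[seq_len(max(3, n %/% 4)), ])
  hi <- stats::lm(y ~ T_K, data = df[(n - max(3, n %/% 4) + 1):n, ])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ thermal_model(T_K, tm, dh, af, bf, au, bu),
      data = df,
      start = list(tm = tm0, dh = 200,
                   af = as.numeric(stats::coef(lo)[1]), bf = as.numeric(stats::coef(lo)[2]),
                   au = as.numeric(stats::coef(hi)[1]), bu = as.numeric(stats::coef(hi)[2])),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(structure(
      class = c("dimerlab_no_transition", "error", "condition"),
      list(message = paste0("no transition detected (fit failed: ",
                            conditionMessage(e), ")"), call = NULL))))
  cf <- summary(fit)$coefficients
  tm_K <- cf["tm", "Estimate"]
  amp <- (cf["au", "Estimate"] + cf["bu", "Estimate"] * tm_K) -
    (cf["af", "Estimate"] + cf["bf", "Estimate"] * tm_K)
  check_transition(fit, tm_K, range(T_K), amp)
  if (cf["dh", "Estimate"] <= 0) {
    stop(structure(class = c("dimerlab_no_transition", "error", "condition"),
                   list(message = "fitted van't Hoff enthalpy is not positive; no unfolding transition",
                        call = NULL)))
  }
  out <- list(midpoint = tm_K - 273.15, midpoint_se = cf["tm", "Std. Error"],
              dh = cf["dh", "Estimate"], dh_se = cf["dh", "Std. Error"],
              baseline_folded = c(intercept = unname(cf["af", "Estimate"]),
                                  slope = unname(cf["bf", "Estimate"])),
              baseline_unfolded = c(intercept = unname(cf["au", "Estimate"]),
                                    slope = unname(cf["bu", "Estimate"])),
              residual_sd = summary(fit)$sigma,
              fitted = stats::fitted(fit),
              data = data.frame(temperature = temperature, signal = signal),
              kind = "thermal")
  class(out) <- "two_state_fit"
  out
}

#' Fit a two-state chemical (urea) denaturation curve
#'
#' Linear-extrapolation model: `dG(u) = dG0 - m * u`,
#' `f(u) = 1 / (1 + exp(-dG(u) / RT))` at 25 C, with linear baselines as in
#' [fit_two_state_thermal()]. The midpoint is `Cm = dG0 / m`.
#'
#' @param denaturant denaturant concentration, molar, strictly increasing.
#' @param signal CD signal, arbitrary units.
#' @param temperature_c assay temperature in Celsius (default 25).
#' @return list of class `two_state_fit` with `midpoint` (Cm, molar),
#'   `dg0` (kJ/mol), `m_value` (kJ/mol/M) and uncertainties;
#'   `kind = "chemical"`.
#' @export
fit_two_state_chemical <- function(denaturant, signal, temperature_c = 25) {
  stopifnot(length(denaturant) == length(signal), all(diff(denaturant) > 0))
  if (length(denaturant) < 10L) stop("need at least 10 points across the transition")
  T_K <- temperature_c + 273.15
  sm <- stats::lowess(denaturant, signal, f = 1 / 4)
  slope <- diff(sm$y) / diff(sm$x)
  cm0 <- sm$x[which.max(abs(slope))]
  df <- data.frame(u = denaturant, y = signal)
  n <- length(signal)
  lo <- stats::lm(y ~ u, data = df[seq_len(max(3, n %/% 4)), ])
  hi <- stats::lm(y ~ u, data = df[(n - max(3, n %/% 4) + 1):n, ])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ chemical_model(u, dg0, m, af, bf, au, bu, T_K),
      data = df,
      start = list(dg0 = max(10, 10 * cm0), m = 10,
                   af = as.numeric(stats::coef(lo)[1]), bf = as.numeric(stats::coef(lo)[2]),
                   au = as.numeric(stats::coef(hi)[1]), bu = as.numeric(stats::coef(hi)[2])),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(structure(
      class = c("dimerlab_no_transition", "error", "condition"),
      list(message = paste0("no transition detected (fit failed: ",
                            conditionMessage(e), ")"), call = NULL))))
  cf <- summary(fit)$coefficients
  dg0 <- cf["dg0", "Estimate"]
  m <- cf["m", "Estimate"]
  cm <- dg0 / m
  amp <- (cf["au", "Estimate"] + cf["bu", "Estimate"] * cm) -
    (cf["af", "Estimate"] + cf["bf", "Estimate"] * cm)
  check_transition(fit, cm, range(denaturant), amp)
  if (m <= 0 || dg0 <= 0) {
    stop(structure(class = c("dimerlab_no_transition", "error", "condition"),
                   list(message = "fitted m-value or dG0 not positive; no unfolding transition",
                        call = NULL)))
  }
  ## SE of Cm = dG0/m by first-order propagation with parameter covariance
  V <- stats::vcov(fit)[c("dg0", "m"), c("dg0", "m")]
  g <- c(1 / m, -dg0 / m^2)
  cm_se <- sqrt(drop(t(g) %*% V %*% g))
  out <- list(midpoint = cm, midpoint_se = cm_se,
              dg0 = dg0, dg0_se = cf["dg0", "Std. Error"],
              m_value = m, m_value_se = cf["m", "Std. Error"],
              baseline_folded = c(intercept = unname(cf["af", "Estimate"]),
                                  slope = unname(cf["bf", "Estimate"])),
              baseline_unfolded = c(intercept = unname(cf["au", "Estimate"]),
                                    slope = unname(cf["bu", "Estimate"])),
              residual_sd = summary(fit)$sigma,
              fitted = stats::fitted(fit),
              data = data.frame(denaturant = denaturant, signal = signal),
              kind = "chemical")
  class(out) <- "two_state_fit"
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (x$kind == "thermal") {
    cat(sprintf("<two_state_fit (thermal): Tm = %.2f +/- %.2g C, dH = %.0f kJ/mol>\n",
                x$midpoint, x$midpoint_se, x$dh))
  } else {
    cat(sprintf("<two_state_fit (chemical): Cm = %.3f +/- %.2g M, dG0 = %.1f kJ/mol, m = %.2f kJ/mol/M>\n",
                x$midpoint, x$midpoint_se, x$dg0, x$m_value))
  }
  invisible(x)
}
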