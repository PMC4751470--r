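#' Linear fit of inverse time constants versus blocker concentration
#'
#' For a two-state blocking scheme the relaxation rate is
#' `1/tau = kon * [B] + koff`, so an ordinary least-squares line through
#' `(conc, 1/tau)` at one voltage yields the second-order on-rate constant
#' (slope, M^-1 s^-1) and the off rate (intercept, s^-1) at that voltage.
#' A non-positive fitted slope is flagged invalid rather than an error.
#'
#' @param taus Data frame with columns `conc` (M) and `tau_ms` (ms), or
#'   `conc` and `rate_s` (s^-1) directly.
#' @param v Voltage label (mV) stored in the result.
#' @return A `rate_conc_fit`: `v`, `slope` (M^-1 s^-1), `intercept` (s^-1),
#'   `r_squared`, `valid`.
#' @export
rate_vs_conc <- function(taus, v = NA_real_) {
  stopifnot(is.data.frame(taus), "conc" %in% names(taus))
  rate <- if ("rate_s" %in% names(taus)) taus$rate_s else {
    if (!"tau_ms" %in% names(taus)) stop("need a tau_ms or rate_s column")
    1000 / taus$tau_ms
  }
  if (nrow(taus) < 3L) stop("need at least 3 concentrations")
  fit <- stats::lm(rate ~ conc, data = data.frame(conc = taus$conc, rate = rate))
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(v = v, slope = unname(cf["conc"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = r2, valid = unname(cf["conc"]) > 0),
            class = "rate_conc_fit")
}

#' Woodhull rate-voltage fit
#'
#' Fits `rate(V) = rate0 * exp(+/- coeff * V / vt)`. Two estimators are
#' provided: `method = "loglinear"` (the default) regresses `log(rate)` on
#' voltage with equal weights, which is exact on noise-free synthetic data
#' and standard for Woodhull analyses; `method = "nls"` fits the
#' exponential itself by Levenberg-Marquardt least squares on the rate
#' scale (the behaviour of common plotting/fitting software, which weights
#' the large-rate end more heavily). The exponent coefficient is
#' reported per thermal voltage (`coeff_per_vt = |slope| * vt`, i.e. the
#' `Zdelta` of a Woodhull barrier model) together with the electrical
#' distance `delta = coeff_per_vt / z_assumed` for a stated blocker valence.
#' `sign = "on"` expects rates increasing with depolarization (entry from
#' the inside), `sign = "off"` decreasing (exit to the inside); a fitted
#' slope of the unexpected sign triggers a warning and `sign_ok = FALSE`.
#'
#' @param rates Data frame with columns `v` (mV) and `rate` (s^-1 or
#'   M^-1 s^-1; must be positive).
#' @param sign `"on"` or `"off"`.
#' @param z_assumed Assumed effective valence (2 for Mg2+, 4 for spermine).
#' @param vt Thermal voltage (mV).
#' @param method `"loglinear"` or `"nls"` (see Description).
#' @return A `rate_voltage_fit`: `rate0` (value at 0 mV), `coeff_per_vt`
#'   (dimensionless, >= 0), `delta`, `z_assumed`, `sign`, `sign_ok`,
#'   `r_squared`, `n`.
#' @export
fit_rate_voltage <- function(rates, sign = c("on", "off"), z_assumed = 2,
                             vt = 25, method = c("loglinear", "nls")) {
  sign <- match.arg(sign)
  method <- match.arg(method)
  stopifnot(is.data.frame(rates), all(c("v", "rate") %in% names(rates)))
  if (nrow(rates) < 3L) stop("need at least 3 voltages")
  if (any(!is.finite(rates$rate)) || any(rates$rate <= 0))
    stop("all rates must be positive and finite")
  fit <- stats::lm(lr ~ v, data = data.frame(v = rates$v, lr = log(rates$rate)))
  cf <- stats::coef(fit)
  if (method == "nls") {
    nfit <- minpack.lm::nlsLM(
      rate ~ exp(la + sl * v), data = rates,
      start = list(la = unname(cf["(Intercept)"]), sl = unname(cf["v"])),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nfit)
    names(cf) <- c("(Intercept)", "v")
  }
  slope <- unname(cf["v"])
  expected <- if (sign == "on") 1 else -1
  sign_ok <- slope == 0 || base::sign(slope) == expected
  if (!sign_ok)
    warning(sprintf("fitted voltage dependence has the opposite sign to '%s'", sign))
  structure(list(rate0 = exp(unname(cf["(Intercept)"])),
                 coeff_per_vt = abs(slope) * vt,
                 delta = abs(slope) * vt / z_assumed,
                 z_assumed = z_assumed, sign = sign, sign_ok = sign_ok,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = nrow(rates)),
            class = "rate_voltage_fit")
}

#' @export
print.rate_voltage_fit <- function(x, ...) {
  cat(sprintf("<rate_voltage_fit> %s: rate0 = %.4g, Zdelta = %.3f (delta = %.3f at z = %d), r^2 = %.4f, n = %d\n",
              x$sign, x$rate0, x$coeff_per_vt, x$delta, x$z_assumed,
              x$r_squared, x$n))
  invisible(x)
}

#' Woodhull off-rate parameters per genotype
#'
#' Chains [tail_kinetics()] and [fit_rate_voltage()] over the genotypes of
#' a two-pulse experiment: the slow-tail decay at each negative tail
#' voltage gives the unblocking relaxation; when the design carries several
#' blocker concentrations per voltage, the off rate at that voltage is
#' taken as the concentration-series intercept of `1/tau` (removing the
#' `kon * [B]` contribution), otherwise as the raw `1/tau`. The resulting
#' `off rate(V)` series is fitted with
#' `off_rate(V) = off_rate(0) * exp(-Zdelta * V / vt)`.
#'
#' @param exp A `kir_experiment` with two-pulse sweeps at >= 3 negative
#'   tail voltages per genotype.
#' @param z_assumed Valence used to report `delta`.
#' @param v_range Tail-voltage window analysed (mV), default -100 to -20.
#' @param blank_ms Blank passed to the relaxation fits.
#' @return A data.frame with one row per genotype: `genotype`, `rate0_s`,
#'   `zdelta`, `delta`, `r_squared`, `n_voltages`; genotypes without
#'   analysable tails are listed in the `skipped` attribute with reasons.
#' @export
woodhull_table <- function(exp, z_assumed = 2, v_range = c(-100, -20),
                           blank_ms = NULL) {
  stopifnot(inherits(exp, "kir_experiment"))
  gens <- unique(exp$design$genotype)
  rows <- list()
  skipped <- character(0)
  for (g in gens) {
    res <- tryCatch({
      tk <- tail_kinetics(exp, genotype = g, blank_ms = blank_ms,
                          require_growth = FALSE)
      off <- tk$off[tk$off$v >= v_range[1] & tk$off$v <= v_range[2], ]
      if (!nrow(off)) stop("no tail fits in the voltage window")
      per_v <- lapply(split(off, off$v), function(d) {
        rate <- if (length(unique(d$conc)) >= 3L)
          rate_vs_conc(d[c("conc", "rate_s")], v = d$v[1])$intercept
        else mean(d$rate_s)
        data.frame(v = d$v[1], rate = rate)
      })
      rv <- do.call(rbind, per_v)
      if (nrow(rv) < 3L) stop("fewer than 3 tail voltages")
      fit <- fit_rate_voltage(rv, sign = "off", z_assumed = z_assumed)
      data.frame(genotype = g, rate0_s = fit$rate0, zdelta = fit$coeff_per_vt,
                 delta = fit$delta, r_squared = fit$r_squared,
                 n_voltages = fit$n, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) skipped[g] <- conditionMessage(res)
    else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no genotype admitted a Woodhull fit")
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
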