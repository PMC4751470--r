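#' Double-mutant-cycle coupling coefficient
#'
#' For two mutations A and B, the coupling coefficient compares the product
#' of the single-mutant Kd fold-changes (each versus wild type) with the
#' double mutant's fold-change:
#' `omega = [(kd_a / kd_wt) * (kd_b / kd_wt)] / (kd_ab / kd_wt)`.
#' `omega = 1` signals purely additive (energetically independent) effects;
#' `omega < 1` negative cooperativity (the double mutant loses more
#' affinity than the singles predict); `omega > 1` positive cooperativity.
#' Omega is invariant to the Kd unit and to swapping A and B.
#'
#' @param kd_wt,kd_a,kd_b,kd_ab Apparent Kd (same unit) of the wild type,
#'   each single mutant and the double mutant, at one stated voltage.
#' @param pair Character pair of mutation labels.
#' @param v Voltage (mV) at which the Kds were measured (metadata).
#' @param additive_band Omega interval called "additive" in the verdict.
#' @return A `cycle_result`: `pair`, `v`, the four Kds, `omega`, `verdict`.
#' @export
coupling_coefficient <- function(kd_wt, kd_a, kd_b, kd_ab,
                                 pair = c("A", "B"), v = NA_real_,
                                 additive_band = c(0.5, 2)) {
  kds <- c(kd_wt, kd_a, kd_b, kd_ab)
  if (any(!is.finite(kds)) || any(kds <= 0))
    stop("all Kd values must be positive and finite")
  omega <- (kd_a / kd_wt) * (kd_b / kd_wt) / (kd_ab / kd_wt)
  verdict <- if (omega < additive_band[1]) "negative-cooperative"
  else if (omega > additive_band[2]) "positive-cooperative"
  else "additive"
  structure(list(pair = pair, v = v, kd_wt = kd_wt, kd_a = kd_a,
                 kd_b = kd_b, kd_ab = kd_ab, omega = omega,
                 verdict = verdict),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> %s + %s at %g mV: omega = %.3g (%s)\n",
              x$pair[1], x$pair[2], x$v, x$omega, x$verdict))
  invisible(x)
}

#' Coupling coefficients for a list of mutation pairs
#'
#' @param kds Named numeric vector (or list) of apparent Kd per genotype at
#'   one voltage; must contain `"WT"`, both singles, and the double (named
#'   `"A/B"`) for each pair analysed.
#' @param pairs List of character pairs `c(a, b)`; the double is looked up
#'   as `"a/b"` (or `"b/a"`).
#' @param v Voltage (mV), metadata.
#' @param additive_band Passed to [coupling_coefficient()].
#' @return A data.frame sorted by omega with one row per analysable pair;
#'   pairs with missing genotypes are listed in the `skipped` attribute.
#' @export
cycle_scan <- function(kds, pairs, v = NA_real_, additive_band = c(0.5, 2)) {
  kds <- unlist(kds)
  if (!"WT" %in% names(kds)) stop("kds must contain a WT entry")
  rows <- list()
  skipped <- character(0)
  for (p in pairs) {
    ab <- if (paste(p[1], p[2], sep = "/") %in% names(kds))
      paste(p[1], p[2], sep = "/") else paste(p[2], p[1], sep = "/")
    want <- c(p[1], p[2], ab)
    if (!all(want %in% names(kds))) {
      skipped[paste(p, collapse = "/")] <-
        paste("missing genotype(s):",
              paste(setdiff(want, names(kds)), collapse = ", "))
      next
    }
    cr <- coupling_coefficient(kds[["WT"]], kds[[p[1]]], kds[[p[2]]],
                               kds[[ab]], pair = p, v = v,
                               additive_band = additive_band)
    rows[[length(rows) + 1L]] <-
      data.frame(mut_a = p[1], mut_b = p[2], double = ab,
                 omega = cr$omega, verdict = cr$verdict,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no pair could be analysed")
  out <- do.call(rbind, rows)
  out <- out[order(out$omega), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

.synergy_groups <- function(exp, v) {
  d <- exp$design
  idx <- function(gr) which(d$group == gr & d$test_mv == v)
  got <- lapply(c(control = "control", a = "A", b = "B", ab = "AB"), idx)
  miss <- names(got)[vapply(got, length, 0L) == 0L]
  if (length(miss))
    stop("design error: missing group(s) at this voltage: ",
         paste(miss, collapse = ", "))
  lapply(got, function(i) exp$sweeps[[i[1]]])
}

#' Steady-state synergy of two coexisting blockers
#'
#' Compares the relative current with both blockers present against two
#' null models built from the single-blocker relative currents at the same
#' voltage:
#'
#' * independence null (independent sites): `f_pred = f_a * f_b`;
#' * competition null (mutually exclusive binding):
#'   `f_pred = 1 / (1 + (1/f_a - 1) + (1/f_b - 1))`.
#'
#' True synergy — e.g. one blocker occluding the other's outward escape
#' path — drives `f_both` below both nulls; the flag is set only in that
#' case, beyond the propagated measurement error. Errors on the steady-
#' state currents are taken as `noise_sd / sqrt(n_averaged)` and propagated
#' to the ratios by the delta method.
#'
#' @param exp A `kir_experiment` from [design_synergy()] (groups `control`,
#'   `A`, `B`, `AB` at the voltage analysed).
#' @param v Test voltage (mV).
#' @param segment Segment index of the test pulse.
#' @param tail_fraction Averaging window for steady-state currents.
#' @return A `synergy_result` with `f_a`, `f_b`, `f_both`, the two
#'   predictions, their propagated SEs, and `flags$steady_state_synergy`.
#' @export
synergy_steady_state <- function(exp, v, segment = 3L, tail_fraction = 0.1) {
  sw <- .synergy_groups(exp, v)
  f_of <- function(x) relative_current(x, sw$control, segment, tail_fraction)
  ra <- f_of(sw$a); rb <- f_of(sw$b); rab <- f_of(sw$ab)
  # SE of a tail-averaged current, then delta-method SE of each ratio
  se_i <- function(x) {
    n <- max(1L, floor(length(segment_samples(x, segment)) * tail_fraction))
    x$meta$noise_sd / sqrt(n)
  }
  se_f <- function(r, x) abs(r$f) * sqrt((se_i(x) / r$i_test)^2 +
                                           (se_i(sw$control) / r$i_control)^2)
  se_a <- se_f(ra, sw$a); se_b <- se_f(rb, sw$b); se_ab <- se_f(rab, sw$ab)
  pred_ind <- ra$f * rb$f
  se_ind <- pred_ind * sqrt((se_a / ra$f)^2 + (se_b / rb$f)^2)
  pred_comp <- 1 / (1 + (1 / ra$f - 1) + (1 / rb$f - 1))
  margin <- 2 * sqrt(se_ab^2 + se_ind^2) + 1e-6 * pred_ind
  flag <- (rab$f < pred_ind - margin) && (rab$f < pred_comp - margin)
  structure(list(v = v, f_a = ra$f, f_b = rb$f, f_both = rab$f,
                 f_pred_independent = pred_ind,
                 f_pred_competition = pred_comp,
                 se = c(f_a = se_a, f_b = se_b, f_both = se_ab,
                        pred_independent = se_ind),
                 flags = list(steady_state_synergy = flag)),
            class = "synergy_result")
}

#' Kinetic additivity of two coexisting blockers
#'
#' Fits the onset (decay of outward current) of each single-blocker group
#' and of the both-blockers group at one voltage, converts to macroscopic
#' rates `1/tau`, and tests rate additivity:
#' `rate_both ~ rate_a + rate_b` within a stated tolerance (default 20%).
#' For parallel entry into two blocked states the initial decay rate of the
#' open probability is exactly `kon_A [A] + kon_B [B]`, so additivity holds
#' whenever unbinding contributes little over the fitted window.
#'
#' @inheritParams synergy_steady_state
#' @param tolerance Relative tolerance of the additivity flag.
#' @param blank_ms Blank passed to [fit_relaxation()].
#' @return A `synergy_result` with `rate_a`, `rate_b`, `rate_both` (s^-1),
#'   `rate_pred_additive` and `flags$kinetic_additivity`.
#' @export
synergy_kinetics <- function(exp, v, segment = 3L, tolerance = 0.2,
                             blank_ms = NULL) {
  sw <- .synergy_groups(exp, v)
  rate_of <- function(x) {
    fit <- fit_relaxation(x, segment, n_components = 1, blank_ms = blank_ms)
    # a segment without a resolvable decay (e.g. no blocker) has rate 0
    floor_amp <- max(3 * x$meta$noise_sd, 1e-8 * max(abs(x$current)))
    if (abs(fit$amplitudes[1]) < floor_amp) return(0)
    1000 / fit$taus[1]
  }
  rate_a <- rate_of(sw$a); rate_b <- rate_of(sw$b); rate_both <- rate_of(sw$ab)
  pred <- rate_a + rate_b
  flag <- abs(rate_both - pred) / pred < tolerance
  structure(list(v = v, rate_a = rate_a, rate_b = rate_b,
                 rate_both = rate_both, rate_pred_additive = pred,
                 tolerance = tolerance,
                 flags = list(kinetic_additivity = flag)),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> V = %g mV\n", x$v))
  if (!is.null(x$f_both))
    cat(sprintf("  f: A %.4g, B %.4g, both %.4g (pred indep %.4g, compet %.4g)\n",
                x$f_a, x$f_b, x$f_both, x$f_pred_independent,
                x$f_pred_competition))
  if (!is.null(x$rate_both))
    cat(sprintf("  rates (s^-1): A %.4g, B %.4g, both %.4g (additive pred %.4g)\n",
                x$rate_a, x$rate_b, x$rate_both, x$rate_pred_additive))
  for (nm in names(x$flags))
    cat(sprintf("  flag %s: %s\n", nm, x$flags[[nm]]))
  invisible(x)
}
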