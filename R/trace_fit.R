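#' Steady-state current of a protocol segment
#'
#' Mean current over the final `tail_fraction` of the segment, the package's
#' operational definition of the steady-state amplitude. The segment should
#' be several relaxation time constants long for this to be unbiased.
#'
#' @param sweep A `kir_sweep`.
#' @param segment Segment index.
#' @param tail_fraction Fraction of the segment averaged (default last 10%).
#' @return Steady-state current (pA).
#' @export
steady_state_current <- function(sweep, segment, tail_fraction = 0.1) {
  idx <- segment_samples(sweep, segment)
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must be in (0, 1]")
  k <- max(1L, floor(length(idx) * tail_fraction))
  mean(sweep$current[idx[(length(idx) - k + 1L):length(idx)]])
}

#' Relative (residual) current of a test sweep versus its control
#'
#' The ratio of steady-state current amplitudes in the presence and absence
#' of blocker at the same voltage — the `f` that enters the Hill dose-
#' response fit. Sweeps must share the same protocol. A control current
#' indistinguishable from zero (|I| below 5 recording-noise SDs) makes the
#' ratio undefined and raises an error.
#'
#' @param test,control `kir_sweep`s with matching protocols.
#' @param segment Segment index at which to compare.
#' @param tail_fraction Passed to [steady_state_current()].
#' @return A list (`relative_current` record): `v` (mV), `conc` (M, named by
#'   blocker, test-sweep concentrations), `f`, `i_test`, `i_control`.
#' @export
relative_current <- function(test, control, segment, tail_fraction = 0.1) {
  stopifnot(inherits(test, "kir_sweep"), inherits(control, "kir_sweep"))
  if (!protocols_equal(test$meta$protocol, control$meta$protocol))
    stop("test and control sweeps have different protocols")
  i_t <- steady_state_current(test, segment, tail_fraction)
  i_c <- steady_state_current(control, segment, tail_fraction)
  thr <- 5 * control$meta$noise_sd
  if (abs(i_c) <= max(thr, .Machine$double.eps))
    stop("control current is indistinguishable from zero; relative current undefined")
  v <- test$meta$protocol$segments$level_mv[segment]
  list(v = v, conc = test$meta$condition$blockers, f = i_t / i_c,
       i_test = i_t, i_control = i_c)
}

# variable-projection residual: for fixed taus, solve baseline+amplitudes by
# least squares and return the fit pieces
.vp_fit <- function(t, y, taus) {
  x <- cbind(1, vapply(taus, function(tau) exp(-t / tau), numeric(length(t))))
  fit <- stats::lm.fit(x, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0   # aliased component (e.g. tau >> window): no amplitude
  list(coef = cf, rss = sum(fit$residuals^2))
}

#' Fit exponential relaxations to a sweep segment
#'
#' Nonlinear least squares of
#' `I(t) = baseline + sum(a_i * exp(-(t - t0) / tau_i))` over one protocol
#' segment, skipping an initial blank (default 10 sample intervals, i.e.
#' 1 ms at the standard 10 kHz) that excludes the settling instant and any
#' very fast occupancy redistribution at the voltage step. Initialization is a deterministic multistart: a log-spaced
#' grid of time constants spanning (5 samples, half the window) scored by
#' variable projection (amplitudes and baseline solved linearly), with the
#' best start polished by Levenberg-Marquardt in log-tau. `n_components =
#' "auto"` chooses 1 vs 2 exponentials by BIC.
#'
#' @param sweep A `kir_sweep`.
#' @param segment Segment index.
#' @param n_components 1, 2 or `"auto"`.
#' @param blank_ms Initial blank skipped at the segment start (ms).
#' @return A `kir_expfit`: `n_components`, `taus` (ms, increasing),
#'   `amplitudes` (pA), `baseline` (pA), `rss` (pA^2), `window` (ms),
#'   `bic`, `converged`.
#' @export
fit_relaxation <- function(sweep, segment, n_components = "auto",
                           blank_ms = NULL) {
  idx <- segment_samples(sweep, segment)
  dt_samp <- sweep$meta$protocol$sample_interval
  if (is.null(blank_ms)) blank_ms <- 10 * dt_samp
  g_start <- sweep$time[idx[1]]
  # integer sample arithmetic: binary round-off in the time grid must not
  # shift the window boundary by a sample between sweeps
  rel <- round((sweep$time[idx] - g_start) / dt_samp)
  keep <- rel >= blank_ms / dt_samp - 1e-9
  idx <- idx[keep]
  if (length(idx) < 20L)
    stop("need at least 20 samples in the fit window")
  t <- sweep$time[idx] - sweep$time[idx[1]]
  y <- sweep$current[idx]
  span <- max(t)
  dt <- sweep$meta$protocol$sample_interval
  lo <- 5 * dt
  hi <- span / 2
  if (lo >= hi) lo <- hi / 10
  grid1 <- exp(seq(log(lo), log(hi), length.out = 25))
  fits <- list()
  for (k in if (identical(n_components, "auto")) 1:2 else as.integer(n_components)) {
    if (k == 1L) {
      cand <- lapply(grid1, function(tau) c(tau))
    } else {
      g2 <- exp(seq(log(lo), log(hi), length.out = 10))
      cand <- list()
      for (a in 1:(length(g2) - 1)) for (b in (a + 1):length(g2))
        cand[[length(cand) + 1L]] <- c(g2[a], g2[b])
    }
    scores <- vapply(cand, function(taus) .vp_fit(t, y, taus)$rss, 0)
    best <- cand[[which.min(scores)]]
    vp <- .vp_fit(t, y, best)
    start <- list(ltau = log(best), a = unname(vp$coef[-1]),
                  b = unname(vp$coef[1]))
    fit <- tryCatch({
      df <- data.frame(t = t, y = y)
      if (k == 1L) {
        m <- minpack.lm::nlsLM(y ~ b + a1 * exp(-t / exp(l1)),
                               data = df,
                               start = list(b = start$b, a1 = start$a[1],
                                            l1 = start$ltau[1]),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(m)
        list(taus = exp(cf["l1"]), amps = cf["a1"], base = cf["b"],
             rss = sum(stats::residuals(m)^2), converged = TRUE)
      } else {
        m <- minpack.lm::nlsLM(y ~ b + a1 * exp(-t / exp(l1)) +
                                 a2 * exp(-t / exp(l2)),
                               data = df,
                               start = list(b = start$b, a1 = start$a[1],
                                            a2 = start$a[2],
                                            l1 = start$ltau[1],
                                            l2 = start$ltau[2]),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(m)
        list(taus = exp(c(cf["l1"], cf["l2"])), amps = c(cf["a1"], cf["a2"]),
             base = cf["b"], rss = sum(stats::residuals(m)^2),
             converged = TRUE)
      }
    }, error = function(e) {
      # fall back to the best multistart grid point (exact for degenerate
      # windows, e.g. zero-amplitude segments)
      list(taus = best, amps = vp$coef[-1], base = vp$coef[1], rss = vp$rss,
           converged = FALSE)
    })
    n <- length(y)
    fit$bic <- n * log(max(fit$rss, 1e-300) / n) + (2 * k + 1) * log(n)
    fit$k <- k
    fits[[length(fits) + 1L]] <- fit
  }
  pick <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  ord <- order(pick$taus)
  structure(list(n_components = pick$k, taus = unname(pick$taus[ord]),
                 amplitudes = unname(pick$amps[ord]),
                 baseline = unname(pick$base), rss = pick$rss,
                 window = c(sweep$time[idx[1]], sweep$time[idx[length(idx)]]),
                 bic = pick$bic, converged = pick$converged),
            class = "kir_expfit")
}

#' @export
print.kir_expfit <- function(x, ...) {
  cat(sprintf("<kir_expfit> %d component(s): tau = %s ms, a = %s pA, baseline = %.4g pA, rss = %.4g\n",
              x$n_components, paste(signif(x$taus, 5), collapse = ", "),
              paste(signif(x$amplitudes, 4), collapse = ", "), x$baseline,
              x$rss))
  invisible(x)
}

# slow-tail amplitude relative to its own steady state (pA, >= 0)
.tail_amplitude <- function(sweep, segment, blank_ms = NULL) {
  fit <- fit_relaxation(sweep, segment, n_components = 1, blank_ms = blank_ms)
  abs(fit$amplitudes[1])
}

#' Blocking/unblocking kinetics from a two-pulse experiment
#'
#' Extracts the three time constants of the two-pulse analysis:
#'
#' * `tau_on1` (ms): single-exponential growth of the slow-tail amplitude
#'   with the length of the preceding depolarization — the course of blocker
#'   binding at the depolarized voltage. Requires >= 3 distinct
#'   depolarization lengths (else an insufficient-design error, or `NA`
#'   with `require_growth = FALSE`).
#' * `tau_on2` (ms): decay of the outward current during the depolarizing
#'   pulse itself, fitted per sweep.
#' * `tau_off` (ms): decay of the slow tail at each tail voltage, the
#'   unblocking relaxation; reported per (voltage, concentration) cell.
#'
#' For a two-state scheme `tau_on1` and `tau_on2` are analytically equal
#' (both are `1/(kon + koff)` at the depolarized voltage), and `tau_off`
#' does not depend on depolarization length.
#'
#' @param exp A `kir_experiment` containing two-pulse sweeps.
#' @param genotype Restrict to one genotype (default: all, analysed jointly —
#'   pass one genotype per call for per-genotype tables).
#' @param blank_ms Blank passed to [fit_relaxation()].
#' @param require_growth If TRUE, error when fewer than 3 depolarization
#'   lengths are present; if FALSE, `tau_on1` is `NA` in that case.
#' @return A list: `growth` (data.frame `depol_ms`, `amplitude`),
#'   `tau_on1_ms`, `on2` (data.frame `depol_ms`, `conc`, `tau_on2_ms`),
#'   `off` (data.frame `v`, `conc`, `tau_off_ms`, `rate_s` = 1000/tau).
#' @export
tail_kinetics <- function(exp, genotype = NULL, blank_ms = NULL,
                          require_growth = TRUE) {
  stopifnot(inherits(exp, "kir_experiment"))
  keep <- exp$design$protocol == "two_pulse"
  if (!is.null(genotype)) keep <- keep & exp$design$genotype == genotype
  ids <- design_blockers(exp$design)
  conc_total <- rowSums(as.matrix(exp$design[paste0("conc.", ids)]))
  keep <- keep & conc_total > 0
  ex <- filter_experiment(exp, keep)
  if (!length(ex$sweeps)) stop("no two-pulse sweeps with blocker present")
  d <- ex$design
  conc <- rowSums(as.matrix(d[paste0("conc.", ids)]))
  depol_seg <- 3L
  tail_seg <- 4L

  lens <- sort(unique(d$depol_ms))
  growth <- NULL
  tau_on1 <- NA_real_
  if (length(lens) >= 3L) {
    vmode <- d$test_mv[which.max(tabulate(match(d$test_mv, unique(d$test_mv))))]
    gi <- which(d$test_mv == vmode)
    amp <- vapply(gi, function(i)
      .tail_amplitude(ex$sweeps[[i]], tail_seg, blank_ms), 0)
    growth <- data.frame(depol_ms = d$depol_ms[gi], amplitude = amp)
    growth <- growth[order(growth$depol_ms), ]
    fit <- minpack.lm::nlsLM(amplitude ~ ainf * (1 - exp(-depol_ms / exp(ltau))),
                             data = growth,
                             start = list(ainf = max(growth$amplitude),
                                          ltau = log(stats::median(growth$depol_ms))))
    tau_on1 <- exp(stats::coef(fit)[["ltau"]])
  } else if (require_growth) {
    stop("insufficient design: need >= 3 distinct depolarization lengths for tau_on1")
  }

  on2 <- do.call(rbind, lapply(seq_along(ex$sweeps), function(i) {
    f <- fit_relaxation(ex$sweeps[[i]], depol_seg, n_components = 1,
                        blank_ms = blank_ms)
    data.frame(depol_ms = d$depol_ms[i], conc = conc[i],
               tau_on2_ms = f$taus[1])
  }))
  off <- do.call(rbind, lapply(seq_along(ex$sweeps), function(i) {
    f <- fit_relaxation(ex$sweeps[[i]], tail_seg, n_components = 1,
                        blank_ms = blank_ms)
    data.frame(v = d$test_mv[i], conc = conc[i], depol_ms = d$depol_ms[i],
               tau_off_ms = f$taus[1], rate_s = 1000 / f$taus[1])
  }))
  list(growth = growth, tau_on1_ms = tau_on1, on2 = on2, off = off)
}
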