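#' One-to-one Hill dose-response
#'
#' Relative current left by a blocker binding one-to-one:
#' `f = 1 / (1 + conc / kd)`. The Hill coefficient is fixed at 1 throughout
#' the pipeline (the binding reaction is one-to-one); [fit_hill()] exposes a
#' free-slope option only as an off-pipeline diagnostic.
#'
#' @param conc Blocker concentration (M), vectorized.
#' @param kd Apparent dissociation constant (M).
#' @return Relative current in (0, 1].
#' @export
hill_relative_current <- function(conc, kd) {
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(conc < 0)) stop("conc must be >= 0")
  1 / (1 + conc / kd)
}

#' Hill fit of relative current versus concentration at one voltage
#'
#' Least-squares estimate of the apparent Kd from `(conc, f)` pairs at a
#' single voltage, fitted in log-Kd space with unweighted residuals on `f`.
#' The standard error is propagated from the Jacobian (delta method from
#' log-Kd). At least 3 concentrations are required; a dose series that does
#' not bracket `f = 0.5` triggers a warning, and a series with essentially
#' no block (all `f` near 1) or complete block (all `f` near 0) is
#' unidentifiable and raises an error.
#'
#' @param points Data frame with columns `conc` (M) and `f`, or a list of
#'   [relative_current()] records.
#' @param v Voltage label (mV) stored in the result (optional).
#' @param free_slope If TRUE, also fit a free Hill slope (diagnostic only).
#' @return A `hill_fit`: list with `v`, `kd` (M), `stderr` (M), `n_points`,
#'   `slope` (1 unless `free_slope`), `rss`.
#' @export
fit_hill <- function(points, v = NA_real_, free_slope = FALSE) {
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, function(p) is.list(p) && !is.null(p$f), TRUE))) {
    v <- points[[1]]$v
    points <- data.frame(conc = vapply(points, function(p) sum(p$conc), 0),
                         f = vapply(points, `[[`, 0, "f"))
  }
  stopifnot(is.data.frame(points), all(c("conc", "f") %in% names(points)))
  points <- points[is.finite(points$conc) & is.finite(points$f), ]
  if (nrow(points) < 3L) stop("need at least 3 concentrations for a Hill fit")
  nz <- points[points$conc > 0, ]
  if (all(nz$f > 0.95) || all(nz$f < 0.05))
    stop("Kd unidentifiable: dose series shows essentially no (or complete) block")
  if (min(nz$f) > 0.5 || max(nz$f) < 0.5)
    warning("dose series does not bracket f = 0.5; Kd is an extrapolation")
  # start from the one-to-one linearization 1/f - 1 = conc/kd
  mid <- nz[nz$f > 0.02 & nz$f < 0.98, ]
  kd0 <- if (nrow(mid)) exp(mean(log(mid$conc / (1 / mid$f - 1)))) else
    stats::median(nz$conc)
  if (free_slope) {
    fit <- minpack.lm::nlsLM(f ~ 1 / (1 + (conc / exp(lkd))^h), data = points,
                             start = list(lkd = log(kd0), h = 1))
  } else {
    fit <- minpack.lm::nlsLM(f ~ 1 / (1 + conc / exp(lkd)), data = points,
                             start = list(lkd = log(kd0)))
  }
  cf <- summary(fit)$coefficients
  kd <- exp(cf["lkd", "Estimate"])
  structure(list(v = v, kd = kd, stderr = kd * cf["lkd", "Std. Error"],
                 n_points = nrow(points),
                 slope = if (free_slope) cf["h", "Estimate"] else 1,
                 rss = sum(stats::residuals(fit)^2)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> V = %g mV: Kd = %.4g M (SE %.2g), n = %d\n",
              x$v, x$kd, x$stderr, x$n_points))
  invisible(x)
}

#' Kd-voltage curve from a dose-series experiment
#'
#' Runs [relative_current()] and [fit_hill()] at every test voltage of a
#' dose-by-voltage experiment. Voltages are restricted to the window where
#' the one-to-one fit is meaningful: by default more positive than -60 mV
#' in symmetric K+, or more positive than -100 mV with 20 mM external /
#' 100 mM internal K+. Voltages whose control current is indistinguishable
#' from zero (near the reversal potential) or whose fit fails are skipped
#' and reported with reasons.
#'
#' @param exp A `kir_experiment` from a dose-by-voltage design with a
#'   control (zero blocker) group.
#' @param segment Segment index of the test pulse (default 3, the step
#'   protocol's test segment).
#' @param v_min,v_max Analysis window (mV); `NULL` applies the default rule.
#' @return A `kd_curve`: data.frame `entries` (`v`, `kd`, `stderr`,
#'   `n_points`) ordered by voltage, plus `skipped` (named character vector
#'   of reasons), `genotype`, `k_in`, `k_out`.
#' @export
kd_curve <- function(exp, segment = 3L, v_min = NULL, v_max = NULL) {
  stopifnot(inherits(exp, "kir_experiment"))
  d <- exp$design
  ids <- design_blockers(d)
  conc <- rowSums(as.matrix(d[paste0("conc.", ids)]))
  if (is.null(v_min))
    v_min <- if (isTRUE(all.equal(d$k_in[1], d$k_out[1]))) -60 else -100
  if (is.null(v_max)) v_max <- Inf
  voltages <- sort(unique(d$test_mv))
  entries <- list()
  skipped <- character(0)
  for (v in voltages) {
    if (v < v_min || v > v_max) {
      skipped[as.character(v)] <- "outside analysis voltage window"
      next
    }
    ctrl_i <- which(d$test_mv == v & conc == 0)
    dose_i <- which(d$test_mv == v & conc > 0)
    if (!length(ctrl_i) || length(dose_i) < 3L) {
      skipped[as.character(v)] <- "needs a control sweep and >= 3 doses"
      next
    }
    res <- tryCatch({
      pts <- lapply(dose_i, function(i)
        relative_current(exp$sweeps[[i]], exp$sweeps[[ctrl_i[1]]], segment))
      suppressWarnings(fit_hill(pts, v = v))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[as.character(v)] <- conditionMessage(res)
    } else {
      entries[[length(entries) + 1L]] <-
        data.frame(v = v, kd = res$kd, stderr = res$stderr,
                   n_points = res$n_points)
    }
  }
  if (!length(entries)) stop("no voltage admitted a Hill fit")
  structure(list(entries = do.call(rbind, entries), skipped = skipped,
                 genotype = d$genotype[1], k_in = d$k_in[1],
                 k_out = d$k_out[1]),
            class = "kd_curve")
}

#' @export
print.kd_curve <- function(x, ...) {
  cat(sprintf("<kd_curve> %s, K+ %g out / %g in mM, %d voltages (%d skipped)\n",
              x$genotype, x$k_out, x$k_in, nrow(x$entries), length(x$skipped)))
  print(transform(x$entries, kd = signif(kd, 4), stderr = signif(stderr, 2)))
  invisible(x)
}

# log Kd at voltage v, log-linearly interpolated when v is between grid
# points; errors outside the curve's range
.log_kd_at <- function(curve, v) {
  e <- curve$entries
  if (v < min(e$v) || v > max(e$v))
    stop(sprintf("voltage %g mV outside the fitted Kd curve range [%g, %g]",
                 v, min(e$v), max(e$v)))
  stats::approx(e$v, log(e$kd), xout = v)$y
}

#' Inward-rectification index of a Kd-voltage curve
#'
#' `Kd(-30 mV) / Kd(+30 mV)`, the scalar measure of how steeply block
#' depends on voltage/flux around the reversal potential. If either voltage
#' is not a grid point, log-Kd is linearly interpolated between neighbours
#' and the result carries `interpolated = TRUE` as an attribute.
#'
#' @param curve A [kd_curve()] result.
#' @return The IR index (dimensionless).
#' @export
ir_index <- function(curve) {
  stopifnot(inherits(curve, "kd_curve"))
  exact <- all(c(-30, 30) %in% curve$entries$v)
  out <- exp(.log_kd_at(curve, -30) - .log_kd_at(curve, 30))
  attr(out, "interpolated") <- !exact
  out
}

#' Voltage shift between two Kd-voltage curves
#'
#' The displacement `delta` (mV) minimizing the summed squared difference of
#' log Kd between `curve_a(v)` and `curve_b(v - delta)` over their
#' overlapping voltage support, found by a golden-section search refined
#' from a 0.1 mV grid scan over the bracket. A curve identical to the other
#' but displaced by -20 mV returns -20.
#'
#' @param curve_a,curve_b [kd_curve()] results.
#' @param bracket Search bracket for the shift (mV).
#' @return The shift (mV), negative when `curve_b` is displaced toward
#'   negative voltages relative to `curve_a`.
#' @export
kd_shift <- function(curve_a, curve_b, bracket = c(-60, 60)) {
  stopifnot(inherits(curve_a, "kd_curve"), inherits(curve_b, "kd_curve"))
  ea <- curve_a$entries; eb <- curve_b$entries
  obj <- function(delta) {
    vv <- ea$v[ea$v + delta >= min(eb$v) & ea$v + delta <= max(eb$v)]
    if (length(vv) < 3L) return(NA_real_)
    lb <- stats::approx(eb$v, log(eb$kd), xout = vv + delta)$y
    la <- stats::approx(ea$v, log(ea$kd), xout = vv)$y
    sum((la - lb)^2) / length(vv)
  }
  grid <- seq(bracket[1], bracket[2], by = 0.1)
  vals <- vapply(grid, obj, 0)
  if (all(is.na(vals))) stop("no voltage overlap between curves within the bracket")
  best <- grid[which.min(vals)]
  lo <- max(bracket[1], best - 0.2); hi <- min(bracket[2], best + 0.2)
  ref <- stats::optimize(function(d) { v <- obj(d); if (is.na(v)) Inf else v },
                         lower = lo, upper = hi, tol = 1e-8)
  ref$minimum
}
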