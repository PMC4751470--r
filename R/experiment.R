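#' Factorial designs for synthetic block experiments
#'
#' Design constructors return a data.frame with one row per sweep. Columns:
#' `genotype`, `k_in`, `k_out` (mM), one `conc.<blocker>` column per blocker
#' (M), `protocol` (`"step"` or `"two_pulse"`), `test_mv`, `depol_ms`
#' (two-pulse only, NA otherwise) and `group` (condition label).
#'
#' * `design_dose_voltage()`: a blocker dose series crossed with a family of
#'   test voltages (the step protocol) — the design behind per-voltage Hill
#'   fits and Kd-voltage curves.
#' * `design_woodhull()`: two-pulse sweeps with a fixed depolarization and a
#'   family of negative tail voltages, optionally crossed with several
#'   blocker concentrations; feeds tail-decay (off-rate) analysis.
#' * `design_tail_growth()`: two-pulse sweeps with variable depolarization
#'   length at a fixed tail voltage; feeds the slow-tail development
#'   (on-rate) analysis.
#' * `design_synergy()`: the four-group two-blocker comparison
#'   (control / A alone / B alone / both) across test voltages.
#'
#' @param doses Blocker concentrations (M); include 0 for the control group.
#' @param test_mv Test (or tail) voltage levels, mV.
#' @param blocker Blocker id the dose series applies to.
#' @param genotype Genotype preset name(s).
#' @param k_in,k_out K+ concentrations, mM.
#' @param conc Fixed blocker concentration (M) for two-pulse designs.
#' @param depol_ms Depolarization length(s), ms.
#' @param conc_a,conc_b Concentrations (M) of the two blockers in
#'   `design_synergy()`.
#' @param blocker_a,blocker_b Blocker ids for `design_synergy()`.
#' @return A design data.frame.
#' @name designs
NULL

#' @rdname designs
#' @export
design_dose_voltage <- function(doses = c(0, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3),
                                test_mv = seq(-150, 100, 10),
                                blocker = "Mg", genotype = "WT",
                                k_in = 100, k_out = 100) {
  d <- expand.grid(conc = doses, test_mv = test_mv, genotype = genotype,
                   stringsAsFactors = FALSE)
  out <- data.frame(genotype = d$genotype, k_in = k_in, k_out = k_out,
                    protocol = "step", test_mv = d$test_mv, depol_ms = NA_real_,
                    group = ifelse(d$conc == 0, "control", "dose"),
                    stringsAsFactors = FALSE)
  out[[paste0("conc.", blocker)]] <- d$conc
  out
}

#' @rdname designs
#' @param test_ms Tail/test segment duration (ms).
#' @param sample_interval Sampling interval (ms). The off-rate (Woodhull)
#'   design defaults to 0.005 ms (200 kHz) with short pulses: unblocking
#'   relaxations of fast genotypes are in the tens of microseconds at
#'   -100 mV and must be digitized accordingly.
#' @param n_replicates Independent sweeps per design cell (separate noise
#'   realizations, as separate patches would give); downstream rate fits
#'   pool them.
#' @export
design_woodhull <- function(conc = 1e-4, test_mv = seq(-100, -20, 20),
                            depol_ms = 10, blocker = "Mg", genotype = "WT",
                            k_in = 100, k_out = 100, test_ms = 10,
                            sample_interval = 0.005, n_replicates = 1) {
  d <- expand.grid(conc = conc, test_mv = test_mv, genotype = genotype,
                   replicate = seq_len(n_replicates),
                   stringsAsFactors = FALSE)
  out <- data.frame(genotype = d$genotype, k_in = k_in, k_out = k_out,
                    protocol = "two_pulse", test_mv = d$test_mv,
                    depol_ms = depol_ms, test_ms = test_ms,
                    sample_interval = sample_interval,
                    group = ifelse(d$conc == 0, "control", "dose"),
                    stringsAsFactors = FALSE)
  out[[paste0("conc.", blocker)]] <- d$conc
  out
}

#' @rdname designs
#' @export
design_tail_growth <- function(conc = 1e-4,
                               depol_ms = c(2, 5, 10, 20, 40, 80),
                               test_mv = -100, blocker = "Mg",
                               genotype = "WT", k_in = 100, k_out = 100) {
  d <- expand.grid(conc = conc, depol_ms = depol_ms, genotype = genotype,
                   stringsAsFactors = FALSE)
  out <- data.frame(genotype = d$genotype, k_in = k_in, k_out = k_out,
                    protocol = "two_pulse", test_mv = test_mv,
                    depol_ms = d$depol_ms,
                    group = ifelse(d$conc == 0, "control", "dose"),
                    stringsAsFactors = FALSE)
  out[[paste0("conc.", blocker)]] <- d$conc
  out
}

#' @rdname designs
#' @export
design_synergy <- function(conc_a = 1e-3, conc_b = 1e-5,
                           blocker_a = "Mg", blocker_b = "SPM",
                           test_mv = 100, genotype = "WT",
                           k_in = 100, k_out = 100) {
  groups <- c("control", "A", "B", "AB")
  d <- expand.grid(group = groups, test_mv = test_mv,
                   stringsAsFactors = FALSE)
  out <- data.frame(genotype = genotype, k_in = k_in, k_out = k_out,
                    protocol = "step", test_mv = d$test_mv,
                    depol_ms = NA_real_, group = d$group,
                    stringsAsFactors = FALSE)
  out[[paste0("conc.", blocker_a)]] <-
    ifelse(d$group %in% c("A", "AB"), conc_a, 0)
  out[[paste0("conc.", blocker_b)]] <-
    ifelse(d$group %in% c("B", "AB"), conc_b, 0)
  out
}

design_blockers <- function(design) {
  sub("^conc\\.", "", grep("^conc\\.", names(design), value = TRUE))
}

#' Generate a complete synthetic experiment
#'
#' Expands a design table (one row per sweep) into simulated sweeps. The
#' state model for each sweep contains every blocker column of the design
#' (zero concentrations included), so all sweeps of an experiment share one
#' state space. Reproducible: per-sweep seeds are derived from the master
#' seed by stable enumeration order.
#'
#' @param design A design data.frame (see [designs]).
#' @param seed Master integer seed.
#' @param presets Preset list from [kir_presets()].
#' @param n_channels,permeability,noise_sd Passed to [simulate_sweep()].
#' @return A `kir_experiment`: list with `sweeps` (list of `kir_sweep`) and
#'   `design` (the input table with a `seed` column added).
#' @examples
#' ex <- generate_experiment(design_synergy(test_mv = 100), seed = 1,
#'                           noise_sd = 0)
#' @export
generate_experiment <- function(design, seed = 1L, presets = kir_presets(),
                                n_channels = 100, permeability = 0.05,
                                noise_sd = 5) {
  if (!is.data.frame(design) || nrow(design) == 0L) stop("empty design")
  need <- c("genotype", "k_in", "k_out", "protocol", "test_mv")
  if (!all(need %in% names(design)))
    stop("design lacks required columns: ",
         paste(setdiff(need, names(design)), collapse = ", "))
  ids <- design_blockers(design)
  if (!length(ids)) stop("design has no conc.<blocker> column")
  unknown <- setdiff(ids, names(presets$blockers))
  if (length(unknown))
    stop("no preset for blocker(s): ", paste(unknown, collapse = ", "))
  design$seed <- as.integer((as.numeric(seed) + 7919 * seq_len(nrow(design))) %%
                              .Machine$integer.max)
  sweeps <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    conc <- vapply(ids, function(b) row[[paste0("conc.", b)]], 0)
    cond <- solution_condition(row$k_in, row$k_out, blockers = conc)
    model <- state_model(unname(presets$blockers[ids]))
    dt <- if (!is.null(row$sample_interval) && is.finite(row$sample_interval))
      row$sample_interval else 0.1
    test_ms <- if (!is.null(row$test_ms) && is.finite(row$test_ms))
      row$test_ms else NULL
    protocol <- if (row$protocol == "two_pulse")
      make_protocol("two_pulse", test_mv = row$test_mv,
                    depol_ms = row$depol_ms, sample_interval = dt,
                    test_ms = if (is.null(test_ms)) 300 else test_ms)
    else make_protocol("step", test_mv = row$test_mv, sample_interval = dt,
                       test_ms = if (is.null(test_ms)) 150 else test_ms)
    gspec <- presets$genotypes[[row$genotype]]
    if (is.null(gspec))
      stop(sprintf("no genotype preset named '%s'", row$genotype))
    sweeps[[i]] <- simulate_sweep(model, protocol, cond,
                                  genotype = gspec,
                                  n_channels = n_channels,
                                  permeability = permeability,
                                  noise_sd = noise_sd, seed = design$seed[i])
  }
  structure(list(sweeps = sweeps, design = design), class = "kir_experiment")
}

#' @export
print.kir_experiment <- function(x, ...) {
  cat(sprintf("<kir_experiment> %d sweeps; genotypes: %s\n",
              length(x$sweeps),
              paste(unique(x$design$genotype), collapse = ", ")))
  invisible(x)
}

#' Subset an experiment by design predicate
#'
#' @param exp A `kir_experiment`.
#' @param keep Logical vector over design rows.
#' @return A `kir_experiment` with the selected sweeps.
#' @export
filter_experiment <- function(exp, keep) {
  stopifnot(inherits(exp, "kir_experiment"), length(keep) == nrow(exp$design))
  keep[is.na(keep)] <- FALSE
  structure(list(sweeps = exp$sweeps[keep],
                 design = exp$design[keep, , drop = FALSE]),
            class = "kir_experiment")
}
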