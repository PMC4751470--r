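#' Voltage-clamp protocol presets
#'
#' Builds piecewise-constant command-voltage protocols. Two presets are
#' provided, mirroring the standard designs for studying intracellular
#' block of inward rectifiers:
#'
#' * `"step"`: hold at 0 mV, repolarize to -100 mV for 20 ms, then step to a
#'   test pulse for 150 ms. `"step_family"` expands this over a family of
#'   test levels (-150 to +100 mV in 10 mV increments by default) and
#'   returns a list of protocols.
#' * `"two_pulse"`: hold at 0 mV, pre-pulse to -100 mV, depolarize to
#'   +100 mV for a variable length, then step to a negative tail voltage.
#'   The growth of the slow tail with depolarization length and the tail
#'   decay report the blocking and unblocking courses respectively.
#'
#' Segment durations must be positive multiples of the sample interval so
#' that segment boundaries land exactly on sample points.
#'
#' @param preset `"step"`, `"step_family"` or `"two_pulse"`.
#' @param test_mv Test-pulse level(s), mV.
#' @param test_ms Test-pulse duration, ms (default 150 for the step preset,
#'   300 for the two-pulse preset).
#' @param hold_ms Initial holding-segment duration at `hold_mv`, ms.
#' @param hold_mv Holding level, mV.
#' @param pre_mv,pre_ms Pre-pulse level (mV) and duration (ms).
#' @param depol_mv,depol_ms Depolarizing-pulse level (mV) and duration (ms),
#'   two-pulse preset only.
#' @param sample_interval Sampling interval, ms (0.1 ms = 10 kHz).
#' @return A `voltage_protocol` (or a list of them for `"step_family"`):
#'   list with `name`, `segments` (data.frame `level_mv`, `duration_ms`) and
#'   `sample_interval`.
#' @examples
#' make_protocol("step", test_mv = 100)
#' length(make_protocol("step_family"))  # 26
#' @export
make_protocol <- function(preset = c("step", "step_family", "two_pulse"),
                          test_mv = 100, test_ms = NULL,
                          hold_ms = 5, hold_mv = 0,
                          pre_mv = -100, pre_ms = 20,
                          depol_mv = 100, depol_ms = 50,
                          sample_interval = 0.1) {
  preset <- match.arg(preset)
  if (preset == "step_family") {
    if (length(test_mv) == 1L && test_mv == 100) test_mv <- seq(-150, 100, 10)
    return(lapply(test_mv, function(v)
      make_protocol("step", test_mv = v, test_ms = test_ms, hold_ms = hold_ms,
                    hold_mv = hold_mv, pre_mv = pre_mv, pre_ms = pre_ms,
                    sample_interval = sample_interval)))
  }
  stopifnot(length(test_mv) == 1L)
  if (is.null(test_ms)) test_ms <- if (preset == "two_pulse") 300 else 150
  seg <- switch(preset,
    step = data.frame(level_mv = c(hold_mv, pre_mv, test_mv),
                      duration_ms = c(hold_ms, pre_ms, test_ms)),
    two_pulse = data.frame(level_mv = c(hold_mv, pre_mv, depol_mv, test_mv),
                           duration_ms = c(hold_ms, pre_ms, depol_ms, test_ms)))
  new_protocol(preset, seg, sample_interval)
}

new_protocol <- function(name, segments, sample_interval) {
  stopifnot(is.data.frame(segments),
            all(c("level_mv", "duration_ms") %in% names(segments)))
  if (any(segments$duration_ms <= 0)) stop("segment durations must be > 0")
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (sample_interval > min(segments$duration_ms))
    stop("sample_interval must not exceed the shortest segment")
  mult <- segments$duration_ms / sample_interval
  if (any(abs(mult - round(mult)) > 1e-9))
    stop("segment durations must be integer multiples of sample_interval")
  structure(list(name = name,
                 segments = segments[c("level_mv", "duration_ms")],
                 sample_interval = sample_interval),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s, %d segments, dt = %g ms\n",
              x$name, nrow(x$segments), x$sample_interval))
  print(x$segments)
  invisible(x)
}

protocols_equal <- function(a, b) {
  identical(a$name, b$name) &&
    isTRUE(all.equal(a$segments, b$segments, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$sample_interval, b$sample_interval))
}

# time grid (ms, starting at 0) and the segment each sample belongs to;
# a boundary sample takes the incoming segment's voltage
protocol_grid <- function(protocol) {
  dt <- protocol$sample_interval
  dur <- protocol$segments$duration_ms
  total <- sum(dur)
  n <- round(total / dt)
  time <- dt * (0:n)
  starts <- cumsum(c(0, dur))
  seg <- findInterval(time, starts, left.open = FALSE)
  seg[seg > nrow(protocol$segments)] <- nrow(protocol$segments)
  list(time = time, segment = seg, starts = starts)
}

#' Indices of a sweep's samples within one protocol segment
#'
#' @param sweep A `kir_sweep`.
#' @param segment Segment index (1-based, into the protocol's segment table).
#' @return Integer vector of sample indices.
#' @export
segment_samples <- function(sweep, segment) {
  protocol <- sweep$meta$protocol
  if (segment < 1L || segment > nrow(protocol$segments))
    stop("segment index out of range")
  g <- protocol_grid(protocol)
  which(g$segment == segment)
}

#' Simulate one voltage-clamp sweep
#'
#' Composes the kinetic model's relaxation solutions segment by segment:
#' the occupancy starts at the stationary distribution of the first
#' (holding) segment and propagates continuously across segment boundaries.
#' The recorded current is
#' `I(t) = N * P_open(t) * i_open(V_segment) + Gaussian noise`, with the
#' open-channel current from the GHK relation. Identical arguments and seed
#' give a bit-identical sweep.
#'
#' @param model A [state_model()].
#' @param protocol A [make_protocol()] result.
#' @param cond A [solution_condition()].
#' @param genotype A [genotype_spec()], a preset genotype name, or `NULL`
#'   (wild type); applied to the model's blocker parameters.
#' @param n_channels Number of channels in the patch.
#' @param permeability Open-channel current scale (see
#'   [open_channel_current()]).
#' @param noise_sd Additive Gaussian recording-noise SD (pA); 0 for
#'   noise-free sweeps.
#' @param seed Integer seed for the noise draw.
#' @return A `kir_sweep`: list with `time` (ms), `current` (pA), `voltage`
#'   (mV) and `meta`.
#' @export
simulate_sweep <- function(model, protocol, cond, genotype = NULL,
                           n_channels = 100, permeability = 0.05,
                           noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "state_model"),
            inherits(protocol, "voltage_protocol"),
            inherits(cond, "solution_condition"))
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  gname <- "WT"
  if (!is.null(genotype)) {
    if (is.character(genotype)) {
      gname <- genotype
      genotype <- kir_presets()$genotypes[[genotype]]
      if (is.null(genotype)) stop(sprintf("unknown genotype preset '%s'", gname))
    } else gname <- genotype$name
    model$blockers <- lapply(model$blockers, apply_genotype, genotype = genotype)
  }
  g <- protocol_grid(protocol)
  nseg <- nrow(protocol$segments)
  voltage <- protocol$segments$level_mv[g$segment]
  p_open <- numeric(length(g$time))
  p_cur <- steady_state(model, protocol$segments$level_mv[1], cond)
  for (s in seq_len(nseg)) {
    idx <- which(g$segment == s)
    v_s <- protocol$segments$level_mv[s]
    local_t <- g$time[idx] - g$starts[s]
    dur <- protocol$segments$duration_ms[s]
    occ <- relax_occupancy(model, v_s, cond, p_cur, c(local_t, dur))
    p_open[idx] <- occ[seq_along(idx), "O"]
    p_cur <- occ[length(local_t) + 1L, ]
    p_cur[p_cur < 0] <- 0
    p_cur <- p_cur / sum(p_cur)
  }
  i_open <- open_channel_current(voltage, cond, permeability)
  current <- n_channels * p_open * i_open
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    current <- current + stats::rnorm(length(current), 0, noise_sd)
  }
  structure(list(time = g$time, current = current, voltage = voltage,
                 meta = list(protocol = protocol, genotype = gname,
                             condition = cond, n_channels = n_channels,
                             permeability = permeability,
                             noise_sd = noise_sd, seed = as.integer(seed))),
            class = "kir_sweep")
}

#' @export
print.kir_sweep <- function(x, ...) {
  cat(sprintf("<kir_sweep> %s, %s, %d samples (%g ms), noise_sd = %g pA\n",
              x$meta$protocol$name, x$meta$genotype, length(x$time),
              max(x$time), x$meta$noise_sd))
  invisible(x)
}
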