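# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the master equation is integrated by brute
# force with explicit micro-steps, and ensembles are simulated channel by
# channel with the Gillespie algorithm.

# explicit micro-step integration of dp/dt = p Q with a 1 microsecond step
# (classical Runge-Kutta so the step truncation error stays below the
# 1e-6 comparison tolerance even at 1e4 /s rates)
euler_relax <- function(q, p0, t_end_s, dt = 1e-6) {
  p <- matrix(p0, 1)
  steps <- round(t_end_s / dt)
  for (i in seq_len(steps)) {
    k1 <- p %*% q
    k2 <- (p + dt / 2 * k1) %*% q
    k3 <- (p + dt / 2 * k2) %*% q
    k4 <- (p + dt * k3) %*% q
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(p)
}

# state occupancy at t_end_s of n independent channels starting from state
# `start`, by vectorized Gillespie jumps
gillespie_occupancy <- function(q, start, t_end_s, n = 1e5, seed = 1) {
  set.seed(seed)
  ns <- nrow(q)
  s <- rep(as.integer(start), n)
  t <- numeric(n)
  alive <- rep(TRUE, n)
  exit_rate <- -diag(q)
  while (any(alive)) {
    i <- which(alive)
    r <- exit_rate[s[i]]
    zero <- r <= 0
    if (any(zero)) { alive[i[zero]] <- FALSE; i <- i[!zero]; r <- r[!zero] }
    if (!length(i)) break
    dt <- stats::rexp(length(i), r)
    done <- t[i] + dt > t_end_s
    alive[i[done]] <- FALSE
    j <- i[!done]
    if (!length(j)) break
    t[j] <- t[j] + dt[!done]
    # jump: sample destination per current state
    for (st in unique(s[j])) {
      k <- j[s[j] == st]
      w <- q[st, ]; w[st] <- 0
      s[k] <- sample.int(ns, length(k), replace = TRUE, prob = w)
    }
  }
  tabulate(s, nbins = ns) / n
}

# a plain two-state blocker with no flux coupling or punch-through
simple_blocker <- function(id = "Mg", kon0 = 5e6, koff0 = 4300,
                           delta_on = 0.08, zdelta_off = 0.48, z = 2) {
  blocker_spec(id, z = z, kon0 = kon0, delta_on = delta_on, koff0 = koff0,
               zdelta_off = zdelta_off, theta = 0)
}

# wrap custom blockers/genotypes in the preset-list shape that
# generate_experiment() expects
custom_presets <- function(blockers, genotypes = list(WT = genotype_spec("WT"))) {
  if (inherits(blockers, "blocker_spec")) blockers <- list(blockers)
  names(blockers) <- vapply(blockers, `[[`, "", "id")
  list(version = "test", blockers = blockers, genotypes = genotypes)
}
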