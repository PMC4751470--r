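#' Continuous-time state model of a blocked channel pore
#'
#' Builds the Markov scheme for a channel pore blocked by one or two
#' intracellular blockers. With a single blocker the states are
#' `{O, B}` (open/conducting, blocked); with two blockers `{O, A, B, AB}`
#' where `AB` is the doubly-occupied pore reached by either binding order.
#' Only `O` conducts. Punch-through (outward escape through the selectivity
#' filter) is allowed from a singly-blocked state if the blocker's
#' `kexit0 > 0`, but never from the doubly-occupied state: a resident second
#' blocker occludes the outward exit path. Unbinding rates from `AB` inherit
#' each blocker's singly-bound rates.
#'
#' @param blockers A [blocker_spec()] or list of one or two of them.
#' @return An object of class `state_model` with fields `blockers`, `states`
#'   and `conducting`.
#' @examples
#' p <- kir_presets()
#' m <- state_model(p$blockers$Mg)
#' m2 <- state_model(list(p$blockers$Mg, p$blockers$SPM))
#' @export
state_model <- function(blockers) {
  if (inherits(blockers, "blocker_spec")) blockers <- list(blockers)
  if (!is.list(blockers) || !length(blockers) %in% 1:2 ||
      !all(vapply(blockers, inherits, TRUE, "blocker_spec")))
    stop("blockers must be one or two blocker_spec objects")
  ids <- vapply(blockers, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("blocker ids must be distinct")
  names(blockers) <- ids
  states <- c("O", ids)
  if (length(ids) == 2L) states <- c(states, paste(ids, collapse = "+"))
  structure(list(blockers = blockers, states = states,
                 conducting = states == "O"),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> states:", paste(x$states, collapse = ", "),
      "(conducting: O)\n")
  invisible(x)
}

#' Voltage- and flux-dependent transition rates
#'
#' `rate_on()` is the pseudo-first-order blocking rate
#' `kon0 * [B] * exp(z * delta_on * V / vt)` (s^-1). `rate_off()` is the
#' unbinding rate to the intracellular side,
#' `koff0 * exp(-zdelta_off * V / vt) * exp(-theta * (1 + tanh((V - E_K)/vs)))`:
#' a Woodhull factor times a flux-coupling factor that saturates at 1 under
#' preponderant inward K+ flux (where off rates are actually measured) and at
#' `exp(-2*theta)` under preponderant outward flux, which sweeps the blocker
#' to the outer end of the flux-coupling segment and hinders its return.
#' `rate_exit()` is the punch-through rate `kexit0 * exp(zdelta_exit * V / vt)`.
#'
#' @param b A [blocker_spec()].
#' @param v Membrane voltage (mV), vectorized.
#' @param cond A [solution_condition()]; must contain an entry for `b$id` in
#'   its `blockers` for `rate_on()`.
#' @return Rate (s^-1), same length as `v`.
#' @export
rate_on <- function(b, v, cond) {
  stopifnot(inherits(b, "blocker_spec"), inherits(cond, "solution_condition"))
  if (!b$id %in% names(cond$blockers))
    stop(sprintf("condition has no concentration for blocker '%s'", b$id))
  conc <- cond$blockers[[b$id]]
  b$kon0 * conc * exp(b$z * b$delta_on * v / cond$vt)
}

#' @rdname rate_on
#' @export
rate_off <- function(b, v, cond) {
  stopifnot(inherits(b, "blocker_spec"), inherits(cond, "solution_condition"))
  ek <- nernst_potential(cond)
  flux <- exp(-b$theta * (1 + tanh((v - ek) / b$vs)))
  b$koff0 * exp(-b$zdelta_off * v / cond$vt) * flux
}

#' @rdname rate_on
#' @export
rate_exit <- function(b, v, cond) {
  stopifnot(inherits(b, "blocker_spec"), inherits(cond, "solution_condition"))
  b$kexit0 * exp(b$zdelta_exit * v / cond$vt)
}

#' Infinitesimal generator of the blocking scheme
#'
#' Assembles the rate matrix (s^-1) of the state model at a given voltage
#' and solution. Rows sum to zero; off-diagonal entries are non-negative.
#' Rows/columns are named by state.
#'
#' @param model A [state_model()].
#' @param v Membrane voltage (mV), scalar.
#' @param cond A [solution_condition()] carrying a concentration for every
#'   blocker in the model.
#' @return A square generator matrix.
#' @export
build_generator <- function(model, v, cond) {
  stopifnot(inherits(model, "state_model"), length(v) == 1L)
  ids <- names(model$blockers)
  missing_ids <- setdiff(ids, names(cond$blockers))
  if (length(missing_ids))
    stop(sprintf("condition lacks concentrations for blocker(s): %s",
                 paste(missing_ids, collapse = ", ")))
  n <- length(model$states)
  q <- matrix(0, n, n, dimnames = list(model$states, model$states))
  for (id in ids) {
    b <- model$blockers[[id]]
    q["O", id] <- rate_on(b, v, cond)
    q[id, "O"] <- rate_off(b, v, cond) + rate_exit(b, v, cond)
  }
  if (length(ids) == 2L) {
    ab <- model$states[4]
    for (k in 1:2) {
      resident <- ids[k]; joining <- ids[3 - k]
      bj <- model$blockers[[joining]]
      q[resident, ab] <- rate_on(bj, v, cond)
      # no punch-through from the doubly-occupied pore
      q[ab, resident] <- rate_off(bj, v, cond)
    }
  }
  diag(q) <- -rowSums(q)
  q
}

#' Stationary occupancy of the blocking scheme
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`. For the two-state scheme this equals
#' `koff_total / (kon + koff_total)` for the open state.
#'
#' @inheritParams build_generator
#' @return Named occupancy vector summing to 1.
#' @export
steady_state <- function(model, v, cond) {
  q <- build_generator(model, v, cond)
  n <- nrow(q)
  a <- rbind(t(q), rep(1, n))
  dec <- qr(a)
  if (dec$rank < n)
    stop("generator is reducible on the active state set; stationary distribution not unique")
  p <- qr.solve(dec, c(rep(0, n), 1))
  if (any(p < -1e-8)) stop("stationary solve produced negative occupancy")
  p[p < 0] <- 0
  p <- p / sum(p)
  names(p) <- model$states
  p
}

#' Closed-form apparent dissociation constant
#'
#' The blocker concentration at which the stationary open probability is
#' one half. For the schemes supported (single blocker with optional
#' punch-through) this is `(rate_off(V) + rate_exit(V)) / k_on(V)` with
#' `k_on(V) = kon0 * exp(z * delta_on * V / vt)` the second-order on-rate
#' constant. Defined per blocker, so only single-blocker models are
#' accepted.
#'
#' @param model A single-blocker [state_model()].
#' @param v Membrane voltage (mV), vectorized.
#' @param cond A [solution_condition()] giving the K+ conditions (the
#'   blocker concentration it carries is irrelevant).
#' @return Apparent Kd (M), same length as `v`.
#' @export
apparent_kd <- function(model, v, cond) {
  stopifnot(inherits(model, "state_model"))
  if (length(model$blockers) != 1L)
    stop("apparent Kd is defined per blocker; use a single-blocker model")
  b <- model$blockers[[1]]
  kon_const <- b$kon0 * exp(b$z * b$delta_on * v / cond$vt)
  (rate_off(b, v, cond) + rate_exit(b, v, cond)) / kon_const
}

#' Relaxation of state occupancies
#'
#' Solves the master equation `dp/dt = p Q` from an initial occupancy over a
#' time grid, by eigendecomposition of the generator (with a matrix-
#' exponential fallback for near-defective generators). Times are in ms;
#' rates are per second internally.
#'
#' @param model A [state_model()].
#' @param v Membrane voltage (mV), scalar.
#' @param cond A [solution_condition()].
#' @param p0 Initial occupancy vector (sums to 1, length = number of states).
#' @param t_ms Numeric vector of times (ms) at which to evaluate.
#' @return Matrix `length(t_ms)` x n_states of occupancies, columns named by
#'   state.
#' @export
relax_occupancy <- function(model, v, cond, p0, t_ms) {
  stopifnot(inherits(model, "state_model"))
  n <- length(model$states)
  if (length(p0) != n) stop("p0 has wrong length for this model")
  if (any(p0 < -1e-12)) stop("p0 must be non-negative")
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  q <- build_generator(model, v, cond)
  t_s <- t_ms / 1000
  p <- .propagate_occupancy(q, p0, t_s)
  colnames(p) <- model$states
  p
}

# p0 row vector propagated through exp(Q t) for each t (seconds)
.propagate_occupancy <- function(q, p0, t_s) {
  n <- nrow(q)
  eg <- eigen(q)
  v <- eg$vectors
  vi <- tryCatch(solve(v), error = function(e) NULL)
  if (!is.null(vi)) {
    w <- as.vector(matrix(p0, 1) %*% v)           # coefficients in eigenbasis
    e <- exp(outer(t_s, eg$values))               # T x n
    p <- Re((e * matrix(w, nrow(e), n, byrow = TRUE)) %*% vi)
  } else {
    # defective generator: step with a matrix exponential on the sorted grid
    ord <- order(t_s)
    ts <- t_s[ord]
    p <- matrix(NA_real_, length(t_s), n)
    cur <- matrix(p0, 1)
    last <- 0
    for (k in seq_along(ts)) {
      dt <- ts[k] - last
      if (dt > 0) cur <- cur %*% as.matrix(Matrix::expm(q * dt))
      p[ord[k], ] <- cur
      last <- ts[k]
    }
  }
  # clip eigen round-off
  p[p < 0 & p > -1e-10] <- 0
  p
}
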