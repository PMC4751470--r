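#' Recording solution condition
#'
#' Bundles the K+ concentrations on either side of the membrane, the free
#' intracellular blocker concentrations, and the thermal voltage used in all
#' exponential rate laws. Potassium is in mM (the unit solutions are made up
#' in); blocker concentrations are in molar.
#'
#' @param k_in Intracellular K+ concentration (mM).
#' @param k_out Extracellular K+ concentration (mM).
#' @param blockers Named numeric vector of free blocker concentrations (M),
#'   e.g. `c(Mg = 1e-4)` or `c(Mg = 1e-3, SPM = 1e-5)`. Zero entries are
#'   allowed and denote a blocker tracked by the state model but absent from
#'   the bath (control solutions).
#' @param vt Thermal voltage (mV). Fixed by convention at 25 mV, the value
#'   used in every printed exponential rate equation in this field, rather
#'   than RT/F at room temperature (25.7 mV).
#'
#' @return An object of class `solution_condition`.
#' @examples
#' cond <- solution_condition(k_in = 100, k_out = 20, blockers = c(Mg = 1e-4))
#' nernst_potential(cond)  # about -40 mV
#' @export
solution_condition <- function(k_in = 100, k_out = 100,
                               blockers = c(Mg = 0), vt = 25) {
  if (!is.numeric(k_in) || length(k_in) != 1L || !is.finite(k_in) || k_in <= 0)
    stop("k_in must be a single positive concentration (mM)")
  if (!is.numeric(k_out) || length(k_out) != 1L || !is.finite(k_out) || k_out <= 0)
    stop("k_out must be a single positive concentration (mM)")
  if (!is.numeric(vt) || length(vt) != 1L || vt <= 0)
    stop("vt must be a single positive voltage (mV)")
  blockers <- unlist(blockers)
  if (length(blockers) > 0) {
    if (is.null(names(blockers)) || any(!nzchar(names(blockers))))
      stop("blockers must be a named vector (blocker id -> concentration in M)")
    if (any(!is.finite(blockers)) || any(blockers < 0))
      stop("blocker concentrations must be finite and >= 0")
  }
  structure(list(k_in = k_in, k_out = k_out,
                 blockers = blockers, vt = vt),
            class = "solution_condition")
}

#' @export
print.solution_condition <- function(x, ...) {
  cat(sprintf("<solution_condition> K+ %g out / %g in mM, vt = %g mV, E_K = %.1f mV\n",
              x$k_out, x$k_in, x$vt, nernst_potential(x)))
  if (length(x$blockers))
    cat("  blockers (M):",
        paste(sprintf("%s = %g", names(x$blockers), x$blockers), collapse = ", "),
        "\n")
  invisible(x)
}

#' Potassium reversal potential
#'
#' Nernst potential for K+, `vt * log(k_out / k_in)`, in mV. With the 25 mV
#' thermal-voltage convention, 20 mM external / 100 mM internal K+ gives
#' about -40 mV.
#'
#' @param cond A [solution_condition()].
#' @return Reversal potential (mV).
#' @export
nernst_potential <- function(cond) {
  stopifnot(inherits(cond, "solution_condition"))
  cond$vt * log(cond$k_out / cond$k_in)
}

#' Open-channel unitary current (GHK)
#'
#' Goldman-Hodgkin-Katz constant-field current for a monovalent cation,
#' giving synthetic sweeps the realistic inward/outward asymmetry of K+
#' currents under asymmetric K+. Sign convention: inward current negative,
#' outward positive. `permeability` is a lumped scale chosen so that typical
#' macro-patch amplitudes (nA with hundreds of channels) come out; it has no
#' mechanistic meaning here.
#'
#' @param v Membrane voltage (mV), vectorized.
#' @param cond A [solution_condition()].
#' @param permeability Positive current scale (pA per mM at unit reduced
#'   voltage).
#' @return Unitary current (pA), same length as `v`.
#' @export
open_channel_current <- function(v, cond, permeability = 0.05) {
  stopifnot(inherits(cond, "solution_condition"))
  if (!is.numeric(permeability) || length(permeability) != 1L || permeability <= 0)
    stop("permeability must be a single positive number")
  u <- v / cond$vt
  i <- numeric(length(u))
  small <- abs(u) < 1e-6
  # GHK: I = P u (k_in - k_out e^{-u}) / (1 - e^{-u}); u -> 0 limit P (k_in - k_out)
  i[!small] <- permeability * u[!small] *
    (cond$k_in - cond$k_out * exp(-u[!small])) / (1 - exp(-u[!small]))
  i[small] <- permeability * (cond$k_in - cond$k_out)
  i
}
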