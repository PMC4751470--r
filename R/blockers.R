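#' Kinetic parameters of a pore blocker
#'
#' Per-blocker rate-law parameters. Binding follows a Woodhull-type law,
#' `kon0 * [B] * exp(z * delta_on * V / vt)`; unbinding to the intracellular
#' side is `koff0 * exp(-zdelta_off * V / vt)` times a flux-coupling factor
#' (see [rate_off()]); `kexit0`/`zdelta_exit` describe punch-through, the
#' outward escape of a long blocker such as spermine through the selectivity
#' filter at strong depolarization (always zero for Mg2+, which cannot
#' traverse the filter).
#'
#' Conventions: `delta_on` is the electrical distance of the entry barrier
#' (reported as delta, with the valence `z` stated alongside); the exit
#' voltage dependence is reported as the product `zdelta_off` (Z times
#' delta), matching how such fits are printed.
#'
#' @param id Blocker label, e.g. `"Mg"` or `"SPM"`.
#' @param z Effective valence (integer 1-4; 2 for Mg2+, 4 for spermine).
#' @param kon0 Second-order blocking rate constant at 0 mV (M^-1 s^-1).
#' @param delta_on Electrical distance of the entry barrier (dimensionless).
#' @param koff0 Unbinding rate at 0 mV (s^-1), in the inward-flux reference
#'   state of the flux-coupling factor.
#' @param zdelta_off Z*delta of unbinding (dimensionless).
#' @param theta Flux-coupling strength (dimensionless, >= 0). 0 disables
#'   flux coupling.
#' @param vs Flux-coupling saturation scale (mV).
#' @param kexit0 Punch-through rate at 0 mV (s^-1); must be 0 for `id = "Mg"`.
#' @param zdelta_exit Voltage sensitivity of punch-through (dimensionless).
#'
#' @return An object of class `blocker_spec`.
#' @examples
#' mg <- blocker_spec("Mg", z = 2, kon0 = 5e6, delta_on = 0.08,
#'                    koff0 = 4300, zdelta_off = 0.48, theta = 1.5)
#' @export
blocker_spec <- function(id, z, kon0, delta_on, koff0, zdelta_off,
                         theta = 0, vs = 4, kexit0 = 0, zdelta_exit = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!(z %in% 1:4)) stop("z must be an integer valence in 1..4")
  if (kon0 <= 0) stop("kon0 must be > 0")
  if (koff0 <= 0) stop("koff0 must be > 0")
  if (kexit0 < 0) stop("kexit0 must be >= 0")
  if (identical(id, "Mg") && kexit0 != 0)
    stop("Mg2+ cannot punch through the selectivity filter: kexit0 must be 0")
  if (theta < 0) stop("theta must be >= 0")
  if (vs <= 0) stop("vs must be > 0")
  structure(list(id = id, z = as.integer(z), kon0 = kon0, delta_on = delta_on,
                 koff0 = koff0, zdelta_off = zdelta_off, theta = theta,
                 vs = vs, kexit0 = kexit0, zdelta_exit = zdelta_exit),
            class = "blocker_spec")
}

#' @export
print.blocker_spec <- function(x, ...) {
  cat(sprintf("<blocker_spec> %s: z=%d kon0=%.3g M-1s-1 (delta_on=%.3g) koff0=%.4g s-1 (Zdelta_off=%.3g) theta=%.4g vs=%g kexit0=%.3g (zdelta_exit=%.3g)\n",
              x$id, x$z, x$kon0, x$delta_on, x$koff0, x$zdelta_off,
              x$theta, x$vs, x$kexit0, x$zdelta_exit))
  invisible(x)
}

#' Genotype as multiplicative parameter overrides
#'
#' A genotype (wild type or mutant) is encoded purely as positive scale
#' factors applied to [blocker_spec()] fields: mutations that raise or lower
#' the entry/exit barrier scale `kon0`/`koff0`, mutations that abolish flux
#' coupling scale `theta` toward zero, and the voltage dependence itself can
#' be rescaled via `zdelta_off`. No structural modelling is implied.
#'
#' @param name Genotype label (`"WT"`, `"E224G"`, ...).
#' @param multipliers Named numeric vector of positive scale factors keyed as
#'   `"<blocker id>.<parameter>"` (e.g. `"Mg.koff0"`) or `"<parameter>"` to
#'   apply to every blocker. Empty for WT.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, multipliers = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  multipliers <- unlist(multipliers)
  if (length(multipliers)) {
    if (is.null(names(multipliers)) || any(!nzchar(names(multipliers))))
      stop("multipliers must be named")
    if (any(!is.finite(multipliers)) || any(multipliers <= 0))
      stop("all genotype multipliers must be positive and finite")
  }
  structure(list(name = name, multipliers = multipliers),
            class = "genotype_spec")
}

#' Apply genotype multipliers to a blocker's kinetic parameters
#'
#' @param blocker A [blocker_spec()].
#' @param genotype A [genotype_spec()], a genotype name resolved against the
#'   shipped presets, or `NULL` (returned unchanged).
#' @return A `blocker_spec` with scaled parameters.
#' @export
apply_genotype <- function(blocker, genotype) {
  stopifnot(inherits(blocker, "blocker_spec"))
  if (is.null(genotype)) return(blocker)
  if (is.character(genotype)) genotype <- kir_presets()$genotypes[[genotype]]
  if (is.null(genotype) || !inherits(genotype, "genotype_spec"))
    stop("unknown genotype")
  m <- genotype$multipliers
  scalable <- c("kon0", "delta_on", "koff0", "zdelta_off", "theta", "vs",
                "kexit0", "zdelta_exit")
  for (key in names(m)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      if (parts[1] != blocker$id) next
      field <- parts[2]
    } else field <- key
    if (!field %in% scalable)
      stop(sprintf("genotype multiplier targets unknown parameter '%s'", key))
    blocker[[field]] <- blocker[[field]] * m[[key]]
  }
  blocker
}

.preset_cache <- new.env(parent = emptyenv())

#' Shipped blocker and genotype presets
#'
#' Loads the versioned preset file distributed with the package (or a user
#' file in the same JSON schema). Blocker presets carry the calibrated
#' default kinetics of intracellular Mg2+ and spermine on the wild-type
#' channel; genotype presets encode mutants of the cytoplasmic pore (E224,
#' E299) and the bundle-crossing region (I176-M183) as parameter
#' multipliers, including double mutants built either additively or with a
#' negative-cooperative interaction factor.
#'
#' @param file Path to a preset JSON file; default: the file shipped in
#'   `inst/extdata`.
#' @return A list with elements `version`, `blockers` (named list of
#'   [blocker_spec()]) and `genotypes` (named list of [genotype_spec()]).
#' @export
kir_presets <- function(file = NULL) {
  default <- is.null(file)
  if (default) {
    if (!is.null(.preset_cache$default)) return(.preset_cache$default)
    file <- system.file("extdata", "kir_presets.json", package = "kirblock")
  }
  if (!nzchar(file) || !file.exists(file)) stop("preset file not found")
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  blockers <- lapply(raw$blockers, function(b) do.call(blocker_spec, b))
  names(blockers) <- vapply(blockers, `[[`, "", "id")
  genotypes <- lapply(raw$genotypes, function(g)
    genotype_spec(g$name, unlist(g$multipliers)))
  names(genotypes) <- vapply(genotypes, `[[`, "", "name")
  out <- list(version = raw$version, blockers = blockers, genotypes = genotypes)
  if (default) .preset_cache$default <- out
  out
}
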