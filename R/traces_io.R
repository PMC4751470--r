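#' Write / read an experiment as plain-text trace files
#'
#' `write_traces()` lays an experiment out as one CSV per sweep (columns
#' `time_ms`, `voltage_mV`, `current_pA`, full double precision), one JSON
#' sidecar per sweep with the complete metadata, and a directory-level
#' `manifest.json` listing the files and the design table. `read_traces()`
#' reconstructs the experiment; the round trip is floating-point exact.
#' Missing sidecars, wrong CSV columns, and manifest/sweep inconsistencies
#' raise errors naming the offending file.
#'
#' @param exp A `kir_experiment`.
#' @param directory Target/source directory.
#' @return `write_traces()`: the directory, invisibly. `read_traces()`: a
#'   `kir_experiment`.
#' @export
write_traces <- function(exp, directory) {
  stopifnot(inherits(exp, "kir_experiment"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- length(exp$sweeps)
  files <- sprintf("sweep_%04d", seq_len(n))
  for (i in seq_len(n)) {
    sw <- exp$sweeps[[i]]
    csv <- file.path(directory, paste0(files[i], ".csv"))
    lines <- c("time_ms,voltage_mV,current_pA",
               sprintf("%.17g,%.17g,%.17g", sw$time, sw$voltage, sw$current))
    writeLines(lines, csv)
    meta <- sw$meta
    sidecar <- list(
      protocol = list(name = meta$protocol$name,
                      segments = meta$protocol$segments,
                      sample_interval = meta$protocol$sample_interval),
      genotype = meta$genotype,
      condition = list(k_in = meta$condition$k_in,
                       k_out = meta$condition$k_out,
                       blockers = as.list(meta$condition$blockers),
                       vt = meta$condition$vt),
      n_channels = meta$n_channels, permeability = meta$permeability,
      noise_sd = meta$noise_sd, seed = meta$seed)
    jsonlite::write_json(sidecar, file.path(directory, paste0(files[i], ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(format = "kirblock-traces", version = "1.0",
                   n_sweeps = n, files = files, design = exp$design)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(directory)
}

#' @rdname write_traces
#' @export
read_traces <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "kirblock-traces"))
    stop("not a kirblock trace directory: ", mf)
  design <- as.data.frame(manifest$design, stringsAsFactors = FALSE)
  # an all-NA numeric column (e.g. depol_ms in a step-only design) comes
  # back from JSON as logical; restore its numeric type
  for (col in names(design))
    if (is.logical(design[[col]]) && all(is.na(design[[col]])))
      design[[col]] <- as.numeric(design[[col]])
  files <- manifest$files
  if (length(files) != manifest$n_sweeps || nrow(design) != manifest$n_sweeps)
    stop("manifest is inconsistent (n_sweeps vs files/design): ", mf)
  sweeps <- vector("list", length(files))
  for (i in seq_along(files)) {
    csv <- file.path(directory, paste0(files[i], ".csv"))
    sidecar <- file.path(directory, paste0(files[i], ".json"))
    if (!file.exists(csv)) stop("trace file listed in manifest is absent: ", csv)
    if (!file.exists(sidecar)) stop("metadata sidecar is absent: ", sidecar)
    tab <- utils::read.csv(csv, colClasses = "numeric")
    if (!identical(names(tab), c("time_ms", "voltage_mV", "current_pA")))
      stop("unexpected columns in ", csv)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    protocol <- new_protocol(meta$protocol$name,
                             as.data.frame(meta$protocol$segments),
                             meta$protocol$sample_interval)
    g <- protocol_grid(protocol)
    if (length(g$time) != nrow(tab))
      stop("trace length does not match its protocol (truncated file?): ", csv)
    cond <- solution_condition(meta$condition$k_in, meta$condition$k_out,
                               blockers = unlist(meta$condition$blockers),
                               vt = meta$condition$vt)
    sweeps[[i]] <- structure(
      list(time = tab$time_ms, current = tab$current_pA,
           voltage = tab$voltage_mV,
           meta = list(protocol = protocol, genotype = meta$genotype,
                       condition = cond, n_channels = meta$n_channels,
                       permeability = meta$permeability,
                       noise_sd = meta$noise_sd,
                       seed = as.integer(meta$seed))),
      class = "kir_sweep")
  }
  structure(list(sweeps = sweeps, design = design), class = "kir_experiment")
}
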