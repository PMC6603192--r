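#' Write a trace bundle to disk
#'
#' Two self-contained plain-text dialects are provided.  `"bundle-csv"`
#' writes a directory with `meta.csv` (key/value), `sweeps.csv` (one row of
#' protocol metadata per sweep) and `samples.csv` (long-format voltage
#' samples); `"bundle-json"` writes a single JSON file.  Both serialize
#' voltages with 17 significant digits so that a write/read round trip is
#' bit-exact.
#'
#' @param bundle a [trace_bundle()]
#' @param path output directory (`bundle-csv`) or file (`bundle-json`)
#' @param dialect `"bundle-csv"` or `"bundle-json"`
#' @return `path`, invisibly
#' @export
write_trace_bundle <- function(bundle, path,
                               dialect = c("bundle-csv", "bundle-json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(bundle, "trace_bundle"))
  if (dialect == "bundle-json") {
    jsonlite::write_json(bundle_to_list(bundle), path, digits = I(17),
                         auto_unbox = TRUE, null = "null", na = "null")
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- c(cell_id = bundle$cell_id,
            access_resistance_MOhm = fmt17(bundle$access_resistance_MOhm))
  if (!is.null(bundle$meta))
    meta <- c(meta, group = bundle$meta$group,
              subregion = bundle$meta$subregion, layer = bundle$meta$layer,
              x_um = fmt17(bundle$meta$x_um), y_um = fmt17(bundle$meta$y_um))
  write.csv(data.frame(key = names(meta), value = unname(meta)),
            file.path(path, "meta.csv"), row.names = FALSE)

  fams <- bundle_families(bundle)
  sw <- do.call(rbind, lapply(names(fams), function(fam) {
    sweeps <- fams[[fam]]
    if (length(sweeps) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(sweeps), function(i) {
      p <- sweeps[[i]]$protocol
      data.frame(family = fam, sweep_index = i,
                 amplitude_pA = p$amplitude_pA, onset_ms = p$onset_ms,
                 duration_ms = p$duration_ms, inter_sweep_s = p$inter_sweep_s,
                 rate_kHz = sweeps[[i]]$sampling_rate_kHz)
    }))
  }))
  write.csv(sw, file.path(path, "sweeps.csv"), row.names = FALSE)

  con <- file(file.path(path, "samples.csv"), "w")
  on.exit(close(con))
  writeLines("family,sweep_index,v_mV", con)
  for (fam in names(fams)) {
    sweeps <- fams[[fam]]
    for (i in seq_along(sweeps)) {
      writeLines(paste0(fam, ",", i, ",",
                        fmt17(sweeps[[i]]$samples_mV)), con)
    }
  }
  invisible(path)
}

#' Read a trace bundle
#'
#' Reads one of the native plain-text dialects back into a validated
#' [trace_bundle()].  The `"bundle-h5"`, `"abf"` and `"nwb"` dialects are
#' optional adapters whose backing packages (an HDF5 binding, an
#' Axon-binary or NWB reader) are not installed here; requesting them
#' raises an informative error rather than a crash, per the adapter
#' contract.
#'
#' @param path directory (`bundle-csv`) or file (`bundle-json`)
#' @param dialect one of `"bundle-csv"`, `"bundle-json"`, `"bundle-h5"`,
#'   `"abf"`, `"nwb"`
#' @return a [trace_bundle()]
#' @export
read_trace_bundle <- function(path, dialect = c("bundle-csv", "bundle-json",
                                                "bundle-h5", "abf", "nwb")) {
  dialect <- match.arg(dialect)
  if (dialect %in% c("bundle-h5", "abf", "nwb"))
    stop("dialect '", dialect, "' requires an optional reader package (",
         switch(dialect, "bundle-h5" = "an HDF5 binding such as 'hdf5r'",
                abf = "an ABF reader", nwb = "an NWB reader"),
         ") that is not installed; convert to 'bundle-csv' or ",
         "'bundle-json' instead", call. = FALSE)
  if (!file.exists(path))
    stop("no such file or directory: ", path, call. = FALSE)

  if (dialect == "bundle-json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(bundle_from_list(x))
  }

  need <- file.path(path, c("meta.csv", "sweeps.csv", "samples.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("malformed bundle-csv: missing ", paste(basename(missing),
         collapse = ", "), call. = FALSE)
  meta <- read.csv(file.path(path, "meta.csv"), colClasses = "character")
  kv <- setNames(meta$value, meta$key)
  sw <- read.csv(file.path(path, "sweeps.csv"))
  smp <- read.csv(file.path(path, "samples.csv"))
  for (col in c("family", "sweep_index", "amplitude_pA", "duration_ms"))
    if (!col %in% names(sw))
      stop("malformed sweeps.csv: missing column '", col, "'", call. = FALSE)

  get_family <- function(fam) {
    rows <- sw[sw$family == fam, , drop = FALSE]
    rows <- rows[order(rows$sweep_index), , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      v <- smp$v_mV[smp$family == fam & smp$sweep_index == r$sweep_index]
      if (length(v) == 0L)
        stop("malformed samples.csv: no samples for family '", fam,
             "' sweep ", r$sweep_index, call. = FALSE)
      voltage_sweep(v, r$rate_kHz,
                    step_protocol(r$amplitude_pA, r$onset_ms, r$duration_ms,
                                  r$inter_sweep_s))
    })
  }
  for (fam in c("rest", "short", "long"))
    if (!fam %in% sw$family)
      stop("incomplete bundle: protocol family '", fam, "' missing",
           call. = FALSE)
  cmeta <- NULL
  if (!is.na(kv["group"]))
    cmeta <- cell_meta(kv[["group"]], kv[["subregion"]], kv[["layer"]],
                       as.numeric(kv[["x_um"]]), as.numeric(kv[["y_um"]]))
  trace_bundle(
    cell_id = kv[["cell_id"]],
    rest_trace = get_family("rest")[[1]],
    short_steps = get_family("short"),
    long_steps = get_family("long"),
    access_resistance_MOhm = as.numeric(kv[["access_resistance_MOhm"]]),
    waveform_steps = if ("waveform" %in% sw$family) get_family("waveform"),
    meta = cmeta)
}

# ---- internal helpers -------------------------------------------------------

fmt17 <- function(x) sprintf("%.17g", x)

bundle_families <- function(bundle) {
  fams <- list(rest = list(bundle$rest_trace),
               short = bundle$short_steps, long = bundle$long_steps)
  if (!is.null(bundle$waveform_steps)) fams$waveform <- bundle$waveform_steps
  fams
}

sweep_to_list <- function(s) {
  list(samples_mV = s$samples_mV, sampling_rate_kHz = s$sampling_rate_kHz,
       protocol = unclass(s$protocol))
}

sweep_from_list <- function(x) {
  p <- x$protocol
  voltage_sweep(as.numeric(x$samples_mV), x$sampling_rate_kHz,
                step_protocol(p$amplitude_pA, p$onset_ms, p$duration_ms,
                              if (is.null(p$inter_sweep_s)) NA_real_
                              else p$inter_sweep_s))
}

bundle_to_list <- function(b) {
  list(cell_id = b$cell_id,
       access_resistance_MOhm = b$access_resistance_MOhm,
       rest_trace = sweep_to_list(b$rest_trace),
       short_steps = lapply(b$short_steps, sweep_to_list),
       long_steps = lapply(b$long_steps, sweep_to_list),
       waveform_steps = if (!is.null(b$waveform_steps))
         lapply(b$waveform_steps, sweep_to_list),
       meta = if (!is.null(b$meta)) unclass(b$meta))
}

bundle_from_list <- function(x) {
  # read_json(simplifyVector = TRUE) turns lists of sweeps into data frames
  # when homogeneous; normalize back to lists of lists
  as_sweep_list <- function(y) {
    if (is.null(y)) return(NULL)
    if (is.data.frame(y))
      y <- lapply(seq_len(nrow(y)), function(i) {
        list(samples_mV = y$samples_mV[[i]],
             sampling_rate_kHz = y$sampling_rate_kHz[[i]],
             protocol = as.list(y$protocol[i, ]))
      })
    lapply(y, sweep_from_list)
  }
  trace_bundle(
    cell_id = x$cell_id,
    rest_trace = sweep_from_list(x$rest_trace),
    short_steps = as_sweep_list(x$short_steps),
    long_steps = as_sweep_list(x$long_steps),
    access_resistance_MOhm = x$access_resistance_MOhm,
    waveform_steps = as_sweep_list(x$waveform_steps),
    meta = if (!is.null(x$meta))
      cell_meta(x$meta$group, x$meta$subregion, x$meta$layer,
                x$meta$x_um, x$meta$y_um))
}
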