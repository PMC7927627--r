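# Run configuration and the machine-readable run manifest.

#' Pipeline run configuration
#'
#' Collects the fixed constants of the quantification chain: which channel
#' holds the nuclei stain and which markers map to fate roles, the nuclear
#' disk radius (5 px, i.e. 3.12 µm at 0.624 µm/px), the cytosolic dilation
#' factor (2), classification thresholds, the profile smoothing span and
#' grid, and morphometric parameters.
#'
#' @param nuclei_channel nuclei (DAPI) channel name.
#' @param roles named character vector mapping fate labels to channels.
#' @param disk_radius_px nuclear sampling disk radius (px, >= 1).
#' @param dilation_factor cytosolic annulus outer radius multiple (>= 2).
#' @param classify_margin winner margin for fate calls.
#' @param classify_floor_k absolute floor in background MADs.
#' @param span profile smoothing span.
#' @param grid_step profile grid step (µm).
#' @param folding_axis_offset folding axis distance from the colony edge
#'   (µm).
#' @param cable_min_length_um minimum cable length (µm).
#' @param seed RNG seed recorded for the run.
#' @return a `run_config` list.
#' @export
run_config <- function(nuclei_channel = "DAPI",
                       roles = c(SOX2 = "SOX2", T = "T", SOX17 = "SOX17"),
                       disk_radius_px = 5L, dilation_factor = 2,
                       classify_margin = 1.2, classify_floor_k = 2,
                       span = 0.3, grid_step = 5,
                       folding_axis_offset = 200,
                       cable_min_length_um = 10, seed = 1L) {
  if (disk_radius_px < 1) stopf("disk_radius_px must be >= 1")
  if (dilation_factor < 2) stopf("dilation_factor must be >= 2")
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with `run_config` fields.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$roles)) raw$roles <- unlist(raw$roles)
  do.call(run_config, raw)
}

#' Write the machine-readable run manifest
#'
#' Records the configuration, seed, package version and input file list of
#' a run so that any figure can be traced back to its inputs.
#'
#' @param config a [run_config()].
#' @param inputs character vector of input paths.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, inputs, path) {
  manifest <- list(
    package = "mpcolony",
    version = as.character(utils::packageVersion("mpcolony")),
    config = unclass(config),
    inputs = as.list(inputs),
    seed = config$seed)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Assemble a structured analysis report
#'
#' Validates the schemas of the stage outputs it is given and assembles a
#' single machine-readable report. Missing stages are recorded with an
#' explicit absence marker rather than silently dropped; schema problems
#' are collected into an itemized error.
#'
#' @param tables named list of stage outputs; recognized names are
#'   `cells`, `profiles`, `morphometrics`, `comparisons`, `manifest`.
#' @param path optional path to also write the report as JSON.
#' @return the report list, invisibly when `path` is given.
#' @export
build_report <- function(tables, path = NULL) {
  schemas <- list(
    cells = c("nucleus_id", "x", "y"),
    profiles = c("distance", "mean", "sem", "n"),
    morphometrics = c("statistic", "value"),
    comparisons = NULL, manifest = NULL)
  unknown <- setdiff(names(tables), names(schemas))
  errors <- character(0)
  if (length(unknown))
    errors <- c(errors, sprintf("unknown table '%s'", unknown))
  for (nm in intersect(names(tables), names(schemas))) {
    need <- schemas[[nm]]
    if (is.null(need)) next
    have <- names(tables[[nm]])
    miss <- setdiff(need, have)
    if (length(miss))
      errors <- c(errors, sprintf("table '%s' lacks column(s): %s", nm,
                                  paste(miss, collapse = ", ")))
  }
  if (length(errors))
    stopf("report schema mismatch:\n- %s", paste(errors, collapse = "\n- "))
  report <- lapply(stats::setNames(names(schemas), names(schemas)),
                   function(nm) {
    if (is.null(tables[[nm]])) list(absent = TRUE) else tables[[nm]]
  })
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns", pretty = TRUE,
                                na = "null"), path)
    return(invisible(report))
  }
  report
}
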