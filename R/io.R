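# CSV readers/writers for the dataset schemas, JSON reporting, and a small
# run manifest for provenance. Units are fixed by convention: doses mg/kg,
# times minutes, potencies -log10 molar.

#' Read a flinch dataset from CSV
#'
#' Expects the schema written by [write_flinch_csv()]: columns `session`,
#' `animal_id`, `arm`, `drug1`, `dose1_mg_kg`, `drug2`, `dose2_mg_kg`,
#' `bin_start_min`, `bin_end_min`, `flinches`. Malformed rows are reported
#' with their row numbers.
#'
#' @param path CSV path.
#' @return A [flinch_data()] object.
#' @export
read_flinch_csv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  flinch_data(df)
}

#' Write a flinch dataset to CSV
#' @param data A [flinch_data()] object.
#' @param path Output path.
#' @export
write_flinch_csv <- function(data, path) {
  data <- flinch_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a binding dataset from CSV
#'
#' Columns `session`, `animal_id`, `arm`, `transporter`, `time_min`,
#' `signal`.
#'
#' @param path CSV path.
#' @return A [binding_data()] object.
#' @export
read_binding_csv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  binding_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a binding dataset to CSV
#' @param data A [binding_data()] object.
#' @param path Output path.
#' @export
write_binding_csv <- function(data, path) {
  data <- binding_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert a result object to a plain reportable list
#'
#' Methods exist for `dose_response_fit`, `ed50_estimate`,
#' `isobologram_result`, data frames (summary tables) and lists of results.
#' The output is schema-stable and serializes cleanly to JSON.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A named list (or list of lists) of plain vectors.
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.dose_response_fit <- function(x, ...) {
  list(
    drug = x$drug_label,
    ed50 = x$ed50,
    log_ed50 = x$log_ed50,
    hill = x$hill,
    ci95 = c(x$ci95[["lower"]], x$ci95[["upper"]]),
    n_points = x$n_points,
    converged = x$converged,
    residual_sd = x$residual_sd
  )
}

#' @export
as_report.ed50_estimate <- function(x, ...) {
  list(
    drug = x$drug_label,
    ed50 = x$ed50,
    ci95 = c(x$ci95[["lower"]], x$ci95[["upper"]])
  )
}

#' @export
as_report.isobologram_result <- function(x, ...) {
  list(
    drug_a = x$drug_a, drug_b = x$drug_b, ratio = x$ratio,
    f = x$f,
    z_add = x$z_add,
    z_add_ci = unname(x$z_add_ci),
    z_obs = x$z_obs,
    z_obs_ci = unname(x$z_obs_ci),
    interaction_index = x$interaction_index,
    verdict = x$verdict
  )
}

#' @export
as_report.data.frame <- function(x, ...) {
  lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
}

#' @export
as_report.list <- function(x, ...) lapply(x, as_report)

#' Write a result object as JSON
#'
#' @param x Any object with an [as_report()] method.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(as_report(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Record a run manifest
#'
#' Captures what was run on which inputs, with a configuration hash stable
#' across re-runs of identical inputs (the timestamp is excluded from the
#' hash).
#'
#' @param command Command or function name.
#' @param inputs,outputs Character vectors of file paths.
#' @param seed Integer seed, or `NULL`.
#' @param config Any serializable configuration object, or `NULL`.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = character(), outputs = character(),
                         seed = NULL, config = NULL) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(list(command = command, inputs = inputs, outputs = outputs,
               seed = seed, config = config),
          tmp, version = 2)
  structure(
    list(
      command = command,
      config_hash = unname(tools::md5sum(tmp)),
      seed = seed,
      input_paths = inputs,
      output_paths = outputs,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' @export
as_report.run_manifest <- function(x, ...) unclass(x)
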