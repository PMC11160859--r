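## Model configuration files. A config names a builtin model, its
## parameters, and optionally a horizon; stored as JSON (round-trips
## exactly through jsonlite with full double precision).

#' Write a model configuration file
#'
#' @param cfg list with elements `model` (builtin model name), `params`
#'   (named list), and optionally `horizon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(is.list(cfg), !is.null(cfg$model))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a model configuration file
#'
#' @param path path to a JSON config written by [write_model_config()].
#' @return the configuration list.
#' @export
read_model_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Instantiate the model named by a configuration
#'
#' @param cfg a configuration list (or path to one).
#' @return a `population_model`.
#' @export
model_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_model_config(cfg)
  builtin_model(cfg$model, as.list(cfg$params))
}

#' Write a history as a tab-separated event log
#'
#' Columns: jump time, mark name, state before, state after (states as
#' comma-joined compartment counts). A header row records the horizon and
#' compartment names.
#'
#' @param h a `history`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# horizon\t%.12g\n", h$horizon), file = con)
  cat(sprintf("# compartments\t%s\n", paste(colnames(h$states), collapse = ",")),
      file = con)
  cat("time\tmark\tstate_before\tstate_after\n", file = con)
  for (k in seq_along(h$times)) {
    cat(sprintf("%.12g\t%s\t%s\t%s\n", h$times[k], h$marks[k],
                paste(h$states[k, ], collapse = ","),
                paste(h$states[k + 1L, ], collapse = ",")), file = con)
  }
  invisible(path)
}
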