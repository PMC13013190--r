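# File outputs: CSV time series and event log, JSON snapshots, and a config
# echo (resolved defaults + seed) so any run can be reproduced bit-exactly.

#' Write simulation outputs to a directory
#'
#' Writes `time_series.csv`, `event_log.csv`, `snapshots.json` and
#' `config.json` (the fully resolved configuration including the seed;
#' re-running [tme_run()] on it reproduces the event log bit-exactly).
#'
#' @param run a [tme_run()] result
#' @param dir destination directory (created if missing)
#' @return named character vector of the written paths, invisibly
#' @export
write_tme_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(time_series = file.path(dir, "time_series.csv"),
             event_log = file.path(dir, "event_log.csv"),
             snapshots = file.path(dir, "snapshots.json"),
             config = file.path(dir, "config.json"))
  utils::write.csv(run$time_series, paths["time_series"], row.names = FALSE)
  utils::write.csv(run$event_log, paths["event_log"], row.names = FALSE)
  jsonlite::write_json(run$snapshots, paths["snapshots"], digits = NA,
                       auto_unbox = TRUE, null = "null")
  cfg <- run$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths["config"], digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}

#' Read a written configuration echo back into a config object
#'
#' @param path a `config.json` written by [write_tme_outputs()]
#' @return a `tme_config`
#' @export
read_tme_config <- function(path) {
  # simplifyVector would drop the names of named parameter vectors (they are
  # serialised as arrays); plain lists merge back losslessly instead
  ov <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- .merge_config(tme_config(), ov)
  class(cfg) <- "tme_config"
  cfg
}
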