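#' Write and read signal traces as delimited text
#'
#' Traces are exchanged as two-column tab-delimited text
#' (`time_s`, `volts`) with a one-line header; metadata (sample rate, start
#' time) goes to an optional JSON sidecar.
#'
#' @param trace A [signal_trace()].
#' @param path Output file path.
#' @param sidecar Write `<path>.json` with the trace metadata
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_signal_trace <- function(trace, path, sidecar = TRUE) {
  readr::write_tsv(
    tibble(time_s = trace$time, volts = trace$voltage), path
  )
  if (sidecar) {
    meta <- list(sample_rate = trace_sample_rate(trace),
                 start_time = attr(trace, "start_time"),
                 units = attr(trace, "units"))
    phases <- attr(trace, "phases")
    if (!is.null(phases)) meta$phases <- phases
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_signal_trace
#' @param sample_rate Sampling rate in Hz; when `NULL` it is recovered from
#'   the JSON sidecar if present, otherwise inferred from the time column.
#' @return `read_signal_trace()` returns a [signal_trace()].
#' @export
read_signal_trace <- function(path, sample_rate = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(ncol(tbl) >= 2)
  time <- tbl[[1]]
  volts <- tbl[[2]]
  sidecar <- paste0(path, ".json")
  if (is.null(sample_rate)) {
    if (file.exists(sidecar)) {
      sample_rate <- jsonlite::read_json(sidecar)$sample_rate
    } else {
      sample_rate <- 1 / stats::median(diff(time))
    }
  }
  signal_trace(volts, sample_rate, start_time = time[1])
}

# construct a signal_spec / noise_spec / contact from a plain named list
spec_from_list <- function(x, constructor) {
  do.call(constructor, x)
}

#' Read a bench configuration from a structured text file
#'
#' The file is YAML whose keys mirror the [bench_config()] and
#' [front_end_params()] field names exactly; any omitted section falls back
#' to the package defaults.
#'
#' @param path Path to the YAML configuration.
#' @return A [bench_config()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "params: {r_shunt: 5000, gain: 50}",
#'   "contact_plus: {r_contact: 100}",
#'   "contact_minus: {r_contact: 51000}",
#'   "mode: bipolar"
#' ), cfg)
#' b <- read_bench_config(cfg)
#' @export
read_bench_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$params)) {
    args$params <- spec_from_list(cfg$params, front_end_params)
  }
  for (ct in c("contact_plus", "contact_minus")) {
    if (!is.null(cfg[[ct]])) args[[ct]] <- spec_from_list(cfg[[ct]],
                                                          electrode_contact)
  }
  for (sp in c("source_plus", "source_minus", "common_mode")) {
    if (!is.null(cfg[[sp]])) args[[sp]] <- spec_from_list(cfg[[sp]],
                                                          signal_spec)
  }
  if (!is.null(cfg$noise)) args$noise <- spec_from_list(cfg$noise, noise_spec)
  for (sc in c("r_common", "ground_potential", "mode", "quantize_output")) {
    if (!is.null(cfg[[sc]])) args[[sc]] <- cfg[[sc]]
  }
  do.call(bench_config, args)
}

#' Write an experiment report
#'
#' @param report An `experiment_report` tibble.
#' @param path Output file; format chosen by `format`.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(report, path)
  } else {
    jsonlite::write_json(
      list(experiment = attr(report, "experiment_name"),
           seed = attr(report, "seed"),
           config = attr(report, "config_snapshot"),
           cases = report),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(path)
}
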