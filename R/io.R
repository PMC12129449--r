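#' @include AllGenerics.R
NULL

#' Read and write signal traces as CSV
#'
#' Traces are stored as a single `sample` column preceded by `#`-prefixed
#' metadata header lines (`sampling_rate_hz`, `units`, `channel`,
#' `start_time_s`), a plain-text container portable across rigs.
#'
#' @param trace a [SignalTrace-class].
#' @param path file path.
#' @return `readTraceCsv()` returns a [SignalTrace-class];
#'   `writeTraceCsv()` returns `path` invisibly.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "SignalTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz: %.10g", samplingRate(trace)),
    sprintf("# units: %s", traceUnits(trace)),
    sprintf("# channel: %s", channelLabel(trace)),
    sprintf("# start_time_s: %.10g", startTime(trace)),
    "sample"
  ), con)
  writeLines(format(samples(trace), trim = TRUE, digits = 15), con)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  if (!file.exists(path)) stop("cannot read trace: no such file: ", path)
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  getMeta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1L]))
  }
  rate <- as.numeric(getMeta("sampling_rate_hz", NA))
  if (!is.finite(rate)) {
    stop("trace file ", path, " lacks a sampling_rate_hz header")
  }
  x <- utils::read.csv(path, comment.char = "#")
  SignalTrace(x$sample, rate, units = getMeta("units", "a.u."),
              channel = getMeta("channel", ""),
              startTime = as.numeric(getMeta("start_time_s", "0")))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config: no such file: ", path)
  yaml::read_yaml(path)
}

# Write the run manifest (parameters + versions; no timestamp so a bundle
# is bit-reproducible from its manifest).
.writeManifest <- function(config, path) {
  manifest <- list(
    package = "phrenoscope",
    package_version = as.character(utils::packageVersion("phrenoscope")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
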