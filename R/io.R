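# Plain-format I/O: label streams and trajectories as CSV, schedules as
# JSON, configs as YAML, movies as multi-page TIFF (via the optional tiff
# package).

#' Read and write label streams
#'
#' CSV with columns `fly_id`, `trial`, `t_s`, `label` (`state`) and
#' `confidence`; extra columns are preserved.
#'
#' @param path file path.
#' @param stream data.frame to write.
#' @return `readLabelStream`: a data.frame.
#' @export
readLabelStream <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("state" %in% names(df) && !"label" %in% names(df))
    names(df)[names(df) == "state"] <- "label"
  need <- c("t_s", "label", "confidence")
  if (!all(need %in% names(df)))
    stop("label stream CSV must have columns t_s, label (or state), confidence")
  df
}

#' @rdname readLabelStream
#' @export
writeLabelStream <- function(stream, path) {
  write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' Read a raw tracking stream from CSV
#'
#' Expects columns `t_s` and `dx` (tracker counts per frame).
#'
#' @param path file path.
#' @return data.frame validated as tracking input.
#' @export
readTrackingCsv <- function(path) {
  df <- read.csv(path)
  checkTrackingRaw(df)
  df
}

#' Write and read a stimulus schedule as JSON
#'
#' @param schedule a [StimulusSchedule-class].
#' @param path file path.
#' @return `readScheduleJson`: a `StimulusSchedule`.
#' @export
writeScheduleJson <- function(schedule, path) {
  jsonlite::write_json(list(
    trials = scheduleTrials(schedule),
    events = scheduleEvents(schedule),
    iti_s = schedule@itiS, puff_n = schedule@puffN,
    puff_period_s = schedule@puffPeriodS, puff_duty = schedule@puffDuty,
    seed = schedule@seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScheduleJson
#' @export
readScheduleJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("StimulusSchedule",
               trials = as.data.frame(x$trials),
               events = as.data.frame(x$events),
               itiS = x$iti_s, puffN = x$puff_n,
               puffPeriodS = x$puff_period_s, puffDuty = x$puff_duty,
               seed = x$seed)
}

#' Read a synthetic-generator config from YAML
#'
#' Field names mirror [syntheticConfig()] arguments; transition matrices
#' may be given as row-major lists of rows.
#'
#' @param path YAML file path.
#' @return a `"SyntheticConfig"`.
#' @export
readSyntheticConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("transitionBaseline", "transitionPostpuff")) {
    if (!is.null(x[[nm]]) && !is.matrix(x[[nm]])) {
      m <- do.call(rbind, x[[nm]])
      dimnames(m) <- list(behaviorStates(), behaviorStates())
      x[[nm]] <- m
    }
  }
  do.call(syntheticConfig, x)
}

#' Write a movie as multi-page TIFF
#'
#' Requires the `tiff` package; intensities are rescaled to \[0, 1\].
#'
#' @param movie array `frames x height x width`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMovieTiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF movies")
  rng <- range(movie)
  scl <- if (diff(rng) > 0) (movie - rng[1]) / diff(rng) else movie * 0
  pages <- lapply(seq_len(dim(movie)[1]), function(i) scl[i, , ])
  tiff::writeTIFF(pages, path)
  invisible(path)
}
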