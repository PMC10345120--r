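#' @import methods
#' @useDynLib flygate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames rowData
#' @importFrom S4Vectors metadata DataFrame SimpleList
#' @importFrom stats approx fft rnorm runif rbinom sd shapiro.test t.test
#'   wilcox.test p.adjust aov kruskal.test anova rexp quantile median complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

#' Stimulus schedule for arena and imaging experiments
#'
#' A `StimulusSchedule` holds either (i) an ordered table of behavioral
#' trials, each with a condition (`"puff-"`, `"puff+"`, `"light-"`,
#' `"light+"`), an initial object side and a recording duration, or (ii) an
#' imaging event timeline (`events`) of rest / puff / visual segments, or
#' both. Timing constants follow the paradigm the package models: 90 s
#' inter-trial interval, a puff block of 10 pulses alternating 500 ms open /
#' 500 ms closed (1 Hz), and photostimulation pulse durations equal to half
#' the stimulation period (50 % duty cycle).
#'
#' @slot trials data.frame with columns `trial`, `condition`,
#'   `object_side_deg` (initial azimuth, -60 or +60), `recording_s`, and
#'   `photostim_hz` (NA when no photostimulation).
#' @slot events data.frame with columns `kind` (`"rest"`, `"puff"`,
#'   `"visual"`), `t_on_s`, `t_off_s`, and `gated` (logical; for visual
#'   segments, whether a puff block ended recently enough for the gate to be
#'   open).
#' @slot itiS inter-trial interval in seconds.
#' @slot puffN number of pulses per puff block.
#' @slot puffPeriodS pulse period in seconds (1 s: 500 ms open, 500 ms closed).
#' @slot puffDuty fraction of the period the valve is open.
#' @slot seed integer seed used to draw the pseudo-random trial order.
#' @export
setClass("StimulusSchedule",
  representation(
    trials = "data.frame",
    events = "data.frame",
    itiS = "numeric",
    puffN = "numeric",
    puffPeriodS = "numeric",
    puffDuty = "numeric",
    seed = "numeric"
  ),
  prototype(
    trials = data.frame(),
    events = data.frame(),
    itiS = 90, puffN = 10, puffPeriodS = 1, puffDuty = 0.5, seed = 0
  )
)

setValidity("StimulusSchedule", function(object) {
  msg <- character()
  if (nrow(object@trials) > 0L) {
    need <- c("trial", "condition", "object_side_deg", "recording_s")
    if (!all(need %in% names(object@trials)))
      msg <- c(msg, "trials must have columns trial, condition, object_side_deg, recording_s")
    else {
      tab <- table(object@trials$condition)
      if (length(unique(tab)) > 1L)
        msg <- c(msg, "conditions must be balanced across trials")
    }
  }
  if (nrow(object@events) > 0L) {
    need <- c("kind", "t_on_s", "t_off_s")
    if (!all(need %in% names(object@events)))
      msg <- c(msg, "events must have columns kind, t_on_s, t_off_s")
    else if (any(object@events$t_off_s <= object@events$t_on_s))
      msg <- c(msg, "event offsets must follow onsets")
  }
  if (object@puffDuty <= 0 || object@puffDuty >= 1)
    msg <- c(msg, "puffDuty must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn StimulusSchedule-class number of trials
#' @param x,object a `StimulusSchedule`
#' @export
setMethod("length", "StimulusSchedule", function(x) nrow(x@trials))

#' Accessors for StimulusSchedule
#'
#' `scheduleTrials()` returns the trial table, `scheduleEvents()` the imaging
#' event timeline, and `puffOnsets()` the valve opening times (s) of a puff
#' block starting at `blockStartS`.
#'
#' @param schedule a [StimulusSchedule-class] object.
#' @param blockStartS start time of the puff block in seconds.
#' @return `scheduleTrials`/`scheduleEvents`: data.frames; `puffOnsets`: a
#'   numeric vector of onset times.
#' @export
scheduleTrials <- function(schedule) schedule@trials

#' @rdname scheduleTrials
#' @export
scheduleEvents <- function(schedule) schedule@events

#' @rdname scheduleTrials
#' @export
puffOnsets <- function(schedule, blockStartS = 0) {
  blockStartS + (seq_len(schedule@puffN) - 1) * schedule@puffPeriodS
}

setMethod("show", "StimulusSchedule", function(object) {
  cat("StimulusSchedule\n")
  if (nrow(object@trials) > 0L) {
    cat(sprintf("  %d trials: %s\n", nrow(object@trials),
                paste(sprintf("%s x%d", names(table(object@trials$condition)),
                              as.integer(table(object@trials$condition))),
                      collapse = ", ")))
  }
  if (nrow(object@events) > 0L) {
    cat(sprintf("  imaging timeline: %d segments over %.1f s\n",
                nrow(object@events), max(object@events$t_off_s)))
  }
  cat(sprintf("  puff block: %d pulses at %.3g Hz, ITI %.3g s\n",
              object@puffN, 1 / object@puffPeriodS, object@itiS))
})

#' Container for calcium-imaging traces
#'
#' `CalciumExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with cells as rows and frames as columns. The `"F"` assay holds raw
#' fluorescence (a.u.); downstream steps add `"dff"` (percent dF/F0) and
#' `"z"` (z-scored dF/F0) assays. The sampling rate and the stimulus event
#' table travel in `metadata()`.
#'
#' @param F numeric matrix, cells x frames, raw fluorescence.
#' @param fsHz sampling rate in Hz (one plane at 152 Hz in the fast-scan
#'   mode this package mainly targets; 4 Hz volumetric traces are accepted
#'   but the oscillation functions refuse bands above their Nyquist).
#' @param events data.frame of stimulus segments (see
#'   [StimulusSchedule-class]); may be empty.
#' @param rowData optional per-cell annotation (e.g. ground-truth responder
#'   flags for synthetic cohorts).
#' @return a `CalciumExperiment`.
#' @export
setClass("CalciumExperiment", contains = "SummarizedExperiment")

#' @rdname CalciumExperiment-class
#' @export
CalciumExperiment <- function(F, fsHz, events = data.frame(), rowData = NULL) {
  F <- as.matrix(F)
  if (is.null(rownames(F)))
    rownames(F) <- sprintf("cell%03d", seq_len(nrow(F)))
  args <- list(assays = S4Vectors::SimpleList(F = F),
               metadata = list(fs_hz = fsHz, events = events))
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("CalciumExperiment", se)
}

setValidity("CalciumExperiment", function(object) {
  msg <- character()
  if (!"F" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'F' (raw fluorescence) is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "F"))))
    msg <- c(msg, "fluorescence values must be finite")
  fs <- S4Vectors::metadata(object)$fs_hz
  if (is.null(fs) || !is.numeric(fs) || fs <= 0)
    msg <- c(msg, "metadata fs_hz must be a positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn CalciumExperiment-class sampling rate in Hz
#' @param object a `CalciumExperiment`
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname CalciumExperiment-class
#' @export
setMethod("samplingRate", "CalciumExperiment",
          function(object) S4Vectors::metadata(object)$fs_hz)

#' @describeIn CalciumExperiment-class stimulus event table
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname CalciumExperiment-class
#' @export
setMethod("eventTable", "CalciumExperiment",
          function(object) S4Vectors::metadata(object)$events)

#' @describeIn CalciumExperiment-class frame times in seconds
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname CalciumExperiment-class
#' @export
setMethod("frameTimes", "CalciumExperiment", function(object) {
  (seq_len(ncol(object)) - 1) / samplingRate(object)
})

setMethod("show", "CalciumExperiment", function(object) {
  callNextMethod()
  cat(sprintf("sampling rate: %.4g Hz; %d stimulus segments\n",
              samplingRate(object),
              nrow(S4Vectors::metadata(object)$events %||% data.frame())))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-frequency power from a Morlet continuous wavelet transform
#'
#' Holds the squared modulus of Morlet wavelet coefficients on a time x
#' frequency grid, with the wavelet parameters (center frequency `omega0`,
#' scale resolution `dj`) and the cone-of-influence boundary.
#'
#' @slot power numeric matrix, time points x frequencies, |W|^2 in z-units^2.
#' @slot time numeric vector of sample times (s).
#' @slot freq numeric vector of center frequencies (Hz), strictly increasing.
#' @slot coiFreqHz per time point, the lowest frequency unaffected by edge
#'   effects; power at frequencies below this value lies inside the cone of
#'   influence and should be interpreted with caution.
#' @slot omega0 Morlet center frequency (nondimensional).
#' @slot dj scale resolution in octaves.
#' @slot fsHz sampling rate of the analyzed trace.
#' @export
setClass("WaveletSpectrum",
  representation(
    power = "matrix",
    time = "numeric",
    freq = "numeric",
    coiFreqHz = "numeric",
    omega0 = "numeric",
    dj = "numeric",
    fsHz = "numeric"
  )
)

setValidity("WaveletSpectrum", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@time))
    msg <- c(msg, "power must have one row per time point")
  if (ncol(object@power) != length(object@freq))
    msg <- c(msg, "power must have one column per frequency")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@freq) && max(object@freq) > object@fsHz / 2 + 1e-9)
    msg <- c(msg, "frequencies must not exceed the Nyquist frequency")
  if (length(msg)) msg else TRUE
})

#' Accessors for WaveletSpectrum
#'
#' @param spectrum a [WaveletSpectrum-class] object.
#' @return `spectrumPower()`: the time x frequency power matrix;
#'   `spectrumFrequencies()`, `spectrumTime()`, `coneOfInfluence()`: numeric
#'   vectors.
#' @export
spectrumPower <- function(spectrum) spectrum@power

#' @rdname spectrumPower
#' @export
spectrumFrequencies <- function(spectrum) spectrum@freq

#' @rdname spectrumPower
#' @export
spectrumTime <- function(spectrum) spectrum@time

#' @rdname spectrumPower
#' @export
coneOfInfluence <- function(spectrum) spectrum@coiFreqHz

setMethod("show", "WaveletSpectrum", function(object) {
  cat(sprintf("WaveletSpectrum: %d time points x %d frequencies\n",
              nrow(object@power), ncol(object@power)))
  cat(sprintf("  %.3g-%.3g Hz (omega0 = %g, dj = %g), fs = %g Hz\n",
              min(object@freq), max(object@freq),
              object@omega0, object@dj, object@fsHz))
})
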