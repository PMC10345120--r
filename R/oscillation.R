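# Morlet continuous wavelet transform of z-scored traces and the band-power
# statistics built on it: per-band mean power over time, the delta-power
# statistic against the preceding 0.5 s bin, responder-restricted averaging
# and cross-cell mean spectra.

#' Canonical frequency bands
#'
#' Theta and alpha follow the printed definitions (4-8 Hz and 8-16 Hz);
#' delta and beta edges are conventions chosen for contiguity and are
#' configurable. All bands are half-open `[lo, hi)`, so 8 Hz belongs to
#' alpha.
#'
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
frequencyBands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 16), beta = c(16, 32))
}

#' Morlet continuous wavelet transform
#'
#' FFT-based continuous wavelet transform with the analytic Morlet mother
#' wavelet in the Torrence-Compo convention: center frequency `omega0 = 6`,
#' log-spaced scales `s_j = s0 * 2^(j * dj)` from `s0 = 2 / fs` up to a
#' quarter of the trace length, and power `|W|^2`. The scale-to-frequency
#' map is `f = (omega0 + sqrt(2 + omega0^2)) / (4 * pi * s)`. Edge effects
#' are summarized by the cone of influence (e-folding time `sqrt(2) * s`).
#'
#' @param z numeric trace (typically z-scored dF/F0).
#' @param fsHz sampling rate in Hz.
#' @param omega0 Morlet center frequency (default 6).
#' @param dj scale resolution in octaves (default 0.25).
#' @param s0 smallest scale (default `2 / fsHz`).
#' @param maxScale largest scale (default trace length / 4 in seconds).
#' @return a [WaveletSpectrum-class] with frequencies in increasing order.
#' @export
morletCWT <- function(z, fsHz, omega0 = 6, dj = 0.25, s0 = 2 / fsHz,
                      maxScale = NULL) {
  n <- length(z)
  stopifnot(fsHz > 0)
  if (n < 16L) stop("trace too short for a wavelet transform")
  dt <- 1 / fsHz
  if (is.null(maxScale)) maxScale <- n * dt / 4
  J <- floor(log2(maxScale / s0) / dj)
  if (J < 1L) stop("scale range is empty; lengthen the trace or lower s0")
  scales <- s0 * 2^(seq(0, J) * dj)
  npad <- 2^ceiling(log2(n))
  x <- c(z - mean(z), rep(0, npad - n))
  xhat <- fft(x)
  k <- seq(0, npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  W <- matrix(0i, nrow = n, ncol = length(scales))
  norm0 <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- sqrt(2 * pi * s / dt) * norm0 *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    Wj <- fft(xhat * psi, inverse = TRUE) / npad
    W[, j] <- Wj[seq_len(n)]
  }
  freq <- 1 / (fourierFactor * scales)
  ord <- order(freq)
  tvec <- (seq_len(n) - 1) * dt
  distEdge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coiScale <- distEdge / sqrt(2)   # scales larger than this are edge-affected
  coiFreq <- ifelse(coiScale > 0, 1 / (fourierFactor * coiScale), Inf)
  methods::new("WaveletSpectrum",
               power = Mod(W[, ord, drop = FALSE])^2,
               time = tvec, freq = freq[ord], coiFreqHz = coiFreq,
               omega0 = omega0, dj = dj, fsHz = fsHz)
}

#' Band power time series
#'
#' Mean wavelet power across the frequencies belonging to a half-open band
#' `[lo, hi)`, per time point.
#'
#' @param spectrum a [WaveletSpectrum-class].
#' @param band `c(lo, hi)` in Hz, or the name of a band in
#'   [frequencyBands()].
#' @return data.frame with `t_s` and `power`.
#' @export
bandPower <- function(spectrum, band = "theta") {
  if (is.character(band)) band <- frequencyBands()[[match.arg(band, names(frequencyBands()))]]
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[2] > spectrum@fsHz / 2 + 1e-9)
    stop("requested band extends above the Nyquist frequency")
  sel <- spectrum@freq >= band[1] & spectrum@freq < band[2]
  if (!any(sel))
    stop("no wavelet frequencies fall inside the requested band")
  data.frame(t_s = spectrum@time,
             power = rowMeans(spectrum@power[, sel, drop = FALSE]))
}

#' Delta band power against the preceding 0.5 s bin
#'
#' Mean band power within the analysis window minus the mean over the
#' 0.5 s bin immediately preceding it.
#'
#' @param bp band-power data.frame (`t_s`, `power`) from [bandPower()].
#' @param window `c(from, to)` in seconds; must start at least `binS` into
#'   the trace.
#' @param binS preceding-bin width in seconds (default 0.5).
#' @return the delta-power scalar.
#' @export
deltaBandPower <- function(bp, window, binS = 0.5) {
  if (window[1] < binS - 1e-9)
    stop("no preceding bin exists before the analysis window")
  inWin <- bp$t_s >= window[1] - 1e-9 & bp$t_s < window[2] - 1e-9
  inBin <- bp$t_s >= window[1] - binS - 1e-9 & bp$t_s < window[1] - 1e-9
  if (!any(inWin) || !any(inBin))
    stop("window or preceding bin contains no samples")
  mean(bp$power[inWin]) - mean(bp$power[inBin])
}

#' Responder-restricted delta-power table
#'
#' Computes, for every puff-responsive cell, the Morlet band power of its
#' z-trace and the delta-power statistic in each analysis window, then
#' averages across responders. The default window set mirrors the imaging
#' paradigm: the first puff block, the visual window before any puff, and
#' the visual window following puffs.
#'
#' @param ce a [CalciumExperiment-class] with a `"z"` assay.
#' @param responders logical per-cell flags; defaults to
#'   [classifyResponder()] on the first puff block.
#' @param bands named list of band edges (default [frequencyBands()]).
#' @param windows named list of `c(from, to)` windows in seconds; defaults
#'   derived from the event table (`puff`, `visual_pre`, `visual_post`).
#' @param ... passed to [morletCWT()].
#' @return list with `mean` (data.frame band x window of mean delta power
#'   across responders), `perCell` (long data.frame with cell, band,
#'   window, delta_power), and `n_responders`. With zero responders both
#'   tables are empty and a warning is raised.
#' @export
responderRestrictedDelta <- function(ce, responders = NULL,
                                     bands = frequencyBands(),
                                     windows = NULL, ...) {
  stopifnot(methods::is(ce, "CalciumExperiment"))
  if (!"z" %in% SummarizedExperiment::assayNames(ce))
    stop("compute deltaFOverF() and zScoreTrace() first")
  if (is.null(windows)) windows <- defaultAnalysisWindows(ce)
  if (is.null(responders)) responders <- classifyResponder(ce)
  if (length(responders) != nrow(ce))
    stop("need one responder flag per cell")
  emptyMean <- data.frame(band = character(), window = character(),
                          delta_power = numeric())
  if (!any(responders)) {
    warning("no responder cells: delta-power table is empty")
    return(list(mean = emptyMean, perCell = emptyMean, n_responders = 0L))
  }
  Z <- SummarizedExperiment::assay(ce, "z")
  fs <- samplingRate(ce)
  rows <- list()
  for (ci in which(responders)) {
    spec <- morletCWT(Z[ci, ], fs, ...)
    for (b in names(bands)) {
      bp <- bandPower(spec, bands[[b]])
      for (w in names(windows)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = rownames(ce)[ci], band = b, window = w,
          delta_power = deltaBandPower(bp, windows[[w]]))
      }
    }
  }
  perCell <- do.call(rbind, rows)
  agg <- stats::aggregate(delta_power ~ band + window, perCell, mean)
  list(mean = agg, perCell = perCell, n_responders = sum(responders))
}

#' Default analysis windows from an imaging event table
#'
#' `puff` is the first puff block, `visual_pre` the first non-gated visual
#' window, `visual_post` the first gated visual window.
#'
#' @param ce a [CalciumExperiment-class] (or an event data.frame).
#' @return named list of `c(from, to)` windows in seconds.
#' @export
defaultAnalysisWindows <- function(ce) {
  ev <- if (is.data.frame(ce)) ce else eventTable(ce)
  pick <- function(sel) {
    i <- which(sel)[1]
    if (is.na(i)) stop("event table lacks a required window")
    c(ev$t_on_s[i], ev$t_off_s[i])
  }
  list(puff = pick(ev$kind == "puff"),
       visual_pre = pick(ev$kind == "visual" & !ev$gated),
       visual_post = pick(ev$kind == "visual" & ev$gated))
}

#' Cross-cell average spectrum
#'
#' Element-wise mean of per-cell wavelet power matrices on identical
#' time/frequency grids.
#'
#' @param spectra list of [WaveletSpectrum-class] objects.
#' @return a `WaveletSpectrum` holding the mean power.
#' @export
averageCrossSpectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!isTRUE(all.equal(s@freq, ref@freq)) ||
        !isTRUE(all.equal(s@time, ref@time)))
      stop("spectra must share identical time and frequency grids")
  }
  avg <- Reduce(`+`, lapply(spectra, spectrumPower)) / length(spectra)
  methods::initialize(ref, power = avg)
}
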