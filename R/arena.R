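# Closed-loop walking arena geometry: tracker calibration, downsampling to the
# 10 Hz analysis rate, gain-scaled object-angle updates, stimulus scheduling
# and the closed-loop integrator.

#' Arena configuration
#'
#' The closed loop multiplies the fly's lateral displacement per step by a
#' fixed gain to move the object's azimuth. The gain was held fixed across
#' flies in the paradigm this package models but its numeric value is a free
#' parameter here.
#'
#' @param gainDegPerUnit degrees of object-angle change per arena-unit of
#'   lateral displacement (default 5).
#' @param seed integer seed controlling the pseudo-random pieces of the
#'   closed loop (initial object side).
#' @return a validated list of class `"ArenaConfig"`.
#' @export
arenaConfig <- function(gainDegPerUnit = 5, seed = 0L) {
  stopifnot(is.numeric(gainDegPerUnit), length(gainDegPerUnit) == 1L,
            is.finite(gainDegPerUnit), gainDegPerUnit > 0)
  structure(list(gainDegPerUnit = gainDegPerUnit, seed = as.integer(seed)),
            class = "ArenaConfig")
}

#' @export
print.ArenaConfig <- function(x, ...) {
  cat(sprintf("ArenaConfig: gain %.3g deg per arena-unit, seed %d\n",
              x$gainDegPerUnit, x$seed))
  invisible(x)
}

#' Visual object geometry
#'
#' The two object types of the paradigm: a small dark spot (22.5 deg wide
#' and high) and a dark vertical bar (22.5 x 57 deg), both at 0 cd/m^2 on
#' an 80 cd/m^2 background. Flies avoid the spot only after puffs and
#' natively fixate the bar.
#'
#' @param kind `"spot"` or `"bar"`.
#' @param widthDeg,heightDeg angular size in degrees (> 0); defaults follow
#'   the kind.
#' @param luminanceCdM2,backgroundCdM2 object and background luminance.
#' @return a validated list of class `"ObjectSpec"`.
#' @export
objectSpec <- function(kind = c("spot", "bar"), widthDeg = 22.5,
                       heightDeg = NULL,
                       luminanceCdM2 = 0, backgroundCdM2 = 80) {
  kind <- match.arg(kind)
  if (is.null(heightDeg)) heightDeg <- if (kind == "spot") 22.5 else 57
  stopifnot(widthDeg > 0, heightDeg > 0)
  structure(list(kind = kind, widthDeg = widthDeg, heightDeg = heightDeg,
                 luminanceCdM2 = luminanceCdM2,
                 backgroundCdM2 = backgroundCdM2),
            class = "ObjectSpec")
}

#' @export
print.ObjectSpec <- function(x, ...) {
  cat(sprintf("ObjectSpec: %s, %.1f x %.1f deg, %g on %g cd/m^2\n",
              x$kind, x$widthDeg, x$heightDeg, x$luminanceCdM2,
              x$backgroundCdM2))
  invisible(x)
}

#' Estimate the tracker's left-right asymmetry
#'
#' The ball tracker reads out lateral displacement at ~192 Hz; a fly not
#' perfectly perpendicular to the sensor produces a constant bias. A
#' calibration segment (3 min in the original paradigm; at least 10 s here)
#' estimates the mean per-frame displacement, which is subtracted from all
#' subsequent frames.
#'
#' @param raw data.frame with columns `t_s` (strictly increasing seconds) and
#'   `dx` (tracker counts per frame).
#' @return the mean `dx` per frame (counts/frame).
#' @export
calibrateAsymmetry <- function(raw) {
  checkTrackingRaw(raw)
  if (diff(range(raw$t_s)) < 10)
    stop("calibration segment must cover at least 10 s")
  mean(raw$dx)
}

checkTrackingRaw <- function(raw) {
  if (!is.data.frame(raw) || !all(c("t_s", "dx") %in% names(raw)) ||
      nrow(raw) == 0L)
    stop("tracking input must be a nonempty data.frame with columns t_s, dx")
  if (!all(is.finite(raw$t_s)) || !all(is.finite(raw$dx)))
    stop("tracking samples must be finite")
  if (is.unsorted(raw$t_s, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  invisible(TRUE)
}

#' Downsample a raw tracking stream to the analysis rate
#'
#' Subtracts the per-frame asymmetry profile, then resamples displacement
#' from the tracker rate (~192 Hz) to `fsOut` (10 Hz) by linear
#' interpolation of cumulative displacement followed by differencing. This
#' conserves total displacement exactly whenever the segment duration is a
#' multiple of the output period.
#'
#' @param raw data.frame with `t_s`, `dx` (see [calibrateAsymmetry()]).
#' @param profile mean per-frame asymmetry to subtract (counts/frame;
#'   default 0).
#' @param fsOut output rate in Hz (default 10).
#' @return data.frame with `t_s` (bin end times at 1/fsOut spacing) and `dx`
#'   (displacement within each bin, asymmetry-corrected).
#' @export
downsampleTrack <- function(raw, profile = 0, fsOut = 10) {
  checkTrackingRaw(raw)
  if (diff(range(raw$t_s)) < 0.2)
    stop("tracking segment too short to downsample (need >= 0.2 s)")
  dx <- raw$dx - profile
  cum <- c(0, cumsum(dx))
  tKnots <- c(raw$t_s[1] - mean(diff(raw$t_s)), raw$t_s)
  # cumulative displacement *after* the frame at t is cum[i + 1]
  nOut <- floor((raw$t_s[length(raw$t_s)] - tKnots[1]) * fsOut + 1e-9)
  tOut <- tKnots[1] + seq(0, nOut) / fsOut
  cumOut <- approx(tKnots, cum, xout = tOut, rule = 2)$y
  data.frame(t_s = tOut[-1] - tKnots[1], dx = diff(cumOut))
}

#' Wrap an angle to [-180, 180)
#' @param angleDeg angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrapAngle <- function(angleDeg) ((angleDeg + 180) %% 360) - 180

#' Update the object azimuth from one step of walking
#'
#' Sign convention: rightward fly displacement is positive `dx`; object
#' angle is positive to the fly's right; leftward walking shifts the object
#' rightward, i.e. `angle' = wrap(angle - gain * dx)`.
#'
#' @param angleDeg current object azimuth in degrees, in \[-180, 180).
#' @param dx lateral displacement this step (arena-units; rightward > 0).
#' @param cfg an [arenaConfig()].
#' @return updated azimuth, wrapped to \[-180, 180).
#' @seealso [objectVisible()]
#' @export
updateObjectPosition <- function(angleDeg, dx, cfg = arenaConfig()) {
  stopifnot(all(is.finite(dx)))
  wrapAngle(angleDeg - cfg$gainDegPerUnit * dx)
}

#' Is the object on the display?
#'
#' The display spans azimuth +/-135 deg; the object state keeps being
#' tracked when it is behind the fly, but is flagged invisible.
#'
#' @param angleDeg azimuth in degrees.
#' @return logical.
#' @export
objectVisible <- function(angleDeg) abs(wrapAngle(angleDeg)) <= 135

#' Build a balanced, pseudo-random trial schedule
#'
#' Conditions are repeated equally often (e.g. 2 conditions x 5 repeats = 10
#' trials) in a seed-reproducible pseudo-random order. Each trial draws its
#' initial object side (-60 or +60 deg) from the same stream. For
#' photostimulation conditions the pulse duration is half the period (50 %
#' duty), e.g. 500 ms at 1 Hz and 83.3 ms at 6 Hz.
#'
#' @param nTrials total number of trials; must be divisible by the number of
#'   conditions.
#' @param conditions character vector of condition labels.
#' @param seed integer seed for the trial order and object sides.
#' @param recordingS closed-loop recording duration per trial (5 s for the
#'   small-spot paradigm, 30 s for bar fixation and no-puff experiments).
#' @param photostimHz optional numeric vector, one frequency per condition
#'   (NA for no light), recycled across repeats.
#' @return a [StimulusSchedule-class].
#' @export
makeSchedule <- function(nTrials, conditions, seed = 0L, recordingS = 5,
                         photostimHz = NULL) {
  nCond <- length(conditions)
  if (nCond < 1L || nTrials %% nCond != 0L)
    stop("nTrials must be a positive multiple of the number of conditions")
  if (!is.null(photostimHz) && length(photostimHz) != nCond)
    stop("photostimHz must give one frequency (or NA) per condition")
  reps <- nTrials / nCond
  cond <- rep(conditions, each = reps)
  freq <- if (is.null(photostimHz)) rep(NA_real_, nTrials) else
    rep(photostimHz, each = reps)
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(nTrials)
    side <- sample(c(-60, 60), nTrials, replace = TRUE)
  })
  trials <- data.frame(
    trial = seq_len(nTrials),
    condition = cond[ord],
    object_side_deg = side,
    recording_s = recordingS,
    photostim_hz = freq[ord]
  )
  trials$pulse_ms <- ifelse(is.na(trials$photostim_hz), NA_real_,
                            1000 * 0.5 / trials$photostim_hz)
  methods::new("StimulusSchedule", trials = trials, seed = as.numeric(seed))
}

#' Imaging stimulus timeline
#'
#' The calcium-imaging paradigm interleaves rest, a 5 s visual-object window
#' before any puff, two 10 s puff blocks (10 pulses at 1 Hz each) and a 5 s
#' visual window immediately after the second block ("forward"), or the same
#' segments in reversed order ("reverse"). A visual segment is flagged
#' `gated` when a puff block ended no more than `gateS` seconds before its
#' onset.
#'
#' @param direction `"forward"` or `"reverse"`.
#' @param gateS gate persistence after puff offset in seconds (default 6;
#'   observed to persist up to 6 s and be gone by 10 s).
#' @return a [StimulusSchedule-class] with an `events` timeline.
#' @export
imagingSchedule <- function(direction = c("forward", "reverse"), gateS = 6) {
  direction <- match.arg(direction)
  seg <- if (direction == "forward") {
    # rest > visual > rest > puff > rest > puff > visual > rest
    data.frame(
      kind = c("rest", "visual", "rest", "puff", "rest", "puff", "visual", "rest"),
      dur = c(10, 5, 15, 10, 10, 10, 5, 10)
    )
  } else {
    # rest > puff > visual > rest > puff > rest > visual > rest
    data.frame(
      kind = c("rest", "puff", "visual", "rest", "puff", "rest", "visual", "rest"),
      dur = c(10, 10, 5, 15, 10, 10, 5, 10)
    )
  }
  tOff <- cumsum(seg$dur)
  events <- data.frame(kind = seg$kind, t_on_s = tOff - seg$dur, t_off_s = tOff)
  events$gated <- FALSE
  puffOffs <- events$t_off_s[events$kind == "puff"]
  vis <- which(events$kind == "visual")
  for (i in vis) {
    gap <- events$t_on_s[i] - puffOffs[puffOffs <= events$t_on_s[i] + 1e-9]
    events$gated[i] <- length(gap) > 0 && min(gap) <= gateS
  }
  methods::new("StimulusSchedule", events = events)
}

#' Run the closed loop over a schedule
#'
#' Integrates [updateObjectPosition()] at 10 Hz over each trial's recording
#' window. The agent is either a function `f(trial, step, angleDeg)`
#' returning the displacement for that step (so simulated behavior can react
#' to the object's current position), or a list of per-trial numeric vectors
#' replayed open-loop.
#'
#' @param agent function or list of numeric vectors (one per trial).
#' @param schedule a [StimulusSchedule-class] with a trial table.
#' @param cfg an [arenaConfig()].
#' @param fs loop rate in Hz (default 10).
#' @return data.frame with columns `trial`, `t_s`, `dx`, `object_side`
#'   (sign of the azimuth when the step began), `angle_deg` (azimuth after
#'   the step) and `visible`.
#' @export
runClosedLoop <- function(agent, schedule, cfg = arenaConfig(), fs = 10) {
  trials <- scheduleTrials(schedule)
  if (nrow(trials) == 0L) stop("schedule has no trials")
  isFun <- is.function(agent)
  if (!isFun && length(agent) != nrow(trials))
    stop("agent must supply one displacement vector per trial")
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    nStep <- round(trials$recording_s[i] * fs)
    if (!isFun && length(agent[[i]]) != nStep)
      stop("agent displacement vector length does not match the recording window")
    angle <- trials$object_side_deg[i]
    dxs <- numeric(nStep); angles <- numeric(nStep); sides <- numeric(nStep)
    for (k in seq_len(nStep)) {
      sides[k] <- sign(angle)
      dx <- if (isFun) agent(i, k, angle) else agent[[i]][k]
      angle <- updateObjectPosition(angle, dx, cfg)
      dxs[k] <- dx
      angles[k] <- angle
    }
    out[[i]] <- data.frame(
      trial = trials$trial[i], t_s = seq_len(nStep) / fs, dx = dxs,
      object_side = sides, angle_deg = angles, visible = objectVisible(angles)
    )
  }
  do.call(rbind, out)
}
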