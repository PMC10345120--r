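# Seed-controlled synthetic cohorts with the statistical structure the
# analysis pipeline assumes: Markov-switching behavior states whose post-puff
# dynamics favor walking, a puff-gated aversive walking bias, calcium traces
# with puff-evoked accumulation/decay in a configurable fraction of cells,
# and a theta-band sinusoid injected only into puff-responsive cells during
# gated visual windows.

#' Behavior state labels used throughout the package
#' @export
behaviorStates <- function() {
  c("grooming", "PER", "stopping", "walking", "flight", "stuck", "freeze")
}

#' Default behavior-state transition matrix
#'
#' Row-stochastic matrices over the seven behavior states at the 10 Hz
#' analysis rate, built as `P = (1 - m) * I + m * 1 w'` so that the
#' stationary distribution is exactly the target weight vector `w`. The
#' baseline target is dominated by grooming and stopping with modest walking
#' (well under the 25 % hyperactivity threshold); the post-puff target is
#' dominated by walking. The rare states (flight, stuck, freeze) carry small
#' nonzero mass so exclusion filters can be exercised.
#'
#' @param kind `"baseline"` or `"postpuff"`.
#' @param mixing probability of leaving the diagonal kernel per step.
#' @return a 7 x 7 row-stochastic matrix with dimnames.
#' @export
defaultTransitionMatrix <- function(kind = c("baseline", "postpuff"),
                                    mixing = 0.1) {
  kind <- match.arg(kind)
  states <- behaviorStates()
  w <- switch(kind,
    baseline = c(grooming = 0.40, PER = 0.05, stopping = 0.38, walking = 0.12,
                 flight = 0.02, stuck = 0.02, freeze = 0.01),
    postpuff = c(grooming = 0.06, PER = 0.02, stopping = 0.10, walking = 0.78,
                 flight = 0.02, stuck = 0.01, freeze = 0.01)
  )
  P <- (1 - mixing) * diag(length(states)) +
    mixing * matrix(w, nrow = length(states), ncol = length(states),
                    byrow = TRUE)
  dimnames(P) <- list(states, states)
  P
}

#' Stationary distribution of a transition matrix
#' @param P row-stochastic matrix.
#' @return the stationary probability vector.
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study conditions the analysis assumes: a binary
#' aversion gate persisting 6 s after puff offset (observed to persist up to
#' 6 s and be gone by 10 s), calcium responses that accumulate while puffs
#' are applied and return to baseline in about 10 s afterwards
#' (`decayTauS = 2.5` gives < 2 % residual at 10 s), 64 % of cells
#' responding to puffs, a 6 Hz theta component during gated visual windows,
#' and 152 Hz trace sampling.
#'
#' @param seed master integer seed; every generated fly and cell derives a
#'   child seed from it (see Details).
#' @param nFlies,nTrialsPerFly cohort size (defaults 20 flies x 10 trials,
#'   5 puff- and 5 puff+ per fly).
#' @param transitionBaseline,transitionPostpuff row-stochastic 7 x 7
#'   matrices over [behaviorStates()].
#' @param aversionGain strength of the away-bias while the gate is open, in
#'   \[0, 1\]: a walking step moves away from the object with probability
#'   `(1 + gain) / 2`.
#' @param gateDurationS gate persistence after the last puff offset (s).
#' @param gateMode `"binary"` (default) or `"exponential"`, in which case
#'   the away-bias decays as `exp(-t / (gateDurationS / 2))` after puff
#'   offset instead of switching off.
#' @param walkSpeedMeanSd length-2 numeric, mean and sd of walking speed in
#'   arena-units/s.
#' @param responderFraction expected fraction of puff-responsive cells
#'   (default 0.64; about 36 % of cells show no calcium elevation).
#' @param puffRiseRate percent dF/F0 added per puff in responder cells.
#' @param riseAmpSdLog lognormal sd of the per-cell response amplitude
#'   factor (0 = homogeneous responses; the true across-cell distribution is
#'   heterogeneous but unquantified, so it is exposed here as a knob).
#' @param decayTauS exponential decay time constant after puff offset (s).
#' @param thetaFreqHz,thetaAmp frequency (Hz) and amplitude (percent dF/F0)
#'   of the oscillatory component injected during gated visual windows.
#' @param noiseSd Gaussian noise sd on dF/F0 (percent).
#' @param fsHz calcium trace sampling rate (Hz); must exceed twice
#'   `thetaFreqHz`.
#' @param preS,labelingRate behavioral-trial plumbing: pre-puff baseline
#'   duration (s) and expected fraction of frames labeled above the 70 %
#'   confidence threshold.
#'
#' @details Child seeds are derived as
#' `(seed * 48271 + stream * 65537) mod (2^31 - 1)`, with a distinct stream
#' index per fly and per cell, so cohorts are reproducible entity-by-entity.
#'
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(seed = 1L,
                            nFlies = 20L,
                            nTrialsPerFly = 10L,
                            transitionBaseline = defaultTransitionMatrix("baseline"),
                            transitionPostpuff = defaultTransitionMatrix("postpuff"),
                            aversionGain = 0.6,
                            gateDurationS = 6,
                            gateMode = c("binary", "exponential"),
                            walkSpeedMeanSd = c(1, 0.2),
                            responderFraction = 0.64,
                            puffRiseRate = 5,
                            riseAmpSdLog = 0,
                            decayTauS = 2.5,
                            thetaFreqHz = 6,
                            thetaAmp = 5,
                            noiseSd = 1,
                            fsHz = 152,
                            preS = 5,
                            labelingRate = 0.93) {
  gateMode <- match.arg(gateMode)
  checkStochastic <- function(P, name) {
    if (!is.matrix(P) || nrow(P) != 7L || ncol(P) != 7L)
      stop(name, " must be a 7 x 7 matrix over the behavior states")
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
      stop(name, " must be row-stochastic (rows summing to 1)")
  }
  checkStochastic(transitionBaseline, "transitionBaseline")
  checkStochastic(transitionPostpuff, "transitionPostpuff")
  stopifnot(aversionGain >= 0, aversionGain <= 1,
            responderFraction >= 0, responderFraction <= 1,
            labelingRate >= 0, labelingRate <= 1,
            gateDurationS > 0, decayTauS > 0, fsHz > 0,
            length(walkSpeedMeanSd) == 2L, walkSpeedMeanSd[1] > 0)
  if (fsHz <= 2 * thetaFreqHz)
    stop("fsHz must exceed twice thetaFreqHz (Nyquist)")
  structure(list(
    seed = as.integer(seed), nFlies = as.integer(nFlies),
    nTrialsPerFly = as.integer(nTrialsPerFly),
    transitionBaseline = transitionBaseline,
    transitionPostpuff = transitionPostpuff,
    aversionGain = aversionGain, gateDurationS = gateDurationS,
    gateMode = gateMode, walkSpeedMeanSd = walkSpeedMeanSd,
    responderFraction = responderFraction, puffRiseRate = puffRiseRate,
    riseAmpSdLog = riseAmpSdLog, decayTauS = decayTauS,
    thetaFreqHz = thetaFreqHz, thetaAmp = thetaAmp, noiseSd = noiseSd,
    fsHz = fsHz, preS = preS, labelingRate = labelingRate
  ), class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "SyntheticConfig: %d flies x %d trials, gain %.2g (%s gate, %.3g s)\n",
    "  responders %.0f%%, rise %.3g %%/puff, tau %.3g s, theta %g Hz x %.3g%%,",
    " noise %.3g%%, fs %g Hz, seed %d\n"),
    x$nFlies, x$nTrialsPerFly, x$aversionGain, x$gateMode, x$gateDurationS,
    100 * x$responderFraction, x$puffRiseRate, x$decayTauS, x$thetaFreqHz,
    x$thetaAmp, x$noiseSd, x$fsHz, x$seed))
  invisible(x)
}

childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 65537) %%
               2147483647)
}

sampleMarkov <- function(n, P, start) {
  states <- seq_len(nrow(P))
  out <- integer(n)
  s <- start
  for (i in seq_len(n)) {
    s <- sample.int(length(states), 1L, prob = P[s, ])
    out[i] <- s
  }
  out
}

#' Generate a synthetic behavioral cohort
#'
#' Each fly receives a balanced pseudo-random schedule of puff- and puff+
#' trials. A trial consists of a baseline segment (`preS` s), a 10 s puff
#' block (puff+ only; puff- flies rest), and a closed-loop recording window
#' (5 s) with the object starting at -60 or +60 deg. Behavior states follow
#' the baseline transition matrix except from puff onset until the gate
#' expires (`gateDurationS` after the last puff offset), where the post-puff
#' matrix applies. While the gate is open and the state is walking, each
#' 10 Hz step moves away from the object's current side with probability
#' `(1 + aversionGain) / 2`; ungated walking is unbiased. Label streams
#' carry the true state with a per-frame confidence; a configurable fraction
#' of frames falls below the 70 % threshold and is emitted as `"unlabeled"`.
#'
#' @param cfg a [syntheticConfig()].
#' @param arenaCfg an [arenaConfig()].
#' @return list of class `"FlyCohort"`: `tracking` (fly_id, trial,
#'   condition, t_s, dx, object_side, angle_deg), `labels` (fly_id, trial,
#'   condition, t_s, label, confidence; t_s < 0 precedes the recording
#'   window), `truth` (per-trial gate windows and conditions), `config`.
#' @export
genBehaviorCohort <- function(cfg = syntheticConfig(), arenaCfg = arenaConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  fs <- 10
  dt <- 1 / fs
  puffS <- 10
  recS <- 5
  states <- behaviorStates()
  iWalk <- match("walking", states)
  trackL <- vector("list", cfg$nFlies)
  labelL <- vector("list", cfg$nFlies)
  truthL <- vector("list", cfg$nFlies)
  for (f in seq_len(cfg$nFlies)) {
    sched <- makeSchedule(cfg$nTrialsPerFly, c("puff-", "puff+"),
                          seed = childSeed(cfg$seed, f), recordingS = recS)
    trials <- scheduleTrials(sched)
    withr::with_seed(childSeed(cfg$seed, 100000L + f), {
      trialTrack <- vector("list", nrow(trials))
      trialLabel <- vector("list", nrow(trials))
      for (ti in seq_len(nrow(trials))) {
        puffed <- trials$condition[ti] == "puff+"
        nPre <- round(cfg$preS * fs); nPuff <- round(puffS * fs)
        nRec <- round(recS * fs)
        # state chain: baseline during pre (and the whole trial if puff-),
        # post-puff matrix from puff onset until gate expiry
        s0 <- sample.int(7L, 1L, prob = stationaryDistribution(cfg$transitionBaseline))
        chainPre <- sampleMarkov(nPre, cfg$transitionBaseline, s0)
        if (puffed) {
          chainPuff <- sampleMarkov(nPuff, cfg$transitionPostpuff,
                                    chainPre[nPre])
          nGate <- min(nRec, round(cfg$gateDurationS * fs))
          chainRec <- sampleMarkov(nGate, cfg$transitionPostpuff,
                                   chainPuff[nPuff])
          if (nGate < nRec)
            chainRec <- c(chainRec,
                          sampleMarkov(nRec - nGate, cfg$transitionBaseline,
                                       chainRec[nGate]))
        } else {
          chainPuff <- sampleMarkov(nPuff, cfg$transitionBaseline,
                                    chainPre[nPre])
          chainRec <- sampleMarkov(nRec, cfg$transitionBaseline,
                                   chainPuff[nPuff])
        }
        # closed-loop recording: gated walking is biased away from the
        # object's current side
        angle <- trials$object_side_deg[ti]
        dxs <- numeric(nRec); sides <- numeric(nRec); angles <- numeric(nRec)
        for (k in seq_len(nRec)) {
          sides[k] <- sign(angle)
          dx <- 0
          if (chainRec[k] == iWalk) {
            speed <- abs(rnorm(1, cfg$walkSpeedMeanSd[1], cfg$walkSpeedMeanSd[2]))
            tRec <- (k - 1) * dt
            gain <- if (!puffed) 0
              else if (cfg$gateMode == "binary") {
                if (tRec < cfg$gateDurationS) cfg$aversionGain else 0
              } else cfg$aversionGain * exp(-tRec / (cfg$gateDurationS / 2))
            pAway <- (1 + gain) / 2
            away <- -sides[k]
            if (away == 0) away <- sample(c(-1, 1), 1L)
            dir <- if (runif(1) < pAway) away else -away
            dx <- dir * speed * dt
          }
          angle <- updateObjectPosition(angle, dx, arenaCfg)
          dxs[k] <- dx; angles[k] <- angle
        }
        trialTrack[[ti]] <- data.frame(
          fly_id = f, trial = ti, condition = trials$condition[ti],
          t_s = seq_len(nRec) / fs, dx = dxs, object_side = sides,
          angle_deg = angles)
        chain <- c(chainPre, chainPuff, chainRec)
        tAll <- seq_along(chain) * dt - (cfg$preS + puffS)
        conf <- ifelse(runif(length(chain)) < cfg$labelingRate,
                       runif(length(chain), 0.72, 0.999),
                       runif(length(chain), 0.30, 0.70))
        trialLabel[[ti]] <- data.frame(
          fly_id = f, trial = ti, condition = trials$condition[ti],
          t_s = tAll,
          label = ifelse(conf > 0.7, states[chain], "unlabeled"),
          confidence = conf)
      }
    })
    trackL[[f]] <- do.call(rbind, trialTrack)
    labelL[[f]] <- do.call(rbind, trialLabel)
    truthL[[f]] <- data.frame(
      fly_id = f, trial = trials$trial, condition = trials$condition,
      object_side_deg = trials$object_side_deg,
      gate_on_s = ifelse(trials$condition == "puff+", 0, NA_real_),
      gate_off_s = ifelse(trials$condition == "puff+",
                          pmin(cfg$gateDurationS, recS), NA_real_))
  }
  structure(list(tracking = do.call(rbind, trackL),
                 labels = do.call(rbind, labelL),
                 truth = do.call(rbind, truthL),
                 config = cfg),
            class = "FlyCohort")
}

#' @export
print.FlyCohort <- function(x, ...) {
  cat(sprintf("FlyCohort: %d flies, %d trials, %d tracking samples\n",
              length(unique(x$tracking$fly_id)),
              nrow(x$truth), nrow(x$tracking)))
  invisible(x)
}

#' Generate a synthetic calcium-imaging cohort
#'
#' Responder cells accumulate `puffRiseRate` percent dF/F0 at each puff
#' onset, hold while the puff block lasts, and decay exponentially with
#' `decayTauS` after the block ends (returning to baseline in about 10 s at
#' the default). During visual windows flagged as gated (those following a
#' puff block within the gate duration) responder cells additionally carry a
#' `thetaFreqHz` sinusoid of amplitude `thetaAmp` with a random phase per
#' cell. Gaussian noise is added everywhere; non-responders carry noise
#' only. Fluorescence is reconstructed as `F = 100 * (1 + dff / 100)`.
#'
#' @param cfg a [syntheticConfig()].
#' @param nCells number of cells (> 0).
#' @param schedule a [StimulusSchedule-class] with an imaging `events`
#'   timeline (default [imagingSchedule()]`("forward")`).
#' @param thetaCells `"responders"` (the modeled condition) or
#'   `"nonresponders"` (an adversarial fixture in which the oscillation is
#'   injected into the wrong cells, used to test responder restriction).
#' @return a [CalciumExperiment-class]; `rowData` carries the ground-truth
#'   `responder` flag and per-cell amplitude factor.
#' @export
genCalciumCohort <- function(cfg = syntheticConfig(), nCells = 200L,
                             schedule = imagingSchedule("forward"),
                             thetaCells = c("responders", "nonresponders")) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  thetaCells <- match.arg(thetaCells)
  if (nCells < 1L) stop("nCells must be positive")
  events <- scheduleEvents(schedule)
  if (nrow(events) == 0L || !any(events$kind == "puff"))
    stop("schedule must contain puff and visual windows")
  fs <- cfg$fsHz
  totalS <- max(events$t_off_s)
  t <- seq(0, totalS - 1 / fs, by = 1 / fs)
  n <- length(t)
  # shared puff-evoked response template: step up at each onset, hold within
  # the block, exponential decay outside
  level <- numeric(n)
  puffEvents <- events[events$kind == "puff", , drop = FALSE]
  onsetTimes <- unlist(lapply(puffEvents$t_on_s,
                              function(s) puffOnsets(schedule, s)))
  blockSpans <- cbind(puffEvents$t_on_s, puffEvents$t_off_s)
  lev <- 0
  onIdx <- rep(FALSE, n)
  onIdx[pmin(n, floor(onsetTimes * fs) + 1L)] <- TRUE
  inBlock <- rowSums(outer(t, blockSpans[, 1], ">=") &
                       outer(t, blockSpans[, 2], "<")) > 0
  decay <- exp(-1 / (fs * cfg$decayTauS))
  for (i in seq_len(n)) {
    if (onIdx[i]) lev <- lev + cfg$puffRiseRate
    else if (!inBlock[i]) lev <- lev * decay
    level[i] <- lev
  }
  visEvents <- events[events$kind == "visual" & events$gated, , drop = FALSE]
  inGatedVis <- rowSums(outer(t, visEvents$t_on_s, ">=") &
                          outer(t, visEvents$t_off_s, "<")) > 0
  dff <- matrix(0, nCells, n)
  responder <- logical(nCells)
  amp <- numeric(nCells)
  phase <- numeric(nCells)
  for (c_ in seq_len(nCells)) {
    withr::with_seed(childSeed(cfg$seed, 200000L + c_), {
      responder[c_] <- runif(1) < cfg$responderFraction
      amp[c_] <- if (cfg$riseAmpSdLog > 0)
        exp(rnorm(1, -cfg$riseAmpSdLog^2 / 2, cfg$riseAmpSdLog)) else 1
      phase[c_] <- runif(1, 0, 2 * pi)
      tr <- numeric(n)
      if (responder[c_]) tr <- amp[c_] * level
      thetaHere <- if (thetaCells == "responders") responder[c_] else !responder[c_]
      if (thetaHere && cfg$thetaAmp > 0 && any(inGatedVis))
        tr[inGatedVis] <- tr[inGatedVis] +
          cfg$thetaAmp * sin(2 * pi * cfg$thetaFreqHz * t[inGatedVis] + phase[c_])
      if (cfg$noiseSd > 0) tr <- tr + rnorm(n, 0, cfg$noiseSd)
      dff[c_, ] <- tr
    })
  }
  F <- 100 * (1 + dff / 100)
  ce <- CalciumExperiment(F, fsHz = fs, events = events,
                          rowData = S4Vectors::DataFrame(
                            responder = responder, amp_factor = amp,
                            theta_phase = phase))
  S4Vectors::metadata(ce)$config <- cfg
  ce
}

#' Render traces into a synthetic soma movie
#'
#' Each soma is drawn as an isotropic 2-D Gaussian whose amplitude follows
#' its trace, on a constant background, with optional shot-like noise whose
#' sd scales with the square root of intensity. Intended as a round-trip
#' fixture for ROI extraction.
#'
#' @param traces numeric matrix, cells x frames (arbitrary units).
#' @param layout data.frame with columns `x`, `y` (pixel centers) and
#'   `sigma` (Gaussian width, pixels). Somata must lie within the frame with
#'   a 3-sigma margin and must not overlap (center distance greater than 3
#'   times the summed sigmas).
#' @param imageSize length-2 integer, `c(height, width)`.
#' @param noiseSd shot-noise scale (0 = noiseless).
#' @param seed integer seed for the noise.
#' @param background constant background level.
#' @return numeric array `frames x height x width`.
#' @export
genFrameStack <- function(traces, layout, imageSize = c(32, 32), noiseSd = 0,
                          seed = 0L, background = 10) {
  traces <- as.matrix(traces)
  H <- imageSize[1]; W <- imageSize[2]
  stopifnot(nrow(layout) == nrow(traces),
            all(c("x", "y", "sigma") %in% names(layout)))
  if (any(layout$x - 3 * layout$sigma < 1 | layout$x + 3 * layout$sigma > W |
          layout$y - 3 * layout$sigma < 1 | layout$y + 3 * layout$sigma > H))
    stop("soma positions must lie within the frame with a 3-sigma margin")
  if (nrow(layout) > 1L) {
    d <- as.matrix(dist(layout[, c("x", "y")]))
    lim <- outer(layout$sigma, layout$sigma, `+`) * 3
    diag(d) <- Inf
    if (any(d <= lim)) stop("soma footprints overlap")
  }
  kernels <- lapply(seq_len(nrow(layout)), function(i) {
    gx <- exp(-((seq_len(W) - layout$x[i])^2) / (2 * layout$sigma[i]^2))
    gy <- exp(-((seq_len(H) - layout$y[i])^2) / (2 * layout$sigma[i]^2))
    outer(gy, gx)
  })
  nF <- ncol(traces)
  movie <- array(background, dim = c(nF, H, W))
  for (f in seq_len(nF)) {
    img <- matrix(background, H, W)
    for (i in seq_along(kernels)) img <- img + traces[i, f] * kernels[[i]]
    movie[f, , ] <- img
  }
  if (noiseSd > 0) {
    withr::with_seed(as.integer(seed), {
      noise <- array(rnorm(length(movie), 0,
                           noiseSd * sqrt(pmax(as.vector(movie), 0) + 1)),
                     dim = dim(movie))
    })
    movie <- movie + noise
  }
  movie
}

# procedural glyphs: one distinct shape per behavior class, drawn on
# normalized [-1, 1] coordinates
glyphMask <- function(class, x, y) {
  r <- sqrt(x^2 + y^2)
  switch(class,
    walking = abs(y) < 0.15 & abs(x) < 0.7,                  # horizontal bar
    PER = abs(x) < 0.15 & abs(y) < 0.7,                      # vertical bar
    grooming = r > 0.45 & r < 0.75,                          # ring
    stopping = abs(x) < 0.45 & abs(y) < 0.45,                # filled square
    stuck = (abs(x - y) < 0.18 | abs(x + y) < 0.18) & r < 0.8,   # X
    freeze = (abs(x) < 0.15 | abs(y) < 0.15) & pmax(abs(x), abs(y)) < 0.7, # +
    flight = abs(y - 1.2 * abs(x) + 0.4) < 0.15 & abs(x) < 0.7,  # V
    stop("no glyph defined for class ", class)
  )
}

renderGlyph <- function(class, H, W, shift = c(0, 0), angleDeg = 0,
                        scale = 1, amp = 1, noiseSd = 0) {
  xs <- (seq_len(W) - (W + 1) / 2) / (W / 2)
  ys <- (seq_len(H) - (H + 1) / 2) / (H / 2)
  g <- expand.grid(y = ys, x = xs)
  xg <- (g$x - shift[1]) / scale
  yg <- (g$y - shift[2]) / scale
  th <- angleDeg * pi / 180
  xr <- cos(th) * xg + sin(th) * yg
  yr <- -sin(th) * xg + cos(th) * yg
  img <- matrix(as.numeric(glyphMask(class, xr, yr)) * amp, H, W)
  if (noiseSd > 0) img <- img + matrix(rnorm(H * W, 0, noiseSd), H, W)
  pmin(pmax(img, 0), 1)
}

#' Generate a labeled procedural-glyph image set
#'
#' Stands in for behavior-video frames: each class is rendered as a distinct
#' glyph (bars, ring, square, X, +, V) with within-class jitter in position,
#' rotation, scale and intensity plus pixel noise. Counts are exactly
#' balanced. Grayscale glyphs are replicated across 3 channels to match the
#' classifier's input convention.
#'
#' @param nPerClass images per class.
#' @param classes character vector of class names (>= 2); defaults to the
#'   seven behavior states.
#' @param imageSize `c(height, width)`, at least 16 x 16.
#' @param jitter jitter magnitude multiplier (0 = identical images within a
#'   class).
#' @param noiseSd pixel noise sd.
#' @param seed integer seed.
#' @return list with `x` (array `n x H x W x 3` in \[0, 1\]), `y` (factor of
#'   labels) and `classes`.
#' @export
genClassifierDataset <- function(nPerClass, classes = behaviorStates(),
                                 imageSize = c(64, 64), jitter = 1,
                                 noiseSd = 0.05, seed = 0L) {
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (min(imageSize) < 16L) stop("imageSize too small to render glyphs")
  H <- imageSize[1]; W <- imageSize[2]
  n <- nPerClass * length(classes)
  x <- array(0, dim = c(n, H, W, 3))
  y <- character(n)
  withr::with_seed(as.integer(seed), {
    i <- 0L
    for (cl in classes) {
      for (k in seq_len(nPerClass)) {
        i <- i + 1L
        img <- renderGlyph(cl, H, W,
                           shift = runif(2, -0.1, 0.1) * jitter,
                           angleDeg = runif(1, -10, 10) * jitter,
                           scale = 1 + runif(1, -0.1, 0.1) * jitter,
                           amp = 1 - runif(1, 0, 0.3) * jitter,
                           noiseSd = noiseSd)
        x[i, , , ] <- array(img, dim = c(H, W, 3))
        y[i] <- cl
      }
    }
  })
  list(x = x, y = factor(y, levels = classes), classes = classes)
}

#' Generate a raw tracking stream
#'
#' Fixture generator for the calibration/downsampling path: frames at
#' `fsHz` (~192 Hz in the modeled rig) whose per-frame displacement is the
#' integral of a velocity profile plus a constant left-right asymmetry and
#' optional Gaussian noise.
#'
#' @param durationS length of the stream (s).
#' @param fsHz tracker frame rate (Hz).
#' @param velocity scalar (arena-units/s) or function of time returning
#'   instantaneous velocity.
#' @param asymmetry constant per-frame offset (counts/frame).
#' @param noiseSd per-frame noise sd.
#' @param seed integer seed.
#' @return data.frame with `t_s`, `dx`.
#' @export
genTrackingRaw <- function(durationS = 60, fsHz = 192, velocity = 0,
                           asymmetry = 0, noiseSd = 0, seed = 0L) {
  dt <- 1 / fsHz
  t <- seq(dt, durationS, by = dt)
  v <- if (is.function(velocity)) vapply(t - dt / 2, velocity, numeric(1))
       else rep(velocity, length(t))
  dx <- v * dt + asymmetry
  if (noiseSd > 0)
    dx <- dx + withr::with_seed(as.integer(seed),
                                rnorm(length(t), 0, noiseSd))
  data.frame(t_s = t, dx = dx)
}
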