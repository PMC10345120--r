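# Ethogram post-processing: confidence thresholding of per-frame class
# probabilities, the trial and fly exclusion filters, behavior probabilities
# over an analysis window and puff-induced per-fly changes.

#' Threshold per-frame class probabilities into a label stream
#'
#' A frame is assigned the most likely class only when its confidence
#' exceeds 70 % (strict); otherwise it is `"unlabeled"`.
#'
#' @param probs numeric matrix, frames x classes; each row must sum to 1
#'   within 1e-6.
#' @param classes class names (defaults to `colnames(probs)`).
#' @param times optional frame times in seconds.
#' @param threshold confidence threshold (default 0.7).
#' @return data.frame with `t_s`, `label`, `confidence`.
#' @export
thresholdLabels <- function(probs, classes = colnames(probs), times = NULL,
                            threshold = 0.7) {
  probs <- as.matrix(probs)
  if (is.null(classes)) stop("class names are required")
  if (ncol(probs) != length(classes))
    stop("probs must have one column per class")
  if (any(!is.finite(probs)) || any(probs < -1e-9) ||
      any(abs(rowSums(probs) - 1) > 1e-6))
    stop("malformed probability rows: each row must be a distribution summing to 1")
  conf <- apply(probs, 1L, max)
  idx <- max.col(probs, ties.method = "first")
  data.frame(
    t_s = if (is.null(times)) seq_len(nrow(probs)) - 1 else times,
    label = ifelse(conf > threshold, classes[idx], "unlabeled"),
    confidence = conf
  )
}

labelFractions <- function(stream) {
  labeled <- stream$label != "unlabeled"
  nLabeled <- sum(labeled)
  frac <- function(which) if (nLabeled == 0) 0 else
    sum(stream$label[labeled] %in% which) / nLabeled
  list(rate = mean(labeled),
       stuckFreeze = frac(c("stuck", "freeze")),
       stuck = frac("stuck"), freeze = frac("freeze"),
       flight = frac("flight"))
}

#' Apply the per-trial exclusion rules
#'
#' Rules, applied in order on one trial's label stream: (1) discard when the
#' labeling rate falls below 70 %; (2) discard when "stuck" or "freeze"
#' account for more than 10 % of successful labels (by default their
#' combined fraction; set `combineStuckFreeze = FALSE` to test each
#' separately); (3) keep but exclude from locomotion/aversion analyses when
#' "flight" exceeds 10 % of successful labels. All comparisons are strict.
#'
#' @param stream a label stream data.frame (`label`, optionally `t_s`,
#'   `confidence`).
#' @param labelingRateMin minimum labeling rate (default 0.7).
#' @param stuckFreezeMax,flightMax fraction thresholds (default 0.1).
#' @param combineStuckFreeze logical; combine stuck + freeze before
#'   comparing (default TRUE).
#' @return list with `decision` (`"keep"`, `"discard"`, or
#'   `"exclude_locomotion_analyses"`) and `reasons` (character).
#' @export
applyTrialExclusions <- function(stream, labelingRateMin = 0.7,
                                 stuckFreezeMax = 0.1, flightMax = 0.1,
                                 combineStuckFreeze = TRUE) {
  if (!is.data.frame(stream) || nrow(stream) == 0L || !"label" %in% names(stream))
    stop("stream must be a nonempty data.frame with a label column")
  f <- labelFractions(stream)
  reasons <- character()
  if (f$rate < labelingRateMin)
    return(list(decision = "discard",
                reasons = sprintf("labeling rate %.3f below %.2f", f$rate,
                                  labelingRateMin)))
  sfExceeds <- if (combineStuckFreeze) f$stuckFreeze > stuckFreezeMax
    else f$stuck > stuckFreezeMax || f$freeze > stuckFreezeMax
  if (sfExceeds)
    return(list(decision = "discard",
                reasons = sprintf("stuck/freeze fraction %.3f above %.2f",
                                  f$stuckFreeze, stuckFreezeMax)))
  if (f$flight > flightMax) {
    return(list(decision = "exclude_locomotion_analyses",
                reasons = sprintf("flight fraction %.3f above %.2f",
                                  f$flight, flightMax)))
  }
  list(decision = "keep", reasons = reasons)
}

#' Behavior probabilities over an analysis window
#'
#' Probability of each analysis behavior among successfully labeled frames
#' within the window (default the initial 5 s of the recording). The
#' denominator is the count of all labeled frames in the window, so
#' probabilities over all labeled categories sum to 1.
#'
#' @param stream label stream with `t_s` and `label`.
#' @param window `c(from, to)` in seconds; frames with `from <= t_s < to`.
#' @param behaviors behaviors to report (default grooming, PER, stopping,
#'   walking).
#' @return named numeric vector of probabilities.
#' @export
behaviorProbabilities <- function(stream, window = c(0, 5),
                                  behaviors = c("grooming", "PER",
                                                "stopping", "walking")) {
  if (window[1] > max(stream$t_s) || window[2] <= min(stream$t_s))
    stop("analysis window lies outside the recording")
  inWin <- stream$t_s >= window[1] & stream$t_s < window[2]
  labels <- stream$label[inWin]
  labels <- labels[labels != "unlabeled"]
  if (length(labels) == 0L)
    stop("no successfully labeled frames in the analysis window")
  vapply(behaviors, function(b) mean(labels == b), numeric(1))
}

#' Exclude hyperactive flies
#'
#' Flies whose average walking probability during trials without puffs
#' exceeds 25 % (strict) are removed, indicating unusually high arousal.
#'
#' @param baselineWalk data.frame with `fly_id` and `p_walk_baseline`, the
#'   per-fly mean walking probability over puff- trials.
#' @param threshold default 0.25.
#' @return list with `kept` (data.frame), `excluded` (fly ids) and
#'   `n_excluded`.
#' @export
excludeHyperactiveFlies <- function(baselineWalk, threshold = 0.25) {
  stopifnot(all(c("fly_id", "p_walk_baseline") %in% names(baselineWalk)))
  if (nrow(baselineWalk) == 0L)
    stop("no flies with puff- trials available")
  hi <- baselineWalk$p_walk_baseline > threshold
  list(kept = baselineWalk[!hi, , drop = FALSE],
       excluded = baselineWalk$fly_id[hi],
       n_excluded = sum(hi))
}

#' Puff-induced change in behavior probabilities per fly
#'
#' For each fly and behavior, the mean probability over puff+ trials minus
#' the mean over puff- trials.
#'
#' @param probTable data.frame with `fly_id`, `condition` (`"puff-"` /
#'   `"puff+"`), and one numeric column per behavior (one row per trial or
#'   per fly x condition).
#' @param conditions length-2 character: the condition subtracted from and
#'   the reference condition.
#' @return data.frame with `fly_id` and one delta column per behavior.
#' @export
deltaProbabilities <- function(probTable,
                               conditions = c("puff+", "puff-")) {
  stopifnot(all(c("fly_id", "condition") %in% names(probTable)))
  behaviors <- setdiff(names(probTable), c("fly_id", "condition", "trial"))
  out <- lapply(split(probTable, probTable$fly_id), function(d) {
    a <- d[d$condition == conditions[1], behaviors, drop = FALSE]
    b <- d[d$condition == conditions[2], behaviors, drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L)
      stop("each fly needs trials in both conditions")
    cbind(data.frame(fly_id = d$fly_id[1]),
          as.data.frame(as.list(colMeans(a) - colMeans(b))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
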