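# Avoidance and bar-fixation (attraction) indices: signed distance
# decomposition of closed-loop trajectories, per-fly condition deltas, and
# baseline-rejection filtering.

#' Decompose a trajectory into away/toward distances
#'
#' Each 10 Hz step is classified by its instantaneous direction relative to
#' the object's side when the step began (the object moves in closed loop,
#' so the side is re-evaluated at every step): a step whose sign matches the
#' object's side is toward, opposite is away. Steps with zero displacement,
#' or taken while the object sits exactly at 0 deg, contribute to neither.
#'
#' @param traj data.frame with `t_s`, `dx` and `object_side` (sign of the
#'   object azimuth when the step began), as produced by [runClosedLoop()]
#'   or [genBehaviorCohort()].
#' @param window `c(from, to)` seconds; steps are bins ending at `t_s`, and
#'   bins with `from < t_s <= to` are used. Default 2-5 s, where directed
#'   walking manifests robustly.
#' @return named numeric `c(d_away, d_toward)` (arena-units, both >= 0).
#' @export
signedDistances <- function(traj, window = c(2, 5)) {
  stopifnot(all(c("t_s", "dx", "object_side") %in% names(traj)))
  sel <- traj$t_s > window[1] + 1e-9 & traj$t_s <= window[2] + 1e-9
  if (!any(sel)) stop("analysis window contains no trajectory steps")
  dx <- traj$dx[sel]
  side <- traj$object_side[sel]
  toward <- sum(abs(dx[sign(dx) * side > 0]))
  away <- sum(abs(dx[sign(dx) * side < 0]))
  c(d_away = away, d_toward = toward)
}

#' Avoidance index
#'
#' `AI = (d_away - d_toward) / (d_away + d_toward)`, in \[-1, 1\]; +1 is
#' pure avoidance, -1 pure approach. Undefined (NaN, with a warning) when
#' the fly did not move; such trials are dropped from per-fly means.
#'
#' @param dAway,dToward non-negative distances (arena-units); vectorized.
#' @return numeric avoidance index (or indices).
#' @export
avoidanceIndex <- function(dAway, dToward) {
  stopifnot(all(dAway >= 0), all(dToward >= 0))
  total <- dAway + dToward
  if (any(total == 0))
    warning("zero total displacement: avoidance index undefined (NaN)")
  ifelse(total > 0, (dAway - dToward) / total, NaN)
}

#' Attraction (bar-fixation) index
#'
#' Fraction of linear distance travelled toward the object:
#' `d_toward / (d_away + d_toward)`, in \[0, 1\]. Related to the avoidance
#' index by the identity `attraction = (1 - AI) / 2`.
#'
#' @inheritParams avoidanceIndex
#' @return numeric attraction index (or indices).
#' @export
attractionIndex <- function(dAway, dToward) {
  stopifnot(all(dAway >= 0), all(dToward >= 0))
  total <- dAway + dToward
  if (any(total == 0))
    warning("zero total displacement: attraction index undefined (NaN)")
  ifelse(total > 0, dToward / total, NaN)
}

#' Reject flies with high baseline avoidance
#'
#' Flies whose mean avoidance index without puffs/photoactivation exceeds
#' 0.4 (strict) are rejected: such high baseline aversion would mask any
#' gating effect. The observed rejection fraction is reported (about 10 % in
#' the modeled wild-type experiments).
#'
#' @param flyMeans data.frame with `fly_id` and `baseline_ai` (mean AI over
#'   the no-stimulus condition).
#' @param threshold default 0.4.
#' @return list with `kept`, `rejected` (fly ids) and `rejection_fraction`.
#' @export
rejectHighBaseline <- function(flyMeans, threshold = 0.4) {
  stopifnot(all(c("fly_id", "baseline_ai") %in% names(flyMeans)))
  if (nrow(flyMeans) == 0L) stop("no flies with baseline trials available")
  hi <- !is.na(flyMeans$baseline_ai) & flyMeans$baseline_ai > threshold
  list(kept = flyMeans[!hi, , drop = FALSE],
       rejected = flyMeans$fly_id[hi],
       rejection_fraction = mean(hi))
}

#' Per-fly change in avoidance index between conditions
#'
#' `dAI = mean AI(stimulus condition) - mean AI(reference condition)`, per
#' fly. Works for puff+/puff- as well as light+/light- designs.
#'
#' @param flyCondMeans data.frame with `fly_id`, `condition`, `mean_ai`.
#' @param conditions length-2 character: stimulus condition and reference
#'   condition.
#' @return data.frame with `fly_id` and `delta_ai`.
#' @export
deltaAvoidance <- function(flyCondMeans, conditions = c("puff+", "puff-")) {
  stopifnot(all(c("fly_id", "condition", "mean_ai") %in% names(flyCondMeans)))
  out <- lapply(split(flyCondMeans, flyCondMeans$fly_id), function(d) {
    a <- d$mean_ai[d$condition == conditions[1]]
    b <- d$mean_ai[d$condition == conditions[2]]
    if (length(a) == 0L || length(b) == 0L)
      stop("each fly needs both conditions to compute a change score")
    data.frame(fly_id = d$fly_id[1], delta_ai = mean(a) - mean(b))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-trial avoidance table for a cohort
#'
#' Applies [signedDistances()] and [avoidanceIndex()] to every trial of a
#' behavioral cohort. Trials with zero in-window displacement get NaN and
#' are excluded from per-fly means downstream.
#'
#' @param cohort a `"FlyCohort"` from [genBehaviorCohort()], or any tracking
#'   data.frame with `fly_id`, `trial`, `condition`, `t_s`, `dx`,
#'   `object_side`.
#' @param window analysis window in seconds (default 2-5 s).
#' @return data.frame with `fly_id`, `trial`, `condition`, `d_away`,
#'   `d_toward`, `ai`.
#' @export
avoidanceTable <- function(cohort, window = c(2, 5)) {
  tracking <- if (inherits(cohort, "FlyCohort")) cohort$tracking else cohort
  keys <- unique(tracking[, c("fly_id", "trial", "condition")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- tracking[tracking$fly_id == keys$fly_id[i] &
                     tracking$trial == keys$trial[i], ]
    d <- signedDistances(tr, window)
    ai <- suppressWarnings(avoidanceIndex(d["d_away"], d["d_toward"]))
    data.frame(fly_id = keys$fly_id[i], trial = keys$trial[i],
               condition = keys$condition[i],
               d_away = unname(d["d_away"]), d_toward = unname(d["d_toward"]),
               ai = unname(ai))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
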