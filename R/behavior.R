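## Go/no-go session scoring, block performance, ROC/AUC with Hanley-McNeil
## standard errors.

#' Classify one go/no-go trial
#'
#' A lick response requires at least one lick in every 0.5-s interval
#' (`criterion = "all"`, the task's reward rule); `"any"` accepts a single
#' licked interval. CS+ with a response is a hit, CS+ without a miss, CS-
#' with a response a false alarm, CS- without a correct rejection.
#'
#' @param csLabel "CS+" or "CS-".
#' @param intervalLicks 0/1 (or lick-count) vector, one entry per interval.
#' @param criterion "all" or "any".
#' @return one of "hit", "miss", "false_alarm", "correct_rejection".
#' @export
classifyTrial <- function(csLabel, intervalLicks,
                          criterion = c("all", "any")) {
  criterion <- match.arg(criterion)
  stopifnot(csLabel %in% c("CS+", "CS-"))
  licked <- intervalLicks > 0
  response <- if (criterion == "all") all(licked) else any(licked)
  if (csLabel == "CS+") {
    if (response) "hit" else "miss"
  } else {
    if (response) "false_alarm" else "correct_rejection"
  }
}

#' Per-block performance and learning criterion
#'
#' Scores every valid trial, tabulates hits/misses/false alarms/correct
#' rejections per block, and evaluates the learning criterion:
#' `mode = "two_blocks"` (default) requires at least `criterionPct` percent
#' correct in at least two blocks anywhere in the session;
#' `mode = "three_consecutive"` requires three consecutive such blocks.
#'
#' @param session a [Session-class].
#' @param criterionPct percent-correct criterion (85 in the study).
#' @param mode "two_blocks" or "three_consecutive".
#' @param criterion lick-response criterion passed to [classifyTrial()].
#' @return list with `blocks` (data.frame: block, nValid, hits, misses,
#'   falseAlarms, correctRejections, percentCorrect) and `criterionReached`.
#' @export
blockPerformance <- function(session, criterionPct = 85,
                             mode = c("two_blocks", "three_consecutive"),
                             criterion = "all") {
  mode <- match.arg(mode)
  stopifnot(is(session, "Session"))
  tr <- session@trials[session@trials$valid, , drop = FALSE]
  if (!nrow(tr)) stop("session has no valid trials")
  outcome <- vapply(seq_len(nrow(tr)), function(i)
    classifyTrial(tr$csLabel[i], tr$intervalLicks[[i]], criterion), "")
  blocks <- sort(unique(tr$block))
  rows <- lapply(blocks, function(b) {
    o <- outcome[tr$block == b]
    data.frame(block = b, nValid = length(o),
               hits = sum(o == "hit"), misses = sum(o == "miss"),
               falseAlarms = sum(o == "false_alarm"),
               correctRejections = sum(o == "correct_rejection"),
               percentCorrect = 100 *
                 sum(o %in% c("hit", "correct_rejection")) / length(o))
  })
  df <- do.call(rbind, rows)
  ok <- df$percentCorrect >= criterionPct
  reached <- if (mode == "two_blocks") {
    sum(ok) >= 2L
  } else {
    any(ok & c(ok[-1], FALSE) & c(ok[-(1:2)], FALSE, FALSE))
  }
  list(blocks = df, criterionReached = reached)
}

## graded decision variable: number of lick-positive intervals (0..4)
.lickScores <- function(trials)
  vapply(trials$intervalLicks, function(l) sum(l > 0), numeric(1))

#' ROC curve and AUC for a window of go/no-go trials
#'
#' The decision variable is the number of lick-positive 0.5-s intervals per
#' trial; sweeping its threshold yields the ROC points (true positive rate =
#' licking to CS+, false positive rate = licking to CS-), and the AUC by the
#' trapezoidal rule. All-or-none responders reduce to the single-point
#' trapezoid `AUC = (TPR + 1 - FPR)/2`. Windows are taken over valid trials
#' in presentation order ("first60"/"last60" use `windowTrials` trials).
#'
#' @param session a [Session-class], or a trials data.frame with columns
#'   csLabel, valid, intervalLicks.
#' @param window "all", "first60", "last60", or "custom" with `windowRange`.
#' @param windowTrials window length in valid trials for first60/last60.
#' @param windowRange integer range (indices into the valid-trial sequence)
#'   when `window = "custom"`.
#' @return a [RocResult-class].
#' @export
rocCurve <- function(session, window = c("all", "first60", "last60", "custom"),
                     windowTrials = 60, windowRange = NULL) {
  window <- match.arg(window)
  tr <- if (is(session, "Session")) session@trials else session
  tr <- tr[tr$valid, , drop = FALSE]
  idx <- switch(window,
    all = seq_len(nrow(tr)),
    first60 = seq_len(min(windowTrials, nrow(tr))),
    last60 = seq(max(1L, nrow(tr) - windowTrials + 1L), nrow(tr)),
    custom = windowRange)
  tr <- tr[idx, , drop = FALSE]
  pos <- tr$csLabel == "CS+"
  if (!any(pos) || !any(!pos))
    stop("ROC window must contain both CS+ and CS- trials")
  scores <- .lickScores(tr)
  sMax <- max(c(scores, 1))
  pts <- t(vapply((sMax + 1):0, function(th) {
    c(fpr = mean(scores[!pos] >= th), tpr = mean(scores[pos] >= th))
  }, numeric(2)))
  pts <- as.data.frame(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  new("RocResult", points = pts, auc = auc,
      seAuc = aucSe(auc, sum(pos), sum(!pos)),
      nPos = as.integer(sum(pos)), nNeg = as.integer(sum(!pos)),
      window = window)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `se = sqrt((A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)) / (n+ n-))`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUC in [0, 1].
#' @param nPos,nNeg numbers of positive (CS+) and negative (CS-) trials.
#' @return standard error of the AUC.
#' @export
aucSe <- function(auc, nPos, nNeg) {
  if (!is.finite(auc) || auc < 0 || auc > 1)
    stop("auc must lie in [0, 1]")
  stopifnot(nPos >= 1, nNeg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
        (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
}

#' Compare two independent AUCs (Hanley-McNeil)
#'
#' `z = (A_a - A_b) / sqrt(se_a^2 + se_b^2)` with a two-sided normal
#' p-value; for independent groups the correlation term is zero.
#'
#' @param rocA,rocB [RocResult-class] objects from independent sessions or
#'   groups.
#' @return list with `z` and `p`.
#' @export
compareAuc <- function(rocA, rocB) {
  stopifnot(is(rocA, "RocResult"), is(rocB, "RocResult"))
  denom <- sqrt(rocA@seAuc^2 + rocB@seAuc^2)
  if (!is.finite(denom) || denom == 0)
    stop("AUC standard errors are zero or undefined; z is not computable")
  z <- (rocA@auc - rocB@auc) / denom
  list(z = z, p = 2 * pnorm(-abs(z)))
}
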