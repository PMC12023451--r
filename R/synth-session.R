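## Synthetic go/no-go sessions: balanced randomised CS order per block,
## block-wise lick probabilities.

#' Generate a synthetic go/no-go session
#'
#' Each block contains equal numbers of CS+ and CS- trials in randomised
#' order. By default a trial is a full lick response (licks in every 0.5-s
#' interval) with the block's probability for its CS, and lick-free
#' otherwise; with `gradedLicks = TRUE` in the spec, each interval is an
#' independent Bernoulli draw, yielding graded interval-count scores.
#'
#' @param spec a [SessionSpec-class] object.
#' @param seed optional integer seed (reproducible sessions).
#' @param animalId,groupLabel,day metadata.
#' @return a [Session-class] object; `meta` records the generating
#'   probabilities.
#' @export
genSession <- function(spec, seed = NULL, animalId = "animal",
                       groupLabel = "NA", day = 1L) {
  stopifnot(is(spec, "SessionSpec"))
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)

  nInt <- spec@lickIntervals
  rows <- vector("list", spec@nBlocks)
  for (b in seq_len(spec@nBlocks)) {
    half <- spec@trialsPerBlock %/% 2L
    labels <- sample(rep(c("CS+", "CS-"), each = half))
    licks <- vector("list", spec@trialsPerBlock)
    valid <- logical(spec@trialsPerBlock)
    for (j in seq_len(spec@trialsPerBlock)) {
      p <- if (labels[j] == "CS+") spec@pLickCsPlus[b] else spec@pLickCsMinus[b]
      valid[j] <- runif(1) >= spec@pInvalid
      licks[[j]] <- if (spec@gradedLicks) {
        as.integer(rbinom(nInt, 1L, p))
      } else {
        rep(as.integer(runif(1) < p), nInt)
      }
    }
    df <- data.frame(block = b, csLabel = labels, valid = valid)
    df$intervalLicks <- licks
    rows[[b]] <- df
  }
  trials <- do.call(rbind, rows)
  trials$trial <- seq_len(nrow(trials))
  trials <- trials[, c("trial", "block", "csLabel", "valid", "intervalLicks")]
  Session(trials, animalId = animalId, groupLabel = groupLabel, day = day,
          meta = list(pLickCsPlus = spec@pLickCsPlus,
                      pLickCsMinus = spec@pLickCsMinus,
                      gradedLicks = spec@gradedLicks))
}
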