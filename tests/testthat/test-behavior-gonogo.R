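## Trial classification, block performance, ROC/AUC, Hanley-McNeil.

test_that("trial classification follows the all-intervals lick rule", {
  expect_equal(classifyTrial("CS+", c(1, 1, 1, 1)), "hit")
  expect_equal(classifyTrial("CS+", c(1, 0, 1, 0)), "miss")
  expect_equal(classifyTrial("CS+", c(0, 0, 0, 0)), "miss")
  expect_equal(classifyTrial("CS-", c(0, 0, 0, 0)), "correct_rejection")
  expect_equal(classifyTrial("CS-", c(1, 1, 1, 1)), "false_alarm")
  ## relaxed criterion: any licked interval counts as a response
  expect_equal(classifyTrial("CS+", c(1, 0, 0, 0), criterion = "any"), "hit")
})

test_that("block performance and the learning criterion modes", {
  ## 90% correct in blocks 4 and 7 only: two-block criterion reached
  pct <- c(50, 50, 50, 90, 50, 50, 90, 50, 50, 50)
  ses <- sessionWithBlockAccuracy(pct)
  bp <- blockPerformance(ses)
  expect_equal(bp$blocks$percentCorrect, pct)
  expect_true(bp$criterionReached)
  ## but not the three-consecutive criterion
  expect_false(blockPerformance(ses, mode = "three_consecutive")$criterionReached)
  ## three consecutive 90% blocks satisfy both
  ses3 <- sessionWithBlockAccuracy(c(50, 90, 90, 90, 50))
  expect_true(blockPerformance(ses3, mode = "three_consecutive")$criterionReached)
  ## chance-level session never reaches criterion
  flat <- sessionWithBlockAccuracy(rep(50, 10))
  expect_false(blockPerformance(flat)$criterionReached)
  ## counts sum to the valid trials per block
  expect_true(all(with(bp$blocks,
    hits + misses + falseAlarms + correctRejections == nValid)))
})

test_that("percent correct is invariant under within-block reordering", {
  ses <- genSession(sessionSpec(pLickCsPlus = 0.8, pLickCsMinus = 0.3,
                                gradedLicks = TRUE), seed = 20)
  before <- blockPerformance(ses)$blocks$percentCorrect
  tr <- trialTable(ses)
  set.seed(21)
  perm <- unlist(lapply(split(seq_len(nrow(tr)), tr$block), sample))
  shuffled <- Session(tr[perm, ])
  expect_equal(blockPerformance(shuffled)$blocks$percentCorrect, before)
})

test_that("ROC curves and AUC follow the interval-count construction", {
  ## all hits, no false alarms: AUC exactly 1
  perfect <- genSession(sessionSpec(pLickCsPlus = 1, pLickCsMinus = 0),
                        seed = 1)
  expect_identical(aucValue(rocCurve(perfect, "all")), 1)

  ## binary responder with TPR 0.8 / FPR 0.2: trapezoid (0.8 + 1 - 0.2)/2
  tr <- data.frame(block = 1, csLabel = rep(c("CS+", "CS-"), each = 10),
                   valid = TRUE)
  tr$intervalLicks <- c(lapply(1:10, function(i) rep(as.integer(i <= 8), 4)),
                        lapply(1:10, function(i) rep(as.integer(i <= 2), 4)))
  roc <- rocCurve(tr, "all")
  expect_equal(aucValue(roc), 0.8)
  ## curve anchors
  expect_equal(unlist(roc@points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc@points[nrow(roc@points), ]), c(fpr = 1, tpr = 1))

  ## windows need both classes
  onlyPos <- data.frame(block = 1, csLabel = rep("CS+", 4), valid = TRUE)
  onlyPos$intervalLicks <- lapply(1:4, function(i) rep(1L, 4))
  expect_error(rocCurve(onlyPos, "all"), "both CS")
})

test_that("interval-count AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(22)
  for (k in 1:12) {
    ses <- genSession(sessionSpec(nBlocks = 1, trialsPerBlock = 20,
                                  pLickCsPlus = runif(1, 0.3, 0.9),
                                  pLickCsMinus = runif(1, 0.1, 0.7),
                                  gradedLicks = TRUE))
    tr <- trialTable(ses)
    scores <- vapply(tr$intervalLicks, function(l) sum(l > 0), numeric(1))
    oracle <- aucOracle(scores[tr$csLabel == "CS+"],
                        scores[tr$csLabel == "CS-"])
    expect_equal(aucValue(rocCurve(ses, "all")), oracle, tolerance = 1e-12)
  }
})

test_that("first/last windows are taken over valid trials in order", {
  ses <- genSession(sessionSpec(pLickCsPlus = c(0.5, 0.5, 0.5, 1, 1, 1, 1, 1,
                                                1, 1),
                                pLickCsMinus = c(0.5, 0.5, 0.5, 0, 0, 0, 0, 0,
                                                 0, 0)),
                    seed = 23)
  early <- rocCurve(ses, "first60")
  late <- rocCurve(ses, "last60")
  expect_equal(early@nPos + early@nNeg, 60)
  expect_equal(late@nPos + late@nNeg, 60)
  expect_identical(aucValue(late), 1)
  expect_lt(aucValue(early), 1)
})

test_that("Hanley-McNeil SE and AUC comparison behave as the closed form", {
  ## direct substitutions
  expect_equal(aucSe(1, 30, 30), 0)
  expect_equal(aucSe(0.5, 1, 1), 0.5)
  expect_error(aucSe(1.2, 10, 10), "0, 1")

  ## closed-form SE within 15% of a bootstrap SE on simulated scores
  set.seed(24)
  n <- 30
  simAuc <- replicate(800, {
    aucOracle(rnorm(n), rnorm(n))
  })
  expect_equal(aucSe(0.5, n, n), sd(simAuc), tolerance = 0.15)

  ## comparison: equal AUCs give z = 0, p = 1; swapping flips the sign
  tr <- data.frame(block = 1, csLabel = rep(c("CS+", "CS-"), each = 15),
                   valid = TRUE)
  tr$intervalLicks <- c(lapply(1:15, function(i) rep(as.integer(i <= 12), 4)),
                        lapply(1:15, function(i) rep(as.integer(i <= 3), 4)))
  rocA <- rocCurve(tr, "all")
  same <- compareAuc(rocA, rocA)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  tr2 <- tr
  tr2$intervalLicks <- c(lapply(1:15, function(i) rep(1L, 4)),
                         lapply(1:15, function(i) rep(0L, 4)))
  rocB <- rocCurve(tr2, "all")    # perfect discrimination, AUC 1
  expect_equal(compareAuc(rocA, rocB)$z, -compareAuc(rocB, rocA)$z)

  ## a perfect window against a mediocre one is significant at these n
  expect_lt(compareAuc(rocB, rocA)$p, 0.05)
  z <- (0.98 - 0.72) / sqrt(aucSe(0.98, 30, 30)^2 + aucSe(0.72, 30, 30)^2)
  expect_lt(2 * pnorm(-abs(z)), 0.01)
})

test_that("equal-AUC comparisons produce roughly uniform p-values", {
  set.seed(25)
  pv <- replicate(400, {
    s1 <- genSession(sessionSpec(nBlocks = 3, trialsPerBlock = 20,
                                 pLickCsPlus = 0.7, pLickCsMinus = 0.3,
                                 gradedLicks = TRUE))
    s2 <- genSession(sessionSpec(nBlocks = 3, trialsPerBlock = 20,
                                 pLickCsPlus = 0.7, pLickCsMinus = 0.3,
                                 gradedLicks = TRUE))
    tryCatch(compareAuc(rocCurve(s1, "all"), rocCurve(s2, "all"))$p,
             error = function(e) NA_real_)
  })
  rate <- mean(pv <= 0.05, na.rm = TRUE)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})
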