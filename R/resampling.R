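## Per-cell balanced bootstrap of cumulative probability distributions and
## the permutation Kolmogorov-Smirnov test.

#' Balanced per-cell resample
#'
#' Draws exactly `nPerCell` values with replacement from every cell and pools
#' them, giving each cell equal representation regardless of how many events
#' it contributed. The default `nPerCell` is the rounded mean event count
#' across cells (375 for the study's sEPSCs, 1000 for sIPSCs).
#'
#' @param cells list of per-cell numeric vectors (each non-empty).
#' @param nPerCell draws per cell; default `round(mean(lengths(cells)))`.
#' @param seed optional integer seed.
#' @return pooled numeric vector of length `nPerCell * length(cells)`.
#' @export
balancedResample <- function(cells, nPerCell = NULL, seed = NULL) {
  if (!length(cells) || any(lengths(cells) == 0L))
    stop("every cell must contribute at least one value")
  if (is.null(nPerCell)) nPerCell <- round(mean(lengths(cells)))
  stopifnot(nPerCell >= 1L)
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(cells, function(v)
    v[sample.int(length(v), nPerCell, replace = TRUE)]), use.names = FALSE)
}

#' Bootstrap-averaged cumulative probability distribution
#'
#' Computes the empirical CDF of each balanced resample on a fixed grid and
#' averages pointwise across iterations (10,000 in the study).
#'
#' @param cells list of per-cell numeric vectors.
#' @param grid evaluation grid; default 512 points spanning the pooled range.
#' @param iterations number of balanced resamples averaged.
#' @param nPerCell draws per cell (default: rounded mean cell count).
#' @param seed optional integer seed.
#' @return a [BootCpdResult-class].
#' @export
bootstrapCpd <- function(cells, grid = NULL, iterations = 10000,
                         nPerCell = NULL, seed = NULL) {
  if (!length(cells) || any(lengths(cells) == 0L))
    stop("every cell must contribute at least one value")
  if (is.null(nPerCell)) nPerCell <- round(mean(lengths(cells)))
  if (is.null(grid)) {
    rng <- range(unlist(cells, use.names = FALSE))
    grid <- seq(rng[1], rng[2], length.out = 512)
  }
  if (!is.null(seed)) set.seed(seed)
  total <- nPerCell * length(cells)
  acc <- numeric(length(grid))
  for (i in seq_len(iterations)) {
    s <- sort(balancedResample(cells, nPerCell))
    acc <- acc + findInterval(grid, s) / total
  }
  new("BootCpdResult", grid = grid, meanCpd = acc / iterations,
      nIterations = as.integer(iterations), nPerCell = as.integer(nPerCell),
      seed = as.integer(seed %||% NA_integer_))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup |ECDF_a - ECDF_b|`, with ties handled by evaluating the ECDF
#' difference only at the last of each tied run.
#'
#' @param a,b non-empty numeric samples.
#' @return D in [0, 1].
#' @export
ksStatistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  w <- c(a, b)
  o <- order(w)
  steps <- cumsum(ifelse(o <= length(a), 1 / length(a), -1 / length(b)))
  ws <- w[o]
  last <- c(diff(ws) != 0, TRUE)
  max(abs(steps[last]))
}

#' Permutation Kolmogorov-Smirnov test on balanced resamples
#'
#' The observed statistic is the mean (and SD) of the two-sample KS D over
#' `iterations` balanced per-cell resamples of the two groups. The null
#' distribution repeats the identical computation after shuffling the data:
#' with `shuffleUnit = "event"` (default) all events are pooled and dealt
#' back into pseudo-cells preserving every cell's event count; with
#' `"cell"` whole cells are reassigned between groups. The p-value is the
#' proportion of null statistics at least as large as the observed mean D,
#' by default with the add-one correction `(b + 1)/(m + 1)`.
#'
#' @param cellsA,cellsB lists of per-cell numeric vectors (>= 2 cells each).
#' @param nPerCellA,nPerCellB draws per cell for each group (default: that
#'   group's rounded mean cell count).
#' @param iterations balanced resamples per statistic.
#' @param nPermutations shuffles forming the null distribution.
#' @param seed optional integer seed.
#' @param shuffleUnit "event" or "cell".
#' @param pEstimator "add_one" or "proportion".
#' @param nullStatistic "mean_resampled" processes each shuffle through the
#'   same `iterations`-resample mean as the observed statistic (calibrated);
#'   "single" uses one balanced resample per shuffle (cheaper, conservative).
#' @return a [PermKsResult-class].
#' @export
permutationKs <- function(cellsA, cellsB, nPerCellA = NULL, nPerCellB = NULL,
                          iterations = 1000, nPermutations = 1000,
                          seed = NULL, shuffleUnit = c("event", "cell"),
                          pEstimator = c("add_one", "proportion"),
                          nullStatistic = c("mean_resampled", "single")) {
  shuffleUnit <- match.arg(shuffleUnit)
  pEstimator <- match.arg(pEstimator)
  nullStatistic <- match.arg(nullStatistic)
  if (length(cellsA) < 2L || length(cellsB) < 2L)
    stop("both groups need at least two cells")
  if (nPermutations < 100L)
    warning("fewer than 100 permutations gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nPerCellA)) nPerCellA <- round(mean(lengths(cellsA)))
  if (is.null(nPerCellB)) nPerCellB <- round(mean(lengths(cellsB)))

  meanD <- function(ca, cb, nIter) {
    d <- numeric(nIter)
    for (i in seq_len(nIter))
      d[i] <- ksStatistic(balancedResample(ca, nPerCellA),
                          balancedResample(cb, nPerCellB))
    d
  }

  obsD <- meanD(cellsA, cellsB, iterations)
  obs <- mean(obsD)

  sizesA <- lengths(cellsA)
  sizesB <- lengths(cellsB)
  pooled <- c(unlist(cellsA, use.names = FALSE),
              unlist(cellsB, use.names = FALSE))
  nullIter <- if (nullStatistic == "mean_resampled") iterations else 1L
  nullD <- numeric(nPermutations)
  for (p in seq_len(nPermutations)) {
    if (shuffleUnit == "event") {
      perm <- pooled[sample.int(length(pooled))]
      splits <- cumsum(c(sizesA, sizesB))
      starts <- c(1, head(splits, -1) + 1)
      cellsP <- mapply(function(s, e) perm[s:e], starts, splits,
                       SIMPLIFY = FALSE)
      ca <- cellsP[seq_along(sizesA)]
      cb <- cellsP[length(sizesA) + seq_along(sizesB)]
    } else {
      allCells <- c(cellsA, cellsB)
      idx <- sample.int(length(allCells))
      ca <- allCells[idx[seq_along(cellsA)]]
      cb <- allCells[idx[length(cellsA) + seq_along(cellsB)]]
    }
    nullD[p] <- mean(meanD(ca, cb, nullIter))
  }

  b <- sum(nullD >= obs)
  pv <- if (pEstimator == "add_one") (b + 1) / (nPermutations + 1)
        else max(b / nPermutations, .Machine$double.xmin)
  new("PermKsResult", observedMeanD = obs, observedSdD = sd(obsD),
      nullD = nullD, pValue = pv, nPermutations = as.integer(nPermutations),
      nIterations = as.integer(iterations),
      seed = as.integer(seed %||% NA_integer_), shuffleUnit = shuffleUnit,
      pEstimator = pEstimator)
}
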