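#' Sample an unsynchronized newborn-size population
#'
#' Draws the sizes of an unsorted cell population, emulating the grey
#' pre-sort size histogram of a flow-cytometry sorting experiment. The
#' default lognormal family keeps sizes positive and right-skewed like
#' FSC histograms; `normal_truncated` resamples any non-positive draws.
#' Both families are parameterized by their mean and coefficient of
#' variation, with the lognormal matching the requested mean exactly in
#' expectation.
#'
#' @param nCells number of cells to draw (>= 2).
#' @param distribution `"lognormal"` (default) or `"normal_truncated"`.
#' @param meanSize mean newborn size, > 0 (default 30, the canonical
#'   fixed point).
#' @param cv coefficient of variation, > 0 (default 0.25).
#' @param seed optional integer seed; identical seeds yield identical
#'   samples.
#' @return numeric vector of `nCells` positive sizes.
#' @examples
#' sizes <- samplePopulation(1000, seed = 1)
#' @export
samplePopulation <- function(nCells,
                             distribution = c("lognormal",
                                              "normal_truncated"),
                             meanSize = 30, cv = 0.25, seed = NULL) {
    distribution <- match.arg(distribution)
    stopifnot(nCells >= 2, meanSize > 0, cv > 0)
    if (!is.null(seed)) set.seed(seed)
    if (distribution == "lognormal") {
        sdlog <- sqrt(log1p(cv^2))
        meanlog <- log(meanSize) - sdlog^2 / 2
        stats::rlnorm(nCells, meanlog = meanlog, sdlog = sdlog)
    } else {
        x <- stats::rnorm(nCells, mean = meanSize, sd = cv * meanSize)
        while (any(bad <- x <= 0))
            x[bad] <- stats::rnorm(sum(bad), mean = meanSize,
                                   sd = cv * meanSize)
        x
    }
}

#' Sort a population into size bins and assay per-bin fold change
#'
#' Emulates the sorting experiment: cells are partitioned into ordered
#' size bins (quantile bins give equal counts up to 1 cell; equal-width
#' bins partition the size range), each cell is cultured in silico for
#' `Tf` hours, and a bin's fold change is the mean proliferation capacity
#' of its cells -- computed from each cell's own size, not the bin mean,
#' so binning artifacts stay visible.
#'
#' @param sizes numeric vector of positive newborn sizes.
#' @param rule a [DivisionRule-class].
#' @param law a [GrowthLaw-class].
#' @param Tf culture horizon in hours.
#' @param nBins number of bins (default 8); must not exceed the number
#'   of cells.
#' @param binning `"quantile"` (default) or `"equal_width"`.
#' @return a data.frame, one row per bin in increasing size order, with
#'   columns `bin_index`, `size_lo`, `size_hi`, `mean_size`, `n_cells`,
#'   `fold_change`.
#' @export
sortAndAssay <- function(sizes, rule, law, Tf, nBins = 8L,
                         binning = c("quantile", "equal_width")) {
    binning <- match.arg(binning)
    .checkPositiveSize(sizes, "sizes")
    stopifnot(nBins >= 2, length(sizes) >= nBins)
    idx <- switch(binning,
        quantile = ceiling(rank(sizes, ties.method = "first") *
                               nBins / length(sizes)),
        equal_width = {
            br <- seq(min(sizes), max(sizes), length.out = nBins + 1L)
            as.integer(cut(sizes, breaks = br, include.lowest = TRUE))
        })
    cap <- 2^vapply(sizes, function(v) .log2Capacity(rule, law, v, Tf),
                    numeric(1))
    out <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
        inBin <- idx == b
        data.frame(bin_index = b,
                   size_lo = min(sizes[inBin]),
                   size_hi = max(sizes[inBin]),
                   mean_size = mean(sizes[inBin]),
                   n_cells = sum(inBin),
                   fold_change = mean(cap[inBin]))
    }))
    out[order(out$mean_size), , drop = FALSE]
}

#' Newborn-size variance across generations under division noise
#'
#' Simulates many independent lineages of the division-timing map with
#' per-generation noise on the newborn size and returns the
#' across-lineage sample variance at each generation. This is the
#' standard homeostasis diagnostic: for `a < 2` the map is an AR(1)
#' process with coefficient `a/2`, so the variance converges to the
#' stationary value \eqn{\sigma^2 / (1 - a^2/4)} (additive noise of
#' standard deviation \eqn{\sigma}), while at `a = 2` (timer) the fixed
#' point is only neutrally stable and the variance grows without bound,
#' adding \eqn{\sigma^2} per generation like a random walk.
#'
#' @param rule a [DivisionRule-class] (its `Tmin` is irrelevant here; the
#'   map acts generation by generation).
#' @param newbornSd additive noise standard deviation on newborn size
#'   (size units), >= 0.
#' @param V0 common founder newborn size, > 0.
#' @param nGenerations number of generations to simulate (>= 1).
#' @param nLineages number of independent lineages (>= 100).
#' @param seed optional integer seed.
#' @param multiplicative if `TRUE`, noise multiplies the newborn size
#'   (`V * (1 + eps)`) instead of adding to it; additive is the default.
#' @param floorSize perturbed sizes are floored at this small positive
#'   minimum (default `Vbar / 100`) to keep them physical.
#' @return a data.frame with columns `generation` (0-based) and
#'   `variance`.
#' @export
newbornVarianceByGeneration <- function(rule, newbornSd, V0, nGenerations,
                                        nLineages = 1000L, seed = NULL,
                                        multiplicative = FALSE,
                                        floorSize = NULL) {
    stopifnot(newbornSd >= 0, V0 > 0, nGenerations >= 1, nLineages >= 100)
    if (is.null(floorSize)) floorSize <- rule@Vbar / 100
    if (!is.null(seed)) set.seed(seed)
    v <- rep(V0, nLineages)
    vars <- numeric(nGenerations + 1L)
    vars[1L] <- 0
    for (g in seq_len(nGenerations)) {
        v <- (rule@a * v + (2 - rule@a) * rule@Vbar) / 2
        eps <- stats::rnorm(nLineages, 0, newbornSd)
        v <- if (multiplicative) v * (1 + eps) else v + eps
        v <- pmax(v, floorSize)
        vars[g + 1L] <- stats::var(v)
    }
    data.frame(generation = 0:nGenerations, variance = vars)
}
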