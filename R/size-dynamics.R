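#' Construct a division rule
#'
#' Builds a validated [DivisionRule-class]. `a = 0` gives a sizer, `a = 1`
#' an adder, `a = 2` a timer (under exponential growth); intermediate
#' values are sizer--adder (`a < 1`) or adder--timer (`a > 1`) mixtures.
#'
#' @param a division-timing parameter in \[0, 2\].
#' @param Vbar fixed-point newborn size, > 0 (size units).
#' @param Tmin minimum cell-cycle duration, >= 0 (hours). Default 0.
#' @return a `DivisionRule`.
#' @examples
#' divisionRule(a = 1, Vbar = 30, Tmin = 20)  # the canonical adder
#' @export
divisionRule <- function(a, Vbar, Tmin = 0) {
    methods::new("DivisionRule", a = as.numeric(a), Vbar = as.numeric(Vbar),
                 Tmin = as.numeric(Tmin))
}

#' @describeIn divisionRule human-readable strategy label for the rule's
#'   `a` value: `"sizer"`, `"adder"`, `"timer"`, `"sizer-adder mixture"`,
#'   or `"adder-timer mixture"`.
#' @param rule a `DivisionRule`.
#' @export
strategyLabel <- function(rule) {
    stopifnot(methods::is(rule, "DivisionRule"))
    a <- rule@a
    if (a == 0) "sizer"
    else if (a == 1) "adder"
    else if (a == 2) "timer"
    else if (a < 1) "sizer-adder mixture"
    else "adder-timer mixture"
}

setMethod("show", "DivisionRule", function(object) {
    cat(sprintf("DivisionRule: a = %g (%s), Vbar = %g, Tmin = %g h\n",
                object@a, strategyLabel(object), object@Vbar, object@Tmin))
    invisible(object)
})

#' Size at division for a newborn of size Vn
#'
#' The mother size just prior to mitosis, \eqn{a V_n + (2-a)\bar V}.
#' For `a < 1` and `Vn` above \eqn{(2-a)\bar V/(1-a)} this falls below
#' the newborn size itself; see [cycleDuration()] for how such cells are
#' handled.
#'
#' @param rule a [DivisionRule-class].
#' @param Vn numeric vector of positive newborn sizes.
#' @return numeric vector of division sizes.
#' @export
divisionSize <- function(rule, Vn) {
    .checkPositiveSize(Vn, "Vn")
    rule@a * Vn + (2 - rule@a) * rule@Vbar
}

#' Newborn size in the next generation
#'
#' One application of the division-timing map: the mother grows to
#' \eqn{a V_n + (2-a)\bar V} and divides symmetrically, so
#' \eqn{V_{n+1} = (a V_n + (2-a)\bar V)/2}. The map's unique fixed point
#' is \eqn{\bar V} for every `a`.
#'
#' @inheritParams divisionSize
#' @return numeric vector of next-generation newborn sizes.
#' @examples
#' rule <- divisionRule(a = 0, Vbar = 30)
#' nextNewborn(rule, 17)  # a sizer corrects in one generation: 30
#' @export
nextNewborn <- function(rule, Vn) divisionSize(rule, Vn) / 2

#' Closed-form newborn-size trajectory
#'
#' Newborn sizes across generations,
#' \eqn{V_n = \bar V + (a/2)^n (V_0 - \bar V)}, equal to repeated
#' application of [nextNewborn()] to machine precision. Converges to
#' \eqn{\bar V} for \eqn{0 \le a < 2}, faster for smaller `a`; at
#' `a = 2` the initial size persists unchanged.
#'
#' @param rule a [DivisionRule-class].
#' @param V0 positive initial newborn size.
#' @param nMax largest generation index (>= 0).
#' @return numeric vector of length `nMax + 1`: sizes at generations
#'   `0:nMax`.
#' @export
newbornTrajectory <- function(rule, V0, nMax) {
    .checkPositiveSize(V0, "V0")
    stopifnot(length(nMax) == 1L, nMax >= 0)
    rule@Vbar + (rule@a / 2)^(0:nMax) * (V0 - rule@Vbar)
}

#' Cell-cycle duration with the minimum-duration floor
#'
#' Time for a newborn of size `Vn` to grow to its division size under the
#' law `law`, floored at the rule's `Tmin`:
#' \eqn{T(V_n) = \max(T_{min}, \int_{V_n}^{a V_n + (2-a)\bar V} dv/f(v))}.
#' When the division size falls at or below the newborn size (possible for
#' `a < 1` and large `Vn`) the signed integral is non-positive and the
#' cell divides after exactly `Tmin`.
#'
#' @param rule a [DivisionRule-class].
#' @param law a [GrowthLaw-class].
#' @param Vn numeric vector of positive newborn sizes.
#' @return numeric vector of durations in hours, each >= `Tmin`.
#' @examples
#' rule <- divisionRule(a = 1, Vbar = 30, Tmin = 20)
#' law <- growthLaw("exponential", alpha = 1/48)
#' cycleDuration(rule, law, 30)  # 48 * log(2), above the 20 h floor
#' @export
cycleDuration <- function(rule, law, Vn) {
    d <- divisionSize(rule, Vn)
    pmax(rule@Tmin, inverseRateIntegral(law, Vn, d))
}

# Iterate the division map until the cumulative cycle time first exceeds
# the horizon. Returns parallel vectors; used by lineage() and the
# capacity solver.
.simulateCycles <- function(rule, law, V0, Tf, maxGenerations = 10000L) {
    .checkPositiveSize(V0, "V0")
    stopifnot(length(Tf) == 1L, is.finite(Tf), Tf > 0)
    newborn <- division <- dur <- cum <- numeric(64L)
    V <- V0; total <- 0; m <- 0L
    repeat {
        m <- m + 1L
        if (m > maxGenerations)
            stop(sprintf(paste0("divergence error: cumulative cycle time ",
                                "did not reach the horizon within %d ",
                                "generations (Tmin = %g)"),
                         maxGenerations, rule@Tmin), call. = FALSE)
        if (m > length(newborn)) {   # grow storage geometrically
            newborn <- c(newborn, numeric(length(newborn)))
            division <- c(division, numeric(length(division)))
            dur <- c(dur, numeric(length(dur)))
            cum <- c(cum, numeric(length(cum)))
        }
        d <- rule@a * V + (2 - rule@a) * rule@Vbar
        t <- max(rule@Tmin, inverseRateIntegral(law, V, d))
        total <- total + t
        newborn[m] <- V; division[m] <- d; dur[m] <- t; cum[m] <- total
        if (total > Tf) break
        V <- d / 2
    }
    list(newborn = newborn[seq_len(m)], division = division[seq_len(m)],
         duration = dur[seq_len(m)], cumulative = cum[seq_len(m)])
}

#' Simulate a lineage of cell cycles up to a culture horizon
#'
#' Iterates the division-timing map from an initial newborn size,
#' recording one row per generation, until the cumulative cycle time
#' first exceeds the horizon `Tf` (the final row is the cycle in progress
#' at the horizon). If `Tmin = 0` and per-cycle durations shrink so fast
#' that the cumulative time cannot reach `Tf`, the simulation aborts with
#' a divergence error after `maxGenerations` generations.
#'
#' @param rule a [DivisionRule-class].
#' @param law a [GrowthLaw-class].
#' @param V0 positive initial newborn size.
#' @param Tf culture horizon in hours, > 0.
#' @param maxGenerations generation cap guarding non-terminating lineages
#'   (default 10000).
#' @return a data.frame with columns `generation` (0-based),
#'   `newborn_size`, `division_size`, `cycle_duration`,
#'   `cumulative_time`; suitable for direct CSV export.
#' @examples
#' rule <- divisionRule(a = 1, Vbar = 30, Tmin = 20)
#' law <- growthLaw("exponential", alpha = 1/48)
#' lineage(rule, law, V0 = 30, Tf = 72)
#' @export
lineage <- function(rule, law, V0, Tf, maxGenerations = 10000L) {
    sim <- .simulateCycles(rule, law, V0, Tf, maxGenerations)
    data.frame(generation = seq_along(sim$newborn) - 1L,
               newborn_size = sim$newborn,
               division_size = sim$division,
               cycle_duration = sim$duration,
               cumulative_time = sim$cumulative)
}
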