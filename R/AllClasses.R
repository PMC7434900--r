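.growthKinds <- c("exponential", "linear", "saturating", "power_saturating",
                  "reciprocal", "custom")
.kindsNeedingVth <- c("saturating", "power_saturating", "reciprocal")

#' GrowthLaw: a size-dependent growth-rate function f(v)
#'
#' A `GrowthLaw` bundles one member of the growth-rate family
#' \eqn{dv/dt = f(v)} with its parameters. Built-in kinds:
#' \describe{
#'   \item{`exponential`}{\eqn{f(v) = \alpha v}: growth proportional to
#'     current size.}
#'   \item{`linear`}{\eqn{f(v) = \alpha}: constant growth in size units per
#'     hour.}
#'   \item{`saturating`}{\eqn{f(v) = \alpha v / (1 + v/V_{th})}: exponential
#'     for small cells, linear (rate \eqn{\alpha V_{th}}) for large ones.}
#'   \item{`power_saturating`}{\eqn{f(v) = \alpha v / (1 + (v/V_{th})^k)}:
#'     Hill-type non-monotonic rate, increasing for small cells and
#'     decreasing (\eqn{\propto v^{1-k}}) for large cells when \eqn{k > 1}.}
#'   \item{`reciprocal`}{\eqn{f(v) = \alpha V_{th}^2 / v}: a strictly
#'     decreasing positive rate, the package's canonical "decreasing
#'     growth rate" law.}
#'   \item{`custom`}{an arbitrary strictly positive user function of size;
#'     cycle durations then fall back to adaptive quadrature.}
#' }
#'
#' Sizes are in abstract size units (\eqn{\mu m} in the motivating
#' experiments) and times in hours; the package never converts units.
#'
#' @slot kind character, one of the kinds above.
#' @slot alpha numeric, rate coefficient (> 0): per hour for the
#'   exponential-family laws, size units per hour for `linear`.
#' @slot Vth numeric, size scale (> 0); required for `saturating`,
#'   `power_saturating` and `reciprocal`.
#' @slot k numeric, dimensionless Hill exponent (>= 1); required for
#'   `power_saturating`. The rate is non-monotonic only for `k > 1`
#'   (at `k = 1` it coincides with `saturating`).
#' @slot rateFun function or NULL; the rate function for `kind = "custom"`.
#'
#' @seealso [growthLaw()], [growthRate()], [inverseRateIntegral()]
#' @name GrowthLaw-class
#' @aliases GrowthLaw
#' @exportClass GrowthLaw
setClass("GrowthLaw",
         representation(kind = "character", alpha = "numeric",
                        Vth = "numeric", k = "numeric",
                        rateFun = "ANY"),
         prototype(kind = "exponential", alpha = 1, Vth = NA_real_,
                   k = NA_real_, rateFun = NULL))

setValidity("GrowthLaw", function(object) {
    msg <- character(0)
    if (length(object@kind) != 1L || !(object@kind %in% .growthKinds))
        return(sprintf("configuration error: 'kind' must be one of %s",
                       paste(sQuote(.growthKinds), collapse = ", ")))
    if (!is.null(object@rateFun) && !is.function(object@rateFun))
        msg <- c(msg, "configuration error: 'rate' must be a function of size or NULL")
    if (object@kind == "custom") {
        if (!is.function(object@rateFun))
            msg <- c(msg, "configuration error: kind 'custom' requires 'rate', a positive function of size")
    } else {
        if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
            object@alpha <= 0)
            msg <- c(msg, sprintf("configuration error: kind '%s' requires 'alpha' > 0",
                                  object@kind))
    }
    if (object@kind %in% .kindsNeedingVth &&
        (length(object@Vth) != 1L || !is.finite(object@Vth) || object@Vth <= 0))
        msg <- c(msg, sprintf("configuration error: kind '%s' requires 'Vth' > 0",
                              object@kind))
    if (object@kind == "power_saturating" &&
        (length(object@k) != 1L || !is.finite(object@k) || object@k < 1))
        msg <- c(msg, "configuration error: kind 'power_saturating' requires 'k' >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DivisionRule: one-parameter division-timing control
#'
#' The discrete newborn-size map \eqn{V_{n+1} = (a V_n + (2-a)\bar V)/2}
#' interpolates the classical division strategies through a single
#' dimensionless parameter \eqn{a \in [0, 2]}: the mother divides at size
#' \eqn{a V_n + (2-a)\bar V} and splits symmetrically. \eqn{a = 0} is a
#' sizer (fixed division threshold \eqn{2\bar V}), \eqn{a = 1} an adder
#' (fixed added size \eqn{\bar V}), \eqn{a = 2} a timer under exponential
#' growth (neutrally stable, non-homeostatic). For \eqn{0 \le a < 2}
#' newborn sizes converge geometrically to the fixed point \eqn{\bar V}
#' at rate \eqn{a/2} per generation.
#'
#' @slot a numeric in \[0, 2\], the division-timing parameter.
#' @slot Vbar numeric > 0, the fixed-point newborn size (size units).
#' @slot Tmin numeric >= 0, minimum cell-cycle duration in hours; every
#'   computed cycle duration is floored at `Tmin`.
#'
#' @seealso [divisionRule()], [nextNewborn()], [cycleDuration()]
#' @name DivisionRule-class
#' @aliases DivisionRule
#' @exportClass DivisionRule
setClass("DivisionRule",
         representation(a = "numeric", Vbar = "numeric", Tmin = "numeric"),
         prototype(a = 1, Vbar = 30, Tmin = 0))

setValidity("DivisionRule", function(object) {
    msg <- character(0)
    if (length(object@a) != 1L || !is.finite(object@a) ||
        object@a < 0 || object@a > 2)
        msg <- c(msg, "'a' must be a single value in [0, 2]")
    if (length(object@Vbar) != 1L || !is.finite(object@Vbar) ||
        object@Vbar <= 0)
        msg <- c(msg, "'Vbar' must be a single positive size")
    if (length(object@Tmin) != 1L || !is.finite(object@Tmin) ||
        object@Tmin < 0)
        msg <- c(msg, "'Tmin' must be a single non-negative duration")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ProliferationResult: divisions completed within a culture horizon
#'
#' Produced by [proliferationCapacity()]. Holds the integer number of
#' completed divisions \eqn{D}, the fractional progress through the cycle
#' in progress at the horizon, and the interpolated proliferation capacity
#' \eqn{2^{D + \mathrm{residual}}}, together with the lineage's
#' generation-by-generation records.
#'
#' @slot completedDivisions integer >= 0, divisions completed by the
#'   horizon.
#' @slot residualFraction numeric in \[0, 1), elapsed fraction of the cycle
#'   in progress at the horizon.
#' @slot capacity numeric, \eqn{2^{D + \mathrm{residual}}}; the modeled
#'   relative fold-change in cell count.
#' @slot cumulativeTimes numeric, partial sums of cycle durations (hours),
#'   one per simulated generation; the last strictly exceeds the horizon.
#' @slot records data.frame, the underlying lineage table (see
#'   [lineage()]).
#'
#' @seealso [proliferationCapacity()], [capacity()],
#'   [completedDivisions()]
#' @name ProliferationResult-class
#' @aliases ProliferationResult
#' @exportClass ProliferationResult
setClass("ProliferationResult",
         representation(completedDivisions = "integer",
                        residualFraction = "numeric",
                        capacity = "numeric",
                        cumulativeTimes = "numeric",
                        records = "data.frame"))

setValidity("ProliferationResult", function(object) {
    msg <- character(0)
    if (object@completedDivisions < 0L)
        msg <- c(msg, "'completedDivisions' must be >= 0")
    if (object@residualFraction < 0 || object@residualFraction >= 1 + 1e-12)
        msg <- c(msg, "'residualFraction' must lie in [0, 1)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Profile: proliferation capacity swept over newborn size
#'
#' Produced by [computeProfile()]. Holds the newborn-size grid, the
#' capacity at each grid point, their normalized counterparts (size
#' divided by \eqn{\bar V}, capacity divided by its value at the
#' reference size) and a qualitative shape label assigned by
#' [classifyShape()].
#'
#' @slot v0 numeric, strictly increasing newborn sizes.
#' @slot capacity numeric, proliferation capacity at each size.
#' @slot v0Normalized numeric, `v0 / Vbar`.
#' @slot capacityNormalized numeric, capacity divided by its
#'   (interpolated) value at `referenceSize`; all ones' reference equals 1.
#' @slot shape character, one of `increasing`, `decreasing`, `constant`,
#'   `unimodal`, `unimodal_then_increasing`, `other`.
#' @slot referenceSize numeric, the size at which capacity is normalized.
#' @slot normalized logical, whether normalization was applied.
#'
#' @seealso [computeProfile()], [classifyShape()], [shapeLabel()]
#' @name Profile-class
#' @aliases Profile
#' @exportClass Profile
setClass("Profile",
         representation(v0 = "numeric", capacity = "numeric",
                        v0Normalized = "numeric",
                        capacityNormalized = "numeric",
                        shape = "character", referenceSize = "numeric",
                        normalized = "logical"))

setValidity("Profile", function(object) {
    msg <- character(0)
    n <- length(object@v0)
    if (length(object@capacity) != n ||
        length(object@v0Normalized) != n ||
        length(object@capacityNormalized) != n)
        msg <- c(msg, "size and capacity vectors must have equal length")
    if (n > 1 && any(diff(object@v0) <= 0))
        msg <- c(msg, "'v0' must be strictly increasing")
    if (any(object@v0 <= 0))
        msg <- c(msg, "'v0' must be positive")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
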