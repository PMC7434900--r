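#' Evaluate a growth law's rate f(v)
#'
#' @param law a [GrowthLaw-class] object.
#' @param v numeric vector of positive sizes.
#' @return numeric vector of growth rates (size units per hour), strictly
#'   positive for every built-in kind.
#' @examples
#' growthRate(growthLaw("exponential", alpha = 1/48), 48)  # 1 size/h
#' @export
setGeneric("growthRate", function(law, v) standardGeneric("growthRate"))

#' Time to grow between two sizes: the inverse-rate integral
#'
#' Computes \eqn{\int_{v_{lo}}^{v_{hi}} dv / f(v)}, the time a cell
#' growing as \eqn{dv/dt = f(v)} takes to grow from `vLo` to `vHi`.
#' Closed forms are used for every built-in kind; `custom` laws fall back
#' to adaptive quadrature (relative tolerance 1e-10, absolute 1e-12).
#' The integral is signed: `vHi < vLo` yields a negative duration, which
#' callers such as [cycleDuration()] use to detect cells born above their
#' division size.
#'
#' @param law a [GrowthLaw-class] object.
#' @param vLo numeric vector of positive sizes (lower limit).
#' @param vHi numeric vector of positive sizes (upper limit); recycled
#'   against `vLo`.
#' @return numeric vector of signed durations in hours.
#' @examples
#' law <- growthLaw("exponential", alpha = 1/48)
#' inverseRateIntegral(law, 30, 60)  # 48 * log(2) hours
#' @export
setGeneric("inverseRateIntegral",
           function(law, vLo, vHi) standardGeneric("inverseRateIntegral"))

#' @describeIn ProliferationResult-class the interpolated proliferation
#'   capacity \eqn{2^{D + \mathrm{residual}}}.
#' @param x a `ProliferationResult`.
#' @export
setGeneric("capacity", function(x) standardGeneric("capacity"))

#' @describeIn ProliferationResult-class the integer number of completed
#'   divisions \eqn{D}.
#' @export
setGeneric("completedDivisions",
           function(x) standardGeneric("completedDivisions"))

#' @describeIn ProliferationResult-class the fractional progress through
#'   the cycle in progress at the horizon, in \[0, 1).
#' @export
setGeneric("residualFraction",
           function(x) standardGeneric("residualFraction"))

#' @describeIn ProliferationResult-class partial sums of cycle durations,
#'   in hours.
#' @export
setGeneric("cumulativeTimes", function(x) standardGeneric("cumulativeTimes"))

#' @describeIn Profile-class the qualitative shape label of a profile.
#' @param x a `Profile`.
#' @export
setGeneric("shapeLabel", function(x) standardGeneric("shapeLabel"))
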