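#' Construct a growth law
#'
#' Builds a validated [GrowthLaw-class] object. See the class page for the
#' formulas; the canonical parameterizations used throughout the scenario
#' presets are `alpha = 1/48` per hour, `Vth = 25` (saturating) or
#' `Vth = 20` with `k = 3` (non-monotonic).
#'
#' @param kind one of `"exponential"`, `"linear"`, `"saturating"`,
#'   `"power_saturating"`, `"reciprocal"`, `"custom"`.
#' @param alpha rate coefficient, > 0 (ignored for `custom`).
#' @param Vth size scale, > 0; required for `saturating`,
#'   `power_saturating`, `reciprocal`.
#' @param k Hill exponent, >= 1; required for `power_saturating`.
#' @param rate for `kind = "custom"`, a vectorized strictly positive
#'   function of size.
#' @return a `GrowthLaw`.
#' @examples
#' growthLaw("saturating", alpha = 1/48, Vth = 25)
#' growthLaw("custom", rate = function(v) v / 48)
#' @export
growthLaw <- function(kind = .growthKinds, alpha = NA_real_, Vth = NA_real_,
                      k = NA_real_, rate = NULL) {
    kind <- match.arg(kind)
    methods::new("GrowthLaw", kind = kind, alpha = as.numeric(alpha),
                 Vth = as.numeric(Vth), k = as.numeric(k), rateFun = rate)
}

.checkPositiveSize <- function(v, what = "v") {
    if (!length(v) || any(!is.finite(v)) || any(v <= 0))
        stop(sprintf("domain error: '%s' must be positive and finite", what),
             call. = FALSE)
    invisible(v)
}

#' @rdname growthRate
#' @export
setMethod("growthRate", "GrowthLaw", function(law, v) {
    .checkPositiveSize(v)
    r <- switch(law@kind,
        exponential      = law@alpha * v,
        linear           = rep_len(law@alpha, length(v)),
        saturating       = law@alpha * v / (1 + v / law@Vth),
        power_saturating = law@alpha * v / (1 + (v / law@Vth)^law@k),
        reciprocal       = law@alpha * law@Vth^2 / v,
        custom           = {
            out <- law@rateFun(v)
            if (length(out) != length(v) || any(!is.finite(out)) ||
                any(out <= 0))
                stop("numerical error: custom rate function must return ",
                     "finite positive rates", call. = FALSE)
            out
        })
    r
})

# Adaptive quadrature of 1/f over one [lo, hi] interval (signed).
.quadOneInterval <- function(law, lo, hi) {
    if (lo == hi) return(0)
    s <- 1
    if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp; s <- -1 }
    res <- tryCatch(
        stats::integrate(function(v) 1 / growthRate(law, v), lo, hi,
                         rel.tol = 1e-10, abs.tol = 1e-12,
                         subdivisions = 500L),
        error = function(e) e)
    if (inherits(res, "error") || res$message != "OK")
        stop(sprintf(paste0("numerical error: quadrature of 1/f over ",
                            "[%g, %g] did not converge (%s)"),
                     lo, hi,
                     if (inherits(res, "error")) conditionMessage(res)
                     else res$message),
             call. = FALSE)
    s * res$value
}

#' @rdname inverseRateIntegral
#' @export
setMethod("inverseRateIntegral", "GrowthLaw", function(law, vLo, vHi) {
    .checkPositiveSize(vLo, "vLo")
    .checkPositiveSize(vHi, "vHi")
    n <- max(length(vLo), length(vHi))
    vLo <- rep_len(vLo, n); vHi <- rep_len(vHi, n)
    switch(law@kind,
        exponential      = log(vHi / vLo) / law@alpha,
        linear           = (vHi - vLo) / law@alpha,
        saturating       = (log(vHi / vLo) + (vHi - vLo) / law@Vth) /
                               law@alpha,
        power_saturating = (log(vHi / vLo) +
                            (vHi^law@k - vLo^law@k) /
                                (law@k * law@Vth^law@k)) / law@alpha,
        reciprocal       = (vHi^2 - vLo^2) / (2 * law@alpha * law@Vth^2),
        custom           = vapply(seq_len(n), function(i)
                               .quadOneInterval(law, vLo[i], vHi[i]),
                               numeric(1)))
})

setMethod("show", "GrowthLaw", function(object) {
    pars <- c(alpha = object@alpha, Vth = object@Vth, k = object@k)
    pars <- pars[!is.na(pars)]
    cat(sprintf("GrowthLaw '%s'", object@kind))
    if (length(pars))
        cat(": ", paste(names(pars), signif(pars, 6), sep = " = ",
                        collapse = ", "), sep = "")
    if (object@kind == "custom") cat(": user-supplied rate function")
    cat("\n")
    invisible(object)
})
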