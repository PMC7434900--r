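# Independent oracles: growth-rate formulas written out directly (not via
# the package), an independent adaptive quadrature of 1/f, and a
# fixed-step 4th-order Runge-Kutta integrator of dv/dt = f(v) that
# measures the time to travel between two sizes.

oracleRate <- function(kind, alpha, Vth = NA, k = NA) {
    switch(kind,
        exponential      = function(v) alpha * v,
        linear           = function(v) rep_len(alpha, length(v)),
        saturating       = function(v) alpha * v / (1 + v / Vth),
        power_saturating = function(v) alpha * v / (1 + (v / Vth)^k),
        reciprocal       = function(v) alpha * Vth^2 / v,
        stop("unknown kind in oracle"))
}

oracleQuadrature <- function(f, lo, hi)
    stats::integrate(function(v) 1 / f(v), lo, hi,
                     rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 500L)$value

# time for dv/dt = f(v) to carry v from vLo[i] to vHi[i], fixed-step RK4;
# the crossing step is linearly interpolated
rk4TravelTime <- function(f, vLo, vHi, dt = 1e-3) {
    n <- length(vLo)
    stopifnot(length(vHi) == n, all(vHi > vLo))
    v <- vLo
    out <- rep(NA_real_, n)
    active <- rep(TRUE, n)
    t <- 0
    while (any(active)) {
        idx <- which(active)
        va <- v[idx]
        k1 <- f(va)
        k2 <- f(va + dt / 2 * k1)
        k3 <- f(va + dt / 2 * k2)
        k4 <- f(va + dt * k3)
        vn <- va + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        hit <- vn >= vHi[idx]
        if (any(hit)) {
            ih <- idx[hit]
            out[ih] <- t + dt * (vHi[ih] - v[ih]) / (vn[hit] - v[ih])
            active[ih] <- FALSE
        }
        v[idx] <- vn
        t <- t + dt
        if (t > 2e3)
            stop("rk4 oracle exceeded its time cap; choose smaller sizes")
    }
    out
}

# the five built-in laws at the canonical preset parameterizations,
# paired with their oracle rate functions
builtinLawSet <- function() {
    list(
        exponential = list(
            law = growthLaw("exponential", alpha = 1 / 48),
            rate = oracleRate("exponential", 1 / 48)),
        linear = list(
            law = growthLaw("linear", alpha = 1),
            rate = oracleRate("linear", 1)),
        saturating = list(
            law = growthLaw("saturating", alpha = 1 / 48, Vth = 25),
            rate = oracleRate("saturating", 1 / 48, Vth = 25)),
        power_saturating = list(
            law = growthLaw("power_saturating", alpha = 1 / 48, Vth = 20,
                            k = 3),
            rate = oracleRate("power_saturating", 1 / 48, Vth = 20, k = 3)),
        reciprocal = list(
            law = growthLaw("reciprocal", alpha = 1 / 48, Vth = 30),
            rate = oracleRate("reciprocal", 1 / 48, Vth = 30)))
}

# per-cycle durations summed over the first m cycles of the division map,
# computed directly from the map and the package integral (no clamping;
# callers keep draws in the positive-increment regime)
mapCycleSum <- function(law, a, Vbar, V0, m) {
    total <- 0
    V <- V0
    for (i in seq_len(m)) {
        d <- a * V + (2 - a) * Vbar
        total <- total + inverseRateIntegral(law, V, d)
        V <- d / 2
    }
    total
}
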