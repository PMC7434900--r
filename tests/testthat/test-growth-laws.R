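test_that("built-in growth rates match their formulas at reference points", {
    expect_equal(growthRate(growthLaw("exponential", alpha = 1 / 48), 48), 1)
    sat <- growthLaw("saturating", alpha = 1 / 48, Vth = 25)
    # large-v asymptote alpha * Vth
    expect_equal(growthRate(sat, 1e9), 25 / 48, tolerance = 1e-7)
    psat <- growthLaw("power_saturating", alpha = 1 / 48, Vth = 20, k = 3)
    expect_equal(growthRate(psat, 20), (20 / 48) / 2)
    rec <- growthLaw("reciprocal", alpha = 1 / 48, Vth = 30)
    expect_equal(growthRate(rec, 30), 30 / 48)
    # all rates strictly positive over a wide size range
    v <- exp(seq(log(0.01), log(1e4), length.out = 50))
    for (entry in builtinLawSet())
        expect_true(all(growthRate(entry$law, v) > 0))
})

test_that("domain and configuration errors are raised", {
    law <- growthLaw("exponential", alpha = 1 / 48)
    expect_error(growthRate(law, 0), "domain error")
    expect_error(growthRate(law, c(3, -1)), "domain error")
    expect_error(inverseRateIntegral(law, 0, 10), "domain error")
    expect_error(growthLaw("saturating", alpha = 1 / 48), "Vth")
    expect_error(growthLaw("power_saturating", alpha = 1 / 48, Vth = 20,
                           k = 0.5), "k")
    expect_error(growthLaw("exponential", alpha = -1), "alpha")
    expect_error(growthLaw("custom"), "custom")
    bad <- growthLaw("custom", rate = function(v) v - 10)  # negative below 10
    expect_error(growthRate(bad, 5), "positive")
})

test_that("power_saturating at k = 1 coincides with saturating", {
    sat <- growthLaw("saturating", alpha = 1 / 48, Vth = 25)
    psat1 <- growthLaw("power_saturating", alpha = 1 / 48, Vth = 25, k = 1)
    set.seed(11)
    v <- exp(runif(50, log(0.1), log(300)))
    expect_equal(growthRate(psat1, v), growthRate(sat, v),
                 tolerance = 1e-12)
    expect_equal(inverseRateIntegral(psat1, v, 2 * v),
                 inverseRateIntegral(sat, v, 2 * v), tolerance = 1e-12)
})

test_that("closed-form integrals match hand-derived reference durations", {
    expect_equal(
        inverseRateIntegral(growthLaw("exponential", alpha = 1 / 48), 30, 60),
        48 * log(2), tolerance = 1e-12)
    expect_equal(
        inverseRateIntegral(growthLaw("linear", alpha = 1), 30, 60), 30)
    expect_equal(
        inverseRateIntegral(growthLaw("saturating", alpha = 1 / 48,
                                      Vth = 25), 30, 60),
        48 * (log(2) + 30 / 25), tolerance = 1e-12)
    expect_equal(
        inverseRateIntegral(growthLaw("power_saturating", alpha = 1 / 48,
                                      Vth = 20, k = 3), 30, 60),
        48 * (log(2) + (60^3 - 30^3) / (3 * 20^3)), tolerance = 1e-12)
    expect_equal(
        inverseRateIntegral(growthLaw("reciprocal", alpha = 1 / 48,
                                      Vth = 30), 30, 60),
        (60^2 - 30^2) * 48 / (2 * 30^2), tolerance = 1e-12)
})

test_that("closed forms agree with independent adaptive quadrature", {
    set.seed(21)
    for (entry in builtinLawSet()) {
        vLo <- exp(runif(20, log(2), log(80)))
        vHi <- vLo * runif(20, 1.05, 3)
        got <- inverseRateIntegral(entry$law, vLo, vHi)
        want <- vapply(seq_along(vLo), function(i)
            oracleQuadrature(entry$rate, vLo[i], vHi[i]), numeric(1))
        expect_equal(got, want, tolerance = 1e-8)
    }
})

test_that("integrals are additive and signed", {
    set.seed(31)
    for (entry in builtinLawSet()) {
        a <- runif(10, 2, 20); b <- a * runif(10, 1.1, 2)
        cc <- b * runif(10, 1.1, 2)
        expect_equal(inverseRateIntegral(entry$law, a, b) +
                         inverseRateIntegral(entry$law, b, cc),
                     inverseRateIntegral(entry$law, a, cc),
                     tolerance = 1e-10)
        expect_equal(inverseRateIntegral(entry$law, b, a),
                     -inverseRateIntegral(entry$law, a, b),
                     tolerance = 1e-12)
        expect_equal(inverseRateIntegral(entry$law, a, a), rep(0, 10))
    }
})

test_that("custom laws integrate by adaptive quadrature", {
    custom <- growthLaw("custom", rate = function(v) v / 48)
    expect_equal(inverseRateIntegral(custom, 30, 60), 48 * log(2),
                 tolerance = 1e-8)
    # signed convention holds on the quadrature path too
    expect_equal(inverseRateIntegral(custom, 60, 30), -48 * log(2),
                 tolerance = 1e-8)
})

test_that("power_saturating rate is unimodal with an interior maximum", {
    law <- growthLaw("power_saturating", alpha = 1 / 48, Vth = 20, k = 3)
    opt <- optimize(function(v) growthRate(law, v), c(0.1, 500),
                    maximum = TRUE)
    vStar <- opt$maximum
    expect_gt(vStar, 1)
    expect_lt(vStar, 100)
    below <- seq(0.5, vStar * 0.99, length.out = 30)
    above <- seq(vStar * 1.01, 500, length.out = 30)
    expect_true(all(diff(growthRate(law, below)) > 0))
    expect_true(all(diff(growthRate(law, above)) < 0))
})

test_that("stepping the growth ODE reproduces integral durations", {
    set.seed(41)
    for (entry in builtinLawSet()) {
        vLo <- runif(3, 15, 30)
        vHi <- vLo * runif(3, 1.15, 1.45)
        want <- inverseRateIntegral(entry$law, vLo, vHi)
        got <- rk4TravelTime(entry$rate, vLo, vHi)
        expect_equal(got, want, tolerance = 1e-4)
    }
})
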