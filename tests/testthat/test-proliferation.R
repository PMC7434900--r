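test_that("capacity solver reproduces the worked adder example", {
    law <- growthLaw("exponential", alpha = 1 / 48)
    rule <- divisionRule(1, 30, Tmin = 20)
    Td <- 48 * log(2)
    res <- proliferationCapacity(rule, law, V0 = 30, Tf = 72)
    expect_equal(completedDivisions(res), 2L)
    expect_equal(residualFraction(res), (72 - 2 * Td) / Td,
                 tolerance = 1e-12)
    expect_equal(capacity(res), 2^(2 + (72 - 2 * Td) / Td),
                 tolerance = 1e-12)
    expect_equal(cumulativeTimes(res), Td * (1:3), tolerance = 1e-12)

    # horizon shorter than the first cycle: no doublings, capacity < 2
    res0 <- proliferationCapacity(rule, law, V0 = 30, Tf = 30)
    expect_equal(completedDivisions(res0), 0L)
    expect_equal(capacity(res0), 2^(30 / Td), tolerance = 1e-12)
    expect_lt(capacity(res0), 2)

    # linear growth + adder: capacity invariant of founder size, 2^2.4
    lin <- growthLaw("linear", alpha = 1)
    adder0 <- divisionRule(1, 30, Tmin = 0)
    for (V0 in c(7, 30, 90))
        expect_equal(capacity(proliferationCapacity(adder0, lin, V0, 72)),
                     2^2.4, tolerance = 1e-12)
})

test_that("capacity lies in [2^D, 2^(D+1)) with residual in [0, 1)", {
    set.seed(5)
    for (entry in builtinLawSet()) {
        for (i in 1:20) {
            rule <- divisionRule(runif(1, 0, 2), 30,
                                 Tmin = sample(c(0, 20), 1))
            res <- proliferationCapacity(rule, entry$law,
                                         V0 = runif(1, 3, 120),
                                         Tf = runif(1, 30, 200))
            D <- completedDivisions(res)
            expect_gte(residualFraction(res), 0)
            expect_lt(residualFraction(res), 1)
            expect_gte(capacity(res), 2^D)
            expect_lt(capacity(res), 2^(D + 1))
        }
    }
})

test_that("real-valued cycle count floors to the division count", {
    law <- growthLaw("exponential", alpha = 1 / 48)
    adder <- divisionRule(1, 30, Tmin = 0)
    # two full doublings at the fixed point
    expect_equal(realValuedCycleCount(adder, law, 30, 2 * 48 * log(2)), 2,
                 tolerance = 1e-12)
    expect_error(realValuedCycleCount(divisionRule(1, 30, 20), law, 30, 72),
                 "usage error")
    set.seed(13)
    for (entry in builtinLawSet()) {
        for (i in 1:20) {
            rule <- divisionRule(runif(1, 1, 2), 30, Tmin = 0)
            V0 <- runif(1, 5, 90); Tf <- runif(1, 40, 250)
            m <- realValuedCycleCount(rule, entry$law, V0, Tf)
            D <- completedDivisions(
                proliferationCapacity(rule, entry$law, V0, Tf))
            expect_equal(floor(m), D)
        }
    }
})

test_that("sizer closed form matches the generic machinery", {
    law <- growthLaw("exponential", alpha = 1 / 48)
    Td <- 48 * log(2)
    expect_equal(sizerCycleCount(law, 30, 30, 72, Tmin = 0),
                 (72 - Td) / Td + 1, tolerance = 1e-12)
    # founder at the division threshold: first cycle is instantaneous
    expect_equal(sizerCycleCount(law, 30, 60, 72, Tmin = 0),
                 72 / Td + 1, tolerance = 1e-12)
    # two independent code paths agree for every law, within the closed
    # form's regime (first cycle completes inside the horizon)
    sizer <- divisionRule(0, 30, Tmin = 0)
    for (entry in builtinLawSet()) {
        for (V0 in c(5, 18, 30, 47)) {
            T0 <- max(0, inverseRateIntegral(entry$law, V0, 60))
            Tbar <- inverseRateIntegral(entry$law, 30, 60)
            Tf <- T0 + 1.7 * Tbar
            expect_equal(
                realValuedCycleCount(sizer, entry$law, V0, Tf),
                sizerCycleCount(entry$law, 30, V0, Tf, Tmin = 0),
                tolerance = 1e-10)
        }
        # count is non-decreasing in founder size
        cnt <- vapply(seq(3, 59, length.out = 40), function(v)
            sizerCycleCount(entry$law, 30, v, 100, Tmin = 0), numeric(1))
        expect_true(all(diff(cnt) >= -1e-12))
    }
})

test_that("exponential cycle sum telescopes and matches the map", {
    al <- 1 / 48
    # fixed point: every cycle is one doubling
    for (m in 0:4)
        expect_equal(exponentialCycleSum(1, 30, 30, al, m), m * log(2) / al,
                     tolerance = 1e-12)
    # first sizer cycle alone
    expect_equal(exponentialCycleSum(0, 30, 12, al, 1), log(60 / 12) / al,
                 tolerance = 1e-12)
    # worked two-cycle adder example, against explicit per-cycle durations
    expect_equal(exponentialCycleSum(1, 30, 60, al, 2), 48 * log(2.5),
                 tolerance = 1e-12)
    expect_equal(exponentialCycleSum(1, 30, 60, al, 2),
                 48 * (log(90 / 60) + log(75 / 45)), tolerance = 1e-12)
    law <- growthLaw("exponential", alpha = al)
    set.seed(23)
    for (i in 1:50) {
        a <- runif(1, 0, 2); Vbar <- runif(1, 10, 50)
        V0 <- Vbar * runif(1, 0.2, 3)
        if (a < 1) V0 <- min(V0, 0.9 * (2 - a) * Vbar / (1 - a))
        m <- sample(1:6, 1)
        expect_equal(exponentialCycleSum(a, Vbar, V0, al, m),
                     mapCycleSum(law, a, Vbar, V0, m), tolerance = 1e-10)
    }
})

test_that("linear cycle sum covers all division strategies", {
    # adder adds exactly Vbar each cycle: sum independent of V0
    for (V0 in c(4, 30, 77))
        expect_equal(linearCycleSum(1, 30, V0, 2, 5), 5 * 30 / 2,
                     tolerance = 1e-12)
    # sizer with a small founder: first cycle carries the extra Vbar - V0
    expect_equal(linearCycleSum(0, 30, 12, 1, 3), 3 * 30 + (30 - 12),
                 tolerance = 1e-12)
    # a > 1: sum strictly increasing in V0 at fixed m
    s <- vapply(c(35, 45, 60), function(v) linearCycleSum(1.5, 30, v, 1, 4),
                numeric(1))
    expect_true(all(diff(s) > 0))
    # timer limit equals the direct summation m * V0 / alpha
    law <- growthLaw("linear", alpha = 1)
    expect_equal(linearCycleSum(2, 30, 42, 1, 5), 5 * 42)
    expect_equal(linearCycleSum(2, 30, 42, 1, 5),
                 mapCycleSum(law, 2, 30, 42, 5), tolerance = 1e-12)
    set.seed(29)
    for (i in 1:50) {
        a <- runif(1, 0, 2); Vbar <- runif(1, 10, 50)
        V0 <- Vbar * runif(1, 0.2, 3)
        if (a < 1) V0 <- min(V0, 0.9 * (2 - a) * Vbar / (1 - a))
        m <- sample(1:6, 1)
        expect_equal(linearCycleSum(a, Vbar, V0, 1.3, m),
                     mapCycleSum(growthLaw("linear", alpha = 1.3),
                                 a, Vbar, V0, m),
                     tolerance = 1e-10)
    }
})

test_that("adder change-of-variables quadrature equals per-cycle integrals", {
    psat <- growthLaw("power_saturating", alpha = 1 / 48, Vth = 20, k = 3)
    expect_equal(adderCycleSumQuadrature(psat, 30, 30, 1),
                 inverseRateIntegral(psat, 30, 60), tolerance = 1e-9)
    expo <- growthLaw("exponential", alpha = 1 / 48)
    expect_equal(adderCycleSumQuadrature(expo, 30, 30, 3), 3 * 48 * log(2),
                 tolerance = 1e-9)
    set.seed(37)
    for (entry in builtinLawSet()) {
        for (i in 1:5) {
            V0 <- runif(1, 5, 90); m <- sample(1:4, 1)
            expect_equal(adderCycleSumQuadrature(entry$law, 30, V0, m),
                         mapCycleSum(entry$law, 1, 30, V0, m),
                         tolerance = 1e-9)
        }
    }
    # monotone-increasing law: the sum decreases with founder size
    sat <- growthLaw("saturating", alpha = 1 / 48, Vth = 25)
    s <- vapply(c(10, 30, 60), function(v)
        adderCycleSumQuadrature(sat, 30, v, 3), numeric(1))
    expect_true(all(diff(s) < 0))
})

test_that("capacity is continuous and non-decreasing in the horizon", {
    law <- growthLaw("saturating", alpha = 1 / 48, Vth = 25)
    rule <- divisionRule(1, 30, Tmin = 0)
    lin <- lineage(rule, law, 20, 400)
    S <- lin$cumulative_time
    for (m in 1:3) {
        below <- capacity(proliferationCapacity(rule, law, 20,
                                                S[m] * (1 - 1e-9)))
        above <- capacity(proliferationCapacity(rule, law, 20,
                                                S[m] * (1 + 1e-9)))
        expect_equal(below, 2^m, tolerance = 1e-8)
        expect_equal(above, 2^m, tolerance = 1e-8)
    }
    tfGrid <- seq(10, 350, length.out = 120)
    caps <- vapply(tfGrid, function(tf)
        capacity(proliferationCapacity(rule, law, 20, tf)), numeric(1))
    expect_true(all(diff(caps) >= -1e-12))
})
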