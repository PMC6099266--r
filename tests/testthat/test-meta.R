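test_that("identical estimates pool to themselves with no heterogeneity", {
    m <- dlRandomEffects(c(-0.2, -0.2), c(0.1, 0.1))
    expect_equal(logOR(m), -0.2)
    h <- heterogeneity(m)
    expect_equal(unname(h["Q"]), 0)
    expect_equal(unname(h["I2"]), 0)
    expect_equal(unname(h["tau2"]), 0)
    # with tau2 = 0 and equal SEs the pooled SE is se/sqrt(k)
    expect_equal(m@pooled_se, 0.1 / sqrt(2))
})

test_that("pooling printed two-region estimates reproduces the published OR", {
    se_eu <- seFromCI(0.98, c(0.67, 1.44))
    se_na <- seFromCI(0.92, c(0.64, 1.34))
    m <- dlRandomEffects(log(c(0.98, 0.92)), c(se_eu, se_na))
    expect_equal(round(oddsRatio(m), 2), 0.95)
    expect_equal(round(confint95(m)[1], 2), 0.73)
    expect_lt(abs(round(confint95(m)[2], 2) - 1.25), 0.011)
})

test_that("adding the outlier region recreates the published heterogeneity", {
    th <- log(c(0.98, 0.92, 3.91))
    se <- c(seFromCI(0.98, c(0.67, 1.44)), seFromCI(0.92, c(0.64, 1.34)),
            seFromCI(3.91, c(1.64, 9.29)))
    m <- dlRandomEffects(th, se)
    h <- heterogeneity(m)
    expect_gt(unname(h["I2"]), 0.70)
    expect_lt(unname(h["I2"]), 0.85)
    expect_lt(unname(h["p_het"]), 0.05)
    # the Higgins-Thompson interval brackets the point I2
    expect_lt(unname(h["I2_lower"]), unname(h["I2"]))
    expect_gt(unname(h["I2_upper"]), unname(h["I2"]))
})

test_that("standard errors back-derived from printed CIs are exact", {
    expect_equal(seFromCI(1.00, c(0.82, 1.22)),
                 (log(1.22) - log(0.82)) / (2 * qnorm(0.975)))
    expect_equal(round(seFromCI(1.00, c(0.82, 1.22)), 4), 0.1014)
    expect_equal(round(seFromCI(3.91, c(1.64, 9.29)), 4), 0.4424)
    # inverse identity for a log-symmetric interval
    se <- 0.2
    ci <- exp(log(1.3) + c(-1, 1) * qnorm(0.975) * se)
    expect_equal(seFromCI(1.3, ci), se)
    expect_warning(seFromCI(2.0, c(0.5, 1.5)), "outside")
    expect_error(seFromCI(1.0, c(-1, 2)), "lower")
})

test_that("I2 interval handles the boundary cases", {
    ci <- i2ConfidenceInterval(q = 2, k = 3)  # Q = k-1: point I2 = 0
    expect_equal(ci[1], 0)
    ci0 <- i2ConfidenceInterval(q = 0, k = 3)
    expect_equal(ci0[1], 0)
    expect_lt(ci0[2], 1)
    expect_error(i2ConfidenceInterval(1, 1), "k >= 2")
})

test_that("degenerate pooling inputs are handled per contract", {
    expect_error(dlRandomEffects(numeric(0), numeric(0)), "no estimates")
    expect_warning(m1 <- dlRandomEffects(0.3, 0.1), "single")
    expect_equal(logOR(m1), 0.3)
    expect_equal(m1@pooled_se, 0.1)
    expect_equal(m1@tau2, 0)
    expect_error(dlRandomEffects(c(0.1, 0.2), c(0.1, -0.1)), "positive")
})

test_that("pooling is permutation-invariant and matches brute force", {
    set.seed(202)
    for (rep in 1:50) {
        k <- sample(2:8, 1)
        th <- rnorm(k, 0, 0.5)
        se <- runif(k, 0.05, 0.6)
        m <- dlRandomEffects(th, se)
        bf <- brute_force_dl(th, se)
        expect_equal(logOR(m), bf$pooled, tolerance = 1e-13)
        expect_equal(m@pooled_se, bf$se, tolerance = 1e-13)
        expect_equal(m@tau2, bf$tau2, tolerance = 1e-13)
        perm <- sample(k)
        mp <- dlRandomEffects(th[perm], se[perm])
        expect_equal(logOR(mp), logOR(m))
        expect_equal(heterogeneity(mp), heterogeneity(m))
    }
})

test_that("DL pooling agrees with the reference metafor implementation", {
    skip_if_not_installed("metafor")
    set.seed(77)
    for (rep in 1:25) {
        k <- sample(2:6, 1)
        th <- rnorm(k, 0, 0.4)
        se <- runif(k, 0.05, 0.5)
        m <- dlRandomEffects(th, se)
        r <- metafor::rma(yi = th, sei = se, method = "DL")
        expect_equal(logOR(m), as.numeric(r$b), tolerance = 1e-12)
        expect_equal(m@pooled_se, r$se, tolerance = 1e-12)
        expect_equal(m@tau2, r$tau2, tolerance = 1e-12)
        expect_equal(m@q, r$QE, tolerance = 1e-12)
    }
})
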