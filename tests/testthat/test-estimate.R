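test_that("a strong causal effect is recovered at large n", {
    cfg <- SimulationConfig(
        strata = data.frame(stratum = "Europe", n_cases = 9000L,
                            n_controls = 11000L),
        causal_log_or = log(2))
    co <- simulateCohort(cfg, seed = 31)
    e <- fitCausalLogistic(co)
    expect_gt(oddsRatio(e), 1.8)
    expect_lt(oddsRatio(e), 2.2)
    expect_lt(pValue(e), 1e-6)
})

test_that("degenerate designs are rejected", {
    w <- toy_weights()
    d <- matrix(1, nrow = 2, ncol = 40, dimnames = list(w$rsid, NULL))
    co <- toy_cohort(d)
    expect_error(fitCausalLogistic(co, spec = AnalysisSpec(
        covariates = character(0))), "zero variance")
    cfg <- small_sim_config(n_cases = 100, n_controls = 100)
    co2 <- simulateCohort(cfg, seed = 2)
    expect_error(
        fitCausalLogistic(co2, spec = AnalysisSpec(stratum = "Mars")),
        "at least one case")
})

test_that("zero weight uncertainty leaves the naive SE untouched", {
    co <- simulateCohort(small_sim_config(), seed = 8)
    w <- variantWeights(co)
    w0 <- w; w0$se <- rep(0, nrow(w0))
    spec <- AnalysisSpec(bootstrap_reps = 25, seed = 4)
    e0 <- bootstrapWeightCorrection(co, w0, spec)
    expect_identical(seCorrected(e0), seNaive(e0))
})

test_that("weight-imprecision correction inflates the SE deterministically", {
    co <- simulateCohort(small_sim_config(), seed = 8)
    spec <- AnalysisSpec(bootstrap_reps = 60, seed = 4)
    e1 <- bootstrapWeightCorrection(co, spec = spec)
    e2 <- bootstrapWeightCorrection(co, spec = spec)
    expect_gte(seCorrected(e1), seNaive(e1))
    expect_identical(seCorrected(e1), seCorrected(e2))  # seeded
    e3 <- bootstrapWeightCorrection(co,
        spec = AnalysisSpec(bootstrap_reps = 60, seed = 5))
    expect_false(identical(seCorrected(e1), seCorrected(e3)))
    # the point estimate is the original-weight fit
    expect_identical(logOR(e1), logOR(fitCausalLogistic(co)))
    # corrected CI/p recomputed from the corrected SE
    expect_equal(confint95(e1),
                 exp(logOR(e1) + c(-1, 1) * qnorm(0.975) * seCorrected(e1)))
})

test_that("the corrected SE is stable in the number of replicates", {
    co <- simulateCohort(small_sim_config(), seed = 14)
    e1 <- bootstrapWeightCorrection(co,
        spec = AnalysisSpec(bootstrap_reps = 300, seed = 101))
    e2 <- bootstrapWeightCorrection(co,
        spec = AnalysisSpec(bootstrap_reps = 300, seed = 202))
    expect_lt(abs(seCorrected(e1) / seCorrected(e2) - 1), 0.01)
})

test_that("estimates are invariant to affine covariate recoding", {
    co <- simulateCohort(small_sim_config(), seed = 12)
    e1 <- fitCausalLogistic(co)
    co2 <- co
    SummarizedExperiment::colData(co2)$pc1 <-
        10 * SummarizedExperiment::colData(co2)$pc1 - 3
    e2 <- fitCausalLogistic(co2)
    expect_equal(logOR(e2), logOR(e1), tolerance = 1e-6)
    expect_equal(seNaive(e2), seNaive(e1), tolerance = 1e-6)
})

test_that("per-stratum estimation covers each region and site", {
    fx <- packagedFixture()
    for (site in c("oral", "oropharyngeal", "combined")) {
        ests <- estimateAllStrata(fx$cohort,
                                  spec = AnalysisSpec(site_filter = site))
        expect_named(ests, c("Europe", "North America", "South America"))
    }
    # a single-stratum cohort reduces to the whole-cohort fit
    co <- simulateCohort(small_sim_config(), seed = 3)
    ests <- estimateAllStrata(co)
    expect_length(ests, 1L)
    whole <- fitCausalLogistic(co)
    expect_equal(logOR(ests[["Europe"]]), logOR(whole))
    expect_equal(seNaive(ests[["Europe"]]), seNaive(whole))
})

test_that("site filters share controls and split cases", {
    fx <- packagedFixture()
    cd <- SummarizedExperiment::colData(fx$cohort)
    e_oral <- fitCausalLogistic(fx$cohort,
                                spec = AnalysisSpec(site_filter = "oral"))
    e_both <- fitCausalLogistic(fx$cohort)
    expect_equal(e_oral@n_controls, sum(!cd$case))
    expect_equal(e_oral@n_cases, sum(cd$site == "oral"))
    expect_equal(e_both@n_cases, sum(cd$case))
})
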