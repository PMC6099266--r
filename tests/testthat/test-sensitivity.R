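spec_fast <- AnalysisSpec(covariates = c("age_band", "sex", "pc1"))

test_that("leave-one-out produces one refit per omitted variant", {
    fx <- packagedFixture()
    loo <- leaveOneOut(fx$cohort, spec = spec_fast)
    expect_equal(nrow(loo), 5L)
    expect_setequal(loo$omitted, vitaminDWeights()$rsid)
    expect_error(leaveOneOut(fx$cohort, toy_weights()[1, ]), "at least 2")
})

test_that("omitting a zero-weight variant does not move the estimate", {
    co <- simulateCohort(small_sim_config(), seed = 21)
    w <- variantWeights(co)
    w$beta[w$rsid == "rs6013897"] <- 0
    s_full <- relativeExposure(dosages(co), w)
    full <- fitCausalLogistic(co, s_full, spec_fast)
    loo <- leaveOneOut(co, w, spec_fast)
    row <- loo[loo$omitted == "rs6013897", ]
    expect_equal(row$log_or, logOR(full))
    expect_equal(row$se_naive, seNaive(full))
})

test_that("all-subsets enumeration is complete and consistent", {
    fx <- packagedFixture()
    subs <- allSubsets(fx$cohort, spec = spec_fast)
    expect_equal(nrow(subs), 31L)  # 2^5 - 1
    expect_equal(as.integer(table(subs$size)), choose(5, 1:5))
    expect_equal(sum(subs$size == 1), 5L)
    # the full subset reproduces the primary analysis exactly
    full_row <- subs[subs$size == 5, ]
    primary <- fitCausalLogistic(fx$cohort, spec = spec_fast)
    expect_equal(full_row$log_or, logOR(primary))
    expect_equal(full_row$se_naive, seNaive(primary))
    # leave-one-out rows coincide with the size-4 subset rows
    loo <- leaveOneOut(fx$cohort, spec = spec_fast)
    for (i in seq_len(nrow(loo))) {
        members <- setdiff(vitaminDWeights()$rsid, loo$omitted[i])
        match_row <- subs[subs$size == 4 &
            !grepl(loo$omitted[i], subs$subset, fixed = TRUE), ]
        match_row <- match_row[vapply(match_row$subset, function(ss)
            setequal(strsplit(ss, ",")[[1]], members), logical(1)), ]
        expect_equal(match_row$log_or, loo$log_or[i])
    }
    # flag column marks membership of the flagged variant
    expect_equal(subs$contains_flag,
                 grepl("rs116970203", subs$subset, fixed = TRUE))
    expect_error(allSubsets(fx$cohort, weights = VariantWeights(
        rsid = paste0("rs", 1:13), chrom = "1", pos = 1:13,
        effect_allele = "G", other_allele = "T", eaf = 0.5,
        beta = 0.1, se = 0.01, pvalue = 1e-9)), "12")
})

test_that("singleton subsets can be excluded", {
    fx <- packagedFixture()
    subs <- allSubsets(fx$cohort, spec = spec_fast,
                       include_singletons = FALSE)
    expect_equal(nrow(subs), 31L - 5L)
    expect_true(all(subs$size >= 2))
})

test_that("confounder balance returns the overall model F-test", {
    set.seed(99)
    s <- rnorm(300)
    g <- sample(c("a", "b", "c"), 300, replace = TRUE)
    bal <- confounderBalance(s, g)
    fit <- lm(s ~ factor(g))
    expect_equal(bal$p_value, anova(fit)[["Pr(>F)"]][1])
    expect_equal(nrow(bal$levels), 3L)
    expect_equal(sum(bal$levels$n), 300L)
    # identical scores across a partition: no association, F = 0, p = 1
    bal0 <- confounderBalance(rep(1.5, 40), rep(c("a", "b"), 20))
    expect_equal(bal0$p_value, 1)
    expect_equal(bal0$f_stat, 0)
    # missing covariate values are dropped, single level errors
    expect_error(confounderBalance(s, rep(c("a", NA), 150)), "2 non-empty")
})

test_that("a structured stratum is flagged by the balance test", {
    cfg <- SimulationConfig(
        strata = data.frame(
            stratum = c("Europe", "South America"),
            n_cases = c(1000L, 500L), n_controls = c(1200L, 600L)),
        structure_scenario = TRUE)
    co <- simulateCohort(cfg, seed = 23)
    s <- relativeExposure(co)
    bal <- confounderBalance(s, as.character(
        SummarizedExperiment::colData(co)$stratum))
    expect_lt(bal$p_value, 0.05)
})

test_that("effect-allele frequencies by group follow the dosages", {
    w <- toy_weights()
    d <- matrix(2, nrow = 2, ncol = 6, dimnames = list(w$rsid, NULL))
    co <- toy_cohort(d, stratum = rep(c("E", "W"), each = 3))
    eafs <- eafByGroup(co)
    expect_equal(unname(eafs), matrix(1, 2, 2))
    expect_equal(colnames(eafs), c("E", "W"))
})
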