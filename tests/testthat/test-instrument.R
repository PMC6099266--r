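test_that("harmonization matches the hand-built orientation truth table", {
    w <- VariantWeights(rsid = "rs1", chrom = "1", pos = 1L,
                        effect_allele = "G", other_allele = "T",
                        eaf = 0.3, beta = 0.2, se = 0.01, pvalue = 1e-9)
    # every ordered pair of distinct alleles against weight pair (G, T);
    # 4 resolvable orientations, the rest irreconcilable
    truth <- list(
        c("G", "T", "identity"), c("T", "G", "swap"),
        c("C", "A", "strand-flip"), c("A", "C", "swap+flip"),
        c("A", "G", "error"), c("G", "A", "error"),
        c("A", "T", "error"), c("T", "A", "error"),
        c("C", "G", "error"), c("G", "C", "error"),
        c("C", "T", "error"), c("T", "C", "error"))
    d <- matrix(c(0, 1, 2, 1), nrow = 1,
                dimnames = list("rs1", paste0("s", 1:4)))
    for (case in truth) {
        alle <- data.frame(rsid = "rs1", a1 = case[1], a2 = case[2],
                           stringsAsFactors = FALSE)
        if (case[3] == "error") {
            expect_error(harmonizeDosages(w, alle, d), "irreconcilable")
        } else {
            h <- harmonizeDosages(w, alle, d)
            expect_equal(h$audit$action, case[3])
            expected <- if (case[3] %in% c("swap", "swap+flip"))
                2 - d else d
            expect_equal(unname(h$dosage), unname(expected))
        }
    }
})

test_that("harmonizing an already-harmonized cohort is the identity", {
    w <- toy_weights()
    d <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 2,
                dimnames = list(w$rsid, paste0("s", 1:3)))
    alle <- data.frame(rsid = w$rsid, a1 = w$effect_allele,
                       a2 = w$other_allele, stringsAsFactors = FALSE)
    h1 <- harmonizeDosages(w, alle, d)
    h2 <- harmonizeDosages(w, alle, h1$dosage)
    expect_identical(h1$dosage, h2$dosage)
    expect_true(all(h2$audit$action == "identity"))
})

test_that("palindromic variants are dropped by default, inferred on request", {
    w <- VariantWeights(rsid = "rsPal", chrom = "1", pos = 5L,
                        effect_allele = "T", other_allele = "A",
                        eaf = 0.8, beta = 0.1, se = 0.01, pvalue = 1e-9)
    d <- matrix(c(2, 2, 1, 2, 1), nrow = 1,
                dimnames = list("rsPal", paste0("s", 1:5)))
    alle <- data.frame(rsid = "rsPal", a1 = "T", a2 = "A",
                       stringsAsFactors = FALSE)
    expect_warning(h <- harmonizeDosages(w, alle, d), "palindromic")
    expect_equal(nrow(h$dosage), 0L)
    expect_equal(h$audit$action, "dropped")
    # cohort frequency 0.8 is nearer the weight EAF 0.8 than 0.2: identity
    h2 <- harmonizeDosages(w, alle, d, palindromic = "infer")
    expect_equal(h2$audit$action, "identity")
    # a low-frequency counted allele implies the strand counts the A allele
    h3 <- harmonizeDosages(w, alle, 2 - d, palindromic = "infer")
    expect_equal(h3$audit$action, "swap")
    expect_equal(unname(h3$dosage), unname(d))
})

test_that("relative exposure is the beta-weighted dosage sum", {
    w <- vitaminDWeights()
    d0 <- matrix(0, nrow = 5, ncol = 1, dimnames = list(w$rsid, "a"))
    expect_equal(unname(relativeExposure(d0, w)), 0)
    d1 <- d0; d1["rs4588", 1] <- 1
    expect_equal(unname(relativeExposure(d1, w)), 0.2469)
    d2 <- matrix(2, nrow = 5, ncol = 1, dimnames = list(w$rsid, "a"))
    expect_equal(unname(relativeExposure(d2, w)), 1.8772)
})

test_that("score is linear in one-variant components", {
    w <- vitaminDWeights()
    set.seed(11)
    d <- matrix(sample(0:2, 5 * 7, replace = TRUE), nrow = 5,
                dimnames = list(w$rsid, paste0("s", 1:7)))
    total <- relativeExposure(d, w)
    parts <- rowSums(vapply(seq_len(5), function(j) {
        dj <- matrix(0, 5, 7, dimnames = dimnames(d))
        dj[j, ] <- d[j, ]
        relativeExposure(dj, w)
    }, numeric(7)))
    expect_equal(total, parts)
})

test_that("missing dosages null the score unless imputed at 2*EAF", {
    w <- toy_weights()
    d <- matrix(c(1, NA, 2, 1), nrow = 2,
                dimnames = list(w$rsid, c("s1", "s2")))
    s <- relativeExposure(d, w)
    expect_true(is.na(s["s1"]))
    expect_equal(unname(s["s2"]), 0.3 * 2 + 0.1 * 1)
    si <- relativeExposure(d, w, impute_missing = TRUE)
    expect_equal(unname(si["s1"]), 0.3 * 1 + 0.1 * (2 * 0.7))
})

test_that("expected instrument R2 follows the HWE variance formula", {
    w <- vitaminDWeights()
    r2 <- expectedInstrumentR2(w)
    expect_equal(r2, sum(w$beta^2 * 2 * w$eaf * (1 - w$eaf)))
    expect_equal(round(r2, 4), 0.0438)
    expect_gt(r2, 0.03)
    expect_lt(r2, 0.05)
    # zero effect contributes nothing
    w0 <- toy_weights(beta = c(0, 0.1))
    expect_equal(expectedInstrumentR2(w0), 0.1^2 * 2 * 0.7 * 0.3)
    # R2 is quadratic in the betas
    wd <- toy_weights(beta = c(0.6, 0.2))
    expect_equal(expectedInstrumentR2(wd),
                 4 * expectedInstrumentR2(toy_weights()))
})
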