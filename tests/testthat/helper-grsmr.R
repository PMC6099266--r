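suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

extfile <- function(name)
    system.file("extdata", name, package = "grsmr", mustWork = TRUE)

## Two-variant toy instrument for unit tests.
toy_weights <- function(beta = c(0.3, 0.1), se = c(0.05, 0.02),
                        eaf = c(0.4, 0.7)) {
    VariantWeights(rsid = c("rsA", "rsB"), chrom = c("1", "2"),
                   pos = c(100L, 200L),
                   effect_allele = c("G", "A"), other_allele = c("T", "C"),
                   eaf = eaf, beta = beta, se = se,
                   pvalue = c(1e-10, 1e-8))
}

## Small deterministic cohort around given dosages.
toy_cohort <- function(dosage, case = NULL, stratum = "Europe",
                       weights = toy_weights()) {
    n <- ncol(dosage)
    if (is.null(case)) case <- rep(c(TRUE, FALSE), length.out = n)
    colnames(dosage) <- sprintf("i%03d", seq_len(n))
    ph <- data.frame(
        id = colnames(dosage), case = case,
        site = ifelse(case, "oral", "control"),
        stratum = rep(stratum, length.out = n),
        sex = rep(c("male", "female"), length.out = n),
        age_band = rep(c("<=50", "50-60"), length.out = n),
        pc1 = seq_len(n) / n,
        stringsAsFactors = FALSE)
    rownames(ph) <- ph$id
    MRCohort(dosage, ph, weights)
}

## Literal transcription of the DerSimonian-Laird formulas, kept independent
## of the package implementation as a brute-force oracle.
brute_force_dl <- function(theta, se) {
    w <- 1 / se^2
    fe <- sum(w * theta) / sum(w)
    q <- sum(w * (theta - fe)^2)
    k <- length(theta)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    list(pooled = sum(ws * theta) / sum(ws),
         se = 1 / sqrt(sum(ws)),
         q = q, tau2 = tau2,
         i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0)
}

## Small-cohort simulation config (fixture scale) for repeated-seed loops.
small_sim_config <- function(n_cases = 450, n_controls = 550, ...) {
    SimulationConfig(strata = data.frame(stratum = "Europe",
                                         n_cases = as.integer(n_cases),
                                         n_controls = as.integer(n_controls)),
                     ...)
}
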