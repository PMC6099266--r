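#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Instrument variant weights
#'
#' A table of instrument SNPs with their summary-statistic weights: one row
#' per variant, carrying the effect and other allele, the effect-allele
#' frequency (EAF) in the source GWAS, and the per-allele effect (beta) on the
#' standardized (SD log) exposure scale with its standard error and p-value.
#' Extends \linkS4class{DFrame}, so all the usual subsetting and column access
#' applies.
#'
#' Required columns: \code{rsid}, \code{chrom}, \code{pos},
#' \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#' \code{se}, \code{pvalue}.
#'
#' @seealso [readVariantWeights()], [vitaminDWeights()]
#' @export
setClass("VariantWeights", contains = "DFrame")

.vw_required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pvalue")

setValidity("VariantWeights", function(object) {
    msg <- character()
    missing <- setdiff(.vw_required, colnames(object))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (anyDuplicated(object$rsid))
        msg <- c(msg, paste("duplicate rsid:",
                 paste(unique(object$rsid[duplicated(object$rsid)]),
                       collapse = ", ")))
    ok_allele <- c("A", "C", "G", "T")
    if (!all(object$effect_allele %in% ok_allele) ||
        !all(object$other_allele %in% ok_allele))
        msg <- c(msg, "alleles must be one of A/C/G/T")
    if (any(object$effect_allele == object$other_allele))
        msg <- c(msg, "effect_allele must differ from other_allele")
    if (any(!is.finite(object$se)) || any(object$se < 0))
        msg <- c(msg, "se must be non-negative and finite")
    if (any(object$eaf <= 0 | object$eaf >= 1))
        msg <- c(msg, "eaf must lie strictly in (0, 1)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a VariantWeights table
#'
#' @param rsid,chrom,pos,effect_allele,other_allele,eaf,beta,se,pvalue
#'   parallel vectors, one entry per instrument SNP. Alleles are upper-cased.
#' @return A \linkS4class{VariantWeights} object.
#' @examples
#' VariantWeights(rsid = "rs4588", chrom = "4", pos = 72618323L,
#'                effect_allele = "G", other_allele = "T",
#'                eaf = 0.717, beta = 0.2469, se = 0.007, pvalue = 1.68e-263)
#' @export
VariantWeights <- function(rsid, chrom, pos, effect_allele, other_allele,
                           eaf, beta, se, pvalue) {
    df <- DataFrame(rsid = as.character(rsid),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    effect_allele = toupper(as.character(effect_allele)),
                    other_allele = toupper(as.character(other_allele)),
                    eaf = as.numeric(eaf),
                    beta = as.numeric(beta),
                    se = as.numeric(se),
                    pvalue = as.numeric(pvalue))
    rownames(df) <- df$rsid
    new("VariantWeights", df)
}

#' @rdname VariantWeights-class
#' @param x a \code{VariantWeights}.
#' @param name,value column replacement, as for a \code{DataFrame}.
#' @export
setReplaceMethod("$", "VariantWeights", function(x, name, value) {
    d <- as(x, "DFrame")
    d[[name]] <- value
    new("VariantWeights", d)
})

#' @rdname VariantWeights-class
#' @param i column index or name for \code{[[<-}.
#' @export
setReplaceMethod("[[", "VariantWeights", function(x, i, ..., value) {
    d <- as(x, "DFrame")
    d[[i]] <- value
    new("VariantWeights", d)
})

#' Case-control cohort with instrument dosages
#'
#' An \linkS4class{MRCohort} holds an individual-level case-control cohort:
#' the \code{"dosage"} assay stores effect-allele dosages (variants in rows,
#' individuals in columns, values in [0, 2], \code{NA} allowed),
#' \code{rowData} the instrument weights plus harmonization audit
#' (\code{action}, \code{cohort_eaf}), and \code{colData} the phenotypes:
#' \code{case} (logical), \code{site} (\code{oral}, \code{oropharyngeal} or
#' \code{control}), \code{stratum}, \code{sex}, \code{age_band},
#' \code{smoking}, \code{alcohol}, principal-component columns
#' \code{pc1..pcK}, and, for simulated cohorts, the latent \code{exposure}.
#'
#' @seealso [readCohort()], [simulateCohort()], [packagedFixture()]
#' @export
setClass("MRCohort", contains = "SummarizedExperiment")

setValidity("MRCohort", function(object) {
    msg <- character()
    if (!"dosage" %in% names(assays(object)))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (any(!is.na(d) & (d < 0 | d > 2)))
        msg <- c(msg, "dosages must lie in [0, 2]")
    cd <- colData(object)
    for (col in c("case", "site", "stratum"))
        if (!col %in% colnames(cd))
            msg <- c(msg, paste("colData column", col, "is required"))
    if (all(c("case", "site") %in% colnames(cd))) {
        site <- as.character(cd$site)
        if (!all(site %in% c("oral", "oropharyngeal", "control")))
            msg <- c(msg, "site must be oral, oropharyngeal or control")
        if (any(xor(cd$case, site != "control")))
            msg <- c(msg, "site == 'control' must coincide with case == FALSE")
    }
    if (!"beta" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must carry the instrument weights (beta)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn MRCohort-class constructor from a dosage matrix (variants x
#'   samples, effect-allele scale), a phenotype \code{DataFrame}/data.frame
#'   (one row per sample) and a \linkS4class{VariantWeights} table.
#' @param dosage numeric matrix, variants in rows (named by rsid), samples in
#'   columns.
#' @param phenotypes data.frame or DataFrame of per-sample phenotypes.
#' @param weights a \linkS4class{VariantWeights} table covering every row of
#'   \code{dosage}.
#' @export
MRCohort <- function(dosage, phenotypes, weights) {
    stopifnot(is.matrix(dosage))
    if (is.null(rownames(dosage)))
        stop("dosage matrix must have rsid rownames")
    idx <- match(rownames(dosage), weights$rsid)
    if (anyNA(idx))
        stop("dosage rows without a matching weight: ",
             paste(rownames(dosage)[is.na(idx)], collapse = ", "))
    rd <- as(weights, "DFrame")[idx, , drop = FALSE]
    if (!"action" %in% colnames(rd)) rd$action <- "identity"
    if (!"cohort_eaf" %in% colnames(rd))
        rd$cohort_eaf <- rowMeans(dosage, na.rm = TRUE) / 2
    cd <- as(phenotypes, "DFrame")
    cd$site <- factor(as.character(cd$site),
                      levels = c("control", "oral", "oropharyngeal"))
    se <- SummarizedExperiment(assays = SimpleList(dosage = dosage),
                               rowData = rd, colData = cd)
    new("MRCohort", se)
}

#' Causal odds-ratio estimate per SD of exposure
#'
#' Value class for a single allele-score logistic regression fit: the log
#' odds ratio per SD of the (log-scale) exposure, its naive (information
#' matrix) standard error, the bootstrap-corrected standard error accounting
#' for instrument-weight imprecision, the Wald 95\% CI on the OR scale, the
#' p-value, and case/control counts.
#'
#' @seealso [fitCausalLogistic()], [bootstrapWeightCorrection()]
#' @export
setClass("CausalEstimate", representation(
    label = "character",
    log_or = "numeric",
    se_naive = "numeric",
    se_corrected = "numeric",
    ci95 = "numeric",
    pvalue = "numeric",
    n_cases = "integer",
    n_controls = "integer"
))

setValidity("CausalEstimate", function(object) {
    msg <- character()
    if (length(object@ci95) != 2L || object@ci95[1] >= object@ci95[2])
        msg <- c(msg, "ci95 must be an increasing (lower, upper) pair")
    if (object@se_corrected <= 0 || object@se_naive <= 0)
        msg <- c(msg, "standard errors must be positive")
    orr <- exp(object@log_or)
    if (length(object@ci95) == 2L &&
        (orr < object@ci95[1] - 1e-12 || orr > object@ci95[2] + 1e-12))
        msg <- c(msg, "exp(log_or) must lie inside ci95")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

.CausalEstimate <- function(label, log_or, se_naive, se_corrected,
                            pvalue, n_cases, n_controls) {
    z <- stats::qnorm(0.975)
    new("CausalEstimate", label = label, log_or = log_or,
        se_naive = se_naive, se_corrected = se_corrected,
        ci95 = exp(log_or + c(-1, 1) * z * se_corrected),
        pvalue = pvalue,
        n_cases = as.integer(n_cases), n_controls = as.integer(n_controls))
}

#' Random-effects meta-analysis result
#'
#' Pooled log odds ratio, its standard error and OR-scale 95\% CI, the
#' DerSimonian-Laird between-stratum variance \code{tau2}, Cochran's
#' \code{Q} with its degrees of freedom and heterogeneity p-value, and the
#' \code{I2} statistic with a Higgins-Thompson confidence interval.
#'
#' @seealso [dlRandomEffects()]
#' @export
setClass("MetaResult", representation(
    pooled_log_or = "numeric",
    pooled_se = "numeric",
    ci95 = "numeric",
    tau2 = "numeric",
    q = "numeric",
    df = "integer",
    i2 = "numeric",
    i2_ci = "numeric",
    p_het = "numeric"
))

setValidity("MetaResult", function(object) {
    msg <- character()
    if (object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
    if (object@q < 0) msg <- c(msg, "q must be >= 0")
    if (object@i2 < 0 || object@i2 > 1)
        msg <- c(msg, "i2 must lie in [0, 1]")
    if (!anyNA(object@i2_ci) &&
        (object@i2 < object@i2_ci[1] - 1e-12 ||
         object@i2 > object@i2_ci[2] + 1e-12))
        msg <- c(msg, "i2 must lie inside i2_ci")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Simulation configuration for a GAME-ON-like case-control cohort
#'
#' Holds everything [simulateCohort()] needs: the instrument weights, the
#' per-stratum case/control counts, the causal effect \code{causal_log_or}
#' (log OR per SD of the exposure), confounder effects on the outcome logit,
#' the population-structure scenario (a latent subpopulation within
#' \code{structure_stratum} whose allele frequencies are shifted and which
#' carries \code{structure_log_or} on the outcome), the number of principal
#' components, the baseline-risk intercept \code{alpha} on the logit scale,
#' the population oversampling factor \code{pop_mult}, and the seed.
#'
#' Defaults reproduce the scale and composition of the emulated consortium:
#' Europe 2,323/2,928, North America 2,254/2,329, South America 556/727
#' (total 11,117), an oral:oropharyngeal case split of 52.6:47.4, and the
#' five-SNP 25OHD instrument, under which the score explains ~4.4\% of the
#' unit exposure variance.
#'
#' @seealso [SimulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig", representation(
    weights = "VariantWeights",
    strata = "data.frame",
    causal_log_or = "numeric",
    noise_sd = "numeric",
    confounder_effects = "numeric",
    oral_fraction = "numeric",
    structure_scenario = "logical",
    structure_stratum = "character",
    eaf_shift = "numeric",
    structure_log_or = "numeric",
    subpop_fraction = "numeric",
    n_pcs = "integer",
    alpha = "numeric",
    pop_mult = "numeric",
    impute_missing = "logical",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    st <- object@strata
    if (!all(c("stratum", "n_cases", "n_controls") %in% colnames(st)))
        return("strata needs columns stratum, n_cases, n_controls")
    if (any(st$n_cases <= 0) || any(st$n_controls <= 0))
        msg <- c(msg, "n_cases and n_controls must be > 0")
    if (object@oral_fraction < 0 || object@oral_fraction > 1)
        msg <- c(msg, "oral_fraction must lie in [0, 1]")
    if (object@structure_scenario) {
        if (!object@structure_stratum %in% st$stratum)
            msg <- c(msg, "structure_stratum must name a stratum")
        w <- object@weights
        shift <- object@eaf_shift
        bad <- names(shift)[!names(shift) %in% w$rsid]
        if (length(bad))
            msg <- c(msg, paste("eaf_shift names unknown rsid:",
                                paste(bad, collapse = ", ")))
        idx <- match(names(shift), w$rsid)
        sub_eaf <- w$eaf[idx] + shift / object@subpop_fraction
        if (any(sub_eaf <= 0 | sub_eaf >= 1, na.rm = TRUE))
            msg <- c(msg, "shifted subpopulation EAFs must stay in (0, 1)")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
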