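.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize cohort dosages to the effect allele of the weights
#'
#' Two-sample designs take weights from an exposure GWAS and genotypes from
#' the outcome cohort, so the allele an individual-level dosage counts need
#' not be the weight's effect allele. For each variant this function decides
#' among \code{identity} (cohort counts the effect allele), \code{swap}
#' (cohort counts the other allele; dosage becomes \code{2 - d}),
#' \code{strand-flip} (cohort reports the opposite strand) and
#' \code{swap+flip}, and re-orients the dosages accordingly. Palindromic
#' (A/T, C/G) variants, for which strand cannot be resolved from alleles
#' alone, are dropped with a warning by default, or resolved by comparing the
#' cohort allele frequency with the weight EAF when
#' \code{palindromic = "infer"}.
#'
#' @param weights a \linkS4class{VariantWeights} table.
#' @param cohort_alleles data.frame with columns \code{rsid}, \code{a1} (the
#'   allele the dosage counts), \code{a2} (the other allele).
#' @param dosage numeric matrix of dosages counting \code{a1}; rows named by
#'   rsid, one column per sample.
#' @param palindromic \code{"drop"} (default) or \code{"infer"}.
#' @return list with \code{dosage} (re-oriented matrix, dropped variants
#'   removed) and \code{audit} (data.frame: rsid, action, cohort_eaf — the
#'   realized effect-allele frequency after orientation).
#' @export
harmonizeDosages <- function(weights, cohort_alleles, dosage,
                             palindromic = c("drop", "infer")) {
    palindromic <- match.arg(palindromic)
    idx <- match(weights$rsid, cohort_alleles$rsid)
    if (anyNA(idx))
        stop("cohort alleles missing for: ",
             paste(weights$rsid[is.na(idx)], collapse = ", "))
    cohort_alleles <- cohort_alleles[idx, , drop = FALSE]
    dosage <- dosage[match(weights$rsid, rownames(dosage)), , drop = FALSE]
    acts <- character(nrow(weights))
    for (j in seq_len(nrow(weights))) {
        E <- weights$effect_allele[j]; O <- weights$other_allele[j]
        a1 <- toupper(cohort_alleles$a1[j]); a2 <- toupper(cohort_alleles$a2[j])
        if (!all(c(a1, a2) %in% names(.complement)))
            stop("non-ACGT cohort alleles for ", weights$rsid[j])
        if (.is_palindromic(E, O)) {
            if (!setequal(c(a1, a2), c(E, O)))
                stop("irreconcilable alleles for palindromic variant ",
                     weights$rsid[j])
            if (palindromic == "drop") {
                warning("dropping palindromic variant ", weights$rsid[j],
                        " (strand unresolvable from alleles)")
                acts[j] <- "dropped"
            } else {
                f <- mean(dosage[j, ], na.rm = TRUE) / 2
                acts[j] <- if (abs(f - weights$eaf[j]) <=
                               abs(f - (1 - weights$eaf[j])))
                    "identity" else "swap"
            }
        } else if (a1 == E && a2 == O) {
            acts[j] <- "identity"
        } else if (a1 == O && a2 == E) {
            acts[j] <- "swap"
        } else if (.complement[a1] == E && .complement[a2] == O) {
            acts[j] <- "strand-flip"
        } else if (.complement[a1] == O && .complement[a2] == E) {
            acts[j] <- "swap+flip"
        } else {
            stop("irreconcilable allele pair (", a1, ",", a2, ") for ",
                 weights$rsid[j], " vs weight (", E, ",", O, ")")
        }
        if (acts[j] %in% c("swap", "swap+flip"))
            dosage[j, ] <- 2 - dosage[j, ]
    }
    keep <- acts != "dropped"
    audit <- data.frame(rsid = weights$rsid, action = acts,
                        cohort_eaf = rowMeans(dosage, na.rm = TRUE) / 2,
                        stringsAsFactors = FALSE)
    disc <- keep & abs(audit$cohort_eaf - weights$eaf) > 0.2
    if (any(disc))
        warning("EAF discordance > 0.2 after harmonization for: ",
                paste(weights$rsid[disc], collapse = ", "))
    list(dosage = dosage[keep, , drop = FALSE],
         audit = audit)
}

#' Per-individual relative exposure (weighted allele score)
#'
#' The instrument score \eqn{s_i = \sum_j \beta_j g_{ij}} over the retained
#' variants, in SD-log-exposure units: because each \eqn{\beta_j} is
#' per-allele on the standardized log scale, a unit increase in the score
#' corresponds to one SD of the log exposure, and no within-cohort
#' re-standardization is applied. Individuals with a missing dosage at any
#' retained variant get \code{NA} (and are excluded from downstream fits)
#' unless \code{impute_missing} replaces missing dosages with \code{2 * EAF}.
#'
#' @param cohort an \linkS4class{MRCohort}, or a dosage matrix (variants x
#'   samples) named by rsid.
#' @param weights a \linkS4class{VariantWeights}; defaults to the weights
#'   carried by the cohort. Variants absent from \code{weights} rows of the
#'   dosage matrix are an error; a subset of weights restricts the score to
#'   that subset.
#' @param impute_missing replace missing dosages by \code{2 * EAF}.
#' @return named numeric vector of scores, one per sample.
#' @examples
#' w <- vitaminDWeights()
#' d <- matrix(2, nrow = 5, ncol = 1, dimnames = list(w$rsid, "s1"))
#' relativeExposure(d, w)  # 2 * sum(beta) = 1.8772
#' @export
relativeExposure <- function(cohort, weights = NULL, impute_missing = FALSE) {
    d <- if (is(cohort, "MRCohort")) dosages(cohort) else cohort
    if (is.null(weights)) {
        if (!is(cohort, "MRCohort"))
            stop("weights must be supplied for a bare dosage matrix")
        weights <- variantWeights(cohort)
    }
    keep <- intersect(rownames(d), weights$rsid)
    if (length(keep) == 0L) stop("no retained variants with a weight")
    d <- d[keep, , drop = FALSE]
    beta <- weights$beta[match(keep, weights$rsid)]
    if (impute_missing && anyNA(d)) {
        eaf <- weights$eaf[match(keep, weights$rsid)]
        for (j in seq_along(keep)) {
            nas <- is.na(d[j, ])
            if (any(nas)) d[j, nas] <- 2 * eaf[j]
        }
    }
    s <- as.numeric(crossprod(d, beta))
    names(s) <- colnames(d)
    s
}

#' Expected variance explained by the instrument
#'
#' Under Hardy-Weinberg and linkage equilibrium, a weighted allele score on a
#' unit-variance standardized trait explains
#' \eqn{R^2 = \sum_j \beta_j^2 \, 2 p_j (1 - p_j)} of the trait variance,
#' where \eqn{p_j} is the effect-allele frequency. For the packaged 25OHD
#' instrument this is 0.0438, inside the 3-5\% band reported for these
#' variants.
#'
#' @param weights a \linkS4class{VariantWeights}.
#' @return the expected \eqn{R^2} fraction.
#' @export
expectedInstrumentR2 <- function(weights) {
    sum(weights$beta^2 * 2 * weights$eaf * (1 - weights$eaf))
}
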