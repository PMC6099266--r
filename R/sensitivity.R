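#' Leave-one-out instrument sensitivity analysis
#'
#' Repeats the causal fit k times, each time rebuilding the score with one
#' variant removed; a single variant whose omission moves the estimate
#' materially (e.g. through a pleiotropic outcome pathway) is thereby
#' exposed.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param weights a \linkS4class{VariantWeights} (default: the cohort's);
#'   needs >= 2 variants.
#' @param spec an [AnalysisSpec()].
#' @return data.frame keyed by \code{omitted} rsid with the refit estimates.
#' @export
leaveOneOut <- function(cohort, weights = NULL, spec = AnalysisSpec()) {
    if (is.null(weights)) weights <- variantWeights(cohort)
    k <- nrow(weights)
    if (k < 2L) stop("leave-one-out needs at least 2 instrument variants")
    rows <- lapply(seq_len(k), function(j) {
        w <- weights[-j, , drop = FALSE]
        s <- relativeExposure(dosages(cohort), w)
        cbind(omitted = weights$rsid[j],
              as.data.frame(fitCausalLogistic(cohort, s, spec)))
    })
    do.call(rbind, rows)
}

#' All-subsets instrument sensitivity analysis
#'
#' Fits the causal model with every non-empty subset of the instrument
#' variants (2^k - 1 scores, singletons included), flagging the subsets that
#' contain a named variant so the resulting OR histogram can be split on it.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param weights a \linkS4class{VariantWeights} (default: the cohort's);
#'   at most 12 variants (use an explicit subset list beyond that).
#' @param spec an [AnalysisSpec()].
#' @param flag_snp rsid whose membership is marked in column
#'   \code{contains_flag} (default: the largest-beta variant).
#' @param include_singletons drop single-variant instruments when
#'   \code{FALSE}.
#' @return data.frame with columns \code{subset} (comma-joined rsids),
#'   \code{size}, \code{contains_flag} and the estimate columns.
#' @export
allSubsets <- function(cohort, weights = NULL, spec = AnalysisSpec(),
                       flag_snp = NULL, include_singletons = TRUE) {
    if (is.null(weights)) weights <- variantWeights(cohort)
    k <- nrow(weights)
    if (k > 12L)
        stop("more than 12 variants (", 2^k - 1, " subsets); ",
             "supply an explicit subset list instead")
    if (is.null(flag_snp))
        flag_snp <- weights$rsid[which.max(abs(weights$beta))]
    d <- dosages(cohort)
    rows <- list()
    for (m in seq_len(2^k - 1)) {
        members <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
        if (!include_singletons && length(members) == 1L) next
        w <- weights[members, , drop = FALSE]
        s <- relativeExposure(d, w)
        rows[[length(rows) + 1L]] <- cbind(
            subset = paste(w$rsid, collapse = ","),
            size = length(members),
            contains_flag = flag_snp %in% w$rsid,
            as.data.frame(fitCausalLogistic(cohort, s, spec)))
    }
    do.call(rbind, rows)
}

#' Instrument-confounder balance test
#'
#' Under valid randomization of alleles the instrument score should be
#' independent of classical confounders. Regresses the score on the
#' categorical covariate (factor coding) and reports the overall F-test
#' p-value of the model against the intercept-only model, plus the per-level
#' mean, SD, range and count (the boxplot summaries).
#'
#' @param scores named numeric score vector.
#' @param covariate vector of categorical values parallel to \code{scores}
#'   (missing values dropped); needs >= 2 non-empty levels.
#' @return list with \code{p_value} (overall F), \code{f_stat},
#'   \code{levels} (data.frame of per-level summaries) and \code{n}.
#' @export
confounderBalance <- function(scores, covariate) {
    ok <- !is.na(scores) & !is.na(covariate) & covariate != ""
    s <- scores[ok]
    f <- droplevels(factor(covariate[ok]))
    if (nlevels(f) < 2L)
        stop("need at least 2 non-empty covariate levels")
    if (stats::var(s) == 0) {
        an <- list(`Pr(>F)` = c(1, NA), `F value` = c(0, NA))
    } else {
        an <- stats::anova(stats::lm(s ~ f))
    }
    lev <- data.frame(
        level = levels(f),
        n = as.integer(table(f)),
        mean = as.numeric(tapply(s, f, mean)),
        sd = as.numeric(tapply(s, f, stats::sd)),
        min = as.numeric(tapply(s, f, min)),
        max = as.numeric(tapply(s, f, max)),
        stringsAsFactors = FALSE)
    list(p_value = an[["Pr(>F)"]][1], f_stat = an[["F value"]][1],
         levels = lev, n = length(s))
}

#' Effect-allele frequency by group
#'
#' Realized effect-allele frequency (mean dosage / 2) of each instrument
#' variant within each level of a grouping variable (by default the
#' geographic stratum) — the per-region allele-frequency comparison.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param weights a \linkS4class{VariantWeights} (default: the cohort's).
#' @param group grouping vector (default: \code{colData(cohort)$stratum}).
#' @return matrix, variants x groups, of EAFs.
#' @export
eafByGroup <- function(cohort, weights = NULL, group = NULL) {
    if (is.null(weights)) weights <- variantWeights(cohort)
    if (is.null(group)) group <- as.character(colData(cohort)$stratum)
    d <- dosages(cohort)[weights$rsid, , drop = FALSE]
    groups <- sort(unique(group))
    out <- vapply(groups, function(gr)
        rowMeans(d[, group == gr, drop = FALSE], na.rm = TRUE) / 2,
        numeric(nrow(d)))
    if (is.null(dim(out)))
        out <- matrix(out, nrow = nrow(d),
                      dimnames = list(weights$rsid, groups))
    out
}
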