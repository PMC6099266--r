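#' Read an instrument weight table
#'
#' Reads a tab-separated table of instrument SNP weights with header columns
#' \code{rsid chrom pos effect_allele other_allele eaf beta se pvalue}.
#' Alleles are upper-cased; duplicated rsids, alleles outside A/C/G/T and
#' non-positive standard errors are errors.
#'
#' @param path path to the TSV file.
#' @return A \linkS4class{VariantWeights} object, one row per data row.
#' @examples
#' w <- readVariantWeights(system.file("extdata", "vitamin_d_weights.tsv",
#'                                     package = "grsmr"))
#' sum(w$beta)  # 0.9386 for the packaged 25OHD instrument
#' @export
readVariantWeights <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    missing <- setdiff(.vw_required, colnames(tab))
    if (length(missing))
        stop("weight table lacks columns: ", paste(missing, collapse = ", "))
    if (any(!is.finite(tab$se) | tab$se <= 0))
        stop("weight table contains se <= 0")
    VariantWeights(rsid = tab$rsid, chrom = tab$chrom, pos = tab$pos,
                   effect_allele = tab$effect_allele,
                   other_allele = tab$other_allele,
                   eaf = tab$eaf, beta = tab$beta, se = tab$se,
                   pvalue = tab$pvalue)
}

#' @rdname readVariantWeights
#' @param weights a \linkS4class{VariantWeights} table to write.
#' @export
writeVariantWeights <- function(weights, path) {
    df <- as.data.frame(weights)[, .vw_required]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' The packaged five-SNP 25OHD instrument
#'
#' Weights for the five variants (GC rs4588, PDE3B rs116970203, DHCR7
#' rs4423214, CYP2R1 rs10741657, CYP24A1 rs6013897) reliably associated with
#' circulating 25-hydroxyvitamin D, with per-allele betas on the SD-log-25OHD
#' scale from the source GWAS.
#'
#' @return A \linkS4class{VariantWeights} with 5 rows.
#' @export
vitaminDWeights <- function() {
    if (is.null(.fixture_env$vitd_weights))
        .fixture_env$vitd_weights <- readVariantWeights(
            system.file("extdata", "vitamin_d_weights.tsv",
                        package = "grsmr", mustWork = TRUE))
    .fixture_env$vitd_weights
}

.read_phenotypes <- function(path) {
    ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""), check.names = FALSE)
    need <- c("id", "case", "site", "stratum")
    missing <- setdiff(need, colnames(ph))
    if (length(missing))
        stop("phenotype table lacks columns: ",
             paste(missing, collapse = ", "))
    ph$id <- as.character(ph$id)
    if (anyDuplicated(ph$id)) stop("duplicate sample ids in phenotype table")
    if (is.character(ph$case))
        ph$case <- tolower(ph$case) %in% c("true", "1", "yes")
    ph$case <- as.logical(ph$case)
    bad <- xor(ph$case, ph$site != "control")
    if (any(bad))
        stop("case/site mismatch for samples: ",
             paste(utils::head(ph$id[bad], 5), collapse = ", "))
    rownames(ph) <- ph$id
    ph
}

## Dosage-table input: samples in rows ('id' column), one column per rsid,
## values already counted on the effect allele of the weight table.
.read_dosage_table <- function(path, weights) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!"id" %in% colnames(tab)) stop("dosage table needs an 'id' column")
    ids <- as.character(tab$id)
    miss <- setdiff(weights$rsid, colnames(tab))
    if (length(miss))
        stop("instrument rsids absent from dosage table: ",
             paste(miss, collapse = ", "))
    d <- t(as.matrix(tab[, weights$rsid, drop = FALSE]))
    colnames(d) <- ids
    storage.mode(d) <- "double"
    list(dosage = d,
         alleles = data.frame(rsid = weights$rsid,
                              a1 = weights$effect_allele,
                              a2 = weights$other_allele,
                              stringsAsFactors = FALSE))
}

## VCF input: ALT-allele dosages from DS when present, else from hard GT
## calls. Returned counted allele a1 = ALT, a2 = REF.
.read_vcf_dosages <- function(path, weights) {
    vcf <- VariantAnnotation::readVcf(path)
    ids <- names(SummarizedExperiment::rowRanges(vcf))
    keep <- match(weights$rsid, ids)
    if (anyNA(keep))
        stop("instrument rsids absent from VCF: ",
             paste(weights$rsid[is.na(keep)], collapse = ", "))
    vcf <- vcf[keep, ]
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
    geno <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(geno)) {
        d <- geno$DS
        storage.mode(d) <- "double"
    } else if ("GT" %in% names(geno)) {
        gt <- geno$GT
        cnt <- function(g) {
            if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
            sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
        }
        d <- apply(gt, c(1, 2), cnt)
    } else stop("VCF has neither DS nor GT genotype fields")
    rownames(d) <- weights$rsid
    list(dosage = d,
         alleles = data.frame(rsid = weights$rsid, a1 = alt, a2 = ref,
                              stringsAsFactors = FALSE))
}

#' Assemble a cohort from genotype and phenotype files
#'
#' Joins a genotype source (VCF, possibly bgzipped, or a TSV dosage matrix)
#' with a phenotype TSV on sample id, harmonizes the dosages to the effect
#' allele of \code{weights} (allele swaps and strand flips resolved via
#' [harmonizeDosages()]) and returns an \linkS4class{MRCohort}. VCF dosages
#' are taken from the DS field when present and from hard GT calls otherwise;
#' dosage-table input is taken verbatim as effect-allele counts.
#'
#' @param genotype_path VCF (\code{.vcf}/\code{.vcf.gz}/\code{.vcf.bgz}) or
#'   dosage TSV (samples in rows, column \code{id} plus one column per rsid).
#' @param phenotype_path phenotype TSV with header
#'   \code{id case site stratum sex age_band smoking alcohol pc1..pcK};
#'   missing values coded as empty strings.
#' @param weights a \linkS4class{VariantWeights} table.
#' @param palindromic policy for A/T and C/G SNPs, see [harmonizeDosages()].
#' @return An \linkS4class{MRCohort} containing the samples present in both
#'   sources; the join cardinality is reported via \code{message()}.
#' @export
readCohort <- function(genotype_path, phenotype_path, weights,
                       palindromic = c("drop", "infer")) {
    palindromic <- match.arg(palindromic)
    ph <- .read_phenotypes(phenotype_path)
    is_vcf <- grepl("\\.vcf(\\.b?gz)?$", genotype_path)
    geno <- if (is_vcf) .read_vcf_dosages(genotype_path, weights)
            else .read_dosage_table(genotype_path, weights)
    shared <- intersect(colnames(geno$dosage), rownames(ph))
    if (length(shared) == 0L)
        stop("no overlapping samples between genotype and phenotype sources")
    message(sprintf("joined %d samples (%d genotyped, %d phenotyped)",
                    length(shared), ncol(geno$dosage), nrow(ph)))
    d <- geno$dosage[, shared, drop = FALSE]
    ## dosage-table input is effect-allele-oriented by contract; only VCF
    ## dosages (ALT counts) need re-orientation
    harm <- if (is_vcf)
        harmonizeDosages(weights, geno$alleles, d, palindromic = palindromic)
    else
        list(dosage = d,
             audit = data.frame(rsid = weights$rsid, action = "identity",
                                cohort_eaf = rowMeans(d, na.rm = TRUE) / 2,
                                stringsAsFactors = FALSE))
    cohort <- MRCohort(harm$dosage, ph[shared, , drop = FALSE],
                       weights[match(rownames(harm$dosage), weights$rsid), ])
    rowData(cohort)$action <- harm$audit$action
    rowData(cohort)$cohort_eaf <- harm$audit$cohort_eaf
    cohort
}

#' Write a cohort as dosage + phenotype TSVs
#'
#' Inverse of [readCohort()] for the dosage-table dialect: writes
#' \code{<prefix>_dosages.tsv} (effect-allele scale) and
#' \code{<prefix>_phenotypes.tsv}.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, prefix) {
    d <- t(dosages(cohort))
    dt <- data.frame(id = rownames(d), d, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ph <- as.data.frame(colData(cohort))
    ph <- data.frame(id = colnames(cohort),
                     ph[, setdiff(colnames(ph), "id"), drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    paths <- paste0(prefix, c("_dosages.tsv", "_phenotypes.tsv"))
    utils::write.table(dt, paths[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ph, paths[2], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(paths)
}
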