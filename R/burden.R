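# Mutation frequency / burden statistics, LOH flag, variant-type tallies,
# and the covariate regressions on burden.

#' Mutation frequency
#'
#' The number of unique mutations (distinct variant keys) in a region
#' divided by the total number of duplex nucleotides sequenced there.
#' Duplicate records of one key count once.
#'
#' @param calls duplex call table (one sample, or a pooled table if a
#'   pooled frequency is wanted), restricted to `region` if given.
#' @param depth a [DepthProfile-class] covering the region.
#' @param region optional [GenomicRanges::GRanges]; both the calls and the
#'   depth denominator are restricted to it.
#' @return mutations per duplex nucleotide.
#' @export
mutationFrequency <- function(calls, depth, region = NULL) {
    calls <- checkCalls(calls)
    if (!is.null(region) && nrow(calls)) {
        keep <- IRanges::overlapsAny(.callGRanges(calls), region)
        calls <- calls[keep, , drop = FALSE]
    }
    tot <- totalDuplexNucleotides(depth, region)
    if (tot <= 0) stop("zero duplex nucleotides in the region")
    length(unique(variantKey(calls))) / tot
}

#' Mutation burden
#'
#' Total mutant duplex reads (bases) over coding calls divided by the total
#' duplex depth summed over coding positions; unlike mutation frequency,
#' burden weights each mutation by its clone size.
#'
#' @param codingCalls duplex call table restricted to coding calls.
#' @param depth a [DepthProfile-class].
#' @param codingRegion [GenomicRanges::GRanges] of coding positions; the
#'   denominator sums depth over these positions only.
#' @return mutant duplex bases per coding duplex nucleotide.
#' @export
mutationBurden <- function(codingCalls, depth, codingRegion) {
    codingCalls <- checkCalls(codingCalls)
    denom <- totalDuplexNucleotides(depth, codingRegion)
    if (denom <= 0) stop("zero coding duplex nucleotides")
    sum(codingCalls$alt_duplex_reads) / denom
}

#' Coding / non-coding mutation frequency ratio
#'
#' @param codingMF,noncodingMF per-sample mutation frequencies over the
#'   coding and non-coding parts of a gene region.
#' @return `codingMF / noncodingMF`; `NA` with a warning where the
#'   non-coding frequency is zero (the ratio is undefined, and infinities
#'   must not propagate into group summaries).
#' @export
codingNoncodingRatio <- function(codingMF, noncodingMF) {
    out <- ifelse(noncodingMF > 0, codingMF / noncodingMF, NA_real_)
    if (any(noncodingMF == 0))
        warning("non-coding MF of 0: ratio reported as missing")
    out
}

#' Loss-of-heterozygosity flag from germline-site VAF
#'
#' Flags a sample as showing allelic imbalance at the germline site iff the
#' germline variant's VAF there is strictly greater than 0.5. Samples where
#' the site is not covered at `minDepth` get a missing flag (`NA`), not
#' `FALSE`.
#'
#' @param siteCalls data.frame with one row per sample: `sample_id`,
#'   `duplex_depth` and `vaf` (or `alt_duplex_reads`) at the germline site.
#' @param samples sample ids to report (default: those present).
#' @param minDepth minimum duplex depth for the site to count as covered.
#' @return named logical vector, one flag per sample (`NA` = uncovered).
#' @export
germlineVafLohFlag <- function(siteCalls, samples = NULL, minDepth = 1000) {
    if (is.null(samples)) samples <- unique(siteCalls$sample_id)
    if (!"vaf" %in% names(siteCalls))
        siteCalls$vaf <- siteCalls$alt_duplex_reads / siteCalls$duplex_depth
    out <- rep(NA, length(samples))
    names(out) <- samples
    m <- match(samples, siteCalls$sample_id)
    got <- !is.na(m)
    covered <- got & siteCalls$duplex_depth[m] >= minDepth
    out[covered] <- siteCalls$vaf[m[covered]] > 0.5
    out
}

#' Tally variant types
#'
#' Counts calls by variant class and by consequence. Multi-nucleotide
#' substitutions (e.g. CC>TT dinucleotides) are single events tallied
#' separately from SNVs; the two tallies each partition the input.
#'
#' @param calls duplex call table (with a `consequence` column for the
#'   consequence tally; absent consequences tally as `NA`).
#' @return list with `byClass` and `byConsequence` tables (all levels
#'   present, zeros included).
#' @export
tallyVariantTypes <- function(calls) {
    calls <- checkCalls(calls)
    classes <- c("SNV", "MNV", "insertion", "deletion")
    cons <- c("synonymous", "missense", "nonsense", "splice", "noncoding",
              "indel_coding", "indel_noncoding")
    byClass <- table(factor(calls$variant_class, classes))
    byCons <- if ("consequence" %in% names(calls))
        table(factor(calls$consequence, cons))
    else table(factor(character(0), cons))
    list(byClass = byClass, byConsequence = byCons)
}

#' Nonsynonymous share of coding mutations
#'
#' The proportion of coding mutations that are nonsynonymous (missense,
#' nonsense or splice), as a whole-number percentage: e.g. 4 of 7 prints
#' as 57, 20 of 24 as 83.
#'
#' @param consequences character vector of consequence labels for coding
#'   mutations.
#' @return list with `n_nonsyn`, `n_total`, and `percent`
#'   (`round(100 * n_nonsyn / n_total)`).
#' @export
nonsynonymousPercent <- function(consequences) {
    nonsyn <- sum(consequences %in% c("missense", "nonsense", "splice"))
    total <- length(consequences)
    if (total == 0L) stop("no coding mutations supplied")
    list(n_nonsyn = nonsyn, n_total = total,
         percent = round(100 * nonsyn / total))
}

#' Burden regressions on age, carrier status and chemotherapy
#'
#' Fits the burden models: univariate ordinary least squares of the
#' response against age in years (`Y ~ 1 + age`), or the multivariate
#' Gaussian identity-link model `Y ~ 1 + age + LFS + CTx` with age in
#' decades and carrier (LFS) and chemotherapy (CTx) status as binary
#' covariates. Responses are typically MF or MB scaled per 1e7 bases;
#' rescaling the response rescales coefficients and intervals but leaves
#' t-statistics and p-values unchanged.
#'
#' @param covariates data.frame with one row per sample: `response`, and
#'   `age_years` (univariate) or `age_decades`, `LFS`, `CTx` (0/1)
#'   (multivariate). No missing values allowed.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame with `term`, `estimate`, `conf.low`, `conf.high`
#'   (95%), `statistic`, `p.value`.
#' @export
fitBurdenModels <- function(covariates,
                            mode = c("univariate", "multivariate")) {
    mode <- match.arg(mode)
    need <- if (mode == "univariate") c("response", "age_years")
            else c("response", "age_decades", "LFS", "CTx")
    miss <- setdiff(need, names(covariates))
    if (length(miss))
        stop("covariate table missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyNA(covariates[need])) stop("missing covariate values")
    if (nrow(covariates) < length(need) + 1L)
        stop("need at least ", length(need) + 1L, " samples")
    fml <- if (mode == "univariate") response ~ age_years
           else response ~ age_decades + LFS + CTx
    fit <- stats::lm(fml, data = covariates)
    if (anyNA(stats::coef(fit)))
        stop("collinear covariates: model is not identifiable")
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit, level = 0.95)
    data.frame(term = rownames(sm), estimate = sm[, 1],
               conf.low = ci[, 1], conf.high = ci[, 2],
               statistic = sm[, 3], p.value = sm[, 4],
               row.names = NULL)
}
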