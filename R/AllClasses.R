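#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' Filter thresholds for the duplex variant filter cascade
#'
#' Container for the post-pipeline filtering thresholds: minimum duplex depth
#' at the variant position, maximum no-call fraction, the VAF above which a
#' call is treated as a germline polymorphism, and the recurrence/mismatch
#' conditions of the recurrent-artifact filter.
#'
#' All comparisons in the cascade are strict (a call at exactly the threshold
#' survives), matching the "lower than"/"greater than" wording of the rules.
#'
#' @slot minDepth minimum duplex depth (reads); calls below are discarded.
#' @slot maxNoCall maximum tolerated no-call fraction.
#' @slot germlineVaf VAF above which a call is considered germline.
#' @slot artifactMinSamples minimum number of carrying samples for the
#'   recurrent-artifact rule.
#' @slot artifactMinMismatches minimum mismatch annotation for the
#'   recurrent-artifact rule.
#' @seealso [filterThresholds()], [applySiteFilters()], [filterCascade()]
#' @exportClass FilterThresholds
setClass("FilterThresholds", representation(
    minDepth = "numeric",
    maxNoCall = "numeric",
    germlineVaf = "numeric",
    artifactMinSamples = "integer",
    artifactMinMismatches = "integer"
))

setValidity("FilterThresholds", function(object) {
    msg <- character()
    if (object@minDepth <= 0) msg <- c(msg, "minDepth must be positive")
    if (object@maxNoCall <= 0 || object@maxNoCall > 1)
        msg <- c(msg, "maxNoCall must be in (0, 1]")
    if (object@germlineVaf <= 0 || object@germlineVaf >= 0.5)
        msg <- c(msg, "germlineVaf must be in (0, 0.5)")
    if (object@artifactMinSamples < 1L)
        msg <- c(msg, "artifactMinSamples must be >= 1")
    if (object@artifactMinMismatches < 1L)
        msg <- c(msg, "artifactMinMismatches must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct filter thresholds
#'
#' Defaults are the thresholds used throughout the package: depth >= 1000
#' duplex reads, no-call fraction <= 0.1, germline VAF cut at 0.3, and
#' recurrent artifacts defined as keys seen in >= 3 samples with a mismatch
#' annotation >= 8.
#'
#' @param minDepth minimum duplex depth at the variant position.
#' @param maxNoCall maximum no-call fraction.
#' @param germlineVaf VAF above which a call is treated as germline.
#' @param artifactMinSamples recurrence threshold (number of samples).
#' @param artifactMinMismatches mismatch-annotation threshold.
#' @return A [FilterThresholds-class] object.
#' @examples
#' filterThresholds()
#' @export
filterThresholds <- function(minDepth = 1000, maxNoCall = 0.1,
                             germlineVaf = 0.3, artifactMinSamples = 3L,
                             artifactMinMismatches = 8L) {
    new("FilterThresholds", minDepth = as.numeric(minDepth),
        maxNoCall = as.numeric(maxNoCall),
        germlineVaf = as.numeric(germlineVaf),
        artifactMinSamples = as.integer(artifactMinSamples),
        artifactMinMismatches = as.integer(artifactMinMismatches))
}

setMethod("show", "FilterThresholds", function(object) {
    cat("FilterThresholds: depth >=", object@minDepth,
        "| no-call <=", object@maxNoCall,
        "| germline VAF >", object@germlineVaf,
        "| artifact >=", object@artifactMinSamples, "samples &",
        object@artifactMinMismatches, "mismatches\n")
})

#' Per-position duplex depth over a set of panel intervals
#'
#' Stores one duplex-consensus depth value per position of a (reduced,
#' sorted) set of genomic intervals. The total number of duplex nucleotides
#' sequenced -- the denominator of every mutation frequency -- is the sum of
#' the per-position depths.
#'
#' @slot regions a sorted, non-overlapping [GenomicRanges::GRanges] of the
#'   covered intervals.
#' @slot depth a list of integer vectors, one per region, each of length
#'   `width(region)`.
#' @seealso [simulateDepth()], [totalDuplexNucleotides()], [depthAt()]
#' @exportClass DepthProfile
setClass("DepthProfile", representation(
    regions = "GRanges",
    depth = "list"
))

setValidity("DepthProfile", function(object) {
    w <- GenomicRanges::width(object@regions)
    if (length(object@depth) != length(object@regions))
        return("one depth vector per region required")
    lens <- vapply(object@depth, length, integer(1))
    if (length(w) && !all(lens == w))
        return("depth vector lengths must equal region widths")
    if (any(vapply(object@depth, function(d) any(d < 0), logical(1))))
        return("depths must be non-negative")
    TRUE
})

#' Gene model: CDS intervals, coding sequence and protein domains
#'
#' A minimal transcript model sufficient for consequence classification,
#' site enumeration and codon-level aggregation: the genomic CDS intervals,
#' the in-frame coding sequence (5'->3' on the coding strand, stop codon
#' included), named protein-domain residue ranges, and the splice padding
#' (+/- 2 nt) used when classifying coding variants.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot cdsIntervals [GenomicRanges::GRanges] of CDS exons in ascending
#'   genomic order.
#' @slot cdsSequence [Biostrings::DNAString] coding sequence; length equals
#'   the summed interval widths and is divisible by 3.
#' @slot domains data.frame with columns `domain`, `start_res`, `end_res`
#'   (1-based residues, inclusive).
#' @slot splicePad integer, nucleotides of intronic splice region adjoining
#'   each internal exon edge that still count as coding context.
#' @seealso [geneModel()], [classifyCoding()], [enumerateSiteCounts()]
#' @exportClass GeneModel
setClass("GeneModel", representation(
    geneId = "character",
    chrom = "character",
    strand = "character",
    cdsIntervals = "GRanges",
    cdsSequence = "DNAString",
    domains = "data.frame",
    splicePad = "integer"
))

setValidity("GeneModel", function(object) {
    msg <- character()
    L <- length(object@cdsSequence)
    if (L %% 3L != 0L) msg <- c(msg, "CDS length must be divisible by 3")
    if (sum(GenomicRanges::width(object@cdsIntervals)) != L)
        msg <- c(msg, "CDS length must equal summed interval widths")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(object@cdsIntervals) &&
        is.unsorted(GenomicRanges::start(object@cdsIntervals)))
        msg <- c(msg, "cdsIntervals must be in ascending genomic order")
    if (nrow(object@domains)) {
        pl <- L %/% 3L
        if (any(object@domains$start_res < 1L) ||
            any(object@domains$end_res > pl) ||
            any(object@domains$start_res > object@domains$end_res))
            msg <- c(msg, "domain residue ranges must lie within the protein")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a gene model
#'
#' @param geneId gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param cdsIntervals `GRanges` (or data.frame with `start`, `end`) of CDS
#'   exons; ascending genomic order.
#' @param cdsSequence coding sequence as a character string or `DNAString`
#'   (coding strand, 5'->3', stop codon included).
#' @param domains data.frame of named residue ranges
#'   (`domain`, `start_res`, `end_res`); may be empty.
#' @param splicePad intronic splice padding in nt (default 2).
#' @return A [GeneModel-class] object.
#' @export
geneModel <- function(geneId, chrom, strand, cdsIntervals, cdsSequence,
                      domains = data.frame(domain = character(),
                                           start_res = integer(),
                                           end_res = integer()),
                      splicePad = 2L) {
    if (is.data.frame(cdsIntervals)) {
        cdsIntervals <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(cdsIntervals$start, cdsIntervals$end))
    }
    cdsIntervals <- GenomicRanges::sort(cdsIntervals)
    if (is.character(cdsSequence))
        cdsSequence <- Biostrings::DNAString(cdsSequence)
    new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
        cdsIntervals = cdsIntervals, cdsSequence = cdsSequence,
        domains = domains, splicePad = as.integer(splicePad))
}

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel", object@geneId, sprintf("(%s%s)", object@chrom,
        object@strand), "|", length(object@cdsIntervals), "CDS exon(s),",
        length(object@cdsSequence), "nt,",
        proteinLength(object), "residues\n")
    if (nrow(object@domains))
        cat("  domains:", paste(sprintf("%s[%d-%d]", object@domains$domain,
            object@domains$start_res, object@domains$end_res),
            collapse = ", "), "\n")
})

#' Possible synonymous and nonsynonymous site counts for a CDS
#'
#' Counts of possible single-nucleotide changes of each class over a coding
#' sequence: every coding position has three alternative bases, so
#' `N + S = 3 * CDS length` (plus any splice positions counted as
#' nonsynonymous sites). The fractions `fN = N/(N+S)` and `fS = S/(N+S)` are
#' the pseudocounts of the dN/dS estimator.
#'
#' @slot nSites possible nonsynonymous changes.
#' @slot sSites possible synonymous changes.
#' @seealso [enumerateSiteCounts()], [dndsPoint()]
#' @exportClass SiteCounts
setClass("SiteCounts", representation(nSites = "numeric", sSites = "numeric"))

setValidity("SiteCounts", function(object) {
    if (object@nSites < 0 || object@sSites < 0)
        return("site counts must be non-negative")
    TRUE
})

#' @describeIn SiteCounts-class constructor.
#' @param nSites,sSites possible nonsynonymous / synonymous change counts.
#' @export
siteCounts <- function(nSites, sSites)
    new("SiteCounts", nSites = as.numeric(nSites), sSites = as.numeric(sSites))

setMethod("show", "SiteCounts", function(object) {
    tot <- object@nSites + object@sSites
    cat(sprintf("SiteCounts: N = %g, S = %g (fN = %.4f, fS = %.4f)\n",
        object@nSites, object@sSites, object@nSites / tot,
        object@sSites / tot))
})

#' Pseudocounted dN/dS estimate with bootstrap interquartile range
#'
#' @slot nObs,sObs observed nonsynonymous / synonymous mutation counts.
#' @slot point pseudocounted point estimate.
#' @slot q25,q75 25th/75th percentiles of the bootstrap distribution.
#' @slot B number of bootstrap replicates.
#' @slot seed RNG seed used for the bootstrap.
#' @slot replicates numeric vector of replicate dN/dS values (length `B`).
#' @seealso [dndsBootstrap()]
#' @exportClass DndsResult
setClass("DndsResult", representation(
    nObs = "integer", sObs = "integer", point = "numeric",
    q25 = "numeric", q75 = "numeric", B = "integer", seed = "integer",
    replicates = "numeric"
))

setValidity("DndsResult", function(object) {
    if (length(object@q25) && length(object@q75) && object@q25 > object@q75)
        return("q25 must not exceed q75")
    TRUE
})

setMethod("show", "DndsResult", function(object) {
    cat(sprintf(
        "DndsResult: dN/dS = %.3f [IQR %.3f-%.3f], N = %d, S = %d, B = %d\n",
        object@point, object@q25, object@q75, object@nObs, object@sObs,
        object@B))
})

#' Germline heterozygous site configuration for read-backed phasing
#'
#' Describes the germline variant against which nearby somatic variants are
#' phased: its genomic coordinate, the reference and carrier (alternate)
#' bases at that position, and the maximum somatic-variant distance at which
#' a duplex read can span both sites. The default is the TP53 p.R181H site
#' (hg38 chr17:7675070) with a 150 bp window, approximately the maximum
#' duplex read length.
#'
#' Bases are genomic-strand bases at the coordinate; no strand arithmetic is
#' applied here, so the configuration works identically for genes on either
#' strand.
#'
#' @slot chrom chromosome.
#' @slot pos 1-based genomic coordinate.
#' @slot ref reference base at the site.
#' @slot alt carrier (germline alternate) base.
#' @slot maxPhaseDistance maximum |somatic pos - germline pos| in nt for a
#'   variant to be a phasing candidate.
#' @seealso [phaseVariants()], [simulateReadObservations()]
#' @exportClass GermlineSite
setClass("GermlineSite", representation(
    chrom = "character", pos = "integer", ref = "character",
    alt = "character", maxPhaseDistance = "integer"
))

setValidity("GermlineSite", function(object) {
    msg <- character()
    if (object@ref == object@alt) msg <- c(msg, "ref and alt must differ")
    if (object@maxPhaseDistance <= 0L)
        msg <- c(msg, "maxPhaseDistance must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a germline phasing site
#'
#' @param chrom,pos genomic coordinate (1-based).
#' @param ref,alt reference and carrier bases at the site.
#' @param maxPhaseDistance maximum phasing distance in nt.
#' @return A [GermlineSite-class] object.
#' @examples
#' germlineSite()  # the default TP53 p.R181H site
#' @export
germlineSite <- function(chrom = "chr17", pos = 7675070L, ref = "C",
                         alt = "T", maxPhaseDistance = 150L) {
    new("GermlineSite", chrom = chrom, pos = as.integer(pos), ref = ref,
        alt = alt, maxPhaseDistance = as.integer(maxPhaseDistance))
}

setMethod("show", "GermlineSite", function(object) {
    cat(sprintf("GermlineSite %s:%d %s>%s (phase window %d nt)\n",
        object@chrom, object@pos, object@ref, object@alt,
        object@maxPhaseDistance))
})

#' Configuration of the synthetic duplex cohort generator
#'
#' Bundles every knob of the generator: the subject table (age, carrier and
#' chemotherapy status, tissue category), the panels with their target mean
#' duplex depth and dispersion, the somatic base rate per duplex nucleotide
#' per year, gene-specific nonsynonymous selection multipliers, the
#' geometric clone-size parameter, the phase bias of TP53 second hits, and
#' the artifact / germline-SNP confounder specifications.
#'
#' @slot seed master RNG seed; a fixed seed gives bit-identical cohorts.
#' @slot subjects data.frame: `subject_id`, `age_years`, `carrier`, `chemo`,
#'   `tissue_category` (one of blood, solid, sun_skin, cancer).
#' @slot panels data.frame: `label`, `mean_depth`, `dispersion`.
#' @slot baseRate somatic mutations per duplex nucleotide per year.
#' @slot geneSelection named numeric, gene -> nonsynonymous weight
#'   (omega_true; 1 = neutral).
#' @slot cloneSizeGeomP geometric parameter on \{1, 2, ...\} for supporting
#'   duplex read counts.
#' @slot phaseBias probability a simulated TP53 somatic variant arises on
#'   the non-carrier chromosome copy.
#' @slot artifactSpec list: `n_artifacts`, `mismatch_annotation` (>= 8),
#'   `n_samples_shared` (>= 3).
#' @slot germlineSnpSpec list: `n_sites`, `vaf_mean` (~0.5).
#' @seealso [simConfig()], [simulateCohort()]
#' @exportClass SimConfig
setClass("SimConfig", representation(
    seed = "integer", subjects = "data.frame", panels = "data.frame",
    baseRate = "numeric", geneSelection = "numeric",
    cloneSizeGeomP = "numeric", phaseBias = "numeric",
    artifactSpec = "list", germlineSnpSpec = "list"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    s <- object@subjects
    need <- c("subject_id", "age_years", "carrier", "chemo",
              "tissue_category")
    if (!all(need %in% names(s)))
        msg <- c(msg, paste("subjects must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(s$age_years < 0)) msg <- c(msg, "ages must be non-negative")
        if (!all(s$tissue_category %in%
                 c("blood", "solid", "sun_skin", "cancer")))
            msg <- c(msg, "unknown tissue_category")
    }
    if (object@baseRate < 0) msg <- c(msg, "baseRate must be >= 0")
    if (any(object@geneSelection <= 0))
        msg <- c(msg, "gene selection weights must be positive")
    if (object@cloneSizeGeomP <= 0 || object@cloneSizeGeomP > 1)
        msg <- c(msg, "cloneSizeGeomP must be in (0, 1]")
    if (object@phaseBias < 0 || object@phaseBias > 1)
        msg <- c(msg, "phaseBias must be in [0, 1]")
    a <- object@artifactSpec
    if (!is.null(a$mismatch_annotation) && a$mismatch_annotation < 8)
        msg <- c(msg, "artifact mismatch_annotation must be >= 8")
    if (!is.null(a$n_samples_shared) && a$n_samples_shared < 3)
        msg <- c(msg, "artifact n_samples_shared must be >= 3")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", nrow(object@subjects), "subjects |",
        nrow(object@panels), "panels | base rate",
        format(object@baseRate), "/nt/yr | seed", object@seed, "\n")
})

#' Synthetic duplex sequencing cohort
#'
#' The generator's output: a single call table for all samples (with
#' ground-truth labels), per-sample depth profiles, subject metadata, the
#' region mask, gene models, the panel reference, duplex read observations
#' around the germline phasing site, and the pathogenicity score table used
#' for selection-weighted draws (if any).
#'
#' @slot calls data.frame of duplex variant calls (see [checkCalls()]) with
#'   an extra `truth` column in \{somatic, artifact, germline\}.
#' @slot depth named list of [DepthProfile-class], one per sample.
#' @slot metadata subject table (as in [SimConfig-class]).
#' @slot mask [GenomicRanges::GRanges] of excluded regions.
#' @slot geneModels named list of [GeneModel-class].
#' @slot reference internal panel reference (regions + bases).
#' @slot reads data.frame of duplex read observations for phasing.
#' @slot scoreTable the [PathogenicityTable-class] used, or `NULL`.
#' @slot config the generating [SimConfig-class].
#' @seealso [simulateCohort()]
#' @exportClass DuplexCohort
setClass("DuplexCohort", representation(
    calls = "data.frame", depth = "list", metadata = "data.frame",
    mask = "GRanges", geneModels = "list", reference = "list",
    reads = "data.frame", scoreTable = "ANY", config = "SimConfig"
))

setMethod("show", "DuplexCohort", function(object) {
    tr <- table(factor(object@calls$truth,
                       c("somatic", "artifact", "germline")))
    cat("DuplexCohort:", nrow(object@metadata), "samples,",
        nrow(object@calls), "calls (",
        paste(names(tr), as.integer(tr), sep = ":", collapse = ", "),
        "),", length(object@geneModels), "genes,",
        nrow(object@reads), "read observations\n")
})

#' Pathogenicity score table
#'
#' Maps substitutions to pathogenicity scores in [0, 1] with the two
#' category thresholds: scores > `pathogenic` are Likely Pathogenic, scores
#' in [`ambiguousLow`, `pathogenic`] are Ambiguous, scores < `ambiguousLow`
#' are Likely Benign. Keys are either protein notation (`"R248Q"`) or
#' genomic SNV notation (`"chr17:7674220:C>T"`), always prefixed by the gene
#' id internally; both dialects may coexist but a key collision with
#' conflicting scores is rejected at load.
#'
#' @slot scores named numeric vector; names are `"<gene>|<key>"`.
#' @slot ambiguousLow lower bound of the Ambiguous band (default 0.34).
#' @slot pathogenic lower strict bound of Likely Pathogenic (default 0.564).
#' @seealso [pathogenicityTable()], [annotatePathogenicity()]
#' @exportClass PathogenicityTable
setClass("PathogenicityTable", representation(
    scores = "numeric", ambiguousLow = "numeric", pathogenic = "numeric"
))

setValidity("PathogenicityTable", function(object) {
    msg <- character()
    if (length(object@scores) &&
        (any(object@scores < 0) || any(object@scores > 1)))
        msg <- c(msg, "scores must be in [0, 1]")
    if (object@ambiguousLow >= object@pathogenic)
        msg <- c(msg, "thresholds must satisfy ambiguousLow < pathogenic")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PathogenicityTable", function(object) {
    cat("PathogenicityTable:", length(object@scores), "scored substitutions",
        sprintf("(benign < %.3g <= ambiguous <= %.3g < pathogenic)\n",
                object@ambiguousLow, object@pathogenic))
})
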