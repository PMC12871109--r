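# Post-pipeline variant filter cascade. Order is fixed: depth -> no-call ->
# germline VAF -> mask -> recurrent artifact -> cross-sample germline, so
# rejection reason codes are stable. All threshold comparisons are strict;
# a call sitting exactly at a threshold survives.

.callGRanges <- function(calls) {
    GenomicRanges::GRanges(calls$chrom,
        IRanges::IRanges(calls$pos, calls$pos + nchar(calls$ref) - 1L))
}

#' Per-site variant filters
#'
#' Rejects a call iff its duplex depth is below `minDepth`, OR its no-call
#' fraction exceeds `maxNoCall`, OR its VAF exceeds `germlineVaf`
#' (germline polymorphism), OR its position intersects the mask. Each
#' rejected call carries the first matching reason in that order
#' (`"depth"`, `"no_call"`, `"germline_vaf"`, `"mask"`).
#'
#' @param calls duplex call table (see [checkCalls()]); records with a
#'   missing depth or no-call fraction raise an error naming the record.
#' @param mask [GenomicRanges::GRanges] of excluded regions (1-based,
#'   closed; BED input is converted on import by [readMaskBed()]).
#' @param thresholds a [FilterThresholds-class].
#' @return list with elements `kept` and `rejected` (the latter with a
#'   `reason` column); together they contain every input row exactly once.
#' @export
applySiteFilters <- function(calls, mask = GenomicRanges::GRanges(),
                             thresholds = filterThresholds()) {
    calls <- checkCalls(calls)
    bad <- is.na(calls$duplex_depth) | is.na(calls$no_call_fraction)
    if (any(bad))
        stop("call(s) missing depth or no-call fraction: ",
             paste(variantKey(calls[bad, , drop = FALSE]), collapse = ", "))
    reason <- rep(NA_character_, nrow(calls))
    inMask <- if (length(mask) && nrow(calls)) {
        IRanges::overlapsAny(.callGRanges(calls),
                             GenomicRanges::reduce(mask))
    } else rep(FALSE, nrow(calls))
    hit <- function(cond, code) reason <<- ifelse(is.na(reason) & cond,
                                                  code, reason)
    hit(calls$duplex_depth < thresholds@minDepth, "depth")
    hit(calls$no_call_fraction > thresholds@maxNoCall, "no_call")
    hit(calls$vaf > thresholds@germlineVaf, "germline_vaf")
    hit(inMask, "mask")
    rejected <- calls[!is.na(reason), , drop = FALSE]
    rejected$reason <- reason[!is.na(reason)]
    list(kept = calls[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Recurrent-artifact filter
#'
#' A variant key (chrom:pos:ref>alt) is removed from every sample iff it
#' occurs in at least `artifactMinSamples` distinct samples AND its mismatch
#' annotation reaches `artifactMinMismatches` in at least one carrying
#' sample (`mode = "any"`, the conservative artifact-removal reading;
#' `mode = "all"` requires it in every carrying sample).
#'
#' @param calls combined duplex call table for the cohort (per-sample
#'   tables identified by `sample_id`).
#' @param thresholds a [FilterThresholds-class].
#' @param mode `"any"` (default) or `"all"`; which carrying samples must
#'   show the mismatch pattern.
#' @return list with `kept` and `removed` (with `reason =
#'   "recurrent_artifact"`).
#' @export
recurrentArtifactFilter <- function(calls, thresholds = filterThresholds(),
                                    mode = c("any", "all")) {
    mode <- match.arg(mode)
    calls <- checkCalls(calls)
    if (nrow(calls) == 0L)
        return(list(kept = calls, removed = calls))
    key <- variantKey(calls)
    nSamples <- vapply(split(calls$sample_id, key),
                       function(s) length(unique(s)), integer(1))
    mm <- split(calls$mismatch_annotation, key)
    mmHit <- vapply(mm, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(FALSE)
        if (mode == "any") any(v >= thresholds@artifactMinMismatches)
        else all(v >= thresholds@artifactMinMismatches)
    }, logical(1))
    artifactKeys <- names(nSamples)[
        nSamples >= thresholds@artifactMinSamples & mmHit[names(nSamples)]]
    drop <- key %in% artifactKeys
    removed <- calls[drop, , drop = FALSE]
    if (nrow(removed)) removed$reason <- "recurrent_artifact"
    list(kept = calls[!drop, , drop = FALSE], removed = removed)
}

#' Cross-sample germline exclusion
#'
#' Any variant key whose VAF exceeds `germlineVaf` in at least one sample is
#' excluded from all other samples (in the high-VAF sample itself it is
#' already removed by the per-site germline VAF rule, so after the full
#' cascade the key is absent everywhere).
#'
#' @param calls combined duplex call table.
#' @param germlineVaf VAF threshold (default 0.3).
#' @param evidence call table in which high-VAF keys are looked for
#'   (default `calls`); the cascade passes the original, pre-filter table
#'   here, since the high-VAF record itself is removed by the per-site
#'   rule before this step runs.
#' @return list with `kept` and `removed` (`reason =
#'   "cross_sample_germline"`).
#' @export
crossSampleGermlineFilter <- function(calls, germlineVaf = 0.3,
                                      evidence = calls) {
    calls <- checkCalls(calls)
    if (nrow(calls) == 0L)
        return(list(kept = calls, removed = calls))
    evidence <- checkCalls(evidence)
    key <- variantKey(calls)
    ek <- variantKey(evidence)
    hot <- unique(ek[!is.na(evidence$vaf) & evidence$vaf > germlineVaf])
    drop <- key %in% hot
    removed <- calls[drop, , drop = FALSE]
    if (nrow(removed)) removed$reason <- "cross_sample_germline"
    list(kept = calls[!drop, , drop = FALSE], removed = removed)
}

#' Full filter cascade
#'
#' Applies, in order: per-site filters (depth, no-call, germline VAF, mask),
#' the recurrent-artifact filter, and the cross-sample germline exclusion.
#' The cascade is idempotent and conserves records: every input row ends in
#' exactly one of `kept` / `removed`, each removal with a reason code.
#'
#' @inheritParams applySiteFilters
#' @param artifactMode passed to [recurrentArtifactFilter()].
#' @return list with `kept` and `removed` (with `reason`).
#' @export
filterCascade <- function(calls, mask = GenomicRanges::GRanges(),
                          thresholds = filterThresholds(),
                          artifactMode = "any") {
    s1 <- applySiteFilters(calls, mask, thresholds)
    s2 <- recurrentArtifactFilter(s1$kept, thresholds, artifactMode)
    s3 <- crossSampleGermlineFilter(s2$kept, thresholds@germlineVaf,
                                    evidence = calls)
    removed <- rbind(s1$rejected, s2$removed, s3$removed)
    list(kept = s3$kept, removed = removed)
}

#' Classify calls as coding or non-coding
#'
#' An SNV or MNV is coding iff its position lies within a CDS exon or at
#' most `splicePad` (2) nt into an adjacent intron; an indel is coding iff
#' its reference span overlaps any CDS exon. Everything else is non-coding.
#'
#' @param calls duplex call table restricted to the gene's chromosome.
#' @param gm a [GeneModel-class].
#' @param panel optional [GenomicRanges::GRanges] of panel intervals; calls
#'   outside it raise an error. Defaults to the gene span padded by 5 kb.
#' @return character vector, `"coding"` / `"noncoding"` per call.
#' @export
classifyCoding <- function(calls, gm, panel = NULL) {
    calls <- checkCalls(calls)
    if (is.null(panel))
        panel <- range(gm@cdsIntervals) + 5000L
    gr <- .callGRanges(calls)
    out <- IRanges::overlapsAny(gr, panel)
    if (any(!out))
        stop("call(s) outside the panel intervals: ",
             paste(variantKey(calls[!out, , drop = FALSE]), collapse = ", "))
    cds <- gm@cdsIntervals
    sp <- spliceSites(gm)
    splice <- if (length(sp)) {
        GenomicRanges::GRanges(gm@chrom, IRanges::IRanges(sp, sp))
    } else GenomicRanges::GRanges()
    isIndel <- calls$variant_class %in% c("insertion", "deletion")
    codingZone <- GenomicRanges::reduce(c(cds, splice))
    res <- character(nrow(calls))
    snvLike <- !isIndel
    res[snvLike] <- ifelse(
        IRanges::overlapsAny(gr[snvLike], codingZone), "coding", "noncoding")
    res[isIndel] <- ifelse(
        IRanges::overlapsAny(gr[isIndel], cds), "coding", "noncoding")
    res
}

#' Annotate calls with gene and consequence
#'
#' Assigns `gene_id` and a `consequence` label to every call: SNVs in a CDS
#' are classified through the codon table (synonymous / missense /
#' nonsense), SNVs within the splice padding of an internal exon edge are
#' `splice`, other SNVs are `noncoding`; MNVs fully inside a CDS are
#' classified by translating the jointly mutated codons (most severe
#' consequence wins); indels are `indel_coding` / `indel_noncoding` by CDS
#' overlap. Calls on chromosomes with no gene model keep `gene_id = NA` and
#' are `noncoding`.
#'
#' @param calls duplex call table.
#' @param geneModels named list of [GeneModel-class].
#' @return the call table with `gene_id` and `consequence` columns.
#' @export
annotateCalls <- function(calls, geneModels) {
    calls <- checkCalls(calls)
    calls$gene_id <- NA_character_
    calls$consequence <- "noncoding"
    if (!nrow(calls)) return(calls)
    for (gm in geneModels) {
        span <- range(gm@cdsIntervals) + 5000L
        onChrom <- which(calls$chrom == gm@chrom)
        if (!length(onChrom)) next
        hit <- IRanges::overlapsAny(
            .callGRanges(calls[onChrom, , drop = FALSE]), span)
        idx <- onChrom[hit]
        if (!length(idx)) next
        calls$gene_id[idx] <- gm@geneId
        cls <- calls$variant_class[idx]
        isIndel <- cls %in% c("insertion", "deletion")
        if (any(isIndel)) {
            ov <- IRanges::overlapsAny(.callGRanges(calls[idx[isIndel], ,
                drop = FALSE]), gm@cdsIntervals)
            calls$consequence[idx[isIndel]] <-
                ifelse(ov, "indel_coding", "indel_noncoding")
        }
        sp <- spliceSites(gm)
        for (i in idx[!isIndel]) {
            positions <- calls$pos[i]:(calls$pos[i] + nchar(calls$ref[i]) - 1L)
            offs <- cdsOffset(gm, positions)
            if (all(is.na(offs))) {
                calls$consequence[i] <-
                    if (any(positions %in% sp)) "splice" else "noncoding"
                next
            }
            inCds <- !is.na(offs)
            refs <- strsplit(calls$ref[i], "")[[1]][inCds]
            alts <- strsplit(calls$alt[i], "")[[1]][inCds]
            cRef <- codingStrandBase(gm, refs)
            cAlt <- codingStrandBase(gm, alts)
            changed <- cRef != cAlt
            if (!any(changed)) { calls$consequence[i] <- "synonymous"; next }
            cons <- .mnvConsequence(gm@cdsSequence, offs[inCds][changed],
                                    cAlt[changed])
            if (any(positions %in% sp) && cons != "nonsense")
                cons <- "splice"
            calls$consequence[i] <- cons
        }
    }
    calls
}

# Joint consequence of >= 1 substitutions applied to the same CDS:
# translate every affected codon after applying all changes, take the most
# severe (nonsense > missense > synonymous).
.mnvConsequence <- function(cds, offsets, alts) {
    s <- strsplit(as.character(cds), "")[[1]]
    mut <- s
    mut[offsets + 1L] <- alts
    ci <- unique(offsets %/% 3L)
    refCodon <- vapply(ci, function(k)
        paste0(s[3L * k + 1L], s[3L * k + 2L], s[3L * k + 3L]), character(1))
    altCodon <- vapply(ci, function(k)
        paste0(mut[3L * k + 1L], mut[3L * k + 2L], mut[3L * k + 3L]),
        character(1))
    refAA <- .translateCodons(refCodon)
    altAA <- .translateCodons(altCodon)
    if (any(altAA == "*" & refAA != "*")) return("nonsense")
    if (any(refAA != altAA)) return("missense")
    "synonymous"
}
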