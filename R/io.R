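# File dialects shared by the generator and the pipeline: per-sample
# minimal VCF v4.2 with duplex INFO keys, bedGraph depth tracks, BED masks
# (0-based half-open on disk, 1-based closed in memory), gene models as
# FASTA + interval TSV, metadata/truth/read-observation TSVs.

.VCF_INFO_HEADER <- c(
    '##INFO=<ID=ADUP,Number=1,Type=Integer,Description="Alt duplex reads">',
    '##INFO=<ID=DDP,Number=1,Type=Integer,Description="Duplex depth">',
    '##INFO=<ID=NCF,Number=1,Type=Float,Description="No-call fraction">',
    '##INFO=<ID=NMM,Number=1,Type=Integer,Description="Mismatch annotation">')

#' Write one sample's calls as minimal VCF v4.2
#'
#' INFO keys: `ADUP` (alt duplex reads), `DDP` (duplex depth), `NCF`
#' (no-call fraction), `NMM` (mismatch annotation).
#'
#' @param calls duplex call table (one sample).
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeDuplexVcf <- function(calls, file) {
    calls <- checkCalls(calls)
    hdr <- c("##fileformat=VCFv4.2", .VCF_INFO_HEADER,
             paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                 "QUAL", "FILTER", "INFO"),
                               collapse = "\t")))
    body <- if (nrow(calls)) sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\tADUP=%d;DDP=%d;NCF=%g;NMM=%d",
        calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
        as.integer(calls$alt_duplex_reads),
        as.integer(calls$duplex_depth), calls$no_call_fraction,
        as.integer(calls$mismatch_annotation)) else character(0)
    writeLines(c(hdr, body), file)
    invisible(file)
}

#' Read a minimal duplex VCF back into a call table
#'
#' @param file VCF path (as written by [writeDuplexVcf()]).
#' @param sampleId sample identifier to attach.
#' @return duplex call table.
#' @export
readDuplexVcf <- function(file, sampleId) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (!nrow(fix)) return(.emptyCalls())
    g <- function(k) as.numeric(vcfR::extract.info(v, k))
    ref <- fix$REF; alt <- fix$ALT
    vc <- ifelse(nchar(ref) == nchar(alt),
                 ifelse(nchar(ref) == 1L, "SNV", "MNV"),
                 ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
    checkCalls(data.frame(
        sample_id = sampleId, chrom = fix$CHROM, pos = as.integer(fix$POS),
        ref = ref, alt = alt, alt_duplex_reads = as.integer(g("ADUP")),
        duplex_depth = as.integer(g("DDP")), no_call_fraction = g("NCF"),
        mismatch_annotation = as.integer(g("NMM")), variant_class = vc,
        stringsAsFactors = FALSE))
}

#' Write / read a depth profile as bedGraph
#'
#' Runs of equal depth are collapsed into bedGraph intervals (0-based
#' half-open on disk); import expands them back to per-position depths.
#'
#' @param depth a [DepthProfile-class].
#' @param file bedGraph path.
#' @return `writeDepthBedGraph`: the path, invisibly;
#'   `readDepthBedGraph`: a [DepthProfile-class].
#' @export
writeDepthBedGraph <- function(depth, file) {
    grs <- list()
    for (i in seq_along(depth@regions)) {
        r <- depth@regions[i]
        d <- depth@depth[[i]]
        rl <- rle(d)
        en <- cumsum(rl$lengths)
        st <- c(1L, utils::head(en, -1L) + 1L)
        grs[[i]] <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(r),
            IRanges::IRanges(GenomicRanges::start(r) + st - 1L,
                             GenomicRanges::start(r) + en - 1L),
            score = rl$values)
    }
    gr <- .cGRanges(grs)
    rtracklayer::export(gr, file, format = "bedGraph")
    invisible(file)
}

#' @rdname writeDepthBedGraph
#' @export
readDepthBedGraph <- function(file) {
    gr <- rtracklayer::import(file, format = "bedGraph")
    red <- GenomicRanges::reduce(gr)
    depth <- lapply(seq_along(red), function(i) {
        hits <- S4Vectors::queryHits(IRanges::findOverlaps(gr, red[i]))
        d <- integer(GenomicRanges::width(red[i]))
        for (j in hits) {
            off <- (GenomicRanges::start(gr[j]):GenomicRanges::end(gr[j])) -
                GenomicRanges::start(red[i]) + 1L
            d[off] <- as.integer(gr$score[j])
        }
        d
    })
    depthProfile(red, depth)
}

#' Write / read a region mask as BED
#'
#' On disk BED is 0-based half-open; in memory masks are 1-based closed
#' `GRanges`. `rtracklayer` performs the conversion on both paths.
#'
#' @param mask a `GRanges`.
#' @param file BED path.
#' @return `writeMaskBed`: the path, invisibly; `readMaskBed`: a `GRanges`.
#' @export
writeMaskBed <- function(mask, file) {
    rtracklayer::export(mask, file, format = "BED")
    invisible(file)
}

#' @rdname writeMaskBed
#' @export
readMaskBed <- function(file) {
    gr <- rtracklayer::import(file, format = "BED")
    S4Vectors::mcols(gr) <- NULL
    gr
}

#' Write / read gene models (FASTA + interval and domain TSVs)
#'
#' `<prefix>.cds.fa` holds the coding sequences, `<prefix>.intervals.tsv`
#' the CDS exon intervals (1-based closed) and strand, and
#' `<prefix>.domains.tsv` the domain residue ranges.
#'
#' @param geneModels named list of [GeneModel-class].
#' @param prefix path prefix.
#' @return `writeGeneModels`: the prefix, invisibly; `readGeneModels`: a
#'   named list of [GeneModel-class].
#' @export
writeGeneModels <- function(geneModels, prefix) {
    seqs <- Biostrings::DNAStringSet(lapply(geneModels,
                                            function(g) g@cdsSequence))
    names(seqs) <- vapply(geneModels, geneId, character(1))
    Biostrings::writeXStringSet(seqs, paste0(prefix, ".cds.fa"))
    iv <- do.call(rbind, lapply(geneModels, function(g) data.frame(
        gene = g@geneId, chrom = g@chrom, strand = g@strand,
        start = GenomicRanges::start(g@cdsIntervals),
        end = GenomicRanges::end(g@cdsIntervals),
        stringsAsFactors = FALSE)))
    utils::write.table(iv, paste0(prefix, ".intervals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dom <- do.call(rbind, lapply(geneModels, function(g)
        if (nrow(g@domains)) cbind(gene = g@geneId, g@domains) else NULL))
    if (is.null(dom))
        dom <- data.frame(gene = character(), domain = character(),
                          start_res = integer(), end_res = integer())
    utils::write.table(dom, paste0(prefix, ".domains.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(prefix)
}

#' @rdname writeGeneModels
#' @export
readGeneModels <- function(prefix) {
    seqs <- Biostrings::readDNAStringSet(paste0(prefix, ".cds.fa"))
    iv <- utils::read.delim(paste0(prefix, ".intervals.tsv"),
                            stringsAsFactors = FALSE)
    dom <- utils::read.delim(paste0(prefix, ".domains.tsv"),
                             stringsAsFactors = FALSE)
    out <- lapply(names(seqs), function(g) {
        ivg <- iv[iv$gene == g, , drop = FALSE]
        dg <- dom[dom$gene == g, c("domain", "start_res", "end_res"),
                  drop = FALSE]
        geneModel(g, ivg$chrom[1], ivg$strand[1],
                  ivg[, c("start", "end")], seqs[[g]], domains = dg)
    })
    stats::setNames(out, names(seqs))
}

#' Write a synthetic cohort to a directory
#'
#' Writes the file dialects the pipeline reads, so a generated cohort
#' doubles as an integration fixture: per-sample VCFs
#' (`<sample>.vcf`), per-sample bedGraph depth (`<sample>.depth.bedGraph`),
#' `mask.bed`, `metadata.tsv`, `truth.tsv` (variant keys with ground-truth
#' labels), `reads.tsv` (duplex read observations) and the gene model
#' files.
#'
#' @param cohort a [DuplexCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in cohort@metadata$subject_id) {
        sub <- cohort@calls[cohort@calls$sample_id == s, , drop = FALSE]
        writeDuplexVcf(sub, file.path(dir, paste0(s, ".vcf")))
        writeDepthBedGraph(cohort@depth[[s]],
                           file.path(dir, paste0(s, ".depth.bedGraph")))
    }
    writeMaskBed(cohort@mask, file.path(dir, "mask.bed"))
    utils::write.table(cohort@metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- data.frame(sample_id = cohort@calls$sample_id,
                        key = variantKey(cohort@calls),
                        truth = cohort@calls$truth)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cohort@reads, file.path(dir, "reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeGeneModels(cohort@geneModels, file.path(dir, "genes"))
    invisible(dir)
}

#' Read duplex read observations from TSV
#'
#' @param file TSV as written by [writeCohort()] (columns `read_id`,
#'   `sample_id`, `chrom`, `start`, `end`, `variant_pos`, `variant_ref`,
#'   `variant_alt`, `base_at_variant`, `base_at_germline`).
#' @return data.frame of read observations.
#' @export
readReadObservations <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
}
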