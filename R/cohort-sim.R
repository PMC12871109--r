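# Synthetic duplex cohort generator. Emulates the statistical structure the
# downstream analysis assumes -- overdispersed per-position duplex depth,
# mostly-singleton somatic clones with a geometric size tail, gene-specific
# nonsynonymous selection, germline heterozygous SNPs with cross-sample
# echoes, recurrent multi-sample artifacts, and duplex reads spanning a
# germline phasing site -- so every pipeline stage is testable without
# external data. Fixed seed => bit-identical cohorts.

.SENSE_CODONS <- NULL  # filled lazily: the 61 non-stop codons

.senseCodons <- function() {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc != "*"]
}

#' Construct a generator configuration
#'
#' Defaults describe the study conditions emulated throughout the package:
#' a cohort of 11 blood subjects aged 25--76 (three germline-variant
#' carriers, one carrier and one control with chemotherapy exposure),
#' panels at a mean duplex depth of 15,000x with mild overdispersion, a
#' somatic base rate of 1e-8 mutations per duplex nucleotide per year,
#' positive selection on DNMT3A/TET2, negative selection on GATA2, a
#' heavy-at-1 geometric clone-size law, a 25/29 phase bias of TP53 second
#' hits toward the non-carrier copy, five recurrent artifacts shared by at
#' least three samples, and three germline SNP sites at VAF ~0.5.
#'
#' @param seed master RNG seed.
#' @param subjects subject table (see [SimConfig-class]).
#' @param panels panel table: `label`, `mean_depth`, `dispersion`.
#' @param baseRate somatic mutations per duplex nucleotide per year.
#' @param geneSelection named nonsynonymous weights (omega_true).
#' @param cloneSizeGeomP geometric parameter for supporting read counts.
#' @param phaseBias probability a TP53 somatic variant arises on the
#'   non-carrier copy.
#' @param artifactSpec list(`n_artifacts`, `mismatch_annotation`,
#'   `n_samples_shared`).
#' @param germlineSnpSpec list(`n_sites`, `vaf_mean`).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      subjects = defaultSubjects(),
                      panels = data.frame(
                          label = c("TP53", "CHIP", "MUT"),
                          mean_depth = c(15000, 15000, 15000),
                          dispersion = c(0.05, 0.05, 0.05)),
                      baseRate = 1e-8,
                      geneSelection = c(TP53 = 2, DNMT3A = 3, TET2 = 2,
                                        GATA2 = 0.3),
                      cloneSizeGeomP = 0.8,
                      phaseBias = 25 / 29,
                      artifactSpec = list(n_artifacts = 5L,
                                          mismatch_annotation = 9L,
                                          n_samples_shared = 3L),
                      germlineSnpSpec = list(n_sites = 3L,
                                             vaf_mean = 0.5)) {
    new("SimConfig", seed = as.integer(seed), subjects = subjects,
        panels = panels, baseRate = baseRate,
        geneSelection = geneSelection, cloneSizeGeomP = cloneSizeGeomP,
        phaseBias = phaseBias, artifactSpec = artifactSpec,
        germlineSnpSpec = germlineSnpSpec)
}

#' Default synthetic subject table
#'
#' Eleven blood subjects aged 25--76: three carriers of the germline
#' variant (one with chemotherapy exposure) and eight non-carrier controls
#' (one with chemotherapy exposure).
#'
#' @return data.frame with `subject_id`, `age_years`, `carrier`, `chemo`,
#'   `tissue_category`.
#' @export
defaultSubjects <- function() {
    data.frame(
        subject_id = c("LFS01", "LFS02", "LFS03", paste0("CON0", 1:8)),
        age_years = c(36, 25, 44, 29, 33, 41, 50, 58, 63, 69, 76),
        carrier = c(TRUE, TRUE, TRUE, rep(FALSE, 8)),
        chemo = c(TRUE, rep(FALSE, 8), TRUE, FALSE),
        tissue_category = "blood",
        stringsAsFactors = FALSE)
}

#' Synthetic gene models for the default panel
#'
#' Deterministically generated stand-ins (not real gene sequences) with the
#' structural features the pipeline exercises: a single-exon minus-strand
#' TP53 model anchored so that codon 181 maps to the germline phasing site
#' chr17:7675070 (codon CGC, Arg; the c.542G>A change is the genomic C>T
#' there) and codon 248 is CGG (Arg, so the R248Q/R248W hotspot spellings
#' arise), with the DNA-binding domain annotated at residues 102--282; a
#' three-exon plus-strand DNMT3A model; a two-exon TET2 model; and a
#' two-exon minus-strand GATA2 model. Sequences are drawn once from a fixed
#' internal seed, so every session sees the same panel.
#'
#' @return named list of [GeneModel-class].
#' @export
makeGeneModels <- function() {
    withSeed(20250925L, {
        sense <- .senseCodons()
        drawCds <- function(nCodon, force = list()) {
            cods <- c("ATG", sample(sense, nCodon - 2L, replace = TRUE),
                      "TAA")
            for (nm in names(force)) cods[as.integer(nm)] <- force[[nm]]
            paste(cods, collapse = "")
        }
        tp53cds <- drawCds(394L, force = list(`181` = "CGC", `248` = "CGG"))
        # minus strand: CDS offset o maps to genomic position 7675611 - o,
        # so codon 181 (offsets 540:542) covers 7675071:7675069 and its
        # middle base sits at chr17:7675070.
        tp53 <- geneModel("TP53", "chr17", "-",
            data.frame(start = 7675611L - 1182L + 1L, end = 7675611L),
            tp53cds,
            domains = data.frame(domain = "DBD", start_res = 102L,
                                 end_res = 282L))
        dnmt3a <- geneModel("DNMT3A", "chr2", "+",
            data.frame(start = c(25000001L, 25001001L, 25002001L),
                       end = c(25000600L, 25001500L, 25002403L)),
            drawCds(501L))
        tet2 <- geneModel("TET2", "chr4", "+",
            data.frame(start = c(106100001L, 106101001L),
                       end = c(106100700L, 106101506L)),
            drawCds(402L))
        gata2 <- geneModel("GATA2", "chr3", "-",
            data.frame(start = c(128480001L, 128480651L),
                       end = c(128480450L, 128481100L)),
            drawCds(300L))
        list(TP53 = tp53, DNMT3A = dnmt3a, TET2 = tet2, GATA2 = gata2)
    })
}

#' Panel region sets for the synthetic cohort
#'
#' @param geneModels named list of [GeneModel-class].
#' @param flank non-coding flank added around each gene span (nt).
#' @param mutRegion the gene-free mutagenesis panel interval.
#' @return named list of [GenomicRanges::GRanges]: `TP53`, `CHIP`
#'   (the non-TP53 genes), `MUT`.
#' @export
panelRegions <- function(geneModels, flank = 600L,
                         mutRegion = GenomicRanges::GRanges("chr1",
                             IRanges::IRanges(1000001, 1020000))) {
    spans <- lapply(geneModels, function(gm) range(gm@cdsIntervals) + flank)
    chip <- spans[setdiff(names(spans), "TP53")]
    list(TP53 = spans$TP53,
         CHIP = GenomicRanges::sort(.cGRanges(chip)),
         MUT = mutRegion)
}

#' Default artifact mask for the synthetic panel
#'
#' A small set of excluded intervals (inside the mutagenesis panel and the
#' TP53 non-coding flank) standing in for repeat/artifact-prone regions.
#'
#' @param regions output of [panelRegions()].
#' @return [GenomicRanges::GRanges] mask (1-based, closed).
#' @export
defaultMask <- function(regions) {
    mutStart <- GenomicRanges::start(regions$MUT)[1]
    tp53Start <- GenomicRanges::start(regions$TP53)[1]
    GenomicRanges::GRanges(
        c("chr1", "chr17"),
        IRanges::IRanges(c(mutStart + 5000L, tp53Start + 50L),
                         c(mutStart + 5199L, tp53Start + 109L)))
}

# Internal reference over the panel: deterministic random bases with CDS
# positions overwritten by the gene sequences (complemented on minus).
makePanelReference <- function(regions, geneModels, seed) {
    gr <- GenomicRanges::sort(.cGRanges(regions))
    bases <- withSeed(seed, lapply(GenomicRanges::width(gr), function(w)
        sample(.BASES, w, replace = TRUE)))
    rc <- as.character(GenomicRanges::seqnames(gr))
    rs <- GenomicRanges::start(gr)
    for (gm in geneModels) {
        s <- strsplit(as.character(gm@cdsSequence), "")[[1]]
        pos <- genomicPos(gm, seq_along(s) - 1L)
        gBase <- codingStrandBase(gm, s)
        for (i in seq_along(gr)) {
            sel <- gm@chrom == rc[i] & pos >= rs[i] &
                pos <= GenomicRanges::end(gr)[i]
            if (any(sel))
                bases[[i]][pos[sel] - rs[i] + 1L] <- gBase[sel]
        }
    }
    list(regions = gr, bases = bases)
}

refAt <- function(reference, chrom, pos) {
    out <- rep(NA_character_, length(pos))
    rc <- as.character(GenomicRanges::seqnames(reference$regions))
    rs <- GenomicRanges::start(reference$regions)
    re <- GenomicRanges::end(reference$regions)
    for (i in seq_along(rs)) {
        sel <- chrom == rc[i] & pos >= rs[i] & pos <= re[i]
        if (any(sel)) out[sel] <- reference$bases[[i]][pos[sel] - rs[i] + 1L]
    }
    out
}

#' Simulate a per-position duplex depth track
#'
#' Depth is drawn per position from a negative binomial law with the given
#' mean and dispersion (`variance = mean + dispersion * mean^2`); zero
#' dispersion gives exactly the (rounded) mean at every position. Capture
#' depth in duplex panels is overdispersed, which the mean alone does not
#' capture. Same seed, same profile.
#'
#' @param regions [GenomicRanges::GRanges] of panel intervals (non-empty).
#' @param meanDepth target mean duplex depth (> 0).
#' @param dispersion non-negative dispersion.
#' @param seed RNG seed.
#' @return A [DepthProfile-class]; for regions of >= 10 kb the empirical
#'   mean is within 5% of `meanDepth`.
#' @export
simulateDepth <- function(regions, meanDepth, dispersion = 0.05,
                          seed = 1L) {
    if (length(regions) == 0L) stop("empty region set")
    if (meanDepth <= 0) stop("meanDepth must be positive")
    if (dispersion < 0) stop("dispersion must be non-negative")
    regions <- GenomicRanges::sort(regions)
    depth <- withSeed(seed, lapply(GenomicRanges::width(regions),
        function(w) {
            if (dispersion == 0) rep(as.integer(round(meanDepth)), w)
            else as.integer(stats::rnbinom(w, mu = meanDepth,
                                           size = 1 / dispersion))
        }))
    depthProfile(regions, depth)
}

# Merge depth profiles over disjoint region sets into one.
mergeDepthProfiles <- function(profiles) {
    gr <- .cGRanges(lapply(profiles, function(p) p@regions))
    depth <- do.call(c, lapply(profiles, function(p) p@depth))
    o <- GenomicRanges::order(gr)
    new("DepthProfile", regions = gr[o], depth = depth[o])
}

# All possible single-nucleotide substitutions over the flattened panel,
# with selection weights: synonymous and non-coding changes weigh 1,
# nonsynonymous changes weigh omega_true of their gene, and missense
# changes are additionally weighted by 2 * pathogenicity score when a
# score table is supplied. Joint sampling of (position, alt) proportional
# to depth * weight makes the expected nonsynonymous:synonymous draw ratio
# equal omega * N_sites : S_sites within each gene.
.substitutionTable <- function(flat, reference, geneModels, config,
                               scoreTable = NULL) {
    ref <- refAt(reference, flat$chrom, flat$pos)
    nPos <- length(flat$pos)
    alt <- matrix(NA_character_, nPos, 3L)
    for (b in seq_along(.BASES)) {
        notRef <- ref != .BASES[b]
        slot <- rowSums(!is.na(alt)) + 1L
        alt[cbind(which(notRef), slot[notRef])] <- .BASES[b]
    }
    posIdx <- rep(seq_len(nPos), 3L)
    altV <- as.vector(alt)
    w <- rep(1, length(altV))
    for (gm in geneModels) {
        onChrom <- flat$chrom[posIdx] == gm@chrom
        if (!any(onChrom)) next
        off <- cdsOffset(gm, flat$pos[posIdx[onChrom]])
        sel <- which(onChrom)[!is.na(off)]
        off <- off[!is.na(off)]
        if (!length(sel)) next
        omega <- config@geneSelection[gm@geneId]
        if (is.na(omega)) omega <- 1
        cAlt <- codingStrandBase(gm, altV[sel])
        cons <- classifyConsequence(gm@cdsSequence, off, cAlt)
        w[sel] <- ifelse(cons == "synonymous", 1, omega)
        if (!is.null(scoreTable)) {
            mis <- cons == "missense"
            if (any(mis)) {
                s <- strsplit(as.character(gm@cdsSequence), "")[[1]]
                ci <- off[mis] %/% 3L
                refCodon <- paste0(s[3L * ci + 1L], s[3L * ci + 2L],
                                   s[3L * ci + 3L])
                altCodon <- refCodon
                substr(altCodon, off[mis] %% 3L + 1L,
                       off[mis] %% 3L + 1L) <- cAlt[mis]
                pk <- paste0(.translateCodons(refCodon), ci + 1L,
                             .translateCodons(altCodon))
                sc <- scoreTable@scores[paste(gm@geneId, pk, sep = "|")]
                ok <- !is.na(sc)
                w[sel[mis][ok]] <- w[sel[mis][ok]] * 2 * sc[ok]
            }
        }
    }
    list(posIdx = posIdx, ref = ref, alt = altV, w = w)
}

# Flatten a depth profile into per-position vectors, dropping masked
# positions.
.flattenDepth <- function(depth, mask) {
    chroms <- character(0); poss <- integer(0); d <- integer(0)
    rc <- as.character(GenomicRanges::seqnames(depth@regions))
    rs <- GenomicRanges::start(depth@regions)
    for (i in seq_along(depth@regions)) {
        p <- rs[i]:(rs[i] + length(depth@depth[[i]]) - 1L)
        chroms <- c(chroms, rep(rc[i], length(p)))
        poss <- c(poss, p)
        d <- c(d, depth@depth[[i]])
    }
    if (length(mask)) {
        gp <- GenomicRanges::GRanges(chroms, IRanges::IRanges(poss, poss))
        keep <- !IRanges::overlapsAny(gp, mask)
        chroms <- chroms[keep]; poss <- poss[keep]; d <- d[keep]
    }
    list(chrom = chroms, pos = poss, depth = d)
}

#' Simulate one sample's somatic variant calls
#'
#' The expected number of unique somatic mutations is
#' `baseRate * age * total duplex nucleotides` (duplex nucleotides = summed
#' per-position depth, masked positions excluded). Each mutation is drawn
#' as a (position, alternate base) pair with probability proportional to
#' the position's depth times a selection weight: nonsynonymous changes
#' weigh omega_true of their gene, synonymous and non-coding changes weigh
#' 1 (and, when a score table is supplied, missense changes are
#' additionally weighted by twice their pathogenicity score, emulating
#' selection for disruptive mutations). Within a gene the expected
#' nonsynonymous:synonymous draw ratio is therefore
#' `omega_true * N_sites : S_sites`, which the dN/dS estimator recovers.
#' Supporting duplex read counts are geometric on \{1, 2, ...\}, so most
#' calls are singletons.
#'
#' @param subject one row of the subject table.
#' @param geneModels named list of [GeneModel-class].
#' @param depth a [DepthProfile-class] for this sample.
#' @param config a [SimConfig-class].
#' @param reference panel reference from the cohort generator (or `NULL`
#'   to build one on the fly from the config seed).
#' @param mask [GenomicRanges::GRanges]; no somatic mutations are placed in
#'   masked positions.
#' @param scoreTable optional [PathogenicityTable-class] for
#'   pathogenicity-weighted missense draws.
#' @param seed RNG seed for this sample.
#' @return duplex call table with `gene_id`, `consequence` and
#'   `truth = "somatic"`.
#' @export
simulateSampleVariants <- function(subject, geneModels, depth, config,
                                   reference = NULL,
                                   mask = GenomicRanges::GRanges(),
                                   scoreTable = NULL, seed = 1L) {
    if (is.null(reference))
        reference <- makePanelReference(list(all = depth@regions),
                                        geneModels, config@seed)
    flat <- .flattenDepth(depth, mask)
    totalNt <- sum(as.numeric(flat$depth))
    lambda <- config@baseRate * subject$age_years * totalNt
    subs <- .substitutionTable(flat, reference, geneModels, config,
                               scoreTable)
    calls <- withSeed(seed, {
        n <- stats::rpois(1, lambda)
        if (n == 0L) .emptyCalls() else {
        prob <- subs$w * flat$depth[subs$posIdx]
        idx <- sample.int(length(subs$alt), n, replace = TRUE, prob = prob)
        pos <- flat$pos[subs$posIdx[idx]]
        chrom <- flat$chrom[subs$posIdx[idx]]
        dpos <- flat$depth[subs$posIdx[idx]]
        altReads <- stats::rgeom(n, config@cloneSizeGeomP) + 1L
        df <- data.frame(
            sample_id = subject$subject_id, chrom = chrom, pos = pos,
            ref = subs$ref[subs$posIdx[idx]], alt = subs$alt[idx],
            alt_duplex_reads = altReads, duplex_depth = dpos,
            no_call_fraction = round(stats::runif(n, 0, 0.05), 4),
            mismatch_annotation = sample(0:3, n, replace = TRUE),
            variant_class = "SNV", vaf = altReads / dpos,
            stringsAsFactors = FALSE)
        df[!duplicated(variantKey(df)), , drop = FALSE]
        }
    })
    if (!nrow(calls)) {
        calls <- .emptyCalls()
        calls$gene_id <- character(0)
        calls$consequence <- character(0)
        calls$truth <- character(0)
        return(calls)
    }
    calls <- annotateCalls(calls, geneModels)
    calls$truth <- "somatic"
    calls
}

#' Simulate duplex read observations around the germline phasing site
#'
#' For each variant within `maxPhaseDistance` of the germline site, emits
#' its supporting (alternate-base) duplex reads spanning both sites, plus
#' `refReadsPerVariant` reference-base reads (uninformative for phase).
#' Each variant's chromosomal phase is drawn once -- non-carrier copy with
#' probability `phaseBias` -- and all of its reads agree: reads from the
#' non-carrier copy show the germline reference base at the site, reads
#' from the carrier copy the alternate base. Variants farther than the
#' phase window get reads that do not span the germline site (no base
#' there), so they phase as `unphased` downstream.
#'
#' @param calls duplex call table of somatic variants (the germline-site
#'   chromosome's calls are the candidates).
#' @param site a [GermlineSite-class].
#' @param phaseBias probability of the non-carrier copy.
#' @param seed RNG seed.
#' @param refReadsPerVariant uninformative reference reads per variant.
#' @return data.frame of read observations (see [phaseVariants()]); the
#'   `"phase_truth"` attribute maps each variant to its simulated phase.
#' @export
simulateReadObservations <- function(calls, site = germlineSite(),
                                     phaseBias = 25 / 29, seed = 1L,
                                     refReadsPerVariant = 2L) {
    calls <- checkCalls(calls)
    calls <- calls[calls$chrom == site@chrom, , drop = FALSE]
    empty <- data.frame(read_id = character(), sample_id = character(),
        chrom = character(), start = integer(), end = integer(),
        variant_pos = integer(), variant_ref = character(),
        variant_alt = character(), base_at_variant = character(),
        base_at_germline = character(), stringsAsFactors = FALSE)
    if (!nrow(calls)) {
        attr(empty, "phase_truth") <- data.frame(key = character(),
                                                 phase = character())
        return(empty)
    }
    withSeed(seed, {
        rows <- list()
        truth <- character(nrow(calls))
        for (i in seq_len(nrow(calls))) {
            dist <- abs(calls$pos[i] - site@pos)
            phaseable <- dist <= site@maxPhaseDistance
            onNoncarrier <- stats::runif(1) < phaseBias
            truth[i] <- if (!phaseable) "unphased"
                else if (onNoncarrier) "noncarrier_copy" else "carrier_copy"
            gBase <- if (onNoncarrier) site@ref else site@alt
            k <- calls$alt_duplex_reads[i]
            if (phaseable) {
                lo <- min(calls$pos[i], site@pos) - 10L
                hi <- max(calls$pos[i], site@pos) + 10L
            } else {
                lo <- calls$pos[i] - 70L
                hi <- calls$pos[i] + 70L
            }
            spansSite <- site@pos >= lo & site@pos <= hi
            mk <- function(nr, vBase, gB) {
                if (nr < 1L) return(NULL)
                data.frame(
                    read_id = sprintf("%s_%d_%s_%d", calls$sample_id[i],
                        calls$pos[i], vBase, seq_len(nr)),
                    sample_id = calls$sample_id[i], chrom = site@chrom,
                    start = lo, end = hi, variant_pos = calls$pos[i],
                    variant_ref = calls$ref[i], variant_alt = calls$alt[i],
                    base_at_variant = vBase,
                    base_at_germline = if (spansSite) gB
                                       else NA_character_,
                    stringsAsFactors = FALSE)
            }
            refG <- sample(c(site@ref, site@alt), refReadsPerVariant,
                           replace = TRUE)
            rows[[length(rows) + 1L]] <- mk(k, calls$alt[i], gBase)
            for (r in seq_len(refReadsPerVariant))
                rows[[length(rows) + 1L]] <- mk(1L, calls$ref[i], refG[r])
        }
        reads <- do.call(rbind, rows)
        if (is.null(reads)) reads <- empty
        reads$read_id <- make.unique(reads$read_id)
        attr(reads, "phase_truth") <- data.frame(
            key = variantKey(calls), sample_id = calls$sample_id,
            phase = truth, stringsAsFactors = FALSE)
        reads
    })
}

#' Inject labelled confounders into a cohort
#'
#' Adds (a) recurrent artifact variants present in at least
#' `n_samples_shared` samples with a mismatch annotation of
#' `mismatch_annotation` (>= 8) in every carrying sample, and (b) germline
#' heterozygous SNP calls at VAF ~`vaf_mean` in one home subject plus
#' low-VAF echoes of the same allele in two other samples. Every injected
#' record carries a ground-truth label (`artifact` / `germline`) so filter
#' recovery is checkable; a correct cascade removes all of them and none of
#' the clean somatic calls.
#'
#' @param cohort a [DuplexCohort-class].
#' @param config a [SimConfig-class] (defaults to the cohort's own).
#' @return the cohort with confounder rows appended to its call table.
#' @export
injectConfounders <- function(cohort, config = cohort@config) {
    calls <- cohort@calls
    samples <- cohort@metadata$subject_id
    if (length(samples) < config@artifactSpec$n_samples_shared)
        stop("need at least ", config@artifactSpec$n_samples_shared,
             " samples to inject shared artifacts")
    ref <- cohort@reference
    flatPos <- do.call(rbind, lapply(seq_along(ref$regions), function(i)
        data.frame(chrom = as.character(
            GenomicRanges::seqnames(ref$regions)[i]),
            pos = GenomicRanges::start(ref$regions)[i] +
                seq_along(ref$bases[[i]]) - 1L,
            stringsAsFactors = FALSE)))
    used <- unique(paste(calls$chrom, calls$pos))
    free <- flatPos[!paste(flatPos$chrom, flatPos$pos) %in% used, ,
                    drop = FALSE]
    newRows <- withSeed(deriveSeed(config@seed, 9991L), {
        rows <- list()
        a <- config@artifactSpec
        pick <- free[sample.int(nrow(free),
            a$n_artifacts + config@germlineSnpSpec$n_sites), , drop = FALSE]
        for (j in seq_len(a$n_artifacts)) {
            chrom <- pick$chrom[j]; pos <- pick$pos[j]
            rb <- refAt(ref, chrom, pos)
            ab <- sample(setdiff(.BASES, rb), 1)
            carriers <- sample(samples,
                sample(a$n_samples_shared:length(samples), 1))
            for (s in carriers) {
                dp <- depthAt(cohort@depth[[s]], chrom, pos)
                ar <- sample(1:2, 1)
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = s, chrom = chrom, pos = pos, ref = rb,
                    alt = ab, alt_duplex_reads = ar, duplex_depth = dp,
                    no_call_fraction = round(stats::runif(1, 0, 0.08), 4),
                    mismatch_annotation = a$mismatch_annotation,
                    variant_class = "SNV", vaf = ar / dp,
                    truth = "artifact", stringsAsFactors = FALSE)
            }
        }
        g <- config@germlineSnpSpec
        for (j in seq_len(g$n_sites)) {
            k <- a$n_artifacts + j
            chrom <- pick$chrom[k]; pos <- pick$pos[k]
            rb <- refAt(ref, chrom, pos)
            ab <- sample(setdiff(.BASES, rb), 1)
            home <- sample(samples, 1)
            echoes <- sample(setdiff(samples, home), 2)
            dp <- depthAt(cohort@depth[[home]], chrom, pos)
            ar <- round(dp * stats::rnorm(1, g$vaf_mean, 0.02))
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = home, chrom = chrom, pos = pos, ref = rb,
                alt = ab, alt_duplex_reads = ar, duplex_depth = dp,
                no_call_fraction = round(stats::runif(1, 0, 0.05), 4),
                mismatch_annotation = sample(0:2, 1),
                variant_class = "SNV", vaf = ar / dp,
                truth = "germline", stringsAsFactors = FALSE)
            for (s in echoes) {
                dpe <- depthAt(cohort@depth[[s]], chrom, pos)
                are <- sample(1:3, 1)
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = s, chrom = chrom, pos = pos, ref = rb,
                    alt = ab, alt_duplex_reads = are, duplex_depth = dpe,
                    no_call_fraction = round(stats::runif(1, 0, 0.05), 4),
                    mismatch_annotation = sample(0:2, 1),
                    variant_class = "SNV", vaf = are / dpe,
                    truth = "germline", stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, rows)
    })
    newRows <- annotateCalls(newRows, cohort@geneModels)
    keep <- union(names(calls), names(newRows))
    for (nm in setdiff(keep, names(calls))) calls[[nm]] <- NA
    for (nm in setdiff(keep, names(newRows))) newRows[[nm]] <- NA
    cohort@calls <- rbind(calls[keep], newRows[keep])
    cohort
}

#' Generate a full synthetic cohort
#'
#' Orchestrates the generator: builds (or takes) the gene models, panel
#' regions, mask and panel reference; simulates a depth profile and somatic
#' variant calls per subject; adds the germline heterozygous variant at the
#' phasing site for carrier subjects (VAF ~0.5); simulates duplex read
#' observations around the phasing site for carrier TP53 somatic variants;
#' and injects labelled artifact and germline-SNP confounders. Every call
#' carries a `truth` label in \{somatic, artifact, germline\}.
#'
#' @param config a [SimConfig-class].
#' @param geneModels named list of [GeneModel-class].
#' @param scoreTable optional [PathogenicityTable-class] for
#'   pathogenicity-weighted missense draws (see
#'   [simulateSampleVariants()]).
#' @param site a [GermlineSite-class] for phasing.
#' @param mask region mask (default [defaultMask()]).
#' @param confounders inject labelled confounders (default `TRUE`).
#' @return A [DuplexCohort-class].
#' @export
simulateCohort <- function(config = simConfig(),
                           geneModels = makeGeneModels(),
                           scoreTable = NULL, site = germlineSite(),
                           mask = NULL, confounders = TRUE) {
    regions <- panelRegions(geneModels)
    regions <- regions[intersect(config@panels$label, names(regions))]
    if (is.null(mask)) {
        allR <- panelRegions(geneModels)
        mask <- defaultMask(allR)
        mask <- mask[IRanges::overlapsAny(mask,
            GenomicRanges::sort(.cGRanges(regions)))]
    }
    reference <- makePanelReference(regions, geneModels,
                                    deriveSeed(config@seed, 7L))
    depths <- list(); allCalls <- list(); readRows <- list()
    truthRows <- list()
    for (i in seq_len(nrow(config@subjects))) {
        subj <- config@subjects[i, , drop = FALSE]
        profs <- lapply(seq_along(regions), function(k) {
            p <- config@panels[config@panels$label == names(regions)[k], ]
            simulateDepth(regions[[k]], p$mean_depth, p$dispersion,
                          seed = deriveSeed(config@seed, 100L * i + k))
        })
        depth <- mergeDepthProfiles(profs)
        depths[[subj$subject_id]] <- depth
        calls <- simulateSampleVariants(subj, geneModels, depth, config,
            reference, mask, scoreTable,
            seed = deriveSeed(config@seed, 1000L + i))
        if (subj$carrier && !is.na(depthAt(depth, site@chrom, site@pos))) {
            dp <- depthAt(depth, site@chrom, site@pos)
            ar <- as.integer(round(dp * 0.5))
            germRow <- annotateCalls(data.frame(
                sample_id = subj$subject_id, chrom = site@chrom,
                pos = site@pos, ref = site@ref, alt = site@alt,
                alt_duplex_reads = ar, duplex_depth = dp,
                no_call_fraction = 0.01,
                mismatch_annotation = 0L, variant_class = "SNV",
                vaf = ar / dp, stringsAsFactors = FALSE), geneModels)
            germRow$truth <- "germline"
            calls <- rbind(calls, germRow)
        }
        allCalls[[i]] <- calls
        if (subj$carrier) {
            som <- calls[calls$truth == "somatic" &
                         calls$chrom == site@chrom, , drop = FALSE]
            if (nrow(som)) {
                rd <- simulateReadObservations(som, site, config@phaseBias,
                    seed = deriveSeed(config@seed, 2000L + i))
                readRows[[length(readRows) + 1L]] <- rd
                truthRows[[length(truthRows) + 1L]] <-
                    attr(rd, "phase_truth")
            }
        }
    }
    reads <- if (length(readRows)) do.call(rbind, readRows) else
        simulateReadObservations(.emptyCalls(), site)
    attr(reads, "phase_truth") <- if (length(truthRows))
        do.call(rbind, truthRows) else
        data.frame(key = character(), sample_id = character(),
                   phase = character())
    cohort <- new("DuplexCohort", calls = do.call(rbind, allCalls),
        depth = depths, metadata = config@subjects, mask = mask,
        geneModels = geneModels, reference = reference, reads = reads,
        scoreTable = scoreTable, config = config)
    if (confounders) cohort <- injectConfounders(cohort)
    cohort
}

#' Synthetic pathogenicity score table for the panel genes
#'
#' Enumerates every possible missense substitution of each gene and assigns
#' a deterministic pseudo-random score in [0, 1] (Beta(2, 2), so centered
#' at 0.5); one score per protein change. A synthetic stand-in for a real
#' score table, sufficient for exercising annotation and score-distribution
#' comparisons.
#'
#' @param geneModels named list of [GeneModel-class].
#' @param seed RNG seed.
#' @return A [PathogenicityTable-class].
#' @export
makeScoreTable <- function(geneModels, seed = 42L) {
    withSeed(seed, {
        tabs <- lapply(geneModels, function(gm) {
            em <- enumerateMissense(gm)
            em <- em[!duplicated(em$protein_key), , drop = FALSE]
            data.frame(gene_id = gm@geneId, key = em$protein_key,
                       score = round(stats::rbeta(nrow(em), 2, 2), 4),
                       stringsAsFactors = FALSE)
        })
        pathogenicityTable(do.call(rbind, tabs))
    })
}
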