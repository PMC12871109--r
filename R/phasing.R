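# Read-backed phasing of somatic variants against the germline heterozygous
# site, exact binomial tests (phase bias, domain enrichment), codon-level
# hotspot recurrence, and cross-sample sharing.

#' Phase somatic variants against the germline site
#'
#' For every candidate variant (within `maxPhaseDistance` of the germline
#' site, same chromosome), the informative reads are those that carry the
#' variant's alternate base AND cover the germline site; reads carrying the
#' reference base say nothing about the mutant haplotype. The germline-site
#' base of the informative reads assigns the phase: the carrier (alternate)
#' base puts the variant on the carrier copy, the reference base on the
#' non-carrier copy. No informative read leaves the variant unphased;
#' disagreeing informative reads yield a distinct `conflict` state rather
#' than a majority vote, so inconsistencies surface loudly.
#'
#' @param calls duplex call table of somatic variants.
#' @param reads data.frame of duplex read observations: `read_id`,
#'   `sample_id`, `start`, `end` (1-based inclusive span),
#'   `variant_pos`, `variant_ref`, `variant_alt` (the somatic site the read
#'   reports on), `base_at_variant`, `base_at_germline` (`NA` when the span
#'   does not cover the respective site). A non-`NA` base at an uncovered
#'   position is a malformed-input error.
#' @param site a [GermlineSite-class].
#' @return data.frame with one row per candidate variant: `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `phase` in \{carrier_copy,
#'   noncarrier_copy, unphased, conflict\}, `n_informative_reads`.
#' @export
phaseVariants <- function(calls, reads, site = germlineSite()) {
    calls <- checkCalls(calls)
    cand <- calls$chrom == site@chrom &
        abs(calls$pos - site@pos) <= site@maxPhaseDistance
    calls <- calls[cand, , drop = FALSE]
    if (nrow(reads)) {
        badV <- !is.na(reads$base_at_variant) &
            (reads$variant_pos < reads$start | reads$variant_pos > reads$end)
        badG <- !is.na(reads$base_at_germline) &
            (site@pos < reads$start | site@pos > reads$end)
        if (any(badV | badG))
            stop("malformed read observation(s): base reported at an ",
                 "uncovered position (read ",
                 paste(reads$read_id[badV | badG], collapse = ", "), ")")
    }
    res <- calls[, c("sample_id", "chrom", "pos", "ref", "alt")]
    res$phase <- rep("unphased", nrow(res))
    res$n_informative_reads <- rep(0L, nrow(res))
    for (i in seq_len(nrow(calls))) {
        sel <- reads$sample_id == calls$sample_id[i] &
            reads$variant_pos == calls$pos[i] &
            !is.na(reads$base_at_variant) &
            reads$base_at_variant == calls$alt[i] &
            !is.na(reads$base_at_germline)
        g <- reads$base_at_germline[sel]
        known <- g %in% c(site@ref, site@alt)
        if (any(!known))
            warning("read(s) with unexpected germline-site base ignored")
        g <- g[known]
        res$n_informative_reads[i] <- length(g)
        if (!length(g)) next
        res$phase[i] <- if (all(g == site@alt)) "carrier_copy"
            else if (all(g == site@ref)) "noncarrier_copy"
            else "conflict"
    }
    res
}

#' Exact binomial test for phase bias
#'
#' Two-sided exact binomial test of the number of phased variants on the
#' non-carrier copy against an equal split (success probability 0.5),
#' using the minimum-likelihood two-sided convention; for p = 0.5 this
#' equals `2 * P(X >= k)` for `k > n/2`, capped at 1. With 25 of 29 phased
#' variants on the non-carrier copy the p-value is 1.04e-4 (0.0001 at the
#' printed precision).
#'
#' @param nNoncarrier phased variants on the non-carrier copy.
#' @param nPhased total phased variants.
#' @return two-sided exact p-value.
#' @examples
#' phaseBinomialTest(25, 29)
#' @export
phaseBinomialTest <- function(nNoncarrier, nPhased) {
    if (nPhased < 1L) stop("no phased variants")
    if (nNoncarrier < 0L || nNoncarrier > nPhased)
        stop("nNoncarrier must be between 0 and nPhased")
    stats::binom.test(nNoncarrier, nPhased, p = 0.5,
                      alternative = "two.sided")$p.value
}

#' Protein-domain enrichment of coding SNVs
#'
#' Tests whether coding SNVs cluster in a named protein domain (by default
#' the DNA-binding domain). The expected proportion is the domain's share
#' of the coding region in base pairs; the observed proportion is the
#' fraction of SNVs whose codon lies in the domain. Significance is an
#' exact binomial test of the observed count against the expected
#' proportion, with a Clopper-Pearson 95% interval on the observed
#' proportion.
#'
#' @param snvs duplex call table of coding SNVs in the gene.
#' @param gm a [GeneModel-class] with the domain annotated.
#' @param domain domain name (default `"DBD"`).
#' @param pooling count every call (`"calls"`) or distinct variant keys
#'   (`"unique"`).
#' @return list: `observed_prop`, `expected_prop`, `p_value`, `conf_int`,
#'   `n_in_domain`, `n`.
#' @export
dbdEnrichment <- function(snvs, gm, domain = "DBD",
                          pooling = c("calls", "unique")) {
    pooling <- match.arg(pooling)
    snvs <- checkCalls(snvs)
    if (!nrow(snvs)) stop("no SNVs supplied")
    d <- gm@domains[gm@domains$domain == domain, , drop = FALSE]
    if (!nrow(d)) stop("domain not annotated on gene model: ", domain)
    if (pooling == "unique")
        snvs <- snvs[!duplicated(variantKey(snvs)), , drop = FALSE]
    off <- cdsOffset(gm, snvs$pos)
    if (anyNA(off)) stop("SNV(s) outside the CDS")
    codon <- off %/% 3L + 1L
    inDomain <- codon >= d$start_res[1] & codon <= d$end_res[1]
    expected <- (3 * (d$end_res[1] - d$start_res[1] + 1)) /
        length(gm@cdsSequence)
    n <- nrow(snvs); x <- sum(inDomain)
    bt <- stats::binom.test(x, n, p = min(expected, 1))
    list(observed_prop = x / n, expected_prop = expected,
         p_value = bt$p.value, conf_int = as.numeric(bt$conf.int),
         n_in_domain = x, n = n)
}

#' Codon-level hotspot recurrence across samples
#'
#' Maps coding SNVs (and MNVs within one codon) to codons and reports, per
#' codon, the number of distinct samples carrying at least one mutation
#' there (a sample counts once however many calls it has) and the set of
#' amino-acid substitution spellings observed (e.g. R248Q, R248W). Calls
#' outside the CDS are skipped with a message.
#'
#' @param calls duplex call table for one gene.
#' @param gm a [GeneModel-class].
#' @return data.frame sorted by decreasing recurrence: `codon`,
#'   `n_samples`, `substitutions` (comma-separated spellings).
#' @export
hotspotRecurrence <- function(calls, gm) {
    calls <- checkCalls(calls)
    if (!nrow(calls))
        return(data.frame(codon = integer(), n_samples = integer(),
                          substitutions = character()))
    off <- cdsOffset(gm, calls$pos)
    out <- is.na(off)
    if (any(out))
        message(sum(out), " call(s) outside the CDS skipped")
    calls <- calls[!out, , drop = FALSE]
    off <- off[!out]
    if (!nrow(calls))
        return(data.frame(codon = integer(), n_samples = integer(),
                          substitutions = character()))
    codon <- off %/% 3L + 1L
    if (!"gene_id" %in% names(calls)) calls$gene_id <- gm@geneId
    calls$gene_id[is.na(calls$gene_id)] <- gm@geneId
    spell <- proteinChange(calls, stats::setNames(list(gm), gm@geneId))
    agg <- lapply(split(seq_len(nrow(calls)), codon), function(ix) {
        sp <- unique(spell[ix])
        data.frame(n_samples = length(unique(calls$sample_id[ix])),
                   substitutions = paste(sort(sp[!is.na(sp)]),
                                         collapse = ","))
    })
    res <- do.call(rbind, agg)
    res <- data.frame(codon = as.integer(names(agg)),
                      n_samples = res$n_samples,
                      substitutions = res$substitutions,
                      stringsAsFactors = FALSE)
    res[order(-res$n_samples, res$codon), , drop = FALSE]
}

#' Pairwise cross-sample variant sharing
#'
#' Symmetric matrix of shared variant-key counts between samples; the
#' diagonal holds each sample's distinct key count.
#'
#' @param calls combined duplex call table.
#' @param samples sample ids to include (default: those present, sorted).
#' @return integer matrix, samples x samples.
#' @export
crossSampleSharing <- function(calls, samples = NULL) {
    calls <- checkCalls(calls)
    if (is.null(samples)) samples <- sort(unique(calls$sample_id))
    keys <- lapply(stats::setNames(samples, samples), function(s)
        unique(variantKey(calls[calls$sample_id == s, , drop = FALSE])))
    n <- length(samples)
    m <- matrix(0L, n, n, dimnames = list(samples, samples))
    for (i in seq_len(n)) for (j in i:n) {
        v <- length(intersect(keys[[i]], keys[[j]]))
        m[i, j] <- v; m[j, i] <- v
    }
    m
}
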