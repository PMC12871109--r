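# Selection inference: consequence classification from the codon table,
# exhaustive enumeration of possible synonymous/nonsynonymous sites, the
# pseudocounted dN/dS estimator, its bootstrap, and group aggregation.

# Translate codons through the standard genetic code, vectorized.
.translateCodons <- function(codons) {
    aa <- Biostrings::GENETIC_CODE[codons]
    if (anyNA(aa)) stop("invalid codon(s): ",
                        paste(unique(codons[is.na(aa)]), collapse = ", "))
    unname(aa)
}

#' Classify the consequence of a coding single-nucleotide change
#'
#' Translates the affected codon before and after the substitution: an
#' unchanged amino acid is synonymous, a gained stop is nonsense, anything
#' else (including loss of the terminal stop) is missense. When a variant
#' carries several annotations elsewhere in the pipeline, the most severe is
#' used with severity order nonsense > splice > missense > synonymous.
#'
#' @param cds coding sequence (character or `DNAString`), in frame,
#'   5'->3' on the coding strand.
#' @param offset 0-based position(s) in the CDS.
#' @param alt alternate base(s) on the coding strand.
#' @return character vector in \{"synonymous", "missense", "nonsense"\}.
#' @examples
#' classifyConsequence("GCTTAC", 2, "A")  # GCT -> GCA, Ala->Ala
#' classifyConsequence("GCTTAC", 5, "A")  # TAC -> TAA, stop gained
#' @export
classifyConsequence <- function(cds, offset, alt) {
    s <- strsplit(toupper(as.character(cds)), "")[[1]]
    L <- length(s)
    if (L %% 3L != 0L) stop("CDS length must be divisible by 3")
    offset <- as.integer(offset)
    if (any(offset < 0L) || any(offset >= L))
        stop("offset outside the CDS")
    alt <- toupper(alt)
    if (any(alt == s[offset + 1L]))
        stop("alt equals the reference base at offset ",
             paste(offset[alt == s[offset + 1L]], collapse = ", "))
    ci <- offset %/% 3L            # codon index, 0-based
    wp <- offset %% 3L             # within-codon position
    b1 <- s[3L * ci + 1L]; b2 <- s[3L * ci + 2L]; b3 <- s[3L * ci + 3L]
    refCodon <- paste0(b1, b2, b3)
    a1 <- ifelse(wp == 0L, alt, b1)
    a2 <- ifelse(wp == 1L, alt, b2)
    a3 <- ifelse(wp == 2L, alt, b3)
    altCodon <- paste0(a1, a2, a3)
    refAA <- .translateCodons(refCodon)
    altAA <- .translateCodons(altCodon)
    ifelse(refAA == altAA, "synonymous",
           ifelse(altAA == "*", "nonsense", "missense"))
}

#' Enumerate possible synonymous and nonsynonymous sites of a CDS
#'
#' Every coding position admits three single-nucleotide changes; each is
#' classified through the codon table and counted, so
#' `N + S = 3 * nchar(cds)`. The terminal stop codon is included:
#' stop-retained changes count as synonymous, stop-lost as nonsynonymous.
#' Splice-region positions are excluded from the site denominator by
#' default; `spliceSiteCount` adds 3 nonsynonymous sites per padded splice
#' position for pipelines that count splice mutations among the observed
#' nonsynonymous events and want matching sites.
#'
#' @param cds in-frame coding sequence (character or `DNAString`).
#' @param spliceSiteCount number of intronic splice-region positions to add
#'   as purely nonsynonymous sites (default 0).
#' @return A [SiteCounts-class].
#' @examples
#' enumerateSiteCounts("ATGGCT")  # N = 15, S = 3
#' @export
enumerateSiteCounts <- function(cds, spliceSiteCount = 0L) {
    cds <- toupper(as.character(cds))
    L <- nchar(cds)
    if (L %% 3L != 0L) stop("CDS length must be divisible by 3")
    s <- strsplit(cds, "")[[1]]
    off <- rep(seq_len(L) - 1L, each = 3L)
    ref <- s[off + 1L]
    alt <- unlist(lapply(seq_len(L), function(i) setdiff(.BASES, s[i])),
                  use.names = FALSE)
    cons <- classifyConsequence(cds, off, alt)
    S <- sum(cons == "synonymous")
    siteCounts(nSites = 3L * L - S + 3L * as.integer(spliceSiteCount),
               sSites = S)
}

#' Pseudocounted dN/dS point estimate
#'
#' The rate ratio of observed nonsynonymous to synonymous mutations, each
#' normalized by its possible-site count, with a pseudocount added so the
#' estimate is defined even with zero synonymous observations: the expected
#' proportion of nonsynonymous mutations (`fN = N_sites/(N_sites+S_sites)`)
#' is added to the numerator count and the expected proportion of synonymous
#' mutations (`fS`) to the denominator count,
#' \deqn{dN/dS = \frac{(N_{obs} + f_N)/N_{sites}}{(S_{obs} + f_S)/S_{sites}}.}
#' Observed counts exactly proportional to the site counts (including 0/0)
#' give exactly 1.
#'
#' @param nObs,sObs observed nonsynonymous and synonymous mutation counts.
#' @param sites a [SiteCounts-class] for the gene (or gene set).
#' @return numeric dN/dS ratio.
#' @examples
#' dndsPoint(10, 0, siteCounts(15, 3))  # 13
#' dndsPoint(0, 0, siteCounts(15, 3))   # exactly 1
#' @export
dndsPoint <- function(nObs, sObs, sites) {
    if (any(nObs < 0) || any(sObs < 0))
        stop("observed counts must be non-negative")
    N <- sites@nSites; S <- sites@sSites
    if (S == 0) stop("no synonymous sites: dN/dS undefined")
    if (N == 0) stop("no nonsynonymous sites: dN/dS undefined")
    fN <- N / (N + S); fS <- S / (N + S)
    ((nObs + fN) / N) / ((sObs + fS) / S)
}

#' Bootstrap a pseudocounted dN/dS estimate
#'
#' Resamples the observed mutation list (the combined nonsynonymous +
#' synonymous list, unstratified) with replacement `B` times, recounting
#' N/S and applying the pseudocounted estimator inside every replicate, and
#' summarizes the replicate distribution by its interquartile range.
#' Percentiles use linear interpolation on the sorted replicates
#' (`quantile type 7`), so IQRs are exactly reproducible for a fixed seed.
#'
#' Nonsynonymous observations are those labelled `missense`, `nonsense` or
#' `splice`; `synonymous` labels are synonymous.
#'
#' @param consequences character vector of per-mutation consequence labels.
#' @param sites a [SiteCounts-class].
#' @param B number of bootstrap replicates (default 5000).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return A [DndsResult-class].
#' @export
dndsBootstrap <- function(consequences, sites, B = 5000L, seed = 1L) {
    ok <- c("synonymous", "missense", "nonsense", "splice")
    bad <- setdiff(unique(consequences), ok)
    if (length(bad))
        stop("unknown consequence label(s): ", paste(bad, collapse = ", "))
    n <- length(consequences)
    if (n < 1L)
        stop("empty mutation list; use dndsPoint() for a point-only estimate")
    if (B < 1L) stop("B must be >= 1")
    nonsyn <- consequences != "synonymous"
    nObs <- sum(nonsyn); sObs <- n - nObs
    point <- dndsPoint(nObs, sObs, sites)
    reps <- withSeed(seed, {
        idx <- sample.int(n, n * B, replace = TRUE)
        Nb <- colSums(matrix(nonsyn[idx], nrow = n, ncol = B))
        vapply(Nb, function(k) dndsPoint(k, n - k, sites), numeric(1))
    })
    q <- unname(stats::quantile(reps, c(0.25, 0.75), type = 7))
    new("DndsResult", nObs = as.integer(nObs), sObs = as.integer(sObs),
        point = point, q25 = q[1], q75 = q[2], B = as.integer(B),
        seed = as.integer(seed), replicates = reps)
}

#' Aggregate mutations into analysis groups
#'
#' Partitions a call table into the groupings used for selection analysis:
#' by gene and carrier status (`"gene_carrier"`), by carrier and
#' chemotherapy status (`"carrier_chemo"`), or by broad anatomical tissue
#' category (`"tissue_category"`). A minimum-mutation rule (default 10)
#' gates which groups are analyzed; the full partition is always returned
#' and the gated subset is recorded in the `"analyzed"` attribute.
#'
#' @param calls duplex call table with a `gene_id` column where needed.
#' @param metadata data.frame with `subject_id`, `carrier`, `chemo`,
#'   `tissue_category`; every `sample_id` in `calls` must appear.
#' @param grouping one of `"gene_carrier"`, `"carrier_chemo"`,
#'   `"tissue_category"`.
#' @param minCount minimum mutations for a group to be analyzed.
#' @return named list of call-table subsets (the full partition), with
#'   attribute `analyzed` naming the groups meeting `minCount`.
#' @export
aggregateGroups <- function(calls, metadata,
                            grouping = c("gene_carrier", "carrier_chemo",
                                         "tissue_category"),
                            minCount = 10L) {
    grouping <- match.arg(grouping)
    if (nrow(calls) == 0L) {
        out <- list()
        attr(out, "analyzed") <- character(0)
        return(out)
    }
    m <- match(calls$sample_id, metadata$subject_id)
    if (anyNA(m))
        stop("sample(s) missing from metadata: ",
             paste(unique(calls$sample_id[is.na(m)]), collapse = ", "))
    carrier <- ifelse(metadata$carrier[m], "carrier", "noncarrier")
    key <- switch(grouping,
        gene_carrier = paste(calls$gene_id, carrier, sep = "."),
        carrier_chemo = paste(carrier,
            ifelse(metadata$chemo[m], "chemo", "nochemo"), sep = "."),
        tissue_category = metadata$tissue_category[m])
    out <- split(calls, key)
    n <- vapply(out, nrow, integer(1))
    attr(out, "analyzed") <- names(out)[n >= minCount]
    out
}
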