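# Shared fixtures: a tiny two-exon gene, call-row builders, an independent
# site-count oracle, and a lazily built cohort reused across test files.

# Two-exon plus-strand gene on "chrT": exons 101-130 and 161-190 (60 nt CDS,
# 20 codons), splice pad 2 nt => intronic splice positions 131,132,159,160.
tinyGene <- function() {
    cds <- paste0("ATG",
                  paste(rep(c("GCT", "TGG", "CGC", "AAA", "TCA", "GAT"),
                            3), collapse = ""),
                  "TAA")  # 20 codons
    geneModel("TINY", "chrT", "+",
              data.frame(start = c(101L, 161L), end = c(130L, 190L)),
              cds,
              domains = data.frame(domain = "DOM", start_res = 5L,
                                   end_res = 10L))
}

makeCall <- function(sample = "S1", chrom = "chrT", pos = 105L, ref = "A",
                     alt = "G", reads = 1L, depth = 5000L, ncf = 0.01,
                     mm = 0L, class = "SNV", ...) {
    data.frame(sample_id = sample, chrom = chrom, pos = as.integer(pos),
               ref = ref, alt = alt, alt_duplex_reads = as.integer(reads),
               duplex_depth = as.integer(depth), no_call_fraction = ncf,
               mismatch_annotation = as.integer(mm), variant_class = class,
               ..., stringsAsFactors = FALSE)
}

bindCalls <- function(...) do.call(rbind, list(...))

# Independent site-count oracle: per-codon translation through seqinr's
# codon table, looped the naive way (never through the package path).
oracleSiteCounts <- function(cds) {
    s <- strsplit(toupper(cds), "")[[1]]
    bases <- c("A", "C", "G", "T")
    nN <- 0L; nS <- 0L
    for (i in seq_along(s)) {
        ci <- (i - 1L) %/% 3L
        codon <- s[(3L * ci + 1L):(3L * ci + 3L)]
        aa0 <- seqinr::translate(codon)
        for (b in setdiff(bases, s[i])) {
            mut <- codon
            mut[i - 3L * ci] <- b
            if (identical(seqinr::translate(mut), aa0)) nS <- nS + 1L
            else nN <- nN + 1L
        }
    }
    c(N = nN, S = nS)
}

randomCds <- function(nCodon) {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    paste(c("ATG", sample(sense, nCodon - 2L, replace = TRUE), "TAA"),
          collapse = "")
}

# One cohort shared by the integration-style tests (built on first use).
.fixtureEnv <- new.env(parent = emptyenv())
sharedCohort <- function() {
    if (is.null(.fixtureEnv$cohort))
        .fixtureEnv$cohort <- simulateCohort(simConfig(seed = 202L))
    .fixtureEnv$cohort
}
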