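# Shared helpers: call-table validation, variant keys, seeded RNG blocks,
# genomic <-> CDS coordinate mapping, depth-profile arithmetic.

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Validate a duplex call table
#'
#' A duplex call table is a data.frame with one row per called variant and
#' the columns `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `alt_duplex_reads`, `duplex_depth`, `no_call_fraction`,
#' `mismatch_annotation`, `variant_class` (SNV, MNV, insertion, deletion)
#' and `vaf`. `vaf` is recomputed as
#' `alt_duplex_reads / duplex_depth` wherever missing and depth > 0.
#' Optional columns used downstream: `gene_id`, `consequence`, `truth`.
#'
#' @param calls data.frame to validate.
#' @param context label used in error messages.
#' @return the validated (possibly vaf-completed) data.frame, invisibly
#'   usable in pipelines.
#' @export
checkCalls <- function(calls, context = "calls") {
    need <- c("sample_id", "chrom", "pos", "ref", "alt", "alt_duplex_reads",
              "duplex_depth", "no_call_fraction", "mismatch_annotation",
              "variant_class")
    miss <- setdiff(need, names(calls))
    if (length(miss))
        stop(context, " is missing column(s): ", paste(miss, collapse = ", "))
    if (!"vaf" %in% names(calls)) calls$vaf <- rep(NA_real_, nrow(calls))
    fix <- is.na(calls$vaf) & !is.na(calls$duplex_depth) &
        calls$duplex_depth > 0
    calls$vaf[fix] <- calls$alt_duplex_reads[fix] / calls$duplex_depth[fix]
    mnv <- calls$variant_class == "MNV"
    bad <- mnv & (nchar(calls$ref) != nchar(calls$alt) | nchar(calls$ref) < 2)
    if (any(bad))
        stop(context, ": MNV rows must have ref and alt of equal length > 1")
    calls
}

#' Variant key
#'
#' The identity used for cross-sample matching: `chrom:pos:ref>alt`. An MNV
#' (e.g. CC>TT) is a single key.
#'
#' @param calls duplex call table (or any data.frame with `chrom`, `pos`,
#'   `ref`, `alt`).
#' @return character vector of keys, one per row.
#' @export
variantKey <- function(calls)
    sprintf("%s:%d:%s>%s", calls$chrom, as.integer(calls$pos), calls$ref,
            calls$alt)

# Evaluate expr with a local, fully restored RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Concatenate GRanges from different chromosomes without the no-common-
# seqlevels warning.
.cGRanges <- function(lst) suppressWarnings(do.call(c, unname(lst)))

# Deterministic stream of sub-seeds below 2^31, LCG on the master seed.
deriveSeed <- function(seed, i)
    as.integer((as.numeric(seed) * 48271 + 1103515245 * i) %% 2147483647)

.emptyCalls <- function() {
    data.frame(sample_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               alt_duplex_reads = integer(), duplex_depth = integer(),
               no_call_fraction = numeric(),
               mismatch_annotation = integer(),
               variant_class = character(), vaf = numeric(),
               stringsAsFactors = FALSE)
}

## ---- DepthProfile ----

#' Build a depth profile
#'
#' @param regions [GenomicRanges::GRanges] of covered intervals (will be
#'   sorted; must be non-overlapping).
#' @param depth list of integer vectors, one per region, or a single value
#'   recycled to every position.
#' @return A [DepthProfile-class].
#' @export
depthProfile <- function(regions, depth) {
    o <- GenomicRanges::order(regions)
    regions <- regions[o]
    if (!is.list(depth)) {
        depth <- lapply(GenomicRanges::width(regions), function(w)
            rep(as.integer(depth), w))
    } else depth <- depth[o]
    new("DepthProfile", regions = regions,
        depth = lapply(depth, as.integer))
}

setMethod("show", "DepthProfile", function(object) {
    tot <- sum(vapply(object@depth, function(d) sum(as.numeric(d)),
                      numeric(1)))
    cat("DepthProfile:", length(object@regions), "region(s),",
        sum(GenomicRanges::width(object@regions)), "positions,",
        format(tot, big.mark = ","), "duplex nucleotides\n")
})

setMethod("totalDuplexNucleotides", "DepthProfile",
    function(x, region = NULL) {
        if (is.null(region))
            return(sum(vapply(x@depth, function(d) sum(as.numeric(d)),
                              numeric(1))))
        region <- GenomicRanges::reduce(GenomicRanges::sort(region))
        tot <- 0
        for (i in seq_along(x@regions)) {
            r <- x@regions[i]
            hits <- IRanges::findOverlaps(r, region)
            if (!length(hits)) next
            for (j in S4Vectors::subjectHits(hits)) {
                q <- region[j]
                lo <- max(GenomicRanges::start(r), GenomicRanges::start(q))
                hi <- min(GenomicRanges::end(r), GenomicRanges::end(q))
                off <- (lo:hi) - GenomicRanges::start(r) + 1L
                tot <- tot + sum(as.numeric(x@depth[[i]][off]))
            }
        }
        tot
    })

setMethod("depthAt", "DepthProfile", function(x, chrom, pos) {
    pos <- as.integer(pos)
    out <- rep(NA_integer_, length(pos))
    rc <- as.character(GenomicRanges::seqnames(x@regions))
    rs <- GenomicRanges::start(x@regions)
    re <- GenomicRanges::end(x@regions)
    for (i in seq_along(x@regions)) {
        sel <- chrom == rc[i] & pos >= rs[i] & pos <= re[i]
        if (any(sel)) out[sel] <- x@depth[[i]][pos[sel] - rs[i] + 1L]
    }
    out
})

## ---- genomic <-> CDS coordinate mapping ----

#' Map genomic positions to 0-based CDS offsets
#'
#' Positions outside the CDS map to `NA`. For minus-strand genes the offset
#' runs antiparallel to the genome, and coding-strand bases are the
#' complement of genomic bases.
#'
#' @param gm a [GeneModel-class].
#' @param pos integer vector of 1-based genomic positions.
#' @return integer vector of 0-based offsets into `cdsSequence(gm)`.
#' @export
cdsOffset <- function(gm, pos) {
    pos <- as.integer(pos)
    st <- GenomicRanges::start(gm@cdsIntervals)
    en <- GenomicRanges::end(gm@cdsIntervals)
    w <- en - st + 1L
    cum <- c(0L, cumsum(w))
    L <- sum(w)
    out <- rep(NA_integer_, length(pos))
    for (i in seq_along(st)) {
        sel <- pos >= st[i] & pos <= en[i]
        if (any(sel)) out[sel] <- cum[i] + (pos[sel] - st[i])
    }
    if (gm@strand == "-") out <- L - 1L - out
    out
}

# Inverse of cdsOffset: 0-based CDS offsets -> genomic positions.
genomicPos <- function(gm, offset) {
    offset <- as.integer(offset)
    w <- GenomicRanges::width(gm@cdsIntervals)
    cum <- c(0L, cumsum(w))
    L <- sum(w)
    asc <- if (gm@strand == "-") L - 1L - offset else offset
    idx <- findInterval(asc, cum[-length(cum)])
    GenomicRanges::start(gm@cdsIntervals)[idx] + (asc - cum[idx])
}

# Genomic-strand base -> coding-strand base for a gene (and back; the
# complement is an involution).
codingStrandBase <- function(gm, base) {
    if (gm@strand == "-") unname(.COMPLEMENT[base]) else base
}

# Intronic splice-region positions (gaps between CDS exons, padded edges).
spliceSites <- function(gm) {
    iv <- gm@cdsIntervals
    if (length(iv) < 2L) return(integer(0))
    en <- GenomicRanges::end(iv)[-length(iv)]
    st <- GenomicRanges::start(iv)[-1L]
    pad <- gm@splicePad
    unlist(lapply(seq_along(en), function(i) {
        gap <- (en[i] + 1L):(st[i] - 1L)
        c(gap[seq_len(min(pad, length(gap)))],
          rev(gap)[seq_len(min(pad, length(gap)))])
    }))
}
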