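# Rule-based pathogenicity annotation from a user-supplied score table
# (AlphaMissense-style scores in [0,1]), large-clone flags, and score
# distribution comparisons against the all-possible-substitution background.

#' Construct a pathogenicity score table
#'
#' @param scores data.frame with columns `gene_id`, `key`, `score`. Keys
#'   are protein notation (`"R248Q"`) or genomic SNV notation
#'   (`"chr17:7674220:C>T"`); the two dialects may coexist. Duplicate keys
#'   with conflicting scores are rejected.
#' @param ambiguousLow,pathogenic category thresholds (defaults 0.34 and
#'   0.564): score > `pathogenic` is Likely Pathogenic, `ambiguousLow` <=
#'   score <= `pathogenic` is Ambiguous, score < `ambiguousLow` is Likely
#'   Benign.
#' @return A [PathogenicityTable-class].
#' @export
pathogenicityTable <- function(scores, ambiguousLow = 0.34,
                               pathogenic = 0.564) {
    need <- c("gene_id", "key", "score")
    if (!all(need %in% names(scores)))
        stop("score table needs columns: ", paste(need, collapse = ", "))
    id <- paste(scores$gene_id, scores$key, sep = "|")
    dup <- duplicated(id)
    if (any(dup)) {
        first <- match(id[dup], id)
        if (any(scores$score[dup] != scores$score[first]))
            stop("conflicting scores for key(s): ",
                 paste(unique(id[dup][scores$score[dup] !=
                                      scores$score[first]]), collapse = ", "))
        scores <- scores[!dup, , drop = FALSE]
        id <- id[!dup]
    }
    v <- scores$score
    names(v) <- id
    new("PathogenicityTable", scores = v,
        ambiguousLow = as.numeric(ambiguousLow),
        pathogenic = as.numeric(pathogenic))
}

#' Read a pathogenicity score table from TSV
#'
#' @param file TSV with header columns `gene_id`, `key`, `score`.
#' @inheritParams pathogenicityTable
#' @return A [PathogenicityTable-class].
#' @export
readPathogenicityTable <- function(file, ambiguousLow = 0.34,
                                   pathogenic = 0.564) {
    pathogenicityTable(utils::read.delim(file, stringsAsFactors = FALSE),
                       ambiguousLow, pathogenic)
}

.scoreCategory <- function(score, table) {
    ifelse(score > table@pathogenic, "Likely Pathogenic",
           ifelse(score >= table@ambiguousLow, "Ambiguous", "Likely Benign"))
}

#' Annotate calls with pathogenicity category and score
#'
#' Applies the mutation-type rules: nonsense variants, indels, splice
#' mutations and multi-nucleotide substitutions are Likely Pathogenic with
#' score 1; synonymous variants are Likely Benign with score 0; missense
#' variants take their table score and the threshold rules (> 0.564 Likely
#' Pathogenic, 0.34--0.564 Ambiguous, < 0.34 Likely Benign). A missense
#' call with no table entry is an error naming the key. Non-coding calls
#' get `NA` category and score.
#'
#' Missense lookup tries the protein key (`"R248Q"`, requires `gene_id` and
#' a gene model to derive it) then the genomic key (`"chrom:pos:ref>alt"`).
#'
#' @param calls duplex call table with `consequence` (see
#'   [annotateCalls()]).
#' @param table a [PathogenicityTable-class].
#' @param geneModels optional named list of [GeneModel-class], used to
#'   spell protein keys for missense lookups.
#' @return the call table with `pathogenicity` and `path_score` columns.
#' @export
annotatePathogenicity <- function(calls, table, geneModels = list()) {
    calls <- checkCalls(calls)
    if (!"consequence" %in% names(calls))
        stop("calls must carry a consequence column; run annotateCalls()")
    calls$pathogenicity <- NA_character_
    calls$path_score <- NA_real_
    lp <- calls$consequence %in% c("nonsense", "splice", "indel_coding") |
        (calls$variant_class == "MNV" & calls$consequence != "noncoding")
    calls$pathogenicity[lp] <- "Likely Pathogenic"
    calls$path_score[lp] <- 1
    syn <- !lp & calls$consequence == "synonymous"
    calls$pathogenicity[syn] <- "Likely Benign"
    calls$path_score[syn] <- 0
    mis <- !lp & calls$consequence == "missense"
    for (i in which(mis)) {
        ids <- paste(calls$gene_id[i],
                     c(proteinChange(calls[i, , drop = FALSE], geneModels),
                       variantKey(calls[i, , drop = FALSE])), sep = "|")
        hit <- ids[ids %in% names(table@scores)]
        if (!length(hit))
            stop("missense call without a pathogenicity score: ",
                 paste(unique(ids), collapse = " / "))
        calls$path_score[i] <- unname(table@scores[hit[1]])
    }
    calls$pathogenicity[mis] <- .scoreCategory(calls$path_score[mis], table)
    calls
}

#' Protein-change spelling of coding SNVs
#'
#' @param calls duplex call table (SNVs with `gene_id`).
#' @param geneModels named list of [GeneModel-class].
#' @return character vector like `"R248Q"` (`NA` where not a coding SNV of
#'   a known gene).
#' @export
proteinChange <- function(calls, geneModels) {
    out <- rep(NA_character_, nrow(calls))
    for (i in seq_len(nrow(calls))) {
        gm <- geneModels[[calls$gene_id[i]]]
        if (is.null(gm) || calls$variant_class[i] != "SNV") next
        off <- cdsOffset(gm, calls$pos[i])
        if (is.na(off)) next
        s <- strsplit(as.character(gm@cdsSequence), "")[[1]]
        alt <- codingStrandBase(gm, calls$alt[i])
        if (alt == s[off + 1L]) next
        ci <- off %/% 3L
        refCodon <- paste0(s[3L * ci + 1L], s[3L * ci + 2L], s[3L * ci + 3L])
        altCodon <- refCodon
        substr(altCodon, off %% 3L + 1L, off %% 3L + 1L) <- alt
        out[i] <- paste0(.translateCodons(refCodon), ci + 1L,
                         .translateCodons(altCodon))
    }
    out
}

#' Large-clone flag
#'
#' A mutation is a large clone iff it is supported by more than one mutant
#' duplex read (each duplex read is an independent DNA molecule, so >= 2
#' reads indicate clonal expansion).
#'
#' @param altDuplexReads integer vector of supporting duplex read counts
#'   (or a call table, from which the column is taken).
#' @return logical vector.
#' @export
largeCloneFlag <- function(altDuplexReads) {
    if (is.data.frame(altDuplexReads))
        altDuplexReads <- altDuplexReads$alt_duplex_reads
    if (any(altDuplexReads < 1))
        stop("a call must be supported by at least one duplex read")
    altDuplexReads > 1
}

#' Enumerate all possible missense substitutions of a gene
#'
#' Generates the background for score-distribution comparisons internally
#' from the CDS, so no external download is needed: every coding position
#' times its three alternative bases, restricted to missense outcomes.
#'
#' @param gm a [GeneModel-class].
#' @return data.frame with `offset` (0-based CDS), `ref`, `alt` (coding
#'   strand), `protein_key` (e.g. `"R248Q"`), `chrom`, `pos`, `g_ref`,
#'   `g_alt` (genomic spelling).
#' @export
enumerateMissense <- function(gm) {
    s <- strsplit(as.character(gm@cdsSequence), "")[[1]]
    L <- length(s)
    off <- rep(seq_len(L) - 1L, each = 3L)
    ref <- s[off + 1L]
    alt <- unlist(lapply(seq_len(L), function(i) setdiff(.BASES, s[i])),
                  use.names = FALSE)
    cons <- classifyConsequence(gm@cdsSequence, off, alt)
    keep <- cons == "missense"
    off <- off[keep]; ref <- ref[keep]; alt <- alt[keep]
    ci <- off %/% 3L
    refCodon <- paste0(s[3L * ci + 1L], s[3L * ci + 2L], s[3L * ci + 3L])
    altCodon <- refCodon
    substr(altCodon, off %% 3L + 1L, off %% 3L + 1L) <- alt
    pk <- paste0(.translateCodons(refCodon), ci + 1L,
                 .translateCodons(altCodon))
    data.frame(offset = off, ref = ref, alt = alt, protein_key = pk,
               chrom = gm@chrom, pos = genomicPos(gm, off),
               g_ref = codingStrandBase(gm, ref),
               g_alt = codingStrandBase(gm, alt),
               stringsAsFactors = FALSE)
}

#' Compare observed pathogenicity scores with the possible-substitution
#' background
#'
#' Summarizes observed missense scores against the background of all
#' possible missense substitutions, optionally stratified by clone size
#' (single-read vs multi-read mutations). The location comparison is
#' descriptive: per-stratum quantiles, median difference from the
#' background, and the probability that a random observed score exceeds a
#' random background score (rank-based, ties counted half).
#'
#' @param observed numeric scores, or a data.frame with `path_score` and
#'   `alt_duplex_reads` (required for stratification).
#' @param background numeric background scores (all possible missense).
#' @param stratifyByClone split observed scores into 1-read and >1-read
#'   strata.
#' @return list of per-stratum summaries (`all`, and `single_read` /
#'   `multi_read` when stratified); empty strata are `NULL`. Each summary
#'   has `n`, `quantiles`, `median_diff`, `p_greater`.
#' @export
scoreDistributionComparison <- function(observed, background,
                                        stratifyByClone = FALSE) {
    if (!length(background)) stop("empty background")
    if (is.data.frame(observed)) {
        reads <- observed$alt_duplex_reads
        observed <- observed$path_score
    } else reads <- NULL
    if (!length(observed)) stop("no observed scores")
    one <- function(x) {
        if (!length(x)) return(NULL)
        r <- outer(x, background, ">") + 0.5 * outer(x, background, "==")
        list(n = length(x),
             quantiles = stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1)),
             median_diff = stats::median(x) - stats::median(background),
             p_greater = mean(r))
    }
    out <- list(all = one(observed),
                background_quantiles =
                    stats::quantile(background, c(0, 0.25, 0.5, 0.75, 1)))
    if (stratifyByClone) {
        if (is.null(reads))
            stop("clone stratification needs alt_duplex_reads")
        out$single_read <- one(observed[reads == 1])
        out$multi_read <- one(observed[reads > 1])
    }
    out
}
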