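# The filter cascade: per-site thresholds (strict boundaries), recurrent
# artifacts, cross-sample germline exclusion, coding classification, and
# the cascade's conservation/idempotence contracts.

test_that("site filters use strict thresholds with ordered reasons", {
    mask <- GenomicRanges::GRanges("chrT", IRanges::IRanges(300, 320))
    calls <- bindCalls(
        makeCall(pos = 101, depth = 999),                    # depth
        makeCall(pos = 102, depth = 1000),                   # boundary kept
        makeCall(pos = 103, ncf = 0.1),                      # boundary kept
        makeCall(pos = 104, ncf = 0.11),                     # no_call
        makeCall(pos = 105, reads = 1550, depth = 5000),     # vaf 0.31
        makeCall(pos = 106, reads = 1500, depth = 5000),     # vaf 0.30 kept
        makeCall(pos = 310))                                 # mask
    r <- applySiteFilters(calls, mask)
    expect_equal(nrow(r$kept) + nrow(r$rejected), nrow(calls))
    expect_setequal(r$kept$pos, c(102, 103, 106))
    expect_equal(r$rejected$reason[match(c(101, 104, 105, 310),
                                         r$rejected$pos)],
                 c("depth", "no_call", "germline_vaf", "mask"))
    # first matching reason wins: low depth AND high ncf reports depth
    both <- makeCall(pos = 120, depth = 500, ncf = 0.5)
    expect_equal(applySiteFilters(both)$rejected$reason, "depth")
})

test_that("calls missing depth or no-call fraction are named in errors", {
    bad <- makeCall(pos = 140)
    bad$duplex_depth <- NA_integer_
    expect_error(applySiteFilters(bad), "chrT:140")
})

test_that("recurrent artifacts need both recurrence and mismatches", {
    k3 <- bindCalls(makeCall("S1", pos = 200, mm = 8),
                    makeCall("S2", pos = 200, mm = 9),
                    makeCall("S3", pos = 200, mm = 8))
    r <- recurrentArtifactFilter(k3)
    expect_equal(nrow(r$kept), 0)
    expect_equal(unique(r$removed$reason), "recurrent_artifact")

    k2 <- bindCalls(makeCall("S1", pos = 201, mm = 12),
                    makeCall("S2", pos = 201, mm = 12))
    expect_equal(nrow(recurrentArtifactFilter(k2)$removed), 0)

    k4 <- bindCalls(makeCall("S1", pos = 202, mm = 2),
                    makeCall("S2", pos = 202, mm = 3),
                    makeCall("S3", pos = 202, mm = 1),
                    makeCall("S4", pos = 202, mm = 0))
    expect_equal(nrow(recurrentArtifactFilter(k4)$removed), 0)

    # "all" mode requires the pattern in every carrying sample
    mixed <- bindCalls(makeCall("S1", pos = 203, mm = 9),
                       makeCall("S2", pos = 203, mm = 2),
                       makeCall("S3", pos = 203, mm = 9))
    expect_equal(nrow(recurrentArtifactFilter(mixed)$removed), 3)
    expect_equal(nrow(recurrentArtifactFilter(mixed,
                                              mode = "all")$removed), 0)
})

test_that("high-VAF keys are excluded from every other sample", {
    calls <- bindCalls(
        makeCall("A", pos = 400, reads = 2250, depth = 5000),  # vaf 0.45
        makeCall("B", pos = 400, reads = 1, depth = 5000),
        makeCall("A", pos = 401, reads = 1450, depth = 5000),  # vaf 0.29
        makeCall("B", pos = 401, reads = 2, depth = 5000))
    r <- crossSampleGermlineFilter(calls)
    expect_setequal(unique(r$kept$pos), 401)
    # single-sample cohort: nothing extra beyond the site filter
    solo <- makeCall("A", pos = 402, reads = 1, depth = 5000)
    expect_equal(nrow(crossSampleGermlineFilter(solo)$removed), 0)
    # cascade removes the echo even though the 0.45 record fell earlier
    fc <- filterCascade(calls)
    expect_false(400 %in% fc$kept$pos)
    expect_setequal(fc$removed$reason[fc$removed$pos == 400],
                    c("germline_vaf", "cross_sample_germline"))
})

test_that("coding classification honours the 2 nt splice padding", {
    gm <- tinyGene()  # exons 101-130, 161-190
    calls <- bindCalls(
        makeCall(pos = 110),    # mid-exon
        makeCall(pos = 132),    # 2 nt into the intron -> coding
        makeCall(pos = 133),    # 3 nt into the intron -> noncoding
        makeCall(pos = 159),    # 2 nt before exon 2 -> coding
        makeCall(pos = 150))    # deep intron
    expect_equal(classifyCoding(calls, gm),
                 c("coding", "coding", "noncoding", "coding", "noncoding"))
    # 5 nt deletion reaching 2 nt into exon 2 overlaps the CDS
    del <- makeCall(pos = 158, ref = "AAAAA", alt = "A",
                    class = "deletion")
    expect_equal(classifyCoding(del, gm), "coding")
    delOut <- makeCall(pos = 140, ref = "AAAA", alt = "A",
                       class = "deletion")
    expect_equal(classifyCoding(delOut, gm), "noncoding")
    expect_error(classifyCoding(makeCall(pos = 99000), gm),
                 "outside the panel")
})

test_that("annotation assigns gene, splice and joint MNV consequences", {
    gm <- list(TINY = tinyGene())
    # exon1 position 104 is CDS offset 3 (codon 2 GCT, first base G)
    snv <- annotateCalls(makeCall(pos = 104, ref = "G", alt = "A"), gm)
    expect_equal(snv$gene_id, "TINY")
    expect_equal(snv$consequence, "missense")
    syn <- annotateCalls(makeCall(pos = 106, ref = "T", alt = "C"), gm)
    expect_equal(syn$consequence, "synonymous")
    spl <- annotateCalls(makeCall(pos = 131, ref = "A", alt = "G"), gm)
    expect_equal(spl$consequence, "splice")
    # CC>TT style dinucleotide inside the CDS is one MNV event
    mnv <- annotateCalls(makeCall(pos = 104, ref = "GC", alt = "TT",
                                  class = "MNV"), gm)
    expect_equal(mnv$consequence, "missense")
    ind <- annotateCalls(makeCall(pos = 110, ref = "AGC", alt = "A",
                                  class = "deletion"), gm)
    expect_equal(ind$consequence, "indel_coding")
})

test_that("cascade conserves records and is idempotent", {
    co <- sharedCohort()
    calls <- cohortCalls(co)
    fc <- filterCascade(calls, cohortMask(co))
    expect_equal(nrow(fc$kept) + nrow(fc$removed), nrow(calls))
    again <- filterCascade(fc$kept, cohortMask(co))
    expect_equal(nrow(again$removed), 0)
    expect_identical(again$kept[names(fc$kept)], fc$kept)
})

test_that("cascade removes all labelled confounders and no clean calls", {
    co <- sharedCohort()
    calls <- cohortCalls(co)
    fc <- filterCascade(calls, cohortMask(co))
    expect_true(all(fc$kept$truth == "somatic"))
    expect_equal(sum(fc$removed$truth == "somatic"), 0)
})
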