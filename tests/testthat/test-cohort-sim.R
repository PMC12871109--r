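# The synthetic cohort generator: depth law, mutation counts, selection
# weighting, clone sizes, read observations, confounders, determinism.

test_that("depth simulation honours mean, dispersion and determinism", {
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 48000))
    flat <- simulateDepth(reg, 15000, dispersion = 0, seed = 1)
    expect_true(all(unlist(flat@depth) == 15000L))
    a <- simulateDepth(reg, 15000, dispersion = 0.05, seed = 7)
    b <- simulateDepth(reg, 15000, dispersion = 0.05, seed = 7)
    expect_identical(a@depth, b@depth)
    m <- totalDuplexNucleotides(a) / 48000
    expect_gte(m, 14250); expect_lte(m, 15750)
    expect_error(simulateDepth(GenomicRanges::GRanges(), 100), "empty")
    expect_error(simulateDepth(reg, 0), "positive")
})

test_that("zero base rate yields zero somatic variants", {
    gm <- makeGeneModels()["TP53"]
    reg <- range(cdsIntervals(gm$TP53))
    dp <- simulateDepth(reg, 5000, 0, seed = 1)
    cfg <- simConfig(baseRate = 0)
    subj <- data.frame(subject_id = "S", age_years = 50, carrier = FALSE,
                       chemo = FALSE, tissue_category = "blood")
    v <- simulateSampleVariants(subj, gm, dp, cfg, seed = 1)
    expect_equal(nrow(v), 0)
    expect_true(all(c("gene_id", "consequence", "truth") %in% names(v)))
})

test_that("neutral genes draw nonsyn:syn at the site-count ratio", {
    gm <- makeGeneModels()["TP53"]
    reg <- range(cdsIntervals(gm$TP53))
    dp <- simulateDepth(reg, 10000, 0, seed = 2)
    cfg <- simConfig(baseRate = 1e-6, geneSelection = c(TP53 = 1))
    subj <- data.frame(subject_id = "S", age_years = 60, carrier = FALSE,
                       chemo = FALSE, tissue_category = "blood")
    v <- simulateSampleVariants(subj, gm, dp, cfg, seed = 3)
    sc <- enumerateSiteCounts(cdsSequence(gm$TP53))
    fN <- sc@nSites / (sc@nSites + sc@sSites)
    coding <- v[v$consequence %in%
                c("synonymous", "missense", "nonsense"), ]
    n <- nrow(coding)
    pHat <- mean(coding$consequence != "synonymous")
    expect_gt(n, 200)  # enough draws for the binomial check
    expect_lt(abs(pHat - fN), 3 * sqrt(fN * (1 - fN) / n))
})

test_that("expected counts follow rate x age x duplex nucleotides", {
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 48000))
    gm <- makeGeneModels()["DNMT3A"]  # not on chr1: panel is non-coding
    subj <- data.frame(subject_id = "S", age_years = 50, carrier = FALSE,
                       chemo = FALSE, tissue_category = "blood")
    cfg <- simConfig(baseRate = 1e-8)
    dp <- simulateDepth(reg, 15000, 0, seed = 5)
    counts <- vapply(1:25, function(s)
        nrow(simulateSampleVariants(subj, gm, dp, cfg, seed = s)),
        numeric(1))
    # lambda = 1e-8 * 50 * 48000 * 15000 = 360
    expect_lt(abs(mean(counts) - 360), 3 * sqrt(360))
    # linear scaling: double the rate, double the mean
    cfg2 <- simConfig(baseRate = 2e-8)
    counts2 <- vapply(1:25, function(s)
        nrow(simulateSampleVariants(subj, gm, dp, cfg2, seed = s)),
        numeric(1))
    expect_lt(abs(mean(counts2) - 720), 3 * sqrt(720))
})

test_that("clone sizes are geometric and mostly singletons", {
    co <- sharedCohort()
    som <- cohortCalls(co)
    som <- som[som$truth == "somatic", ]
    expect_gt(mean(som$alt_duplex_reads == 1), 0.7)
    p <- co@config@cloneSizeGeomP
    expect_lt(abs(mean(som$alt_duplex_reads) - 1 / p),
              3 * sqrt((1 - p) / p^2 / nrow(som)))
})

test_that("read observations obey the phase window and bias", {
    site <- germlineSite()
    base <- makeCall("LFS02", chrom = "chr17", ref = "G", alt = "A")
    near <- base; near$pos <- site@pos - 40L
    far <- base; far$pos <- site@pos + 151L
    calls <- rbind(near, far)
    rd <- simulateReadObservations(calls, site, phaseBias = 1, seed = 2)
    ph <- phaseVariants(calls, rd, site)
    expect_equal(ph$phase[ph$pos == near$pos], "noncarrier_copy")
    # 151 nt away: not a candidate, and its reads never span the site
    expect_false(far$pos %in% ph$pos)
    farReads <- rd[rd$variant_pos == far$pos, ]
    expect_true(all(is.na(farReads$base_at_germline)))
    rd2 <- simulateReadObservations(calls, site, phaseBias = 1, seed = 2)
    expect_identical(rd, rd2)
})

test_that("phase truth labels match what phasing recovers", {
    co <- sharedCohort()
    reads <- cohortReads(co)
    truth <- attr(reads, "phase_truth")
    som <- cohortCalls(co)
    som <- som[som$truth == "somatic", ]
    ph <- phaseVariants(som[som$sample_id %in% c("LFS01", "LFS02", "LFS03"), ],
                        reads)
    ph$key <- sprintf("%s:%d:%s>%s", ph$chrom, ph$pos, ph$ref, ph$alt)
    m <- merge(ph, truth, by = c("key", "sample_id"))
    expect_gt(nrow(m), 0)
    expect_true(all(m$phase.x == m$phase.y))
})

test_that("confounder injection matches its specification", {
    co <- sharedCohort()
    calls <- cohortCalls(co)
    spec <- co@config@artifactSpec
    art <- calls[calls$truth == "artifact", ]
    keys <- split(art, variantKey(art))
    expect_length(keys, spec$n_artifacts)
    for (k in keys) {
        expect_gte(length(unique(k$sample_id)), spec$n_samples_shared)
        expect_true(all(k$mismatch_annotation >= 8))
    }
    germ <- calls[calls$truth == "germline", ]
    gkeys <- split(germ, variantKey(germ))
    highVaf <- vapply(gkeys, function(g) any(g$vaf > 0.3), logical(1))
    expect_true(all(highVaf))
    # every record is labelled
    expect_true(all(calls$truth %in% c("somatic", "artifact", "germline")))
})

test_that("a fixed seed reproduces the cohort bit for bit", {
    cfg <- simConfig(seed = 77L,
                     subjects = defaultSubjects()[c(2, 5, 8, 9), ],
                     panels = data.frame(label = "TP53",
                                         mean_depth = 8000,
                                         dispersion = 0.05))
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(cohortCalls(a), cohortCalls(b))
    expect_identical(cohortReads(a), cohortReads(b))
    expect_identical(lapply(cohortDepth(a), function(d) d@depth),
                     lapply(cohortDepth(b), function(d) d@depth))
})
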