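# Read-backed phasing, the exact binomial phase test, domain enrichment,
# hotspot recurrence and cross-sample sharing.

.site <- function() germlineSite(chrom = "chrP", pos = 5000L, ref = "C",
                                 alt = "T")

.read <- function(sample = "S1", vpos, vref = "G", valt = "A", bVar = "A",
                  bGerm = "C", lo = 4900L, hi = 5100L, id = "r1") {
    data.frame(read_id = id, sample_id = sample, chrom = "chrP",
               start = lo, end = hi, variant_pos = as.integer(vpos),
               variant_ref = vref, variant_alt = valt,
               base_at_variant = bVar, base_at_germline = bGerm,
               stringsAsFactors = FALSE)
}

test_that("phasing follows the germline-site base of informative reads", {
    site <- .site()
    call <- makeCall(chrom = "chrP", pos = 4950, ref = "G", alt = "A")
    # alt-carrying read with the carrier base at the site
    ph <- phaseVariants(call, .read(vpos = 4950, bGerm = "T"), site)
    expect_equal(ph$phase, "carrier_copy")
    expect_equal(ph$n_informative_reads, 1L)
    ph2 <- phaseVariants(call, .read(vpos = 4950, bGerm = "C"), site)
    expect_equal(ph2$phase, "noncarrier_copy")
    # no informative read: unphased
    none <- .read(vpos = 4950, bGerm = NA_character_, hi = 4990L)
    expect_equal(phaseVariants(call, none, site)$phase, "unphased")
    # reference-carrying reads are not informative
    refOnly <- .read(vpos = 4950, bVar = "G", bGerm = "T")
    expect_equal(phaseVariants(call, refOnly, site)$phase, "unphased")
    # disagreeing informative reads surface as conflict
    two <- rbind(.read(vpos = 4950, bGerm = "T", id = "a"),
                 .read(vpos = 4950, bGerm = "C", id = "b"))
    expect_equal(phaseVariants(call, two, site)$phase, "conflict")
    # distance gate: 151 nt away is not a candidate
    farCall <- makeCall(chrom = "chrP", pos = 5151, ref = "G", alt = "A")
    farRead <- .read(vpos = 5151, lo = 5101L, hi = 5250L,
                     bGerm = NA_character_)
    expect_equal(nrow(phaseVariants(farCall, farRead, site)), 0)
})

test_that("phase states partition the candidates", {
    site <- .site()
    calls <- do.call(rbind, lapply(c(4950, 4960, 4970, 4980),
        function(p) makeCall(chrom = "chrP", pos = p, ref = "G",
                             alt = "A")))
    reads <- rbind(.read(vpos = 4950, bGerm = "T", id = "a"),
                   .read(vpos = 4960, bGerm = "C", id = "b"),
                   .read(vpos = 4970, bGerm = "T", id = "c"),
                   .read(vpos = 4970, bGerm = "C", id = "d"))
    ph <- phaseVariants(calls, reads, site)
    expect_equal(sort(ph$phase), sort(c("carrier_copy", "noncarrier_copy",
                                        "conflict", "unphased")))
})

test_that("malformed read observations are rejected", {
    site <- .site()
    call <- makeCall(chrom = "chrP", pos = 4950, ref = "G", alt = "A")
    bad <- .read(vpos = 4950, bGerm = "C", hi = 4990L)  # span misses site
    expect_error(phaseVariants(call, bad, site), "uncovered position")
})

test_that("exact binomial phase test matches the closed-form tail", {
    p <- phaseBinomialTest(25, 29)
    expect_equal(round(p, 4), 1e-4)
    # independent route: two-sided tail sum at p = 0.5
    oracle <- 2 * sum(stats::dbinom(25:29, 29, 0.5))
    expect_equal(p, oracle, tolerance = 1e-12)
    expect_equal(phaseBinomialTest(29, 29), 2 / 2^29, tolerance = 1e-12)
    expect_gte(phaseBinomialTest(15, 29), 0.85)
    # null symmetry
    for (n in c(10, 29)) for (k in 0:n)
        expect_equal(phaseBinomialTest(k, n), phaseBinomialTest(n - k, n))
    expect_error(phaseBinomialTest(3, 0), "no phased")
    expect_error(phaseBinomialTest(30, 29), "between")
})

test_that("phase-bias recovery averages to the configured bias", {
    site <- germlineSite()
    calls <- do.call(rbind, lapply(seq_len(29), function(i)
        makeCall("LFS01", chrom = "chr17", pos = site@pos - 75L + 5L * i,
                 ref = "G", alt = "A", reads = 2)))
    counts <- vapply(1:100, function(s) {
        rd <- simulateReadObservations(calls, site, phaseBias = 25 / 29,
                                       seed = s)
        ph <- phaseVariants(calls, rd, site)
        sum(ph$phase == "noncarrier_copy")
    }, numeric(1))
    sd1 <- sqrt(29 * (25 / 29) * (4 / 29))
    expect_lt(abs(mean(counts) - 25), 3 * sd1)
    expect_true(all(counts <= 29))
})

test_that("domain enrichment matches the exact binomial oracle", {
    gm <- makeGeneModels()$TP53  # DBD residues 102-282 of 394 codons
    expProp <- 3 * 181 / 1182
    # all 20 SNVs inside the domain
    pos <- DuplexSelect:::genomicPos(gm, 3L * (150:169) + 1L)
    snvs <- do.call(rbind, lapply(seq_along(pos), function(i)
        makeCall("S1", chrom = "chr17", pos = pos[i], ref = "G",
                 alt = "A")))
    r <- dbdEnrichment(snvs, gm)
    expect_equal(r$expected_prop, expProp)
    expect_equal(r$observed_prop, 1)
    oracle <- stats::binom.test(20, 20, expProp)$p.value
    expect_equal(r$p_value, oracle)
    # null-consistent observation is not significant
    inD <- round(expProp * 20)
    posMix <- DuplexSelect:::genomicPos(gm,
        3L * c(110:(110 + inD - 1), 20:(20 + (20 - inD) - 1)) + 1L)
    mix <- do.call(rbind, lapply(posMix, function(p)
        makeCall("S1", chrom = "chr17", pos = p, ref = "G", alt = "A")))
    expect_gte(dbdEnrichment(mix, gm)$p_value, 0.5)
    expect_error(dbdEnrichment(snvs[0, ], gm), "no SNVs")
})

test_that("hotspot recurrence pools samples at the codon level", {
    gm <- makeGeneModels()$TP53
    # codon 248 is CGG; R248Q via middle-base G>A (coding), R248W via
    # first-base C>T; genomic bases are complements on the minus strand
    p1 <- DuplexSelect:::genomicPos(gm, 742L)  # codon 248 middle base
    p0 <- DuplexSelect:::genomicPos(gm, 741L)  # codon 248 first base
    calls <- bindCalls(
        makeCall("S1", chrom = "chr17", pos = p1, ref = "C", alt = "T"),
        makeCall("S2", chrom = "chr17", pos = p1, ref = "C", alt = "T"),
        makeCall("S3", chrom = "chr17", pos = p0, ref = "G", alt = "A"))
    r <- hotspotRecurrence(calls, gm)
    expect_equal(r$codon[1], 248L)
    expect_equal(r$n_samples[1], 3L)
    expect_equal(r$substitutions[1], "R248Q,R248W")
    # one sample with two distinct calls at a codon counts once
    dup <- bindCalls(
        makeCall("S1", chrom = "chr17", pos = p1, ref = "C", alt = "T"),
        makeCall("S1", chrom = "chr17", pos = p0, ref = "G", alt = "A"))
    expect_equal(hotspotRecurrence(dup, gm)$n_samples, 1L)
    empty <- hotspotRecurrence(makeCall()[0, ], gm)
    expect_equal(nrow(empty), 0)
})

test_that("cross-sample sharing is symmetric with key counts on the diagonal", {
    a <- bindCalls(makeCall("A", pos = 1), makeCall("A", pos = 2))
    b <- bindCalls(makeCall("B", pos = 3), makeCall("B", pos = 4))
    m <- crossSampleSharing(rbind(a, b))
    expect_equal(unname(diag(m)), c(2L, 2L))
    expect_equal(m["A", "B"], 0L)
    same <- rbind(a, within(a, sample_id <- "B"))
    m2 <- crossSampleSharing(same)
    expect_true(all(m2 == 2L))
    expect_identical(m2, t(m2))
})
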