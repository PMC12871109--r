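# Mutation frequency / burden arithmetic, LOH flags, tallies and the
# covariate regressions.

test_that("mutation frequency counts unique keys per duplex nucleotide", {
    reg <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 20000))
    dp <- depthProfile(reg, 5000L)  # 1e8 duplex nt
    calls <- do.call(rbind, lapply(1:5, function(i) makeCall(pos = i)))
    expect_equal(mutationFrequency(calls, dp), 5e-8)
    expect_equal(mutationFrequency(calls[0, ], dp), 0)
    dup <- rbind(calls, calls[1, ])
    expect_equal(mutationFrequency(dup, dp), 5e-8)
    expect_error(mutationFrequency(calls, depthProfile(reg, 0L)),
                 "zero duplex nucleotides")
})

test_that("doubling depth halves MF and leaves the numerator alone", {
    reg <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 10000))
    calls <- do.call(rbind, lapply(1:7, function(i) makeCall(pos = i)))
    mf1 <- mutationFrequency(calls, depthProfile(reg, 3000L))
    mf2 <- mutationFrequency(calls, depthProfile(reg, 6000L))
    expect_equal(mf2, mf1 / 2)
})

test_that("mutation burden weighs calls by their clone size", {
    reg <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 2000))
    dp <- depthProfile(reg, 5000L)  # 1e7 coding nt
    one <- makeCall(pos = 10, reads = 10)
    expect_equal(mutationBurden(one, dp, reg), 1e-6)
    two <- bindCalls(makeCall(pos = 10, reads = 3),
                     makeCall(pos = 11, reads = 2))
    expect_equal(mutationBurden(two, dp, reg), 5 / 1e7)
    expect_equal(mutationBurden(two[0, ], dp, reg), 0)
    # MB >= MF on the same region when every call has >= 1 read
    expect_gte(mutationBurden(two, dp, reg),
               mutationFrequency(two, dp, reg))
})

test_that("coding/non-coding ratio handles zero denominators as missing", {
    expect_equal(codingNoncodingRatio(2e-7, 1e-7), 2)
    expect_equal(codingNoncodingRatio(1e-7, 1e-7), 1)
    expect_equal(codingNoncodingRatio(0, 1e-7), 0)
    expect_warning(r <- codingNoncodingRatio(1e-7, 0), "missing")
    expect_true(is.na(r))
})

test_that("LOH flag is strict at VAF 0.5 and missing when uncovered", {
    site <- data.frame(sample_id = c("A", "B", "C", "D"),
                       duplex_depth = c(8000, 8000, 8000, 400),
                       vaf = c(0.65, 0.50, 0.49, 0.9))
    f <- germlineVafLohFlag(site, samples = c("A", "B", "C", "D", "E"))
    expect_identical(unname(f), c(TRUE, FALSE, FALSE, NA, NA))
})

test_that("variant-type tallies keep dinucleotides separate from SNVs", {
    calls <- bindCalls(
        makeCall(pos = 1), makeCall(pos = 2), makeCall(pos = 3),
        makeCall(pos = 4, ref = "CC", alt = "TT", class = "MNV"),
        makeCall(pos = 6, ref = "GG", alt = "AA", class = "MNV"))
    t <- tallyVariantTypes(calls)
    expect_equal(as.integer(t$byClass[c("SNV", "MNV")]), c(3L, 2L))
    t0 <- tallyVariantTypes(calls[0, ])
    expect_true(all(t0$byClass == 0))
    one <- makeCall(pos = 4, ref = "CC", alt = "TT", class = "MNV")
    t1 <- tallyVariantTypes(one)
    expect_equal(as.integer(t1$byClass["MNV"]), 1L)
    expect_equal(as.integer(t1$byClass["SNV"]), 0L)
})

test_that("nonsynonymous percentages round as printed", {
    carrier <- nonsynonymousPercent(c(rep("missense", 3), "nonsense",
                                      rep("synonymous", 3)))
    expect_equal(carrier$percent, 57)
    noncarrier <- nonsynonymousPercent(c(rep("missense", 16),
                                         rep("nonsense", 2),
                                         rep("splice", 2),
                                         rep("synonymous", 4)))
    expect_equal(noncarrier$percent, 83)
    expect_error(nonsynonymousPercent(character(0)), "no coding")
})

test_that("noiseless burden regressions interpolate exactly", {
    d <- data.frame(age_decades = c(2, 3, 4, 5, 6, 7),
                    LFS = c(0, 1, 0, 1, 0, 1),
                    CTx = c(0, 0, 1, 1, 0, 0))
    d$response <- 1 + 2 * d$age_decades
    fit <- suppressWarnings(fitBurdenModels(d, "multivariate"))
    expect_equal(fit$estimate[fit$term == "age_decades"], 2)
    expect_equal(fit$estimate[fit$term == "LFS"], 0)
    expect_equal(fit$estimate[fit$term == "CTx"], 0)
})

test_that("rescaling the response rescales estimates, not t-statistics", {
    set.seed(5)
    d <- data.frame(age_years = seq(25, 76, length.out = 12))
    d$response <- 1e-7 * (1 + 0.05 * d$age_years + rnorm(12, 0, 0.3))
    f1 <- fitBurdenModels(d, "univariate")
    d2 <- d; d2$response <- d$response * 1e7
    f2 <- fitBurdenModels(d2, "univariate")
    expect_equal(f2$estimate, f1$estimate * 1e7)
    expect_equal(f2$conf.low, f1$conf.low * 1e7)
    expect_equal(f2$statistic, f1$statistic)
    expect_equal(f2$p.value, f1$p.value)
})

test_that("collinear covariates raise an error", {
    d <- data.frame(age_decades = c(2, 3, 4, 5, 6, 7),
                    LFS = c(0, 1, 0, 1, 0, 1))
    d$CTx <- d$LFS
    d$response <- rnorm(6)
    expect_error(fitBurdenModels(d, "multivariate"), "collinear")
})

test_that("an uninformative covariate's interval covers zero", {
    hits <- 0L
    for (s in 1:100) {
        set.seed(s)
        n <- 40
        d <- data.frame(age_decades = runif(n, 2, 8),
                        LFS = rbinom(n, 1, 0.4),
                        CTx = rbinom(n, 1, 0.3))
        d$response <- 2 + 1.5 * d$age_decades + rnorm(n)
        fit <- fitBurdenModels(d, "multivariate")
        row <- fit[fit$term == "LFS", ]
        if (row$conf.low <= 0 && row$conf.high >= 0) hits <- hits + 1L
    }
    expect_gte(hits, 90L)
})

test_that("sample MF tracks base_rate times age across subjects", {
    co <- sharedCohort()
    cfg <- co@config
    fc <- filterCascade(cohortCalls(co), cohortMask(co))
    offMask <- GenomicRanges::setdiff(co@reference$regions,
                                      cohortMask(co))
    for (s in c("LFS02", "CON04", "CON08")) {
        age <- cfg@subjects$age_years[cfg@subjects$subject_id == s]
        kept <- fc$kept[fc$kept$sample_id == s, ]
        mf <- mutationFrequency(kept, cohortDepth(co, s), offMask)
        expected <- cfg@baseRate * age
        tot <- totalDuplexNucleotides(cohortDepth(co, s), offMask)
        se <- sqrt(expected * tot) / tot  # Poisson SE on the frequency
        expect_lt(abs(mf - expected), 3 * se)
    }
})
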