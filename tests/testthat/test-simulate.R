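.uniCfg <- function(...) {
    simulationConfig(genomeLength = 60000L, nComplete = 5L,
                     nTruncated = 1L, nSoloTir = 2L,
                     spanDistribution = list(type = "uniform",
                                             min = 1500, max = 5000),
                     ...)
}

test_that("generation is byte-identical for a fixed seed", {
    cfg <- .uniCfg(seed = 1L)
    sim1 <- generateGenome(cfg)
    sim2 <- generateGenome(cfg)
    expect_identical(as.character(simGenome(sim1)),
                     as.character(simGenome(sim2)))
    expect_identical(as.data.frame(simTruth(sim1)),
                     as.data.frame(simTruth(sim2)))
    expect_equal(sum(S4Vectors::mcols(simTruth(sim1))$type == "complete"),
                 5L)
    # a different seed changes the genome
    expect_false(identical(
        as.character(simGenome(generateGenome(.uniCfg(seed = 2L)))),
        as.character(simGenome(sim1))))
})

test_that("generator leaves the caller's RNG state untouched", {
    set.seed(123)
    before <- .Random.seed
    generateGenome(.uniCfg(seed = 4L))
    expect_identical(.Random.seed, before)
})

test_that("complete elements are flanked by identical TSD trinucleotides", {
    sim <- generateGenome(.uniCfg(seed = 8L))
    g <- as.character(simGenome(sim))[[1L]]
    tr <- simTruth(sim)
    complete <- tr[S4Vectors::mcols(tr)$type == "complete"]
    for (i in seq_along(complete)) {
        s <- BiocGenerics::start(complete)[i]
        e <- BiocGenerics::end(complete)[i]
        expect_equal(substr(g, s - 3L, s - 1L), substr(g, e + 1L, e + 3L))
        expect_equal(substr(g, s - 3L, s - 1L),
                     S4Vectors::mcols(complete)$tsd[i])
    }
})

test_that("truncated derivatives keep a partial 5' TSD and one TIR", {
    cfg <- simulationConfig(genomeLength = 50000L, nComplete = 0L,
                            nTruncated = 4L, nSoloTir = 0L,
                            spanDistribution = list(type = "uniform",
                                                    min = 2000,
                                                    max = 5000),
                            seed = 12L)
    sim <- generateGenome(cfg)
    g <- as.character(simGenome(sim))[[1L]]
    tr <- simTruth(sim)
    expect_true(all(S4Vectors::mcols(tr)$type == "truncated"))
    for (i in seq_along(tr)) {
        s <- BiocGenerics::start(tr)[i]
        e <- BiocGenerics::end(tr)[i]
        tsd <- S4Vectors::mcols(tr)$tsd[i]
        # partial TSD: last 2 of 3 bases, immediately 5' of the retained part
        expect_equal(substr(g, s - 2L, s - 1L), substr(tsd, 2L, 3L))
        expect_equal(substr(g, e + 1L, e + 3L), tsd)
        # retained portion ends with the right TIR, read inward as revcomp
        inward <- oracleRevcomp(substr(g, e - 27L, e))
        expect_equal(substr(inward, 1L, 5L), "CACTA")
        frac <- S4Vectors::mcols(tr)$retainedFraction[i]
        expect_true(frac > 0 && frac < 1)
    }
})

test_that("planted spans stay inside the configured support", {
    cfg <- simulationConfig(genomeLength = 400000L, nComplete = 30L,
                            nTruncated = 0L, nSoloTir = 0L, seed = 21L)
    tr <- simTruth(generateGenome(cfg))
    w <- IRanges::width(tr)
    expect_true(all(w >= 1000L & w <= 30000L))
    # features never overlap one another
    expect_true(all(diff(BiocGenerics::start(sort(tr))) >
                    head(w[order(BiocGenerics::start(tr))], -1L)))
})

test_that("planted TSD frequencies follow the configured distribution", {
    cfg <- simulationConfig(genomeLength = 150000L, nComplete = 0L,
                            nTruncated = 0L, nSoloTir = 1000L,
                            seed = 3L)
    tr <- simTruth(generateGenome(cfg))
    tsd <- S4Vectors::mcols(tr)$tsd
    w <- defaultTsdWeights()
    counts <- table(factor(tsd, levels = names(w)))
    n <- length(tsd)
    # joint goodness-of-fit: the 64-category spectrum is consistent with
    # the configured probabilities
    gof <- suppressWarnings(stats::chisq.test(counts, p = w))
    expect_gt(gof$p.value, 1e-3)
    # per-category deviations stay within binomial sampling error; with 64
    # categories at most one is allowed past 3 standard errors by chance
    z <- abs(as.integer(counts) - n * w) / sqrt(n * w * (1 - w))
    expect_lte(sum(z > 3), 1L)
    expect_true(all(z < 4.5))
    # AT-rich categories dominate in expectation and here empirically
    expect_gt(sum(counts[c("AAA", "ATT", "TTT", "TAA", "AAT", "TTA")]),
              sum(counts[c("GGG", "GCC", "CCC", "CGG", "GGC", "CCG")]))
})

test_that("infeasible packing is rejected up front", {
    cfg <- .uniCfg(seed = 1L)
    cfg$genomeLength <- 10000L
    expect_error(generateGenome(cfg), "infeasible packing")
})

test_that("TIR sequences failing the seed motif are rejected", {
    expect_error(simulationConfig(tirA = paste0("CCCTACTAGAAA",
                                                strrep("A", 16L))),
                 "seed motif")
})

test_that("FASTA + truth files round-trip the simulation", {
    sim <- generateGenome(.uniCfg(seed = 6L))
    fa <- withr::local_tempfile(fileext = ".fa")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeSimulation(sim, fa, tsv)
    g <- readGenome(fa)
    expect_identical(as.character(g), as.character(simGenome(sim)))
    tr <- readTruthTsv(tsv)
    expect_equal(as.data.frame(tr)[, c("start", "end")],
                 as.data.frame(simTruth(sim))[, c("start", "end")])
    expect_equal(S4Vectors::mcols(tr)$type,
                 S4Vectors::mcols(simTruth(sim))$type)
})

test_that("recovery scoring handles empty and undetectable cases", {
    sim <- generateGenome(.uniCfg(seed = 2L))
    noCalls <- callElements(findTirOccurrences(c(x = strrep("G", 100L))))
    sc <- evaluateRecovery(noCalls, simTruth(sim))
    expect_equal(sc$true_positives, 0L)
    expect_equal(sc$false_negatives, 5L)
    expect_equal(sc$recall, 0)
    expect_equal(sc$precision, 1)  # no calls made

    # matching tolerance: shifted endpoints only match when allowed
    calls <- callElements(findTirOccurrences(simGenome(sim)))
    shifted <- GenomicRanges::shift(calls, 2L)
    mcShift <- new("CactaCalls", shifted)
    expect_equal(evaluateRecovery(mcShift, simTruth(sim))$true_positives,
                 0L)
    expect_equal(evaluateRecovery(mcShift, simTruth(sim),
                                  tolerance = 2L)$true_positives,
                 length(calls))
})

test_that("recall degrades in expectation as TIR mutations accumulate", {
    recallAt <- function(rate) {
        rs <- vapply(1:20, function(s) {
            cfg <- simulationConfig(
                genomeLength = 30000L, nComplete = 3L, nTruncated = 0L,
                nSoloTir = 0L,
                spanDistribution = list(type = "uniform", min = 1200,
                                        max = 3000),
                tirMutationRate = rate, seed = s)
            sim <- generateGenome(cfg)
            calls <- callElements(findTirOccurrences(simGenome(sim)))
            evaluateRecovery(calls, simTruth(sim))$recall
        }, numeric(1L))
        mean(rs)
    }
    r0 <- recallAt(0)
    r10 <- recallAt(0.10)
    r20 <- recallAt(0.20)
    expect_equal(r0, 1)
    expect_gte(r0, r10)
    expect_gte(r10, r20)
    expect_lt(r20, 0.5)  # a 20% per-base TIR mutation load is crippling
})
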