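test_that("a perfect planted element yields exactly one forced call", {
    fx <- elementFixture(span = 2000L, tsd = "ACC")
    occ <- findTirOccurrences(c(chr1 = fx$contig))
    calls <- callElements(occ)
    expect_equal(length(calls), 1L)
    expect_equal(elementSpan(calls), 2000L)
    expect_equal(elementTsd(calls), "ACC")
    expect_equal(BiocGenerics::start(calls), fx$start)
    expect_equal(BiocGenerics::end(calls), fx$end)
    expect_equal(leftTir(calls), TIR_B_DEFAULT)
    expect_equal(rightTir(calls), TIR_A_DEFAULT)
})

test_that("TSD mismatch and out-of-window spans are filtered", {
    # right flank mutated: ACC vs ACG
    fxBad <- elementFixture(span = 2000L, tsd = "ACC", rightTsd = "ACG")
    expect_equal(length(callElements(
        findTirOccurrences(c(chr1 = fxBad$contig)))), 0L)

    fxShort <- elementFixture(span = 800L)
    expect_equal(length(callElements(
        findTirOccurrences(c(chr1 = fxShort$contig)))), 0L)

    # same fixture passes once the window is relaxed to include it
    occ <- findTirOccurrences(c(chr1 = fxShort$contig))
    expect_equal(length(callElements(occ, minSpan = 100L)), 1L)
})

test_that("policy = all equals the exhaustive pair oracle", {
    set.seed(20)
    for (rep in 1:5) {
        # 4 left + 4 right TIRs at randomized positions, shared TSD pool
        pieces <- character(0)
        tsdPool <- c("ACC", "TAA")
        for (i in 1:4) {
            pieces <- c(pieces,
                randomDnaStr(sample(200:900, 1L)),
                paste0(sample(tsdPool, 1L), TIR_B_DEFAULT),
                randomDnaStr(sample(200:900, 1L)),
                paste0(oracleRevcomp(TIR_A_DEFAULT), sample(tsdPool, 1L)))
        }
        contig <- paste0(paste(pieces, collapse = ""),
                         randomDnaStr(300L))
        occ <- findTirOccurrences(c(chr1 = contig))
        got <- callsAsPairFrame(
            callElements(occ, minSpan = 100L, maxSpan = 5000L,
                         policy = "all"))
        want <- oraclePairs(occ, minSpan = 100L, maxSpan = 5000L)
        expect_equal(got, want, info = paste("rep", rep))
    }
})

test_that("nearest and innermost are single-use subsets of all", {
    set.seed(33)
    pieces <- character(0)
    for (i in 1:5) {
        pieces <- c(pieces,
            randomDnaStr(sample(100:400, 1L)),
            paste0("ACC", TIR_B_DEFAULT),
            randomDnaStr(sample(100:400, 1L)),
            paste0(oracleRevcomp(TIR_A_DEFAULT), "ACC"))
    }
    contig <- paste0(paste(pieces, collapse = ""), randomDnaStr(200L))
    occ <- findTirOccurrences(c(chr1 = contig))
    all <- callsAsPairFrame(callElements(occ, minSpan = 100L,
                                         maxSpan = 10000L, policy = "all"))
    for (pol in c("nearest", "innermost")) {
        sub <- callsAsPairFrame(callElements(occ, minSpan = 100L,
                                             maxSpan = 10000L,
                                             policy = pol))
        key <- function(d) paste(d$contig, d$start, d$end)
        expect_true(all(key(sub) %in% key(all)), info = pol)
        # single use: no occurrence terminus appears twice
        expect_equal(anyDuplicated(sub$start), 0L, info = pol)
        expect_equal(anyDuplicated(sub$end), 0L, info = pol)
    }
})

test_that("calling is idempotent and invariant to occurrence order", {
    fxA <- elementFixture(span = 1500L, tsd = "ACC")
    fxB <- elementFixture(span = 2500L, tsd = "TTA",
                          flankL = strrep("C", 25L))
    genome <- c(chr1 = fxA$contig, chr2 = fxB$contig)
    occ <- findTirOccurrences(genome)
    calls <- callElements(occ)
    set.seed(9)
    shuffled <- occ[sample(seq_along(occ))]
    expect_identical(callsAsTable(callElements(shuffled)),
                     callsAsTable(calls))
    expect_identical(callsAsTable(callElements(occ)),
                     callsAsTable(calls))
    # no cross-contig pairing ever
    expect_equal(sort(as.character(GenomeInfoDb::seqnames(calls))),
                 c("chr1", "chr2"))
})

test_that("strict TIR-identity mode drops imperfect pairs only", {
    fxImp <- elementFixture(span = 1500L)  # B/A pair: imperfect
    fxId <- elementFixture(span = 1500L, leftTirSeq = TIR_A_DEFAULT,
                           rightTirSeq = TIR_A_DEFAULT)
    occImp <- findTirOccurrences(c(c1 = fxImp$contig))
    occId <- findTirOccurrences(c(c1 = fxId$contig))
    expect_equal(length(callElements(occImp)), 1L)
    expect_equal(length(callElements(occImp,
                                     requireIdenticalTir = TRUE)), 0L)
    expect_equal(length(callElements(occId,
                                     requireIdenticalTir = TRUE)), 1L)
})

test_that("element statistics match direct arithmetic", {
    spans <- c(2000L, 3000L, 10000L)
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(
        start = c(1, 5001, 10001), width = spans))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        span = spans, tsd = rep("ACC", 3),
        leftTir = rep(TIR_B_DEFAULT, 3), rightTir = rep(TIR_A_DEFAULT, 3),
        leftSeedVariant = rep("C", 3), rightSeedVariant = rep("A", 3))
    st <- summarizeElements(new("CactaCalls", gr))
    expect_equal(st$n_elements, 3L)
    expect_equal(st$total_length, 15000L)
    expect_equal(st$mean_length, 5000)
    expect_equal(st$median_length, 3000)

    empty <- callElements(findTirOccurrences(c(x = strrep("A", 100L))))
    expect_equal(unlist(summarizeElements(empty)),
                 c(n_elements = 0, total_length = 0, mean_length = 0,
                   median_length = 0))

    # even count: median is the midpoint of the two central spans
    spans4 <- c(spans, 5000L)
    gr4 <- GenomicRanges::GRanges("c", IRanges::IRanges(
        start = c(1, 5001, 20001, 40001), width = spans4))
    S4Vectors::mcols(gr4) <- S4Vectors::DataFrame(
        span = spans4, tsd = rep("ACC", 4),
        leftTir = rep(TIR_B_DEFAULT, 4), rightTir = rep(TIR_A_DEFAULT, 4),
        leftSeedVariant = rep("C", 4), rightSeedVariant = rep("A", 4))
    expect_equal(summarizeElements(new("CactaCalls", gr4))$median_length,
                 4000)
})

test_that("summary stats agree with recomputation from the emitted TSV", {
    cfg <- simulationConfig(genomeLength = 120000L, nComplete = 12L,
                            nTruncated = 0L, nSoloTir = 0L,
                            spanDistribution = list(type = "uniform",
                                                    min = 1500,
                                                    max = 5000),
                            seed = 17L)
    sim <- generateGenome(cfg)
    calls <- callElements(findTirOccurrences(simGenome(sim)))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeCalls(calls, tsv, format = "tsv")
    fromFile <- read.table(tsv, sep = "\t", header = TRUE)
    st <- summarizeElements(calls)
    expect_equal(st$n_elements, nrow(fromFile))
    expect_equal(st$total_length, sum(fromFile$span))
    expect_equal(st$mean_length, mean(fromFile$span))
    expect_equal(st$median_length, median(fromFile$span))
})
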