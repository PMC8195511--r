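#' Default 28-nt TIR sequences for simulation
#'
#' Two inward-read 28-mers whose first 12 nt match [CACTA_SEED_MOTIF]; they
#' differ at seed position 8 (the A-type/B-type discriminator) and at two
#' downstream bases, mirroring an imperfect natural TIR pair. The full
#' 28-nt TIRs of any real family are configuration, not fixed constants.
#'
#' @name tirDefaults
#' @export
TIR_A_DEFAULT <- "CACTACTAGAAACGGTTGCAAGTCGTAC"

#' @rdname tirDefaults
#' @export
TIR_B_DEFAULT <- "CACTACTCGAAACGGTTGCAAGTCGACT"

#' AT-rich default TSD trinucleotide distribution
#'
#' Probabilities over the 64 trinucleotides built from independent per-base
#' probabilities A = T = 0.3, C = G = 0.2, so AT-rich trinucleotides are
#' the most likely while every category has positive mass — the qualitative
#' structure reported for natural CACTA target sites.
#'
#' @return A named numeric vector of 64 probabilities summing to 1.
#' @export
defaultTsdWeights <- function() {
    p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    tri <- .allTrinucleotides()
    w <- vapply(strsplit(tri, ""), function(b) prod(p[b]), numeric(1L))
    stats::setNames(w / sum(w), tri)
}

#' Configuration for the synthetic-genome generator
#'
#' @param genomeLength total genome length in nt.
#' @param gcContent background GC fraction.
#' @param nComplete,nTruncated,nSoloTir numbers of planted complete
#'   elements, one-TIR truncated derivatives, and solo TIRs.
#' @param spanDistribution TIR-inclusive span distribution for complete
#'   elements: `list(type = "lognormal", median, sigma, min, max)`
#'   (truncated lognormal; the default median 5600 nt with sigma 0.62
#'   reproduces a mean/median ratio near the one reported for a natural
#'   element family) or `list(type = "uniform", min, max)`.
#' @param tsdWeights named probability vector over the 64 trinucleotides.
#' @param tirA,tirB inward-read TIR 28-mers; their first 12 nt must match
#'   [CACTA_SEED_MOTIF]. `tirB` is planted at element starts (left/5' TIR)
#'   and `tirA` at element ends, matching the observed 5'-B/3'-A layout.
#' @param tirMutationRate per-base substitution probability applied
#'   independently to every planted TIR copy.
#' @param truncatedTsdKeep how many 3'-most bases of the 5' TSD copy a
#'   truncated derivative retains (default 2, the observed partial-TSD
#'   geometry).
#' @param truncatedFractionRange range of the element fraction (from the 3'
#'   end) retained by truncated derivatives.
#' @param scrubBackground remove accidental seed-motif matches from random
#'   background/filler sequence so planted TIRs are the only motif hits at
#'   zero mismatches (default `TRUE`; see the package vignette).
#' @param contigName name of the single simulated contig.
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the configuration.
#' @return A validated configuration list for [generateGenome()].
#' @export
simulationConfig <- function(genomeLength = 300000L,
                             gcContent = 0.4,
                             nComplete = 20L,
                             nTruncated = 3L,
                             nSoloTir = 5L,
                             spanDistribution = list(type = "lognormal",
                                                     median = 5600,
                                                     sigma = 0.62,
                                                     min = 1000,
                                                     max = 30000),
                             tsdWeights = defaultTsdWeights(),
                             tirA = TIR_A_DEFAULT,
                             tirB = TIR_B_DEFAULT,
                             tirMutationRate = 0,
                             truncatedTsdKeep = 2L,
                             truncatedFractionRange = c(0.2, 0.6),
                             scrubBackground = TRUE,
                             contigName = "synth1",
                             seed = 1L) {
    stopifnot(genomeLength > 0, gcContent >= 0, gcContent <= 1,
              nComplete >= 0, nTruncated >= 0, nSoloTir >= 0,
              tirMutationRate >= 0, tirMutationRate <= 1,
              truncatedTsdKeep >= 0, truncatedTsdKeep <= 3)
    for (tir in c(tirA, tirB)) {
        .checkDnaAlphabet(tir, "TIR")
        if (.countMismatches(substr(tir, 1L, nchar(CACTA_SEED_MOTIF)),
                             CACTA_SEED_MOTIF) != 0L)
            stop("TIR does not match the seed motif at its 5' end: ", tir)
    }
    if (nchar(tirA) != nchar(tirB))
        stop("tirA and tirB must have equal length")
    if (abs(sum(tsdWeights) - 1) > 1e-8 || any(tsdWeights < 0))
        stop("tsdWeights must be a probability vector")
    if (!setequal(names(tsdWeights), .allTrinucleotides()))
        stop("tsdWeights must cover the 64 trinucleotides")
    if (!spanDistribution$type %in% c("lognormal", "uniform"))
        stop("spanDistribution$type must be 'lognormal' or 'uniform'")
    list(genomeLength = as.integer(genomeLength), gcContent = gcContent,
         nComplete = as.integer(nComplete),
         nTruncated = as.integer(nTruncated),
         nSoloTir = as.integer(nSoloTir),
         spanDistribution = spanDistribution,
         tsdWeights = tsdWeights, tirA = tirA, tirB = tirB,
         tirMutationRate = tirMutationRate,
         truncatedTsdKeep = as.integer(truncatedTsdKeep),
         truncatedFractionRange = truncatedFractionRange,
         scrubBackground = isTRUE(scrubBackground),
         contigName = contigName, seed = as.integer(seed))
}

#' Generate a synthetic genome with planted CACTA-like elements
#'
#' Builds an i.i.d. background at the configured GC content and plants
#' three feature types at non-overlapping positions:
#'
#' * complete elements: `TSD + [tirB + filler + revcomp(tirA)] + TSD`,
#'   i.e. two inward-facing TIRs bracketed by identical TSD copies;
#' * truncated derivatives: `partial TSD + 3' portion of an element
#'   (right TIR only) + TSD` — the one-TIR geometry that pair-calling
#'   cannot detect;
#' * solo TIRs: a single TIR with one TSD copy.
#'
#' Planted TIR copies are mutated independently at `tirMutationRate`.
#' Generation is deterministic for a fixed configuration (including seed),
#' and the caller's RNG state is left untouched.
#'
#' @param config a [simulationConfig()] list.
#' @return A [CactaSimulation-class] holding the genome, the ground-truth
#'   `GRanges` (TIR-inclusive intervals for complete elements,
#'   retained-portion intervals for truncated ones), and `config`.
#' @importFrom stats runif rlnorm
#' @export
generateGenome <- function(config) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(config$seed)

    feats <- .buildFeatures(config)
    insLen <- vapply(feats, function(f) nchar(f$insert), integer(1L))
    minGap <- 100L
    nFeat <- length(feats)
    bgLen <- config$genomeLength - sum(insLen)
    if (bgLen < (nFeat + 1L) * minGap)
        stop("infeasible packing: planted footprint ", sum(insLen),
             " nt leaves too little background in ", config$genomeLength,
             " nt")
    gaps <- .drawGaps(nFeat + 1L, bgLen, minGap)
    ord <- sample.int(nFeat)
    feats <- feats[ord]

    pieces <- character(2L * nFeat + 1L)
    truthRows <- vector("list", nFeat)
    pos <- 0L
    for (i in seq_len(nFeat + 1L)) {
        pieces[2L * i - 1L] <- .randomDna(gaps[i], config$gcContent)
        pos <- pos + gaps[i]
        if (i <= nFeat) {
            f <- feats[[i]]
            pieces[2L * i] <- f$insert
            truthRows[[i]] <- data.frame(
                start = pos + f$featOffset + 1L,
                end = pos + f$featOffset + f$featLen,
                featureId = f$id, type = f$type, tsd = f$tsd,
                retainedFraction = f$retainedFraction,
                stringsAsFactors = FALSE)
            pos <- pos + nchar(f$insert)
        }
    }
    genomeSeq <- paste0(pieces, collapse = "")
    truth <- do.call(rbind, truthRows)
    if (is.null(truth))
        truth <- data.frame(start = integer(0), end = integer(0),
                            featureId = character(0), type = character(0),
                            tsd = character(0),
                            retainedFraction = numeric(0))
    truth <- truth[order(truth$start), , drop = FALSE]

    if (config$scrubBackground && nFeat > 0L)
        genomeSeq <- .scrubSpuriousSeeds(genomeSeq, truth, config)

    genome <- Biostrings::DNAStringSet(
        stats::setNames(genomeSeq, config$contigName))
    gr <- GRanges(config$contigName,
                  IRanges::IRanges(truth$start, truth$end))
    mcols(gr) <- DataFrame(featureId = truth$featureId, type = truth$type,
                           tsd = truth$tsd,
                           retainedFraction = truth$retainedFraction)
    new("CactaSimulation", genome = genome, truth = gr, config = config)
}

.randomDna <- function(n, gc) {
    if (n <= 0L) return("")
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
           collapse = "")
}

.drawGaps <- function(k, total, minGap) {
    slack <- total - k * minGap
    cuts <- sort(stats::runif(k - 1L, 0, slack))
    extras <- diff(c(0, cuts, slack))
    gaps <- minGap + floor(extras)
    gaps[k] <- gaps[k] + (total - sum(gaps))
    as.integer(gaps)
}

.mutateTir <- function(tir, rate) {
    if (rate <= 0) return(tir)
    bases <- strsplit(tir, "")[[1L]]
    hit <- stats::runif(length(bases)) < rate
    for (i in which(hit))
        bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
    paste0(bases, collapse = "")
}

.drawSpans <- function(n, dist) {
    if (n == 0L) return(integer(0))
    if (dist$type == "uniform")
        return(as.integer(round(stats::runif(n, dist$min, dist$max))))
    out <- integer(0)
    while (length(out) < n) {
        s <- as.integer(round(stats::rlnorm(n, log(dist$median),
                                            dist$sigma)))
        out <- c(out, s[s >= dist$min & s <= dist$max])
    }
    out[seq_len(n)]
}

.buildFeatures <- function(config) {
    tirLen <- nchar(config$tirA)
    tsdLen <- 3L
    feats <- list()
    idx <- 0L
    mkId <- function(type) {
        idx <<- idx + 1L
        sprintf("%s_%03d", type, idx)
    }
    buildElement <- function(span) {
        left <- .mutateTir(config$tirB, config$tirMutationRate)
        right <- .mutateTir(config$tirA, config$tirMutationRate)
        filler <- .randomDna(span - 2L * tirLen, config$gcContent)
        paste0(left, filler, .revcomp(right))
    }
    spans <- .drawSpans(config$nComplete, config$spanDistribution)
    for (s in spans) {
        tsd <- sample(names(config$tsdWeights), 1L,
                      prob = config$tsdWeights)
        feats[[length(feats) + 1L]] <- list(
            id = mkId("complete"), type = "complete", tsd = tsd,
            insert = paste0(tsd, buildElement(s), tsd),
            featOffset = tsdLen, featLen = s, retainedFraction = NA_real_)
    }
    truncSpans <- .drawSpans(config$nTruncated, config$spanDistribution)
    for (s in truncSpans) {
        tsd <- sample(names(config$tsdWeights), 1L,
                      prob = config$tsdWeights)
        frac <- stats::runif(1L, config$truncatedFractionRange[1L],
                             config$truncatedFractionRange[2L])
        r <- as.integer(round(frac * s))
        r <- max(r, tirLen + 10L)          # must keep the whole right TIR
        r <- min(r, s - tirLen - 10L)      # must drop the whole left TIR
        elem <- buildElement(s)
        retained <- substr(elem, s - r + 1L, s)
        keep <- config$truncatedTsdKeep
        partial <- if (keep > 0L) substr(tsd, tsdLen - keep + 1L, tsdLen)
                   else ""
        feats[[length(feats) + 1L]] <- list(
            id = mkId("truncated"), type = "truncated", tsd = tsd,
            insert = paste0(partial, retained, tsd),
            featOffset = keep, featLen = r, retainedFraction = r / s)
    }
    for (i in seq_len(config$nSoloTir)) {
        tsd <- sample(names(config$tsdWeights), 1L,
                      prob = config$tsdWeights)
        tir <- .mutateTir(sample(c(config$tirA, config$tirB), 1L),
                          config$tirMutationRate)
        asLeft <- stats::runif(1L) < 0.5
        insert <- if (asLeft) paste0(tsd, tir)
                  else paste0(.revcomp(tir), tsd)
        feats[[length(feats) + 1L]] <- list(
            id = mkId("solo_tir"), type = "solo_tir", tsd = tsd,
            insert = insert,
            featOffset = if (asLeft) tsdLen else 0L,
            featLen = tirLen, retainedFraction = NA_real_)
    }
    feats
}

# Remove seed-motif matches arising by chance in random background/filler:
# any zero-mismatch hit whose footprint is not a planted TIR terminus gets
# one base (outside planted TIR/TSD intervals) re-drawn. Keeps the planted
# features the only exact motif hits, so ground truth is complete.
.scrubSpuriousSeeds <- function(genomeSeq, truth, config) {
    k <- nchar(CACTA_SEED_MOTIF)
    tirLen <- nchar(config$tirA)
    tsdLen <- 3L
    planted <- .plantedSeedStarts(truth, k, tirLen)
    protect <- .protectedPositions(truth, tirLen, tsdLen,
                                   nchar(genomeSeq))
    for (iter in 1:10) {
        hits <- scanSeeds(c(g = genomeSeq), maxMismatches = 0L)
        key <- paste(BiocGenerics::start(hits),
                     as.character(BiocGenerics::strand(hits)))
        spurious <- hits[!key %in% planted]
        if (!length(spurious)) break
        bases <- strsplit(genomeSeq, "")[[1L]]
        for (i in seq_along(spurious)) {
            fp <- BiocGenerics::start(spurious)[i]:
                BiocGenerics::end(spurious)[i]
            free <- setdiff(fp, protect)
            if (!length(free)) next  # inside a planted feature; leave it
            j <- free[ceiling(length(free) / 2)]
            bases[j] <- sample(setdiff(c("A", "C", "G", "T"), bases[j]), 1L)
        }
        genomeSeq <- paste0(bases, collapse = "")
    }
    genomeSeq
}

.plantedSeedStarts <- function(truth, k, tirLen) {
    out <- character(0)
    for (r in seq_len(nrow(truth))) {
        s <- truth$start[r]; e <- truth$end[r]
        type <- truth$type[r]
        if (type == "complete")
            out <- c(out, paste(s, "+"), paste(e - k + 1L, "-"))
        else if (type == "truncated")
            out <- c(out, paste(e - k + 1L, "-"))
        else  # solo: orientation unknown; protect both readings
            out <- c(out, paste(s, "+"), paste(e - k + 1L, "-"))
    }
    out
}

.protectedPositions <- function(truth, tirLen, tsdLen, L) {
    pos <- integer(0)
    for (r in seq_len(nrow(truth))) {
        s <- truth$start[r]; e <- truth$end[r]
        lo <- max(1L, s - tsdLen)
        hi <- min(L, e + tsdLen)
        pos <- c(pos, lo:min(hi, s + tirLen - 1L),
                 max(lo, e - tirLen + 1L):hi)
    }
    unique(pos)
}

#' Write a simulation to FASTA plus a ground-truth table
#'
#' @param sim a [CactaSimulation-class].
#' @param fastaPath output FASTA for the genome.
#' @param truthPath output TSV for the truth set (1-based inclusive
#'   coordinates).
#' @return Invisibly, `c(fastaPath, truthPath)`.
#' @export
writeSimulation <- function(sim, fastaPath, truthPath) {
    stopifnot(is(sim, "CactaSimulation"))
    writeGenome(simGenome(sim), fastaPath)
    tr <- simTruth(sim)
    df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(tr)),
                     start = BiocGenerics::start(tr),
                     end = BiocGenerics::end(tr),
                     feature_id = mcols(tr)$featureId,
                     type = mcols(tr)$type,
                     tsd = mcols(tr)$tsd,
                     retained_fraction = mcols(tr)$retainedFraction,
                     stringsAsFactors = FALSE)
    utils::write.table(df, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(fastaPath, truthPath))
}

#' Read a ground-truth table written by [writeSimulation()]
#'
#' @param path truth TSV path.
#' @return A `GRanges` with the truth metadata columns.
#' @export
readTruthTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(contig = "character",
                                           feature_id = "character",
                                           type = "character",
                                           tsd = "character"),
                            stringsAsFactors = FALSE)
    gr <- GRanges(df$contig, IRanges::IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(featureId = df$feature_id, type = df$type,
                           tsd = df$tsd,
                           retainedFraction = df$retained_fraction)
    gr
}

#' Score element calls against a simulation's ground truth
#'
#' A call matches a `complete` truth feature when both endpoints agree
#' within `tolerance` nt; matching is one-to-one and greedy by coordinate.
#' Truncated and solo-TIR features are not matchable by pair-calling (they
#' have a single TIR), so calls overlapping them still count as false
#' positives and they never contribute false negatives.
#'
#' @param calls a [CactaCalls-class] object.
#' @param truth a truth `GRanges` (from [simTruth()] or [readTruthTsv()]).
#' @param tolerance endpoint tolerance in nt (default 0).
#' @return A list with counts `true_positives`, `false_positives`,
#'   `false_negatives` and rates `precision`, `recall`, `f1`
#'   (`matching_tolerance` echoes the input). Precision is 1 when no calls
#'   were made; recall is 1 when there are no matchable truth features.
#' @export
evaluateRecovery <- function(calls, truth, tolerance = 0L) {
    stopifnot(is(calls, "CactaCalls"))
    matchable <- truth[mcols(truth)$type == "complete"]
    usedT <- logical(length(matchable))
    tp <- 0L
    if (length(calls) && length(matchable)) {
        o <- order(BiocGenerics::start(calls))
        for (ci in o) {
            sameContig <- as.character(GenomeInfoDb::seqnames(matchable)) ==
                as.character(GenomeInfoDb::seqnames(calls))[ci]
            hit <- which(!usedT & sameContig &
                abs(BiocGenerics::start(matchable) -
                    BiocGenerics::start(calls)[ci]) <= tolerance &
                abs(BiocGenerics::end(matchable) -
                    BiocGenerics::end(calls)[ci]) <= tolerance)
            if (length(hit)) {
                usedT[hit[1L]] <- TRUE
                tp <- tp + 1L
            }
        }
    }
    fp <- length(calls) - tp
    fn <- length(matchable) - tp
    precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    list(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = precision, recall = recall, f1 = f1,
         matching_tolerance = as.integer(tolerance))
}
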