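# Independent oracles and fixture builders. The oracles share no code with
# the package: plain character arithmetic, exhaustive enumeration.

.ORACLE_IUPAC <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracleRevcomp <- function(s) {
    paste(rev(.ORACLE_COMP[strsplit(s, "")[[1L]]]), collapse = "")
}

# Brute-force sliding-window scan of one contig. Returns a data.frame
# (start [1-based], strand, mismatches) for every window on either strand
# matching `motif` with <= mm substitutions; a genome N never matches.
oracleScan <- function(seqStr, motif = "CACTACTNGAAA", mm = 0L) {
    k <- nchar(motif)
    L <- nchar(seqStr)
    if (L < k)
        return(data.frame(start = integer(0), strand = character(0),
                          mismatches = integer(0)))
    mot <- strsplit(motif, "")[[1L]]
    chars <- strsplit(seqStr, "")[[1L]]
    starts <- seq_len(L - k + 1L)
    mmPlus <- integer(length(starts))
    mmMinus <- integer(length(starts))
    for (j in seq_len(k)) {
        set <- .ORACLE_IUPAC[[mot[j]]]
        mmPlus <- mmPlus + !(chars[starts + j - 1L] %in% set)
        # motif position j reads the complement of plus base start + k - j
        mmMinus <- mmMinus +
            !(.ORACLE_COMP[chars[starts + k - j]] %in% set)
    }
    keepP <- which(mmPlus <= mm)
    keepM <- which(mmMinus <= mm)
    out <- rbind(
        data.frame(start = starts[keepP],
                   strand = rep("+", length(keepP)),
                   mismatches = mmPlus[keepP]),
        data.frame(start = starts[keepM],
                   strand = rep("-", length(keepM)),
                   mismatches = mmMinus[keepM]))
    out[order(out$start, out$strand), , drop = FALSE]
}

scanAsFrame <- function(hits) {
    df <- data.frame(start = BiocGenerics::start(hits),
                     strand = as.character(BiocGenerics::strand(hits)),
                     mismatches = S4Vectors::mcols(hits)$mismatches)
    df <- df[order(df$start, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
}

# Exhaustive enumeration of all (left, right) occurrence pairs passing the
# orientation, span-window, and TSD-identity filters (policy = "all").
oraclePairs <- function(occ, minSpan = 1000L, maxSpan = 30000L,
                        requireIdenticalTir = FALSE) {
    ct <- as.character(GenomeInfoDb::seqnames(occ))
    st <- BiocGenerics::start(occ)
    en <- BiocGenerics::end(occ)
    ori <- orientation(occ)
    tsd <- tsdCandidate(occ)
    inw <- inwardSequence(occ)
    rows <- list()
    for (i in seq_along(occ)) for (j in seq_along(occ)) {
        if (ori[i] != "left" || ori[j] != "right") next
        if (ct[i] != ct[j]) next
        if (st[i] >= st[j]) next
        span <- en[j] - st[i] + 1L
        if (span < minSpan || span > maxSpan) next
        if (tsd[i] != tsd[j] || grepl("N", tsd[i])) next
        if (requireIdenticalTir && inw[i] != inw[j]) next
        rows[[length(rows) + 1L]] <-
            data.frame(contig = ct[i], start = st[i], end = en[j],
                       tsd = tsd[i])
    }
    if (!length(rows))
        return(data.frame(contig = character(0), start = integer(0),
                          end = integer(0), tsd = character(0)))
    df <- do.call(rbind, rows)
    df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
}

callsAsPairFrame <- function(calls) {
    df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(calls)),
                     start = BiocGenerics::start(calls),
                     end = BiocGenerics::end(calls),
                     tsd = elementTsd(calls))
    df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
}

# Motif-free random DNA (any accidental exact seed hit re-rolled).
randomDnaStr <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    repeat {
        s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
        if (!nrow(oracleScan(s, mm = 0L))) return(s)
    }
}

# A contig carrying one perfect planted element:
# flankL + TSD + leftTir + filler + revcomp(rightTir) + TSD + flankR.
# The filler repeat unit contains no CACTA, so the two TIRs hold the only
# seed matches. Returns the contig string and the expected element bounds.
elementFixture <- function(span = 2000L, tsd = "ACC",
                           leftTirSeq = TIR_B_DEFAULT,
                           rightTirSeq = TIR_A_DEFAULT,
                           flankL = strrep("G", 40L),
                           flankR = strrep("G", 40L),
                           rightTsd = tsd) {
    stopifnot(span >= 2L * nchar(leftTirSeq))
    fillerLen <- span - nchar(leftTirSeq) - nchar(rightTirSeq)
    filler <- substr(strrep("TGA", ceiling(fillerLen / 3) + 1L),
                     1L, fillerLen)
    contig <- paste0(flankL, tsd, leftTirSeq, filler,
                     oracleRevcomp(rightTirSeq), rightTsd, flankR)
    list(contig = contig,
         start = nchar(flankL) + nchar(tsd) + 1L,
         end = nchar(flankL) + nchar(tsd) + span)
}
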