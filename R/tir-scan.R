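#' Default CACTA TIR seed motif
#'
#' The conserved 12-nt terminus of CACTA-superfamily TIRs used as the scan
#' query. Position 8 is degenerate (N) so that one query finds both TIR
#' variants of an element family; the base observed there tags each
#' occurrence as A-type or B-type.
#'
#' @export
CACTA_SEED_MOTIF <- "CACTACTNGAAA"

#' Scan a genome for degenerate seed motif hits on both strands
#'
#' Finds every position, on both strands of every contig, where the IUPAC
#' motif matches with at most `maxMismatches` substitutions. Matching is
#' substitution-only (no indels); an N in the genome never matches any
#' motif code, including motif N, and always scores as a mismatch.
#' Candidate windows are located with [Biostrings::matchPattern()] and then
#' re-scored under this exact rule.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character
#'   vector), uppercase over \{A,C,G,T,N\}.
#' @param motif IUPAC motif, default [CACTA_SEED_MOTIF]; length >= 8.
#' @param maxMismatches non-negative substitution budget (default 0).
#' @return A [GenomicRanges::GRanges] of seed hits, one range per motif
#'   footprint on the plus strand, sorted by (contig, start, strand), with
#'   metadata columns `matched` (the 12-mer as read in motif orientation;
#'   reverse complement of the plus-strand slice for minus-strand hits) and
#'   `mismatches`.
#' @examples
#' g <- c(chr1 = "GGGCACTACTAGAAAGGG")
#' scanSeeds(g)
#' @importFrom Biostrings DNAString matchPattern reverseComplement
#' @export
scanSeeds <- function(genome, motif = CACTA_SEED_MOTIF,
                      maxMismatches = 0L) {
    genome <- .asGenome(genome)
    motif <- toupper(motif)
    if (nchar(motif) < 8L)
        stop("motif must be at least 8 nt")
    if (maxMismatches < 0L)
        stop("maxMismatches must be non-negative")
    .motifMatchMatrix(motif)  # validates IUPAC codes
    k <- nchar(motif)
    rcMotif <- .revcomp(motif)
    hits <- lapply(names(genome), function(contig) {
        subject <- genome[[contig]]
        if (length(subject) < k)
            return(NULL)
        res <- list()
        for (str in c("+", "-")) {
            pat <- if (str == "+") motif else rcMotif
            m <- Biostrings::matchPattern(
                Biostrings::DNAString(pat), subject,
                max.mismatch = maxMismatches, fixed = "subject")
            if (!length(m)) next
            slice <- as.character(m)
            matched <- if (str == "+") slice else .revcomp(slice)
            mm <- .countMismatches(matched, motif)
            keep <- mm <= maxMismatches
            if (!any(keep)) next
            res[[str]] <- data.frame(
                start = BiocGenerics::start(m)[keep],
                strand = str,
                matched = matched[keep],
                mismatches = mm[keep],
                stringsAsFactors = FALSE)
        }
        if (!length(res)) return(NULL)
        df <- do.call(rbind, res)
        df$contig <- contig
        df
    })
    hits <- hits[!vapply(hits, is.null, logical(1L))]
    if (!length(hits)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(matched = character(0),
                               mismatches = integer(0))
        return(gr)
    }
    df <- do.call(rbind, hits)
    o <- order(df$contig, df$start, df$strand)
    df <- df[o, , drop = FALSE]
    gr <- GRanges(df$contig,
                  IRanges::IRanges(df$start, width = k),
                  strand = df$strand)
    mcols(gr) <- DataFrame(matched = df$matched,
                           mismatches = df$mismatches)
    gr
}

#' Extend seed hits to uniform-length TIR occurrences with flanking TSDs
#'
#' Each seed hit is extended inward (into the putative element) to a
#' uniform TIR length, and the trinucleotide immediately outside the TIR is
#' recorded as the putative target-site duplication. A plus-strand hit
#' starting at `p` (1-based) becomes a left TIR covering
#' `[p, p + tirLength - 1]` with TSD `[p - tsdLength, p - 1]`; a
#' minus-strand hit whose motif footprint covers `[q, q + k - 1]` becomes a
#' right TIR covering `[q + k - tirLength, q + k - 1]` whose inward
#' sequence is the reverse complement of that slice, with TSD
#' `[q + k, q + k + tsdLength - 1]` (read on the plus strand; TSD copies
#' are direct repeats). Hits too close to a contig edge, or whose TIR or
#' TSD contains an N, are rejected with a reason rather than reported.
#'
#' @param hits a seed-hit `GRanges` from [scanSeeds()].
#' @param genome the genome the hits came from.
#' @param tirLength uniform TIR length (default 28: the 12-nt seed extended
#'   16 nt into the element).
#' @param tsdLength TSD length (default 3, the CACTA target-site
#'   duplication size).
#' @return A [TirOccurrences-class] object. Rejected hits are recorded in
#'   `metadata(x)$rejected`, a data.frame with columns contig, start,
#'   strand, reason; scan parameters in `metadata(x)$tirLength` and
#'   `$tsdLength`.
#' @export
extendToTir <- function(hits, genome, tirLength = 28L, tsdLength = 3L) {
    genome <- .asGenome(genome)
    if (tirLength < 12L)
        stop("tirLength must be >= seed length")
    k <- if (length(hits)) unique(IRanges::width(hits)) else NA_integer_
    if (length(k) > 1L)
        stop("seed hits must share one motif length")
    n <- length(hits)
    contig <- as.character(GenomeInfoDb::seqnames(hits))
    p <- BiocGenerics::start(hits)
    str <- as.character(BiocGenerics::strand(hits))
    L <- stats::setNames(Biostrings::width(genome), names(genome))[contig]

    tirStart <- ifelse(str == "+", p, p + k - tirLength)
    tirEnd <- tirStart + tirLength - 1L
    tsdStart <- ifelse(str == "+", tirStart - tsdLength, tirEnd + 1L)
    tsdEnd <- tsdStart + tsdLength - 1L

    reason <- character(n)
    reason[str == "+" & tirEnd > L] <- "incomplete TIR extension"
    reason[str == "-" & tirStart < 1L] <- "incomplete TIR extension"
    noFlank <- reason == "" &
        ((str == "+" & tsdStart < 1L) | (str == "-" & tsdEnd > L))
    reason[noFlank] <- "incomplete TSD flank"

    ok <- reason == ""
    inward <- character(n)
    tsd <- character(n)
    if (any(ok)) {
        slices <- .sliceGenome(genome, contig[ok], tirStart[ok], tirEnd[ok])
        inward[ok] <- ifelse(str[ok] == "+", slices, .revcomp(slices))
        tsd[ok] <- .sliceGenome(genome, contig[ok], tsdStart[ok], tsdEnd[ok])
        hasN <- ok & (grepl("N", inward) | grepl("N", tsd))
        reason[hasN] <- "ambiguous base in TIR or TSD"
        ok <- reason == ""
    }

    rejected <- data.frame(contig = contig[!ok], start = p[!ok],
                           strand = str[!ok], reason = reason[!ok],
                           stringsAsFactors = FALSE)
    gr <- GRanges(contig[ok],
                  IRanges::IRanges(tirStart[ok], tirEnd[ok]),
                  strand = str[ok])
    mcols(gr) <- DataFrame(
        orientation = ifelse(str[ok] == "+", "left", "right"),
        inward = inward[ok],
        tsd = tsd[ok],
        seedVariant = substr(inward[ok], 8L, 8L),
        mismatches = if (n) mcols(hits)$mismatches[ok] else integer(0))
    occ <- new("TirOccurrences", sort(gr, ignore.strand = TRUE))
    metadata(occ)$rejected <- rejected
    metadata(occ)$tirLength <- as.integer(tirLength)
    metadata(occ)$tsdLength <- as.integer(tsdLength)
    occ
}

.sliceGenome <- function(genome, contig, start, end) {
    vapply(seq_along(contig), function(i)
        as.character(Biostrings::subseq(genome[[contig[i]]],
                                        start[i], end[i])),
        character(1L))
}

#' Scan and extend in one step
#'
#' Convenience wrapper running [scanSeeds()] then [extendToTir()].
#'
#' @inheritParams scanSeeds
#' @inheritParams extendToTir
#' @return A [TirOccurrences-class] object.
#' @export
findTirOccurrences <- function(genome, motif = CACTA_SEED_MOTIF,
                               maxMismatches = 0L, tirLength = 28L,
                               tsdLength = 3L) {
    genome <- .asGenome(genome)
    extendToTir(scanSeeds(genome, motif, maxMismatches), genome,
                tirLength = tirLength, tsdLength = tsdLength)
}
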