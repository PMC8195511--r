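#' TIR-family redundancy: total vs confirmed copy counts
#'
#' Groups TIR occurrences by their exact inward-read sequence and counts,
#' per distinct sequence, the total genomic occurrences and how many of
#' them serve as a terminus of a called element (the "confirmed" copies).
#' An occurrence is confirmed when its contig, TIR interval, and
#' orientation coincide with the left or right terminus of some call.
#'
#' @param occurrences a [TirOccurrences-class] object.
#' @param calls a [CactaCalls-class] object from the same run.
#' @return A `data.frame` with columns `tir_sequence`, `total_count`,
#'   `confirmed_count`, sorted by `total_count` descending with
#'   lexicographic tie-break.
#' @export
tirAbundance <- function(occurrences, calls) {
    stopifnot(is(occurrences, "TirOccurrences"), is(calls, "CactaCalls"))
    if (!length(occurrences))
        return(data.frame(tir_sequence = character(0),
                          total_count = integer(0),
                          confirmed_count = integer(0)))
    tirLength <- metadata(occurrences)$tirLength
    if (is.null(tirLength))
        tirLength <- nchar(inwardSequence(occurrences)[1L])
    occKey <- paste(as.character(GenomeInfoDb::seqnames(occurrences)),
                    BiocGenerics::start(occurrences),
                    orientation(occurrences))
    callKey <- character(0)
    if (length(calls)) {
        ct <- as.character(GenomeInfoDb::seqnames(calls))
        callKey <- c(paste(ct, BiocGenerics::start(calls), "left"),
                     paste(ct, BiocGenerics::end(calls) - tirLength + 1L,
                           "right"))
    }
    confirmed <- occKey %in% callKey
    seqs <- inwardSequence(occurrences)
    total <- table(seqs)
    conf <- table(factor(seqs[confirmed], levels = names(total)))
    df <- data.frame(tir_sequence = names(total),
                     total_count = as.integer(total),
                     confirmed_count = as.integer(conf),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$total_count, df$tir_sequence), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' TSD trinucleotide frequency table
#'
#' Tallies the verified TSD of each element call over all 64 trinucleotides
#' \{A,C,G,T\}^3; absent trinucleotides appear with count zero, so the table
#' always has exactly 64 categories and sums to the number of calls.
#'
#' @param calls a [CactaCalls-class] object.
#' @return A 64-row `data.frame` with columns `tsd` (lexicographic) and
#'   `count`.
#' @export
tsdFrequency <- function(calls) {
    stopifnot(is(calls, "CactaCalls"))
    levels <- .allTrinucleotides()
    tsd <- if (length(calls)) elementTsd(calls) else character(0)
    tab <- table(factor(tsd, levels = levels))
    data.frame(tsd = levels, count = as.integer(tab),
               stringsAsFactors = FALSE)
}

#' Overlap between element calls and a prior annotation
#'
#' Intersects two interval sets (typically element calls vs an existing
#' repeat annotation) and summarizes the shared bases. By default every
#' nonempty query/subject pair contributes its own intersection segment
#' (`intersect`-style per-pair semantics); with `merged = TRUE` both sets
#' are first reduced and the merged intersection segments are counted
#' instead.
#'
#' @param query,subject `GRanges` (or [CactaCalls-class]) interval sets on
#'   a shared contig namespace; strand is ignored.
#' @param merged count merged intersection segments instead of per-pair
#'   segments (default `FALSE`).
#' @return A list with `total_overlap_bp`, `n_overlapping_segments`, and
#'   `mean_segment_length` (0 when there are no segments).
#' @importFrom GenomicRanges findOverlaps pintersect reduce
#' @importFrom IRanges width
#' @export
annotationOverlap <- function(query, subject, merged = FALSE) {
    query <- .asPlainRanges(query)
    subject <- .asPlainRanges(subject)
    if (merged) {
        segs <- GenomicRanges::intersect(
            GenomicRanges::reduce(query),
            GenomicRanges::reduce(subject), ignore.strand = TRUE)
        w <- IRanges::width(segs)
    } else {
        hits <- GenomicRanges::findOverlaps(query, subject,
                                            ignore.strand = TRUE)
        w <- IRanges::width(GenomicRanges::pintersect(
            query[S4Vectors::queryHits(hits)],
            subject[S4Vectors::subjectHits(hits)], ignore.strand = TRUE))
    }
    total <- sum(w)
    n <- length(w)
    list(total_overlap_bp = as.integer(total),
         n_overlapping_segments = as.integer(n),
         mean_segment_length = if (n) total / n else 0)
}

.asPlainRanges <- function(x) {
    gr <- GRanges(GenomeInfoDb::seqnames(x), IRanges::ranges(x))
    BiocGenerics::strand(gr) <- "*"
    gr
}
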