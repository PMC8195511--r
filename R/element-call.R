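#' Pair inward-facing TIR occurrences into candidate CACTA elements
#'
#' Applies the discovery filters to all left/right TIR occurrence pairs on
#' each contig: (1) both TIRs on the same contig with a left-orientation
#' occurrence upstream of a right-orientation occurrence (inverted, i.e.
#' forward-reverse, orientation); (2) TIR-inclusive span — first base of
#' the left TIR through last base of the right TIR — inside
#' `[minSpan, maxSpan]`; (3) identical flanking TSD trinucleotides. TSDs
#' containing N never validate. When one occurrence could enter several
#' pairs, `policy` resolves the conflict:
#'
#' * `"nearest"` (default): left TIRs are processed left-to-right and each
#'   pairs with the closest valid right TIR; every occurrence is used at
#'   most once.
#' * `"innermost"`: valid pairs are accepted shortest-span-first, each
#'   occurrence used at most once.
#' * `"all"`: every valid pair is reported (occurrences may recur; useful
#'   for oracle comparison and nested-element exploration).
#'
#' @param occurrences a [TirOccurrences-class] object from one scan run.
#' @param minSpan,maxSpan span window in nt (defaults 1000 and 30000, the
#'   expected size range of complete elements).
#' @param policy pairing policy, see above.
#' @param requireIdenticalTir require the two inward TIR sequences to be
#'   identical (default `FALSE`: natural TIR pairs are imperfect repeats).
#' @return A [CactaCalls-class] object sorted by coordinate.
#' @export
callElements <- function(occurrences, minSpan = 1000L, maxSpan = 30000L,
                         policy = c("nearest", "all", "innermost"),
                         requireIdenticalTir = FALSE) {
    policy <- match.arg(policy)
    stopifnot(is(occurrences, "TirOccurrences"))
    if (minSpan >= maxSpan)
        stop("minSpan must be less than maxSpan")
    if (!length(occurrences))
        return(.emptyCalls())
    contig <- as.character(GenomeInfoDb::seqnames(occurrences))
    rows <- lapply(unique(contig), function(ct) {
        occ <- occurrences[contig == ct]
        .callOneContig(occ, ct, minSpan, maxSpan, policy,
                       requireIdenticalTir)
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || !nrow(df))
        return(.emptyCalls())
    df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
    gr <- GRanges(df$contig, IRanges::IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(span = as.integer(df$end - df$start + 1L),
                           tsd = df$tsd,
                           leftTir = df$leftTir, rightTir = df$rightTir,
                           leftSeedVariant = df$leftVar,
                           rightSeedVariant = df$rightVar)
    new("CactaCalls", gr)
}

.emptyCalls <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(span = integer(0), tsd = character(0),
                           leftTir = character(0), rightTir = character(0),
                           leftSeedVariant = character(0),
                           rightSeedVariant = character(0))
    new("CactaCalls", gr)
}

.callOneContig <- function(occ, ct, minSpan, maxSpan, policy,
                           requireIdenticalTir) {
    ori <- orientation(occ)
    lefts <- occ[ori == "left"]
    rights <- occ[ori == "right"]
    if (!length(lefts) || !length(rights))
        return(NULL)
    lefts <- lefts[order(BiocGenerics::start(lefts))]
    rights <- rights[order(BiocGenerics::start(rights))]
    ls <- BiocGenerics::start(lefts)
    re <- BiocGenerics::end(rights)
    rs <- BiocGenerics::start(rights)
    # valid pair matrix over (left i, right j)
    pairs <- expand.grid(i = seq_along(lefts), j = seq_along(rights))
    span <- re[pairs$j] - ls[pairs$i] + 1L
    valid <- ls[pairs$i] < rs[pairs$j] &
        span >= minSpan & span <= maxSpan &
        tsdCandidate(lefts)[pairs$i] == tsdCandidate(rights)[pairs$j] &
        !grepl("N", tsdCandidate(lefts)[pairs$i])
    if (requireIdenticalTir)
        valid <- valid &
            inwardSequence(lefts)[pairs$i] == inwardSequence(rights)[pairs$j]
    pairs <- pairs[valid, , drop = FALSE]
    span <- span[valid]
    if (!nrow(pairs))
        return(NULL)
    keep <- switch(policy,
        all = seq_len(nrow(pairs)),
        nearest = .pickNearest(pairs, rs),
        innermost = .pickInnermost(pairs, span, ls))
    pairs <- pairs[keep, , drop = FALSE]
    data.frame(contig = ct,
               start = ls[pairs$i],
               end = re[pairs$j],
               tsd = tsdCandidate(lefts)[pairs$i],
               leftTir = inwardSequence(lefts)[pairs$i],
               rightTir = inwardSequence(rights)[pairs$j],
               leftVar = seedVariant(lefts)[pairs$i],
               rightVar = seedVariant(rights)[pairs$j],
               stringsAsFactors = FALSE)
}

# Left-to-right greedy: each left takes the closest (smallest start) valid
# unused right; both become unused for later pairs.
.pickNearest <- function(pairs, rightStarts) {
    usedR <- logical(max(pairs$j))
    keep <- integer(0)
    for (i in sort(unique(pairs$i))) {
        js <- pairs$j[pairs$i == i]
        js <- js[!usedR[js]]
        if (!length(js)) next
        j <- js[which.min(rightStarts[js])]
        keep <- c(keep, which(pairs$i == i & pairs$j == j))
        usedR[j] <- TRUE
    }
    keep
}

# Shortest-span-first greedy; ties broken by leftmost coordinate.
.pickInnermost <- function(pairs, span, leftStarts) {
    o <- order(span, leftStarts[pairs$i], pairs$j)
    usedL <- logical(max(pairs$i))
    usedR <- logical(max(pairs$j))
    keep <- integer(0)
    for (k in o) {
        if (usedL[pairs$i[k]] || usedR[pairs$j[k]]) next
        keep <- c(keep, k)
        usedL[pairs$i[k]] <- TRUE
        usedR[pairs$j[k]] <- TRUE
    }
    sort(keep)
}

#' Summary statistics of a call set
#'
#' @param calls a [CactaCalls-class] object.
#' @return A one-row `data.frame` with `n_elements`, `total_length`,
#'   `mean_length`, and `median_length` (nt) of the TIR-inclusive spans;
#'   all zero for an empty call set. The median of an even count is the
#'   midpoint of the two central spans.
#' @importFrom stats median
#' @export
summarizeElements <- function(calls) {
    stopifnot(is(calls, "CactaCalls"))
    if (!length(calls))
        return(data.frame(n_elements = 0L, total_length = 0,
                          mean_length = 0, median_length = 0))
    sp <- elementSpan(calls)
    data.frame(n_elements = length(sp), total_length = sum(sp),
               mean_length = mean(sp), median_length = stats::median(sp))
}
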