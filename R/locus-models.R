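#' Insertion alleles and genotyping assays
#'
#' `insertionAllele()` describes one allele of an insertion locus: the
#' element length in nt (0 for the insertion-free allele) and the length of
#' the extra TSD copy the insertion created (3 for a full trinucleotide
#' TSD, 2 for a truncated derivative retaining a partial TSD, 0 for wild
#' type). `primerAssay()` describes a PCR genotyping assay by its amplicon
#' length on the insertion-free allele and whether its primers span the
#' insertion site.
#'
#' @param elementLength element length in nt (>= 0).
#' @param tsdCopyLength extra TSD copy length in nt (0-3).
#' @param label allele name.
#' @return A validated list of class `InsertionAllele` /` PrimerAssay`.
#' @examples
#' full <- insertionAllele(3913, 3, "full-length")
#' insertionObservedLength(full)  # 3916
#' @export
insertionAllele <- function(elementLength, tsdCopyLength, label = "") {
    if (elementLength < 0 || tsdCopyLength < 0)
        stop("lengths must be non-negative")
    if (tsdCopyLength > 3)
        stop("tsdCopyLength cannot exceed the 3-nt TSD")
    structure(list(elementLength = as.numeric(elementLength),
                   tsdCopyLength = as.numeric(tsdCopyLength),
                   label = label),
              class = "InsertionAllele")
}

#' @rdname insertionAllele
#' @param assayId assay name.
#' @param baselineAmpliconLength amplicon length (nt) on the insertion-free
#'   allele.
#' @param spansInsertionSite do the primers bracket the insertion site?
#' @export
primerAssay <- function(assayId, baselineAmpliconLength,
                        spansInsertionSite = TRUE) {
    if (baselineAmpliconLength <= 0)
        stop("baseline amplicon length must be positive")
    structure(list(assayId = assayId,
                   baselineAmpliconLength =
                       as.numeric(baselineAmpliconLength),
                   spansInsertionSite = isTRUE(spansInsertionSite)),
              class = "PrimerAssay")
}

#' Apparent insertion length of an allele
#'
#' The size difference a spanning PCR (or alignment) observes between an
#' insertion allele and the insertion-free allele: the element length plus
#' the extra TSD copy created at insertion. A 3,913-nt element with a full
#' 3-nt TSD appears as a 3,916-nt insert; a 1,094-nt truncated derivative
#' with a 2-nt partial TSD appears as 1,096 nt.
#'
#' @param allele an [insertionAllele()].
#' @return Observed insertion length in nt.
#' @export
insertionObservedLength <- function(allele) {
    stopifnot(inherits(allele, "InsertionAllele"))
    allele$elementLength + allele$tsdCopyLength
}

#' Predicted genotyping amplicon length for an allele
#'
#' For an assay whose primers span the insertion site, the amplicon grows
#' by the allele's apparent insertion length over the insertion-free
#' baseline.
#'
#' @param assay a [primerAssay()] spanning the insertion site.
#' @param allele an [insertionAllele()].
#' @return Predicted amplicon length in nt.
#' @examples
#' ans1 <- primerAssay("ANS1", 280)
#' ampliconLength(ans1, insertionAllele(3913, 3))  # 4196
#' ampliconLength(ans1, insertionAllele(1094, 2))  # 1376
#' @export
ampliconLength <- function(assay, allele) {
    stopifnot(inherits(assay, "PrimerAssay"),
              inherits(allele, "InsertionAllele"))
    if (!assay$spansInsertionSite)
        stop("assay does not span the insertion site; amplicon length is ",
             "not derivable from insertion arithmetic")
    assay$baselineAmpliconLength + insertionObservedLength(allele)
}

#' Observed-length loss between a full and a truncated allele
#'
#' Difference of apparent insertion lengths, i.e. how much shorter the
#' truncated derivative appears in a spanning assay. Computed on observed
#' lengths (element + TSD copy); the element-only difference is smaller
#' when the truncated allele retains a partial TSD.
#'
#' @param full,truncated [insertionAllele()] objects, observed length of
#'   `truncated` not exceeding `full`.
#' @return Loss in nt.
#' @export
truncationLoss <- function(full, truncated) {
    lf <- insertionObservedLength(full)
    lt <- insertionObservedLength(truncated)
    if (lt > lf)
        stop("truncated allele is longer than the full allele")
    lf - lt
}

#' Insert an element into a sequence, duplicating the target site
#'
#' Models CACTA insertion: the element lands immediately after `pos` and
#' the `tsdLength` host bases ending at `pos` are duplicated on its far
#' side, so the host trinucleotide flanks the element on both sides.
#'
#' @param sequence host sequence (character or `DNAString`).
#' @param pos 1-based position of the last host base before the element;
#'   must be at least `tsdLength`.
#' @param element element sequence to insert.
#' @param tsdLength target-site duplication length (default 3).
#' @return A list with `sequence` (the post-insertion character sequence)
#'   and `elementInterval` (`c(start, end)`, 1-based inclusive span of the
#'   element itself, excluding both TSD copies).
#' @export
plantElement <- function(sequence, pos, element, tsdLength = 3L) {
    sequence <- as.character(sequence)
    element <- as.character(element)
    if (pos < tsdLength || pos > nchar(sequence))
        stop("insertion point leaves no room for the TSD")
    tsd <- substr(sequence, pos - tsdLength + 1L, pos)
    out <- paste0(substr(sequence, 1L, pos), element, tsd,
                  substr(sequence, pos + 1L, nchar(sequence)))
    list(sequence = out,
         elementInterval = c(start = pos + 1L,
                             end = pos + nchar(element)))
}

#' Excise an element, restoring the pre-insertion sequence
#'
#' Footprint-free excision: the element and exactly one of its two TSD
#' copies are removed, so planting followed by excision is the identity.
#' The element must be flanked by identical TSD copies — a one-TIR
#' truncated derivative with a partial 5' TSD is not excisable.
#'
#' @param sequence sequence carrying the element (character or
#'   `DNAString`).
#' @param elementStart,elementEnd 1-based inclusive bounds of the element
#'   (TIR-inclusive, excluding TSD copies).
#' @param tsdLength TSD length (default 3).
#' @return The restored character sequence.
#' @export
excise <- function(sequence, elementStart, elementEnd, tsdLength = 3L) {
    sequence <- as.character(sequence)
    L <- nchar(sequence)
    if (elementStart - tsdLength < 1L || elementEnd + tsdLength > L)
        stop("not excisable: no room for flanking TSD copies")
    left <- substr(sequence, elementStart - tsdLength, elementStart - 1L)
    right <- substr(sequence, elementEnd + 1L, elementEnd + tsdLength)
    if (left != right)
        stop("not excisable: flanking TSD copies differ ('", left,
             "' vs '", right, "')")
    paste0(substr(sequence, 1L, elementStart - 1L),
           substr(sequence, elementEnd + tsdLength + 1L, L))
}
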