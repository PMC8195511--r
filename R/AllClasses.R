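#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges
NULL

.TIR_MCOLS <- c("orientation", "inward", "tsd", "seedVariant", "mismatches")
.CALL_MCOLS <- c("span", "tsd", "leftTir", "rightTir",
                 "leftSeedVariant", "rightSeedVariant")

#' TIR occurrences on a genome
#'
#' A [GenomicRanges::GRanges] subclass holding candidate terminal inverted
#' repeats (TIRs): each range covers one uniform-length TIR on the plus
#' strand of its contig. Metadata columns record the orientation
#' (`"left"` = element start, read inward rightward; `"right"` = element
#' end, read inward leftward), the inward-read TIR sequence (5'->3' into
#' the putative element), the flanking putative target-site-duplication
#' (TSD) trinucleotide read on the plus strand, the base at the seed
#' position that distinguishes TIR variants, and the seed mismatch count.
#'
#' @slot ranges inherited from `GRanges`; one range per TIR occurrence.
#' @seealso [extendToTir()], [callElements()]
#' @exportClass TirOccurrences
setClass("TirOccurrences", contains = "GRanges")

setValidity("TirOccurrences", function(object) {
    mc <- mcols(object)
    missing <- setdiff(.TIR_MCOLS, colnames(mc))
    if (length(missing))
        return(paste("missing metadata columns:",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (!all(mc$orientation %in% c("left", "right")))
            return("orientation must be 'left' or 'right'")
        if (length(unique(nchar(mc$inward))) > 1L)
            return("inward sequences must share one TIR length")
        if (any(nchar(mc$inward) != unique(IRanges::width(object))))
            return("inward sequence length must equal range width")
    }
    TRUE
})

#' Candidate CACTA element calls
#'
#' A [GenomicRanges::GRanges] subclass in which each range spans one called
#' element from the first base of its left TIR through the last base of its
#' right TIR (TIR-inclusive). Metadata columns carry the span in
#' nucleotides, the verified TSD trinucleotide, both inward-read TIR
#' sequences, and the seed-variant base of each TIR.
#'
#' @seealso [callElements()], [writeCalls()], [summarizeElements()]
#' @exportClass CactaCalls
setClass("CactaCalls", contains = "GRanges")

setValidity("CactaCalls", function(object) {
    mc <- mcols(object)
    missing <- setdiff(.CALL_MCOLS, colnames(mc))
    if (length(missing))
        return(paste("missing metadata columns:",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (!all(mc$span == IRanges::width(object)))
            return("span must equal range width")
        if (!all(nchar(mc$tsd) == nchar(mc$tsd[1L])))
            return("TSDs must share one length")
    }
    TRUE
})

#' A simulated genome with planted CACTA-like elements
#'
#' Container for one synthetic genome and its ground truth: the genome as a
#' [Biostrings::DNAStringSet], a truth [GenomicRanges::GRanges] with one
#' range per planted feature (metadata columns `featureId`, `type` in
#' complete/truncated/solo_tir, `tsd`, `retainedFraction`), and the
#' generating configuration.
#'
#' @slot genome a `DNAStringSet`, one entry per contig.
#' @slot truth a `GRanges` of planted features.
#' @slot config the `simulationConfig()` list used for generation.
#' @seealso [generateGenome()], [evaluateRecovery()]
#' @exportClass CactaSimulation
setClass("CactaSimulation",
         representation(genome = "DNAStringSet",
                        truth = "GRanges",
                        config = "list"))

setValidity("CactaSimulation", function(object) {
    need <- c("featureId", "type", "tsd", "retainedFraction")
    missing <- setdiff(need, colnames(mcols(object@truth)))
    if (length(missing))
        return(paste("truth lacks metadata columns:",
                     paste(missing, collapse = ", ")))
    if (length(object@truth) &&
        !all(mcols(object@truth)$type %in%
             c("complete", "truncated", "solo_tir")))
        return("truth type must be complete, truncated, or solo_tir")
    if (!all(as.character(GenomeInfoDb::seqnames(object@truth)) %in%
             names(object@genome)))
        return("truth contigs absent from genome")
    TRUE
})

setMethod("show", "TirOccurrences", function(object) {
    cat(class(object), "with", length(object), "TIR occurrence(s)\n")
    if (length(object)) {
        tab <- table(mcols(object)$orientation)
        cat("  orientation:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    callNextMethod()
})

setMethod("show", "CactaCalls", function(object) {
    cat(class(object), "with", length(object), "element call(s)\n")
    if (length(object))
        cat("  span range:", min(mcols(object)$span), "-",
            max(mcols(object)$span), "nt\n")
    callNextMethod()
})

setMethod("show", "CactaSimulation", function(object) {
    cat("CactaSimulation\n")
    cat("  genome:", length(object@genome), "contig(s),",
        sum(Biostrings::width(object@genome)), "nt\n")
    tab <- table(mcols(object@truth)$type)
    cat("  planted:",
        if (length(tab)) paste(names(tab), tab, sep = "=", collapse = ", ")
        else "none", "\n")
    invisible(NULL)
})
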