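#' Read a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a [Biostrings::DNAStringSet], normalizes
#' to uppercase, and enforces the scan alphabet \{A,C,G,T,N\}: IUPAC
#' ambiguity codes other than N are either rejected or collapsed to N.
#' Contig names are truncated at the first whitespace and must be unique.
#'
#' @param path path to a FASTA file.
#' @param illegal what to do with ambiguity codes other than N:
#'   `"error"` (default) or `"toN"`.
#' @return A `DNAStringSet`, one entry per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' readGenome(fa)
#' @importFrom Biostrings readDNAStringSet DNAStringSet
#' @export
readGenome <- function(path, illegal = c("error", "toN")) {
    illegal <- match.arg(illegal)
    if (!file.exists(path))
        stop("file not found: ", path)
    dna <- Biostrings::readDNAStringSet(path, format = "fasta")
    if (!length(dna))
        stop("no FASTA records in ", path)
    names(dna) <- sub("\\s.*$", "", names(dna))
    if (anyDuplicated(names(dna)))
        stop("duplicate contig ids: ",
             paste(unique(names(dna)[duplicated(names(dna))]),
                   collapse = ", "))
    if (any(Biostrings::width(dna) == 0L))
        stop("empty FASTA record(s): ",
             paste(names(dna)[Biostrings::width(dna) == 0L], collapse = ", "))
    freq <- Biostrings::alphabetFrequency(dna)
    extra <- freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                  drop = FALSE]
    if (any(extra > 0L)) {
        if (illegal == "error")
            stop("sequence contains characters outside {A,C,G,T,N}; ",
                 "use illegal = \"toN\" to mask them")
        dna <- Biostrings::DNAStringSet(
            Biostrings::replaceAmbiguities(dna, new = "N"))
    }
    dna
}

#' Write a genome to FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom Biostrings writeXStringSet
#' @export
writeGenome <- function(genome, path) {
    genome <- .asGenome(genome)
    Biostrings::writeXStringSet(genome, filepath = path, format = "fasta")
    invisible(path)
}

.asGenome <- function(genome) {
    if (is.character(genome)) {
        if (is.null(names(genome)))
            stop("character genomes must be named by contig")
        genome <- Biostrings::DNAStringSet(toupper(genome))
    }
    if (is(genome, "DNAString"))
        genome <- Biostrings::DNAStringSet(stats::setNames(list(genome),
                                                           "seq1"))
    if (!is(genome, "DNAStringSet"))
        stop("genome must be a DNAStringSet, DNAString, or named character")
    if (is.null(names(genome)) || anyDuplicated(names(genome)))
        stop("contig names must be present and unique")
    genome
}

#' Length of a 1-based inclusive interval
#'
#' Reported genome coordinates in the literature are 1-based and inclusive,
#' so a feature printed as `start..end` spans `end - start + 1`
#' nucleotides; e.g. coordinates 18,848,559-18,852,487 describe a 3,929-nt
#' segment.
#'
#' @param start,end positive integers, `end >= start` (vectorized).
#' @return `end - start + 1`.
#' @examples
#' intervalLength1Based(18848559, 18852487)  # 3929
#' @export
intervalLength1Based <- function(start, end) {
    if (any(start < 1L) || any(end < 1L))
        stop("coordinates must be positive")
    if (any(end < start))
        stop("end must be >= start")
    as.integer(end - start + 1L)
}

#' Write element calls to GFF3, BED, or TSV
#'
#' GFF3 is emitted 1-based inclusive with feature type
#' `terminal_inverted_repeat_element` and attributes for the TSD and both
#' TIR sequences; BED is 0-based half-open; TSV mirrors every field with
#' 1-based inclusive coordinates.
#'
#' @param calls a [CactaCalls-class] object.
#' @param path output file.
#' @param format one of `"gff3"`, `"bed"`, `"tsv"`.
#' @return `path`, invisibly.
#' @importFrom rtracklayer export
#' @importFrom utils write.table
#' @export
writeCalls <- function(calls, path, format = c("gff3", "bed", "tsv")) {
    format <- match.arg(format)
    stopifnot(is(calls, "CactaCalls"))
    ids <- sprintf("cacta_call_%04d", seq_along(calls))
    if (format == "gff3") {
        gr <- GRanges(GenomeInfoDb::seqnames(calls), IRanges::ranges(calls))
        mcols(gr) <- DataFrame(
            source = "CactaScan",
            type = "terminal_inverted_repeat_element",
            ID = ids,
            tsd = elementTsd(calls),
            left_tir = leftTir(calls),
            right_tir = rightTir(calls))
        rtracklayer::export(gr, path, format = "gff3")
    } else if (format == "bed") {
        gr <- GRanges(GenomeInfoDb::seqnames(calls), IRanges::ranges(calls))
        mcols(gr) <- DataFrame(name = ids)
        rtracklayer::export(gr, path, format = "bed")
    } else {
        utils::write.table(callsAsTable(calls), file = path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Tabular view of element calls
#'
#' @param calls a [CactaCalls-class] object.
#' @return A `data.frame` with 1-based inclusive coordinates and all call
#'   fields; zero rows for an empty call set.
#' @export
callsAsTable <- function(calls) {
    stopifnot(is(calls, "CactaCalls"))
    data.frame(
        contig = as.character(GenomeInfoDb::seqnames(calls)),
        start = BiocGenerics::start(calls),
        end = BiocGenerics::end(calls),
        span = if (length(calls)) elementSpan(calls) else integer(0),
        tsd = if (length(calls)) elementTsd(calls) else character(0),
        left_tir = if (length(calls)) leftTir(calls) else character(0),
        right_tir = if (length(calls)) rightTir(calls) else character(0),
        left_seed_variant = if (length(calls))
            mcols(calls)$leftSeedVariant else character(0),
        right_seed_variant = if (length(calls))
            mcols(calls)$rightSeedVariant else character(0),
        stringsAsFactors = FALSE)
}

#' Read element calls back from a TSV written by [writeCalls()]
#'
#' @param path TSV path.
#' @return A [CactaCalls-class] object.
#' @importFrom utils read.table
#' @export
readCallsTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(contig = "character",
                                           tsd = "character",
                                           left_tir = "character",
                                           right_tir = "character",
                                           left_seed_variant = "character",
                                           right_seed_variant = "character"),
                            stringsAsFactors = FALSE)
    gr <- GRanges(df$contig, IRanges::IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(span = as.integer(df$span), tsd = df$tsd,
                           leftTir = df$left_tir, rightTir = df$right_tir,
                           leftSeedVariant = df$left_seed_variant,
                           rightSeedVariant = df$right_seed_variant)
    new("CactaCalls", gr)
}

#' Write and read TIR occurrences as TSV
#'
#' One row per occurrence, 1-based inclusive coordinates, columns mirroring
#' all [TirOccurrences-class] fields.
#'
#' @param occurrences a [TirOccurrences-class] object.
#' @param path TSV path.
#' @return `writeOccurrences()`: `path`, invisibly; `readOccurrencesTsv()`:
#'   a `TirOccurrences` object.
#' @export
writeOccurrences <- function(occurrences, path) {
    stopifnot(is(occurrences, "TirOccurrences"))
    df <- data.frame(
        contig = as.character(GenomeInfoDb::seqnames(occurrences)),
        start = BiocGenerics::start(occurrences),
        end = BiocGenerics::end(occurrences),
        strand = as.character(BiocGenerics::strand(occurrences)),
        orientation = orientation(occurrences),
        inward = inwardSequence(occurrences),
        tsd = tsdCandidate(occurrences),
        seed_variant = seedVariant(occurrences),
        mismatches = mcols(occurrences)$mismatches,
        stringsAsFactors = FALSE)
    utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeOccurrences
#' @export
readOccurrencesTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    gr <- GRanges(df$contig,
                  IRanges::IRanges(as.integer(df$start), as.integer(df$end)),
                  strand = df$strand)
    mcols(gr) <- DataFrame(orientation = df$orientation, inward = df$inward,
                           tsd = df$tsd, seedVariant = df$seed_variant,
                           mismatches = as.integer(df$mismatches))
    new("TirOccurrences", gr)
}
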