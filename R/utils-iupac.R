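# IUPAC degeneracy tables used by the seed scanner. A genome base matches a
# motif code when it belongs to the code's base set; an N in the genome
# never matches anything (identity cannot be verified), so it always scores
# as a mismatch even against motif N.

.IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
)

# 4 x k logical: does genome base (row, A/C/G/T) match motif position
# (column)? Genome N is handled by the caller (never a match).
.motifMatchMatrix <- function(motif) {
    codes <- strsplit(motif, "")[[1L]]
    bad <- setdiff(codes, names(.IUPAC_SETS))
    if (length(bad))
        stop("motif contains non-IUPAC code(s): ",
             paste(unique(bad), collapse = ", "))
    vapply(codes, function(cd) c("A", "C", "G", "T") %in% .IUPAC_SETS[[cd]],
           logical(4L))
}

# Mismatch counts for fixed-width windows against a motif. `windows` is a
# character vector of sequences, all nchar(motif) long, over {A,C,G,T,N}.
.countMismatches <- function(windows, motif) {
    if (!length(windows)) return(integer(0))
    mm <- .motifMatchMatrix(motif)
    mat <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = nchar(motif))
    idx <- match(mat, c("A", "C", "G", "T"))  # N and others -> NA
    ok <- matrix(FALSE, nrow = nrow(mat), ncol = ncol(mat))
    has <- !is.na(idx)
    ok[has] <- mm[cbind(idx[has], row(mat)[has])]
    as.integer(colSums(!ok))
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.checkDnaAlphabet <- function(x, what = "sequence") {
    if (grepl("[^ACGTN]", x))
        stop(what, " contains characters outside {A,C,G,T,N}")
    invisible(TRUE)
}

# All 64 trinucleotides over {A,C,G,T}, lexicographic.
.allTrinucleotides <- function() {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
    sort(paste0(g$b1, g$b2, g$b3))
}
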