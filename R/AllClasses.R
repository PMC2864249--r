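#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm p.adjust rmultinom runif rnorm setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib mirnaome, .registration = TRUE
NULL

#' SignatureTable: collapsed small RNA signatures with two-library counts
#'
#' The central currency of the pipeline: unique small RNA sequences
#' ("signatures") with raw read counts in each of two libraries (A and B,
#' e.g. wild type and mutant), plus the total retained read count of each
#' library. Sequences are held internally in the DNA alphabet; all report
#' and export functions emit RNA (U).
#'
#' @slot sequences character vector of unique signature sequences (DNA
#'   alphabet, uppercase).
#' @slot counts integer matrix with one row per signature and columns
#'   \code{A} and \code{B} holding raw read counts.
#' @slot librarySizes named numeric of length 2 (\code{A}, \code{B});
#'   total retained reads per library, equal to the column sums of
#'   \code{counts}.
#'
#' @seealso [collapseAndFilter()], [signatures()], [librarySizes()]
#' @export
setClass("SignatureTable",
    representation(
        sequences    = "character",
        counts       = "matrix",
        librarySizes = "numeric"
    )
)

setValidity("SignatureTable", function(object) {
    msg <- character()
    n <- length(object@sequences)
    if (!is.numeric(object@counts) || nrow(object@counts) != n)
        msg <- c(msg, "counts must be a numeric matrix with one row per sequence")
    if (ncol(object@counts) != 2L ||
        !identical(colnames(object@counts), c("A", "B")))
        msg <- c(msg, "counts must have columns 'A' and 'B'")
    if (anyDuplicated(object@sequences))
        msg <- c(msg, "signature sequences must be unique")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(object@librarySizes) != 2L ||
        !identical(names(object@librarySizes), c("A", "B")))
        msg <- c(msg, "librarySizes must be named numeric c(A=, B=)")
    else if (n > 0 && !all(object@librarySizes == colSums(object@counts)))
        msg <- c(msg, "librarySizes must equal column sums of counts")
    if (length(msg)) msg else TRUE
})

#' Construct a SignatureTable
#'
#' @param sequences character vector of unique sequences (DNA or RNA
#'   alphabet; U is normalised to T internally).
#' @param countA,countB non-negative integer read counts per signature in
#'   libraries A and B.
#' @return A [SignatureTable-class] object. Library sizes are computed from
#'   the counts.
#' @examples
#' SignatureTable(c("TGACAGAAGAGAGTGAGCAC", "TTGACAGAAGATAGAGAGCAC"),
#'                c(10L, 3L), c(2L, 0L))
#' @export
SignatureTable <- function(sequences, countA, countB) {
    sequences <- toDNA(as.character(sequences))
    counts <- cbind(A = as.integer(countA), B = as.integer(countB))
    new("SignatureTable",
        sequences = sequences, counts = counts,
        librarySizes = c(A = sum(counts[, "A"]), B = sum(counts[, "B"])))
}

#' @describeIn SignatureTable-class number of signatures
#' @param x a SignatureTable
#' @export
setMethod("length", "SignatureTable", function(x) length(x@sequences))

setMethod("show", "SignatureTable", function(object) {
    cat("SignatureTable with", length(object), "signatures\n")
    cat("  library sizes: A =", object@librarySizes[["A"]],
        ", B =", object@librarySizes[["B"]], "\n")
    if (length(object) > 0) {
        k <- min(5L, length(object))
        df <- data.frame(sequence = toRNA(object@sequences[seq_len(k)]),
                         count_A = object@counts[seq_len(k), "A"],
                         count_B = object@counts[seq_len(k), "B"])
        print(df, row.names = FALSE)
        if (length(object) > k) cat("  ...", length(object) - k, "more rows\n")
    }
})

#' Access signature sequences
#'
#' @param x a [SignatureTable-class]
#' @param as report alphabet, \code{"DNA"} (internal) or \code{"RNA"}.
#' @return character vector of sequences.
#' @export
signatures <- function(x, as = c("DNA", "RNA")) {
    stopifnot(is(x, "SignatureTable"))
    as <- match.arg(as)
    if (as == "RNA") toRNA(x@sequences) else x@sequences
}

#' Access the count matrix of a SignatureTable
#' @param x a [SignatureTable-class]
#' @return integer matrix with columns A and B.
#' @export
signatureCounts <- function(x) {
    stopifnot(is(x, "SignatureTable"))
    x@counts
}

#' Access library sizes (total retained reads per library)
#' @param x a [SignatureTable-class]
#' @return named numeric, \code{c(A=, B=)}.
#' @export
librarySizes <- function(x) {
    stopifnot(is(x, "SignatureTable"))
    x@librarySizes
}

#' Coerce a SignatureTable to data.frame (RNA alphabet)
#' @param x a [SignatureTable-class]
#' @param row.names,optional,... passed through for the generic signature
#' @return data.frame with sequence, count_A, count_B.
#' @method as.data.frame SignatureTable
#' @export
as.data.frame.SignatureTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    data.frame(sequence = toRNA(x@sequences),
               count_A = x@counts[, "A"], count_B = x@counts[, "B"],
               stringsAsFactors = FALSE)
}

#' FoldResult: a maximum-weight nested secondary structure
#'
#' Result of folding an RNA sequence by weighted nested base-pair
#' maximisation (Watson-Crick pairs weight 1, G:U wobble pairs a
#' configurable weight). The structure is guaranteed pseudoknot-free.
#'
#' @slot sequence the folded sequence (DNA alphabet internally).
#' @slot structure dot-bracket string of the same length.
#' @slot partner integer vector; \code{partner[i]} is the 1-based pairing
#'   partner of position i, or 0 if unpaired.
#' @slot score total pair weight of the structure.
#' @seealso [foldRna()]
#' @export
setClass("FoldResult",
    representation(
        sequence  = "character",
        structure = "character",
        partner   = "integer",
        score     = "numeric"
    )
)

setValidity("FoldResult", function(object) {
    n <- nchar(object@sequence)
    msg <- character()
    if (nchar(object@structure) != n)
        msg <- c(msg, "structure must have the same length as sequence")
    if (length(object@partner) != n)
        msg <- c(msg, "partner map must have one entry per position")
    p <- object@partner
    paired <- which(p > 0L)
    if (any(p[p[paired]] != paired))
        msg <- c(msg, "partner map must be symmetric")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FoldResult", function(object) {
    cat("FoldResult (", nchar(object@sequence), " nt, score ",
        format(object@score), ", ", sum(object@partner > 0L) / 2,
        " pairs)\n", sep = "")
    cat(" ", toRNA(object@sequence), "\n ", object@structure, "\n")
})

#' Fold score accessor
#' @param x a [FoldResult-class]
#' @return numeric weighted pair count.
#' @export
foldScore <- function(x) { stopifnot(is(x, "FoldResult")); x@score }

#' Pair-map accessor
#' @param x a [FoldResult-class]
#' @return integer vector of 1-based partners (0 = unpaired).
#' @export
pairMap <- function(x) { stopifnot(is(x, "FoldResult")); x@partner }

#' Dot-bracket accessor
#' @param x a [FoldResult-class]
#' @return dot-bracket string.
#' @export
dotBracket <- function(x) { stopifnot(is(x, "FoldResult")); x@structure }
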