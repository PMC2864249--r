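# Alphabet helpers and small shared utilities.

#' Normalise a sequence to the internal DNA alphabet (U -> T, uppercase)
#' @param x character vector of sequences
#' @return character vector, DNA alphabet
#' @export
toDNA <- function(x) chartr("U", "T", toupper(x))

#' Report a sequence in the RNA alphabet (T -> U)
#' @param x character vector of sequences
#' @return character vector, RNA alphabet
#' @export
toRNA <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement (DNA alphabet)
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
revComp <- function(x) {
    if (!length(x)) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round half away from zero at `digits` decimals (commercial rounding);
# matches the one-decimal arithmetic of the reported tables (5.672 -> 5.7)
#' Round half away from zero
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 1) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic child seed streams below 2^31, derived from one user seed
childSeed <- function(seed, k) {
    (as.integer(seed) %% 1000003L) * 2011L + 7L * as.integer(k) %% 2147483629L
}

#' Write sequences as FASTA
#' @param sequences named character vector (DNA alphabet; written as-is)
#' @param path output file
#' @return invisibly, the path
#' @export
writeFasta <- function(sequences, path) {
    stopifnot(!is.null(names(sequences)))
    x <- Biostrings::DNAStringSet(unname(sequences))
    names(x) <- names(sequences)
    Biostrings::writeXStringSet(x, path, width = 80L)
    invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file
#' @return named character vector (DNA alphabet, uppercase)
#' @export
readFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    out <- toDNA(as.character(x))
    names(out) <- names(x)
    out
}

#' Write reads as FASTQ (Phred+33, constant dummy quality "I")
#' @param reads character vector of read sequences
#' @param path output file
#' @param ids optional read identifiers (default read_1..n)
#' @return invisibly, the path
#' @export
writeFastq <- function(reads, path, ids = NULL) {
    if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
    con <- file(path, open = "wb")  # binary: byte-identical across platforms
    on.exit(close(con))
    if (length(reads)) {
        rec <- paste0("@", ids, "\n", reads, "\n+\n",
                      strrep("I", nchar(reads)))
        writeLines(rec, con, sep = "\n")
    }
    invisible(path)
}

#' Read a FASTQ file as a character vector of read sequences
#' @param path FASTQ file
#' @return character vector (DNA alphabet, uppercase)
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    toDNA(as.character(x))
}

# write a data.frame as TSV with stable formatting (determinism across runs)
writeTsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    invisible(path)
}

#' Write a SignatureTable as TSV (sequence, count_A, count_B; RNA alphabet)
#' @param table a [SignatureTable-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeSignatureTable <- function(table, path) {
    writeTsv(as.data.frame(table), path)
}

#' Read a SignatureTable written by [writeSignatureTable()]
#' @param path TSV file
#' @return a [SignatureTable-class]
#' @export
readSignatureTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    SignatureTable(df$sequence, df$count_A, df$count_B)
}
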