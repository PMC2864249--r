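# Raw reads -> filtered, collapsed two-library signature table.
#
# Trimming anchors on the exact last 7 nt of the 5' adapter and the exact
# first 7 nt of the 3' adapter; the insert is the substring strictly
# between the two anchors. Collapsing keeps unique sequences with
# per-library counts, drops ambiguous bases, enforces the length window
# and the minimum-count rule, and recomputes library sizes afterwards.

#' Trim adapters from reads by 7-nt anchor matching
#'
#' Locates the first occurrence of the last 7 nt of the 5' adapter and the
#' first occurrence, after it, of the first 7 nt of the 3' adapter; the
#' insert is the substring strictly between the anchors. Reads lacking
#' either anchor, with anchors out of order or abutting (empty insert), or
#' empty reads are rejected with a reason code.
#'
#' @param reads character vector of read sequences (DNA).
#' @param adapter_5p,adapter_3p adapter sequences, each at least 7 nt.
#' @return data.frame with columns \code{insert} (NA when rejected) and
#'   \code{reason} (\code{"ok"}, \code{"empty"}, \code{"no_5p_anchor"},
#'   \code{"no_3p_anchor"}, \code{"no_insert"}).
#' @examples
#' trimReads("ACGTACGTGACAGAAGAGAGTGAGCACTGCATGCNNN",
#'           adapter_5p = "ACGTACG", adapter_3p = "TGCATGC")
#' @export
trimReads <- function(reads, adapter_5p, adapter_3p) {
    adapter_5p <- toDNA(adapter_5p)
    adapter_3p <- toDNA(adapter_3p)
    stopifnot(nchar(adapter_5p) >= 7, nchar(adapter_3p) >= 7)
    a5 <- substr(adapter_5p, nchar(adapter_5p) - 6, nchar(adapter_5p))
    a3 <- substr(adapter_3p, 1, 7)

    reads <- toDNA(reads)
    n <- length(reads)
    insert <- rep(NA_character_, n)
    reason <- rep("ok", n)

    empty <- is.na(reads) | nchar(reads) == 0
    reason[empty] <- "empty"

    p5 <- rep(-1L, n)
    p5[!empty] <- regexpr(a5, reads[!empty], fixed = TRUE)
    no5 <- !empty & p5 < 0
    reason[no5] <- "no_5p_anchor"

    ok5 <- !empty & p5 > 0
    start <- p5 + 7L                       # first insert position
    rest <- substr(reads, start, nchar(reads))
    p3 <- rep(-1L, n)
    p3[ok5] <- regexpr(a3, rest[ok5], fixed = TRUE)
    no3 <- ok5 & p3 < 0
    reason[no3] <- "no_3p_anchor"

    hit <- ok5 & p3 > 0
    len <- p3 - 1L                         # insert length
    zero <- hit & len == 0
    reason[zero] <- "no_insert"
    keep <- hit & len > 0
    insert[keep] <- substr(rest[keep], 1L, len[keep])
    data.frame(insert = insert, reason = reason, stringsAsFactors = FALSE)
}

#' Collapse trimmed inserts into a filtered SignatureTable
#'
#' Drops inserts with ambiguous characters (anything outside A/C/G/T/U),
#' keeps lengths within \code{[min_len, max_len]}, collapses identical
#' sequences into signatures with per-library counts, and retains a
#' signature only when its count reaches \code{min_count} in at least one
#' library. Library sizes are the retained totals, recomputed after all
#' filters.
#'
#' @param inserts_A,inserts_B character vectors of inserts per library
#'   (NAs ignored).
#' @param min_len,max_len retained insert length window (nt).
#' @param min_count minimum per-library count (in at least one library).
#' @return a [SignatureTable-class]; empty input yields an empty table.
#' @export
collapseAndFilter <- function(inserts_A, inserts_B,
                              min_len = 18, max_len = 30, min_count = 3) {
    clean <- function(x) {
        x <- toDNA(x[!is.na(x)])
        x <- x[!grepl("[^ACGT]", x)]
        x[nchar(x) >= min_len & nchar(x) <= max_len]
    }
    a <- clean(inserts_A)
    b <- clean(inserts_B)
    seqs <- sort(unique(c(a, b)))
    if (length(seqs) == 0)
        return(SignatureTable(character(0), integer(0), integer(0)))
    ca <- table(factor(a, levels = seqs))
    cb <- table(factor(b, levels = seqs))
    keep <- pmax(ca, cb) >= min_count
    SignatureTable(seqs[keep], as.integer(ca[keep]), as.integer(cb[keep]))
}

#' Length distribution of a SignatureTable
#'
#' Two normalised distributions over lengths 18-30: by unique signatures
#' and by total reads (both libraries pooled).
#'
#' @param table a non-empty [SignatureTable-class].
#' @param lengths integer vector of lengths to tabulate over.
#' @return data.frame with columns \code{length}, \code{unique_frac},
#'   \code{reads_frac}; each fraction column sums to 1.
#' @export
lengthHistogram <- function(table, lengths = 18:30) {
    stopifnot(is(table, "SignatureTable"), length(table) > 0)
    len <- nchar(signatures(table))
    reads <- rowSums(signatureCounts(table))
    f <- factor(len, levels = lengths)
    uniq <- tabulate(f, nbins = length(lengths))
    tot <- vapply(split(reads, f), sum, numeric(1))
    data.frame(length = lengths,
               unique_frac = uniq / sum(uniq),
               reads_frac = as.numeric(tot) / sum(tot))
}

#' Process two FASTQ libraries into a SignatureTable
#'
#' Convenience wrapper: read FASTQ, trim both libraries, collapse and
#' filter.
#'
#' @param fastq_a,fastq_b FASTQ file paths for libraries A and B.
#' @param adapter_5p,adapter_3p adapter sequences.
#' @param min_len,max_len,min_count see [collapseAndFilter()].
#' @return a [SignatureTable-class]; trimming statistics are attached as
#'   attribute \code{"trim_stats"}.
#' @export
processLibraries <- function(fastq_a, fastq_b, adapter_5p, adapter_3p,
                             min_len = 18, max_len = 30, min_count = 3) {
    ta <- trimReads(readFastq(fastq_a), adapter_5p, adapter_3p)
    tb <- trimReads(readFastq(fastq_b), adapter_5p, adapter_3p)
    out <- collapseAndFilter(ta$insert, tb$insert,
                             min_len = min_len, max_len = max_len,
                             min_count = min_count)
    attr(out, "trim_stats") <- list(A = table(ta$reason), B = table(tb$reason))
    out
}
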