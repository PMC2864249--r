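# Signature classification: non-coding RNA classes, coding sense/antisense,
# known miRNA homology, and a category summary of the kind printed by
# comparative small RNA surveys (distinct counts, total counts, mean
# frequencies per library).
#
# Precedence follows the sequential exclusion implied by the field's
# standard workflow: ncRNA classes -> known miRNA -> novel candidates ->
# coding sense/antisense -> other.

# exact substring matching of signatures against a reference set, grouped
# by query width for Biostrings::PDict
matchSubstrings <- function(queries, subjects, both_strands = FALSE) {
    out <- data.frame(query = integer(), subject = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    if (length(queries) == 0 || length(subjects) == 0) return(out)
    subj <- Biostrings::DNAStringSet(unname(subjects))
    subj_rc <- if (both_strands) Biostrings::reverseComplement(subj) else NULL
    res <- list()
    for (w in unique(nchar(queries))) {
        qi <- which(nchar(queries) == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries[qi]))
        hits <- Biostrings::vwhichPDict(pd, subj)
        for (s in seq_along(hits)) {
            if (length(hits[[s]]))
                res[[length(res) + 1L]] <- data.frame(
                    query = qi[hits[[s]]], subject = s, strand = "+",
                    stringsAsFactors = FALSE)
        }
        if (both_strands) {
            hits <- Biostrings::vwhichPDict(pd, subj_rc)
            for (s in seq_along(hits)) {
                if (length(hits[[s]]))
                    res[[length(res) + 1L]] <- data.frame(
                        query = qi[hits[[s]]], subject = s, strand = "-",
                        stringsAsFactors = FALSE)
            }
        }
    }
    if (length(res)) out <- do.call(rbind, res)
    out[order(out$query, out$subject, out$strand), , drop = FALSE]
}

#' Assign signatures to non-coding RNA classes
#'
#' A signature matching any ncRNA reference record as an exact substring is
#' assigned that record's class (from a \code{class=} token in the FASTA
#' header) and is excluded from downstream miRNA discovery. When a
#' signature matches records of several classes, precedence is
#' rRNA > tRNA > snRNA > snoRNA.
#'
#' @param table a [SignatureTable-class].
#' @param ncrna named character vector of ncRNA reference sequences; names
#'   must carry \code{class=rRNA|tRNA|snRNA|snoRNA} tokens.
#' @param both_strands match the reverse complement too (default FALSE).
#' @return data.frame with \code{sequence}, \code{category},
#'   \code{hit_id} for matched signatures only.
#' @export
matchNoncoding <- function(table, ncrna, both_strands = FALSE) {
    stopifnot(is(table, "SignatureTable"))
    empty <- data.frame(sequence = character(), category = character(),
                        hit_id = character(), stringsAsFactors = FALSE)
    if (length(ncrna) == 0 || length(table) == 0) return(empty)
    cls <- sub(".*class=([A-Za-z]+).*", "\\1", names(ncrna))
    if (any(cls == names(ncrna)) ||
        !all(cls %in% c("rRNA", "tRNA", "snRNA", "snoRNA")))
        stop("ncRNA reference headers must carry class=rRNA|tRNA|snRNA|snoRNA tags")
    hits <- matchSubstrings(signatures(table), ncrna, both_strands)
    if (nrow(hits) == 0) return(empty)
    prec <- c(rRNA = 1, tRNA = 2, snRNA = 3, snoRNA = 4)
    hits$class <- cls[hits$subject]
    hits <- hits[order(hits$query, prec[hits$class], hits$subject), ]
    hits <- hits[!duplicated(hits$query), ]
    data.frame(sequence = signatures(table)[hits$query],
               category = hits$class,
               hit_id = sub(" .*", "", names(ncrna)[hits$subject]),
               stringsAsFactors = FALSE)
}

#' Match signatures perfectly to transcripts on both strands
#'
#' Perfect substring match to a transcript is a sense hit; perfect match to
#' its reverse complement is an antisense hit. All hits are reported; the
#' per-signature primary orientation is sense when any sense hit exists
#' (a signature matching both orientations is tallied in both but carries
#' the sense primary orientation).
#'
#' @param table a [SignatureTable-class].
#' @param transcripts named character vector of transcript sequences.
#' @return list with \code{hits} (data.frame: sequence, transcript_id,
#'   strand) and \code{primary} (data.frame: sequence, strand).
#' @export
matchTranscripts <- function(table, transcripts) {
    stopifnot(is(table, "SignatureTable"))
    sq <- signatures(table)
    h <- matchSubstrings(sq, transcripts, both_strands = TRUE)
    hits <- data.frame(sequence = sq[h$query],
                       transcript_id = names(transcripts)[h$subject],
                       strand = h$strand, stringsAsFactors = FALSE)
    if (nrow(h)) {
        strands <- split(h$strand, h$query)
        primary <- data.frame(
            sequence = sq[as.integer(names(strands))],
            strand = vapply(strands, function(s)
                if ("+" %in% s) "+" else "-", character(1)),
            stringsAsFactors = FALSE)
    } else {
        primary <- data.frame(sequence = character(), strand = character(),
                              stringsAsFactors = FALSE)
    }
    list(hits = hits, primary = primary)
}

# family token from a mature miRNA header, e.g. "ath-miR156a" -> "miR156"
mirnaFamily <- function(id) {
    m <- regmatches(id, regexpr("miR[0-9]+", id, ignore.case = TRUE))
    out <- rep(NA_character_, length(id))
    out[regexpr("miR[0-9]+", id, ignore.case = TRUE) > 0] <- m
    ifelse(is.na(out), id, out)
}

#' Assign signatures to known miRNAs by bounded-mismatch homology
#'
#' Distance is an ungapped sliding alignment over all offsets: mismatches
#' in the overlap plus one per unaligned overhang position, minimised over
#' offsets. A signature is assigned to its best reference when the distance
#' is at most \code{max_mm}; ties are broken by fewest mismatches, then
#' lexicographically smallest reference id. Input orientation is preserved
#' (miRNAs are strand-specific).
#'
#' @param table a [SignatureTable-class].
#' @param matures named character vector of mature miRNA reference
#'   sequences (miRBase-like ids).
#' @param max_mm maximum allowed distance (default 4).
#' @return data.frame with \code{sequence}, \code{hit_id}, \code{family},
#'   \code{mismatches} for assigned signatures only.
#' @export
matchKnownMirnas <- function(table, matures, max_mm = 4) {
    stopifnot(is(table, "SignatureTable"))
    empty <- data.frame(sequence = character(), hit_id = character(),
                        family = character(), mismatches = integer(),
                        stringsAsFactors = FALSE)
    if (length(matures) == 0 || length(table) == 0) return(empty)
    matures <- matures[order(names(matures))]   # id tie-break
    refs <- toDNA(matures)
    res <- .best_reference_distance(signatures(table), unname(refs))
    keep <- which(res$distance <= max_mm)
    if (!length(keep)) return(empty)
    ids <- names(refs)[res$which[keep]]
    data.frame(sequence = signatures(table)[keep],
               hit_id = ids, family = mirnaFamily(ids),
               mismatches = res$distance[keep], stringsAsFactors = FALSE)
}

.CATEGORIES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "known_miRNA",
                 "novel_miRNA_candidate", "coding_sense",
                 "coding_antisense", "other")

#' Assign one primary category per signature
#'
#' Applies the precedence ncRNA classes, then known miRNA, then novel
#' miRNA (sequences called by the hairpin-discovery stage, mature or
#' star), then coding sense/antisense, then other.
#'
#' @param table a [SignatureTable-class].
#' @param nc output of [matchNoncoding()].
#' @param known output of [matchKnownMirnas()].
#' @param tx output of [matchTranscripts()].
#' @param novel character vector of signature sequences called novel
#'   (matures and stars), DNA or RNA alphabet.
#' @return data.frame (one row per signature): \code{sequence},
#'   \code{category}, \code{hit_id}, \code{mismatches}, \code{strand}.
#' @export
categorizeSignatures <- function(table, nc, known, tx,
                                 novel = character(0)) {
    sq <- signatures(table)
    n <- length(sq)
    cat <- rep("other", n)
    hit <- rep("", n)
    mm <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)

    i <- match(tx$primary$sequence, sq)
    cat[i] <- ifelse(tx$primary$strand == "+", "coding_sense",
                     "coding_antisense")
    strand[i] <- tx$primary$strand

    i <- match(intersect(toDNA(novel), sq), sq)
    cat[i] <- "novel_miRNA_candidate"

    i <- match(known$sequence, sq)
    cat[i] <- "known_miRNA"
    hit[i] <- known$hit_id
    mm[i] <- known$mismatches

    i <- match(nc$sequence, sq)
    cat[i] <- nc$category
    hit[i] <- nc$hit_id
    mm[i] <- 0L

    data.frame(sequence = sq, category = cat, hit_id = hit,
               mismatches = mm, strand = strand, stringsAsFactors = FALSE)
}

#' Per-category library summary (distinct, total, mean frequency)
#'
#' For each library separately (a signature counts towards a library only
#' if its count there is positive): the number of distinct signatures per
#' category, the total read count, the percentage of the library totals,
#' and the mean frequency (total / distinct).
#'
#' @param table a [SignatureTable-class].
#' @param records output of [categorizeSignatures()].
#' @return data.frame with one row per category plus a \code{total} row.
#' @export
summarizeCategories <- function(table, records) {
    cnt <- signatureCounts(table)
    stopifnot(nrow(records) == length(table))
    one <- function(lib) {
        present <- cnt[, lib] > 0
        f <- factor(records$category[present], levels = .CATEGORIES)
        distinct <- tabulate(f, nbins = length(.CATEGORIES))
        total <- vapply(split(cnt[present, lib], f), sum, numeric(1))
        list(distinct = distinct, total = as.numeric(total))
    }
    A <- one("A"); B <- one("B")
    mean_freq <- function(tot, dis) ifelse(dis > 0, tot / dis, NA_real_)
    df <- data.frame(
        category = .CATEGORIES,
        distinct_A = A$distinct, distinct_B = B$distinct,
        total_A = A$total, total_B = B$total,
        pct_distinct_A = 100 * A$distinct / max(1, sum(A$distinct)),
        pct_distinct_B = 100 * B$distinct / max(1, sum(B$distinct)),
        pct_total_A = 100 * A$total / max(1, sum(A$total)),
        pct_total_B = 100 * B$total / max(1, sum(B$total)),
        mean_freq_A = mean_freq(A$total, A$distinct),
        mean_freq_B = mean_freq(B$total, B$distinct),
        stringsAsFactors = FALSE)
    tot <- data.frame(category = "total",
                      distinct_A = sum(A$distinct), distinct_B = sum(B$distinct),
                      total_A = sum(A$total), total_B = sum(B$total),
                      pct_distinct_A = 100, pct_distinct_B = 100,
                      pct_total_A = 100, pct_total_B = 100,
                      mean_freq_A = mean_freq(sum(A$total), sum(A$distinct)),
                      mean_freq_B = mean_freq(sum(B$total), sum(B$distinct)),
                      stringsAsFactors = FALSE)
    rbind(df, tot)
}

#' Aggregate signature counts into per-miRNA counts
#'
#' Known miRNA signatures are summed per family; novel matures are counted
#' by their exact mature sequence.
#'
#' @param table a [SignatureTable-class].
#' @param known output of [matchKnownMirnas()].
#' @param novel_matures named character vector (id -> mature sequence) of
#'   called novel miRNAs (optional).
#' @return data.frame \code{id}, \code{x1}, \code{x2} with a
#'   \code{librarySizes} attribute, suitable for [profileDifferential()].
#' @export
mirnaCountMatrix <- function(table, known, novel_matures = character(0)) {
    sq <- signatures(table)
    cnt <- signatureCounts(table)
    rows <- list()
    if (nrow(known)) {
        i <- match(known$sequence, sq)
        agg_a <- tapply(cnt[i, "A"], known$family, sum)
        agg_b <- tapply(cnt[i, "B"], known$family, sum)
        rows[[1]] <- data.frame(id = names(agg_a),
                                x1 = as.numeric(agg_a),
                                x2 = as.numeric(agg_b),
                                stringsAsFactors = FALSE)
    }
    if (length(novel_matures)) {
        i <- match(toDNA(novel_matures), sq)
        rows[[length(rows) + 1L]] <- data.frame(
            id = names(novel_matures),
            x1 = ifelse(is.na(i), 0, cnt[i, "A"]),
            x2 = ifelse(is.na(i), 0, cnt[i, "B"]),
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(id = character(), x1 = numeric(), x2 = numeric(),
                           stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out <- out[order(out$id), , drop = FALSE]
    attr(out, "librarySizes") <- librarySizes(table)
    out
}
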