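# Plant miRNA target prediction by complementarity penalty scoring, and
# the miRNA-target "hotspot" small RNA statistics.
#
# Scoring scheme (plant convention): per aligned position, match 0, G:U
# wobble 0.5, mismatch 1, gap/bulged base 2; penalties double at miRNA
# positions 2-13 from the 5' end. A site is the transcript window whose
# reverse-complement orientation aligns to the miRNA, with at most one
# single-nucleotide bulge.

.DEFAULT_SCORING <- list(wobble = 0.5, mismatch = 1, gap = 2,
                         core = c(2L, 13L))

siteBasePenalty <- function(m, t, pos, sc = .DEFAULT_SCORING) {
    pen <- if ((m == "A" && t == "T") || (m == "T" && t == "A") ||
               (m == "G" && t == "C") || (m == "C" && t == "G")) 0
           else if ((m == "G" && t == "T") || (m == "T" && t == "G"))
               sc$wobble
           else sc$mismatch
    if (pos >= sc$core[1] && pos <= sc$core[2]) pen <- 2 * pen
    pen
}

#' Score one miRNA/site alignment
#'
#' The site is given 5'->3' in transcript orientation and is aligned
#' end-to-end against the miRNA: ungapped when site and miRNA lengths are
#' equal; one bulged site base when the site is one longer; one unpaired
#' miRNA base when one shorter. For bulged alignments the minimum score
#' over all bulge placements is returned.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA).
#' @param site target site sequence, 5'->3' (length within miRNA length
#'   plus or minus 1).
#' @param scoring penalty scheme (see package defaults).
#' @return numeric penalty score (>= 0).
#' @examples
#' scoreSite("UGACAGAAGAGAGUGAGCAC", revComp(toDNA("UGACAGAAGAGAGUGAGCAC")))
#' @export
scoreSite <- function(mirna, site, scoring = .DEFAULT_SCORING) {
    m <- strsplit(toDNA(mirna), "")[[1]]
    s <- strsplit(toDNA(site), "")[[1]]
    L <- length(m); Ls <- length(s)
    core_pen <- function(pos, pen)
        if (pos >= scoring$core[1] && pos <= scoring$core[2]) 2 * pen else pen
    if (Ls == L) {
        sum(vapply(seq_len(L), function(i)
            siteBasePenalty(m[i], s[L + 1 - i], i, scoring), numeric(1)))
    } else if (Ls == L + 1) {
        # one bulged site base between miRNA positions b and b+1
        min(vapply(seq_len(L - 1), function(b) {
            core_pen(b + 1, scoring$gap) +
                sum(vapply(seq_len(L), function(i) {
                    sidx <- if (i <= b) Ls + 1 - i else Ls - i
                    siteBasePenalty(m[i], s[sidx], i, scoring)
                }, numeric(1)))
        }, numeric(1)))
    } else if (Ls == L - 1) {
        # one unpaired (bulged) miRNA base at position b
        min(vapply(2:(L - 1), function(b) {
            core_pen(b, scoring$gap) +
                sum(vapply(setdiff(seq_len(L), b), function(i) {
                    sidx <- if (i < b) Ls + 1 - i else Ls + 2 - i
                    siteBasePenalty(m[i], s[sidx], i, scoring)
                }, numeric(1)))
        }, numeric(1)))
    } else stop("site length must be within miRNA length +/- 1")
}

# three-line alignment strings: miRNA 5'->3', match line, site 3'->5'
alignmentStrings <- function(mirna, site, btype, bpos) {
    m <- strsplit(toDNA(mirna), "")[[1]]
    s <- rev(strsplit(toDNA(site), "")[[1]])  # site 3'->5'
    L <- length(m)
    if (btype == 1) m <- append(m, "-", after = bpos)
    if (btype == 2) s <- append(s, "-", after = bpos - 1)
    sym <- vapply(seq_along(m), function(i) {
        a <- m[i]; b <- s[i]
        if (a == "-" || b == "-") " "
        else if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
                 (a == "G" && b == "C") || (a == "C" && b == "G")) "|"
        else if ((a == "G" && b == "T") || (a == "T" && b == "G")) "o"
        else " "
    }, character(1))
    c(mirna = toRNA(paste(m, collapse = "")),
      match = paste(sym, collapse = ""),
      site = toRNA(paste(s, collapse = "")))
}

#' Predict miRNA target sites on transcripts by penalty scoring
#'
#' Scans every transcript window of miRNA length (plus single-bulge
#' variants) and reports the best-scoring variant per start position when
#' its penalty is at most \code{cutoff}. Hits are sorted by (score,
#' transcript id, site start).
#'
#' @param mirnas named character vector of miRNA sequences (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum penalty score (default 4.0, the common plant
#'   convention).
#' @param allow_bulge permit one single-nucleotide bulge per duplex
#'   (default TRUE).
#' @param scoring penalty scheme.
#' @return data.frame: \code{mirna_id}, \code{transcript_id},
#'   \code{site_start}, \code{site_end} (0-based half-open),
#'   \code{score}, \code{align_mirna}, \code{align_match},
#'   \code{align_site}, \code{duplex_pseudo_energy} (diagnostic weighted
#'   pair sum, not a thermodynamic energy).
#' @export
predictTargets <- function(mirnas, transcripts, cutoff = 4.0,
                           allow_bulge = TRUE, scoring = .DEFAULT_SCORING) {
    cols <- data.frame(mirna_id = character(), transcript_id = character(),
                       site_start = integer(), site_end = integer(),
                       score = numeric(), align_mirna = character(),
                       align_match = character(), align_site = character(),
                       duplex_pseudo_energy = numeric(),
                       stringsAsFactors = FALSE)
    if (!length(mirnas) || !length(transcripts)) return(cols)
    mirnas <- toDNA(mirnas)
    transcripts <- toDNA(transcripts)
    rows <- list()
    for (mid in names(mirnas)) {
        for (tid in names(transcripts)) {
            h <- .scan_target_sites(mirnas[[mid]], transcripts[[tid]],
                                    cutoff, scoring$gap, scoring$wobble,
                                    scoring$mismatch, scoring$core[1],
                                    scoring$core[2], allow_bulge)
            if (!nrow(h)) next
            site <- substring(transcripts[[tid]], h$start + 1, h$end)
            al <- mapply(alignmentStrings, mirnas[[mid]], site, h$btype,
                         h$bpos)
            n_wc <- vapply(seq_len(nrow(h)), function(i)
                sum(strsplit(al[2, i], "")[[1]] == "|"), numeric(1))
            n_gu <- vapply(seq_len(nrow(h)), function(i)
                sum(strsplit(al[2, i], "")[[1]] == "o"), numeric(1))
            rows[[length(rows) + 1L]] <- data.frame(
                mirna_id = mid, transcript_id = tid,
                site_start = h$start, site_end = h$end, score = h$score,
                align_mirna = al[1, ], align_match = al[2, ],
                align_site = al[3, ],
                duplex_pseudo_energy = n_wc + 0.5 * n_gu,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(cols)
    out <- do.call(rbind, rows)
    out <- out[order(out$score, out$transcript_id, out$site_start,
                     out$mirna_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Small RNA hotspot statistics over predicted miRNA-target genes
#'
#' For each predicted target gene and each library, classifies the gene by
#' whether perfectly matching signatures exist on the sense strand, the
#' antisense strand, both, or neither, and reports inclusive tallies
#' (sense includes both, antisense includes both), exclusive tallies, the
#' overlap, and the total with either orientation, with percentages of
#' the target-gene set.
#'
#' @param target_gene_ids character vector of predicted target gene ids.
#' @param tx_hits perfect-match hit table from [matchTranscripts()]
#'   (element \code{hits}).
#' @param table the [SignatureTable-class] (per-library presence requires
#'   a positive count in that library).
#' @return data.frame with one row per library (A, B): \code{n_targets},
#'   inclusive/exclusive sense and antisense counts, \code{n_both},
#'   \code{n_either}, and the corresponding percentages.
#' @export
hotspotStats <- function(target_gene_ids, tx_hits, table) {
    target_gene_ids <- unique(target_gene_ids)
    sq <- signatures(table)
    cnt <- signatureCounts(table)
    one <- function(lib) {
        present <- sq[cnt[, lib] > 0]
        h <- tx_hits[tx_hits$sequence %in% present &
                     tx_hits$transcript_id %in% target_gene_ids, ,
                     drop = FALSE]
        sense <- unique(h$transcript_id[h$strand == "+"])
        anti <- unique(h$transcript_id[h$strand == "-"])
        both <- intersect(sense, anti)
        either <- union(sense, anti)
        n <- length(target_gene_ids)
        pct <- function(k) if (n > 0) 100 * k / n else 0
        data.frame(library = lib, n_targets = n,
                   n_sense_incl = length(sense),
                   n_antisense_incl = length(anti),
                   n_sense_only = length(setdiff(sense, anti)),
                   n_antisense_only = length(setdiff(anti, sense)),
                   n_both = length(both), n_either = length(either),
                   pct_sense_incl = pct(length(sense)),
                   pct_antisense_incl = pct(length(anti)),
                   pct_both = pct(length(both)),
                   pct_either = pct(length(either)),
                   stringsAsFactors = FALSE)
    }
    rbind(one("A"), one("B"))
}

#' Fraction of antisense-sRNA genes that also bear sense sRNAs
#'
#' Per library: among genes producing perfectly matching antisense
#' signatures, the fraction that also produce sense signatures (the
#' cognate-sense-transcript fraction).
#'
#' @param tx_hits hit table from [matchTranscripts()] (element
#'   \code{hits}).
#' @param table the [SignatureTable-class].
#' @return named numeric of length 2 (A, B); NA when no gene has
#'   antisense signatures.
#' @export
antisenseCognateFraction <- function(tx_hits, table) {
    sq <- signatures(table)
    cnt <- signatureCounts(table)
    one <- function(lib) {
        present <- sq[cnt[, lib] > 0]
        h <- tx_hits[tx_hits$sequence %in% present, , drop = FALSE]
        sense <- unique(h$transcript_id[h$strand == "+"])
        anti <- unique(h$transcript_id[h$strand == "-"])
        if (!length(anti)) return(NA_real_)
        length(intersect(anti, sense)) / length(anti)
    }
    c(A = one("A"), B = one("B"))
}
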