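# Novel miRNA discovery: candidate precursor windows around perfect
# transcript matches, maximum-weight nested folding, plant-miRNA
# structural criteria, and the sequenced-miRNA* evidence requirement.

#' Fold a sequence by maximum-weight nested base pairing
#'
#' Nussinov-style dynamic programming over Watson-Crick (weight 1) and G:U
#' wobble pairs (weight \code{wobble_weight}), with hairpin loops of at
#' least \code{min_loop} unpaired bases and a deterministic traceback
#' (each subproblem's 5'-most base pairs its 3'-most admissible partner
#' whenever pairing achieves the optimum). This tests stem-loop geometry;
#' it does not estimate thermodynamic free energies.
#'
#' @param sequence RNA or DNA string, length at most 400.
#' @param min_loop minimum unpaired bases in a hairpin loop (default 3).
#' @param wobble_weight weight of a G:U pair (default 1.0).
#' @return a [FoldResult-class].
#' @examples
#' foldRna("GGGGAAAACCCC")
#' @export
foldRna <- function(sequence, min_loop = 3, wobble_weight = 1.0) {
    seq <- toDNA(sequence)
    if (grepl("[^ACGT]", seq)) stop("invalid characters in sequence")
    if (nchar(seq) > 400) stop("sequence longer than 400 nt")
    res <- .fold_nussinov(seq, as.integer(min_loop), wobble_weight)
    p <- res$partner
    db <- rep(".", length(p))
    db[p > seq_along(p)] <- "("
    db[p > 0 & p < seq_along(p)] <- ")"
    new("FoldResult", sequence = seq,
        structure = paste(db, collapse = ""),
        partner = as.integer(p), score = res$score)
}

#' Extract candidate precursor windows around perfect transcript matches
#'
#' For every perfect match of a candidate mature signature to a transcript
#' (forward strand) or to its reverse complement (window evaluated on the
#' reverse-complemented transcript), one window is produced per flank
#' configuration, clipped at the transcript ends; duplicates are removed.
#'
#' @param candidates character vector of candidate mature sequences (DNA).
#' @param transcripts named character vector of transcript sequences.
#' @param flank_sets list of length-2 numeric vectors (5' flank, 3' flank)
#'   in window orientation.
#' @param mature_len_range retained candidate lengths (plant mature miRNA
#'   lengths by default).
#' @return data.frame: \code{mature_seq}, \code{transcript_id},
#'   \code{strand}, \code{window} (window sequence in match orientation),
#'   \code{mature_off} (0-based offset of the mature in the window),
#'   \code{win_start}, \code{win_end} (0-based half-open, forward
#'   transcript coordinates).
#' @export
extractCandidates <- function(candidates, transcripts,
                              flank_sets = list(c(100, 20), c(20, 100),
                                                c(60, 60)),
                              mature_len_range = c(20, 24)) {
    candidates <- unique(toDNA(candidates))
    len <- nchar(candidates)
    candidates <- candidates[len >= mature_len_range[1] &
                             len <= mature_len_range[2]]
    out <- data.frame(mature_seq = character(), transcript_id = character(),
                      strand = character(), window = character(),
                      mature_off = integer(), win_start = integer(),
                      win_end = integer(), stringsAsFactors = FALSE)
    if (!length(candidates) || !length(transcripts)) return(out)

    hits <- matchSubstrings(candidates, transcripts, both_strands = TRUE)
    if (!nrow(hits)) return(out)

    rc_tx <- revComp(transcripts)
    rows <- list()
    for (k in seq_len(nrow(hits))) {
        q <- hits$query[k]; s <- hits$subject[k]; st <- hits$strand[k]
        mat <- candidates[q]
        subj <- if (st == "+") transcripts[[s]] else rc_tx[[s]]
        L <- nchar(subj)
        pos <- as.integer(gregexpr(mat, subj, fixed = TRUE)[[1]])  # 1-based
        for (p in pos) {
            for (fl in flank_sets) {
                a <- max(1L, p - as.integer(fl[1]))
                b <- min(L, p + nchar(mat) - 1L + as.integer(fl[2]))
                # forward-transcript coordinates, 0-based half-open
                ws <- if (st == "+") a - 1L else L - b
                we <- if (st == "+") b else L - a + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    mature_seq = mat,
                    transcript_id = names(transcripts)[s], strand = st,
                    window = substr(subj, a, b),
                    mature_off = p - a, win_start = ws, win_end = we,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    out[!duplicated(out[, c("mature_seq", "window", "mature_off")]), ,
        drop = FALSE]
}

#' Forward-coordinate loci of perfect signature matches on transcripts
#'
#' @param seqs character vector of signature sequences (DNA).
#' @param transcripts named character vector.
#' @return data.frame: sequence, transcript_id, strand, start, end
#'   (0-based half-open forward transcript coordinates).
#' @export
perfectHitLoci <- function(seqs, transcripts) {
    out <- data.frame(sequence = character(), transcript_id = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    seqs <- unique(toDNA(seqs))
    if (!length(seqs) || !length(transcripts)) return(out)
    hits <- matchSubstrings(seqs, transcripts, both_strands = TRUE)
    if (!nrow(hits)) return(out)
    rc_tx <- revComp(transcripts)
    rows <- list()
    for (k in seq_len(nrow(hits))) {
        q <- hits$query[k]; s <- hits$subject[k]; st <- hits$strand[k]
        subj <- if (st == "+") transcripts[[s]] else rc_tx[[s]]
        L <- nchar(subj)
        w <- nchar(seqs[q])
        pos <- as.integer(gregexpr(seqs[q], subj, fixed = TRUE)[[1]])
        for (p in pos) {
            a <- if (st == "+") p - 1L else L - (p + w - 1L)
            rows[[length(rows) + 1L]] <- data.frame(
                sequence = seqs[q], transcript_id = names(transcripts)[s],
                strand = st, start = a, end = a + w,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

# smallest most-frequent value
statMode <- function(x) {
    t <- table(x)
    as.integer(names(t)[which.max(t)])
}

# Project the miRNA* region implied by the mature's duplex pairing.
# Under the canonical duplex geometry (2-nt 3' overhangs on both strands)
# every paired duplex position i (0-based, i in 0..L-3) with 0-based
# partner pp implies star boundaries s0 = pp - (L-3-i) and
# e = pp + i + 2 (inclusive), on either arm. Partners inside the mature
# are ignored; the dominant side (up- or downstream) defines the arm; each
# boundary takes the most frequent projection from the half of the duplex
# nearest to it, which tolerates terminal fraying and stray pairs and
# reproduces bulge-induced star length differences.
projectStar <- function(fold, mature_off, mature_len) {
    p <- pairMap(fold)
    L <- mature_len
    m1 <- mature_off + 1L                       # 1-based mature start
    m2 <- mature_off + L                        # 1-based mature end
    i0 <- seq_len(L - 2L) - 1L
    part <- p[m1 + i0]
    ok <- part > 0L & (part < m1 | part > m2)   # paired outside the mature
    if (sum(ok) < 2L) return(NULL)
    i0 <- i0[ok]
    pp <- part[ok] - 1L
    up <- pp > (m2 - 1L)
    dominant_up <- sum(up) >= sum(!up)
    keep <- up == dominant_up
    if (sum(keep) < 2L) return(NULL)
    i0 <- i0[keep]; pp <- pp[keep]
    s0_proj <- pp - (L - 3L - i0)
    e_proj <- pp + i0 + 2L
    n <- length(i0)
    upper <- which(rank(i0, ties.method = "first") > n / 2)
    lower <- which(rank(i0, ties.method = "first") <= n / 2)
    if (!length(upper)) upper <- seq_len(n)
    if (!length(lower)) lower <- seq_len(n)
    s0 <- statMode(s0_proj[upper])
    e <- statMode(e_proj[lower])
    if (e <= s0) return(NULL)
    list(star_start = s0, star_end = e + 1L,    # 0-based half-open
         arm = if (dominant_up) "5p" else "3p",
         duplex_i0 = i0, duplex_pp = pp)
}

#' Evaluate plant-miRNA hairpin criteria for a mature within a fold
#'
#' Passes when (a) the mature lies on one arm of a stem-loop and does not
#' span the terminal loop (all duplex partners on one side, none inside
#' the mature), (b) at most \code{max_duplex_mm} positions of the mature
#' duplex region (the mature minus its canonical 2-nt 3' overhang) are
#' unpaired, (c) no asymmetric internal bulge in the duplex exceeds
#' \code{max_asym_bulge}, and (d) the paired fraction of the whole mature
#' is at least \code{min_paired_frac}.
#'
#' @param fold a [FoldResult-class] of the candidate window.
#' @param mature_off 0-based offset of the mature in the window.
#' @param mature_len mature length (nt).
#' @param max_duplex_mm,max_asym_bulge,min_paired_frac structural
#'   thresholds encoding the community conventions for plant miRNA
#'   annotation (configurable).
#' @return list with \code{pass}, \code{reason} (\code{"ok"},
#'   \code{"spans_loop"}, \code{"bad_structure"}), \code{arm}
#'   (\code{"5p"}/\code{"3p"}/NA).
#' @export
evaluateHairpin <- function(fold, mature_off, mature_len,
                            max_duplex_mm = 4, max_asym_bulge = 2,
                            min_paired_frac = 0.60) {
    proj <- projectStar(fold, mature_off, mature_len)
    if (is.null(proj))
        return(list(pass = FALSE, reason = "bad_structure", arm = NA))
    m1 <- mature_off + 1L
    m2 <- mature_off + mature_len
    # star region overlapping the mature means the mature straddles the
    # terminal loop of its own stem
    if (proj$star_start < m2 && m1 - 1L < proj$star_end)
        return(list(pass = FALSE, reason = "spans_loop", arm = NA))
    if (proj$star_start < 0L || proj$star_end > nchar(fold@sequence))
        return(list(pass = FALSE, reason = "bad_structure", arm = proj$arm))

    # A duplex position is consistent when it pairs into the projected
    # star region in (close to) the dominant register; the register
    # deviation of a position is exactly the asymmetric-bulge size at that
    # point of the duplex, so |deviation| > max_asym_bulge marks it
    # inconsistent. Unpaired or inconsistent duplex positions are the
    # duplex mismatches.
    p <- pairMap(fold)
    mi <- m1:m2
    L <- mature_len
    i0_all <- seq_len(L) - 1L
    part <- p[mi]
    in_star <- part > proj$star_start & part <= proj$star_end
    s0_proj <- (part - 1L) - (L - 3L - i0_all)
    s0_mode <- statMode(s0_proj[in_star & i0_all <= L - 3L])
    consistent <- in_star & abs(s0_proj - s0_mode) <= max_asym_bulge

    mm <- sum(!consistent[seq_len(L - 2L)])   # minus canonical 3' overhang
    if (mm > max_duplex_mm)
        return(list(pass = FALSE, reason = "bad_structure", arm = proj$arm))

    if (sum(consistent) / L < min_paired_frac)
        return(list(pass = FALSE, reason = "bad_structure", arm = proj$arm))

    list(pass = TRUE, reason = "ok", arm = proj$arm)
}

#' Locate the miRNA* of a mature within a fold
#'
#' The star is the region pairing with the mature, shifted to give the
#' canonical 2-nt 3' overhang on both duplex ends. Both star boundaries
#' are projected from the paired duplex positions under that geometry;
#' each boundary takes the most frequent projection from the half of the
#' duplex nearest to it, which makes the result robust to terminal fraying
#' and reproduces bulge-induced length differences.
#'
#' @param fold a [FoldResult-class] of the window.
#' @param mature_off,mature_len 0-based mature offset and length.
#' @return list with \code{star_seq}, \code{star_start}, \code{star_end}
#'   (0-based half-open in window coordinates), or NULL when no duplex
#'   pairing exists or the projection leaves the window.
#' @export
findStar <- function(fold, mature_off, mature_len) {
    proj <- projectStar(fold, mature_off, mature_len)
    if (is.null(proj)) return(NULL)
    if (proj$star_start < 0L || proj$star_end > nchar(fold@sequence))
        return(NULL)
    list(star_seq = substr(fold@sequence, proj$star_start + 1L,
                           proj$star_end),
         star_start = proj$star_start, star_end = proj$star_end,
         arm = proj$arm)
}

#' Call novel miRNAs from candidate windows with miRNA* evidence
#'
#' Folds every candidate window, applies [evaluateHairpin()], locates the
#' star with [findStar()], and accepts a candidate only when its star
#' sequence is present in the signature table (count at least 1 in either
#' library, exact match). One call is kept per distinct mature (the
#' best-scoring precursor); when two accepted calls come from the same
#' precursor locus (overlapping transcript intervals, either strand —
#' the reverse complement of a hairpin is the same locus), only the most
#' abundant call is reported as the mature and the others are marked
#' \code{secondary_arm}, the field's convention for miRNA/miRNA* pairs.
#'
#' @param candidates output of [extractCandidates()].
#' @param table the [SignatureTable-class] (for star lookup and counts).
#' @param min_loop,wobble_weight folding parameters, see [foldRna()].
#' @param max_duplex_mm,max_asym_bulge,min_paired_frac see
#'   [evaluateHairpin()].
#' @param exclude_loci optional data.frame (\code{transcript_id},
#'   \code{start}, \code{end}) of annotated miRNA loci; candidate windows
#'   overlapping them (either strand) are skipped, the usual masking of
#'   known precursors before novel discovery.
#' @return data.frame with one row per distinct candidate mature:
#'   sequence, locus, arm, star sequence and counts, fold score,
#'   dot-bracket, and \code{status} (\code{accepted}, \code{no_star},
#'   \code{bad_structure}, \code{secondary_arm}).
#' @export
callNovelMirnas <- function(candidates, table, min_loop = 3,
                            wobble_weight = 1.0, max_duplex_mm = 4,
                            max_asym_bulge = 2, min_paired_frac = 0.60,
                            exclude_loci = NULL) {
    if (!is.null(exclude_loci) && nrow(exclude_loci) &&
        nrow(candidates)) {
        drop <- vapply(seq_len(nrow(candidates)), function(i) {
            e <- exclude_loci[exclude_loci$transcript_id ==
                              candidates$transcript_id[i], , drop = FALSE]
            any(candidates$win_start[i] < e$end &
                e$start < candidates$win_end[i])
        }, logical(1))
        candidates <- candidates[!drop, , drop = FALSE]
    }
    cols <- c("mature_seq", "transcript_id", "strand", "precursor_start",
              "precursor_end", "mature_arm", "star_seq", "star_count_A",
              "star_count_B", "mature_count_A", "mature_count_B",
              "fold_score", "dot_bracket", "status")
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols), stringsAsFactors = FALSE)
    if (!nrow(candidates)) return(empty)

    sq <- signatures(table)
    cnt <- signatureCounts(table)
    lookup <- function(s) {
        i <- match(s, sq)
        if (is.na(i)) c(0L, 0L) else c(cnt[i, "A"], cnt[i, "B"])
    }

    rows <- list()
    for (mat in unique(candidates$mature_seq)) {
        sub <- candidates[candidates$mature_seq == mat, , drop = FALSE]
        best <- NULL
        for (k in seq_len(nrow(sub))) {
            fold <- foldRna(sub$window[k], min_loop, wobble_weight)
            verdict <- evaluateHairpin(fold, sub$mature_off[k], nchar(mat),
                                       max_duplex_mm, max_asym_bulge,
                                       min_paired_frac)
            if (!verdict$pass) next
            star <- findStar(fold, sub$mature_off[k], nchar(mat))
            if (is.null(star)) next
            if (is.null(best) || foldScore(fold) > best$score)
                best <- list(k = k, fold = fold, verdict = verdict,
                             star = star, score = foldScore(fold))
        }
        mc <- lookup(mat)
        if (is.null(best)) {
            rows[[length(rows) + 1L]] <- data.frame(
                mature_seq = mat, transcript_id = sub$transcript_id[1],
                strand = sub$strand[1],
                precursor_start = sub$win_start[1],
                precursor_end = sub$win_end[1],
                mature_arm = NA_character_, star_seq = NA_character_,
                star_count_A = 0L, star_count_B = 0L,
                mature_count_A = mc[1], mature_count_B = mc[2],
                fold_score = NA_real_, dot_bracket = NA_character_,
                status = "bad_structure", stringsAsFactors = FALSE)
            next
        }
        sc <- lookup(best$star$star_seq)
        rows[[length(rows) + 1L]] <- data.frame(
            mature_seq = mat,
            transcript_id = sub$transcript_id[best$k],
            strand = sub$strand[best$k],
            precursor_start = sub$win_start[best$k],
            precursor_end = sub$win_end[best$k],
            mature_arm = best$verdict$arm,
            star_seq = best$star$star_seq,
            star_count_A = sc[1], star_count_B = sc[2],
            mature_count_A = mc[1], mature_count_B = mc[2],
            fold_score = best$score,
            dot_bracket = dotBracket(best$fold),
            status = if (sum(sc) >= 1) "accepted" else "no_star",
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)

    # locus deduplication: among accepted calls sharing an overlapping
    # window on the same transcript and strand, the more abundant arm is
    # the mature; the other is its star.
    acc <- which(out$status == "accepted")
    if (length(acc) > 1) {
        ord <- acc[order(-(out$mature_count_A[acc] + out$mature_count_B[acc]),
                         out$mature_seq[acc])]
        taken <- logical(0)
        kept <- integer(0)
        for (i in ord) {
            clash <- FALSE
            for (j in kept) {
                if (out$transcript_id[i] == out$transcript_id[j] &&
                    out$precursor_start[i] < out$precursor_end[j] &&
                    out$precursor_start[j] < out$precursor_end[i]) {
                    clash <- TRUE
                    break
                }
            }
            if (clash) out$status[i] <- "secondary_arm"
            else kept <- c(kept, i)
        }
    }
    rownames(out) <- NULL
    out[order(out$status != "accepted", out$mature_seq), , drop = FALSE]
}
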