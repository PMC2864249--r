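# Folding engine, hairpin criteria, star geometry and novel calling.

test_that("fold handles trivial and constructed cases", {
    f <- foldRna("AAAAAAAAAA")
    expect_equal(foldScore(f), 0)
    expect_equal(dotBracket(f), strrep(".", 10))

    f2 <- foldRna("GGGGAAAACCCC")
    expect_equal(foldScore(f2), 4)
    expect_equal(dotBracket(f2), "((((....))))")

    expect_error(foldRna("ACGTN"), "invalid")
    expect_error(foldRna(strrep("A", 401)), "400")
})

test_that("fold structures are valid: balanced, symmetric, min-loop, legal pairs", {
    set.seed(14)
    for (r in 1:25) {
        s <- randomDna(sample(20:80, 1))
        f <- foldRna(s)
        p <- pairMap(f)
        paired <- which(p > 0)
        expect_true(all(p[p[paired]] == paired))           # symmetry
        x <- strsplit(s, "")[[1]]
        for (i in paired[p[paired] > paired]) {
            j <- p[i]
            expect_gt(j - i, 3)                            # min loop
            expect_true(oraclePairWeight(x[i], x[j]) > 0)  # legal pair
        }
        # dot-bracket brackets balance
        db <- strsplit(dotBracket(f), "")[[1]]
        expect_equal(sum(db == "("), sum(db == ")"))
    }
})

test_that("DP fold score equals the exhaustive structure-enumeration oracle", {
    set.seed(5)
    for (r in 1:60) {
        n <- sample(5:13, 1)
        s <- randomDna(n)
        wv <- sample(c(1, 0.5), 1)
        expect_equal(foldScore(foldRna(s, wobble_weight = wv)),
                     oracleFoldScore(s, 3, wv), info = s)
    }
})

test_that("fold is deterministic for fixed input", {
    s <- randomDna(120)
    expect_identical(dotBracket(foldRna(s)), dotBracket(foldRna(s)))
})

test_that("a mature centred on the terminal loop is rejected as spans_loop", {
    stem5 <- randomDna(30)
    hp <- paste0(stem5, "AACAA", revComp(stem5))
    f <- foldRna(hp)
    # mature straddling the loop: starts on the 5' arm, ends on the 3' arm
    v <- evaluateHairpin(f, 15, 21)
    expect_false(v$pass)
    expect_equal(v$reason, "spans_loop")
})

test_that("an unstructured window is rejected", {
    v <- evaluateHairpin(foldRna(strrep("A", 100)), 40, 21)
    expect_false(v$pass)
    expect_equal(v$reason, "bad_structure")
})

test_that("star geometry: perfect duplex and bulged duplex", {
    # perfect 22-nt duplex planted on the 5' arm
    mat <- paste0(randomDna(20), "AC")
    star <- paste0(revComp(substr(mat, 1, 20)), "CA")
    hp <- paste0("GGAGG", mat, "ACCACCAAAC", star, "GGTGG")
    f <- foldRna(hp)
    st <- findStar(f, 5, 22)
    expect_equal(st$star_seq, star)
    expect_equal(st$arm, "5p")

    # a 1-nt internal bulge in the mature shifts the star length by 1
    mat2 <- "GGATCCGGTTCAGCATCGAAC"        # 21 nt
    # star pairs the mature duplex region minus position 11 (bulged out)
    left <- substr(mat2, 1, 10); right <- substr(mat2, 12, 19)
    star2 <- paste0(revComp(right), revComp(left), "CA")   # 20 nt
    hp2 <- paste0("GGAGG", mat2, "AAACAAAAA", star2, "GGTGG")
    f2 <- foldRna(hp2)
    st2 <- findStar(f2, 5, 21)
    expect_equal(abs(nchar(st2$star_seq) - 21), 1)
})

test_that("shuffled planted precursors rarely pass the hairpin criteria", {
    refs <- smallStudy()$refs
    set.seed(404)
    n <- 0; pass <- 0
    for (k in seq_len(min(10, nrow(refs$planted)))) {
        g <- refs$planted[k, ]
        off <- g$mature_start - g$precursor_start
        for (r in 1:5) {
            s <- paste(sample(strsplit(g$precursor_seq, "")[[1]]),
                       collapse = "")
            s <- paste0(substr(s, 1, off), g$mature_seq,
                        substr(s, off + nchar(g$mature_seq) + 1, nchar(s)))
            v <- evaluateHairpin(foldRna(s), off, nchar(g$mature_seq))
            n <- n + 1
            if (v$pass) pass <- pass + 1
        }
    }
    expect_lt(pass / n, 0.10)
})

test_that("candidate windows cover planted precursors and clip at ends", {
    refs <- smallStudy()$refs
    tx <- refs$transcripts
    novel <- refs$planted[refs$planted$class == "novel", ]
    cands <- extractCandidates(novel$mature_seq, tx)
    for (k in seq_len(nrow(novel))) {
        g <- novel[k, ]
        cc <- cands[cands$mature_seq == g$mature_seq &
                    cands$transcript_id == g$host_transcript &
                    cands$strand == "+", ]
        expect_gt(nrow(cc), 0)
        # at least one window contains the full mature/star duplex
        span_lo <- min(g$mature_start,
                       g$precursor_start +
                       regexpr(g$star_seq, g$precursor_seq, fixed = TRUE)[1] - 1)
        span_hi <- max(g$mature_start + nchar(g$mature_seq),
                       g$precursor_start +
                       regexpr(g$star_seq, g$precursor_seq, fixed = TRUE)[1] - 1 +
                       nchar(g$star_seq))
        expect_true(any(cc$win_start <= span_lo & cc$win_end >= span_hi))
    }
    # a hit at position 0 clips the 5' flank and stays valid
    m <- randomDna(21)
    txx <- c(TT = paste0(m, randomDna(200)))
    cc <- extractCandidates(m, txx)
    expect_true(all(cc$win_start == 0))
    expect_true(all(cc$mature_off == 0))
    # no perfect hit -> no candidates
    expect_equal(nrow(extractCandidates(randomDna(21), txx)), 0)
})

test_that("novel calling demands star evidence and dedups loci", {
    st <- smallStudy()
    refs <- st$refs
    tab <- st$table
    novel <- refs$planted[refs$planted$class == "novel", ]
    cands <- extractCandidates(novel$mature_seq, refs$transcripts)
    calls <- callNovelMirnas(cands, tab)
    acc <- calls[calls$status == "accepted", ]
    # one call per planted gene, stars exactly the analytic stars
    expect_equal(sort(acc$mature_seq), sort(novel$mature_seq))
    i <- match(novel$mature_seq, acc$mature_seq)
    expect_equal(acc$star_seq[i], novel$star_seq)
    expect_equal(acc$mature_arm[i], novel$arm)

    # removing the star from the table forces status no_star
    g <- novel[1, ]
    keep <- signatures(tab) != g$star_seq
    tab2 <- SignatureTable(signatures(tab)[keep],
                           signatureCounts(tab)[keep, "A"],
                           signatureCounts(tab)[keep, "B"])
    calls2 <- callNovelMirnas(cands[cands$mature_seq == g$mature_seq, ], tab2)
    expect_equal(calls2$status, "no_star")

    # acceptance is monotone in star evidence: adding star reads never
    # un-calls
    extra <- SignatureTable(signatures(tab),
                            signatureCounts(tab)[, "A"] +
                                as.integer(signatures(tab) == g$star_seq) * 50L,
                            signatureCounts(tab)[, "B"])
    calls3 <- callNovelMirnas(cands, extra)
    expect_true(all(acc$mature_seq %in%
                    calls3$mature_seq[calls3$status == "accepted"]))
})

test_that("the star arm of a called locus is folded into one call, not two", {
    st <- smallStudy()
    refs <- st$refs
    novel <- refs$planted[refs$planted$class == "novel", ]
    # offer both the matures and their stars as candidates (stars are
    # sequenced signatures and perfect transcript matches too)
    cands <- extractCandidates(c(novel$mature_seq, novel$star_seq),
                               refs$transcripts)
    calls <- callNovelMirnas(cands, st$table)
    acc <- calls[calls$status == "accepted", ]
    # each locus yields exactly one accepted call, the abundant (mature) arm
    expect_equal(sort(acc$mature_seq), sort(novel$mature_seq))
    expect_true(any(calls$status == "secondary_arm"))
})
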