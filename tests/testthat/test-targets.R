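# Plant target complementarity scoring and hotspot statistics.

test_that("site scoring applies the penalty scheme positionally", {
    m <- "UGACAGAAGAGAGUGAGCAC"              # 20 nt
    site <- revComp(toDNA(m))
    expect_equal(scoreSite(m, site), 0)

    # a G:U wobble at miRNA position 15 costs 0.5; at position 5 the core
    # doubling makes it 1.0. Site position pairing miRNA pos i is L+1-i.
    md <- toDNA(m)
    wob_at <- function(pos) {
        s <- strsplit(site, "")[[1]]
        i <- nchar(site) + 1 - pos
        s[i] <- if (substr(md, pos, pos) == "G") "T" else "G"
        paste(s, collapse = "")
    }
    # position 15 of m is G -> target T gives G:U
    expect_equal(substr(md, 15, 15), "G")
    expect_equal(scoreSite(m, wob_at(15)), 0.5)
    # position 6 is G, inside the 2-13 core -> the wobble doubles to 1.0
    expect_equal(substr(md, 6, 6), "G")
    expect_equal(scoreSite(m, wob_at(6)), 1.0)

    # a mismatch outside the core costs 1, inside 2
    mm_at <- function(pos) {
        s <- strsplit(site, "")[[1]]
        i <- nchar(site) + 1 - pos
        s[i] <- setdiff(c("A", "C"), s[i])[1]  # never complement or wobble
        paste(s, collapse = "")
    }
    expect_equal(scoreSite(m, mm_at(18)) -
                 scoreSite(m, site), 1)
    expect_equal(scoreSite(m, mm_at(8)), 2)
})

test_that("scoring is invariant under swapping the strand roles", {
    set.seed(33)
    # the duplex formed by (miRNA m, site s) is the duplex of (m read as
    # the site, s read as the miRNA): with position doubling disabled the
    # score must not depend on which strand is called the miRNA
    plain <- list(wobble = 0.5, mismatch = 1, gap = 2, core = c(0L, 0L))
    for (r in 1:10) {
        m <- randomDna(21)
        s <- randomDna(21)
        expect_equal(scoreSite(m, s, scoring = plain),
                     scoreSite(s, m, scoring = plain))
    }
})

test_that("predict_targets equals the brute-force window oracle", {
    set.seed(17)
    for (r in 1:6) {
        m <- setNames(randomDna(21), "q")
        tx <- randomDna(400)
        pos <- sample(100:250, 1)
        tx <- paste0(substr(tx, 1, pos), revComp(m),
                     substr(tx, pos + 22, 400))
        txs <- c(T1 = tx)
        hits <- predictTargets(m, txs, cutoff = 5)
        oracle <- oracleTargetScan(m[[1]], tx, 5)
        expect_equal(sort(hits$site_start), sort(oracle$start))
        expect_equal(hits$score[order(hits$site_start)],
                     oracle$score[order(oracle$start)])
        # the planted perfect complement is found with score 0
        expect_true(any(hits$score == 0 & hits$site_start == pos))
    }
})

test_that("hit sets are monotone in the cutoff and empty inputs are safe", {
    set.seed(23)
    m <- setNames(randomDna(21), "q")
    txs <- setNames(replicate(3, randomDna(500)), paste0("T", 1:3))
    h0 <- predictTargets(m, txs, cutoff = 0)
    h4 <- predictTargets(m, txs, cutoff = 4)
    h8 <- predictTargets(m, txs, cutoff = 8)
    expect_true(all(h0$score == 0))
    key <- function(h) paste(h$transcript_id, h$site_start)
    expect_true(all(key(h4) %in% key(h8)))
    expect_true(all(key(h0) %in% key(h4)))
    expect_equal(nrow(predictTargets(m, character(0))), 0)
    expect_equal(nrow(predictTargets(character(0), txs)), 0)
})

test_that("hotspot tallies follow the inclusive and exclusive conventions", {
    # three target genes: sense-only, both, none
    sigs <- c(s_only = randomDna(21), both_s = randomDna(21),
              both_a = randomDna(21))
    tab <- SignatureTable(unname(sigs), c(5L, 5L, 5L), c(5L, 5L, 0L))
    hits <- data.frame(
        sequence = unname(sigs),
        transcript_id = c("G1", "G2", "G2"),
        strand = c("+", "+", "-"), stringsAsFactors = FALSE)
    hs <- hotspotStats(c("G1", "G2", "G3"), hits, tab)
    a <- hs[hs$library == "A", ]
    expect_equal(a$n_targets, 3)
    expect_equal(a$n_sense_incl, 2)       # sense-only + both
    expect_equal(a$n_sense_only, 1)
    expect_equal(a$n_antisense_incl, 1)
    expect_equal(a$n_antisense_only, 0)
    expect_equal(a$n_both, 1)
    expect_equal(a$n_either, 2)
    # identity: sense-only + antisense-only + both = either
    expect_equal(a$n_sense_only + a$n_antisense_only + a$n_both, a$n_either)
    expect_equal(a$pct_either, 100 * 2 / 3)
    # in library B the antisense signature is absent
    b <- hs[hs$library == "B", ]
    expect_equal(b$n_both, 0)
    expect_equal(b$n_sense_incl, 2)
    # no matching sRNAs at all -> zeros
    hs0 <- hotspotStats(c("G1", "G2"), hits[0, ], tab)
    expect_true(all(hs0$n_either == 0))
})

test_that("antisense cognate fraction spans its boundary cases", {
    sigs <- c(a1 = randomDna(21), s1 = randomDna(21), a2 = randomDna(21))
    tab <- SignatureTable(unname(sigs), c(3L, 3L, 3L), c(3L, 3L, 3L))
    # all antisense genes also bear sense sRNAs
    h1 <- data.frame(sequence = unname(sigs[c(1, 2)]),
                     transcript_id = c("G1", "G1"),
                     strand = c("-", "+"), stringsAsFactors = FALSE)
    expect_equal(unname(antisenseCognateFraction(h1, tab)["A"]), 1)
    # disjoint sense and antisense gene sets
    h2 <- data.frame(sequence = unname(sigs),
                     transcript_id = c("G1", "G2", "G3"),
                     strand = c("-", "+", "-"), stringsAsFactors = FALSE)
    expect_equal(unname(antisenseCognateFraction(h2, tab)["A"]), 0)
})

test_that("cognate fraction on synthetic data matches the anchor layout", {
    st <- smallStudy()
    tab <- st$table
    tx <- matchTranscripts(tab, st$refs$transcripts)
    got <- antisenseCognateFraction(tx$hits, tab)
    # expected from the generator's anchors: transcripts with an antisense
    # anchor that also carry a sense anchor (planted miRNA loci add sense
    # mass to their hosts)
    an <- st$refs$anchors
    sense_tx <- unique(c(an$transcript[an$strand == "+"],
        match(st$refs$planted$host_transcript,
              names(st$refs$transcripts))))
    anti_tx <- unique(an$transcript[an$strand == "-"])
    exp_frac <- mean(anti_tx %in% sense_tx)
    expect_lt(abs(got[["A"]] - exp_frac), 0.25)
})
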