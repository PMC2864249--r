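# Adapter trimming, collapsing and filtering.

test_that("anchored trimming extracts the insert between the 7-nt anchors", {
    insert <- toDNA("UGACAGAAGAGAGUGAGCAC")
    read <- paste0("ACGTACG", insert, "TGCATGCNNN")
    out <- trimReads(read, adapter_5p = "ACGTACG", adapter_3p = "TGCATGC")
    expect_equal(out$insert, insert)
    expect_equal(out$reason, "ok")

    # anchors are the LAST 7 nt of the 5' adapter / FIRST 7 of the 3'
    long5 <- paste0("GGGGG", "ACGTACG")
    long3 <- paste0("TGCATGC", "AAAAA")
    out2 <- trimReads(read, long5, long3)
    expect_equal(out2$insert, insert)
})

test_that("trimming rejects reads with missing or degenerate anchors", {
    a5 <- "ACGTACG"; a3 <- "TGCATGC"
    out <- trimReads(c("",                          # empty
                       "TTTTTTTTTTTTTTTTTTTTTT",    # no anchors
                       paste0(a5, "ACGTACGTACGT"),  # no 3' anchor
                       paste0(a5, a3)),             # abutting anchors
                     a5, a3)
    expect_equal(out$reason,
                 c("empty", "no_5p_anchor", "no_3p_anchor", "no_insert"))
    expect_true(all(is.na(out$insert)))
})

test_that("simulated reads trim back to their generating inserts", {
    st <- smallStudy()
    truth <- st$sim$truth_A
    tr <- st$trim_A
    a5 <- substr(st$cfg$adapter_5p, nchar(st$cfg$adapter_5p) - 6,
                 nchar(st$cfg$adapter_5p))
    a3 <- substr(st$cfg$adapter_3p, 1, 7)
    real <- truth$origin != "junk"
    # inserts that happen to contain an anchor heptamer are legitimately
    # truncated at it; all others must round-trip exactly
    clean <- real & !grepl(a3, truth$insert, fixed = TRUE) &
        !grepl(a5, truth$insert, fixed = TRUE)
    expect_gt(mean(clean[real]), 0.99)
    expect_equal(tr$insert[clean], truth$insert[clean])
    trunc <- real & !clean & tr$reason == "ok"
    expect_true(all(startsWith(truth$insert[trunc], tr$insert[trunc])))
    # junk reads carry no anchors
    expect_true(all(tr$reason[!real] != "ok"))
})

test_that("collapse counts match a brute-force dictionary count", {
    set.seed(31)
    pool <- replicate(40, randomDna(sample(16:32, 1)))
    a <- sample(pool, 500, TRUE)
    b <- sample(pool, 300, TRUE)
    tab <- collapseAndFilter(a, b, min_count = 3)
    df <- as.data.frame(tab)
    df$sequence <- toDNA(df$sequence)
    for (k in seq_len(nrow(df))) {
        expect_equal(df$count_A[k], sum(a == df$sequence[k]))
        expect_equal(df$count_B[k], sum(b == df$sequence[k]))
    }
    # no retained row violates the filters
    expect_true(all(nchar(df$sequence) >= 18 & nchar(df$sequence) <= 30))
    expect_true(all(pmax(df$count_A, df$count_B) >= 3))
    # library sizes are the retained totals
    expect_equal(unname(librarySizes(tab)),
                 c(sum(df$count_A), sum(df$count_B)))
})

test_that("length and count filters act on the documented boundaries", {
    s <- randomDna(20)
    # kept at the min_count boundary in a single library
    tab <- collapseAndFilter(rep(s, 3), character(0))
    expect_equal(as.data.frame(tab)$count_A, 3)
    expect_equal(as.data.frame(tab)$count_B, 0)
    # a 17-nt sequence is discarded no matter how abundant
    tab2 <- collapseAndFilter(rep(randomDna(17), 100), character(0))
    expect_equal(length(tab2), 0)
    # ambiguous characters are discarded
    tab3 <- collapseAndFilter(rep(paste0(substr(s, 1, 19), "N"), 5),
                              character(0))
    expect_equal(length(tab3), 0)
    # min_count must hold in at least one library, not both
    tab4 <- collapseAndFilter(rep(s, 2), rep(s, 2))
    expect_equal(length(tab4), 0)
    tab5 <- collapseAndFilter(rep(s, 3), rep(s, 2))
    expect_equal(length(tab5), 1)
})

test_that("collapse is permutation-invariant and filtering idempotent", {
    set.seed(8)
    pool <- replicate(25, randomDna(sample(18:30, 1)))
    a <- sample(pool, 200, TRUE); b <- sample(pool, 150, TRUE)
    t1 <- collapseAndFilter(a, b)
    t2 <- collapseAndFilter(sample(a), sample(b))
    expect_equal(as.data.frame(t1), as.data.frame(t2))
    # feeding the collapsed rows back in (expanded) reproduces the table
    df <- as.data.frame(t1)
    sq <- toDNA(df$sequence)
    t3 <- collapseAndFilter(rep(sq, df$count_A), rep(sq, df$count_B))
    expect_equal(as.data.frame(t3), df)
})

test_that("length histogram is normalised and scale-invariant in uniques", {
    s24 <- randomDna(24)
    tab <- SignatureTable(s24, 5L, 0L)
    h <- lengthHistogram(tab)
    expect_equal(h$unique_frac[h$length == 24], 1)
    expect_equal(sum(h$unique_frac), 1)
    expect_equal(sum(h$reads_frac), 1)

    st <- smallStudy()
    h2 <- lengthHistogram(st$table)
    expect_equal(h2$length[which.max(h2$reads_frac)], 24)
    # unique-signature histogram ignores count scaling
    tab2 <- SignatureTable(signatures(st$table),
                           10L * signatureCounts(st$table)[, "A"],
                           10L * signatureCounts(st$table)[, "B"])
    expect_equal(lengthHistogram(tab2)$unique_frac, h2$unique_frac)
})
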