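# Classification hierarchy, bounded-mismatch homology, and the
# per-category summary identities.

test_that("ncRNA substring matches are assigned with class precedence", {
    trna <- randomDna(120)
    frag <- substr(trna, 40, 61)
    tab <- SignatureTable(c(frag, randomDna(22)), c(5L, 5L), c(1L, 0L))
    nc <- matchNoncoding(tab, c("NC001 class=tRNA" = trna))
    expect_equal(nrow(nc), 1)
    expect_equal(nc$category, "tRNA")
    expect_equal(nc$hit_id, "NC001")

    # signature matching both rRNA and tRNA records -> rRNA precedence
    shared <- randomDna(20)
    refs <- c("NC001 class=tRNA" = paste0(randomDna(30), shared, randomDna(30)),
              "NC002 class=rRNA" = paste0(randomDna(10), shared, randomDna(50)))
    tab2 <- SignatureTable(shared, 3L, 0L)
    expect_equal(matchNoncoding(tab2, refs)$category, "rRNA")

    # references without class tags are a configuration error
    expect_error(matchNoncoding(tab2, c(NCX = randomDna(50))), "class=")
})

test_that("all ncRNA-derived inserts classify to their true class", {
    st <- smallStudy()
    truth <- rbind(st$sim$truth_A, st$sim$truth_B)
    nc_inserts <- unique(truth$insert[truth$origin == "bg_ncrna"])
    tab <- st$table
    in_table <- intersect(nc_inserts, signatures(tab))
    nc <- matchNoncoding(tab, st$refs$ncrna)
    expect_true(all(in_table %in% nc$sequence))
    cls <- sub(".*class=([A-Za-z]+).*", "\\1", names(st$refs$ncrna))
    for (k in seq_len(nrow(nc))) {
        hit <- which(startsWith(names(st$refs$ncrna), nc$hit_id[k]))
        expect_equal(nc$category[k], cls[hit])
    }
})

test_that("transcript matching reports strands and a sense-first primary", {
    tx <- c(T1 = randomDna(200))
    sense <- substr(tx, 50, 70)
    anti <- revComp(substr(tx, 100, 120))
    tab <- SignatureTable(c(sense, anti), c(4L, 4L), c(0L, 0L))
    m <- matchTranscripts(tab, tx)
    expect_equal(nrow(m$hits), 2)
    expect_equal(m$hits$strand[m$hits$sequence == sense], "+")
    expect_equal(m$hits$strand[m$hits$sequence == anti], "-")

    # a signature matching both orientations is tallied in both but is
    # primarily sense
    pal <- paste0(randomDna(9), "AT")
    pal <- paste0(pal, revComp(pal))   # reverse-complement palindrome
    tx2 <- c(T2 = paste0(randomDna(40), pal, randomDna(40)))
    tab2 <- SignatureTable(pal, 3L, 0L)
    m2 <- matchTranscripts(tab2, tx2)
    expect_setequal(m2$hits$strand, c("+", "-"))
    expect_equal(m2$primary$strand, "+")
})

test_that("transcript hit tallies equal a naive scan on small references", {
    set.seed(12)
    tx <- setNames(replicate(4, randomDna(150)), paste0("T", 1:4))
    sigs <- unique(c(substr(tx[[1]], 10, 30), revComp(substr(tx[[2]], 50, 70)),
                     replicate(10, randomDna(21))))
    tab <- SignatureTable(sigs, rep(3L, length(sigs)), rep(0L, length(sigs)))
    m <- matchTranscripts(tab, tx)
    for (s in sigs) for (tn in names(tx)) {
        naive_sense <- grepl(s, tx[[tn]], fixed = TRUE)
        naive_anti <- grepl(s, revComp(tx[[tn]]), fixed = TRUE)
        hits <- m$hits[m$hits$sequence == s & m$hits$transcript_id == tn, ]
        expect_equal("+" %in% hits$strand, naive_sense)
        expect_equal("-" %in% hits$strand, naive_anti)
    }
})

test_that("known-miRNA distance equals the naive sliding oracle and is bounded", {
    set.seed(21)
    refs <- setNames(replicate(6, randomDna(21)), paste0("ath-miR", 201:206))
    sigs <- c(refs[[1]],                                   # identical
              paste0(substr(refs[[2]], 1, 17), "AAAA"),    # mutated tail
              replicate(8, randomDna(sample(19:24, 1))))
    tab <- SignatureTable(unique(sigs), rep(3L, length(unique(sigs))),
                          rep(0L, length(unique(sigs))))
    kn <- matchKnownMirnas(tab, refs, max_mm = 4)
    # identical sequence: 0 mismatches
    expect_equal(kn$mismatches[kn$sequence == refs[[1]]], 0)
    # every assignment distance matches the naive oracle to its reference
    for (k in seq_len(nrow(kn))) {
        ref <- refs[[kn$hit_id[k]]]
        expect_equal(kn$mismatches[k],
                     oracleSlidingDistance(kn$sequence[k], ref))
        # and no reference is strictly closer
        expect_true(all(vapply(refs, function(r)
            oracleSlidingDistance(kn$sequence[k], r), numeric(1)) >=
            kn$mismatches[k]))
    }
    # unassigned signatures are all at distance > 4 from every reference
    un <- setdiff(signatures(tab), kn$sequence)
    for (s in un)
        expect_true(min(vapply(refs, function(r)
            oracleSlidingDistance(s, r), numeric(1))) > 4)
})

test_that("known-miRNA assignment is stable under reference reordering", {
    set.seed(77)
    base <- randomDna(21)
    refs <- c("zma-miR310" = base, "ath-miR309" = base)  # exact tie
    tab <- SignatureTable(base, 3L, 0L)
    k1 <- matchKnownMirnas(tab, refs)
    k2 <- matchKnownMirnas(tab, rev(refs))
    expect_equal(k1$hit_id, "ath-miR309")   # lexicographically smallest id
    expect_equal(k1, k2)
})

test_that("categorisation partitions signatures and summary identities hold", {
    st <- smallStudy()
    tab <- st$table
    nc <- matchNoncoding(tab, st$refs$ncrna)
    kn <- matchKnownMirnas(tab, st$refs$matures)
    tx <- matchTranscripts(tab, st$refs$transcripts)
    rec <- categorizeSignatures(tab, nc, kn, tx)
    expect_equal(nrow(rec), length(tab))
    expect_equal(anyDuplicated(rec$sequence), 0)

    s <- summarizeCategories(tab, rec)
    tot <- s[s$category == "total", ]
    body <- s[s$category != "total", ]
    # distinct and total columns are conserved
    expect_equal(sum(body$distinct_A), tot$distinct_A)
    expect_equal(sum(body$total_A), tot$total_A)
    cnt <- signatureCounts(tab)
    expect_equal(tot$distinct_A, sum(cnt[, "A"] > 0))
    expect_equal(tot$total_A, sum(cnt[, "A"]))
    # mean frequency x distinct = total, per category and library
    nz <- body$distinct_B > 0
    expect_equal(body$mean_freq_B[nz] * body$distinct_B[nz],
                 body$total_B[nz])
    # percentages sum to 100
    expect_equal(sum(body$pct_distinct_A), 100)
})

test_that("mean frequency is total over distinct (single-row worked case)", {
    tab <- SignatureTable(randomDna(21), 10L, 0L)
    rec <- categorizeSignatures(tab,
        nc = data.frame(sequence = character(), category = character(),
                        hit_id = character()),
        known = data.frame(sequence = character(), hit_id = character(),
                           family = character(), mismatches = integer()),
        tx = list(hits = data.frame(sequence = character(),
                                    transcript_id = character(),
                                    strand = character()),
                  primary = data.frame(sequence = character(),
                                       strand = character())))
    s <- summarizeCategories(tab, rec)
    expect_equal(s$mean_freq_A[s$category == "other"], 10)
})
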