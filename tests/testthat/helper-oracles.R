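# Independent oracles used by the test suite. These deliberately avoid the
# package's own algorithmic paths: the folding oracle enumerates every
# nested structure explicitly and scores each; the distance and target
# oracles are naive loops.

oraclePairWeight <- function(a, b, wobble = 1) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(1)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(wobble)
    0
}

# all nested structures on positions i..j as lists of pair matrices
enumStructures <- function(i, j, min_loop = 3) {
    if (j - i < min_loop + 1) return(list(matrix(0L, 0, 2)))
    out <- lapply(enumStructures(i + 1, j, min_loop), identity)
    for (k in (i + min_loop + 1):j) {
        left <- enumStructures(i + 1, k - 1, min_loop)
        right <- enumStructures(k + 1, j, min_loop)
        for (a in left) for (b in right)
            out[[length(out) + 1]] <- rbind(matrix(c(i, k), 1, 2), a, b)
    }
    out
}

# maximum structure weight over the explicit enumeration
oracleFoldScore <- function(seq, min_loop = 3, wobble = 1) {
    x <- strsplit(toDNA(seq), "")[[1]]
    best <- 0
    for (st in enumStructures(1, length(x), min_loop)) {
        if (nrow(st) == 0) next
        w <- sum(apply(st, 1, function(p)
            oraclePairWeight(x[p[1]], x[p[2]], wobble)))
        ok <- all(apply(st, 1, function(p)
            oraclePairWeight(x[p[1]], x[p[2]], wobble) > 0))
        if (ok && w > best) best <- w
    }
    best
}

# naive sliding-alignment distance (loops, no vectorisation)
oracleSlidingDistance <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    best <- la + lb
    for (s in seq(-(lb - 1), la - 1)) {
        mism <- 0; overlap <- 0
        for (i in seq_len(la)) {
            j <- i - s
            if (j >= 1 && j <= lb) {
                overlap <- overlap + 1
                if (av[i] != bv[j]) mism <- mism + 1
            }
        }
        if (overlap > 0)
            best <- min(best, mism + (la - overlap) + (lb - overlap))
    }
    best
}

# brute-force all-window target scan built on scoreSite
oracleTargetScan <- function(mirna, tx, cutoff) {
    L <- nchar(mirna); n <- nchar(tx)
    rows <- list()
    if (n < L - 1) return(data.frame(start = integer(), score = numeric()))
    for (p in 0:(n - L + 1)) {
        scores <- numeric(0)
        if (p + L <= n)
            scores <- c(scores, scoreSite(mirna, substr(tx, p + 1, p + L)))
        if (p + L + 1 <= n)
            scores <- c(scores, scoreSite(mirna, substr(tx, p + 1, p + L + 1)))
        if (p + L - 1 <= n && L > 3)
            scores <- c(scores, scoreSite(mirna, substr(tx, p + 1, p + L - 1)))
        if (length(scores) && min(scores) <= cutoff)
            rows[[length(rows) + 1]] <- data.frame(start = p,
                                                   score = min(scores))
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(start = integer(), score = numeric())
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# a small synthetic study shared by several tests (built once per run)
smallStudy <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simulationConfig(seed = 7)
            refs <- buildReferences(cfg)
            sim <- simulateLibraries(refs)
            ta <- trimReads(sim$reads_A, cfg$adapter_5p, cfg$adapter_3p)
            tb <- trimReads(sim$reads_B, cfg$adapter_5p, cfg$adapter_3p)
            tab <- collapseAndFilter(ta$insert, tb$insert)
            cache <<- list(cfg = cfg, refs = refs, sim = sim,
                           trim_A = ta, trim_B = tb, table = tab)
        }
        cache
    }
})
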