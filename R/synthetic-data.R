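# Synthetic two-condition small RNA study generator.
#
# Produces reference sets (transcripts, non-coding RNAs, a mature miRNA
# catalogue), planted miRNA genes with analytically constructed miRNA*
# partners, and two FASTQ libraries with known ground truth, emulating a
# two-library (wild type vs mutant) plant small RNA sequencing design.

#' Build a validated simulation configuration
#'
#' Defaults emulate a desk-scale version of a two-condition plant small RNA
#' study: two libraries of 2e5 reads, a 24-nt modal insert length
#' distribution with >90% of mass at 21-24 nt, 20 planted miRNA genes
#' (half present in the mature catalogue, i.e. "known"; half withheld,
#' i.e. "novel"), and background signatures drawn from coding transcripts,
#' non-coding RNAs and a hidden "dark matter" pool standing in for
#' genome-derived small RNAs that match no catalogued reference.
#'
#' @param n_transcripts number of transcript (unigene-like) references.
#' @param transcript_len_range length range (nt) of transcripts.
#' @param n_mirnas total planted miRNA genes.
#' @param n_known how many planted genes are in the mature catalogue.
#' @param n_noncoding_refs number of non-coding RNA references (cycled over
#'   classes rRNA, tRNA, snRNA, snoRNA).
#' @param library_sizes reads per condition, length-2 numeric (A, B).
#' @param length_mode_weights named numeric over insert lengths 18..30;
#'   must sum to 1.
#' @param adapter_5p,adapter_3p adapter sequences (DNA), each >= 7 nt.
#' @param junk_rate fraction of reads carrying no adapter anchors.
#' @param star_fraction fraction of each gene's reads from the star arm.
#' @param background_split length-3 numeric (transcript, ncRNA, dark
#'   matter) fractions of background mass; must sum to 1.
#' @param abundance_range per-gene total abundance range (TPM), sampled
#'   log-uniformly.
#' @param fold_effects pool of condition-B fold effects sampled per gene
#'   (1 = null gene); values < 1 mean higher in A.
#' @param read_length sequencer read length (nt).
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @return a validated list of class \code{simulation_config}.
#' @export
simulationConfig <- function(n_transcripts = 30,
                             transcript_len_range = c(400L, 1200L),
                             n_mirnas = 20,
                             n_known = 10,
                             n_noncoding_refs = 8,
                             library_sizes = c(A = 2e5, B = 2e5),
                             length_mode_weights = defaultLengthWeights(),
                             adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                             adapter_3p = "TCGTATGCCGTCTTCTGCTTG",
                             junk_rate = 0.01,
                             star_fraction = 0.2,
                             background_split = c(transcript = 0.35,
                                                  ncrna = 0.08,
                                                  dark = 0.57),
                             abundance_range = c(200, 2000),
                             fold_effects = c(1, 1, 2, 4, 8, 0.5, 0.25),
                             read_length = 50L,
                             seed = 1L) {
    cfg <- list(n_transcripts = as.integer(n_transcripts),
                transcript_len_range = as.integer(transcript_len_range),
                n_mirnas = as.integer(n_mirnas),
                n_known = as.integer(n_known),
                n_noncoding_refs = as.integer(n_noncoding_refs),
                library_sizes = setNames(as.numeric(library_sizes), c("A", "B")),
                length_mode_weights = length_mode_weights,
                adapter_5p = toDNA(adapter_5p), adapter_3p = toDNA(adapter_3p),
                junk_rate = junk_rate, star_fraction = star_fraction,
                background_split = background_split,
                abundance_range = as.numeric(abundance_range),
                fold_effects = as.numeric(fold_effects),
                read_length = as.integer(read_length),
                seed = as.integer(seed))
    stopifnot(cfg$n_transcripts > 0, cfg$n_mirnas >= 0,
              cfg$n_known >= 0, cfg$n_known <= cfg$n_mirnas,
              cfg$n_mirnas <= cfg$n_transcripts,
              cfg$n_noncoding_refs >= 0,
              all(cfg$library_sizes > 0),
              nchar(cfg$adapter_5p) >= 7, nchar(cfg$adapter_3p) >= 7,
              cfg$junk_rate >= 0, cfg$junk_rate < 1,
              cfg$star_fraction >= 0, cfg$star_fraction < 1,
              abs(sum(cfg$length_mode_weights) - 1) < 1e-8,
              abs(sum(cfg$background_split) - 1) < 1e-8,
              all(cfg$fold_effects > 0))
    class(cfg) <- "simulation_config"
    cfg
}

#' Default insert length distribution (18-30 nt, 24-nt mode)
#'
#' Mass 0.92 on 21-24 nt with 0.55 at 24 nt, the shape typical of plant
#' small RNA libraries dominated by 24-nt heterochromatic siRNAs.
#' @return named numeric over "18".."30" summing to 1.
#' @export
defaultLengthWeights <- function() {
    setNames(c(0.005, 0.005, 0.010, 0.150, 0.100, 0.120, 0.550,
               0.020, 0.015, 0.010, 0.005, 0.004, 0.006),
             as.character(18:30))
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# point substitutions at the given rate (never to the original base)
mutateSeq <- function(s, rate) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(x)) < rate)
    for (i in hit)
        x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    paste(x, collapse = "")
}

# Analytic miRNA/miRNA* duplex construction, embedded in a realistic
# extended-stem precursor. The star core is the reverse complement of the
# mature minus its 2-nt 3' overhang; two extra star bases form the star's
# own 3' overhang. Loop and overhang bases are drawn from {A, C} so they
# cannot pair with each other or with the mature's last two bases (also
# {A, C}); the regions below the duplex continue the stem as an imperfect
# helix (point mismatches), the way plant pre-miRNA lower stems do, so the
# planted duplex is the dominant helix of the precursor while the ground
# truth stays analytic, independent of any folding engine.
buildPlantedGene <- function(id, mature_len, loop_len, arm,
                             lower_len, tail5_len, tail3_len,
                             stem_mut_rate = 0.12) {
    mature <- paste0(randomSeq(mature_len - 2),
                     randomSeq(2, c("A", "C")))
    star <- paste0(revComp(substr(mature, 1, mature_len - 2)),
                   randomSeq(2, c("A", "C")))
    loop <- randomSeq(loop_len, c("A", "C"))
    lower5 <- randomSeq(lower_len)
    lower3 <- mutateSeq(revComp(lower5), stem_mut_rate)
    tail5 <- randomSeq(tail5_len)
    tail3 <- randomSeq(tail3_len)
    if (arm == "5p") {
        core <- paste0(mature, loop, star)
        mature_off <- tail5_len + lower_len
    } else {
        core <- paste0(star, loop, mature)
        mature_off <- tail5_len + lower_len + nchar(star) + loop_len
    }
    precursor <- paste0(tail5, lower5, core, lower3, tail3)
    list(id = id, mature_seq = mature, star_seq = star,
         precursor_seq = precursor, mature_start = mature_off, arm = arm)
}

#' Build synthetic references and planted miRNA ground truth
#'
#' Generates transcripts, embeds one planted pre-miRNA hairpin per host
#' transcript, builds a non-coding RNA reference (class-tagged headers) and
#' a mature miRNA catalogue containing the "known" planted matures (plus
#' decoys) while withholding the "novel" ones.
#'
#' @param config a [simulationConfig()] object.
#' @return list with elements \code{transcripts}, \code{ncrna},
#'   \code{matures} (named character vectors), \code{planted} (ground-truth
#'   manifest data.frame) and \code{dark} (hidden background pool).
#' @export
buildReferences <- function(config) {
    stopifnot(inherits(config, "simulation_config"))
    set.seed(childSeed(config$seed, 1L))

    n_tx <- config$n_transcripts
    tx_len <- sample(seq(config$transcript_len_range[1],
                         config$transcript_len_range[2]), n_tx, replace = TRUE)
    transcripts <- vapply(tx_len, randomSeq, character(1))
    names(transcripts) <- sprintf("TX%04d", seq_len(n_tx))

    # planted genes, one per distinct host transcript
    planted <- NULL
    if (config$n_mirnas > 0) {
        hosts <- sample(n_tx, config$n_mirnas)
        rows <- vector("list", config$n_mirnas)
        for (g in seq_len(config$n_mirnas)) {
            ok <- FALSE
            for (try in seq_len(20L)) {
                gene <- buildPlantedGene(
                    id = sprintf("gene%02d", g),
                    mature_len = sample(20:24, 1,
                                        prob = c(.15, .50, .20, .10, .05)),
                    loop_len = sample(8:15, 1), arm = sample(c("5p", "3p"), 1),
                    lower_len = sample(15:50, 1),
                    tail5_len = sample(5:15, 1), tail3_len = sample(5:15, 1))
                pre <- gene$precursor_seq
                host <- transcripts[[hosts[g]]]
                pos <- sample(nchar(host) - nchar(pre) + 1, 1)  # 1-based
                new_host <- paste0(substr(host, 1, pos - 1), pre,
                                   substr(host, pos + nchar(pre),
                                          nchar(host)))
                # mature must occur exactly once in precursor and host
                one_in <- function(p, s)
                    length(gregexpr(p, s, fixed = TRUE)[[1]]) == 1 &&
                        gregexpr(p, s, fixed = TRUE)[[1]][1] != -1
                if (one_in(gene$mature_seq, pre) &&
                    one_in(gene$mature_seq, new_host) &&
                    one_in(gene$star_seq, new_host)) {
                    transcripts[[hosts[g]]] <- new_host
                    rows[[g]] <- data.frame(
                        id = gene$id,
                        class = if (g <= config$n_known) "known" else "novel",
                        mature_seq = gene$mature_seq,
                        star_seq = gene$star_seq,
                        precursor_seq = gene$precursor_seq,
                        host_transcript = names(transcripts)[hosts[g]],
                        mature_start = pos - 1L + gene$mature_start,
                        precursor_start = pos - 1L,
                        precursor_end = pos - 1L + nchar(pre),
                        arm = gene$arm,
                        base_abundance = exp(runif(1,
                            log(config$abundance_range[1]),
                            log(config$abundance_range[2]))),
                        fold_effect = sample(config$fold_effects, 1),
                        star_fraction = config$star_fraction,
                        stringsAsFactors = FALSE)
                    ok <- TRUE
                    break
                }
            }
            if (!ok) stop("precursor construction failed for gene ",
                          sprintf("gene%02d", g))
        }
        planted <- do.call(rbind, rows)
    } else {
        planted <- data.frame(id = character(), class = character(),
                              mature_seq = character(), star_seq = character(),
                              precursor_seq = character(),
                              host_transcript = character(),
                              mature_start = integer(),
                              precursor_start = integer(),
                              precursor_end = integer(), arm = character(),
                              base_abundance = numeric(),
                              fold_effect = numeric(),
                              star_fraction = numeric(),
                              stringsAsFactors = FALSE)
    }

    # non-coding RNA references with class-tagged headers
    nc_classes <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"),
                      length.out = config$n_noncoding_refs)
    ncrna <- vapply(seq_len(config$n_noncoding_refs),
                    function(i) randomSeq(sample(80:300, 1)), character(1))
    if (config$n_noncoding_refs > 0)
        names(ncrna) <- sprintf("NC%03d class=%s",
                                seq_len(config$n_noncoding_refs), nc_classes)
    else
        names(ncrna) <- character(0)

    # mature catalogue: known planted matures under homolog family names,
    # plus decoy entries matching nothing
    known <- planted[planted$class == "known", , drop = FALSE]
    matures <- character(0)
    if (nrow(known) > 0) {
        matures <- known$mature_seq
        names(matures) <- sprintf("ath-miR%03d", 100L + seq_len(nrow(known)))
    }
    n_decoy <- 5L
    decoys <- vapply(seq_len(n_decoy), function(i) randomSeq(21), character(1))
    names(decoys) <- sprintf("osa-miR%03d", 900L + seq_len(n_decoy))
    matures <- c(matures, decoys)

    # hidden dark-matter pool: finite set of background sequences matching
    # no reference, with long-tailed sampling weights
    lens <- as.integer(names(config$length_mode_weights))
    n_dark <- 4000L
    dark_len <- sample(lens, n_dark, replace = TRUE,
                       prob = config$length_mode_weights)
    dark <- vapply(dark_len, randomSeq, character(1))
    dark_w <- exp(rnorm(n_dark, 0, 1.5))

    # transcript-derived background sRNAs come from discrete producing
    # loci ("anchors"), not uniform tiling: per transcript a Poisson
    # number of sense and antisense loci with long-tailed weights, the
    # clustered coverage pattern real small RNA data show
    anchors <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
        L <- nchar(transcripts[[i]])
        n_s <- rpois(1, 1.2)
        n_a <- rpois(1, 0.8)
        n <- n_s + n_a
        if (n == 0 || L < 80) return(NULL)
        data.frame(transcript = i,
                   pos = sample(seq_len(L - 40L), n, replace = TRUE),
                   strand = c(rep("+", n_s), rep("-", n_a)),
                   weight = exp(rnorm(n, 0, 1)),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(anchors))
        anchors <- data.frame(transcript = integer(), pos = integer(),
                              strand = character(), weight = numeric(),
                              stringsAsFactors = FALSE)

    list(transcripts = transcripts, ncrna = ncrna, matures = matures,
         planted = planted, dark = dark, dark_weights = dark_w,
         anchors = anchors, config = config)
}

sampleFragments <- function(seqs, weights, n, lens, len_weights) {
    if (n == 0) return(character(0))
    idx <- sample(length(seqs), n, replace = TRUE, prob = weights)
    len <- sample(lens, n, replace = TRUE, prob = len_weights)
    L <- nchar(seqs)[idx]
    len <- pmin(len, L)
    start <- floor(runif(n) * (L - len + 1)) + 1
    substring(seqs[idx], start, start + len - 1)
}

# length-stratified draw from the dark-matter pool: the insert length is
# drawn from the configured distribution first, then a pool member of that
# length by its weight, so the realised length marginal matches the
# configured weights exactly in expectation
sampleDark <- function(refs, n, lens, len_weights) {
    if (n == 0) return(character(0))
    pool_len <- nchar(refs$dark)
    len <- sample(lens, n, replace = TRUE, prob = len_weights)
    out <- character(n)
    for (l in unique(len)) {
        in_bin <- which(pool_len == l)
        take <- which(len == l)
        if (!length(in_bin))
            out[take] <- vapply(rep(l, length(take)), randomSeq,
                                character(1))
        else
            out[take] <- refs$dark[sample(in_bin, length(take),
                                          replace = TRUE,
                                          prob = refs$dark_weights[in_bin])]
    }
    out
}

# clustered fragments around sRNA-producing anchor loci (start jitter of a
# few nt, lengths per the global length distribution)
sampleAnchoredFragments <- function(transcripts, anchors, n, lens,
                                    len_weights, jitter = 4L) {
    if (n == 0 || nrow(anchors) == 0) return(character(0))
    a <- sample(nrow(anchors), n, replace = TRUE, prob = anchors$weight)
    len <- sample(lens, n, replace = TRUE, prob = len_weights)
    L <- nchar(transcripts)[anchors$transcript[a]]
    start <- anchors$pos[a] + sample(-jitter:jitter, n, replace = TRUE)
    start <- pmax(1L, pmin(start, L - len + 1L))
    frag <- substring(transcripts[anchors$transcript[a]], start,
                      start + len - 1)
    rc <- anchors$strand[a] == "-"
    if (any(rc)) frag[rc] <- revComp(frag[rc])
    frag
}

#' Simulate two small RNA FASTQ libraries from built references
#'
#' Reads are \code{<5' adapter tail> + insert + <3' adapter head>}, padded
#' to the configured read length with random bases (Phred+33, dummy quality
#' "I"). Insert identity is drawn by multinomial sampling over planted
#' matures (condition-B abundance multiplied by each gene's fold effect),
#' their stars, background fragments of the transcript/ncRNA references and
#' the dark-matter pool, and adapter-free junk.
#'
#' @param refs output of [buildReferences()].
#' @param config the same [simulationConfig()] used to build \code{refs}.
#' @return list with \code{reads_A}, \code{reads_B} (read sequences),
#'   \code{truth_A}, \code{truth_B} (per-read origin and insert), and
#'   \code{config}.
#' @export
simulateLibraries <- function(refs, config = refs$config) {
    stopifnot(inherits(config, "simulation_config"))
    set.seed(childSeed(config$seed, 2L))
    planted <- refs$planted
    lens <- as.integer(names(config$length_mode_weights))

    one_library <- function(lib) {
        N <- config$library_sizes[[lib]]
        fold <- if (lib == "B") planted$fold_effect else rep(1, nrow(planted))
        p_mat <- planted$base_abundance * (1 - planted$star_fraction) *
            fold / 1e6
        p_star <- planted$base_abundance * planted$star_fraction * fold / 1e6
        p_junk <- config$junk_rate
        p_bg <- max(0, 1 - sum(p_mat) - sum(p_star) - p_junk)
        bg <- config$background_split * p_bg
        atoms <- c(p_mat, p_star, bg[["transcript"]], bg[["ncrna"]],
                   bg[["dark"]], p_junk)
        cnt <- as.vector(rmultinom(1, N, atoms))
        ng <- nrow(planted)
        n_mat <- cnt[seq_len(ng)]
        n_star <- cnt[ng + seq_len(ng)]
        n_tx <- cnt[2 * ng + 1]; n_nc <- cnt[2 * ng + 2]
        n_dark <- cnt[2 * ng + 3]; n_junk <- cnt[2 * ng + 4]

        inserts <- c(rep(planted$mature_seq, n_mat),
                     rep(planted$star_seq, n_star),
                     sampleAnchoredFragments(refs$transcripts,
                                             refs$anchors, n_tx, lens,
                                             config$length_mode_weights),
                     sampleFragments(refs$ncrna,
                                     rep(1, length(refs$ncrna)), n_nc, lens,
                                     config$length_mode_weights),
                     sampleDark(refs, n_dark, lens,
                                config$length_mode_weights))
        gene_lab <- function(kind)
            if (ng > 0) paste0(planted$id, ":", kind) else character(0)
        origin <- c(rep(gene_lab("mature"), n_mat),
                    rep(gene_lab("star"), n_star),
                    rep("bg_transcript", n_tx), rep("bg_ncrna", n_nc),
                    rep("bg_dark", n_dark))

        head5 <- substr(config$adapter_5p,
                        max(1, nchar(config$adapter_5p) - 9),
                        nchar(config$adapter_5p))
        space <- config$read_length - nchar(head5) - nchar(inserts)
        a3 <- substr(config$adapter_3p, 1, pmax(0, space))
        pad_n <- pmax(0, space - nchar(a3))
        pads <- vapply(pad_n, randomSeq, character(1))
        reads <- paste0(head5, inserts, a3, pads)

        junk <- vapply(rep(config$read_length, n_junk), randomSeq,
                       character(1))
        reads <- c(reads, junk)
        origin <- c(origin, rep("junk", n_junk))
        inserts <- c(inserts, rep(NA_character_, n_junk))

        ord <- sample(length(reads))
        truth <- data.frame(
            id = sprintf("%s_%06d", lib, seq_along(ord)),
            origin = origin[ord], insert = inserts[ord],
            stringsAsFactors = FALSE)
        list(reads = reads[ord], truth = truth)
    }

    A <- one_library("A")
    B <- one_library("B")
    list(reads_A = A$reads, reads_B = B$reads,
         truth_A = A$truth, truth_B = B$truth, config = config)
}

#' Write a full synthetic dataset to disk
#'
#' Writes the reference FASTAs, the two FASTQ libraries and the
#' ground-truth manifest TSV; the manifest alone suffices to score every
#' downstream stage.
#'
#' @param refs output of [buildReferences()].
#' @param sim output of [simulateLibraries()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
writeSimulatedData <- function(refs, sim, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
        transcripts = file.path(outdir, "transcripts.fasta"),
        ncrna = file.path(outdir, "ncrna.fasta"),
        matures = file.path(outdir, "matures.fasta"),
        fastq_a = file.path(outdir, "library_A.fastq"),
        fastq_b = file.path(outdir, "library_B.fastq"),
        manifest = file.path(outdir, "manifest.tsv"))
    writeFasta(refs$transcripts, paths$transcripts)
    writeFasta(refs$ncrna, paths$ncrna)
    writeFasta(refs$matures, paths$matures)
    writeFastq(sim$reads_A, paths$fastq_a, sim$truth_A$id)
    writeFastq(sim$reads_B, paths$fastq_b, sim$truth_B$id)
    writeTsv(refs$planted[, setdiff(names(refs$planted), "precursor_seq")],
             paths$manifest)
    invisible(paths)
}

#' Simulate per-gene tag counts for two libraries (count-level model)
#'
#' A light-weight generator used for statistical calibration of the
#' two-proportion Z test: per-gene abundances are drawn log-uniformly, and
#' raw counts arise by multinomial sampling of each library against a
#' background remainder cell. \code{fold_effect} multiplies condition B.
#'
#' @param n_genes number of genes.
#' @param library_sizes length-2 numeric (A, B) total tag counts.
#' @param fold_effect scalar or per-gene vector of condition-B effects
#'   (1 = null).
#' @param abundance_range TPM range for log-uniform abundance draws; the
#'   default keeps expected counts large enough for the normal
#'   approximation of the Z test to hold.
#' @param seed integer seed.
#' @return data.frame with \code{id}, \code{x1}, \code{x2} and attributes
#'   \code{librarySizes}.
#' @export
simulateTagCounts <- function(n_genes, library_sizes = c(1e6, 1e6),
                              fold_effect = 1,
                              abundance_range = c(50, 2000), seed = 1L) {
    set.seed(childSeed(seed, 3L))
    abund <- exp(runif(n_genes, log(abundance_range[1]),
                       log(abundance_range[2])))
    fold <- rep_len(fold_effect, n_genes)
    p1 <- abund / 1e6
    p2 <- abund * fold / 1e6
    draw <- function(p, N) {
        stopifnot(sum(p) < 1)
        as.vector(rmultinom(1, N, c(p, 1 - sum(p))))[seq_along(p)]
    }
    out <- data.frame(id = sprintf("g%04d", seq_len(n_genes)),
                      x1 = draw(p1, library_sizes[1]),
                      x2 = draw(p2, library_sizes[2]),
                      stringsAsFactors = FALSE)
    attr(out, "librarySizes") <- c(A = library_sizes[1], B = library_sizes[2])
    out
}
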