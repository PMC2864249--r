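# End-to-end orchestration: trim -> collapse/filter -> ncRNA -> known
# miRNA -> hairpin discovery with miRNA* evidence -> categorisation ->
# differential Z-score profiling -> target prediction -> hotspot
# statistics, with a TSV output bundle and a run manifest. The stage order
# fixes the precedence semantics of the classification.

#' Build or load a validated run configuration
#'
#' @param fastq_a,fastq_b FASTQ files for libraries A and B.
#' @param transcripts,ncrna,matures reference FASTA files.
#' @param adapter_5p,adapter_3p adapter sequences.
#' @param outdir output directory.
#' @param min_len,max_len,min_count signature filters.
#' @param max_mm known-miRNA mismatch bound.
#' @param alpha differential significance level.
#' @param cutoff target-prediction penalty cutoff.
#' @param flank_sets hairpin candidate flank configurations.
#' @param min_loop,wobble_weight,max_duplex_mm,max_asym_bulge,min_paired_frac
#'   folding/hairpin thresholds.
#' @param mature_len_range candidate mature length window.
#' @return validated list of class \code{run_config}.
#' @export
runConfig <- function(fastq_a, fastq_b, transcripts, ncrna, matures,
                      adapter_5p, adapter_3p, outdir = "mirnaome_out",
                      min_len = 18, max_len = 30, min_count = 3,
                      max_mm = 4, alpha = 0.01, cutoff = 4.0,
                      flank_sets = list(c(100, 20), c(20, 100), c(60, 60)),
                      min_loop = 3, wobble_weight = 1.0, max_duplex_mm = 4,
                      max_asym_bulge = 2, min_paired_frac = 0.60,
                      mature_len_range = c(20, 24)) {
    cfg <- list(fastq_a = fastq_a, fastq_b = fastq_b,
                transcripts = transcripts, ncrna = ncrna, matures = matures,
                adapter_5p = toDNA(adapter_5p),
                adapter_3p = toDNA(adapter_3p), outdir = outdir,
                min_len = min_len, max_len = max_len, min_count = min_count,
                max_mm = max_mm, alpha = alpha, cutoff = cutoff,
                flank_sets = flank_sets, min_loop = min_loop,
                wobble_weight = wobble_weight, max_duplex_mm = max_duplex_mm,
                max_asym_bulge = max_asym_bulge,
                min_paired_frac = min_paired_frac,
                mature_len_range = mature_len_range)
    for (f in c("fastq_a", "fastq_b", "transcripts", "ncrna", "matures"))
        if (!file.exists(cfg[[f]]))
            stop("missing input file for '", f, "': ", cfg[[f]])
    stopifnot(cfg$min_len >= 1, cfg$max_len >= cfg$min_len,
              cfg$min_count >= 1, cfg$max_mm >= 0,
              cfg$alpha > 0, cfg$alpha < 1, cfg$cutoff >= 0)
    class(cfg) <- "run_config"
    cfg
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields map directly onto [runConfig()] arguments;
#' \code{flank_sets} is a list of two-element lists. Paths are resolved
#' relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return validated \code{run_config}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    rel <- function(p) if (grepl("^/", p)) p else file.path(base, p)
    for (f in c("fastq_a", "fastq_b", "transcripts", "ncrna", "matures",
                "outdir"))
        if (!is.null(y[[f]])) y[[f]] <- rel(y[[f]])
    if (!is.null(y$flank_sets))
        y$flank_sets <- lapply(y$flank_sets, unlist)
    do.call(runConfig, y)
}

#' Run the full small RNA -> miRNAome pipeline
#'
#' Executes every stage in fixed order and writes the output bundle:
#' category summary, known-miRNA table, novel-miRNA table, differential
#' table, target and hotspot tables, the signature table and a run
#' manifest with all parameters. The run is deterministic for fixed
#' inputs and configuration.
#'
#' @param config a [runConfig()] object (or path to a YAML file).
#' @return invisibly, the in-memory bundle (list of all stage results and
#'   output paths).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "run_config"))
    log <- character(0)
    say <- function(...) {
        msg <- paste0(...)
        log <<- c(log, msg)
        message(msg)
    }

    say("stage trim+collapse: reading FASTQ")
    table <- processLibraries(config$fastq_a, config$fastq_b,
                              config$adapter_5p, config$adapter_3p,
                              config$min_len, config$max_len,
                              config$min_count)
    ls <- librarySizes(table)
    say("  retained ", length(table), " signatures; library sizes A=",
        ls[["A"]], " B=", ls[["B"]])

    transcripts <- readFasta(config$transcripts)
    names(transcripts) <- sub(" .*", "", names(transcripts))
    ncrna <- readFasta(config$ncrna)
    matures <- readFasta(config$matures)
    names(matures) <- sub(" .*", "", names(matures))

    say("stage ncRNA classification")
    nc <- matchNoncoding(table, ncrna)
    say("  ", nrow(nc), " signatures in ncRNA classes")

    say("stage known-miRNA assignment (max_mm=", config$max_mm, ")")
    remaining <- setdiff(signatures(table), nc$sequence)
    known <- matchKnownMirnas(table, matures, config$max_mm)
    known <- known[known$sequence %in% remaining, , drop = FALSE]
    say("  ", nrow(known), " signatures assigned to ",
        length(unique(known$family)), " families")

    say("stage hairpin discovery")
    cand_seqs <- setdiff(remaining, known$sequence)
    cands <- extractCandidates(cand_seqs, transcripts, config$flank_sets,
                               config$mature_len_range)
    known_loci <- perfectHitLoci(known$sequence, transcripts)
    calls <- callNovelMirnas(cands, table, config$min_loop,
                             config$wobble_weight, config$max_duplex_mm,
                             config$max_asym_bulge, config$min_paired_frac,
                             exclude_loci = known_loci)
    acc <- calls[calls$status == "accepted", , drop = FALSE]
    say("  ", length(unique(cands$mature_seq)), " candidate matures, ",
        nrow(acc), " novel calls with miRNA* evidence")
    novel_ids <- character(0)
    if (nrow(acc)) {
        novel_ids <- sprintf("novel-%02d", seq_len(nrow(acc)))
        acc$id <- novel_ids
    }

    say("stage transcript matching + categorisation")
    tx <- matchTranscripts(table, transcripts)
    records <- categorizeSignatures(table, nc, known, tx,
                                    novel = c(acc$mature_seq, acc$star_seq))
    summary_tab <- summarizeCategories(table, records)

    say("stage differential profiling (alpha=", config$alpha, ")")
    novel_matures <- if (nrow(acc)) setNames(acc$mature_seq, acc$id)
                     else character(0)
    cm <- mirnaCountMatrix(table, known, novel_matures)
    diff <- profileDifferential(cm, librarySizes(table),
                                alpha = config$alpha)
    ds <- attr(diff, "summary")
    say("  ", ds$n_significant, " of ", ds$n, " miRNAs significant; ",
        ds$n_two_fold, " with >2-fold change")

    say("stage target prediction (cutoff=", config$cutoff, ")")
    # one representative sequence per profiled miRNA: the most abundant
    # assigned signature for a known family, the mature for a novel call
    rep_seq <- c()
    if (nrow(known)) {
        i <- match(known$sequence, signatures(table))
        tot <- rowSums(signatureCounts(table))[i]
        for (fam in unique(known$family)) {
            j <- which(known$family == fam)
            rep_seq[fam] <- known$sequence[j[which.max(tot[j])]]
        }
    }
    rep_seq <- c(rep_seq, novel_matures)
    diff_ids <- diff$id[diff$significant]
    query <- rep_seq[names(rep_seq) %in% diff_ids]
    targets <- predictTargets(query, transcripts, config$cutoff)
    say("  ", nrow(targets), " target sites on ",
        length(unique(targets$transcript_id)), " genes for ",
        length(query), " differential miRNAs")

    say("stage hotspot statistics")
    hot <- hotspotStats(unique(targets$transcript_id), tx$hits, table)
    cognate <- antisenseCognateFraction(tx$hits, table)

    # ---- write bundle -------------------------------------------------
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    N <- librarySizes(table)
    novel_tab <- if (nrow(acc)) data.frame(
        id = acc$id, sequence = toRNA(acc$mature_seq),
        tpm_A = roundHalfUp(tpm(acc$mature_count_A, N[["A"]])),
        tpm_B = roundHalfUp(tpm(acc$mature_count_B, N[["B"]])),
        fold_change = ifelse(
            acc$mature_count_A == 0 | acc$mature_count_B == 0, NA,
            roundHalfUp(foldChange(tpm(acc$mature_count_A, N[["A"]]),
                                   tpm(acc$mature_count_B, N[["B"]])
                        )$fold_change)),
        precursor_id = acc$transcript_id, strand = acc$strand,
        start = acc$precursor_start, end = acc$precursor_end,
        mature_arm = acc$mature_arm, star_seq = toRNA(acc$star_seq),
        star_found = "Yes", stringsAsFactors = FALSE)
        else data.frame()
    known_tab <- diff[diff$id %in% unique(known$family), , drop = FALSE]

    paths <- list(
        signatures = file.path(outdir, "signature_table.tsv"),
        annotation = file.path(outdir, "annotation.tsv"),
        category_summary = file.path(outdir, "category_summary.tsv"),
        novel = file.path(outdir, "novel_mirnas.tsv"),
        novel_structures = file.path(outdir, "novel_structures.txt"),
        differential = file.path(outdir, "differential.tsv"),
        known = file.path(outdir, "known_mirnas.tsv"),
        targets = file.path(outdir, "targets.tsv"),
        hotspots = file.path(outdir, "hotspots.tsv"),
        manifest = file.path(outdir, "run_manifest.yaml"))
    writeSignatureTable(table, paths$signatures)
    ann_out <- records
    ann_out$sequence <- toRNA(ann_out$sequence)
    writeTsv(ann_out, paths$annotation)
    writeTsv(summary_tab, paths$category_summary)
    writeTsv(novel_tab, paths$novel)
    con <- file(paths$novel_structures, "wb")
    if (nrow(acc))
        writeLines(paste0(">", acc$id, " ", acc$transcript_id, ":",
                          acc$precursor_start, "-", acc$precursor_end,
                          "\n", acc$dot_bracket),
                   con)
    close(con)
    writeTsv(diff, paths$differential)
    writeTsv(known_tab, paths$known)
    writeTsv(targets, paths$targets)
    writeTsv(hot, paths$hotspots)
    manifest <- c(config[setdiff(names(config), "flank_sets")],
                  list(flank_sets = lapply(config$flank_sets, as.integer),
                       n_signatures = length(table),
                       library_size_A = unname(N[["A"]]),
                       library_size_B = unname(N[["B"]]),
                       cognate_fraction_A = unname(cognate[["A"]]),
                       cognate_fraction_B = unname(cognate[["B"]])))
    yaml::write_yaml(manifest, paths$manifest)

    invisible(list(table = table, annotation = records,
                   category_summary = summary_tab, nc = nc, known = known,
                   candidates = cands, calls = calls, novel = acc,
                   novel_table = novel_tab, tx_hits = tx$hits,
                   differential = diff, targets = targets, hotspots = hot,
                   cognate_fraction = cognate, paths = paths, log = log,
                   config = config))
}

#' Human-readable summary of a pipeline run
#'
#' @param bundle the (invisible) return value of [runPipeline()].
#' @return character vector of report lines (also printed).
#' @export
pipelineReport <- function(bundle) {
    s <- bundle$category_summary
    ds <- attr(bundle$differential, "summary")
    lines <- c(
        "== mirnaome run report ==",
        sprintf("signatures: %d (library sizes A=%d B=%d)",
                length(bundle$table),
                as.integer(librarySizes(bundle$table)[["A"]]),
                as.integer(librarySizes(bundle$table)[["B"]])),
        "category (distinct A / distinct B / %distinct A):",
        sprintf("  %-22s %7d %7d %6.2f%%",
                s$category, s$distinct_A, s$distinct_B, s$pct_distinct_A),
        sprintf("novel miRNA calls with miRNA* evidence: %d",
                nrow(bundle$novel)),
        sprintf("differential miRNAs at alpha=%g: %d of %d (%d with >2-fold)",
                ds$alpha, ds$n_significant, ds$n, ds$n_two_fold),
        sprintf("target sites: %d on %d genes", nrow(bundle$targets),
                length(unique(bundle$targets$transcript_id))),
        sprintf("antisense cognate fraction: A=%.3f B=%.3f",
                bundle$cognate_fraction[["A"]],
                bundle$cognate_fraction[["B"]]))
    cat(lines, sep = "\n")
    invisible(lines)
}
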