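# TPM normalisation and the two-library tag-count Z test (pooled
# two-proportion statistic), with per-miRNA fold changes and significance
# profiling. The test runs on raw counts; TPM is for reporting and fold
# changes only.

#' Transcripts-per-million normalisation
#'
#' @param x raw count(s), \code{0 <= x <= N}.
#' @param N library size (> 0).
#' @return \code{x / N * 1e6} at full precision (reports round to one
#'   decimal with [roundHalfUp()]).
#' @examples
#' tpm(394, 1790395)   # 220.06...
#' @export
tpm <- function(x, N) {
    stopifnot(N > 0, all(x >= 0), all(x <= N))
    x / N * 1e6
}

#' Fold change between two TPM values (ratio >= 1 with direction)
#'
#' @param tpm1,tpm2 abundances in libraries A (1) and B (2); not both
#'   zero.
#' @return data.frame with \code{fold_change} (max/min; \code{Inf} when
#'   one side is zero) and \code{direction} (\code{"up_in_B"},
#'   \code{"up_in_A"}, \code{"equal"}, or \code{"exclusive_A"}/
#'   \code{"exclusive_B"} when one side is zero).
#' @examples
#' foldChange(220.1, 1248.5)   # 5.672..., up_in_B
#' @export
foldChange <- function(tpm1, tpm2) {
    stopifnot(length(tpm1) == length(tpm2), all(tpm1 >= 0), all(tpm2 >= 0),
              all(tpm1 + tpm2 > 0))
    fc <- pmax(tpm1, tpm2) / pmin(tpm1, tpm2)
    direction <- ifelse(tpm1 == 0, "exclusive_B",
                 ifelse(tpm2 == 0, "exclusive_A",
                 ifelse(tpm2 > tpm1, "up_in_B",
                 ifelse(tpm1 > tpm2, "up_in_A", "equal"))))
    data.frame(fold_change = fc, direction = direction,
               stringsAsFactors = FALSE)
}

#' Two-library tag-count Z test (pooled two-proportion statistic)
#'
#' With sample proportions \eqn{\hat p_1 = x_1/N_1},
#' \eqn{\hat p_2 = x_2/N_2} and pooled proportion
#' \eqn{\hat p_0 = (x_1+x_2)/(N_1+N_2)}:
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p_0 (1-\hat p_0)(1/N_1 + 1/N_2)}}}
#' and the p value is the two-sided standard-normal tail. \code{x1 = x2 =
#' 0} (or a degenerate pooled proportion) gives \code{z = 0, p = 1} by
#' convention.
#'
#' @param x1,x2 raw counts in libraries 1 and 2 (vectors allowed).
#' @param N1,N2 library sizes (> 0).
#' @return data.frame with columns \code{z} and \code{p}.
#' @examples
#' zTest(100, 1e6, 200, 1e6)   # z ~ -5.77, p ~ 8e-9
#' @export
zTest <- function(x1, N1, x2, N2) {
    stopifnot(N1 > 0, N2 > 0, all(x1 >= 0), all(x2 >= 0))
    p1 <- x1 / N1
    p2 <- x2 / N2
    p0 <- (x1 + x2) / (N1 + N2)
    denom <- sqrt(p0 * (1 - p0) * (1 / N1 + 1 / N2))
    z <- ifelse(p0 <= 0 | p0 >= 1 | p1 == p2, 0, (p1 - p2) / denom)
    p <- ifelse(z == 0, 1, 2 * pnorm(-abs(z)))
    data.frame(z = z, p = p)
}

#' Differential abundance profile of miRNA counts between two libraries
#'
#' Computes per-miRNA TPM, fold change, Z statistic and two-sided p, flags
#' significance at \code{alpha} (raw p, mirroring single-library-pair
#' practice) and two-fold changes; an optional Benjamini-Hochberg column
#' is available behind \code{bh}.
#'
#' @param counts data.frame with columns \code{id}, \code{x1}, \code{x2}
#'   (raw counts), e.g. from [mirnaCountMatrix()] or
#'   [simulateTagCounts()].
#' @param librarySizes length-2 numeric (N1, N2); defaults to the
#'   \code{librarySizes} attribute of \code{counts}.
#' @param alpha significance level on the raw p value (default 0.01).
#' @param bh add a Benjamini-Hochberg adjusted column \code{p_bh}.
#' @return data.frame sorted by p (ties by id): id, raw counts, TPMs,
#'   fold change and direction, z, p, \code{significant}, \code{two_fold};
#'   summary counts are attached as attribute \code{"summary"}.
#' @export
profileDifferential <- function(counts, librarySizes = NULL, alpha = 0.01,
                                bh = FALSE) {
    if (is.null(librarySizes))
        librarySizes <- attr(counts, "librarySizes")
    stopifnot(!is.null(librarySizes), length(librarySizes) == 2,
              all(librarySizes > 0),
              all(c("id", "x1", "x2") %in% names(counts)))
    N1 <- librarySizes[[1]]; N2 <- librarySizes[[2]]
    tpm1 <- tpm(counts$x1, N1)
    tpm2 <- tpm(counts$x2, N2)
    both_zero <- counts$x1 == 0 & counts$x2 == 0
    fc <- data.frame(fold_change = rep(NA_real_, nrow(counts)),
                     direction = rep("equal", nrow(counts)),
                     stringsAsFactors = FALSE)
    if (any(!both_zero)) fc[!both_zero, ] <- foldChange(tpm1[!both_zero],
                                                        tpm2[!both_zero])
    zt <- zTest(counts$x1, N1, counts$x2, N2)
    out <- data.frame(id = counts$id, x1 = counts$x1, x2 = counts$x2,
                      tpm1 = tpm1, tpm2 = tpm2,
                      fold_change = fc$fold_change,
                      direction = fc$direction,
                      z = zt$z, p = zt$p,
                      significant = zt$p < alpha,
                      two_fold = !is.na(fc$fold_change) & fc$fold_change > 2,
                      stringsAsFactors = FALSE)
    if (bh) {
        out$p_bh <- p.adjust(out$p, method = "BH")
        out$significant_bh <- out$p_bh < alpha
    }
    out <- out[order(out$p, out$id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "summary") <- list(
        n = nrow(out), n_significant = sum(out$significant),
        n_two_fold = sum(out$two_fold),
        n_significant_two_fold = sum(out$significant & out$two_fold),
        alpha = alpha)
    out
}
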