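#' Observed phenotype-class frequencies per marker
#'
#' Converts genotype counts into the three observed phenotype fractions
#' used by the trinomial Hardy-Weinberg estimators: `pO` (A-like
#' homozygotes), `qO` (B-like homozygotes) and `pqO`
#' (heterozygote-like), each divided by the chosen denominator `n`.
#' The default denominator counts only successfully called individuals;
#' `"total"` uses all samples including no-calls, which in the presence
#' of a frequent null allele gives slightly smaller loss estimates.
#'
#' @param x a [GenotypeCounts-class] object
#' @param denominator `"called"` (default) or `"total"`
#' @param onDegenerate what to do with markers whose denominator is
#'   zero: `"error"` (default) or `"na"` (return `NA` fractions)
#' @return `DataFrame` with columns `pO`, `qO`, `pqO`, `n`,
#'   `noCallRate` (no-calls over total samples), one row per marker.
#' @examples
#' gc <- genotypeCounts(rbind(m1 = c(nAA = 32, nAB = 32, nBB = 32,
#'     nNoCall = 4)))
#' phenotypeFrequencies(gc)
#' @export
phenotypeFrequencies <- function(x,
        denominator = c("called", "total"),
        onDegenerate = c("error", "na")) {
    denominator <- match.arg(denominator)
    onDegenerate <- match.arg(onDegenerate)
    cnt <- countsMatrix(x)
    called <- nCalled(x)
    total <- nTotal(x)
    n <- if (denominator == "called") called else total
    if (any(n == 0L)) {
        if (onDegenerate == "error")
            stop("degenerate marker(s) with zero denominator: '",
                markerNames(x)[which(n == 0L)[1L]], "'")
        n[n == 0L] <- NA_integer_
    }
    res <- DataFrame(
        pO = unname(cnt[, "nAA"] / n),
        qO = unname(cnt[, "nBB"] / n),
        pqO = unname(cnt[, "nAB"] / n),
        n = unname(n),
        noCallRate = unname(
            ifelse(total > 0L, cnt[, "nNoCall"] / total, NA_real_)))
    rownames(res) <- markerNames(x)
    res
}

#' Closed-form copy-loss (null-allele) frequency estimator
#'
#' Under a three-allele Hardy-Weinberg model with a silent (null) allele
#' at frequency r, expected phenotype fractions are
#' `pO = p^2 + 2pr`, `qO = q^2 + 2qr`, `pqO = 2pq`, and inverting the
#' trinomial expansion of `(p + q + r)^2 = 1` gives the estimator
#'
#' `rl = sqrt(0.25 - 0.25 * pqO + pO * qO / pqO) - 0.5`
#'
#' Negative values are retained: they are meaningful evidence of copy
#' gain (a duplication makes the locus look "better than HWE"). Values
#' above 1 cannot arise on an autosome and are the signature of
#' misplaced sex-chromosome markers (see [flagNonAutosomal()]).
#'
#' Edge cases: `pqO == 0` with both homozygote classes present returns
#' `Inf` (total absence of heterozygotes, hemizygous-like);
#' a monomorphic marker (fewer than two phenotype classes observed)
#' returns `NA`.
#'
#' @param pO,qO,pqO observed phenotype fractions (vectorised), e.g.
#'   columns of [phenotypeFrequencies()]
#' @return numeric vector of loss-allele frequencies (dimensionless
#'   fractions; multiply by 100 for the percent scale)
#' @examples
#' estimateLoss(0.32, 0.32, 0.32)  # null allele at r = 0.2
#' estimateLoss(0.25, 0.25, 0.50)  # exact HWE: 0
#' @export
estimateLoss <- function(pO, qO, pqO) {
    rl <- rep(NA_real_, length(pqO))
    pos <- !is.na(pqO) & pqO > 0
    rad <- 0.25 - 0.25 * pqO[pos] + pO[pos] * qO[pos] / pqO[pos]
    rl[pos] <- sqrt(pmax(rad, 0)) - 0.5
    sexlike <- !is.na(pqO) & pqO == 0 & pO > 0 & qO > 0
    rl[sexlike] <- Inf
    # monomorphic (fewer than two observed classes): undefined
    mono <- !is.na(pqO) &
        ((pqO > 0) + (pO > 0) + (qO > 0)) < 2L
    rl[mono] <- NA_real_
    rl
}

#' Closed-form copy-gain (duplication-allele) frequency estimator
#'
#' Under a gain model where the duplicated haplotype carries both SNP
#' alleles (so every carrier looks heterozygote-like), expected
#' fractions are `pO = p^2`, `qO = q^2`, `pqO = 1 - p^2 - q^2`, giving
#'
#' `rg = sqrt(pO + qO + pqO) - sqrt(pO) - sqrt(qO)`
#'
#' At a pure-HWE biallelic locus this is 0; at a null-allele (deletion)
#' locus it is negative with magnitude close to the loss frequency,
#' which is why loss and gain estimates are strongly anti-correlated.
#'
#' @inheritParams estimateLoss
#' @param polymorphic optional logical vector; markers marked `FALSE`
#'   return `NA`
#' @return numeric vector of gain-allele frequencies
#' @examples
#' estimateGain(0.25, 0.09, 0.66)  # gain allele at g = 0.2
#' @export
estimateGain <- function(pO, qO, pqO, polymorphic = NULL) {
    rg <- sqrt(pO + qO + pqO) - sqrt(pO) - sqrt(qO)
    if (!is.null(polymorphic))
        rg[!polymorphic] <- NA_real_
    rg
}

#' Chi-square test of Hardy-Weinberg equilibrium per marker
#'
#' Standard biallelic 1-df goodness-of-fit chi-square on called
#' genotypes, no continuity correction. Allele frequency is estimated
#' as `(2 nAA + nAB) / (2 nCalled)`, expected class counts are
#' `nCalled * (p^2, 2pq, q^2)`. Monomorphic markers get statistic 0 and
#' p-value 1 (no test possible).
#'
#' @param x a [GenotypeCounts-class] object
#' @return `DataFrame` with columns `chi2` and `chi2P`
#' @examples
#' gc <- genotypeCounts(rbind(m1 = c(nAA = 25, nAB = 50, nBB = 25,
#'     nNoCall = 0)))
#' hweChisq(gc)
#' @export
hweChisq <- function(x) {
    cnt <- countsMatrix(x)
    nc <- nCalled(x)
    p <- ifelse(nc > 0, (2 * cnt[, "nAA"] + cnt[, "nAB"]) / (2 * nc), NA)
    q <- 1 - p
    stat <- rep(NA_real_, nrow(cnt))
    ok <- !is.na(p) & p > 0 & p < 1
    e <- cbind(p[ok]^2, 2 * p[ok] * q[ok], q[ok]^2) * nc[ok]
    o <- cnt[ok, c("nAA", "nAB", "nBB"), drop = FALSE]
    stat[ok] <- rowSums((o - e)^2 / e)
    stat[!is.na(p) & !ok] <- 0
    pval <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    pval[stat == 0] <- 1
    res <- DataFrame(chi2 = stat, chi2P = pval)
    rownames(res) <- markerNames(x)
    res
}

#' Expected number of no-calls under a segregating null allele
#'
#' Individuals homozygous for a null allele at frequency `rl` give no
#' genotype signal, so at least `n * rl^2` no-calls are expected among
#' `n` individuals. Negative loss estimates (gain evidence) contribute
#' nothing and are clamped to zero; non-finite estimates return `NA`.
#'
#' @param rl loss-allele frequency (fraction)
#' @param n number of individuals
#' @return expected no-call count (vectorised)
#' @examples
#' expectedNoCalls(0.5, 912)  # 228
#' @export
expectedNoCalls <- function(rl, n) {
    out <- n * pmax(rl, 0)^2
    out[!is.finite(rl)] <- NA_real_
    out
}

#' Per-marker Hardy-Weinberg copy-number scan
#'
#' Runs the full per-marker HWE analysis: phenotype fractions, loss and
#' gain frequency estimates, the HWE chi-square screen, the expected
#' no-call count, the polymorphism filter, and the non-autosomal flag
#' (`rl > 1`, i.e. a loss frequency above 100%, impossible on a true
#' autosome).
#'
#' @param x a [GenotypeCounts-class] object
#' @param denominator passed to [phenotypeFrequencies()]
#' @return `DataFrame` with one row per marker: `markerId`,
#'   `chromosome`, `position`, `nCalled`, `nNoCall`, `pO`, `qO`, `pqO`,
#'   `rl`, `rg`, `chi2P`, `expNoCalls`, `polymorphic`,
#'   `nonautosomalFlag`. `rl` and `rg` are fractions; multiply by 100
#'   for the percent scale used in reports.
#' @seealso [writeMarkerMetrics()], [combineMetrics()]
#' @export
hweScan <- function(x, denominator = c("called", "total")) {
    denominator <- match.arg(denominator)
    cnt <- countsMatrix(x)
    fr <- phenotypeFrequencies(x, denominator, onDegenerate = "na")
    poly <- rowSums(cnt[, c("nAA", "nAB", "nBB"), drop = FALSE] > 0L) >= 2L
    rl <- estimateLoss(fr$pO, fr$qO, fr$pqO)
    rl[!poly] <- NA_real_
    rg <- estimateGain(fr$pO, fr$qO, fr$pqO, polymorphic = poly)
    chi <- hweChisq(x)
    res <- DataFrame(
        markerId = markerNames(x),
        chromosome = markerMap(x)$chromosome,
        position = markerMap(x)$position,
        nCalled = unname(nCalled(x)),
        nNoCall = unname(cnt[, "nNoCall"]),
        pO = fr$pO, qO = fr$qO, pqO = fr$pqO,
        rl = rl, rg = rg,
        chi2P = chi$chi2P,
        expNoCalls = expectedNoCalls(rl, fr$n),
        polymorphic = poly,
        nonautosomalFlag = !is.na(rl) & rl > 1)
    rownames(res) <- markerNames(x)
    res
}

#' Report markers flagged as non-autosomal, grouped into runs
#'
#' Markers whose loss-frequency estimate exceeds 100% (`rl > 1`,
#' including the infinite no-heterozygote case) cannot be autosomal
#' under the model; clustered runs of such markers point to a
#' sex-chromosome region misplaced onto an autosome in the assembly.
#' Flagged markers are grouped into maximal runs of markers that are
#' consecutive in their chromosome's position order, so a misplaced
#' block shows up as one contiguous run.
#'
#' @param metrics output of [hweScan()] (needs columns `markerId`,
#'   `chromosome`, `position`, `nonautosomalFlag`)
#' @return `DataFrame` with one row per run: `chromosome`, `start`,
#'   `end`, `nMarkers`, `markerIds` (comma-separated, position order)
#' @export
flagNonAutosomal <- function(metrics) {
    df <- as.data.frame(metrics[, c("markerId", "chromosome", "position",
        "nonautosomalFlag")])
    df <- df[!is.na(df$chromosome) & !is.na(df$position), , drop = FALSE]
    out <- list()
    for (chr in unique(df$chromosome)) {
        d <- df[df$chromosome == chr, , drop = FALSE]
        d <- d[order(d$position), , drop = FALSE]
        r <- rle(d$nonautosomalFlag)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
            idx <- starts[k]:ends[k]
            out[[length(out) + 1L]] <- DataFrame(
                chromosome = chr,
                start = d$position[idx[1L]],
                end = d$position[idx[length(idx)]],
                nMarkers = length(idx),
                markerIds = paste(d$markerId[idx], collapse = ","))
        }
    }
    if (!length(out))
        return(DataFrame(chromosome = character(), start = integer(),
            end = integer(), nMarkers = integer(),
            markerIds = character()))
    do.call(rbind, out)
}

#' Write per-marker metrics as a tab-delimited table
#'
#' Frequencies are written both as fractions (`rl`, `rg`) and percent
#' (`rlPct`, `rgPct`) to match the reporting convention of SNP-array
#' CNV surveys.
#'
#' @param metrics output of [hweScan()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMarkerMetrics <- function(metrics, path) {
    df <- as.data.frame(metrics)
    df$rlPct <- 100 * df$rl
    df$rgPct <- 100 * df$rg
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read back a per-marker metrics table written by [writeMarkerMetrics()]
#' @param path file path
#' @return `DataFrame` of metrics
#' @export
readMarkerMetrics <- function(path) {
    df <- utils::read.delim(path, header = TRUE,
        colClasses = list(chromosome = "character"))
    DataFrame(df)
}
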