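#' @import methods
#' @importFrom S4Vectors DataFrame isEmpty
NULL

#' Per-marker genotype phenotype-class counts
#'
#' `GenotypeCounts` holds, for each SNP marker, the number of samples in
#' each of the four observable phenotype classes of a biallelic call:
#' A-like homozygote, heterozygote-like, B-like homozygote, and no-call.
#' These four counts are the sufficient statistic for all the
#' Hardy-Weinberg copy-number mathematics in this package.
#'
#' The optional marker map carries chromosome labels and 1-based bp
#' positions. Markers without map information are retained in the counts
#' (their `chromosome`/`position` are `NA`) but excluded from
#' position-dependent steps such as region clustering.
#'
#' @slot counts integer matrix, one row per marker, columns
#'   `nAA`, `nAB`, `nBB`, `nNoCall`; rownames are marker identifiers.
#' @slot map [S4Vectors::DataFrame] aligned with the rows of `counts`,
#'   with columns `chromosome` (character) and `position` (integer,
#'   1-based).
#'
#' @seealso [genotypeCounts()], [countsFromMatrix()], [readFinalReport()]
#' @export
setClass("GenotypeCounts",
    slots = c(counts = "matrix", map = "DataFrame"))

setValidity("GenotypeCounts", function(object) {
    cnt <- object@counts
    msg <- character()
    if (!identical(colnames(cnt), c("nAA", "nAB", "nBB", "nNoCall")))
        msg <- c(msg, "counts columns must be nAA, nAB, nBB, nNoCall")
    if (is.null(rownames(cnt)))
        msg <- c(msg, "counts must have marker identifiers as rownames")
    else if (anyDuplicated(rownames(cnt)))
        msg <- c(msg, sprintf("duplicated marker identifier: '%s'",
            rownames(cnt)[anyDuplicated(rownames(cnt))]))
    if (length(cnt) && (any(is.na(cnt)) || any(cnt < 0)))
        msg <- c(msg, "all counts must be non-negative and non-missing")
    if (nrow(object@map) != nrow(cnt))
        msg <- c(msg, "map must have one row per marker")
    if (!all(c("chromosome", "position") %in% colnames(object@map)))
        msg <- c(msg, "map must have columns chromosome and position")
    pos <- object@map$position
    if (any(!is.na(pos) & pos < 1))
        msg <- c(msg, "positions must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Simulation scenario: planted per-marker truth
#'
#' A `ScenarioSpec` describes a synthetic SNP panel marker by marker:
#' the inheritance model at each locus, its allele frequencies, the
#' planted CNV-allele frequency, and panel-level nuisance parameters.
#' Together with a seed it fully determines the simulator output.
#'
#' Models:
#' \describe{
#'   \item{`hwe`}{ordinary biallelic Hardy-Weinberg locus (`p + q = 1`,
#'     `cnvFreq = 0`).}
#'   \item{`null_allele`}{segregating deletion: a third, silent allele at
#'     frequency `cnvFreq`; heterozygous carriers look homozygous,
#'     deletion homozygotes are no-calls (`p + q + cnvFreq = 1`).}
#'   \item{`gain_allele`}{segregating duplication carrying both SNP
#'     alleles at frequency `cnvFreq`; every carrier looks
#'     heterozygote-like (`p + q + cnvFreq = 1`).}
#'   \item{`hemizygous_x`}{single-copy (X-like in an all-male panel)
#'     locus: one gamete drawn, so no true heterozygotes
#'     (`p + q = 1`).}
#' }
#'
#' Markers sharing a `clusterId` share one CNV event per individual
#' (the deletion or duplication haplotype spans the whole cluster), which
#' is what makes planted clusters recoverable as multi-marker regions.
#'
#' @slot markers [S4Vectors::DataFrame] with columns `markerId`,
#'   `chromosome`, `position`, `model`, `p`, `q`, `cnvFreq`, `clusterId`.
#' @slot nSamples integer, number of individuals (default study scale 912).
#' @slot noCallRate numeric in `[0,1]`, independent technical no-call
#'   probability applied after the genetic model.
#' @slot siDetectionRate numeric in `[0,1]`, probability that a true CNV
#'   carrier yields a rawcnv call at its cluster.
#' @slot falsePositiveRate numeric in `[0,1]`, probability that a
#'   non-carrier yields a spurious single-copy-loss call at a CNV cluster.
#'
#' @seealso [scenarioSpec()], [simulateGenotypes()], [simulateRawcnv()]
#' @export
setClass("ScenarioSpec",
    slots = c(markers = "DataFrame", nSamples = "integer",
        noCallRate = "numeric", siDetectionRate = "numeric",
        falsePositiveRate = "numeric"))

.scenarioModels <- c("hwe", "null_allele", "gain_allele", "hemizygous_x")

setValidity("ScenarioSpec", function(object) {
    m <- object@markers
    msg <- character()
    need <- c("markerId", "chromosome", "position", "model", "p", "q",
        "cnvFreq", "clusterId")
    if (!all(need %in% colnames(m)))
        return(paste("markers must have columns:",
            paste(need, collapse = ", ")))
    if (anyDuplicated(m$markerId))
        msg <- c(msg, "markerId must be unique")
    if (!all(m$model %in% .scenarioModels))
        msg <- c(msg, paste("model must be one of:",
            paste(.scenarioModels, collapse = ", ")))
    bad <- m$p < 0 | m$q < 0 | m$cnvFreq < 0 | m$cnvFreq > 1
    if (any(bad))
        msg <- c(msg, "allele frequencies must lie in [0,1]")
    tot <- m$p + m$q + ifelse(m$model %in% c("null_allele", "gain_allele"),
        m$cnvFreq, 0)
    if (any(abs(tot - 1) > 1e-8))
        msg <- c(msg, "per-marker allele frequencies must sum to 1")
    if (any(m$model %in% c("hwe", "hemizygous_x") & m$cnvFreq != 0))
        msg <- c(msg, "cnvFreq must be 0 for hwe/hemizygous_x markers")
    if (object@nSamples < 1L)
        msg <- c(msg, "nSamples must be >= 1")
    for (nm in c("noCallRate", "siDetectionRate", "falsePositiveRate")) {
        v <- slot(object, nm)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("%s must be a single value in [0,1]", nm))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeCounts", function(object) {
    cnt <- object@counts
    cat(sprintf("GenotypeCounts: %d markers x %d samples\n",
        nrow(cnt), if (nrow(cnt)) sum(cnt[1L, ]) else 0L))
    mapped <- sum(!is.na(object@map$chromosome))
    cat(sprintf("  markers with map positions: %d\n", mapped))
    if (nrow(cnt)) {
        k <- head(seq_len(nrow(cnt)), 5L)
        print(cbind(as.data.frame(cnt[k, , drop = FALSE]),
            as.data.frame(object@map[k, , drop = FALSE])))
        if (nrow(cnt) > 5L) cat("  ...\n")
    }
    invisible(NULL)
})

setMethod("show", "ScenarioSpec", function(object) {
    tab <- table(object@markers$model)
    cat(sprintf(
        "ScenarioSpec: %d markers, %d samples\n", nrow(object@markers),
        object@nSamples))
    cat("  models:", paste(sprintf("%s=%d", names(tab), tab),
        collapse = ", "), "\n")
    cat(sprintf(
        "  noCallRate=%g siDetectionRate=%g falsePositiveRate=%g\n",
        object@noCallRate, object@siDetectionRate,
        object@falsePositiveRate))
    invisible(NULL)
})
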