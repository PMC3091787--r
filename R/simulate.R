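#' Build a block of scenario markers
#'
#' Helper for assembling the per-marker table of a [ScenarioSpec-class].
#' All markers in a block share a model; allele frequencies may be
#' scalar or per-marker vectors. For the CNV models, `p` and `q` are
#' scaled so that `p + q + cnvFreq = 1` if they were given as a
#' two-allele simplex.
#'
#' @param n number of markers
#' @param model one of `"hwe"`, `"null_allele"`, `"gain_allele"`,
#'   `"hemizygous_x"`
#' @param chromosome chromosome label(s)
#' @param start position of the first marker (bp)
#' @param spacing gap between consecutive markers (bp)
#' @param p,q SNP allele frequencies (recycled)
#' @param cnvFreq CNV-allele frequency (`r` for loss, `g` for gain)
#' @param clusterId optional shared cluster label; markers sharing it
#'   carry one CNV event per individual (a haplotype spanning the
#'   cluster)
#' @param prefix marker-name prefix
#' @return `DataFrame` of scenario marker rows
#' @export
markerBlock <- function(n, model = "hwe", chromosome = "1",
        start = 1e6, spacing = 5e4, p = 0.5, q = NULL, cnvFreq = 0,
        clusterId = NA_character_, prefix = "m") {
    cnv <- if (model %in% c("null_allele", "gain_allele")) cnvFreq else 0
    p <- rep_len(p, n); cnv <- rep_len(cnv, n)
    if (is.null(q)) q <- 1 - p - cnv else q <- rep_len(q, n)
    # rescale a two-allele simplex to leave room for the CNV allele
    off <- abs(p + q + cnv - 1) > 1e-8 & abs(p + q - 1) < 1e-8
    p[off] <- p[off] * (1 - cnv[off])
    q[off] <- q[off] * (1 - cnv[off])
    DataFrame(
        markerId = sprintf("%s%03d", prefix, seq_len(n)),
        chromosome = rep_len(as.character(chromosome), n),
        position = as.integer(round(start + (seq_len(n) - 1L) * spacing)),
        model = model,
        p = p, q = q,
        cnvFreq = rep_len(cnvFreq, n) *
            (model %in% c("null_allele", "gain_allele")),
        clusterId = rep_len(as.character(clusterId), n))
}

#' Construct a ScenarioSpec
#'
#' @param markers per-marker table, e.g. built with [markerBlock()]
#'   (rows from several blocks can be combined with `rbind`)
#' @param nSamples number of individuals (default 912, the study scale
#'   of a national AI-sire genotyping panel)
#' @param noCallRate technical no-call probability (default 0.01)
#' @param siDetectionRate probability that a true CNV carrier yields a
#'   rawcnv call (default 0.3; per-sample CNV calling from array
#'   intensities is conservative, with moderate power)
#' @param falsePositiveRate probability that a non-carrier yields a
#'   spurious loss call at a CNV cluster (default 0)
#' @return a [ScenarioSpec-class]
#' @export
scenarioSpec <- function(markers, nSamples = 912L, noCallRate = 0.01,
        siDetectionRate = 0.3, falsePositiveRate = 0) {
    new("ScenarioSpec", markers = DataFrame(markers),
        nSamples = as.integer(nSamples), noCallRate = noCallRate,
        siDetectionRate = siDetectionRate,
        falsePositiveRate = falsePositiveRate)
}

#' Study-style scenario: HWE background plus planted CNV clusters
#'
#' Builds a panel shaped like the estimators' target data: a large
#' background of ordinary HWE markers (allele frequencies drawn
#' uniformly from `pRange`) spread over autosomes 1-29 at chip-like
#' spacing, plus planted multi-marker null-allele and gain-allele
#' clusters whose members sit `clusterGap` bp apart (close enough to be
#' chained into one region by the default 500 bp clustering rule).
#'
#' @param nBackground number of background HWE markers
#' @param nLossClusters,nGainClusters number of planted clusters
#' @param clusterSize markers per planted cluster
#' @param cnvFreq planted CNV-allele frequency
#' @param clusterGap gap between cluster members, bp
#' @param spacing background marker spacing, bp
#' @param pRange range of background allele frequencies
#' @param seed RNG seed for the background frequency draw
#' @param ... further arguments to [scenarioSpec()]
#' @return a [ScenarioSpec-class]
#' @export
makeStudyScenario <- function(nBackground = 5000L, nLossClusters = 10L,
        nGainClusters = 10L, clusterSize = 5L, cnvFreq = 0.15,
        clusterGap = 300, spacing = 5e4, pRange = c(0.1, 0.9),
        seed = 1L, ...) {
    set.seed(seed)
    nchr <- 29L
    perChr <- ceiling(nBackground / nchr)
    chrom <- rep(as.character(seq_len(nchr)), each = perChr)[
        seq_len(nBackground)]
    within <- (seq_len(nBackground) - 1L) %% perChr
    bg <- markerBlock(nBackground, "hwe", prefix = "bg")
    bg$chromosome <- chrom
    bg$position <- as.integer(1e6 + within * spacing)
    bg$p <- stats::runif(nBackground, pRange[1L], pRange[2L])
    bg$q <- 1 - bg$p
    blocks <- list(bg)
    addClusters <- function(kind, nClusters, tag, base) {
        for (i in seq_len(nClusters)) {
            blk <- markerBlock(clusterSize, kind,
                chromosome = as.character((i - 1L) %% nchr + 1L),
                start = base + (i - 1L) * 1e6, spacing = clusterGap,
                p = 0.5, q = 0.5, cnvFreq = cnvFreq,
                clusterId = sprintf("%s%02d", tag, i),
                prefix = sprintf("%s%02d_", tag, i))
            blocks[[length(blocks) + 1L]] <<- blk
        }
    }
    addClusters("null_allele", nLossClusters, "loss", 5e8)
    addClusters("gain_allele", nGainClusters, "gain", 7e8)
    scenarioSpec(do.call(rbind, blocks), ...)
}

.clusterKeys <- function(markers) {
    ifelse(is.na(markers$clusterId) | markers$clusterId == "NA",
        paste0(".singleton.", markers$markerId), markers$clusterId)
}

#' Simulate a genotype panel from a scenario
#'
#' Each individual receives two gametes drawn i.i.d. from the marker's
#' allele distribution (one gamete for hemizygous markers). Phenotype
#' mapping: at a null-allele locus, deletion heterozygotes look
#' homozygous for their remaining allele and deletion homozygotes are
#' no-calls; at a gain locus every duplication carrier looks
#' heterozygote-like; otherwise the usual three biallelic classes.
#' Technical no-calls are then applied independently at the scenario's
#' `noCallRate`. Markers sharing a `clusterId` share one CNV copy state
#' per individual.
#'
#' @param spec a [ScenarioSpec-class]
#' @param seed integer seed; the same spec and seed give identical
#'   output
#' @return list with elements
#'   \describe{
#'     \item{`genotypes`}{integer matrix samples x markers, codes
#'       `0/1/2/NA`}
#'     \item{`truth`}{the scenario markers plus realised class counts
#'       (`nAA`, `nAB`, `nBB`, `nNoCall`) tallied at generation time}
#'     \item{`cnvCopies`}{integer matrix samples x CNV clusters of true
#'       copy numbers (2 - k deletions or 2 + k duplications)}
#'     \item{`clusters`}{`DataFrame` describing each CNV cluster (key,
#'       model, chromosome, span, member markers)}
#'   }
#' @export
simulateGenotypes <- function(spec, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    mk <- spec@markers
    n <- spec@nSamples
    samples <- sprintf("s%04d", seq_len(n))
    geno <- matrix(NA_integer_, nrow = n, ncol = nrow(mk),
        dimnames = list(samples, mk$markerId))
    keys <- .clusterKeys(mk)
    isCnv <- mk$model %in% c("null_allele", "gain_allele")
    cnvKeys <- unique(keys[isCnv])
    copies <- matrix(2L, nrow = n, ncol = length(cnvKeys),
        dimnames = list(samples, cnvKeys))
    # one CNV-allele dosage per individual per cluster
    kDose <- lapply(cnvKeys, function(key) {
        i <- which(keys == key)[1L]
        if (mk$cnvFreq[i] == 0) rep(0L, n)   # exact HWE nesting
        else stats::rbinom(n, 2L, mk$cnvFreq[i])
    })
    names(kDose) <- cnvKeys
    for (j in seq_len(nrow(mk))) {
        model <- mk$model[j]
        p <- mk$p[j]; q <- mk$q[j]
        pA <- p / (p + q)
        if (model == "hemizygous_x") {
            g <- ifelse(stats::runif(n) < pA, 0L, 2L)
        } else if (model == "hwe") {
            g <- 2L - stats::rbinom(n, 2L, pA)
        } else {
            k <- kDose[[keys[j]]]
            g <- integer(n)
            two <- k == 0L
            g[two] <- 2L - stats::rbinom(sum(two), 2L, pA)
            if (model == "null_allele") {
                one <- k == 1L
                g[one] <- ifelse(stats::runif(sum(one)) < pA, 0L, 2L)
                g[k == 2L] <- NA_integer_
                copies[, keys[j]] <- 2L - k
            } else {
                g[k >= 1L] <- 1L
                copies[, keys[j]] <- 2L + k
            }
        }
        geno[, j] <- g
    }
    if (spec@noCallRate > 0)
        geno[stats::runif(length(geno)) < spec@noCallRate] <- NA_integer_
    truth <- mk
    truth$nAA <- as.integer(colSums(geno == 0L, na.rm = TRUE))
    truth$nAB <- as.integer(colSums(geno == 1L, na.rm = TRUE))
    truth$nBB <- as.integer(colSums(geno == 2L, na.rm = TRUE))
    truth$nNoCall <- as.integer(colSums(is.na(geno)))
    clusters <- do.call(rbind, lapply(cnvKeys, function(key) {
        idx <- which(keys == key)
        idx <- idx[order(mk$position[idx])]
        DataFrame(key = key, model = mk$model[idx[1L]],
            chromosome = mk$chromosome[idx[1L]],
            start = min(mk$position[idx]), end = max(mk$position[idx]),
            nMarkers = length(idx),
            startSnp = mk$markerId[idx[1L]],
            endSnp = mk$markerId[idx[length(idx)]])
    }))
    list(genotypes = geno, truth = truth, cnvCopies = copies,
        clusters = clusters)
}

#' Simulate a matched rawcnv call list
#'
#' Each true CNV carrier (an individual with copy number other than 2
#' at a planted cluster) emits a call spanning the cluster with
#' probability `siDetectionRate`; the call's copy number is the
#' carrier's true copy number. Non-carriers emit a spurious
#' single-copy-loss call with probability `falsePositiveRate`
#' (default 0).
#'
#' @param spec the [ScenarioSpec-class] used for [simulateGenotypes()]
#' @param sim the result of [simulateGenotypes()]
#' @param seed integer seed
#' @return `GRanges` of calls, writable with [writeRawcnv()]
#' @export
simulateRawcnv <- function(spec, sim, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    cl <- sim$clusters
    out <- list()
    samples <- rownames(sim$genotypes)
    for (i in seq_len(if (is.null(cl)) 0L else nrow(cl))) {
        cn <- sim$cnvCopies[, cl$key[i]]
        carrier <- which(cn != 2L)
        hit <- carrier[stats::runif(length(carrier)) <
            spec@siDetectionRate]
        emitCn <- cn[hit]
        if (spec@falsePositiveRate > 0) {
            nonc <- which(cn == 2L)
            fp <- nonc[stats::runif(length(nonc)) <
                spec@falsePositiveRate]
            hit <- c(hit, fp)
            emitCn <- c(emitCn, rep(1L, length(fp)))
        }
        if (!length(hit)) next
        gr <- GRanges(rep(cl$chromosome[i], length(hit)),
            IRanges(rep(cl$start[i], length(hit)),
                rep(cl$end[i], length(hit))))
        mcols(gr) <- DataFrame(
            copyNumber = as.integer(emitCn),
            state = .cnToState(emitCn),
            numSnps = rep(cl$nMarkers[i], length(hit)),
            sampleId = samples[hit],
            startSnp = rep(cl$startSnp[i], length(hit)),
            endSnp = rep(cl$endSnp[i], length(hit)),
            conf = rep(NA_real_, length(hit)))
        out[[length(out) + 1L]] <- gr
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(copyNumber = integer(), state = integer(),
            numSnps = integer(), sampleId = character(),
            startSnp = character(), endSnp = character(),
            conf = numeric())
        return(gr)
    }
    suppressWarnings(do.call(c, out))
}

#' Simulate a scenario and write its files
#'
#' Writes the four artifacts of a synthetic study into `dir`: a
#' GenomeStudio-style final report (`report.txt`), the marker map
#' (`map.tsv`), the matched rawcnv call list (`calls.rawcnv`) and the
#' planted-truth table (`truth.tsv`).
#'
#' @param spec a [ScenarioSpec-class]
#' @param dir output directory (created if needed)
#' @param seed integer seed governing all randomness
#' @return named list of file paths, plus the in-memory `sim` result
#' @export
simulateScenario <- function(spec, dir, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    sim <- simulateGenotypes(spec)
    calls <- simulateRawcnv(spec, sim)
    paths <- list(
        report = file.path(dir, "report.txt"),
        map = file.path(dir, "map.tsv"),
        rawcnv = file.path(dir, "calls.rawcnv"),
        truth = file.path(dir, "truth.tsv"))
    writeFinalReport(sim$genotypes, paths$report)
    writeMarkerMap(as.data.frame(spec@markers), paths$map)
    writeRawcnv(calls, paths$rawcnv)
    utils::write.table(as.data.frame(sim$truth), paths$truth,
        sep = "\t", quote = FALSE, row.names = FALSE)
    c(paths, list(sim = sim, calls = calls))
}
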