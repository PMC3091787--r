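#' Merge HWE and SI per-marker metrics into one table
#'
#' Joins the output of [hweScan()] with the output of
#' [markerSiFrequencies()] by marker identifier and adds the percent
#' columns (`rlPct`, `rgPct`) on which thresholds are calibrated.
#' Markers missing from the SI table get `lSi = gSi = 0` (no CNV call
#' covering them means two reference copies).
#'
#' @param hwe output of [hweScan()]
#' @param si output of [markerSiFrequencies()]
#' @return combined `DataFrame`
#' @export
combineMetrics <- function(hwe, si) {
    idx <- match(hwe$markerId, si$markerId)
    res <- hwe
    res$rlPct <- 100 * hwe$rl
    res$rgPct <- 100 * hwe$rg
    res$lSi <- ifelse(is.na(idx), 0, si$lSi[idx])
    res$gSi <- ifelse(is.na(idx), 0, si$gSi[idx])
    res
}

.eligible <- function(metrics) {
    metrics$polymorphic & !metrics$nonautosomalFlag &
        is.finite(metrics$rlPct) & is.finite(metrics$rgPct)
}

.meanSd <- function(v) {
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))  # population SD
    c(mean = mu, sd = sdev, threshold = mu + sdev)
}

#' Calibrate mean + 1 SD selection thresholds
#'
#' For each of the four per-marker metrics (HWE loss `rlPct`, SI loss
#' `lSi`, HWE gain `rgPct`, SI gain `gSi`) the threshold is the mean
#' plus `sdMultiplier` population standard deviations, computed over
#' eligible markers only: polymorphic, not flagged non-autosomal, with
#' finite estimates. Thresholds are on the percent scale.
#'
#' @param metrics combined metrics table from [combineMetrics()]
#' @param sdMultiplier number of SDs above the mean (default 1)
#' @return list with per-metric `mean`, `sd` and thresholds
#'   `tRl`, `tLsi`, `tRg`, `tGsi`
#' @export
calibrateThresholds <- function(metrics, sdMultiplier = 1) {
    keep <- .eligible(metrics)
    if (sum(keep) < 2L)
        stop("need at least 2 eligible markers to calibrate thresholds")
    stats <- lapply(list(rl = metrics$rlPct[keep], lSi = metrics$lSi[keep],
        rg = metrics$rgPct[keep], gSi = metrics$gSi[keep]), .meanSd)
    if (any(vapply(stats, `[`, 0, "sd") == 0))
        warning("a metric is constant over eligible markers; its ",
            "threshold equals the mean")
    thr <- function(s) unname(s["mean"] + sdMultiplier * s["sd"])
    list(tRl = thr(stats$rl), tLsi = thr(stats$lSi),
        tRg = thr(stats$rg), tGsi = thr(stats$gSi),
        stats = stats, sdMultiplier = sdMultiplier,
        nEligible = sum(keep))
}

#' Select CNV-evidence markers by dual-method thresholds
#'
#' A marker enters the loss set when its HWE loss estimate and its SI
#' loss frequency both exceed their thresholds (strict AND, the
#' default); the gain set is analogous on `rgPct`/`gSi`. An `"or"` mode
#' (either method suffices) is provided for sensitivity analyses.
#' Non-autosomal-flagged and monomorphic markers are never selected.
#'
#' @param metrics combined metrics table from [combineMetrics()]
#' @param thresholds output of [calibrateThresholds()]
#' @param type `"loss"` or `"gain"`
#' @param mode `"and"` (default) or `"or"`
#' @return the selected rows of `metrics`
#' @export
selectMarkers <- function(metrics, thresholds,
        type = c("loss", "gain"), mode = c("and", "or")) {
    type <- match.arg(type)
    mode <- match.arg(mode)
    keep <- .eligible(metrics)
    if (type == "loss") {
        a <- metrics$rlPct > thresholds$tRl
        b <- metrics$lSi > thresholds$tLsi
    } else {
        a <- metrics$rgPct > thresholds$tRg
        b <- metrics$gSi > thresholds$tGsi
    }
    sel <- keep & if (mode == "and") a & b else a | b
    sel[is.na(sel)] <- FALSE
    metrics[sel, , drop = FALSE]
}

#' Cluster selected markers into CNV regions
#'
#' Single-linkage chaining per chromosome: consecutive selected markers
#' of the same type at most `clusterDistance` bp apart are merged into
#' one region; singletons are allowed (a single-marker region may
#' represent an indel shorter than the chip resolution). The region
#' span is the bp range of its member markers. Each region's
#' `frequency` is the mean over member markers of the average of the
#' two defining metrics (HWE and SI percent frequencies); the
#' per-method means are reported separately as `freqHwe` and `freqSi`.
#'
#' @param selected output of [selectMarkers()]; all rows must carry map
#'   coordinates
#' @param type `"loss"` or `"gain"` (stored on the result)
#' @param clusterDistance maximum gap between consecutive member
#'   markers, bp (default 500)
#' @return `GRanges` of regions with metadata columns `cnvType`,
#'   `nMarkers`, `markerIds` (comma-separated), `freqHwe`, `freqSi`,
#'   `frequency`
#' @export
clusterRegions <- function(selected, type = c("loss", "gain"),
        clusterDistance = 500) {
    type <- match.arg(type)
    df <- as.data.frame(selected[, c("markerId", "chromosome",
        "position", if (type == "loss") c("rlPct", "lSi") else
            c("rgPct", "gSi"))])
    colnames(df)[4:5] <- c("hwePct", "siPct")
    if (any(is.na(df$chromosome) | is.na(df$position)))
        stop("selected marker '",
            df$markerId[which(is.na(df$position))[1L]],
            "' has no map coordinates")
    if (!nrow(df)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(cnvType = character(),
            nMarkers = integer(), markerIds = character(),
            freqHwe = numeric(), freqSi = numeric(),
            frequency = numeric())
        return(gr)
    }
    df <- df[order(df$chromosome, df$position), , drop = FALSE]
    newChrom <- c(TRUE, df$chromosome[-1L] !=
        df$chromosome[-nrow(df)])
    gap <- c(Inf, diff(df$position))
    grp <- cumsum(newChrom | gap > clusterDistance)
    pieces <- split(df, grp)
    gr <- GRanges(
        vapply(pieces, function(p) p$chromosome[1L], ""),
        IRanges(vapply(pieces, function(p) min(p$position), 0),
            vapply(pieces, function(p) max(p$position), 0)))
    mcols(gr) <- DataFrame(
        cnvType = type,
        nMarkers = unname(vapply(pieces, nrow, 0L)),
        markerIds = unname(vapply(pieces,
            function(p) paste(p$markerId, collapse = ","), "")),
        freqHwe = unname(vapply(pieces, function(p) mean(p$hwePct), 0)),
        freqSi = unname(vapply(pieces, function(p) mean(p$siPct), 0)),
        frequency = unname(vapply(pieces,
            function(p) mean((p$hwePct + p$siPct) / 2), 0)))
    names(gr) <- NULL
    gr
}

#' Read a catalog of documented CNV intervals
#'
#' Accepts BED (0-based half-open, detected by a `.bed` extension or
#' `format = "bed"`) or a 4-column 1-based inclusive TSV
#' (`chrom  start  end  label`).
#'
#' @param path file path
#' @param format `"auto"`, `"bed"` or `"tsv"`
#' @return `GRanges` with a `label` metadata column
#' @export
readCnvCatalog <- function(path, format = c("auto", "bed", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE))
            "bed" else "tsv"
    df <- utils::read.delim(path, header = FALSE,
        col.names = c("chrom", "start", "end", "label")[1:4],
        colClasses = c("character", "integer", "integer", "character"))
    start1 <- if (format == "bed") df$start + 1L else df$start
    gr <- GRanges(sub("^chr", "", df$chrom), IRanges(start1, df$end))
    mcols(gr)$label <- df$label
    gr
}

#' Confirm detected regions against a documented-CNV catalog
#'
#' A region is confirmed when a catalog interval on the same chromosome
#' lies within `proximity` bp of it: overlap, or a gap between closest
#' edges of at most `proximity`. The symmetric catalog-side rate (the
#' fraction of catalog entries with a detected region nearby) is also
#' returned.
#'
#' @param regions `GRanges` from [clusterRegions()]
#' @param catalog `GRanges` from [readCnvCatalog()]
#' @param proximity maximum edge-to-edge gap, bp (default 500)
#' @return list: `regions` (input with a logical `confirmed` metadata
#'   column), `nConfirmed`, `catalogConfirmed` (logical per catalog
#'   entry), `catalogRate`
#' @export
confirmAgainstCatalog <- function(regions, catalog, proximity = 500) {
    # pad the catalog on each side by `proximity`: overlap with the
    # padded interval <=> edge gap (start2 - end1 style) <= proximity
    padded <- GRanges(seqnames(catalog),
        IRanges(pmax(1L, start(catalog) - proximity),
            end(catalog) + proximity))
    # regions and catalog may legitimately cover disjoint chromosomes
    hits <- suppressWarnings(findOverlaps(regions, padded))
    confirmed <- seq_along(regions) %in% queryHits(hits)
    mcols(regions)$confirmed <- confirmed
    catalogConfirmed <- seq_along(catalog) %in% subjectHits(hits)
    list(regions = regions,
        nConfirmed = sum(confirmed),
        catalogConfirmed = catalogConfirmed,
        catalogRate = if (length(catalog))
            mean(catalogConfirmed) else NA_real_)
}

#' Write CNV regions as BED and as a richer TSV
#'
#' The BED file is 0-based half-open with name `CNVR#<k>`, score =
#' region frequency in percent times 10 (rounded), and the type in
#' column 6. The TSV keeps 1-based inclusive coordinates, member
#' markers and both per-method frequency averages.
#'
#' @param regions `GRanges` from [clusterRegions()] (optionally after
#'   [confirmAgainstCatalog()])
#' @param path output path (`.bed` written as BED; anything else as the
#'   richer TSV)
#' @return `path`, invisibly
#' @export
writeRegions <- function(regions, path) {
    mc <- mcols(regions)
    name <- sprintf("CNVR#%d", seq_along(regions))
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        df <- data.frame(
            chrom = as.character(seqnames(regions)),
            start = start(regions) - 1L,
            end = end(regions),
            name = name,
            score = round(mc$frequency * 10),
            type = mc$cnvType)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    } else {
        df <- data.frame(
            name = name,
            chromosome = as.character(seqnames(regions)),
            start = start(regions),
            end = end(regions),
            cnvType = mc$cnvType,
            nMarkers = mc$nMarkers,
            frequency = mc$frequency,
            freqHwe = mc$freqHwe,
            freqSi = mc$freqSi,
            markerIds = mc$markerIds)
        if (!is.null(mc$confirmed)) df$confirmed <- mc$confirmed
        utils::write.table(df, path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = TRUE)
    }
    invisible(path)
}

#' End-to-end dual-evidence CNV region detection
#'
#' Convenience wrapper: combine metrics, calibrate thresholds, select
#' loss and gain markers, and cluster each set into regions. Loss and
#' gain pipelines run independently; a locus passing both appears twice
#' with distinct types.
#'
#' @param hwe output of [hweScan()]
#' @param si output of [markerSiFrequencies()]
#' @param clusterDistance bp, see [clusterRegions()]
#' @param sdMultiplier see [calibrateThresholds()]
#' @param mode see [selectMarkers()]
#' @return list: `regions` (`GRanges`, loss then gain), `thresholds`,
#'   `metrics` (combined table), `lossMarkers`, `gainMarkers`
#' @export
detectCnvRegions <- function(hwe, si, clusterDistance = 500,
        sdMultiplier = 1, mode = c("and", "or")) {
    mode <- match.arg(mode)
    metrics <- combineMetrics(hwe, si)
    thresholds <- calibrateThresholds(metrics, sdMultiplier)
    loss <- selectMarkers(metrics, thresholds, "loss", mode)
    gain <- selectMarkers(metrics, thresholds, "gain", mode)
    regions <- suppressWarnings(c(
        clusterRegions(loss, "loss", clusterDistance),
        clusterRegions(gain, "gain", clusterDistance)))
    list(regions = regions, thresholds = thresholds, metrics = metrics,
        lossMarkers = loss$markerId, gainMarkers = gain$markerId)
}
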