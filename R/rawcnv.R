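#' @importFrom GenomicRanges GRanges start end seqnames mcols mcols<-
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

.rawcnvPattern <- paste0(
    "^chr([^:[:space:]]+):([0-9,]+)-([0-9,]+)\\s+",
    "numsnp=([0-9,]+)\\s+length=([0-9,]+)\\s+",
    "state([0-9]+),cn=([0-9]+)\\s+",
    "(\\S+)\\s+startsnp=(\\S+)\\s+endsnp=(\\S+)",
    "(\\s+conf=(\\S+))?\\s*$")

#' Parse a PennCNV rawcnv call list
#'
#' One CNV call per line, whitespace-separated tokens:
#' `chr<C>:<start>-<end> numsnp=<k> length=<L> state<s>,cn=<c>
#' <samplefile> startsnp=<id> endsnp=<id> [conf=<x>]`.
#' Coordinates are 1-based and fully closed; the `length` token may
#' contain thousands-separator commas. The sample identifier is the
#' per-line file token with a trailing `.txt` stripped. Copy number 2 is
#' not a CNV and is rejected.
#'
#' @param path file path
#' @return a [GenomicRanges::GRanges] (one range per call, `chr` prefix
#'   stripped from seqnames) with metadata columns `sampleId`,
#'   `copyNumber`, `state`, `numSnps`, `startSnp`, `endSnp`, `conf`
#'   (`NA` when absent)
#' @examples
#' f <- tempfile()
#' writeLines(paste0("chr7:100-200 numsnp=3 length=101 state2,cn=1 ",
#'     "bull42.txt startsnp=m1 endsnp=m3 conf=15.1"), f)
#' parseRawcnv(f)
#' @export
parseRawcnv <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(copyNumber = integer(),
            state = integer(), numSnps = integer(),
            sampleId = character(), startSnp = character(),
            endSnp = character(), conf = numeric())
        return(gr)
    }
    m <- regmatches(lines, regexec(.rawcnvPattern, lines))
    bad <- which(lengths(m) == 0L)
    if (length(bad))
        stop("malformed rawcnv line ", bad[1L], ": '", lines[bad[1L]], "'")
    m <- do.call(rbind, m)
    denum <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
    cn <- as.integer(m[, 8L])
    if (any(cn == 2L))
        stop("rawcnv line ", which(cn == 2L)[1L],
            ": copy number 2 is not a CNV")
    startPos <- denum(m[, 3L]); endPos <- denum(m[, 4L])
    if (any(startPos > endPos))
        stop("rawcnv line ", which(startPos > endPos)[1L],
            ": start > end")
    gr <- GRanges(m[, 2L], IRanges(startPos, endPos))
    mcols(gr) <- DataFrame(
        copyNumber = cn,
        state = as.integer(m[, 7L]),
        numSnps = as.integer(denum(m[, 5L])),
        sampleId = sub("\\.txt$", "", m[, 9L]),
        startSnp = m[, 10L],
        endSnp = m[, 11L],
        conf = ifelse(nzchar(m[, 13L]), suppressWarnings(denum(m[, 13L])),
            NA_real_))
    gr
}

.cnToState <- function(cn) c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L,
    `5` = 6L)[as.character(cn)]

#' Write CNV calls in PennCNV rawcnv format
#'
#' @param calls a `GRanges` as returned by [parseRawcnv()] or
#'   [simulateRawcnv()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeRawcnv <- function(calls, path) {
    mc <- mcols(calls)
    lines <- sprintf(
        "chr%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s.txt startsnp=%s endsnp=%s%s",
        as.character(seqnames(calls)), start(calls), end(calls),
        mc$numSnps,
        formatC(end(calls) - start(calls) + 1L, big.mark = ",",
            format = "d"),
        if (!is.null(mc$state)) mc$state else .cnToState(mc$copyNumber),
        mc$copyNumber, mc$sampleId, mc$startSnp, mc$endSnp,
        ifelse(is.na(mc$conf), "", sprintf(" conf=%.1f", mc$conf)))
    writeLines(lines, path)
    invisible(path)
}

#' Per-marker signal-intensity loss and gain frequencies
#'
#' Maps per-sample CNV calls onto markers and counts copies lost and
#' gained. A marker lies inside a call iff the chromosome matches and
#' `start <= position <= end` (endpoints included, matching the
#' startsnp/endsnp semantics of the call format). Samples without a
#' covering call contribute the reference two copies. Per marker,
#' `L = sum over samples of max(0, 2 - cn)` and
#' `G = sum over samples of max(0, cn - 2)`; the percent frequencies are
#' `lSi = 100 L / (2 nSamples)` and `gSi = 100 G / (2 nSamples)`.
#' When all events at a marker are losses (or all gains) this equals
#' the single absolute-value statistic `100 * |1 - Nt / (2 nSamples)|`
#' on the total copy count `Nt`; splitting loss and gain keeps mixed
#' loci informative instead of letting the two signs cancel.
#'
#' @param calls `GRanges` of CNV calls (see [parseRawcnv()])
#' @param map marker map data.frame (`markerId`, `chromosome`,
#'   `position`)
#' @param nSamples number of genotyped samples (denominator; the call
#'   list only names samples that have calls)
#' @return `DataFrame` with one row per map marker: `markerId`,
#'   `chromosome`, `position`, `nT` (total copies over all samples),
#'   `lSi`, `gSi` (percent)
#' @export
markerSiFrequencies <- function(calls, map, nSamples) {
    stopifnot(nSamples >= 1L)
    markers <- GRanges(as.character(map$chromosome),
        IRanges(map$position, width = 1L))
    hits <- findOverlaps(markers, calls)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    key <- paste(qh, mcols(calls)$sampleId[sh], sep = "\r")
    if (anyDuplicated(key)) {
        d <- which(duplicated(key))[1L]
        stop("ambiguous copy state: sample '",
            mcols(calls)$sampleId[sh[d]], "' has multiple calls covering ",
            "marker '", map$markerId[qh[d]], "'")
    }
    cn <- mcols(calls)$copyNumber[sh]
    L <- numeric(nrow(map)); G <- numeric(nrow(map))
    lost <- tapply(pmax(0L, 2L - cn), factor(qh, seq_len(nrow(map))), sum)
    gain <- tapply(pmax(0L, cn - 2L), factor(qh, seq_len(nrow(map))), sum)
    L[!is.na(lost)] <- lost[!is.na(lost)]
    G[!is.na(gain)] <- gain[!is.na(gain)]
    res <- DataFrame(
        markerId = map$markerId,
        chromosome = as.character(map$chromosome),
        position = as.integer(map$position),
        nT = 2 * nSamples - L + G,
        lSi = 100 * L / (2 * nSamples),
        gSi = 100 * G / (2 * nSamples))
    rownames(res) <- map$markerId
    res
}

#' Write/read the per-marker SI frequency table
#' @param si output of [markerSiFrequencies()]
#' @param path file path
#' @return `path` / `DataFrame`
#' @export
writeSiFrequencies <- function(si, path) {
    utils::write.table(as.data.frame(si), path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSiFrequencies
#' @export
readSiFrequencies <- function(path) {
    DataFrame(utils::read.delim(path, header = TRUE,
        colClasses = list(chromosome = "character")))
}
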