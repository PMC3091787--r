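#' Construct a GenotypeCounts object
#'
#' @param counts matrix or data.frame with columns `nAA`, `nAB`, `nBB`,
#'   `nNoCall` and marker identifiers as rownames.
#' @param map optional marker map: a data.frame/`DataFrame` with columns
#'   `markerId`, `chromosome`, `position` (1-based bp). Markers present
#'   in `counts` but absent from the map are retained with `NA`
#'   coordinates and a warning; they are excluded from
#'   position-dependent steps downstream.
#'
#' @return a [GenotypeCounts-class] object
#' @examples
#' cnt <- rbind(m1 = c(nAA = 1, nAB = 1, nBB = 0, nNoCall = 1))
#' genotypeCounts(cnt)
#' @export
genotypeCounts <- function(counts, map = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    ids <- rownames(counts)
    if (is.null(map)) {
        mapdf <- DataFrame(chromosome = rep(NA_character_, nrow(counts)),
            position = rep(NA_integer_, nrow(counts)))
    } else {
        map <- as.data.frame(map)
        stopifnot(all(c("markerId", "chromosome", "position") %in%
            colnames(map)))
        idx <- match(ids, map$markerId)
        if (anyNA(idx))
            warning(sum(is.na(idx)), " marker(s) absent from the map ",
                "(e.g. '", ids[which(is.na(idx))[1L]], "'); retained in ",
                "counts, excluded from position-dependent steps")
        mapdf <- DataFrame(
            chromosome = as.character(map$chromosome)[idx],
            position = as.integer(map$position)[idx])
    }
    rownames(mapdf) <- ids
    new("GenotypeCounts", counts = counts, map = mapdf)
}

#' Read or write a marker map
#'
#' The map is a 3-column tab-delimited file: marker identifier,
#' chromosome label (autosomes `"1"`..`"29"`, `"X"`), 1-based bp
#' position. A header line is tolerated on input and detected by a
#' non-numeric third field.
#'
#' @param path file path
#' @return `readMarkerMap`: data.frame with columns `markerId`,
#'   `chromosome`, `position`.
#' @export
readMarkerMap <- function(path) {
    first <- readLines(path, n = 1L)
    skip <- if (length(first) &&
        is.na(suppressWarnings(as.integer(strsplit(first, "\t")[[1L]][3L]))))
        1L else 0L
    df <- utils::read.delim(path, header = FALSE, skip = skip,
        colClasses = c("character", "character", "integer"),
        col.names = c("markerId", "chromosome", "position"))
    if (anyDuplicated(df$markerId))
        stop("duplicated marker identifier in map: '",
            df$markerId[anyDuplicated(df$markerId)], "'")
    if (any(df$position < 1L))
        stop("marker positions must be >= 1")
    df
}

#' @rdname readMarkerMap
#' @param map data.frame with columns `markerId`, `chromosome`, `position`
#' @export
writeMarkerMap <- function(map, path) {
    utils::write.table(
        map[, c("markerId", "chromosome", "position")], path,
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Per-marker genotype counts from a coded genotype matrix
#'
#' Codes: 0 = A-like homozygote, 1 = heterozygote, 2 = B-like
#' homozygote, `NA` = no-call. Column order of the matrix is preserved.
#'
#' @param mat numeric/integer matrix, samples in rows, markers in
#'   columns; colnames are marker identifiers.
#' @param map optional marker map (see [genotypeCounts()]).
#' @return a [GenotypeCounts-class] object; a zero-row matrix yields
#'   all-zero counts with a warning (degenerate input).
#' @examples
#' m <- cbind(m1 = c(0, 0, 1, 2, NA))
#' countsMatrix(countsFromMatrix(m))
#' @export
countsFromMatrix <- function(mat, map = NULL) {
    mat <- as.matrix(mat)
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("m", seq_len(ncol(mat)))
    vals <- mat[!is.na(mat)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
        stop("genotype codes must be 0, 1, 2 or NA; found '",
            vals[which(!vals %in% c(0, 1, 2))[1L]], "'")
    if (nrow(mat) == 0L)
        warning("degenerate input: 0 samples, all counts are zero")
    counts <- cbind(
        nAA = colSums(mat == 0, na.rm = TRUE),
        nAB = colSums(mat == 1, na.rm = TRUE),
        nBB = colSums(mat == 2, na.rm = TRUE),
        nNoCall = colSums(is.na(mat)))
    rownames(counts) <- colnames(mat)
    genotypeCounts(counts, map)
}

#' Read or write a coded genotype matrix
#'
#' Tab-delimited: first column sample identifier, remaining columns one
#' marker each, cells in `{0, 1, 2, NA}`.
#'
#' @param path file path
#' @return `readGenotypeMatrix`: integer matrix, samples x markers.
#' @export
readGenotypeMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
        colClasses = "character", na.strings = "NA")
    raw <- as.matrix(df[, -1L, drop = FALSE])
    bad <- !is.na(raw) & !(raw %in% c("0", "1", "2"))
    if (any(bad))
        stop("genotype codes must be 0, 1, 2 or NA; found '",
            raw[bad][1L], "'")
    mat <- raw
    storage.mode(mat) <- "integer"
    rownames(mat) <- df[[1L]]
    mat
}

#' @rdname readGenotypeMatrix
#' @param mat samples x markers matrix of codes
#' @export
writeGenotypeMatrix <- function(mat, path) {
    df <- data.frame(sampleId = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a GenomeStudio-style final report into genotype counts
#'
#' The file has a free-form header block terminated by a `[Data]` line,
#' then a tab-delimited table whose columns include `SNP Name`,
#' `Sample ID`, `Allele1 - Top` and `Allele2 - Top`. Allele symbols are
#' `A`, `C`, `G`, `T` or `-` (missing). Heterozygotes are identified by
#' an unordered allele pair; a call with exactly one missing allele is
#' treated as a no-call. Homozygote orientation is lexicographic: the
#' alphabetically smaller of a marker's observed alleles is the A-like
#' allele. Every (marker, sample) pair is counted exactly once.
#'
#' @param path file path
#' @param map optional marker map (see [genotypeCounts()]); markers in
#'   the report but not in the map are retained with a warning.
#' @return a [GenotypeCounts-class] object
#' @export
readFinalReport <- function(path, map = NULL) {
    lines <- readLines(path)
    dataAt <- which(trimws(lines) == "[Data]")
    if (!length(dataAt))
        stop("not a final report: no [Data] line found in '", path, "'")
    dataAt <- dataAt[1L]
    if (dataAt + 1L > length(lines))
        stop("no data rows after [Data] line")
    header <- strsplit(lines[dataAt + 1L], "\t", fixed = TRUE)[[1L]]
    need <- c("SNP Name", "Sample ID", "Allele1 - Top", "Allele2 - Top")
    ci <- match(need, header)
    if (anyNA(ci))
        stop("missing final-report column(s): ",
            paste(need[is.na(ci)], collapse = ", "))
    rows <- lines[-seq_len(dataAt + 1L)]
    rows <- rows[nzchar(rows)]
    fields <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < max(ci))) {
        bad <- which(nf < max(ci))[1L]
        stop("malformed final-report line ", dataAt + 1L + bad,
            ": expected at least ", max(ci), " fields, found ", nf[bad])
    }
    fm <- matrix(unlist(lapply(fields, `[`, ci)), ncol = 4L, byrow = TRUE)
    marker <- fm[, 1L]; sample <- fm[, 2L]
    a1 <- fm[, 3L]; a2 <- fm[, 4L]
    ok <- c("A", "C", "G", "T", "-")
    bad <- !(a1 %in% ok) | !(a2 %in% ok)
    if (any(bad)) {
        i <- which(bad)[1L]
        stop("malformed final-report line ", dataAt + 1L + i,
            ": invalid allele symbol '",
            if (a1[i] %in% ok) a2[i] else a1[i], "'")
    }
    key <- paste(marker, sample, sep = "\r")
    if (anyDuplicated(key)) {
        i <- which(duplicated(key))[1L]
        stop("duplicate (marker, sample) row: ('", marker[i], "', '",
            sample[i], "')")
    }
    markers <- unique(marker)
    mi <- match(marker, markers)
    noc <- a1 == "-" | a2 == "-"
    het <- !noc & a1 != a2
    counts <- matrix(0L, nrow = length(markers), ncol = 4L,
        dimnames = list(markers, c("nAA", "nAB", "nBB", "nNoCall")))
    counts[, "nNoCall"] <- tabulate(mi[noc], length(markers))
    counts[, "nAB"] <- tabulate(mi[het], length(markers))
    # orient homozygotes: smaller observed allele symbol is A-like
    hom <- !noc & !het
    alleles <- c(a1[!noc], a2[!noc])
    amarker <- c(mi[!noc], mi[!noc])
    minAllele <- vapply(split(alleles, factor(amarker,
        levels = seq_along(markers))),
        function(a) if (length(a)) min(a) else NA_character_,
        character(1L))
    isA <- hom & a1 == minAllele[mi]
    counts[, "nAA"] <- tabulate(mi[isA], length(markers))
    counts[, "nBB"] <- tabulate(mi[hom & !isA], length(markers))
    gc <- genotypeCounts(counts, map)
    if (!is.null(map)) {
        unknown <- markers[!markers %in% map$markerId]
        if (length(unknown))
            message(length(unknown), " report marker(s) not in map: ",
                paste(head(unknown, 5L), collapse = ", "),
                if (length(unknown) > 5L) ", ..." else "")
    }
    gc
}

#' Write a coded genotype matrix as a GenomeStudio-style final report
#'
#' Inverse of [readFinalReport()]: codes 0/1/2/NA become allele pairs
#' `A A` / `A B` / `B B` / `- -` using per-marker allele symbols.
#'
#' @param mat samples x markers matrix of codes `{0,1,2,NA}`
#' @param path output path
#' @param alleleA,alleleB allele symbols per marker (recycled); defaults
#'   `"A"` and `"G"` keep the A-like allele lexicographically first so a
#'   write/read round trip preserves orientation.
#' @return `path`, invisibly
#' @export
writeFinalReport <- function(mat, path, alleleA = "A", alleleB = "G") {
    markers <- colnames(mat)
    samples <- rownames(mat)
    alleleA <- rep_len(alleleA, length(markers))
    alleleB <- rep_len(alleleB, length(markers))
    mi <- rep(seq_along(markers), each = nrow(mat))
    g <- as.vector(mat)
    a1 <- ifelse(is.na(g), "-", ifelse(g == 2, alleleB[mi], alleleA[mi]))
    a2 <- ifelse(is.na(g), "-", ifelse(g == 0, alleleA[mi], alleleB[mi]))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("[Header]",
        "GSGT Version\t1.0",
        sprintf("Num SNPs\t%d", length(markers)),
        sprintf("Num Samples\t%d", nrow(mat)),
        "[Data]",
        "SNP Name\tSample ID\tAllele1 - Top\tAllele2 - Top"), con)
    writeLines(paste(markers[mi], rep(samples, length(markers)),
        a1, a2, sep = "\t"), con)
    invisible(path)
}
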