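.metricsRow <- function(id, chrom, pos, rlPct = 0, lSi = 0, rgPct = 0,
        gSi = 0, polymorphic = TRUE, flag = FALSE) {
    S4Vectors::DataFrame(markerId = id, chromosome = chrom,
        position = as.integer(pos), rlPct = rlPct, lSi = lSi,
        rgPct = rgPct, gSi = gSi, polymorphic = polymorphic,
        nonautosomalFlag = flag)
}

.metricsTable <- function(...) do.call(rbind, list(...))

test_that("thresholds are mean plus one population SD", {
    m <- .metricsTable(
        .metricsRow("a", "1", 1000, rlPct = 0),
        .metricsRow("b", "1", 2000, rlPct = 0),
        .metricsRow("c", "1", 3000, rlPct = 0),
        .metricsRow("d", "1", 4000, rlPct = 4))
    expect_warning(thr <- calibrateThresholds(m), "constant")
    expect_equal(thr$tRl, 1 + sqrt(3))
    expect_equal(thr$tLsi, 0)
    expect_equal(thr$nEligible, 4L)
})

test_that("flagged and monomorphic markers never enter calibration", {
    base <- .metricsTable(
        .metricsRow("a", "1", 1000, rlPct = 1),
        .metricsRow("b", "1", 2000, rlPct = 2),
        .metricsRow("c", "1", 3000, rlPct = 3))
    withFlagged <- rbind(base,
        .metricsRow("x", "1", 4000, rlPct = 500, flag = TRUE),
        .metricsRow("y", "1", 5000, rlPct = 500, polymorphic = FALSE))
    expect_equal(suppressWarnings(calibrateThresholds(withFlagged))$tRl,
        suppressWarnings(calibrateThresholds(base))$tRl)
    expect_error(calibrateThresholds(base[0, ]), "at least 2")
})

test_that("marker selection is a strict AND of the two methods", {
    m <- .metricsTable(
        .metricsRow("both", "1", 1000, rlPct = 10, lSi = 5),
        .metricsRow("hweOnly", "1", 2000, rlPct = 10, lSi = 0),
        .metricsRow("siOnly", "1", 3000, rlPct = 0, lSi = 5),
        .metricsRow("neither", "1", 4000),
        .metricsRow("flagged", "1", 5000, rlPct = 10, lSi = 5,
            flag = TRUE))
    thr <- list(tRl = 1, tLsi = 1, tRg = 1, tGsi = 1)
    expect_equal(selectMarkers(m, thr, "loss")$markerId, "both")
    expect_setequal(selectMarkers(m, thr, "loss", mode = "or")$markerId,
        c("both", "hweOnly", "siOnly"))
})

test_that("selection is monotone in the thresholds", {
    set.seed(31)
    m <- do.call(rbind, lapply(1:50, function(i)
        .metricsRow(paste0("m", i), "1", i * 1000,
            rlPct = stats::runif(1, 0, 10),
            lSi = stats::runif(1, 0, 2))))
    hi <- list(tRl = 5, tLsi = 1, tRg = 5, tGsi = 1)
    lo <- list(tRl = 2, tLsi = 0.3, tRg = 5, tGsi = 1)
    selHi <- selectMarkers(m, hi, "loss")$markerId
    selLo <- selectMarkers(m, lo, "loss")$markerId
    expect_true(all(selHi %in% selLo))
})

test_that("single-linkage chaining at 500 bp merges adjacent markers", {
    sel <- .metricsTable(
        .metricsRow("a", "1", 1000, rlPct = 5, lSi = 2),
        .metricsRow("b", "1", 1400, rlPct = 7, lSi = 4),
        .metricsRow("c", "1", 10000, rlPct = 9, lSi = 1))
    reg <- clusterRegions(sel, "loss", clusterDistance = 500)
    expect_equal(length(reg), 2L)
    expect_equal(GenomicRanges::start(reg), c(1000L, 10000L))
    expect_equal(GenomicRanges::end(reg), c(1400L, 10000L))
    mc <- GenomicRanges::mcols(reg)
    expect_equal(mc$nMarkers, c(2L, 1L))
    expect_equal(mc$freqHwe, c(6, 9))
    expect_equal(mc$frequency, c((6 + 3) / 2, (9 + 1) / 2))
    # distance 0: every marker its own region
    expect_equal(length(clusterRegions(sel, "loss", 0)), 3L)
    # larger distance never increases the region count
    expect_lte(length(clusterRegions(sel, "loss", 1e6)),
        length(clusterRegions(sel, "loss", 500)))
})

test_that("every selected marker lands in exactly one region", {
    set.seed(77)
    sel <- do.call(rbind, lapply(1:40, function(i)
        .metricsRow(paste0("m", i),
            chrom = as.character(sample(1:3, 1)),
            pos = sample(1e6, 1), rlPct = 5, lSi = 2)))
    reg <- clusterRegions(sel, "loss", clusterDistance = 500)
    members <- unlist(strsplit(GenomicRanges::mcols(reg)$markerIds, ","))
    expect_setequal(members, sel$markerId)
    expect_equal(length(members), nrow(sel))
})

test_that("clustering requires map coordinates", {
    sel <- .metricsRow("a", NA_character_, NA, rlPct = 5, lSi = 2)
    expect_error(clusterRegions(sel, "loss"), "no map coordinates")
})

test_that("catalog confirmation uses the edge-gap rule", {
    reg <- GenomicRanges::GRanges("1", IRanges::IRanges(100, 200))
    GenomicRanges::mcols(reg) <- S4Vectors::DataFrame(cnvType = "loss",
        nMarkers = 1L, markerIds = "a", freqHwe = 5, freqSi = 2,
        frequency = 3.5)
    cat1 <- GenomicRanges::GRanges("1", IRanges::IRanges(600, 700))
    expect_true(confirmAgainstCatalog(reg, cat1,
        proximity = 500)$regions$confirmed)
    expect_false(confirmAgainstCatalog(reg, cat1,
        proximity = 300)$regions$confirmed)
    # different chromosome never confirms
    cat2 <- GenomicRanges::GRanges("2", IRanges::IRanges(100, 200))
    expect_false(confirmAgainstCatalog(reg, cat2, 500)$regions$confirmed)
    # catalog-side rate counts confirmed entries
    both <- suppressWarnings(c(cat1, cat2))
    conf <- confirmAgainstCatalog(reg, both, 500)
    expect_equal(conf$catalogRate, 0.5)
})

test_that("random-interval confirmation rate matches the analytic expectation", {
    # one random catalog interval near a region iff its start falls in a
    # window of width wR + wC + 2 * proximity + 1 around the region
    set.seed(101)
    G <- 2.5e7   # one-chromosome toy genome
    wR <- 1000L; wC <- 1000L; prox <- 500
    nReg <- 300L; nCat <- 300L
    regs <- GenomicRanges::GRanges("1",
        IRanges::IRanges(sample(G, nReg), width = wR))
    cats <- GenomicRanges::GRanges("1",
        IRanges::IRanges(sample(G, nCat), width = wC))
    GenomicRanges::mcols(regs) <- S4Vectors::DataFrame(
        cnvType = "loss", nMarkers = 1L, markerIds = "x",
        freqHwe = 0, freqSi = 0, frequency = 0)
    rate <- mean(confirmAgainstCatalog(regs, cats,
        prox)$regions$confirmed)
    pPair <- (wR + wC + 2 * prox + 1) / G
    pConf <- 1 - (1 - pPair)^nCat
    se <- sqrt(pConf * (1 - pConf) / nReg)
    expect_lt(abs(rate - pConf), 4 * se + 0.01)
})

test_that("catalog files read in both BED and TSV conventions", {
    bed <- tmpWrite(c("chr1\t99\t200\tsrcA", "2\t0\t50\tsrcB"),
        ext = ".bed")
    gr <- readCnvCatalog(bed)
    expect_equal(GenomicRanges::start(gr), c(100L, 1L))
    expect_equal(GenomicRanges::end(gr), c(200L, 50L))
    tsv <- tmpWrite("1\t100\t200\tsrcA", ext = ".tsv")
    gr2 <- readCnvCatalog(tsv)
    expect_equal(GenomicRanges::start(gr2), 100L)
})

test_that("regions write as BED (0-based) and as a rich TSV", {
    sel <- .metricsTable(
        .metricsRow("a", "1", 1000, rlPct = 5, lSi = 2),
        .metricsRow("b", "1", 1400, rlPct = 7, lSi = 4))
    reg <- clusterRegions(sel, "loss")
    fb <- tempfile(fileext = ".bed")
    writeRegions(reg, fb)
    bed <- utils::read.delim(fb, header = FALSE)
    expect_equal(bed$V2, 999L)
    expect_equal(bed$V3, 1400L)
    expect_equal(bed$V4, "CNVR#1")
    ft <- tempfile(fileext = ".tsv")
    writeRegions(reg, ft)
    tsv <- utils::read.delim(ft)
    expect_equal(tsv$start, 1000L)
    expect_equal(tsv$markerIds, "a,b")
})
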