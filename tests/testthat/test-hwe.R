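test_that("phenotype frequencies honour the denominator choice", {
    gc <- makeCounts(m1 = c(32L, 32L, 32L, 4L))
    fr <- phenotypeFrequencies(gc)
    expect_equal(unname(c(fr$pO, fr$qO, fr$pqO)), rep(1 / 3, 3))
    frTot <- phenotypeFrequencies(gc, denominator = "total")
    expect_equal(frTot$pO, 0.32)
    expect_equal(frTot$n, 100L)
    expect_error(phenotypeFrequencies(makeCounts(m1 = c(0L, 0L, 0L, 10L))),
        "degenerate")
})

test_that("loss estimator inverts the null-allele model exactly", {
    # oracle: trinomial expansion fractions must return r itself
    grid <- expand.grid(p = seq(0.05, 0.9, by = 0.05),
        r = seq(0, 0.9, by = 0.05))
    grid$q <- 1 - grid$p - grid$r
    grid <- grid[grid$q > 0.049, ]
    fr <- nullModelFractions(grid$p, grid$q, grid$r)
    expect_equal(estimateLoss(fr$pO, fr$qO, fr$pqO), grid$r,
        tolerance = 1e-10)
    # at exact HWE both estimators are zero
    expect_equal(estimateLoss(0.25, 0.25, 0.5), 0, tolerance = 1e-12)
})

test_that("gain estimator inverts the gain model exactly", {
    grid <- expand.grid(p = seq(0.05, 0.9, by = 0.05),
        g = seq(0, 0.9, by = 0.05))
    grid$q <- 1 - grid$p - grid$g
    grid <- grid[grid$q > 0.049, ]
    fr <- gainModelFractions(grid$p, grid$q, grid$g)
    expect_equal(estimateGain(fr$pO, fr$qO, fr$pqO), grid$g,
        tolerance = 1e-10)
    expect_equal(estimateGain(0.25, 0.25, 0.5), 0, tolerance = 1e-12)
})

test_that("loss and gain estimates anti-correlate across models", {
    # a deletion locus drives the gain estimator negative and vice versa
    frNull <- nullModelFractions(0.4, 0.4, 0.2)
    expect_lt(estimateGain(frNull$pO, frNull$qO, frNull$pqO), 0)
    frGain <- gainModelFractions(0.4, 0.4, 0.2)
    expect_lt(estimateLoss(frGain$pO, frGain$qO, frGain$pqO), 0)
})

test_that("degenerate heterozygote-free markers give sentinels", {
    # both homozygote classes, no heterozygotes: hemizygous signature
    expect_identical(estimateLoss(0.6, 0.4, 0), Inf)
    # monomorphic: undefined
    expect_true(is.na(estimateLoss(1, 0, 0)))
    expect_true(is.na(estimateLoss(0, 0, 0)))
})

test_that("the loss radicand is never negative on valid frequencies", {
    set.seed(123)
    for (i in 1:500) {
        x <- stats::runif(4)
        x <- x / sum(x)   # (pO, qO, pqO, noCall) simplex
        rl <- estimateLoss(x[1], x[2], x[3])
        expect_false(is.nan(rl))
    }
})

test_that("chi-square HWE screen matches hand-computed values", {
    gc <- makeCounts(m1 = c(25L, 50L, 25L, 0L), m2 = c(50L, 0L, 50L, 0L),
        m3 = c(100L, 0L, 0L, 0L))
    res <- hweChisq(gc)
    expect_equal(res$chi2[1], 0)
    expect_equal(res$chi2P[1], 1)
    # (50,0,50): p=0.5, expected (25,50,25) -> 25 + 50 + 25 = 100
    expect_equal(res$chi2[2], 100)
    expect_lt(res$chi2P[2], 1e-20)
    # monomorphic: no test possible
    expect_equal(res$chi2[3], 0)
    expect_equal(res$chi2P[3], 1)
})

test_that("expected no-calls clamp losses-only and scale as n r^2", {
    expect_equal(expectedNoCalls(0.5, 912), 228)
    expect_equal(expectedNoCalls(-0.1, 912), 0)
    expect_true(is.na(expectedNoCalls(Inf, 912)))
    # simulation: no-call count at a null locus is Binomial(n, r^2)
    spec <- scenarioSpec(markerBlock(1, "null_allele", cnvFreq = 0.2,
        p = 0.4, q = 0.4), nSamples = 912L, noCallRate = 0)
    sim <- simulateGenotypes(spec, seed = 5)
    obs <- sim$truth$nNoCall[1]
    expect_lt(abs(obs - 912 * 0.04), 4 * sqrt(912 * 0.04 * 0.96))
})

test_that("hweScan assembles metrics and flags consistently", {
    map <- tinyMap(c("a", "b", "c"), position = c(1000L, 2000L, 3000L))
    gc <- makeCounts(a = c(25L, 50L, 25L, 0L), b = c(60L, 0L, 40L, 0L),
        c = c(100L, 0L, 0L, 0L), map = map)
    m <- hweScan(gc)
    expect_equal(m$rl[1], 0, tolerance = 1e-12)
    expect_identical(m$rl[2], Inf)
    expect_true(m$nonautosomalFlag[2])
    expect_false(m$polymorphic[3])
    expect_true(is.na(m$rl[3]))
    expect_false(m$nonautosomalFlag[3])
})

test_that("called-only denominator slightly raises the loss estimate", {
    fr <- nullModelFractions(0.4, 0.4, 0.2)
    called <- 1 - fr$noCall
    rlCalled <- estimateLoss(fr$pO / called, fr$qO / called,
        fr$pqO / called)
    rlTotal <- estimateLoss(fr$pO, fr$qO, fr$pqO)
    expect_gt(rlCalled, rlTotal)
})

test_that("flagged markers are grouped into contiguous runs", {
    ids <- paste0("m", 1:10)
    map <- tinyMap(ids, position = seq(1000L, by = 1000L, length.out = 10))
    flag <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
        FALSE)
    metrics <- S4Vectors::DataFrame(markerId = ids, chromosome = "1",
        position = map$position, nonautosomalFlag = flag)
    runs <- flagNonAutosomal(metrics)
    expect_equal(nrow(runs), 2L)
    expect_equal(runs$nMarkers, c(5L, 1L))
    expect_equal(runs$start[1], 2000L)
    expect_equal(runs$end[1], 6000L)
    expect_equal(runs$markerIds[1], "m2,m3,m4,m5,m6")
})

test_that("marker metrics tables round-trip through disk", {
    map <- tinyMap(c("a", "b"))
    gc <- makeCounts(a = c(25L, 50L, 25L, 0L), b = c(30L, 40L, 28L, 2L),
        map = map)
    m <- hweScan(gc)
    f <- tempfile(fileext = ".tsv")
    writeMarkerMetrics(m, f)
    back <- readMarkerMetrics(f)
    expect_equal(back$rl, m$rl, tolerance = 1e-12)
    expect_equal(back$chi2P, m$chi2P, tolerance = 1e-12)
    expect_equal(back$rlPct, 100 * m$rl, tolerance = 1e-12)
})
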