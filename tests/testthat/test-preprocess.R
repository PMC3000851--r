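grid <- canonicalRawGrid()

test_that("two-point baseline correction annihilates affine components", {
    # constant spectrum -> zeros
    s <- Spectrum(grid, rep(3.2, length(grid)))
    expect_equal(absorbance(baselineCorrect(s)), rep(0, length(grid)))
    # exactly linear spectrum -> zeros
    s <- Spectrum(grid, 0.4 + 0.002 * grid)
    expect_equal(absorbance(baselineCorrect(s)), rep(0, length(grid)),
                 tolerance = 1e-12)
    # line + interior Gaussian -> the pure Gaussian (tails ~0 at anchors)
    band <- bandProfile(1400, 20, 0.7, grid)
    s <- Spectrum(grid, 0.1 - 3e-4 * grid + band)
    out <- baselineCorrect(s)
    expect_lt(max(abs(absorbance(out) - band)), 1e-9)
    expect_identical(spectrumKind(out), "baseline_corrected")
    # arbitrary spectrum: chain(s + affine) == chain(s)
    set.seed(4)
    y <- bandProfile(1200, 40, 0.5, grid) + rnorm(length(grid), 0, 0.01)
    a1 <- absorbance(baselineCorrect(Spectrum(grid, y)))
    a2 <- absorbance(baselineCorrect(Spectrum(grid, y + 2 - 0.001 * grid)))
    expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("baseline anchors outside the grid span are rejected", {
    s <- Spectrum(canonicalFingerprintGrid(), rep(1, 442))
    expect_error(baselineCorrect(s), "anchor")
})

test_that("fingerprint crop keeps exactly the 442 canonical points", {
    s <- Spectrum(grid, seq_along(grid))
    out <- cropFingerprint(s)
    expect_length(wavenumbers(out), 442)
    expect_equal(range(wavenumbers(out)), c(950, 1800))
    # crop bounds equal to the grid extremes -> identity
    p <- preprocessParams(anchor_low = 800, anchor_high = 1900,
                          crop_low = min(grid), crop_high = max(grid))
    expect_equal(wavenumbers(cropFingerprint(s, p)), grid)
    # grid not covering the crop interval -> error
    s2 <- Spectrum(seq(1000, 1500, by = 2), rep(1, 251))
    expect_error(cropFingerprint(s2), "does not cover")
})

test_that("vector normalization yields unit norm and scale invariance", {
    s <- Spectrum(c(1000, 1002), c(3, 4))
    expect_equal(absorbance(vectorNormalize(s)), c(0.6, 0.8))
    set.seed(8)
    y <- runif(442, -1, 1)
    s <- Spectrum(canonicalFingerprintGrid(), y)
    out <- vectorNormalize(s)
    expect_equal(sqrt(sum(absorbance(out)^2)), 1, tolerance = 1e-12)
    out7 <- vectorNormalize(Spectrum(canonicalFingerprintGrid(), 7 * y))
    expect_equal(absorbance(out7), absorbance(out), tolerance = 1e-12)
    expect_error(vectorNormalize(Spectrum(c(1000, 1002), c(0, 0))),
                 "all-zero")
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
    fp <- canonicalFingerprintGrid()
    expect_equal(absorbance(sgSecondDerivative(Spectrum(fp, rep(5, 442)))),
                 rep(0, 442), tolerance = 1e-9)
    out <- sgSecondDerivative(Spectrum(fp, fp^2))
    expect_equal(absorbance(out), rep(2, 442), tolerance = 1e-6)
    expect_identical(spectrumKind(out), "second_derivative")
})

test_that("Savitzky-Golay second derivative tracks a finite-difference oracle", {
    fp <- canonicalFingerprintGrid()
    y <- sin(2 * pi * fp / 200)
    d2 <- absorbance(sgSecondDerivative(Spectrum(fp, y)))
    h <- 850 / 441
    n <- length(y)
    fd <- (y[-c(1, 2)] - 2 * y[-c(1, n)] + y[-c(n - 1, n)]) / h^2
    interior <- 5:(n - 5)
    scale <- max(abs(fd))
    expect_lt(max(abs(d2[interior] - fd[interior - 1])) / scale, 0.02)
})

test_that("Savitzky-Golay second derivative is linear and needs a uniform grid", {
    fp <- canonicalFingerprintGrid()
    set.seed(2)
    y1 <- rnorm(442); y2 <- rnorm(442)
    p <- preprocessParams()
    d <- function(y) absorbance(sgSecondDerivative(Spectrum(fp, y), p))
    expect_equal(d(2 * y1 - 3 * y2), 2 * d(y1) - 3 * d(y2), tolerance = 1e-9)
    bad <- Spectrum(c(fp[1] - 50, fp[-1]), y1)
    expect_error(sgSecondDerivative(bad), "uniform")
    short <- Spectrum(fp[1:5], y1[1:5])
    expect_error(sgSecondDerivative(short), "window")
})

test_that("SG second-derivative coefficients agree for polynomial orders 2 and 3", {
    fp <- canonicalFingerprintGrid()
    set.seed(3)
    y <- rnorm(442)
    d2 <- absorbance(sgSecondDerivative(Spectrum(fp, y),
                                        preprocessParams(sg_polyorder = 2)))
    d3 <- absorbance(sgSecondDerivative(Spectrum(fp, y),
                                        preprocessParams(sg_polyorder = 3)))
    expect_equal(d2[5:438], d3[5:438], tolerance = 1e-9)
})

test_that("the chain is invariant to multiplicative replicate gain", {
    cfg <- cohortConfig(n_cancer = 1, n_normal = 1, replicates = 1, seed = 6)
    coh <- generateCohort(cfg)
    m <- absorbance(coh)
    coh2 <- FTIRCohort(m %*% diag(c(2.5, 0.4)), wavenumbers(coh),
                       sampleIds(coh), replicateIndices(coh),
                       classLabels(coh))
    expect_equal(absorbance(preprocessCohort(coh2)),
                 absorbance(preprocessCohort(coh)),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("baseline and normalization stages are idempotent", {
    cfg <- small_config(seed = 13)
    coh <- generateCohort(cfg)
    b1 <- baselineCorrect(coh)
    b2 <- baselineCorrect(b1)
    expect_equal(absorbance(b2), absorbance(b1), tolerance = 1e-12)
    v1 <- vectorNormalize(cropFingerprint(b1))
    v2 <- vectorNormalize(v1)
    expect_equal(absorbance(v2), absorbance(v1), tolerance = 1e-12)
})

test_that("replicate aggregation takes pointwise medians (or means)", {
    w <- c(1000, 1002)
    m <- cbind(c(1, 1), c(2, 2), c(9, 9))
    coh <- FTIRCohort(m, w, rep("s1", 3), 1:3, rep("cancer", 3),
                      metadata = data.frame(smoking_status = rep("ex", 3)))
    agg <- aggregateReplicates(coh)
    expect_equal(absorbance(agg)[, 1], c(2, 2), ignore_attr = TRUE)
    expect_equal(ncol(agg), 1L)
    expect_equal(colData(agg)$smoking_status, "ex")
    aggm <- aggregateReplicates(coh, preprocessParams(replicate_aggregate = "mean"))
    expect_equal(absorbance(aggm)[, 1], c(4, 4), ignore_attr = TRUE)
    # identical replicates pass through unchanged
    coh2 <- FTIRCohort(cbind(c(1, 2), c(1, 2)), w, rep("s1", 2), 1:2,
                       rep("normal", 2))
    expect_equal(absorbance(aggregateReplicates(coh2))[, 1], c(1, 2),
                 ignore_attr = TRUE)
})

test_that("group median spectra behave as pointwise medians", {
    w <- c(1000, 1002)
    coh <- FTIRCohort(cbind(c(1, 1), c(5, 5), c(10, 20)), w,
                      c("a", "b", "c"), c(1, 1, 1),
                      c("cancer", "cancer", "normal"))
    # class of two -> pointwise midpoint
    expect_equal(absorbance(groupMedianSpectrum(coh, "cancer")), c(3, 3))
    # single-sample class -> that spectrum
    expect_equal(absorbance(groupMedianSpectrum(coh, "normal")), c(10, 20))
    expect_error(groupMedianSpectrum(coh, "healthy"), "unknown class")
})

test_that("class medians differ most near a planted differential band", {
    cfg <- cohortConfig(n_cancer = 2, n_normal = 2, gain_sd = 0, noise_sd = 0,
                        subject_amplitude_jitter_sd = 0, seed = 1)
    coh <- generateCohort(cfg)
    agg <- aggregateReplicates(preprocessCohort(coh))
    d <- abs(absorbance(groupMedianSpectrum(agg, "cancer")) -
             absorbance(groupMedianSpectrum(agg, "normal")))
    w_at_max <- wavenumbers(agg)[which.max(d)]
    b <- defaultBandTable()
    cents <- c(b$centre_normal[b$differential], b$centre_cancer[b$differential])
    expect_lte(min(abs(cents - w_at_max)), 10)
})
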