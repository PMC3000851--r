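test_that("Mann-Whitney U matches hand-enumerated exact cases", {
    r <- mannWhitneyU(c(1, 2), c(3, 4), mode = "exact")
    expect_equal(r$U, 0)
    expect_equal(r$p, 1 / 3)
    r <- mannWhitneyU(c(1, 3), c(2, 4), mode = "exact")
    expect_equal(r$U, 1)
    expect_equal(r$p, 2 / 3)
    # swapping the samples maps U -> n1 n2 - U with the same p
    x <- c(0.2, 1.4, 2.2); y <- c(0.9, 3.1)
    a <- mannWhitneyU(x, y, "exact"); b <- mannWhitneyU(y, x, "exact")
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p, b$p)
    expect_error(mannWhitneyU(numeric(0), 1), "nonempty")
})

test_that("Mann-Whitney U agrees with wilcox.test on tie-free samples", {
    set.seed(10)
    for (i in 1:20) {
        n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
        x <- rnorm(n1); y <- rnorm(n2, 0.5)
        mine <- mannWhitneyU(x, y, "exact")
        ref <- wilcox.test(x, y, exact = TRUE)
        expect_equal(mine$U, unname(ref$statistic))
        expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
    for (i in 1:20) {
        x <- rnorm(25); y <- rnorm(25, 0.3)
        mine <- mannWhitneyU(x, y, "normal_approx")
        ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
})

test_that("tied observations get the half-count and tie-corrected variance", {
    # x = (1, 2), y = (2, 3): no wins, one tie -> U = 0.5
    r <- mannWhitneyU(c(1, 2), c(2, 3), "exact")
    expect_equal(r$U, 0.5)
    x <- c(rep(1, 10), rep(2, 10)); y <- c(rep(1, 5), rep(2, 15))
    mine <- mannWhitneyU(x, y, "normal_approx")
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("Holm adjustment reproduces the hand step-down rule", {
    r <- holmAdjust(c(0.01, 0.02, 0.04), alpha = 0.05)
    expect_equal(r$p_adjusted, c(0.03, 0.04, 0.04))
    expect_true(all(r$reject))
    r <- holmAdjust(c(0.001, 0.5, 0.9), alpha = 0.05)
    expect_equal(r$p_adjusted, c(0.003, 1, 1))
    expect_equal(r$reject, c(TRUE, FALSE, FALSE))
    # single p unchanged
    expect_equal(holmAdjust(0.03)$p_adjusted, 0.03)
    expect_error(holmAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    # independent step-down oracle on random vectors
    set.seed(3)
    for (i in 1:10) {
        p <- runif(sample(2:40, 1))
        expect_equal(holmAdjust(p)$p_adjusted, holm_oracle(p))
    }
})

test_that("Holm rejections are a subset of unadjusted rejections and monotone", {
    set.seed(5)
    p <- c(runif(30, 0, 0.2), runif(30))
    r <- holmAdjust(p, alpha = 0.05)
    expect_true(all(r$p_adjusted >= p))
    expect_true(all(p[r$reject] <= 0.05))
    ord <- order(p)
    expect_true(all(diff(r$p_adjusted[ord]) >= 0))
})

test_that("Shapiro-Wilk screen flags heavy tails but accepts normal draws", {
    normal_ok <- vapply(1:100, function(s) {
        set.seed(s); shapiroWilkScreen(rnorm(25))$p > 0.05
    }, logical(1))
    expect_gte(mean(normal_ok), 0.9)
    skew_caught <- vapply(1:100, function(s) {
        set.seed(s); shapiroWilkScreen(runif(25)^4)$p < 0.01
    }, logical(1))
    expect_gte(mean(skew_caught), 0.9)
    r <- shapiroWilkScreen(rep(1, 25))
    expect_true(r$degenerate)
    expect_true(is.na(r$W))
})

test_that("screening controls the family-wise error under the global null", {
    any_rej <- vapply(1:20, function(s) {
        coh <- generateCohort(null_config(seed = 400 + s))
        sum(screenWavenumbers(processed_samples(coh))$reject) > 0
    }, logical(1))
    expect_lte(mean(any_rej), 0.1)  # alpha = 0.05 plus Monte-Carlo slack
})

test_that("permuting class labels of a planted cohort kills the signal", {
    coh <- generateCohort(small_config(seed = 31))
    agg <- processed_samples(coh)
    n_perm_rej <- vapply(1:10, function(s) {
        set.seed(500 + s)
        perm <- agg
        colData(perm)$class <- sample(classLabels(agg))
        sum(screenWavenumbers(perm)$reject)
    }, numeric(1))
    expect_lte(mean(n_perm_rej > 0), 0.05 + 0.25)
    expect_gt(sum(screenWavenumbers(agg)$reject), 0)
})

test_that("screening output satisfies the significance-table invariants", {
    coh <- generateCohort(small_config(seed = 17))
    sig <- screenWavenumbers(processed_samples(coh))
    expect_equal(nrow(sig), 442)
    expect_true(all(sig$p_holm >= sig$p_raw - 1e-12))
    expect_true(all(sig$p_raw >= 0 & sig$p_holm <= 1))
    rk <- sig$rank[sig$reject]
    expect_setequal(rk, seq_len(sum(sig$reject)))
    ord <- order(sig$p_raw[sig$reject], sig$wavenumber[sig$reject])
    expect_equal(sort(rk), rk[order(rk)])
    expect_equal(sig$rank[sig$reject][ord], seq_along(rk))
    expect_true(all(is.na(sig$rank[!sig$reject])))
    # rank-based test: common monotone rescaling leaves the table unchanged
    tr <- processed_samples(coh)
    assay(tr, "absorbance") <- exp(assay(tr, "absorbance") * 50)
    sig2 <- screenWavenumbers(tr)
    expect_equal(sig2$p_raw, sig$p_raw, tolerance = 1e-12)
    # single-class cohort is rejected
    only <- processed_samples(coh)[, classLabels(processed_samples(coh)) == "cancer"]
    expect_error(screenWavenumbers(only), "both classes")
})

test_that("band-centre detection finds Gaussian minima and respects sign", {
    fp <- canonicalFingerprintGrid()
    flat <- Spectrum(fp, rep(0, 442), kind = "second_derivative")
    expect_equal(nrow(detectBandCentres(flat)), 0L)
    # single band: second derivative has its minimum at the band centre
    band <- bandProfile(1100, 12, 0.5, fp)
    d2 <- sgSecondDerivative(Spectrum(fp, band))
    pk <- detectBandCentres(d2)
    expect_equal(nrow(pk), 1L)
    expect_lt(abs(pk$centre - 1100), 850 / 441)
    expect_lt(pk$depth, 0)
    # two overlapping glycogen-region bands resolve into two centres
    two <- bandProfile(1024, 12, 0.5, fp) + bandProfile(1049, 12, 0.4, fp)
    pk2 <- detectBandCentres(sgSecondDerivative(Spectrum(fp, two)))
    expect_equal(nrow(pk2), 2L)
    expect_lt(abs(pk2$centre[1] - 1024), 850 / 441)
    expect_lt(abs(pk2$centre[2] - 1049), 850 / 441)
    # flipping the sign swaps the minimum/maximum roles exactly: the band
    # centre disappears and only the former sidelobe maxima are detected
    neg <- Spectrum(fp, -absorbance(d2), kind = "second_derivative")
    pk_neg <- detectBandCentres(neg)
    expect_true(all(abs(pk_neg$centre - 1100) > 2))
    y0 <- absorbance(d2)
    for (cc in pk_neg$centre) {
        i <- which.min(abs(fp - cc))
        expect_true(y0[i] > y0[i - 1] && y0[i] > y0[i + 1])
    }
    expect_error(detectBandCentres(Spectrum(fp, band)), "second-derivative")
})

test_that("peak matching honours ranks and is monotone in tolerance", {
    sig <- data.frame(wavenumber = c(1022, 1024, 1100, 1200),
                      reject = c(TRUE, TRUE, TRUE, FALSE),
                      rank = c(2L, 1L, 3L, NA))
    peaks <- data.frame(centre = c(1023.5, 1150, 1199), depth = -1,
                        prominence = 1, matched_rank = NA_integer_,
                        annotation = NA_character_)
    m <- matchSignificantToPeaks(sig, peaks, tolerance = 4)
    expect_equal(m$centre, 1023.5)
    expect_equal(m$matched_rank, 1)
    # no rejected wavenumbers -> empty matched set
    sig0 <- sig; sig0$reject <- FALSE
    expect_equal(nrow(matchSignificantToPeaks(sig0, peaks, 4)), 0L)
    # shrinking the tolerance can only shrink the matched set
    wide <- matchSignificantToPeaks(sig, peaks, tolerance = 80)
    expect_true(all(m$centre %in% wide$centre))
    expect_gte(nrow(wide), nrow(m))
})

test_that("the MVA panel drops the glycogen peak next to the mucin band", {
    matched <- data.frame(centre = c(964, 1024, 1049, 1411, 1577, 1656),
                          depth = -1, prominence = 1,
                          matched_rank = 1:6, annotation = NA_character_)
    expect_equal(selectMvaPanel(matched), c(964, 1024, 1411, 1577, 1656))
    # no mucin references, or a zero window -> identity on the top set
    expect_equal(selectMvaPanel(matched, mucin_refs = numeric(0)),
                 c(964, 1024, 1049, 1411, 1577, 1656))
    expect_equal(selectMvaPanel(matched, exclusion_window = 0),
                 c(964, 1024, 1049, 1411, 1577, 1656))
    # everything excluded -> diagnostic error
    one <- matched[3, , drop = FALSE]
    expect_error(selectMvaPanel(one), "1049")
})
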