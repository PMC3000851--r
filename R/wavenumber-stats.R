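#' @include preprocess.R
NULL

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples.  The statistic is
#' `U = #\{(x_i, y_j): x_i > y_j\} + 0.5 * #ties`, i.e. the number of pairs
#' won by `x` counting ties as half.  Under `mode = "exact"` the two-sided
#' p-value is obtained by complete enumeration of all allocations of the
#' pooled observed values to the two groups (a permutation null, valid
#' with ties); under `"normal_approx"` by the tie-corrected normal
#' approximation with continuity correction.  `"auto"` enumerates when
#' `n1 + n2 <= 12` and approximates otherwise.
#'
#' @param x,y numeric samples, both nonempty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `U` and two-sided `p`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4), mode = "exact")  # U = 0, p = 1/3
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y)) stop("both samples must be nonempty")
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (mode == "auto") mode <- if (n <= 12) "exact" else "normal_approx"
    if (mode == "exact") {
        offset <- n1 * (n1 + 1) / 2
        Us <- utils::combn(n, n1, function(idx) sum(r[idx]) - offset)
        p <- 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))
    } else {
        mu <- n1 * n2 / 2
        ties <- table(pooled)
        sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sig2 <= 0) {
            p <- 1
        } else {
            z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
            p <- 2 * stats::pnorm(-abs(z))
        }
    }
    list(U = U, p = min(1, p))
}

#' Holm sequential Bonferroni adjustment
#'
#' Step-down adjustment: with raw p-values sorted ascending,
#' `adj_(i) = max_(j <= i) min(1, (m - j + 1) p_(j))`; a hypothesis is
#' rejected while the adjusted value stays at or below `alpha`.  Results
#' are returned in input order.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha family-wise error level (default 0.05).
#' @return list with `p_adjusted` and logical `reject`.
#' @export
holmAdjust <- function(p, alpha = 0.05) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    adj <- stats::p.adjust(p, method = "holm")
    list(p_adjusted = adj, reject = adj <= alpha)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory per-wavenumber normality check of the pooled per-sample
#' values.  The screening never switches the pipeline to a parametric
#' branch (the per-wavenumber distributions in sputum FTIR data are not
#' normal); it only reports how many wavenumbers fail.  Constant samples
#' are flagged and given `NA` statistics rather than raising an error.
#'
#' @param values numeric vector (one wavenumber's values across samples).
#' @return list with `W`, `p` and logical `degenerate`.
#' @export
shapiroWilkScreen <- function(values) {
    values <- values[is.finite(values)]
    if (length(values) < 3 || stats::sd(values) == 0)
        return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
    sw <- stats::shapiro.test(values)
    list(W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

#' Per-wavenumber screening of cancer vs normal
#'
#' Runs the Mann-Whitney U test at every fingerprint wavenumber on the
#' per-sample second-derivative values (cancer as the first sample), then
#' applies Holm's sequential Bonferroni correction across all wavenumbers
#' at level `alpha`.  Rejected wavenumbers receive ranks 1..K by ascending
#' raw p-value (rank 1 = most significant), ties broken by ascending
#' wavenumber.  An advisory Shapiro-Wilk normality screen of the pooled
#' values is reported per wavenumber.
#'
#' @param cohort a replicate-aggregated second-derivative
#'   [FTIRCohort-class] with both classes present (>= 2 samples each).
#' @param alpha family-wise error level (default 0.05).
#' @param mode Mann-Whitney p-value mode, see [mannWhitneyU()].
#' @return `data.frame` (one row per wavenumber) with columns
#'   `wavenumber`, `u_statistic`, `p_raw`, `p_holm`, `reject`, `rank`,
#'   `shapiro_w`, `shapiro_p`.
#' @export
screenWavenumbers <- function(cohort, alpha = 0.05,
                              mode = c("auto", "exact", "normal_approx")) {
    mode <- match.arg(mode)
    cls <- classLabels(cohort)
    if (length(unique(cls)) < 2)
        stop("screening requires both classes in the cohort")
    if (min(table(cls)) < 2)
        stop("screening requires >= 2 samples per class")
    mat <- absorbance(cohort)
    w <- wavenumbers(cohort)
    can <- cls == "cancer"
    res <- lapply(seq_along(w), function(i) {
        mw <- mannWhitneyU(mat[i, can], mat[i, !can], mode = mode)
        sw <- shapiroWilkScreen(mat[i, ])
        c(U = mw$U, p = mw$p, W = sw$W, sp = sw$p)
    })
    res <- do.call(rbind, res)
    hol <- holmAdjust(res[, "p"], alpha)
    out <- data.frame(wavenumber = w,
                      u_statistic = res[, "U"],
                      p_raw = res[, "p"],
                      p_holm = hol$p_adjusted,
                      reject = hol$reject,
                      rank = NA_integer_,
                      shapiro_w = res[, "W"],
                      shapiro_p = res[, "sp"])
    rej <- which(out$reject)
    if (length(rej)) {
        ord <- rej[order(out$p_raw[rej], out$wavenumber[rej])]
        out$rank[ord] <- seq_along(ord)
    }
    out
}

#' Detect band centres in a second-derivative spectrum
#'
#' Absorption band centres appear as local minima of the second
#' derivative.  Strict local minima are kept when their prominence (depth
#' below the lower of the two flanking local maxima, with the trace ends
#' acting as maxima) reaches `min_prominence`.  With `refine = TRUE` the
#' centre is sharpened off-grid by a parabola through the minimum and its
#' two neighbours, standard sub-grid peak interpolation.
#'
#' @param spectrum a second-derivative [Spectrum-class].
#' @param min_prominence minimum prominence (absorbance * cm^2; default
#'   1e-5, small relative to band depths of vector-normalized spectra).
#' @param refine logical, parabolic sub-grid centre refinement.
#' @return `data.frame` with columns `centre`, `depth` (the negative
#'   second-derivative value at the minimum), `prominence`,
#'   `matched_rank` (`NA` until matched), `annotation`; centres ascending.
#' @export
detectBandCentres <- function(spectrum, min_prominence = 1e-5, refine = TRUE) {
    if (spectrumKind(spectrum) != "second_derivative")
        stop("band centres are detected on second-derivative spectra")
    y <- absorbance(spectrum)
    w <- wavenumbers(spectrum)
    n <- length(y)
    empty <- data.frame(centre = numeric(0), depth = numeric(0),
                        prominence = numeric(0), matched_rank = integer(0),
                        annotation = character(0), stringsAsFactors = FALSE)
    if (n < 3) return(empty)
    i <- 2:(n - 1)
    minima <- i[y[i] < y[i - 1] & y[i] < y[i + 1]]
    maxima <- c(1, i[y[i] > y[i - 1] & y[i] > y[i + 1]], n)
    keep <- logical(length(minima))
    prom <- numeric(length(minima))
    for (k in seq_along(minima)) {
        m <- minima[k]
        lmax <- maxima[maxima < m]
        rmax <- maxima[maxima > m]
        flank <- min(y[lmax[length(lmax)]], y[rmax[1]])
        prom[k] <- flank - y[m]
        keep[k] <- prom[k] >= min_prominence
    }
    minima <- minima[keep]; prom <- prom[keep]
    if (!length(minima)) return(empty)
    centre <- w[minima]
    if (refine && length(minima)) {
        step <- stats::median(diff(w))
        for (k in seq_along(minima)) {
            m <- minima[k]
            denom <- y[m - 1] - 2 * y[m] + y[m + 1]
            if (denom > 0) {
                off <- 0.5 * (y[m - 1] - y[m + 1]) / denom
                centre[k] <- w[m] + max(-0.5, min(0.5, off)) * step
            }
        }
    }
    data.frame(centre = centre, depth = y[minima], prominence = prom,
               matched_rank = NA_integer_,
               annotation = NA_character_, stringsAsFactors = FALSE)
}

#' Band centres of the per-class median spectra
#'
#' Detects band centres on each class's median second-derivative spectrum
#' and merges the two peak lists: peaks from the two classes closer than
#' `collapse_tolerance` are collapsed to one consensus peak at their mean
#' centre (keeping the deeper minimum), while class-shifted bands further
#' apart than the tolerance remain distinct.
#'
#' @param cohort a replicate-aggregated second-derivative
#'   [FTIRCohort-class] containing both classes.
#' @param min_prominence see [detectBandCentres()].
#' @param collapse_tolerance merge radius in 1/cm (default two grid steps).
#' @return a peak `data.frame` as from [detectBandCentres()].
#' @export
detectClassPeaks <- function(cohort, min_prominence = 1e-5,
                             collapse_tolerance = 2 * 850 / 441) {
    pk <- rbind(
        detectBandCentres(groupMedianSpectrum(cohort, "normal"), min_prominence),
        detectBandCentres(groupMedianSpectrum(cohort, "cancer"), min_prominence))
    if (!nrow(pk)) return(pk)
    pk <- pk[order(pk$centre), , drop = FALSE]
    grp <- cumsum(c(1, diff(pk$centre) > collapse_tolerance))
    merged <- do.call(rbind, lapply(split(pk, grp), function(g)
        data.frame(centre = mean(g$centre), depth = min(g$depth),
                   prominence = max(g$prominence),
                   matched_rank = NA_integer_, annotation = NA_character_,
                   stringsAsFactors = FALSE)))
    rownames(merged) <- NULL
    merged
}

#' Match significant wavenumbers to band centres
#'
#' A detected band centre is "matched" when at least one Holm-rejected
#' wavenumber lies within `tolerance` of it; `matched_rank` records the
#' best (smallest) significance rank among those wavenumbers.  This is the
#' deterministic counterpart of reading significant wavenumbers off the
#' second-derivative median spectra by spectral alignment.
#'
#' @param sig_table a [screenWavenumbers()] result.
#' @param peaks a peak table from [detectBandCentres()] or
#'   [detectClassPeaks()].
#' @param tolerance matching radius in 1/cm (default two grid steps of the
#'   canonical fingerprint grid, about 3.9 1/cm).
#' @return the matched subset of `peaks`, sorted by `matched_rank`.
#' @export
matchSignificantToPeaks <- function(sig_table, peaks,
                                    tolerance = 2 * 850 / 441) {
    if (tolerance <= 0) stop("tolerance must be positive")
    rej <- sig_table[sig_table$reject, , drop = FALSE]
    if (!nrow(peaks)) return(peaks)
    peaks$matched_rank <- vapply(peaks$centre, function(cc) {
        near <- rej$rank[abs(rej$wavenumber - cc) <= tolerance]
        if (length(near)) min(near) else NA_integer_
    }, numeric(1))
    out <- peaks[!is.na(peaks$matched_rank), , drop = FALSE]
    out <- out[order(out$matched_rank), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Select the multivariate analysis panel
#'
#' Takes the top `panel_size` matched peaks by significance rank, then
#' removes any peak lying within `exclusion_window` of a mucin reference
#' wavenumber: mucin C-O bands (1040, 1076, 1120 1/cm) are airway-mucus
#' confounders in sputum, so glycogen-region peaks that could be mucin
#' related are not carried into clustering or PCA.
#'
#' @param matched a matched peak table from [matchSignificantToPeaks()].
#' @param mucin_refs mucin reference wavenumbers (1/cm).
#' @param exclusion_window exclusion radius around each reference (1/cm).
#' @param panel_size number of top-ranked peaks considered (default 6).
#' @return ascending numeric vector of panel wavenumbers (1/cm).
#' @export
selectMvaPanel <- function(matched, mucin_refs = c(1040, 1076, 1120),
                           exclusion_window = 10, panel_size = 6) {
    if (!nrow(matched)) stop("no matched peaks to select a panel from")
    top <- matched[order(matched$matched_rank), , drop = FALSE]
    top <- utils::head(top, panel_size)
    excl <- vapply(top$centre, function(cc)
        any(abs(cc - mucin_refs) <= exclusion_window), logical(1))
    panel <- sort(top$centre[!excl])
    if (!length(panel))
        stop("panel empty after mucin exclusion; excluded centres: ",
             paste(sprintf("%.1f", top$centre[excl]), collapse = ", "))
    panel
}
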