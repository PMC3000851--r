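#' @include AllGenerics.R
NULL

#' Pre-processing parameters
#'
#' Defaults follow the sputum cell-pellet protocol: baseline anchors at 900
#' and 1850 1/cm (chosen outside the region of interest, where absorbance
#' is stable across samples), fingerprint crop to [950, 1800] 1/cm, and a
#' nine-point Savitzky-Golay second derivative.  The polynomial order is
#' not critical: orders 2 and 3 share identical second-derivative
#' convolution coefficients on a symmetric window.
#'
#' @param anchor_low,anchor_high baseline anchor wavenumbers (1/cm).
#' @param crop_low,crop_high fingerprint crop bounds (1/cm).
#' @param sg_window Savitzky-Golay window length (odd, default 9).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3).
#' @param replicate_aggregate `"median"` (default) or `"mean"` pointwise
#'   aggregation of technical replicates.
#' @return a validated list of class `"PreprocessParams"`.
#' @export
preprocessParams <- function(anchor_low = 900, anchor_high = 1850,
                             crop_low = 950, crop_high = 1800,
                             sg_window = 9, sg_polyorder = 3,
                             replicate_aggregate = c("median", "mean")) {
    replicate_aggregate <- match.arg(replicate_aggregate)
    if (!(anchor_low < crop_low && crop_low < crop_high && crop_high < anchor_high))
        stop("require anchor_low < crop_low < crop_high < anchor_high")
    if (sg_window %% 2 != 1) stop("sg_window must be odd")
    if (sg_window < sg_polyorder + 2)
        stop("sg_window must be >= sg_polyorder + 2")
    structure(list(anchor_low = anchor_low, anchor_high = anchor_high,
                   crop_low = crop_low, crop_high = crop_high,
                   sg_window = as.integer(sg_window),
                   sg_polyorder = as.integer(sg_polyorder),
                   replicate_aggregate = replicate_aggregate),
              class = "PreprocessParams")
}

.nearest_anchor <- function(w, anchor) {
    step <- stats::median(diff(w))
    i <- which.min(abs(w - anchor))
    if (abs(w[i] - anchor) > step / 2 + 1e-9)
        stop(sprintf("baseline anchor %g 1/cm lies outside the grid span", anchor))
    i
}

.baseline_core <- function(w, mat, params) {
    ilo <- .nearest_anchor(w, params$anchor_low)
    ihi <- .nearest_anchor(w, params$anchor_high)
    slope <- (mat[ihi, , drop = FALSE] - mat[ilo, , drop = FALSE]) /
        (w[ihi] - w[ilo])
    sweep_term <- outer(w - w[ilo], drop(slope)) +
        matrix(rep(mat[ilo, ], each = length(w)), nrow = length(w))
    mat - sweep_term
}

#' @rdname preprocessing-generics
#' @export
setMethod("baselineCorrect", "Spectrum", function(x, params = preprocessParams()) {
    m <- .baseline_core(x@wavenumber, cbind(x@absorbance), params)
    Spectrum(x@wavenumber, drop(m), kind = "baseline_corrected")
})

#' @rdname preprocessing-generics
#' @export
setMethod("baselineCorrect", "FTIRCohort", function(x, params = preprocessParams()) {
    assay(x, "absorbance") <- .baseline_core(wavenumbers(x),
                                             assay(x, "absorbance"), params)
    metadata(x)$kind <- "baseline_corrected"
    x
})

.crop_idx <- function(w, params) {
    if (min(w) > params$crop_low || max(w) < params$crop_high)
        stop(sprintf("grid [%g, %g] does not cover the crop interval [%g, %g]",
                     min(w), max(w), params$crop_low, params$crop_high))
    keep <- which(w >= params$crop_low - 1e-9 & w <= params$crop_high + 1e-9)
    if (!length(keep)) stop("empty grid after cropping")
    keep
}

#' @rdname preprocessing-generics
#' @export
setMethod("cropFingerprint", "Spectrum", function(x, params = preprocessParams()) {
    keep <- .crop_idx(x@wavenumber, params)
    Spectrum(x@wavenumber[keep], x@absorbance[keep], kind = x@kind)
})

#' @rdname preprocessing-generics
#' @export
setMethod("cropFingerprint", "FTIRCohort", function(x, params = preprocessParams()) {
    keep <- .crop_idx(wavenumbers(x), params)
    x[keep, ]
})

.vecnorm_core <- function(mat) {
    nrm <- sqrt(colSums(mat^2))
    zero <- which(nrm == 0)
    if (length(zero))
        stop("cannot vector-normalize an all-zero spectrum (column ",
             zero[1], ")")
    sweep(mat, 2, nrm, "/")
}

#' @rdname preprocessing-generics
#' @export
setMethod("vectorNormalize", "Spectrum", function(x) {
    m <- .vecnorm_core(cbind(x@absorbance))
    Spectrum(x@wavenumber, drop(m), kind = "normalized")
})

#' @rdname preprocessing-generics
#' @export
setMethod("vectorNormalize", "FTIRCohort", function(x) {
    assay(x, "absorbance") <- .vecnorm_core(assay(x, "absorbance"))
    metadata(x)$kind <- "normalized"
    x
})

.sg_core <- function(w, mat, params) {
    if (length(w) < params$sg_window)
        stop("spectrum shorter than the Savitzky-Golay window")
    d <- diff(w)
    step <- mean(d)
    if (max(abs(d - step)) / step > 1e-6)
        stop("Savitzky-Golay differentiation requires a uniform grid")
    apply(mat, 2, function(y)
        signal::sgolayfilt(y, p = params$sg_polyorder, n = params$sg_window,
                           m = 2, ts = step))
}

#' @rdname preprocessing-generics
#' @export
setMethod("sgSecondDerivative", "Spectrum", function(x, params = preprocessParams()) {
    m <- .sg_core(x@wavenumber, cbind(x@absorbance), params)
    Spectrum(x@wavenumber, drop(m), kind = "second_derivative")
})

#' @rdname preprocessing-generics
#' @export
setMethod("sgSecondDerivative", "FTIRCohort", function(x, params = preprocessParams()) {
    assay(x, "absorbance") <- .sg_core(wavenumbers(x),
                                       assay(x, "absorbance"), params)
    metadata(x)$kind <- "second_derivative"
    x
})

#' Full pre-processing chain
#'
#' Applies, in the fixed order, two-point baseline correction, fingerprint
#' cropping, vector normalization and the Savitzky-Golay second derivative
#' to every spectrum of a cohort.  Baseline correction must precede
#' cropping because the anchors lie outside the fingerprint region.
#'
#' @param cohort a raw [FTIRCohort-class].
#' @param params a [preprocessParams()].
#' @return a second-derivative [FTIRCohort-class] on the cropped grid.
#' @export
preprocessCohort <- function(cohort, params = preprocessParams()) {
    cohort <- baselineCorrect(cohort, params)
    cohort <- cropFingerprint(cohort, params)
    cohort <- vectorNormalize(cohort)
    sgSecondDerivative(cohort, params)
}

#' Aggregate technical replicates
#'
#' Collapses each sample's replicate spectra to a single spectrum by
#' pointwise median (default) or mean; per-sample metadata is carried
#' through.  Sample order follows first appearance in the cohort.
#'
#' @param cohort an [FTIRCohort-class].
#' @param params a [preprocessParams()] (uses `replicate_aggregate`).
#' @return an [FTIRCohort-class] with one spectrum per sample
#'   (`replicate == 1`).
#' @export
aggregateReplicates <- function(cohort, params = preprocessParams()) {
    sid <- sampleIds(cohort)
    ids <- unique(sid)
    mat <- absorbance(cohort)
    fun <- if (params$replicate_aggregate == "median") stats::median else mean
    agg <- vapply(ids, function(s)
        apply(mat[, sid == s, drop = FALSE], 1, fun),
        numeric(nrow(mat)))
    first <- match(ids, sid)
    cd <- colData(cohort)[first, , drop = FALSE]
    meta_col <- setdiff(names(cd), c("sample_id", "replicate", "class"))
    FTIRCohort(agg, wavenumbers(cohort), sample_id = ids,
               replicate = rep(1L, length(ids)),
               class_label = cd$class,
               metadata = as.data.frame(cd[, meta_col, drop = FALSE]),
               kind = spectrumKind(cohort))
}

#' Pointwise class median spectrum
#'
#' Median absorbance across all of a class's spectra at each wavenumber
#' (medians rather than means: the per-wavenumber values are not normally
#' distributed).
#'
#' @param cohort an [FTIRCohort-class] (normally replicate-aggregated).
#' @param class_label `"cancer"` or `"normal"`.
#' @return a [Spectrum-class] of the cohort's current kind.
#' @export
groupMedianSpectrum <- function(cohort, class_label) {
    if (!class_label %in% c("cancer", "normal"))
        stop("unknown class label: ", class_label)
    sel <- classLabels(cohort) == class_label
    if (!any(sel)) stop("no samples with class '", class_label, "'")
    Spectrum(wavenumbers(cohort),
             apply(absorbance(cohort)[, sel, drop = FALSE], 1, stats::median),
             kind = spectrumKind(cohort))
}
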