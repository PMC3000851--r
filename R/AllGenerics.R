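#' @include AllClasses.R
NULL

#' Accessors for spectra and cohorts
#'
#' `wavenumbers()` returns the (ascending) grid, `absorbance()` the trace
#' or matrix of traces, `spectrumKind()` the processing state,
#' `classLabels()`, `sampleIds()` and `replicateIndices()` the per-column
#' design of a cohort, and `getSpectrum()` extracts one column of a cohort
#' as a [Spectrum-class].
#'
#' @param x a [Spectrum-class] or [FTIRCohort-class].
#' @param j column index or name (for `getSpectrum`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))
#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("replicateIndices", function(x) standardGeneric("replicateIndices"))
#' @rdname accessors
#' @export
setGeneric("getSpectrum", function(x, j) standardGeneric("getSpectrum"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@wavenumber)
#' @rdname accessors
#' @export
setMethod("wavenumbers", "FTIRCohort", function(x) rowData(x)$wavenumber)
#' @rdname accessors
#' @export
setMethod("absorbance", "Spectrum", function(x) x@absorbance)
#' @rdname accessors
#' @export
setMethod("absorbance", "FTIRCohort", function(x) assay(x, "absorbance"))
#' @rdname accessors
#' @export
setMethod("spectrumKind", "Spectrum", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("spectrumKind", "FTIRCohort", function(x) metadata(x)$kind)
#' @rdname accessors
#' @export
setMethod("classLabels", "FTIRCohort", function(x) colData(x)$class)
#' @rdname accessors
#' @export
setMethod("sampleIds", "FTIRCohort", function(x) colData(x)$sample_id)
#' @rdname accessors
#' @export
setMethod("replicateIndices", "FTIRCohort", function(x) colData(x)$replicate)
#' @rdname accessors
#' @export
setMethod("getSpectrum", "FTIRCohort", function(x, j) {
    Spectrum(wavenumbers(x), assay(x, "absorbance")[, j], spectrumKind(x))
})

setMethod("show", "Spectrum", function(object) {
    w <- object@wavenumber
    cat(sprintf("Spectrum (%s): %d points", object@kind, length(w)))
    if (length(w))
        cat(sprintf(", %.1f-%.1f 1/cm", min(w), max(w)))
    cat("\n")
})

setMethod("show", "FTIRCohort", function(object) {
    cl <- table(factor(classLabels(object), levels = c("cancer", "normal")))
    cat(sprintf("FTIRCohort (%s): %d wavenumbers x %d spectra\n",
                spectrumKind(object), nrow(object), ncol(object)))
    cat(sprintf("  %d samples (%d cancer / %d normal spectra)\n",
                length(unique(sampleIds(object))), cl[["cancer"]], cl[["normal"]]))
    callNextMethod()
})

#' Spectral pre-processing generics
#'
#' The pre-processing chain applied to raw absorbance spectra, in the fixed
#' order: [baselineCorrect()] (two-point linear subtraction anchored outside
#' the fingerprint region), [cropFingerprint()] (950-1800 1/cm),
#' [vectorNormalize()] (unit Euclidean norm), [sgSecondDerivative()]
#' (Savitzky-Golay smoothed second derivative).  Each is defined for both a
#' single [Spectrum-class] and an [FTIRCohort-class] (applied column-wise).
#'
#' @param x a [Spectrum-class] or [FTIRCohort-class].
#' @param params a [preprocessParams()] list.
#' @name preprocessing-generics
NULL

#' @rdname preprocessing-generics
#' @export
setGeneric("baselineCorrect",
    function(x, params = preprocessParams()) standardGeneric("baselineCorrect"))
#' @rdname preprocessing-generics
#' @export
setGeneric("cropFingerprint",
    function(x, params = preprocessParams()) standardGeneric("cropFingerprint"))
#' @rdname preprocessing-generics
#' @export
setGeneric("vectorNormalize", function(x) standardGeneric("vectorNormalize"))
#' @rdname preprocessing-generics
#' @export
setGeneric("sgSecondDerivative",
    function(x, params = preprocessParams()) standardGeneric("sgSecondDerivative"))
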