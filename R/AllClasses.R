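#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays rowData colData colData<-
NULL

.SPECTRUM_KINDS <- c("raw", "baseline_corrected", "normalized", "second_derivative")

#' Single FTIR spectrum
#'
#' An ordered wavenumber grid together with one absorbance trace.  The grid
#' is stored ascending; descending input (the native ordering of many FTIR
#' instruments) is reversed on construction.  `kind` records the processing
#' state of the trace.
#'
#' @slot wavenumber strictly increasing, finite, positive wavenumbers (1/cm).
#' @slot absorbance finite absorbance values, one per grid point
#'   (dimensionless for raw/normalized traces; absorbance * cm^2 after a
#'   second derivative).
#' @slot kind one of `"raw"`, `"baseline_corrected"`, `"normalized"`,
#'   `"second_derivative"`.
#' @exportClass Spectrum
setClass("Spectrum",
    slots = c(wavenumber = "numeric", absorbance = "numeric", kind = "character"))

setValidity("Spectrum", function(object) {
    w <- object@wavenumber
    a <- object@absorbance
    msg <- character()
    if (length(a) != length(w))
        msg <- c(msg, "absorbance and wavenumber must have equal length")
    if (length(w) && (!all(is.finite(w)) || any(w <= 0)))
        msg <- c(msg, "wavenumbers must be finite and positive")
    if (length(w) > 1 && any(diff(w) <= 0))
        msg <- c(msg, "wavenumbers must be strictly increasing")
    if (length(a) && !all(is.finite(a)))
        msg <- c(msg, "absorbance values must be finite")
    if (length(object@kind) != 1 || !object@kind %in% .SPECTRUM_KINDS)
        msg <- c(msg, sprintf("kind must be one of: %s",
                              paste(.SPECTRUM_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param wavenumber numeric grid (1/cm), strictly monotone in either
#'   direction; descending input is normalized to ascending.
#' @param absorbance numeric values, same length as `wavenumber`.
#' @param kind processing state, see [Spectrum-class].
#' @return a [Spectrum-class] object with an ascending grid.
#' @examples
#' s <- Spectrum(seq(950, 1800, by = 2), rep(0.1, 426))
#' @export
Spectrum <- function(wavenumber, absorbance, kind = "raw") {
    wavenumber <- as.numeric(wavenumber)
    absorbance <- as.numeric(absorbance)
    if (length(wavenumber) > 1 && all(diff(wavenumber) < 0)) {
        wavenumber <- rev(wavenumber)
        absorbance <- rev(absorbance)
    }
    new("Spectrum", wavenumber = wavenumber, absorbance = absorbance, kind = kind)
}

#' Cohort of FTIR spectra
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"absorbance"` holds wavenumbers in rows and individual measured spectra
#' (replicates) in columns.  `rowData` carries the wavenumber grid;
#' `colData` carries `sample_id`, `replicate`, `class` (exactly `"cancer"`
#' or `"normal"`) and free-form per-sample metadata such as
#' `smoking_status`, `prior_cancer` and `cough`.  The processing state of
#' the whole cohort is kept in `metadata(x)$kind`.
#'
#' @exportClass FTIRCohort
setClass("FTIRCohort", contains = "SummarizedExperiment")

setValidity("FTIRCohort", function(object) {
    msg <- character()
    if (!"absorbance" %in% names(assays(object)))
        return("assay 'absorbance' is required")
    w <- rowData(object)$wavenumber
    if (is.null(w))
        return("rowData column 'wavenumber' is required")
    if (length(w) > 1 && any(diff(w) <= 0))
        msg <- c(msg, "wavenumber grid must be strictly increasing")
    if (length(w) && (!all(is.finite(w)) || any(w <= 0)))
        msg <- c(msg, "wavenumbers must be finite and positive")
    cd <- colData(object)
    for (col in c("sample_id", "replicate", "class"))
        if (!col %in% names(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (length(msg)) return(msg)
    if (ncol(object)) {
        if (!all(cd$class %in% c("cancer", "normal")))
            msg <- c(msg, "class labels must be 'cancer' or 'normal'")
        if (!all(is.finite(assay(object, "absorbance"))))
            msg <- c(msg, "absorbance values must be finite")
        for (sid in unique(cd$sample_id)) {
            reps <- sort(cd$replicate[cd$sample_id == sid])
            if (!identical(as.integer(reps), seq_along(reps)))
                msg <- c(msg, sprintf(
                    "sample '%s': replicate indices must be contiguous from 1", sid))
        }
    }
    kind <- metadata(object)$kind
    if (is.null(kind) || !kind %in% .SPECTRUM_KINDS)
        msg <- c(msg, "metadata 'kind' must be a valid spectrum kind")
    if (length(msg)) msg else TRUE
})

#' Construct an FTIRCohort
#'
#' @param absorbance numeric matrix, wavenumbers in rows, spectra in columns.
#' @param wavenumber grid of length `nrow(absorbance)`; descending input is
#'   normalized to ascending (rows are reversed accordingly).
#' @param sample_id character vector, one entry per column.
#' @param replicate integer replicate index per column (contiguous from 1
#'   within each sample).
#' @param class_label `"cancer"` or `"normal"` per column; must be constant
#'   within a sample.
#' @param metadata optional `DataFrame`/`data.frame` of additional
#'   per-spectrum columns (e.g. `smoking_status`, `prior_cancer`, `cough`).
#' @param kind processing state of the absorbance values.
#' @return an [FTIRCohort-class].
#' @export
FTIRCohort <- function(absorbance, wavenumber, sample_id, replicate,
                       class_label, metadata = NULL, kind = "raw") {
    absorbance <- as.matrix(absorbance)
    wavenumber <- as.numeric(wavenumber)
    if (length(wavenumber) > 1 && all(diff(wavenumber) < 0)) {
        wavenumber <- rev(wavenumber)
        absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
    }
    rownames(absorbance) <- NULL
    n <- ncol(absorbance)
    cd <- DataFrame(sample_id = as.character(sample_id),
                    replicate = as.integer(replicate),
                    class = as.character(class_label))
    if (!is.null(metadata) && ncol(as.data.frame(metadata)) > 0)
        cd <- cbind(cd, DataFrame(as.data.frame(metadata)))
    if (n) colnames(absorbance) <- sprintf("%s_r%d", cd$sample_id, cd$replicate)
    rownames(cd) <- colnames(absorbance)
    se <- SummarizedExperiment(
        assays = list(absorbance = absorbance),
        rowData = DataFrame(wavenumber = wavenumber),
        colData = cd, metadata = list(kind = kind))
    new("FTIRCohort", se)
}
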