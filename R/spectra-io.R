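#' @include AllClasses.R
NULL

#' Canonical wavenumber grids
#'
#' The fingerprint analysis region is defined as 442 evenly spaced points
#' covering 950 to 1800 1/cm inclusive (step 850/441, about 1.93 1/cm).
#' The raw acquisition grid extends the same arithmetic sequence 26 steps
#' below 950 and 26 steps above 1800 (about 899.9 to 1850.1 1/cm) so that
#' both baseline anchor points (900 and 1850 1/cm) fall on the grid span.
#'
#' @return numeric vector of wavenumbers, ascending.
#' @examples
#' length(canonicalFingerprintGrid())  # 442
#' length(canonicalRawGrid())          # 494
#' @export
canonicalFingerprintGrid <- function() {
    950 + (0:441) * (850 / 441)
}

#' @rdname canonicalFingerprintGrid
#' @export
canonicalRawGrid <- function() {
    950 + (-26:467) * (850 / 441)
}

#' Absorbance from sample/reference beam intensities
#'
#' Converts a pair of single-beam intensity traces into an absorbance
#' spectrum, A = -log10(IS/IR), where IS is the intensity after absorption
#' by the sample and IR the reference beam intensity.
#'
#' @param sample_intensity positive intensities (IS), one per grid point.
#' @param reference_intensity positive intensities (IR), same length.
#' @param wavenumber wavenumber grid of the same length.
#' @return a raw [Spectrum-class].
#' @examples
#' s <- computeAbsorbance(rep(0.5, 5), rep(1, 5), seq(1000, 1008, by = 2))
#' absorbance(s)  # 0.30103 everywhere
#' @export
computeAbsorbance <- function(sample_intensity, reference_intensity, wavenumber) {
    if (length(sample_intensity) != length(reference_intensity))
        stop("sample and reference intensities must have equal length (",
             length(sample_intensity), " vs ", length(reference_intensity), ")")
    bad <- which(!is.finite(sample_intensity) | sample_intensity <= 0)
    if (length(bad))
        stop("sample intensity must be positive; offending index: ", bad[1])
    bad <- which(!is.finite(reference_intensity) | reference_intensity <= 0)
    if (length(bad))
        stop("reference intensity must be positive; offending index: ", bad[1])
    Spectrum(wavenumber, -log10(sample_intensity / reference_intensity),
             kind = "raw")
}

.fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read a spectrum cohort from CSV
#'
#' Two dialects are supported.  `wide_csv` has one row per measured
#' spectrum with columns `sample_id,replicate,class,<metadata...>` followed
#' by one column per wavenumber (numeric column names).  `long_csv` has
#' columns `sample_id,replicate,class,wavenumber,absorbance` (metadata
#' columns, if present, must be constant within a spectrum).
#'
#' @param file path or connection.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @param kind processing state to record, default `"raw"`.
#' @return an [FTIRCohort-class]; row order of the input is preserved as
#'   column (spectrum) insertion order.
#' @export
readCohortMatrix <- function(file, dialect = c("wide_csv", "long_csv"),
                             kind = "raw") {
    dialect <- match.arg(dialect)
    df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
    req <- c("sample_id", "replicate", "class")
    if (!all(req %in% names(df)))
        stop("missing required columns: ",
             paste(setdiff(req, names(df)), collapse = ", "))
    if (dialect == "wide_csv") .read_wide(df, kind) else .read_long(df, kind)
}

.read_wide <- function(df, kind) {
    wn_col <- suppressWarnings(!is.na(as.numeric(names(df))))
    meta_col <- setdiff(names(df)[!wn_col], c("sample_id", "replicate", "class"))
    w <- as.numeric(names(df)[wn_col])
    if (length(w) < 1) stop("wide_csv: no wavenumber columns found")
    mat <- df[, wn_col, drop = FALSE]
    for (j in seq_along(mat)) {
        v <- suppressWarnings(as.numeric(mat[[j]]))
        bad <- which(is.na(v) & !is.na(mat[[j]]))
        if (length(bad) || anyNA(v))
            stop("wide_csv: non-numeric absorbance in row ",
                 if (length(bad)) bad[1] else which(is.na(v))[1])
        mat[[j]] <- v
    }
    dup <- duplicated(df[c("sample_id", "replicate")])
    if (any(dup))
        stop("wide_csv: duplicate (sample_id, replicate) in row ", which(dup)[1])
    FTIRCohort(t(as.matrix(mat)), w,
               sample_id = df$sample_id, replicate = df$replicate,
               class_label = df$class,
               metadata = df[, meta_col, drop = FALSE], kind = kind)
}

.read_long <- function(df, kind) {
    for (col in c("wavenumber", "absorbance")) {
        if (!col %in% names(df)) stop("long_csv: missing column '", col, "'")
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v)))
            stop("long_csv: non-numeric ", col, " in row ",
                 which(is.na(v) & !is.na(df[[col]]))[1])
        df[[col]] <- v
    }
    key <- paste(df$sample_id, df$replicate, sep = "\r")
    dup <- duplicated(paste(key, df$wavenumber, sep = "\r"))
    if (any(dup))
        stop("long_csv: duplicate (sample_id, replicate, wavenumber) in row ",
             which(dup)[1])
    specs <- unique(key)
    w <- sort(unique(df$wavenumber))
    mat <- matrix(NA_real_, length(w), length(specs))
    rows <- split(seq_len(nrow(df)), factor(key, levels = specs))
    meta_col <- setdiff(names(df), c("sample_id", "replicate", "class",
                                     "wavenumber", "absorbance"))
    first <- vapply(rows, `[`, integer(1), 1)
    for (i in seq_along(specs)) {
        idx <- rows[[i]]
        if (length(idx) != length(w) ||
            !setequal(df$wavenumber[idx], w))
            stop("long_csv: incomplete wavenumber grid for sample '",
                 df$sample_id[idx[1]], "' replicate ", df$replicate[idx[1]])
        mat[match(df$wavenumber[idx], w), i] <- df$absorbance[idx]
    }
    FTIRCohort(mat, w,
               sample_id = df$sample_id[first], replicate = df$replicate[first],
               class_label = df$class[first],
               metadata = df[first, meta_col, drop = FALSE], kind = kind)
}

#' Write a spectrum cohort to CSV
#'
#' Inverse of [readCohortMatrix()]; values (including the wavenumber
#' header) are written at full double precision so that a write/read
#' round trip is value-exact.
#'
#' @param cohort an [FTIRCohort-class].
#' @param file path or connection.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return `file`, invisibly.
#' @export
writeCohortMatrix <- function(cohort, file, dialect = c("wide_csv", "long_csv")) {
    dialect <- match.arg(dialect)
    stopifnot(is(cohort, "FTIRCohort"))
    w <- wavenumbers(cohort)
    cd <- as.data.frame(colData(cohort))
    meta_col <- setdiff(names(cd), c("sample_id", "replicate", "class"))
    mat <- absorbance(cohort)
    if (dialect == "wide_csv") {
        vals <- matrix(.fmt_full(t(mat)), nrow = ncol(mat), ncol = length(w))
        out <- cbind(cd[c("sample_id", "replicate", "class")],
                     cd[meta_col],
                     as.data.frame(vals, stringsAsFactors = FALSE))
        names(out) <- c("sample_id", "replicate", "class", meta_col, .fmt_full(w))
        utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    } else {
        n <- ncol(mat)
        idx <- rep(seq_len(n), each = length(w))
        out <- data.frame(sample_id = cd$sample_id[idx],
                          replicate = cd$replicate[idx],
                          class = cd$class[idx],
                          stringsAsFactors = FALSE)
        for (mc in meta_col) out[[mc]] <- cd[[mc]][idx]
        out$wavenumber <- .fmt_full(rep(w, times = n))
        out$absorbance <- .fmt_full(as.vector(mat))
        utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    }
    invisible(file)
}
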