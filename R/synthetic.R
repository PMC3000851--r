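#' @include spectra-io.R
NULL

#' Default band table for synthetic sputum spectra
#'
#' Six class-differential Gaussian bands with the centres reported for
#' sputum cell pellets (phosphate/C-C near 964/966, glycogen C-O near 1024
#' and 1049/1051, protein COO-/C-H near 1417/1411, amide II at 1577 and
#' amide I near 1656/1654), each with a higher amplitude in the cancer
#' class, plus five class-neutral "distractor" bands filling out the
#' fingerprint region so that normalization and clustering are exercised
#' against a realistic background.
#'
#' The protein COO- band is planted at 1417 1/cm in normal spectra shifting
#' to 1411 1/cm in cancer spectra by default; `d_orientation = "table"`
#' swaps that pair for sensitivity analyses.
#'
#' @param d_orientation `"text"` (normal 1417 -> cancer 1411, default) or
#'   `"table"` (the transposed reading).
#' @return data.frame with columns `band`, `centre_normal`, `centre_cancer`,
#'   `fwhm`, `amplitude_normal`, `amplitude_cancer`, `differential`,
#'   `annotation`.
#' @export
defaultBandTable <- function(d_orientation = c("text", "table")) {
    d_orientation <- match.arg(d_orientation)
    d <- if (d_orientation == "text") c(1417, 1411) else c(1411, 1417)
    tab <- data.frame(
        band = c("A", "B", "C", "D", "E", "F",
                 "bg1", "bg2", "bg3", "bg4", "bg5"),
        centre_normal = c(964, 1024, 1049, d[1], 1577, 1656,
                          1160, 1240, 1310, 1455, 1740),
        centre_cancer = c(966, 1024, 1051, d[2], 1577, 1654,
                          1160, 1240, 1310, 1455, 1740),
        fwhm = c(10, 14, 14, 18, 22, 28, 20, 24, 20, 16, 16),
        amplitude_normal = c(0.10, 0.22, 0.28, 0.30, 0.45, 0.80,
                             0.18, 0.25, 0.15, 0.28, 0.10),
        amplitude_cancer = c(0.135, 0.30, 0.36, 0.38, 0.63, 0.95,
                             0.18, 0.25, 0.15, 0.28, 0.10),
        differential = c(rep(TRUE, 6), rep(FALSE, 5)),
        annotation = c(
            "PO4 stretch; C-C stretch (protein and nucleic acid)",
            "C-O stretch, C-O bend (glycogen)",
            "C-O stretch, C-O bend (glycogen)",
            "COO- stretch, C-H bend (protein)",
            "Amide II, N-H bend, C-N stretch (protein and nucleic acid)",
            "Amide I, C=O stretch (protein)",
            "class-neutral background", "class-neutral background",
            "class-neutral background", "class-neutral background",
            "class-neutral background (lipid ester region)"),
        stringsAsFactors = FALSE)
    tab
}

.MUCIN_REFS <- c(1040, 1076, 1120)

.validate_bands <- function(bands) {
    req <- c("centre_normal", "centre_cancer", "fwhm",
             "amplitude_normal", "amplitude_cancer")
    if (!all(req %in% names(bands)))
        stop("band table must have columns: ", paste(req, collapse = ", "))
    if (any(bands$fwhm < 4 | bands$fwhm > 60))
        stop("band fwhm must lie in [4, 60] 1/cm")
    if (any(bands$amplitude_normal < 0) || any(bands$amplitude_cancer < 0))
        stop("band amplitudes must be non-negative")
    if (any(abs(bands$centre_cancer - bands$centre_normal) > 10))
        stop("class centre shifts larger than 10 1/cm are not supported")
    invisible(bands)
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic spectrum generator.  Each measured spectrum
#' is built on the canonical raw grid as
#' `gain * (baseline(v) + sum_b jitter_b * A_b * G(v; centre_b, fwhm_b)) + noise`,
#' where `G` is a unit-amplitude Gaussian, `jitter_b` is a per-sample
#' lognormal amplitude factor shared across that sample's replicates,
#' `gain` is a per-replicate lognormal factor, and `noise` is i.i.d.
#' Gaussian per grid point.
#'
#' @param n_cancer,n_normal number of subjects per class (defaults 25/25).
#' @param replicates technical replicates per subject (default 3).
#' @param bands band table as from [defaultBandTable()].
#' @param baseline_intercept,baseline_slope,baseline_curvature polynomial
#'   baseline coefficients (absorbance; per 1/cm; per (1/cm)^2), evaluated
#'   in `(v - 900)`.
#' @param gain_sd sd of log replicate gain (default 0.05).
#' @param subject_amplitude_jitter_sd sd of log per-sample, per-band
#'   amplitude jitter (default 0.03).
#' @param noise_sd additive noise sd, absorbance units (default 0.003).
#' @param mucin_bands_enabled add class-neutral mucin C-O bands at 1040,
#'   1076 and 1120 1/cm (default `FALSE`; the sputum processing emulated
#'   here removes most mucus).
#' @param mucin_amplitude amplitude of the mucin bands when enabled.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a validated configuration list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(n_cancer = 25, n_normal = 25, replicates = 3,
                         bands = defaultBandTable(),
                         baseline_intercept = 0.05,
                         baseline_slope = 2e-5,
                         baseline_curvature = 0,
                         gain_sd = 0.05,
                         subject_amplitude_jitter_sd = 0.02,
                         noise_sd = 0.003,
                         mucin_bands_enabled = FALSE,
                         mucin_amplitude = 0.06,
                         seed = NULL) {
    if (n_cancer < 1 || n_normal < 1) stop("need at least one subject per class")
    if (replicates < 1) stop("replicates must be >= 1")
    if (gain_sd < 0 || subject_amplitude_jitter_sd < 0 || noise_sd < 0)
        stop("standard deviations must be non-negative")
    .validate_bands(bands)
    if (mucin_bands_enabled) {
        mu <- data.frame(
            band = paste0("mucin", seq_along(.MUCIN_REFS)),
            centre_normal = .MUCIN_REFS, centre_cancer = .MUCIN_REFS,
            fwhm = 12,
            amplitude_normal = mucin_amplitude,
            amplitude_cancer = mucin_amplitude,
            differential = FALSE,
            annotation = "C-O stretch (mucin)", stringsAsFactors = FALSE)
        bands <- rbind(bands, mu)
    }
    structure(list(
        n_cancer = as.integer(n_cancer), n_normal = as.integer(n_normal),
        replicates = as.integer(replicates), bands = bands,
        baseline_intercept = baseline_intercept,
        baseline_slope = baseline_slope,
        baseline_curvature = baseline_curvature,
        gain_sd = gain_sd,
        subject_amplitude_jitter_sd = subject_amplitude_jitter_sd,
        noise_sd = noise_sd,
        mucin_bands_enabled = mucin_bands_enabled,
        mucin_amplitude = mucin_amplitude,
        seed = if (is.null(seed)) NULL else as.integer(seed)),
        class = "CohortConfig")
}

#' Gaussian band profile
#'
#' `amplitude * exp(-4 ln 2 (v - centre)^2 / fwhm^2)` evaluated on a grid;
#' the value at `centre +/- fwhm/2` is half the amplitude.
#'
#' @param centre band centre (1/cm).
#' @param fwhm full width at half maximum (1/cm), must be positive.
#' @param amplitude peak absorbance, non-negative.
#' @param grid wavenumber grid.
#' @return numeric vector of band absorbances on `grid`.
#' @export
bandProfile <- function(centre, fwhm, amplitude, grid) {
    if (fwhm <= 0) stop("fwhm must be positive")
    if (amplitude < 0) stop("amplitude must be non-negative")
    amplitude * exp(-4 * log(2) * (grid - centre)^2 / fwhm^2)
}

.class_cols <- function(bands, class_label) {
    if (class_label == "cancer")
        list(centre = bands$centre_cancer, amp = bands$amplitude_cancer)
    else
        list(centre = bands$centre_normal, amp = bands$amplitude_normal)
}

#' Noise-free class profile
#'
#' The deterministic band sum plus baseline for one class (the spectrum a
#' subject of that class would produce with all noise, gain and jitter
#' terms at zero).
#'
#' @param class_label `"cancer"` or `"normal"`.
#' @param config a [cohortConfig()].
#' @param grid wavenumber grid (default canonical raw grid).
#' @return a raw [Spectrum-class].
#' @export
classProfile <- function(class_label = c("normal", "cancer"),
                         config = cohortConfig(),
                         grid = canonicalRawGrid()) {
    class_label <- match.arg(class_label)
    cc <- .class_cols(config$bands, class_label)
    x <- grid - 900
    y <- config$baseline_intercept + config$baseline_slope * x +
        config$baseline_curvature * x^2
    for (b in seq_len(nrow(config$bands)))
        y <- y + bandProfile(cc$centre[b], config$bands$fwhm[b], cc$amp[b], grid)
    Spectrum(grid, y, kind = "raw")
}

.generate_one <- function(class_label, config, grid, jitter, gain) {
    cc <- .class_cols(config$bands, class_label)
    x <- grid - 900
    y <- config$baseline_intercept + config$baseline_slope * x +
        config$baseline_curvature * x^2
    for (b in seq_len(nrow(config$bands)))
        y <- y + jitter[b] * bandProfile(cc$centre[b], config$bands$fwhm[b],
                                         cc$amp[b], grid)
    y <- gain * y
    if (config$noise_sd > 0)
        y <- y + stats::rnorm(length(grid), 0, config$noise_sd)
    y
}

#' Generate one synthetic spectrum
#'
#' Draws a single measured spectrum for one subject (fresh jitter and gain)
#' from the current RNG state; use [generateCohort()] for full designs.
#'
#' @inheritParams classProfile
#' @return a raw [Spectrum-class] on the canonical raw grid.
#' @export
generateSpectrum <- function(class_label = c("normal", "cancer"),
                             config = cohortConfig()) {
    class_label <- match.arg(class_label)
    grid <- canonicalRawGrid()
    nb <- nrow(config$bands)
    jitter <- exp(stats::rnorm(nb, 0, config$subject_amplitude_jitter_sd))
    gain <- exp(stats::rnorm(1, 0, config$gain_sd))
    Spectrum(grid, .generate_one(class_label, config, grid, jitter, gain),
             kind = "raw")
}

#' Generate a labelled synthetic cohort
#'
#' Produces `(n_cancer + n_normal) * replicates` spectra on the canonical
#' raw grid.  Subject-level band-amplitude jitter is shared across a
#' subject's replicates; replicate gain and additive noise are independent
#' per measured spectrum.  Per-subject metadata (`smoking_status` with
#' class-specific current/ex/never proportions, `prior_cancer`, `cough`)
#' is drawn to mirror a bronchoscopy-recruited cancer arm and a healthy
#' volunteer arm; the metadata does not feed back into the spectra.
#'
#' @param config a [cohortConfig()]; `config$seed`, when non-NULL, makes
#'   the cohort bit-reproducible.
#' @return a raw [FTIRCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(n_cancer = 3, n_normal = 3, seed = 1))
#' @export
generateCohort <- function(config = cohortConfig()) {
    if (!inherits(config, "CohortConfig")) stop("config must be a cohortConfig()")
    if (!is.null(config$seed)) set.seed(config$seed)
    grid <- canonicalRawGrid()
    nb <- nrow(config$bands)
    n <- config$n_cancer + config$n_normal
    cls <- rep(c("cancer", "normal"), c(config$n_cancer, config$n_normal))
    sid <- sprintf("%s%02d", ifelse(cls == "cancer", "C", "N"),
                   c(seq_len(config$n_cancer), seq_len(config$n_normal)))
    smoke_p <- list(cancer = c(current = 0.44, ex = 0.44, never = 0.12),
                    normal = c(current = 0.48, ex = 0.20, never = 0.32))
    prior_p <- c(cancer = 0.16, normal = 0)
    cough_p <- c(cancer = 0.60, normal = 0.24)
    mats <- vector("list", n * config$replicates)
    meta <- data.frame(smoking_status = character(0), prior_cancer = logical(0),
                       cough = logical(0))
    sample_id <- character(0); replicate <- integer(0); class_label <- character(0)
    k <- 0L
    for (i in seq_len(n)) {
        jitter <- exp(stats::rnorm(nb, 0, config$subject_amplitude_jitter_sd))
        smoking <- sample(names(smoke_p[[cls[i]]]), 1, prob = smoke_p[[cls[i]]])
        prior <- stats::runif(1) < prior_p[[cls[i]]]
        cough <- stats::runif(1) < cough_p[[cls[i]]]
        for (r in seq_len(config$replicates)) {
            gain <- exp(stats::rnorm(1, 0, config$gain_sd))
            k <- k + 1L
            mats[[k]] <- .generate_one(cls[i], config, grid, jitter, gain)
            sample_id <- c(sample_id, sid[i])
            replicate <- c(replicate, r)
            class_label <- c(class_label, cls[i])
            meta <- rbind(meta, data.frame(smoking_status = smoking,
                                           prior_cancer = prior, cough = cough))
        }
    }
    FTIRCohort(do.call(cbind, mats), grid, sample_id, replicate, class_label,
               metadata = meta, kind = "raw")
}
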