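#' @include multivariate.R
NULL

.RUN_KEYS <- c("cohort", "cohort_file", "preprocess", "alpha", "tolerance",
               "mucin_refs", "exclusion_window", "panel_size",
               "min_prominence", "distance", "standardize",
               "retention_threshold", "n_clusters", "out_dir", "seed")

#' Validate a pipeline configuration
#'
#' Fills defaults and checks every invariant of a full-pipeline run
#' configuration supplied as a named list or as a YAML file.  Unknown keys
#' are errors, and all violations are collected and reported together.
#'
#' Recognised keys: `cohort` (named list passed to [cohortConfig()]),
#' `cohort_file` (wide CSV read instead of simulating), `preprocess`
#' (named list passed to [preprocessParams()]), `alpha`, `tolerance`,
#' `mucin_refs`, `exclusion_window`, `panel_size`, `min_prominence`,
#' `distance` (`"correlation"` or `"euclidean"`), `standardize`,
#' `retention_threshold`, `n_clusters`, `out_dir`, `seed`.
#'
#' @param config named list of settings, or a path to a YAML file.
#' @return a validated list of class `"RunConfig"`.
#' @examples
#' cfg <- validateConfig(list(alpha = 0.01))
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config) && length(config) == 1)
        config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    if (!is.list(config)) stop("config must be a named list or YAML path")
    errs <- character()
    unknown <- setdiff(names(config), .RUN_KEYS)
    if (length(unknown))
        errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
    defaults <- list(cohort = list(), cohort_file = NULL, preprocess = list(),
                     alpha = 0.05, tolerance = 2 * 850 / 441,
                     mucin_refs = c(1040, 1076, 1120), exclusion_window = 10,
                     panel_size = 6, min_prominence = 1e-5,
                     distance = "correlation", standardize = TRUE,
                     retention_threshold = 0.05, n_clusters = 2,
                     out_dir = NULL, seed = NULL)
    cfg <- utils::modifyList(defaults, config[intersect(names(config), .RUN_KEYS)])
    if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
        errs <- c(errs, "alpha must lie strictly between 0 and 1")
    if (!is.numeric(cfg$tolerance) || cfg$tolerance <= 0)
        errs <- c(errs, "tolerance must be positive")
    if (cfg$exclusion_window < 0)
        errs <- c(errs, "exclusion_window must be non-negative")
    if (cfg$panel_size < 1)
        errs <- c(errs, "panel_size must be >= 1")
    if (!cfg$distance %in% c("correlation", "euclidean"))
        errs <- c(errs, "distance must be 'correlation' or 'euclidean'")
    if (cfg$retention_threshold < 0 || cfg$retention_threshold > 1)
        errs <- c(errs, "retention_threshold must lie in [0, 1]")
    if (cfg$n_clusters < 1)
        errs <- c(errs, "n_clusters must be >= 1")
    pp <- tryCatch(do.call(preprocessParams, cfg$preprocess),
                   error = function(e) {
                       errs <<- c(errs, paste0("preprocess: ", conditionMessage(e)))
                       NULL
                   })
    cc <- NULL
    if (is.null(cfg$cohort_file))
        cc <- tryCatch(do.call(cohortConfig, cfg$cohort),
                       error = function(e) {
                           errs <<- c(errs, paste0("cohort: ", conditionMessage(e)))
                           NULL
                       })
    if (length(errs))
        stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
    cfg$preprocess <- pp
    cfg$cohort <- cc
    class(cfg) <- "RunConfig"
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full discovery pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> screen -> panel ->
#' multivariate analysis.  When no class-differential signal survives the
#' Holm correction the panel and multivariate stages are skipped
#' gracefully and the summary records why.  With `out_dir` set, every
#' intermediate artifact is written (processed matrix, significance and
#' peak tables, panel JSON, Newick tree, cluster assignments, PCA scores /
#' loadings / scree CSVs) together with a JSON run manifest and a plain
#' text summary.
#'
#' @param config a [validateConfig()] result (or a raw list / YAML path,
#'   which is validated first).
#' @return (invisibly) a list with elements `cohort`, `processed`,
#'   `aggregated`, `significance`, `peaks`, `matched`, `panel`,
#'   `panel_matrix`, `tree`, `clusters`, `purity`, `pca`, `summary` and
#'   `manifest`; unreached stages are `NULL`.
#' @export
runPipeline <- function(config = list()) {
    if (!inherits(config, "RunConfig")) config <- validateConfig(config)
    if (!is.null(config$seed)) set.seed(config$seed)
    res <- list()
    summary_lines <- character()
    say <- function(...) summary_lines <<- c(summary_lines, sprintf(...))

    res$cohort <- .stage("cohort", {
        if (!is.null(config$cohort_file))
            readCohortMatrix(config$cohort_file, "wide_csv")
        else generateCohort(config$cohort)
    })
    per_sample <- tapply(classLabels(res$cohort), sampleIds(res$cohort),
                         `[`, 1)
    say("cohort: %d spectra, %d samples (%d cancer / %d normal)",
        ncol(res$cohort), length(per_sample),
        sum(per_sample == "cancer"), sum(per_sample == "normal"))

    res$processed <- .stage("preprocess",
        preprocessCohort(res$cohort, config$preprocess))
    res$aggregated <- .stage("aggregate",
        aggregateReplicates(res$processed, config$preprocess))
    say("preprocess: %d fingerprint wavenumbers, %d aggregated samples",
        nrow(res$aggregated), ncol(res$aggregated))

    res$significance <- .stage("screen",
        screenWavenumbers(res$aggregated, alpha = config$alpha))
    n_sig <- sum(res$significance$reject)
    say("screen: %d of %d wavenumbers significant after Holm (alpha = %g)",
        n_sig, nrow(res$significance), config$alpha)
    sw_frac <- mean(res$significance$shapiro_p < 0.05, na.rm = TRUE)
    say("screen: %.0f%% of wavenumbers non-normal by Shapiro-Wilk screen",
        100 * sw_frac)

    res$peaks <- .stage("peaks",
        detectClassPeaks(res$aggregated, config$min_prominence,
                         config$tolerance))
    say("peaks: %d band centres detected on class median spectra",
        nrow(res$peaks))

    if (n_sig == 0) {
        say("panel: no significant wavenumbers; panel selection and multivariate analysis skipped")
    } else {
        res$matched <- .stage("match",
            matchSignificantToPeaks(res$significance, res$peaks,
                                    config$tolerance))
        panel_or_null <- tryCatch(
            selectMvaPanel(res$matched, config$mucin_refs,
                           config$exclusion_window, config$panel_size),
            error = function(e) {
                say("panel: selection aborted (%s)", conditionMessage(e))
                NULL
            })
        res$panel <- panel_or_null
        if (!is.null(res$panel)) {
            say("panel: %d wavenumbers retained: %s", length(res$panel),
                paste(sprintf("%.0f", res$panel), collapse = ", "))
            res$panel_matrix <- .stage("panel_matrix",
                panelMatrix(res$aggregated, res$panel))
            d <- .stage("distance",
                if (config$distance == "correlation")
                    correlationDistance(res$panel_matrix)
                else stats::dist(res$panel_matrix$features))
            res$tree <- .stage("hca", upgmaTree(d))
            res$clusters <- .stage("cut", cutTree(res$tree, config$n_clusters))
            res$purity <- .stage("purity",
                clusterPurity(res$clusters, res$panel_matrix$class_label))
            say("hca: k = %d clusters; class capture: %s", config$n_clusters,
                paste(sprintf("%s %.1f%%", names(res$purity$capture),
                              res$purity$capture), collapse = ", "))
            res$pca <- .stage("pca",
                pcaPanel(res$panel_matrix, config$standardize,
                         config$retention_threshold))
            say("pca: %d component(s) with >= %.0f%% variance; fractions: %s",
                res$pca$retained, 100 * config$retention_threshold,
                paste(sprintf("%.1f%%", 100 * res$pca$variance_fraction),
                      collapse = ", "))
        }
    }

    res$summary <- summary_lines
    res$manifest <- list(
        package = "sputumFTIR",
        version = as.character(utils::packageVersion("sputumFTIR")),
        seed = config$seed,
        config = .manifest_config(config))
    if (!is.null(config$out_dir)) .write_bundle(res, config)
    invisible(res)
}

.manifest_config <- function(config) {
    cfg <- unclass(config)
    cfg$out_dir <- NULL
    cfg$preprocess <- unclass(cfg$preprocess)
    if (!is.null(cfg$cohort)) {
        cfg$cohort <- unclass(cfg$cohort)
        cfg$cohort$bands <- NULL   # tabulated separately in band_table.csv
    }
    cfg
}

.write_bundle <- function(res, config) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    writeCohortMatrix(res$aggregated, p("processed_matrix.csv"), "wide_csv")
    utils::write.csv(res$significance, p("significance_table.csv"),
                     row.names = FALSE)
    utils::write.csv(res$peaks, p("peak_table.csv"), row.names = FALSE)
    if (!is.null(config$cohort))
        utils::write.csv(config$cohort$bands, p("band_table.csv"),
                         row.names = FALSE)
    if (!is.null(res$panel))
        jsonlite::write_json(res$panel, p("panel.json"), digits = NA)
    if (!is.null(res$tree))
        exportNewick(res$tree, p("dendrogram.nwk"))
    if (!is.null(res$clusters))
        utils::write.csv(data.frame(sample_id = names(res$clusters),
                                    cluster = unname(res$clusters),
                                    class = res$panel_matrix$class_label),
                         p("clusters.csv"), row.names = FALSE)
    if (!is.null(res$pca)) {
        utils::write.csv(res$pca$scores, p("pca_scores.csv"))
        utils::write.csv(res$pca$loadings, p("pca_loadings.csv"))
        utils::write.csv(data.frame(
            component = seq_along(res$pca$variance_fraction),
            variance_fraction = res$pca$variance_fraction),
            p("pca_scree.csv"), row.names = FALSE)
    }
    jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    writeLines(res$summary, p("summary.txt"))
    invisible(config$out_dir)
}
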