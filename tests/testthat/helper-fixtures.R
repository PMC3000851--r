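# Shared fixtures, built in code.

suppressMessages(library(SummarizedExperiment))

# Small planted cohort config (fast; same band structure as the default).
small_config <- function(seed = 1, ...) {
    cohortConfig(n_cancer = 12, n_normal = 12, replicates = 2, seed = seed, ...)
}

# Band table with every class effect removed (global null).
null_bands <- function() {
    b <- defaultBandTable()
    b$amplitude_cancer <- b$amplitude_normal
    b$centre_cancer <- b$centre_normal
    b
}

null_config <- function(seed = 1, n = 10, ...) {
    cohortConfig(n_cancer = n, n_normal = n, replicates = 2,
                 bands = null_bands(), seed = seed, ...)
}

# Preprocess + aggregate in one call.
processed_samples <- function(cohort, params = preprocessParams()) {
    aggregateReplicates(preprocessCohort(cohort, params), params)
}

# Independent step-down Holm oracle (direct transcription of the rule).
holm_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    run <- 0
    for (i in seq_len(m)) {
        run <- max(run, min(1, (m - i + 1) * p[ord[i]]))
        adj[ord[i]] <- run
    }
    adj
}

# Brute-force average cross-cluster distance from the original matrix.
avg_link_oracle <- function(D, a, b) mean(D[a, b])
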