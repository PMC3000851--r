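#' @include wavenumber-stats.R
NULL

#' Per-sample panel feature matrix
#'
#' Extracts, for every sample, the second-derivative absorbance values at
#' the panel wavenumbers (nearest grid point to each requested centre).
#'
#' @param cohort a replicate-aggregated second-derivative
#'   [FTIRCohort-class].
#' @param panel numeric panel wavenumbers (1/cm), e.g. from
#'   [selectMvaPanel()].
#' @return a list of class `"PanelMatrix"` with elements `features`
#'   (samples x panel matrix, rownames = sample ids, colnames = grid
#'   wavenumbers used), `class_label`, `sample_id` and `metadata`.
#' @export
panelMatrix <- function(cohort, panel) {
    if (!length(panel)) stop("panel must contain at least one wavenumber")
    w <- wavenumbers(cohort)
    idx <- vapply(panel, function(p) which.min(abs(w - p)), integer(1))
    feats <- t(absorbance(cohort)[idx, , drop = FALSE])
    colnames(feats) <- sprintf("%.2f", w[idx])
    rownames(feats) <- sampleIds(cohort)
    cd <- colData(cohort)
    meta_col <- setdiff(names(cd), c("sample_id", "replicate", "class"))
    structure(list(features = feats,
                   sample_id = sampleIds(cohort),
                   class_label = classLabels(cohort),
                   metadata = as.data.frame(cd[, meta_col, drop = FALSE])),
              class = "PanelMatrix")
}

.panel_features <- function(x) {
    if (inherits(x, "PanelMatrix")) x$features else as.matrix(x)
}

#' Correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation between the
#' two samples' panel feature vectors; values lie in `[0, 2]`.
#'
#' @param x a [panelMatrix()] result or a samples-by-features matrix.
#' @return a `dist` object.
#' @export
correlationDistance <- function(x) {
    feats <- .panel_features(x)
    if (ncol(feats) < 2)
        stop("correlation distance needs >= 2 features per sample")
    sds <- apply(feats, 1, stats::sd)
    if (any(sds == 0))
        stop("zero feature variance for sample(s): ",
             paste(rownames(feats)[sds == 0], collapse = ", "))
    stats::as.dist(1 - stats::cor(t(feats)))
}

.min_leaf_label <- function(members, labels) min(labels[members])

#' UPGMA (average linkage) hierarchical clustering
#'
#' Agglomerative clustering by the unweighted pair-group method with
#' arithmetic mean: at each step the two clusters with the smallest
#' average cross-pair leaf distance are merged at a height equal to that
#' average.  Ties are broken deterministically in favour of the pair whose
#' (label-sorted) smallest leaf labels come first, so the tree is
#' invariant to the input order of the leaves.
#'
#' @param distances a `dist` object or symmetric non-negative matrix.
#' @param labels optional leaf labels (default taken from `distances`).
#' @return an object of class `hclust` (usable with [stats::cutree()],
#'   `plot()`, and [exportNewick()]).
#' @export
upgmaTree <- function(distances, labels = NULL) {
    D <- as.matrix(distances)
    n <- nrow(D)
    if (n < 2) stop("need at least two leaves")
    if (!isSymmetric(unname(D), tol = 1e-12))
        stop("distance matrix must be symmetric")
    if (any(D < 0)) stop("distances must be non-negative")
    if (is.null(labels)) labels <- rownames(D)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    members <- as.list(seq_len(n))        # leaf sets per active cluster
    ids <- -seq_len(n)                    # hclust merge coding
    sizes <- rep(1L, n)
    active <- seq_len(n)
    merge <- matrix(0L, n - 1, 2)
    height <- numeric(n - 1)
    W <- D
    diag(W) <- Inf
    for (s in seq_len(n - 1)) {
        sub <- W[active, active, drop = FALSE]
        m <- min(sub)
        cand <- which(sub == m, arr.ind = TRUE)
        cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
        key <- apply(cand, 1, function(rc) {
            a <- .min_leaf_label(members[[active[rc[1]]]], labels)
            b <- .min_leaf_label(members[[active[rc[2]]]], labels)
            paste(sort(c(a, b)), collapse = "\r")
        })
        pick <- cand[order(key)[1], ]
        i <- active[pick[1]]; j <- active[pick[2]]
        pr <- sort(c(ids[i], ids[j]))
        merge[s, ] <- pr
        height[s] <- m
        # Lance-Williams update for average linkage
        ni <- sizes[i]; nj <- sizes[j]
        newd <- (ni * W[i, ] + nj * W[j, ]) / (ni + nj)
        W[i, ] <- newd; W[, i] <- newd; W[i, i] <- Inf
        members[[i]] <- c(members[[i]], members[[j]])
        sizes[i] <- ni + nj
        ids[i] <- s
        active <- setdiff(active, j)
    }
    tr <- list(merge = merge, height = height,
               order = .hclust_order(merge), labels = labels,
               method = "average", call = match.call(),
               dist.method = "correlation")
    class(tr) <- "hclust"
    tr
}

.hclust_order <- function(merge) {
    walk <- function(node) {
        if (node < 0) return(-node)
        c(walk(merge[node, 1]), walk(merge[node, 2]))
    }
    walk(nrow(merge))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges and labels the resulting clusters
#' 1..k by order of their first leaf (leaf input order), so the labelling
#' is deterministic.
#'
#' @param tree an `hclust` tree, e.g. from [upgmaTree()].
#' @param k number of clusters, `1 <= k <=` leaf count.
#' @return integer cluster assignment named by leaf label.
#' @export
cutTree <- function(tree, k) {
    n <- length(tree$order)
    if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
    raw <- stats::cutree(tree, k = k)
    first <- unique(raw)
    out <- match(raw, first)
    names(out) <- names(raw)
    out
}

#' Cluster composition and class capture
#'
#' Cross-tabulates a cluster assignment against class labels and reports,
#' for each class, the percentage of that class's samples captured by the
#' cluster in which the class is the majority (its modal cluster).  With
#' `k = 2` this is the usual "X% of cancers in the cancer cluster /
#' Y% of normals in the normal cluster" summary.
#'
#' @param assignment integer/factor cluster ids per sample.
#' @param class_labels class label per sample, same length.
#' @return list with `contingency` (clusters x classes table) and
#'   `capture` (named percentages per class).
#' @export
clusterPurity <- function(assignment, class_labels) {
    if (length(assignment) != length(class_labels))
        stop("assignment and class labels must have equal length")
    tab <- table(cluster = assignment, class = class_labels)
    capture <- vapply(colnames(tab), function(cl) {
        100 * max(tab[, cl]) / sum(tab[, cl])
    }, numeric(1))
    list(contingency = tab, capture = capture)
}

#' PCA of the panel features
#'
#' Centres (and by default scales to unit variance) the panel features,
#' then eigendecomposes their covariance via [stats::prcomp()].  The
#' number of retained components is the count of components whose
#' variance fraction is at least `retention_threshold` (default 5%).
#' Loading signs are fixed so that each column's largest-magnitude entry
#' is positive, making score plots reproducible across platforms.
#'
#' @param x a [panelMatrix()] result or samples-by-features matrix.
#' @param standardize scale features to unit variance (default `TRUE`).
#' @param retention_threshold variance-fraction cutoff for retention.
#' @return list of class `"PCAResult"` with `scores` (samples x
#'   components), `loadings` (features x components, orthonormal columns),
#'   `variance_fraction` (non-increasing, sums to 1) and `retained`.
#' @export
pcaPanel <- function(x, standardize = TRUE, retention_threshold = 0.05) {
    feats <- .panel_features(x)
    sds <- apply(feats, 2, stats::sd)
    if (standardize && any(sds == 0))
        stop("zero-variance feature(s) cannot be standardized: ",
             paste(colnames(feats)[sds == 0], collapse = ", "))
    pc <- stats::prcomp(feats, center = TRUE, scale. = standardize)
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    flip <- apply(pc$rotation, 2, function(v) v[which.max(abs(v))] < 0)
    pc$rotation[, flip] <- -pc$rotation[, flip, drop = FALSE]
    pc$x[, flip] <- -pc$x[, flip, drop = FALSE]
    structure(list(scores = pc$x, loadings = pc$rotation,
                   variance_fraction = vf,
                   retained = sum(vf >= retention_threshold),
                   standardized = standardize,
                   class_label = if (inherits(x, "PanelMatrix")) x$class_label
                                 else NULL),
              class = "PCAResult")
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are derived from the merge heights: a child's branch is
#' its parent's merge height minus its own (leaves sit at height 0).
#'
#' @param tree an `hclust` tree.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to `file`).
#' @export
exportNewick <- function(tree, file = NULL) {
    build <- function(node) {
        if (node < 0)
            list(txt = tree$labels[-node], h = 0)
        else {
            l <- build(tree$merge[node, 1])
            r <- build(tree$merge[node, 2])
            h <- tree$height[node]
            list(txt = sprintf("(%s:%.10g,%s:%.10g)",
                               l$txt, h - l$h, r$txt, h - r$h),
                 h = h)
        }
    }
    nwk <- paste0(build(nrow(tree$merge))$txt, ";")
    if (is.null(file)) return(nwk)
    writeLines(nwk, file)
    invisible(nwk)
}
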