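#' @include classes-dataset.R preprocess.R dataset-ops.R
NULL

corrSpectrumFromPaired <- function(paired) {
    n <- nSamples(paired)
    if (n < 3L)
        stop("need at least 3 paired samples for a correlation spectrum")
    lod <- lodValues(paired)
    if (stats::sd(lod) < 1e-24)
        stop("reference moisture values have zero variance")
    X <- intensities(paired)
    sds <- apply(X, 2L, stats::sd)
    r <- rep(NA_real_, ncol(X))
    ok <- sds > 1e-24
    if (any(ok))
        r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], lod))
    data.frame(wavelength = wavelengths(paired), r = r, n = n)
}

#' @describeIn correlationSpectrum Pearson correlation between the LOD
#'   values and the intensity at each wavelength of already-paired data.
#'   Zero-variance columns yield `NA`, not 0.
#' @return a data.frame with columns `wavelength`, `r` and `n`.
#' @export
setMethod("correlationSpectrum", "PairedData", function(object, ...) {
    corrSpectrumFromPaired(object)
})

#' @describeIn correlationSpectrum correlation spectrum for one batch;
#'   optional time smoothing (`k` points) is applied to the full spectra
#'   stream before the pairing values are extracted.
#' @param refs a [ReferenceSet-class] (SpectraBatch method).
#' @param k odd smoothing window width; 1 = raw data.
#' @param maxGap see [matchReferences()].
#' @export
setMethod("correlationSpectrum", "SpectraBatch",
          function(object, refs, k = 1L, maxGap = 60, ...) {
    if (k > 1L)
        object@intensities <- timeSmooth(object@intensities, k)
    corrSpectrumFromPaired(matchReferences(object, refs, maxGap = maxGap))
})

#' @describeIn correlationSpectrum correlation spectrum pooled over all
#'   batches of a campaign (smoothing applied per batch).
#' @export
setMethod("correlationSpectrum", "ProcessDataset",
          function(object, k = 1L, maxGap = 60, ...) {
    corrSpectrumFromPaired(pairCampaign(object, k = k, maxGap = maxGap))
})

## ---------------------------------------------------------------------------
## PCA
## ---------------------------------------------------------------------------

#' Principal component model of a spectral matrix
#'
#' @slot center mean spectrum used for centering.
#' @slot loadings p x A matrix of orthonormal loading vectors.
#' @slot scores n x A matrix of scores (centered data projected on the
#'   loadings).
#' @slot explainedVar percentage of total (centered) variance per PC,
#'   non-increasing.
#'
#' @seealso [fitPCA()]
#' @export
setClass("PCAModel",
         representation(center = "numeric",
                        loadings = "matrix",
                        scores = "matrix",
                        explainedVar = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- character()
    A <- ncol(object@loadings)
    G <- crossprod(object@loadings)
    if (max(abs(G - diag(A))) > 1e-8)
        msg <- c(msg, "loadings are not orthonormal")
    if (A > 1L && any(diff(object@explainedVar) > 1e-8))
        msg <- c(msg, "explained variances must be non-increasing")
    if (sum(object@explainedVar) > 100 + 1e-6)
        msg <- c(msg, "explained variances exceed 100%")
    if (length(msg)) msg else TRUE
})

#' Fit a centered principal component model
#'
#' Column-mean-centered PCA computed by singular value decomposition
#' (via [stats::prcomp()]). The sign of each component is fixed so that the
#' loading element of largest magnitude is positive, making results
#' reproducible. Explained variance is reported relative to the total
#' centered variance.
#'
#' @param X numeric matrix (rows = spectra).
#' @param nComponents number of components, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return a [PCAModel-class].
#' @examples
#' X <- outer(1:5, c(1, 2, 3))        # rank-1
#' fitPCA(X, 1)@explainedVar          # 100
#' @export
fitPCA <- function(X, nComponents) {
    X <- as.matrix(X)
    if (nComponents < 1L || nComponents > min(nrow(X) - 1L, ncol(X)))
        stop("nComponents must be between 1 and min(n - 1, p)")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                        rank. = nComponents)
    load <- pc$rotation
    scores <- pc$x
    for (a in seq_len(ncol(load))) {
        j <- which.max(abs(load[, a]))
        if (load[j, a] < 0) {
            load[, a] <- -load[, a]
            scores[, a] <- -scores[, a]
        }
    }
    dimnames(load) <- NULL
    dimnames(scores) <- NULL
    ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    new("PCAModel", center = as.numeric(pc$center), loadings = load,
        scores = scores, explainedVar = ev[seq_len(nComponents)])
}

setMethod("show", "PCAModel", function(object) {
    cat(sprintf("PCAModel: %d components over %d channels\n",
                ncol(object@loadings), nrow(object@loadings)))
    cat("  explained variance (%):",
        paste(sprintf("%.2f", object@explainedVar), collapse = ", "), "\n")
})

#' Per-batch PCA score trajectories
#'
#' Combines the scores of a fitted [PCAModel-class] with the (batch, time)
#' row labels of the augmented matrix it was fitted on, producing a tidy
#' table of process trajectories suitable for plotting scores versus
#' process time.
#'
#' @param model a [PCAModel-class].
#' @param labels data.frame with columns `batch` and `time`, one row per
#'   score row (as returned by [augmentBatches()]).
#' @return data.frame with columns `batch`, `time`, `t1`, ..., `tA`;
#'   batch order and within-batch time order are preserved.
#' @export
scoresVsTime <- function(model, labels) {
    stopifnot(is(model, "PCAModel"))
    if (!all(c("batch", "time") %in% names(labels)))
        stop("labels must have columns 'batch' and 'time'")
    if (nrow(labels) != nrow(model@scores))
        stop("label rows (", nrow(labels), ") do not match score rows (",
             nrow(model@scores), ")")
    sc <- as.data.frame(model@scores)
    names(sc) <- paste0("t", seq_len(ncol(sc)))
    cbind(labels[, c("batch", "time")], sc)
}

#' Similarity of two loading (or weight) vectors
#'
#' Pearson correlation between two loading vectors; with
#' `absolute = TRUE` the sign-invariant |r| is reported, useful when
#' comparing components whose sign convention differs.
#'
#' @param a,b numeric vectors of equal length.
#' @param absolute report |r| instead of r.
#' @return a single correlation value.
#' @export
loadingSimilarity <- function(a, b, absolute = FALSE) {
    if (length(a) != length(b))
        stop("loading vectors differ in length")
    if (stats::sd(a) < 1e-24 || stats::sd(b) < 1e-24)
        stop("correlation undefined for a constant vector")
    r <- stats::cor(a, b)
    if (absolute) abs(r) else r
}
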