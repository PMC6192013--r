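#' @include classes-dataset.R
NULL

#' Pair reference samples with their nearest-in-time spectra
#'
#' Each non-excluded reference sample is paired with the spectrum whose
#' acquisition time is closest to the sampling time; ties are broken toward
#' the earlier spectrum (the datum already observed). The pairing distance
#' is recorded and a warning is raised when it exceeds `maxGap`.
#'
#' @param batch a [SpectraBatch-class].
#' @param refs a [ReferenceSet-class] with the same batch id.
#' @param maxGap pairing distance (s) above which a warning is raised; the
#'   row is kept. Default 60 s (about 12 acquisition steps at 5 s).
#' @return a [PairedData-class] with one row per non-excluded reference.
#' @examples
#' sb <- SpectraBatch("B", c(0, 5, 10), c(1100, 1900),
#'                    matrix(1:6, 3, 2))
#' rs <- ReferenceSet("B", sampleTimes = 6, lodValues = 12)
#' matchReferences(sb, rs)  # pairs with the t = 5 spectrum
#' @export
matchReferences <- function(batch, refs, maxGap = 60) {
    stopifnot(is(batch, "SpectraBatch"), is(refs, "ReferenceSet"))
    if (batchId(batch) != batchId(refs))
        stop("batch ids differ: '", batchId(batch), "' vs '",
             batchId(refs), "'")
    keep <- !refs@excluded
    if (nSpectra(batch) == 0L)
        stop("batch '", batchId(batch), "' has no spectra")
    if (!any(keep))
        stop("no non-excluded reference samples in batch '",
             batchId(refs), "'")
    st <- refs@sampleTimes[keep]
    lod <- refs@lodValues[keep]
    span <- range(batch@times)
    if (any(st < span[1] | st > span[2]))
        warning("reference sample time outside batch '", batchId(batch),
                "' time span")
    idx <- vapply(st, function(t) {
        d <- abs(batch@times - t)
        # which.min returns the first minimum = earlier spectrum on ties
        which.min(d)
    }, integer(1))
    gap <- abs(batch@times[idx] - st)
    if (any(gap > maxGap))
        warning(sum(gap > maxGap), " pairing(s) in batch '", batchId(batch),
                "' exceed maxGap = ", maxGap, " s")
    PairedData(batchIds = rep(batchId(batch), length(st)),
               sampleTimes = st, lod = lod,
               spectra = batch@intensities[idx, , drop = FALSE],
               wavelengths = batch@wavelengths, pairingGap = gap)
}

#' Pair all batches of a campaign, optionally time-smoothing first
#'
#' Convenience driver: for each selected batch the spectra stream is
#' smoothed along the time axis with a `k`-point window (see
#' [timeSmooth()]; `k = 1` leaves the data untouched), then paired with its
#' references. Smoothing is always applied per batch — never across batch
#' boundaries — and uses no reference values, so it cannot leak information
#' across validation folds.
#'
#' @param dataset a [ProcessDataset-class].
#' @param k odd smoothing window width in points (default 1, no smoothing).
#' @param ids batches to use; defaults to all batches with references.
#' @param maxGap see [matchReferences()].
#' @return a multi-batch [PairedData-class].
#' @export
pairCampaign <- function(dataset, k = 1L, ids = names(dataset@references),
                         maxGap = 60) {
    stopifnot(is(dataset, "ProcessDataset"), length(ids) > 0L)
    parts <- lapply(ids, function(id) {
        b <- getBatch(dataset, id)
        if (k > 1L)
            b@intensities <- timeSmooth(b@intensities, k)
        matchReferences(b, getReferences(dataset, id), maxGap = maxGap)
    })
    do.call(rbindPaired, parts)
}

#' Row-wise concatenation of batches for augmented-data PCA
#'
#' Stacks the intensity matrices of the selected batches into one matrix,
#' preserving within-batch time order and the stated batch order, with
#' (batch, time) row labels. All batches must share the wavelength grid.
#'
#' @param dataset a [ProcessDataset-class].
#' @param ids batch ids to stack, in order; defaults to all.
#' @return a list with elements `matrix` (n x p), `labels` (data.frame with
#'   columns `batch`, `time`) and `wavelengths`.
#' @export
augmentBatches <- function(dataset, ids = batchIds(dataset)) {
    stopifnot(is(dataset, "ProcessDataset"), length(ids) > 0L)
    wl <- wavelengths(getBatch(dataset, ids[1]))
    mats <- vector("list", length(ids))
    labs <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        b <- getBatch(dataset, ids[i])
        if (!isTRUE(all.equal(wavelengths(b), wl)))
            stop("batch '", ids[i], "' is on a different wavelength grid")
        mats[[i]] <- intensities(b)
        labs[[i]] <- data.frame(batch = rep(batchId(b), nSpectra(b)),
                                time = acqTimes(b))
    }
    list(matrix = do.call(rbind, mats),
         labels = do.call(rbind, labs),
         wavelengths = wl)
}

#' Restrict paired data to a moisture range
#'
#' Keeps rows with `lod < maxLod` (strict inequality, matching the
#' "< 20 %" style range definitions); `maxLod = NULL` returns the input
#' unchanged (the full dataset). The operation is idempotent and monotone
#' in `maxLod`.
#'
#' @param paired a [PairedData-class].
#' @param maxLod upper moisture bound (%) or `NULL` for no restriction.
#' @return a [PairedData-class] with the retained rows.
#' @export
restrictRange <- function(paired, maxLod = NULL) {
    stopifnot(is(paired, "PairedData"))
    if (is.null(maxLod))
        return(paired)
    if (!is.numeric(maxLod) || length(maxLod) != 1L || maxLod <= 0)
        stop("maxLod must be a single positive number or NULL")
    paired[paired@lod < maxLod]
}
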