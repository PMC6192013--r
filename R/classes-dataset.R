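#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## SpectraBatch
## ---------------------------------------------------------------------------

#' One batch of time-ordered in-line NIR spectra
#'
#' A `SpectraBatch` holds the diffuse-reflectance spectra of one drying batch
#' as an `n_times x n_wavelengths` matrix in lg(1/R) units, together with the
#' acquisition times (seconds from batch start) and the shared wavelength
#' grid (nm). Both axes are strictly increasing.
#'
#' @slot batchId single character label.
#' @slot times numeric, acquisition times in seconds, strictly increasing.
#' @slot wavelengths numeric, wavelength grid in nm, strictly increasing.
#' @slot intensities numeric matrix, `length(times)` rows and
#'   `length(wavelengths)` columns, lg(1/R) units, no missing values.
#'
#' @seealso [readSpectra()], [matchReferences()], [timeSmooth()]
#' @export
setClass("SpectraBatch",
         representation(batchId = "character",
                        times = "numeric",
                        wavelengths = "numeric",
                        intensities = "matrix"))

setValidity("SpectraBatch", function(object) {
    msg <- character()
    if (length(object@batchId) != 1L || is.na(object@batchId))
        msg <- c(msg, "batchId must be a single non-NA string")
    n <- length(object@times)
    p <- length(object@wavelengths)
    if (n > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (p > 1L && any(diff(object@wavelengths) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    if (!identical(dim(object@intensities), c(n, p)))
        msg <- c(msg, sprintf("intensity matrix is %d x %d, expected %d x %d",
                              nrow(object@intensities),
                              ncol(object@intensities), n, p))
    if (anyNA(object@intensities) || anyNA(object@times) ||
        anyNA(object@wavelengths))
        msg <- c(msg, "missing values are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct a SpectraBatch
#'
#' @param batchId single character label.
#' @param times numeric vector of acquisition times (s). Rows of
#'   `intensities` are re-sorted if `times` is not increasing.
#' @param wavelengths numeric vector of wavelengths (nm), strictly
#'   increasing.
#' @param intensities numeric matrix, `length(times)` x
#'   `length(wavelengths)`, lg(1/R).
#' @return a validated [SpectraBatch-class] object.
#' @examples
#' sb <- SpectraBatch("B01", times = c(0, 5, 10),
#'                    wavelengths = c(1100, 1400, 1700, 1900),
#'                    intensities = matrix(rnorm(12), 3, 4))
#' nSpectra(sb)
#' @export
SpectraBatch <- function(batchId, times, wavelengths, intensities) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    times <- as.numeric(times)
    ord <- order(times)
    if (is.unsorted(times))
        intensities <- intensities[ord, , drop = FALSE]
    dimnames(intensities) <- NULL
    new("SpectraBatch", batchId = as.character(batchId),
        times = times[ord], wavelengths = as.numeric(wavelengths),
        intensities = intensities)
}

#' @rdname procspec-generics
#' @export
setMethod("batchId", "SpectraBatch", function(object) object@batchId)

#' @rdname procspec-generics
#' @export
setMethod("acqTimes", "SpectraBatch", function(object) object@times)

#' @rdname procspec-generics
#' @export
setMethod("wavelengths", "SpectraBatch", function(object) object@wavelengths)

#' @rdname procspec-generics
#' @export
setMethod("intensities", "SpectraBatch", function(object) object@intensities)

#' @rdname procspec-generics
#' @export
setMethod("nSpectra", "SpectraBatch", function(object) length(object@times))

#' @rdname procspec-generics
#' @export
setMethod("nChannels", "SpectraBatch",
          function(object) length(object@wavelengths))

setMethod("show", "SpectraBatch", function(object) {
    cat(sprintf("SpectraBatch '%s': %d spectra x %d channels\n",
                object@batchId, nSpectra(object), nChannels(object)))
    if (nSpectra(object))
        cat(sprintf("  time %.0f..%.0f s, wavelengths %.1f..%.1f nm\n",
                    min(object@times), max(object@times),
                    min(object@wavelengths), max(object@wavelengths)))
})

## ---------------------------------------------------------------------------
## ReferenceSet
## ---------------------------------------------------------------------------

#' Reference moisture measurements for one batch
#'
#' Time-stamped loss-on-drying (LOD, % w/w) reference values with an optional
#' per-sample exclusion flag for manually rejected outliers.
#'
#' @slot batchId single character label.
#' @slot sampleTimes numeric, sampling times in seconds.
#' @slot lodValues numeric, moisture content, % w/w, non-negative.
#' @slot excluded logical, `TRUE` marks a sample to skip in all analyses.
#'
#' @export
setClass("ReferenceSet",
         representation(batchId = "character",
                        sampleTimes = "numeric",
                        lodValues = "numeric",
                        excluded = "logical"))

setValidity("ReferenceSet", function(object) {
    msg <- character()
    n <- length(object@sampleTimes)
    if (length(object@batchId) != 1L)
        msg <- c(msg, "batchId must be a single string")
    if (length(object@lodValues) != n || length(object@excluded) != n)
        msg <- c(msg, "sampleTimes, lodValues and excluded lengths differ")
    if (any(object@lodValues < 0))
        msg <- c(msg, "lodValues must be non-negative")
    if (anyNA(object@sampleTimes) || anyNA(object@lodValues) ||
        anyNA(object@excluded))
        msg <- c(msg, "missing values are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param batchId single character label.
#' @param sampleTimes numeric sampling times (s).
#' @param lodValues numeric LOD moisture values (%), non-negative.
#' @param excluded logical exclusion flags; defaults to all `FALSE`.
#' @return a validated [ReferenceSet-class] object.
#' @export
ReferenceSet <- function(batchId, sampleTimes, lodValues,
                         excluded = rep(FALSE, length(sampleTimes))) {
    new("ReferenceSet", batchId = as.character(batchId),
        sampleTimes = as.numeric(sampleTimes),
        lodValues = as.numeric(lodValues),
        excluded = as.logical(excluded))
}

#' @rdname procspec-generics
#' @export
setMethod("batchId", "ReferenceSet", function(object) object@batchId)

#' @rdname procspec-generics
#' @export
setMethod("sampleTimes", "ReferenceSet", function(object) object@sampleTimes)

#' @rdname procspec-generics
#' @export
setMethod("lodValues", "ReferenceSet", function(object) object@lodValues)

#' @rdname procspec-generics
#' @export
setMethod("excluded", "ReferenceSet", function(object) object@excluded)

#' @rdname procspec-generics
#' @export
setMethod("nSamples", "ReferenceSet",
          function(object) length(object@sampleTimes))

setMethod("show", "ReferenceSet", function(object) {
    cat(sprintf("ReferenceSet '%s': %d samples (%d excluded)\n",
                object@batchId, nSamples(object), sum(object@excluded)))
    if (nSamples(object))
        cat(sprintf("  LOD %.2f..%.2f %%\n",
                    min(object@lodValues), max(object@lodValues)))
})

## ---------------------------------------------------------------------------
## PairedData
## ---------------------------------------------------------------------------

#' Reference samples paired with their nearest-in-time spectra
#'
#' Rows of (batch, sampling time, spectrum, LOD) produced by
#' [matchReferences()], possibly concatenated over several batches. The
#' spectra share one wavelength grid; `pairingGap` records the absolute time
#' distance between the reference sample and its matched spectrum.
#'
#' @slot batchIds character, one per row (needed by leave-a-batch-out CV).
#' @slot sampleTimes numeric, seconds.
#' @slot lod numeric, moisture %, one per row.
#' @slot spectra numeric matrix, one spectrum per row.
#' @slot wavelengths numeric, shared wavelength axis (nm).
#' @slot pairingGap numeric, |t_spectrum - t_sample| per row (s).
#'
#' @export
setClass("PairedData",
         representation(batchIds = "character",
                        sampleTimes = "numeric",
                        lod = "numeric",
                        spectra = "matrix",
                        wavelengths = "numeric",
                        pairingGap = "numeric"))

setValidity("PairedData", function(object) {
    msg <- character()
    n <- length(object@lod)
    if (length(object@batchIds) != n || length(object@sampleTimes) != n ||
        nrow(object@spectra) != n || length(object@pairingGap) != n)
        msg <- c(msg, "row components have differing lengths")
    if (ncol(object@spectra) != length(object@wavelengths))
        msg <- c(msg, "spectrum length differs from wavelength axis")
    if (anyNA(object@batchIds))
        msg <- c(msg, "every row needs a batch id")
    if (length(msg)) msg else TRUE
})

#' Construct a PairedData object
#'
#' Usually produced by [matchReferences()] / [pairCampaign()] rather than
#' called directly.
#'
#' @param batchIds character vector, one per row.
#' @param sampleTimes numeric, seconds.
#' @param lod numeric moisture values (%).
#' @param spectra numeric matrix, one row per sample.
#' @param wavelengths shared wavelength axis (nm).
#' @param pairingGap numeric pairing distances (s); defaults to 0.
#' @return a [PairedData-class] object.
#' @export
PairedData <- function(batchIds, sampleTimes, lod, spectra, wavelengths,
                       pairingGap = rep(0, length(lod))) {
    spectra <- as.matrix(spectra)
    dimnames(spectra) <- NULL
    new("PairedData", batchIds = as.character(batchIds),
        sampleTimes = as.numeric(sampleTimes), lod = as.numeric(lod),
        spectra = spectra, wavelengths = as.numeric(wavelengths),
        pairingGap = as.numeric(pairingGap))
}

#' @rdname procspec-generics
#' @export
setMethod("batchIds", "PairedData", function(object) object@batchIds)

#' @rdname procspec-generics
#' @export
setMethod("sampleTimes", "PairedData", function(object) object@sampleTimes)

#' @rdname procspec-generics
#' @export
setMethod("lodValues", "PairedData", function(object) object@lod)

#' @rdname procspec-generics
#' @export
setMethod("wavelengths", "PairedData", function(object) object@wavelengths)

#' @rdname procspec-generics
#' @export
setMethod("intensities", "PairedData", function(object) object@spectra)

#' @rdname procspec-generics
#' @export
setMethod("nSamples", "PairedData", function(object) length(object@lod))

setMethod("show", "PairedData", function(object) {
    cat(sprintf("PairedData: %d samples from %d batch(es), %d channels\n",
                nSamples(object), length(unique(object@batchIds)),
                length(object@wavelengths)))
    if (nSamples(object))
        cat(sprintf("  LOD %.2f..%.2f %%, max pairing gap %.1f s\n",
                    min(object@lod), max(object@lod),
                    max(object@pairingGap)))
})

#' Subset rows of a PairedData object
#'
#' @param x a [PairedData-class] object.
#' @param i integer or logical row index.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "PairedData", function(x, i, j, ..., drop = FALSE) {
    PairedData(x@batchIds[i], x@sampleTimes[i], x@lod[i],
               x@spectra[i, , drop = FALSE], x@wavelengths,
               x@pairingGap[i])
})

#' Concatenate PairedData objects row-wise
#'
#' @param x a [PairedData-class] object.
#' @param ... further [PairedData-class] objects on the same wavelength grid.
#' @return a combined [PairedData-class] object.
#' @export
rbindPaired <- function(x, ...) {
    more <- list(...)
    for (y in more) {
        if (!isTRUE(all.equal(x@wavelengths, y@wavelengths)))
            stop("cannot combine PairedData on different wavelength grids")
        x <- PairedData(c(x@batchIds, y@batchIds),
                        c(x@sampleTimes, y@sampleTimes),
                        c(x@lod, y@lod),
                        rbind(x@spectra, y@spectra),
                        x@wavelengths,
                        c(x@pairingGap, y@pairingGap))
    }
    x
}

## ---------------------------------------------------------------------------
## ProcessDataset
## ---------------------------------------------------------------------------

#' A drying campaign: batches, references and roles
#'
#' Container for a multi-batch campaign: one [SpectraBatch-class] and one
#' [ReferenceSet-class] per batch, plus an optional calibration/validation
#' role per batch.
#'
#' @slot batches list of [SpectraBatch-class], unique batch ids.
#' @slot references list of [ReferenceSet-class], ids matching `batches`.
#' @slot roles named character, `"calibration"` or `"validation"` per batch.
#'
#' @export
setClass("ProcessDataset",
         representation(batches = "list",
                        references = "list",
                        roles = "character"))

setValidity("ProcessDataset", function(object) {
    msg <- character()
    ids <- vapply(object@batches, batchId, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "batch ids must be unique")
    rids <- vapply(object@references, batchId, character(1))
    if (!all(rids %in% ids))
        msg <- c(msg, "every ReferenceSet needs a matching SpectraBatch")
    if (length(object@roles) &&
        !all(object@roles %in% c("calibration", "validation")))
        msg <- c(msg, "roles must be 'calibration' or 'validation'")
    if (length(msg)) msg else TRUE
})

#' Construct a ProcessDataset
#'
#' @param batches list of [SpectraBatch-class] objects with unique ids.
#' @param references list of [ReferenceSet-class] objects whose ids match
#'   `batches`.
#' @param roles optional named character vector
#'   (`"calibration"`/`"validation"`), names being batch ids.
#' @return a validated [ProcessDataset-class].
#' @export
ProcessDataset <- function(batches, references, roles = character()) {
    ids <- vapply(batches, batchId, character(1))
    names(batches) <- ids
    names(references) <- vapply(references, batchId, character(1))
    references <- references[intersect(ids, names(references))]
    new("ProcessDataset", batches = batches, references = references,
        roles = roles)
}

#' @rdname procspec-generics
#' @export
setMethod("batchIds", "ProcessDataset",
          function(object)
              unname(vapply(object@batches, batchId, character(1))))

#' Extract one batch or its references from a campaign
#'
#' @param dataset a [ProcessDataset-class].
#' @param id batch id.
#' @return `getBatch()` a [SpectraBatch-class]; `getReferences()` a
#'   [ReferenceSet-class].
#' @export
getBatch <- function(dataset, id) {
    if (!id %in% names(dataset@batches))
        stop("no batch with id '", id, "'")
    dataset@batches[[id]]
}

#' @rdname getBatch
#' @export
getReferences <- function(dataset, id) {
    if (!id %in% names(dataset@references))
        stop("no references for batch id '", id, "'")
    dataset@references[[id]]
}

#' Batch roles of a campaign
#'
#' @param dataset a [ProcessDataset-class].
#' @param role `"calibration"` or `"validation"`.
#' @return character vector of batch ids holding that role; if no roles were
#'   assigned, all batch ids for `"calibration"` and none for
#'   `"validation"`.
#' @export
roleIds <- function(dataset, role = c("calibration", "validation")) {
    role <- match.arg(role)
    if (!length(dataset@roles))
        return(if (role == "calibration") batchIds(dataset) else character())
    names(dataset@roles)[dataset@roles == role]
}

setMethod("show", "ProcessDataset", function(object) {
    nref <- sum(vapply(object@references, nSamples, integer(1)))
    cat(sprintf("ProcessDataset: %d batches, %d reference samples\n",
                length(object@batches), nref))
    if (length(object@roles))
        cat(sprintf("  roles: %d calibration, %d validation\n",
                    sum(object@roles == "calibration"),
                    sum(object@roles == "validation")))
})
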