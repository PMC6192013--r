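#' @include validate.R
NULL

#' Evaluate the full smoothing / pairing / range / PLS pipeline
#'
#' Driver running the complete modelling pipeline on a campaign: time-smooth
#' each batch stream with a `k`-point window, pair references with spectra,
#' restrict to a moisture range, then fit and validate a PLS model.
#'
#' @param dataset a [ProcessDataset-class].
#' @param k odd time-smoothing window width (1 = raw).
#' @param method sample-wise preprocessing label (see [parseMethod()]);
#'   time smoothing is controlled by `k`, not by the label.
#' @param maxLod moisture range restriction (%) or `NULL` for the full
#'   range.
#' @param scheme validation scheme: `"lbo"`, `"loo"`, `"calibration"` or
#'   `"external"` (the latter uses the dataset's batch roles).
#' @param A number of latent variables.
#' @param ids batches to include (default: all with references; ignored for
#'   `"external"`, which uses the roles).
#' @return a [ValidationReport-class].
#' @export
evaluatePipeline <- function(dataset, k = 1L, method = "none",
                             maxLod = NULL,
                             scheme = c("lbo", "loo", "calibration",
                                        "external"),
                             A = 7L, ids = names(dataset@references)) {
    scheme <- match.arg(scheme)
    if (scheme == "external") {
        cal <- roleIds(dataset, "calibration")
        val <- roleIds(dataset, "validation")
        if (!length(val))
            stop("external validation needs batches with role 'validation'")
        calP <- restrictRange(pairCampaign(dataset, k = k, ids = cal),
                              maxLod)
        valP <- restrictRange(pairCampaign(dataset, k = k, ids = val),
                              maxLod)
        return(validateExternal(calP, valP, A = A, method = method))
    }
    paired <- restrictRange(pairCampaign(dataset, k = k, ids = ids), maxLod)
    switch(scheme,
           lbo = lboCV(paired, A = A, method = method),
           loo = looCV(paired, A = A, method = method),
           calibration = calibrationStats(paired, A = A, method = method))
}

#' Scan the time-smoothing window width
#'
#' Runs the full pipeline (smooth, pair, range-restrict, PLS, validate) for
#' every odd window width between `kMin` and `kMax` and selects the
#' smallest width whose RMSE is within a relative tolerance of the global
#' minimum — light smoothing is technically preferred because the in-line
#' delay grows with the window.
#'
#' @inheritParams evaluatePipeline
#' @param kMin,kMax odd scan bounds (inclusive), `kMin <= kMax`.
#' @param tolerance relative RMSE tolerance for the selection rule
#'   (default 0.02: the chosen k is the smallest with
#'   `rmse <= (1 + tolerance) * min(rmse)`).
#' @return a list with `table` (data.frame of `k`, `rmse`, `delay`) and
#'   `chosenK`.
#' @export
windowScan <- function(dataset, kMin = 3L, kMax = 101L, A = 7L,
                       scheme = "lbo", method = "none", maxLod = NULL,
                       tolerance = 0.02, dt = NULL) {
    kMin <- checkOddK(kMin); kMax <- checkOddK(kMax)
    if (kMin > kMax)
        stop("kMin must not exceed kMax")
    ks <- seq.int(kMin, kMax, by = 2L)
    if (is.null(dt)) {
        tb <- acqTimes(getBatch(dataset, batchIds(dataset)[1]))
        dt <- if (length(tb) > 1L) stats::median(diff(tb)) else 1
    }
    rmses <- vapply(ks, function(k)
        evaluatePipeline(dataset, k = k, method = method, maxLod = maxLod,
                         scheme = scheme, A = A)@rmse, numeric(1))
    chosen <- chooseWindow(ks, rmses, tolerance)
    list(table = data.frame(k = ks, rmse = rmses,
                            delay = (ks - 1) / 2 * dt),
         chosenK = chosen)
}

#' Window selection rule: smallest width within tolerance of the minimum
#'
#' Given the scanned widths and their validation RMSEs, returns the
#' smallest `k` whose RMSE is within `(1 + tolerance)` of the global
#' minimum. Light smoothing is preferred because the in-line delay grows
#' linearly with the window.
#'
#' @param ks numeric vector of window widths, ascending.
#' @param rmses matching RMSE values.
#' @param tolerance relative tolerance (default 0.02).
#' @return the chosen width.
#' @export
chooseWindow <- function(ks, rmses, tolerance = 0.02) {
    if (length(ks) != length(rmses) || !length(ks))
        stop("ks and rmses must be non-empty and of equal length")
    ks[which(rmses <= (1 + tolerance) * min(rmses))[1]]
}

## ---------------------------------------------------------------------------
## Model cascade / dynamic focusing
## ---------------------------------------------------------------------------

#' Cascade of moisture-range PLS models for dynamic focusing
#'
#' An ordered list of (upper moisture threshold, PLS model) stages. During
#' prediction the monitor starts with the full-range model and switches to
#' the next, more precisely calibrated narrow-range model once predictions
#' have stayed below that stage's threshold for `debounce` consecutive
#' points; switching is one-way.
#'
#' @slot upperLod numeric, upper moisture bound (%) per stage; `NA` for the
#'   unrestricted first stage; strictly decreasing afterwards.
#' @slot models list of [PLSModel-class], one per stage.
#' @slot k odd time-smoothing window width shared by all stages.
#' @slot debounce consecutive below-threshold predictions required before a
#'   switch.
#'
#' @seealso [buildCascade()], [dynamicPredict()]
#' @export
setClass("ModelCascade",
         representation(upperLod = "numeric",
                        models = "list",
                        k = "integer",
                        debounce = "integer"))

setValidity("ModelCascade", function(object) {
    msg <- character()
    if (length(object@models) != length(object@upperLod))
        msg <- c(msg, "one model per threshold required")
    thr <- object@upperLod[!is.na(object@upperLod)]
    if (length(thr) > 1L && any(diff(thr) >= 0))
        msg <- c(msg, "thresholds must be strictly decreasing")
    if (length(object@upperLod) > 1L && anyNA(object@upperLod[-1]))
        msg <- c(msg, "only the first stage may be unrestricted (NA)")
    if (object@debounce < 1L)
        msg <- c(msg, "debounce must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModelCascade", function(object) {
    lab <- ifelse(is.na(object@upperLod), "full range",
                  sprintf("< %g%%", object@upperLod))
    cat(sprintf("ModelCascade: %d stage(s), k = %d, debounce = %d\n",
                length(object@models), object@k, object@debounce))
    cat("  stages:", paste(lab, collapse = " -> "), "\n")
})

#' Build a cascade of moisture-range models
#'
#' Fits one PLS model per moisture threshold on the range-restricted
#' training data (`lod < threshold`; a leading `NA` stage uses the full
#' range). Stages are ordered full range first, thresholds strictly
#' decreasing.
#'
#' @param dataset a [ProcessDataset-class] (calibration-role batches are
#'   used when roles are assigned).
#' @param thresholds numeric vector of upper moisture bounds (%), e.g.
#'   `c(NA, 20, 15, 10)`; a leading `NA` denotes the full-range stage.
#' @param A latent variables per stage model.
#' @param k odd time-smoothing window width applied to each batch stream.
#' @param debounce consecutive below-threshold points required for a stage
#'   switch during monitoring.
#' @return a [ModelCascade-class].
#' @export
buildCascade <- function(dataset, thresholds = c(NA, 20, 15, 10), A = 7L,
                         k = 15L, debounce = 3L) {
    k <- checkOddK(k)
    finite <- thresholds[!is.na(thresholds)]
    if (length(finite) > 1L && any(diff(finite) >= 0))
        stop("thresholds must be strictly decreasing")
    ids <- roleIds(dataset, "calibration")
    ids <- intersect(ids, names(dataset@references))
    paired <- pairCampaign(dataset, k = k, ids = ids)
    models <- vector("list", length(thresholds))
    for (s in seq_along(thresholds)) {
        thr <- thresholds[s]
        sub <- restrictRange(paired, if (is.na(thr)) NULL else thr)
        if (nSamples(sub) < A + 2L)
            stop("range ", if (is.na(thr)) "full" else paste0("< ", thr, "%"),
                 " has only ", nSamples(sub), " samples; need at least ",
                 A + 2L)
        models[[s]] <- fitPLS(sub, A = A)
    }
    new("ModelCascade", upperLod = as.numeric(thresholds), models = models,
        k = k, debounce = as.integer(debounce))
}

#' Monitor a drying run with dynamic model focusing
#'
#' Streams a batch through the cascade: spectra are smoothed along time
#' with the cascade's `k`-point window (a centered window emitted with its
#' `(k-1)/2`-point delay; start-of-stream points use the reduced symmetric
#' end windows), each smoothed spectrum is predicted with the currently
#' active stage model, and the monitor advances to the next stage once the
#' prediction has stayed below that stage's threshold for `debounce`
#' consecutive points. Switching is one-way: the monitor never returns to
#' a wetter-range model.
#'
#' @param cascade a [ModelCascade-class].
#' @param stream a [SpectraBatch-class] on the training wavelength grid.
#' @return data.frame with one row per spectrum: `time` (s), `predicted`
#'   (moisture %), `stage` (1-based active stage index, non-decreasing) and
#'   `availableAt` (time at which the smoothed point can be emitted
#'   in-line, `time + delay`).
#' @export
dynamicPredict <- function(cascade, stream) {
    stopifnot(is(cascade, "ModelCascade"), is(stream, "SpectraBatch"))
    if (nSpectra(stream) == 0L)
        stop("empty spectra stream")
    Xs <- timeSmooth(intensities(stream), cascade@k)
    nStage <- length(cascade@models)
    n <- nrow(Xs)
    pred <- numeric(n)
    stage <- integer(n)
    s <- 1L
    below <- 0L
    for (i in seq_len(n)) {
        pred[i] <- predict(cascade@models[[s]], Xs[i, , drop = FALSE])
        stage[i] <- s
        if (s < nStage) {
            if (pred[i] < cascade@upperLod[s + 1L]) {
                below <- below + 1L
                if (below >= cascade@debounce) {
                    s <- s + 1L
                    below <- 0L
                }
            } else {
                below <- 0L
            }
        }
    }
    delay <- (cascade@k - 1) / 2 *
        (if (nSpectra(stream) > 1L) stats::median(diff(acqTimes(stream)))
         else 0)
    data.frame(time = acqTimes(stream), predicted = pred, stage = stage,
               availableAt = acqTimes(stream) + delay)
}

#' Serialize a model cascade to JSON
#'
#' Writes thresholds, smoother width, debounce and the per-stage PLS
#' coefficients/centers so a monitor can be re-created without the
#' training data.
#'
#' @param cascade a [ModelCascade-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeCascade <- function(cascade, path) {
    stages <- lapply(seq_along(cascade@models), function(s) {
        m <- cascade@models[[s]]
        list(upperLod = if (is.na(cascade@upperLod[s])) NULL
                        else cascade@upperLod[s],
             A = m@A,
             xCenter = m@xCenter,
             yCenter = m@yCenter,
             coefficients = m@coefficients[, m@A],
             weights = m@weights,
             xLoadings = m@xLoadings,
             yLoadings = m@yLoadings,
             coefficientMatrix = m@coefficients)
    })
    jsonlite::write_json(list(k = cascade@k, debounce = cascade@debounce,
                              stages = stages),
                         path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' Read a model cascade from JSON
#'
#' @param path JSON file written by [writeCascade()].
#' @return a [ModelCascade-class].
#' @export
readCascade <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    asMat <- function(x, A) {
        # JSON matrices arrive as a list of rows
        do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
    }
    models <- lapply(obj$stages, function(st) {
        A <- as.integer(st$A)
        new("PLSModel",
            xCenter = as.numeric(unlist(st$xCenter)),
            yCenter = as.numeric(st$yCenter),
            weights = asMat(st$weights, A),
            xLoadings = asMat(st$xLoadings, A),
            yLoadings = as.numeric(unlist(st$yLoadings)),
            scores = matrix(0, 0L, A),
            coefficients = asMat(st$coefficientMatrix, A),
            A = A)
    })
    thr <- vapply(obj$stages, function(st) {
        v <- st$upperLod
        if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    new("ModelCascade", upperLod = thr, models = models,
        k = as.integer(obj$k), debounce = as.integer(obj$debounce))
}
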