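#' @include pls.R preprocess.R dataset-ops.R
NULL

#' Validation report for a calibration model
#'
#' Holds the per-sample predictions and summary accuracy of one validation
#' scheme.
#'
#' @slot scheme one of `"calibration"`, `"loo"`, `"lbo"`, `"external"`.
#' @slot rmse root-mean-square error, moisture %.
#' @slot r2 coefficient of determination (about the evaluated set's mean).
#' @slot predictions data.frame with columns `batch`, `time`, `lod`,
#'   `predicted`.
#'
#' @export
setClass("ValidationReport",
         representation(scheme = "character",
                        rmse = "numeric",
                        r2 = "numeric",
                        predictions = "data.frame"))

setValidity("ValidationReport", function(object) {
    msg <- character()
    if (object@rmse < 0)
        msg <- c(msg, "RMSE must be non-negative")
    if (object@r2 > 1 + 1e-12)
        msg <- c(msg, "R^2 cannot exceed 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("ValidationReport (%s): RMSE = %.4f %%, R2 = %.4f, n = %d\n",
                object@scheme, object@rmse, object@r2,
                nrow(object@predictions)))
})

makeReport <- function(scheme, paired, yHat) {
    y <- lodValues(paired)
    new("ValidationReport", scheme = scheme, rmse = rmse(y, yHat),
        r2 = rsq(y, yHat),
        predictions = data.frame(batch = batchIds(paired),
                                 time = sampleTimes(paired),
                                 lod = y, predicted = yHat))
}

## Row-wise (sample-wise) preprocessing with fold-safe parameter learning.
## Returns the transformed training matrix and a closure applying the same
## learned transformation (e.g. the MSC reference) to new spectra.
rowPreprocessor <- function(method, Xtrain) {
    switch(method$rowMethod,
           none = list(train = Xtrain, apply = identity),
           snv = list(train = snv(Xtrain), apply = snv),
           sg = {
               f <- function(X) sgDerivative(X, window = method$sgWindow,
                                             polyorder = method$sgOrder,
                                             deriv = method$sgDeriv)
               list(train = f(Xtrain), apply = f)
           },
           msc = {
               fit <- msc(Xtrain)
               list(train = fit$x,
                    apply = function(X) msc(X, ref = fit$reference)$x)
           },
           stop("unknown row method '", method$rowMethod, "'"))
}

## method may be a label ("s15", "msc", ...) or a parsed list.
asMethod <- function(method) {
    if (is.character(method)) parseMethod(method) else method
}

#' Calibration (resubstitution) statistics
#'
#' Fits on all rows of `paired` and evaluates on the same rows.
#'
#' @param paired a [PairedData-class]. Any time smoothing must already be
#'   applied at pairing time (see [pairCampaign()]); `method` controls the
#'   sample-wise preprocessing.
#' @param A number of latent variables.
#' @param method preprocessing label or parsed list (see [parseMethod()]);
#'   only its row-wise part (`none`/`msc`/`snv`/`sg`) is used here.
#' @return a [ValidationReport-class].
#' @export
calibrationStats <- function(paired, A = 7L, method = "none") {
    method <- asMethod(method)
    prep <- rowPreprocessor(method, intensities(paired))
    model <- fitPLS(prep$train, lodValues(paired), A)
    makeReport("calibration", paired, predict(model, prep$train))
}

#' Leave-one-sample-out cross-validation
#'
#' Each paired sample is predicted by a model fitted on all other samples
#' (full CV). Preprocessing that learns parameters (the MSC reference) is
#' re-fitted inside each fold; time smoothing is a per-batch stream
#' operation applied before pairing and uses no reference values, so it
#' does not leak across folds.
#'
#' @inheritParams calibrationStats
#' @return a [ValidationReport-class] with scheme `"loo"`.
#' @export
looCV <- function(paired, A = 7L, method = "none") {
    method <- asMethod(method)
    n <- nSamples(paired)
    if (n < A + 2L)
        stop("need at least A + 2 samples for leave-one-out CV")
    X <- intensities(paired)
    y <- lodValues(paired)
    yHat <- numeric(n)
    for (i in seq_len(n)) {
        prep <- rowPreprocessor(method, X[-i, , drop = FALSE])
        model <- fitPLS(prep$train, y[-i], A)
        yHat[i] <- predict(model, prep$apply(X[i, , drop = FALSE]))
    }
    makeReport("loo", paired, yHat)
}

#' Leave-a-batch-out cross-validation
#'
#' Folds are batches: all samples of the held-out batch are predicted by a
#' model fitted on the remaining batches; RMSE is aggregated over all
#' held-out predictions. This is typically the most conservative
#' validation scheme for batch process data.
#'
#' @inheritParams calibrationStats
#' @return a [ValidationReport-class] with scheme `"lbo"`.
#' @export
lboCV <- function(paired, A = 7L, method = "none") {
    method <- asMethod(method)
    ids <- batchIds(paired)
    folds <- unique(ids)
    if (length(folds) < 2L)
        stop("leave-a-batch-out CV needs at least 2 batches")
    X <- intensities(paired)
    y <- lodValues(paired)
    yHat <- numeric(length(y))
    for (b in folds) {
        out <- ids == b
        prep <- rowPreprocessor(method, X[!out, , drop = FALSE])
        model <- fitPLS(prep$train, y[!out], A)
        yHat[out] <- predict(model, prep$apply(X[out, , drop = FALSE]))
    }
    makeReport("lbo", paired, yHat)
}

#' Validation by a preselected external set
#'
#' Fits on the calibration samples and predicts the validation samples
#' (RMSEP). The two sets must come from disjoint batches.
#'
#' @param calibration,validation [PairedData-class] objects on the same
#'   wavelength grid, with disjoint batch ids.
#' @inheritParams calibrationStats
#' @return a [ValidationReport-class] with scheme `"external"`.
#' @export
validateExternal <- function(calibration, validation, A = 7L,
                             method = "none") {
    method <- asMethod(method)
    overlap <- intersect(unique(batchIds(calibration)),
                         unique(batchIds(validation)))
    if (length(overlap))
        stop("calibration and validation share batch id(s): ",
             paste(overlap, collapse = ", "))
    prep <- rowPreprocessor(method, intensities(calibration))
    model <- fitPLS(prep$train, lodValues(calibration), A)
    makeReport("external", validation,
               predict(model, prep$apply(intensities(validation))))
}

#' RMSE as a function of the number of latent variables
#'
#' Evaluates the chosen validation scheme for every number of latent
#' variables from 1 to `aMax`. For cross-validation schemes each fold is
#' fitted once with `aMax` components and truncated per `a` (NIPALS
#' components are nested), so the scan costs little more than a single CV.
#'
#' @inheritParams calibrationStats
#' @param aMax largest number of latent variables.
#' @param scheme `"calibration"`, `"loo"` or `"lbo"`.
#' @return data.frame with columns `a` and `rmse` (one row per latent
#'   variable count).
#' @export
lvScan <- function(paired, aMax = 10L, scheme = c("lbo", "loo",
                                                  "calibration"),
                   method = "none") {
    scheme <- match.arg(scheme)
    method <- asMethod(method)
    X <- intensities(paired)
    y <- lodValues(paired)
    n <- length(y)
    predAll <- matrix(NA_real_, n, aMax)
    if (scheme == "calibration") {
        prep <- rowPreprocessor(method, X)
        model <- fitPLS(prep$train, y, aMax)
        for (a in seq_len(aMax))
            predAll[, a] <- predict(model, prep$train, a = a)
    } else {
        folds <- if (scheme == "loo") as.list(seq_len(n))
                 else {
                     ids <- batchIds(paired)
                     lapply(unique(ids), function(b) which(ids == b))
                 }
        if (scheme == "lbo" && length(folds) < 2L)
            stop("leave-a-batch-out CV needs at least 2 batches")
        for (fold in folds) {
            prep <- rowPreprocessor(method, X[-fold, , drop = FALSE])
            model <- fitPLS(prep$train, y[-fold], aMax)
            Xout <- prep$apply(X[fold, , drop = FALSE])
            for (a in seq_len(aMax))
                predAll[fold, a] <- predict(model, Xout, a = a)
        }
    }
    data.frame(a = seq_len(aMax),
               rmse = vapply(seq_len(aMax),
                             function(a) rmse(y, predAll[, a]), numeric(1)))
}
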