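#' @include classes-dataset.R
NULL

#' Parameters of the synthetic drying-campaign simulator
#'
#' Defaults reproduce the geometry and statistical structure of a typical
#' pilot-scale fluidized-bed drying campaign monitored by a 256-channel
#' diode-array NIR spectrometer: spectra on a linear 1091.8-2106.5 nm grid
#' every 5 s, 396-1213 spectra per batch, moisture falling roughly
#' exponentially from about 26 to about 2.4 % LOD, water absorption bands
#' near 1440 and 1930 nm (the 1930 nm band about three times stronger), a
#' wavelength-flat baseline component proportional to moisture (the
#' refractive "watermark" effect), strong stochastic whole-spectrum
#' intensity fluctuations (the "scatter effect", multiplicative plus
#' offset), and 5-26 reference samples per batch with 0.06 % LOD
#' reproducibility.
#'
#' @slot nChannels number of wavelength channels.
#' @slot wlRange wavelength span, nm (linear grid).
#' @slot dt acquisition interval, s.
#' @slot nSpectraRange integer range of spectra per batch.
#' @slot m0Range initial moisture range, % LOD.
#' @slot mEndRange final (asymptotic) moisture range, % LOD.
#' @slot tauRange drying time-constant range, s.
#' @slot bandCenters water band centers, nm.
#' @slot bandWidths Gaussian band SD widths, nm.
#' @slot bandAmps band amplitudes, lg(1/R) per % LOD.
#' @slot alpha wavelength-flat "watermark" slope, lg(1/R) per % LOD.
#' @slot sigmaF SD of the log multiplicative scatter factor.
#' @slot sigmaO SD of the additive whole-spectrum offset, lg(1/R).
#' @slot sigmaEps SD of iid channel noise, lg(1/R).
#' @slot nRefRange integer range of reference samples per batch.
#' @slot lodNoiseSd reference method SD, % LOD.
#'
#' @seealso [simParams()], [simulateBatch()], [simulateCampaign()]
#' @export
setClass("SimParams",
         representation(nChannels = "integer",
                        wlRange = "numeric",
                        dt = "numeric",
                        nSpectraRange = "integer",
                        m0Range = "numeric",
                        mEndRange = "numeric",
                        tauRange = "numeric",
                        bandCenters = "numeric",
                        bandWidths = "numeric",
                        bandAmps = "numeric",
                        alpha = "numeric",
                        sigmaF = "numeric",
                        sigmaO = "numeric",
                        sigmaEps = "numeric",
                        nRefRange = "integer",
                        lodNoiseSd = "numeric"))

setValidity("SimParams", function(object) {
    msg <- character()
    if (object@nChannels < 2L)
        msg <- c(msg, "nChannels must be >= 2")
    if (any(c(object@sigmaF, object@sigmaO, object@sigmaEps,
              object@lodNoiseSd) < 0))
        msg <- c(msg, "noise SDs must be non-negative")
    if (any(object@tauRange <= 0))
        msg <- c(msg, "tau must be positive")
    if (any(object@bandCenters < object@wlRange[1] |
            object@bandCenters > object@wlRange[2]))
        msg <- c(msg, "band centers must lie inside the wavelength span")
    if (length(object@bandCenters) != length(object@bandWidths) ||
        length(object@bandCenters) != length(object@bandAmps))
        msg <- c(msg, "band parameter lengths differ")
    if (object@dt <= 0)
        msg <- c(msg, "dt must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct simulator parameters
#'
#' @param nChannels,wlRange,dt,nSpectraRange,m0Range,mEndRange,tauRange
#'   see [SimParams-class].
#' @param bandCenters,bandWidths,bandAmps,alpha,sigmaF,sigmaO,sigmaEps
#'   see [SimParams-class].
#' @param nRefRange,lodNoiseSd see [SimParams-class].
#' @return a validated [SimParams-class].
#' @export
simParams <- function(nChannels = 256L,
                      wlRange = c(1091.8, 2106.5),
                      dt = 5,
                      nSpectraRange = c(396L, 1213L),
                      m0Range = c(24.5, 26.5),
                      mEndRange = c(2.2, 3.0),
                      tauRange = c(600, 1500),
                      bandCenters = c(1440, 1930),
                      bandWidths = c(35, 50),
                      bandAmps = c(0.004, 0.012),
                      alpha = 0.006,
                      sigmaF = 0.05,
                      sigmaO = 0.02,
                      sigmaEps = 5e-4,
                      nRefRange = c(5L, 26L),
                      lodNoiseSd = 0.06) {
    new("SimParams", nChannels = as.integer(nChannels),
        wlRange = wlRange, dt = dt,
        nSpectraRange = as.integer(nSpectraRange),
        m0Range = m0Range, mEndRange = mEndRange, tauRange = tauRange,
        bandCenters = bandCenters, bandWidths = bandWidths,
        bandAmps = bandAmps, alpha = alpha, sigmaF = sigmaF,
        sigmaO = sigmaO, sigmaEps = sigmaEps,
        nRefRange = as.integer(nRefRange), lodNoiseSd = lodNoiseSd)
}

setMethod("show", "SimParams", function(object) {
    cat(sprintf(paste0("SimParams: %d channels %.1f-%.1f nm, dt = %g s, ",
                       "%d-%d spectra/batch\n"),
                object@nChannels, object@wlRange[1], object@wlRange[2],
                object@dt, object@nSpectraRange[1], object@nSpectraRange[2]))
    cat(sprintf("  scatter sigmaF = %g, sigmaO = %g, watermark alpha = %g\n",
                object@sigmaF, object@sigmaO, object@alpha))
})

#' One simulated batch with its ground truth
#'
#' @slot batch the observed [SpectraBatch-class].
#' @slot moisture true moisture trajectory m(t), % LOD, one value per
#'   spectrum.
#' @slot params the [SimParams-class] used.
#'
#' @export
setClass("SimBatch",
         representation(batch = "SpectraBatch",
                        moisture = "numeric",
                        params = "SimParams"))

setValidity("SimBatch", function(object) {
    if (length(object@moisture) != nSpectra(object@batch))
        "moisture trajectory length differs from spectra count"
    else TRUE
})

setMethod("show", "SimBatch", function(object) {
    cat("SimBatch with ground-truth trajectory\n")
    show(object@batch)
})

## deterministic smooth instrument/matrix baseline, lg(1/R)
simBaseline <- function(u) 0.25 + 0.08 * u + 0.05 * u^2

## wavelength response to moisture: flat watermark term + water bands
simMoistureResponse <- function(wl, params) {
    h <- rep(params@alpha, length(wl))
    for (b in seq_along(params@bandCenters))
        h <- h + params@bandAmps[b] *
            exp(-(wl - params@bandCenters[b])^2 /
                (2 * params@bandWidths[b]^2))
    h
}

#' Simulate one fluidized-bed drying batch
#'
#' Generative model: the true moisture follows
#' `m(t) = mEnd + (m0 - mEnd) * exp(-t / tau)`; the clean spectrum is
#' `A0(wl, t) = b(wl) + alpha * m(t) + m(t) * sum(bands)` (a fixed smooth
#' baseline, the wavelength-flat "watermark" term, and Gaussian water
#' bands); the observed spectrum is
#' `A = f_t * A0 + o_t + eps` with `f_t` lognormal (median 1), `o_t` a
#' Normal whole-spectrum offset and `eps` iid channel noise. Fully
#' deterministic given `seed`; batch-level parameters (`n`, `tau`, `m0`,
#' `mEnd`) are drawn from the ranges in `params`.
#'
#' @param params a [SimParams-class].
#' @param seed integer seed for this batch.
#' @param batchId batch label.
#' @return a [SimBatch-class].
#' @export
simulateBatch <- function(params = simParams(), seed = 1L,
                          batchId = "SIM01") {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    if (!exists(".Random.seed", envir = globalenv()))
        stats::runif(1)  # initialise the RNG so its state can be restored
    oldSeed <- .Random.seed
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)
    n <- sample.int(params@nSpectraRange[2] - params@nSpectraRange[1] + 1L,
                    1L) + params@nSpectraRange[1] - 1L
    tau <- stats::runif(1, params@tauRange[1], params@tauRange[2])
    m0 <- stats::runif(1, params@m0Range[1], params@m0Range[2])
    mEnd <- stats::runif(1, params@mEndRange[1], params@mEndRange[2])
    times <- (seq_len(n) - 1L) * params@dt
    wl <- seq(params@wlRange[1], params@wlRange[2],
              length.out = params@nChannels)
    u <- (wl - params@wlRange[1]) / diff(params@wlRange)
    m <- mEnd + (m0 - mEnd) * exp(-times / tau)
    h <- simMoistureResponse(wl, params)
    A0 <- outer(m, h) + matrix(simBaseline(u), n, params@nChannels,
                               byrow = TRUE)
    f <- exp(stats::rnorm(n, 0, params@sigmaF))
    o <- stats::rnorm(n, 0, params@sigmaO)
    eps <- matrix(stats::rnorm(n * params@nChannels, 0, params@sigmaEps),
                  n, params@nChannels)
    X <- A0 * f + o + eps
    new("SimBatch",
        batch = SpectraBatch(batchId, times, wl, X),
        moisture = m, params = params)
}

#' Draw reference samples from a simulated batch
#'
#' Sampling times are stratified-uniform over the batch duration (one draw
#' per equal-width stratum) and snapped to the nearest acquisition time;
#' the reported LOD is the true moisture at that time plus Normal
#' measurement noise, truncated at zero.
#'
#' @param sim a [SimBatch-class].
#' @param n number of reference samples (>= 1, at most the spectra count);
#'   default: drawn from the params' `nRefRange`.
#' @param lodNoiseSd reference noise SD (%); default from the params.
#' @param seed integer seed.
#' @return a [ReferenceSet-class].
#' @export
sampleReferences <- function(sim, n = NULL, lodNoiseSd = NULL, seed = 1L) {
    stopifnot(is(sim, "SimBatch"))
    params <- sim@params
    if (!exists(".Random.seed", envir = globalenv()))
        stats::runif(1)  # initialise the RNG so its state can be restored
    oldSeed <- .Random.seed
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)
    if (is.null(n))
        n <- sample.int(params@nRefRange[2] - params@nRefRange[1] + 1L,
                        1L) + params@nRefRange[1] - 1L
    if (is.null(lodNoiseSd))
        lodNoiseSd <- params@lodNoiseSd
    if (n < 1L)
        stop("need at least one reference sample")
    nt <- nSpectra(sim@batch)
    if (n > nt)
        stop("cannot draw more references than spectra")
    tmax <- max(acqTimes(sim@batch))
    edges <- seq(0, tmax, length.out = n + 1L)
    st <- stats::runif(n, edges[-(n + 1L)], edges[-1])
    idx <- vapply(st, function(t) which.min(abs(acqTimes(sim@batch) - t)),
                  integer(1))
    idx <- sort(unique(idx))
    lod <- pmax(0, sim@moisture[idx] +
                    stats::rnorm(length(idx), 0, lodNoiseSd))
    ReferenceSet(batchId(sim@batch), acqTimes(sim@batch)[idx], lod)
}

#' Simulate a multi-batch drying campaign
#'
#' Generates `nBatches` batches with per-batch parameter jitter (each batch
#' draws its own `n`, `tau`, `m0`, `mEnd` from the ranges in `params`),
#' samples references for each, and randomly assigns `validationBatches`
#' batches the validation role. Per-batch seeds are derived from the master
#' seed, so any batch is reproducible independently of the others.
#'
#' @param params a [SimParams-class].
#' @param nBatches number of batches (default 25).
#' @param validationBatches number of validation-role batches (default 8,
#'   must be `< nBatches`).
#' @param seed master integer seed.
#' @return a [ProcessDataset-class] with roles assigned.
#' @export
simulateCampaign <- function(params = simParams(), nBatches = 25L,
                             validationBatches = 8L, seed = 1L) {
    nBatches <- as.integer(nBatches)
    validationBatches <- as.integer(validationBatches)
    if (nBatches < 1L || validationBatches < 0L ||
        validationBatches >= nBatches)
        stop("need 0 <= validationBatches < nBatches")
    if (!exists(".Random.seed", envir = globalenv()))
        stats::runif(1)  # initialise the RNG so its state can be restored
    oldSeed <- .Random.seed
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)
    batchSeeds <- sample.int(2147483646L, nBatches)
    refSeeds <- sample.int(2147483646L, nBatches)
    valIdx <- sample.int(nBatches, validationBatches)
    ids <- sprintf("B%02d", seq_len(nBatches))
    batches <- vector("list", nBatches)
    references <- vector("list", nBatches)
    for (i in seq_len(nBatches)) {
        sim <- simulateBatch(params, seed = batchSeeds[i], batchId = ids[i])
        batches[[i]] <- sim@batch
        references[[i]] <- sampleReferences(sim, seed = refSeeds[i])
    }
    roles <- rep("calibration", nBatches)
    roles[valIdx] <- "validation"
    names(roles) <- ids
    ProcessDataset(batches, references, roles)
}
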