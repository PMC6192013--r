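# Small deterministic fixtures built in code.

toyWavelengths <- c(1100, 1400, 1700, 1900)

# Tiny deterministic batch: a falling "moisture" factor on 4 channels.
toyBatch <- function(id = "T1", n = 12, seed = 1) {
    set.seed(seed)
    times <- (seq_len(n) - 1) * 5
    m <- 20 * exp(-times / 30) + 2
    h <- c(0.01, 0.02, 0.01, 0.03)
    X <- outer(m, h) + 0.3 + matrix(rnorm(n * 4, 0, 1e-3), n, 4)
    SpectraBatch(id, times, toyWavelengths, X)
}

toyRefs <- function(id = "T1", times = c(10, 25, 40),
                    lod = c(15, 8, 4), excluded = NULL) {
    if (is.null(excluded)) excluded <- rep(FALSE, length(times))
    ReferenceSet(id, times, lod, excluded)
}

# A small noise-free-ish multi-batch campaign where lod is an exact linear
# function of a single spectral factor (useful for exact-recovery tests).
toySingleFactorPaired <- function(nPerBatch = 4, nBatches = 3) {
    h <- c(1, 0.5, -0.2, 0.1)
    rows <- list()
    set.seed(42)
    for (b in seq_len(nBatches)) {
        lod <- runif(nPerBatch, 2, 25)
        # minute full-rank jitter so latent-variable scans beyond the
        # single factor remain well defined
        X <- outer(lod, h) + 0.1 +
            matrix(rnorm(nPerBatch * 4, 0, 1e-9), nPerBatch, 4)
        rows[[b]] <- PairedData(rep(sprintf("B%d", b), nPerBatch),
                                sampleTimes = seq_len(nPerBatch) * 10,
                                lod = lod, spectra = X,
                                wavelengths = toyWavelengths)
    }
    do.call(rbindPaired, rows)
}

# Desk-scale simulator conditions: shorter batches with the drying time
# constant scaled down in proportion, preserving the duration/tau ratio of
# the full-scale defaults.
deskParams <- function(...) {
    simParams(nSpectraRange = c(150L, 300L), tauRange = c(180, 420), ...)
}
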