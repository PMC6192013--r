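test_that("single-factor noise-free data is fit exactly with one LV", {
    p <- toySingleFactorPaired()
    m <- fitPLS(p, A = 1)
    expect_lt(rmse(lodValues(p), predict(m, p)), 1e-8)
    # prediction on a training row is exact
    expect_equal(predict(m, intensities(p)[3, , drop = FALSE]),
                 lodValues(p)[3], tolerance = 1e-8)
})

test_that("PLS coefficients agree with an independent NIPALS oracle", {
    set.seed(51)
    X <- matrix(rnorm(6 * 4), 6, 4)
    y <- rnorm(6)
    Xnew <- matrix(rnorm(3 * 4), 3, 4)
    for (A in 1:3) {
        m <- fitPLS(X, y, A)
        expect_equal(predict(m, Xnew), oraclePLSPredict(X, y, A, Xnew),
                     tolerance = 1e-8)
    }
})

test_that("PLS at full rank equals ordinary least squares", {
    set.seed(52)
    for (i in 1:10) {
        n <- sample(8:15, 1)
        p <- sample(3:6, 1)
        X <- matrix(rnorm(n * p), n, p)
        y <- rnorm(n)
        m <- fitPLS(X, y, p)
        expect_equal(predict(m, X), unname(fitted(lm(y ~ X))),
                     tolerance = 1e-6)
    }
})

test_that("NIPALS scores are mutually orthogonal", {
    set.seed(53)
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
    m <- fitPLS(X, y, 5)
    G <- crossprod(m@scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
})

test_that("prediction is affine in X and validates the grid", {
    set.seed(54)
    X <- matrix(rnorm(10 * 4), 10, 4)
    y <- rnorm(10)
    m <- fitPLS(X, y, 2)
    # constant spectra predict yCenter + offset term only
    xc <- matrix(m@xCenter, 2, 4, byrow = TRUE)
    expect_equal(predict(m, xc), rep(m@yCenter, 2), tolerance = 1e-10)
    # affine combinations of spectra give affine combinations of predictions
    A1 <- matrix(rnorm(8), 2, 4); A2 <- matrix(rnorm(8), 2, 4)
    expect_equal(predict(m, 0.3 * A1 + 0.7 * A2),
                 0.3 * predict(m, A1) + 0.7 * predict(m, A2),
                 tolerance = 1e-9)
    expect_error(predict(m, matrix(0, 2, 5)), "grid")
})

test_that("fit validation errors", {
    X <- matrix(rnorm(12), 4, 3)
    expect_error(fitPLS(X, rep(1, 4), 2), "zero variance")
    expect_error(fitPLS(X, rnorm(4), 4), "at least")
    expect_error(fitPLS(outer(1:6, c(1, 2, 3)), rnorm(6), 3), "rank")
})

test_that("rmse and rsq hand arithmetic", {
    y <- c(1, 3, 5)
    expect_equal(rmse(y, y), 0)
    expect_equal(rsq(y, y), 1)
    expect_equal(rsq(y, rep(mean(y), 3)), 0)
    expect_equal(rmse(c(0, 2), c(1, 1)), 1)
    expect_equal(rsq(c(0, 2), c(1, 1)), 0)  # SS_res = SS_tot = 2
    expect_error(rmse(1:3, 1:4), "length")
})

test_that("leave-one-out CV equals an explicit loop oracle", {
    set.seed(55)
    h <- c(1, 0.4, -0.3, 0.2)
    lod <- runif(8, 3, 24)
    X <- outer(lod, h) + matrix(rnorm(32, 0, 0.05), 8, 4)
    p <- PairedData(rep(c("A", "B"), each = 4), 1:8, lod, X,
                    toyWavelengths)
    rep1 <- looCV(p, A = 2)
    expect_equal(rep1@predictions$predicted,
                 oracleLOO(X, lod, 2), tolerance = 1e-8)
    expect_equal(nrow(rep1@predictions), 8L)
    # noise-free single factor: near-exact cross-validated recovery
    pf <- toySingleFactorPaired()
    expect_lt(looCV(pf, A = 1)@rmse, 1e-6)
})

test_that("leave-a-batch-out CV equals an explicit loop oracle", {
    set.seed(56)
    h <- c(1, 0.4, -0.3, 0.2)
    lod <- runif(12, 3, 24)
    ids <- rep(c("A", "B", "C"), each = 4)
    X <- outer(lod, h) + matrix(rnorm(48, 0, 0.05), 12, 4)
    p <- PairedData(ids, 1:12, lod, X, toyWavelengths)
    rep1 <- lboCV(p, A = 2)
    expect_equal(rep1@predictions$predicted, oracleLBO(X, lod, ids, 2),
                 tolerance = 1e-8)
    # fold sample counts sum to n; single batch is an error
    expect_equal(nrow(rep1@predictions), 12L)
    expect_error(lboCV(p[1:4], A = 2), "2 batches")
})

test_that("external validation enforces disjoint batches", {
    p <- toySingleFactorPaired(nPerBatch = 5, nBatches = 3)
    cal <- p[batchIds(p) %in% c("B1", "B2")]
    val <- p[batchIds(p) == "B3"]
    r <- validateExternal(cal, val, A = 1)
    expect_lt(r@rmse, 1e-6)
    expect_error(validateExternal(cal, cal, A = 1), "share batch")
    # validation equal to calibration data gives calibration stats
    calCopy <- PairedData(paste0("X", batchIds(cal)), sampleTimes(cal),
                          lodValues(cal), intensities(cal),
                          wavelengths(cal))
    rc <- calibrationStats(cal, A = 1)
    re <- validateExternal(cal, calCopy, A = 1)
    expect_equal(re@rmse, rc@rmse, tolerance = 1e-10)
})

test_that("MSC reference is re-learned inside each CV fold", {
    set.seed(57)
    h <- c(1, 0.4, -0.3, 0.2)
    lod <- runif(10, 3, 24)
    ids <- rep(c("A", "B"), each = 5)
    X <- outer(lod, h) + 0.5 + matrix(rnorm(40, 0, 0.05), 10, 4)
    p <- PairedData(ids, 1:10, lod, X, toyWavelengths)
    r <- lboCV(p, A = 2, method = "msc")
    # oracle: explicit loop re-fitting the reference per fold
    yhat <- numeric(10)
    for (b in c("A", "B")) {
        out <- ids == b
        ref <- colMeans(X[!out, , drop = FALSE])
        Xtr <- oracleMSC(X[!out, , drop = FALSE], ref)
        Xte <- oracleMSC(X[out, , drop = FALSE], ref)
        yhat[out] <- oraclePLSPredict(Xtr, lod[!out], 2, Xte)
    }
    expect_equal(r@predictions$predicted, yhat, tolerance = 1e-6)
})

test_that("lv scan: calibration RMSE non-increasing, plateau structure", {
    p <- toySingleFactorPaired(nPerBatch = 6, nBatches = 3)
    sc <- lvScan(p, aMax = 4, scheme = "calibration")
    expect_equal(nrow(sc), 4L)
    expect_true(all(diff(sc$rmse) <= 1e-10))
    expect_lt(sc$rmse[1], 1e-8)       # single factor plateaus at A = 1
    # per-fold truncation equals refitting at each A
    set.seed(58)
    lod <- runif(12, 3, 24)
    X <- outer(lod, c(1, 0.4, -0.3, 0.2)) +
        matrix(rnorm(48, 0, 0.1), 12, 4)
    p2 <- PairedData(rep(c("A", "B", "C"), each = 4), 1:12, lod, X,
                     toyWavelengths)
    sc2 <- lvScan(p2, aMax = 3, scheme = "lbo")
    for (a in 1:3)
        expect_equal(sc2$rmse[a], lboCV(p2, A = a)@rmse, tolerance = 1e-8)
})

test_that("LBO CV is more conservative than calibration on simulated data", {
    ds <- simulateCampaign(deskParams(), nBatches = 6,
                           validationBatches = 1, seed = 12)
    p <- pairCampaign(ds, k = 15)
    expect_gt(lboCV(p, A = 7)@rmse, calibrationStats(p, A = 7)@rmse)
})
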