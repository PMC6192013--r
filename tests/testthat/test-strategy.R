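test_that("window selection rule prefers the lightest near-optimal smoothing", {
    expect_equal(chooseWindow(c(3, 15, 47), c(1.00, 0.80, 0.79), 0.02), 15)
    expect_equal(chooseWindow(c(3, 15, 47), c(1.00, 0.85, 0.79), 0.02), 47)
    expect_equal(chooseWindow(c(3, 15), c(0.5, 0.5), 0), 3)
    expect_error(chooseWindow(c(3, 5), 1), "equal length")
})

test_that("window scan covers every odd width exactly once", {
    ds <- simulateCampaign(simParams(nSpectraRange = c(60L, 90L),
                                     tauRange = c(80, 150)),
                           nBatches = 3, validationBatches = 1, seed = 21)
    res <- windowScan(ds, kMin = 3, kMax = 21, A = 3)
    expect_equal(res$table$k, seq(3, 21, by = 2))
    expect_equal(nrow(res$table), (21 - 3) / 2 + 1)
    expect_false(anyDuplicated(res$table$k) > 0)
    expect_true(res$chosenK %in% res$table$k)
    # delay column mirrors the smoothing-delay arithmetic at dt = 5
    expect_equal(res$table$delay, (res$table$k - 1) / 2 * 5)
    expect_error(windowScan(ds, kMin = 4, kMax = 8), "odd")
    expect_error(windowScan(ds, kMin = 21, kMax = 3), "exceed")
})

test_that("cascade construction: one model per threshold, decreasing sizes", {
    ds <- simulateCampaign(deskParams(), nBatches = 5,
                           validationBatches = 0, seed = 22)
    casc <- buildCascade(ds, thresholds = c(NA, 20, 15, 10), A = 5, k = 15)
    expect_length(casc@models, 4L)
    ns <- vapply(casc@models, function(m) nrow(m@scores), integer(1))
    expect_true(all(diff(ns) <= 0))   # narrower range, fewer samples
    expect_error(buildCascade(ds, thresholds = c(NA, 10, 15)), "decreasing")
    expect_error(buildCascade(ds, thresholds = c(NA, 20, 0.01), A = 5),
                 "samples")
})

test_that("dynamic focusing walks the stages one way on a drying run", {
    ds <- simulateCampaign(deskParams(), nBatches = 5,
                           validationBatches = 0, seed = 23)
    casc <- buildCascade(ds, thresholds = c(NA, 20, 15, 10), A = 5, k = 15)
    sim <- simulateBatch(deskParams(), seed = 99, batchId = "MON")
    traj <- dynamicPredict(casc, sim@batch)
    expect_equal(nrow(traj), nSpectra(sim@batch))
    expect_true(all(diff(traj$stage) >= 0))
    expect_equal(traj$stage[nrow(traj)], 4L)    # ends in the driest stage
    expect_equal(traj$availableAt, traj$time + 35)  # k = 15 at 5-s steps
    # predictions track the true trajectory reasonably well
    expect_lt(sqrt(mean((traj$predicted - sim@moisture)^2)), 0.5)
})

test_that("narrow-range final stage beats the full-range model on dry samples", {
    ds <- simulateCampaign(deskParams(), seed = 24)
    p <- pairCampaign(ds, k = 15)
    full <- lboCV(p, A = 7)
    d10 <- lboCV(restrictRange(p, 10), A = 7)
    dry <- full@predictions$lod < 10
    rmseFullOnDry <- sqrt(mean((full@predictions$lod[dry] -
                                full@predictions$predicted[dry])^2))
    expect_lt(d10@rmse, rmseFullOnDry)
})

test_that("debounce blocks single-point threshold dips", {
    # two-stage cascade whose models simply read out channel 1, so the
    # prediction sequence equals a hand-built trajectory
    passthrough <- new("PLSModel", xCenter = rep(0, 4), yCenter = 0,
                       weights = matrix(c(1, 0, 0, 0), 4, 1),
                       xLoadings = matrix(c(1, 0, 0, 0), 4, 1),
                       yLoadings = 1, scores = matrix(0, 0, 1),
                       coefficients = matrix(c(1, 0, 0, 0), 4, 1), A = 1L)
    casc <- new("ModelCascade", upperLod = c(NA, 15), k = 1L,
                models = list(passthrough, passthrough), debounce = 3L)
    mkStream <- function(vals)
        SpectraBatch("HB", (seq_along(vals) - 1) * 5, toyWavelengths,
                     cbind(vals, 0, 0, 0))
    # one-point dip below 15 then recovery: no switch
    dip <- mkStream(c(20, 19, 14, 19, 20, 21, 22))
    expect_equal(dynamicPredict(casc, dip)$stage, rep(1L, 7))
    # three consecutive points below 15: switch after the third
    drop3 <- mkStream(c(20, 14, 13, 12, 20, 20))
    expect_equal(dynamicPredict(casc, drop3)$stage,
                 c(1L, 1L, 1L, 1L, 2L, 2L))
    # always above the threshold: stays in stage 1
    expect_equal(dynamicPredict(casc, mkStream(rep(25, 5)))$stage,
                 rep(1L, 5))
    expect_error(dynamicPredict(casc,
        SpectraBatch("E", numeric(), toyWavelengths,
                     matrix(numeric(), 0, 4))), "empty")
})

test_that("cascade JSON serialization round-trips predictions", {
    dir <- withr::local_tempdir()
    ds <- simulateCampaign(deskParams(), nBatches = 4,
                           validationBatches = 0, seed = 25)
    casc <- buildCascade(ds, thresholds = c(NA, 15), A = 4, k = 15)
    f <- file.path(dir, "cascade.json")
    writeCascade(casc, f)
    casc2 <- readCascade(f)
    expect_equal(casc2@upperLod, casc@upperLod)
    expect_equal(casc2@k, casc@k)
    sim <- simulateBatch(deskParams(), seed = 26)
    t1 <- dynamicPredict(casc, sim@batch)
    t2 <- dynamicPredict(casc2, sim@batch)
    expect_equal(t2$predicted, t1$predicted, tolerance = 1e-10)
    expect_equal(t2$stage, t1$stage)
})
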