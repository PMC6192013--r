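test_that("spectra CSV round-trips preserve the batch", {
    dir <- withr::local_tempdir()
    cases <- list(
        toyBatch("RT1", n = 3),
        SpectraBatch("one", 0, 1500, matrix(0.5, 1, 1)),
        SpectraBatch("neg", c(0, 5), c(1100, 1200),
                     matrix(c(-1.5, 2, -0.25, 3e-7), 2, 2)))
    for (b in cases) {
        f <- file.path(dir, paste0(batchId(b), ".csv"))
        writeSpectra(b, f)
        b2 <- readSpectra(f, batchId = batchId(b))
        expect_equal(acqTimes(b2), acqTimes(b), tolerance = 1e-12)
        expect_equal(wavelengths(b2), wavelengths(b), tolerance = 1e-12)
        expect_equal(intensities(b2), intensities(b), tolerance = 1e-12)
    }
})

test_that("readSpectra validates the file and sorts rows by time", {
    dir <- withr::local_tempdir()
    f <- file.path(dir, "s.csv")
    writeLines(c("time_s,1100,1200", "10,1,2", "5,3,4", "0,5,6"), f)
    b <- readSpectra(f)
    expect_equal(acqTimes(b), c(0, 5, 10))
    expect_equal(intensities(b)[1, ], c(5, 6))  # row followed its time

    writeLines(c("wl,1100,1200", "0,1,2"), f)
    expect_error(readSpectra(f), "header")
    writeLines(c("time_s,1100,abc", "0,1,2"), f)
    expect_error(readSpectra(f), "wavelength")
    writeLines(c("time_s,1200,1100", "0,1,2"), f)
    expect_error(readSpectra(f), "increasing")
})

test_that("reference CSV round-trips, flags and validation", {
    dir <- withr::local_tempdir()
    f <- file.path(dir, "r.csv")
    writeLines(c("sample_time_s,lod_percent", "100,20.0", "900,5.0"), f)
    r <- readReferences(f, batchId = "B")
    expect_equal(nSamples(r), 2L)
    expect_equal(lodValues(r), c(20, 5))
    expect_false(any(excluded(r)))

    writeLines(c("sample_time_s,lod_percent,excluded",
                 "100,20.0,0", "900,5.0,1"), f)
    expect_equal(excluded(readReferences(f)), c(FALSE, TRUE))

    writeLines(c("sample_time_s,lod_percent", "100,-1"), f)
    expect_error(readReferences(f), "negative LOD")

    r2 <- toyRefs(excluded = c(FALSE, TRUE, FALSE))
    writeReferences(r2, f)
    r3 <- readReferences(f, batchId = "T1")
    expect_equal(lodValues(r3), lodValues(r2), tolerance = 1e-12)
    expect_equal(excluded(r3), excluded(r2))
})

test_that("matchReferences pairs with the nearest spectrum, earlier on ties", {
    b <- SpectraBatch("B", c(0, 5, 10), c(1100, 1900),
                      matrix(as.numeric(1:6), 3, 2))
    expect_equal(intensities(matchReferences(
        b, ReferenceSet("B", 6, 12)))[1, ],
        intensities(b)[2, ])                   # t=6 -> t=5 spectrum
    expect_equal(intensities(matchReferences(
        b, ReferenceSet("B", 7.5, 12)))[1, ],
        intensities(b)[2, ])                   # tie 5/10 -> earlier
    p <- matchReferences(b, ReferenceSet("B", c(1, 9), c(3, 4),
                                         excluded = c(FALSE, TRUE)))
    expect_equal(nSamples(p), 1L)              # excluded sample dropped
    expect_equal(lodValues(p), 3)
})

test_that("matchReferences errors and warnings", {
    b <- toyBatch()
    expect_error(matchReferences(b, toyRefs(id = "OTHER")), "ids differ")
    expect_error(matchReferences(
        b, ReferenceSet("T1", c(1, 2), c(3, 4), excluded = c(TRUE, TRUE))),
        "non-excluded")
    # a sample beyond the span warns both about the span and the gap
    expect_warning(expect_warning(
        matchReferences(b, ReferenceSet("T1", 500, 5)), "outside"),
        "maxGap")
    expect_warning(matchReferences(b, ReferenceSet("T1", 41, 5),
                                   maxGap = 1e-6), "maxGap")
    # pairing keeps one row per non-excluded reference inside the span
    p <- matchReferences(b, toyRefs())
    expect_equal(nSamples(p), 3L)
})

test_that("augmentBatches stacks matrices in order with labels", {
    ds <- ProcessDataset(list(toyBatch("A", n = 3), toyBatch("B", n = 4)),
                         list())
    aug <- augmentBatches(ds, c("A", "B"))
    expect_equal(nrow(aug$matrix), 7L)
    expect_equal(aug$labels$batch, rep(c("A", "B"), c(3, 4)))
    expect_equal(aug$matrix[1:3, ], intensities(getBatch(ds, "A")))

    one <- augmentBatches(ds, "A")
    expect_identical(one$matrix, intensities(getBatch(ds, "A")))

    bad <- SpectraBatch("C", c(0, 5), toyWavelengths + c(0, 0, 0, 1),
                        matrix(0, 2, 4))
    ds2 <- ProcessDataset(list(toyBatch("A", n = 3), bad), list())
    expect_error(augmentBatches(ds2, c("A", "C")), "grid")
})

test_that("restrictRange filters strictly, idempotently and monotonically", {
    p <- PairedData(rep("B", 3), 1:3, c(25.9, 19.0, 9.5),
                    matrix(0, 3, 4), toyWavelengths)
    expect_equal(nSamples(restrictRange(p, 20)), 2L)
    expect_equal(lodValues(restrictRange(p, 19)), 9.5)  # strict <
    expect_identical(restrictRange(p, NULL), p)
    # idempotence and monotonicity over a grid of cutoffs
    for (a in c(5, 10, 15, 20, 30)) {
        r1 <- restrictRange(p, a)
        expect_equal(lodValues(restrictRange(r1, a)), lodValues(r1))
        for (b in c(5, 10, 15, 20, 30)[c(5, 10, 15, 20, 30) >= a])
            expect_true(all(lodValues(r1) %in%
                            lodValues(restrictRange(p, b))))
    }
    expect_error(restrictRange(p, -2), "positive")
})

test_that("campaign manifest round-trips with roles", {
    dir <- withr::local_tempdir()
    ds <- ProcessDataset(
        list(toyBatch("A"), toyBatch("B", seed = 2)),
        list(toyRefs("A"), toyRefs("B")),
        roles = c(A = "calibration", B = "validation"))
    man <- writeCampaign(ds, dir)
    ds2 <- readCampaign(man)
    expect_equal(batchIds(ds2), c("A", "B"))
    expect_equal(roleIds(ds2, "validation"), "B")
    expect_equal(intensities(getBatch(ds2, "A")),
                 intensities(getBatch(ds, "A")), tolerance = 1e-12)
    expect_equal(lodValues(getReferences(ds2, "B")),
                 lodValues(getReferences(ds, "B")), tolerance = 1e-12)
})
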