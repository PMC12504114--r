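## A small fitted model shared by several blocks.
alphaCoupledModel <- function(seed = 31, duration = 30, order = 9) {
    spec <- simSpec(nPerGroup = 1, nSources = 2, sampleRate = 100,
                    duration = duration, seed = seed,
                    couplings = list(list(source = 1, target = 2,
                                          band = "alpha", strength = 0.3)))
    rec <- simulateMvarCohort(spec)$recordings[[1]]
    fitMvar(rec$series, order = order, sampleRate = 100)
}

test_that("rPDC matches the brute-force renormalization to 1e-12", {
    m <- alphaCoupledModel()
    freqs <- c(2, 6, 10.5, 22, 37)
    sc <- computeRpdc(m, freqs = freqs)
    for (pair in list(c(2, 1), c(1, 2))) {
        want <- bruteRpdc(mvarCoef(m), noiseCov(m), m@regressorCov,
                          m@nSamples, 100, freqs, pair[1], pair[2])
        expect_equal(sc@values[pair[1], pair[2], ], want, tolerance = 1e-12)
    }
})

test_that("null rPDC is calibrated against the chi-squared(2) oracle", {
    v <- vapply(1:60, nullRpdcDraw, numeric(1))
    expect_gt(mean(v), 1.5); expect_lt(mean(v), 2.5)
    expect_gt(stats::ks.test(v, stats::pchisq, df = 2)$p.value, 0.01)
})

test_that("planted coupling direction is recovered at the coupling frequency", {
    hits <- 0
    for (s in 1:20) {
        spec <- simSpec(nPerGroup = 1, nSources = 2, sampleRate = 100,
                        duration = 20, seed = 400 + s,
                        couplings = list(list(source = 1, target = 2,
                                              band = "alpha", strength = 0.3)))
        rec <- simulateMvarCohort(spec)$recordings[[1]]
        sc <- computeRpdc(fitMvar(rec$series, order = 4, sampleRate = 100),
                          freqs = 10)
        hits <- hits + (sc@values[2, 1, 1] > sc@values[1, 2, 1])
    }
    expect_gte(hits, 18)
})

test_that("rPDC is invariant to a common amplitude rescaling", {
    spec <- simSpec(nPerGroup = 1, nSources = 2, sampleRate = 100,
                    duration = 20, seed = 32)
    rec <- simulateMvarCohort(spec)$recordings[[1]]
    s1 <- computeRpdc(fitMvar(rec$series, order = 3, sampleRate = 100))
    s2 <- computeRpdc(fitMvar(rec$series * 7.3, order = 3, sampleRate = 100))
    expect_equal(s1@values, s2@values, tolerance = 1e-9)
})

test_that("relabeling uninvolved channels leaves a pair's rPDC unchanged", {
    spec <- simSpec(nPerGroup = 1, nSources = 4, sampleRate = 100,
                    duration = 40, seed = 33,
                    couplings = list(list(source = 1, target = 2,
                                          band = "alpha", strength = 0.3)))
    rec <- simulateMvarCohort(spec)$recordings[[1]]
    x <- rec$series
    s1 <- computeRpdc(fitMvar(x, order = 4, sampleRate = 100), freqs = 10)
    s2 <- computeRpdc(fitMvar(x[, c(1, 2, 4, 3)], order = 4, sampleRate = 100),
                      freqs = 10)
    expect_equal(s1@values[2, 1, 1], s2@values[2, 1, 1], tolerance = 1e-9)
})

test_that("invalid rPDC requests fail loudly", {
    m <- alphaCoupledModel(duration = 10, order = 2)
    expect_error(computeRpdc(m, freqs = c(10, 60)), "strictly inside")
    spec <- simSpec(nPerGroup = 1, nSources = 2, sampleRate = 100,
                    duration = 10, seed = 34)
    rec <- simulateMvarCohort(spec)$recordings[[1]]
    m1 <- fitMvar(rec$series, order = 1, sampleRate = 100)
    expect_error(computeRpdc(m1), "order >= 2")
})

test_that("band averaging follows the printed band edges", {
    bands <- eegBands()
    expect_equal(bands$delta, c(1, 4)); expect_equal(bands$theta, c(4, 8))
    expect_equal(bands$alpha, c(8, 14)); expect_equal(bands$beta, c(14, 30))
    expect_equal(bands$gamma, c(30, 40))
    mk <- function(freqs, vals) {
        v <- array(NA_real_, c(2, 2, length(freqs)))
        v[2, 1, ] <- vals; v[1, 2, ] <- vals
        new("SpectralConnectivity", freqs = freqs, values = v,
            nSamples = 100L, sampleRate = 100, channelNames = c("a", "b"))
    }
    ## constant spectrum: every band equals the constant
    sc <- mk(seq(1, 40, 0.5), 3.7)
    bc <- bandAverage(sc)
    expect_true(all(bc@values[2, 1, ] == 3.7))
    ## two-point mean inside delta; band edges are left-closed/right-open
    sc2 <- mk(c(2, 3, 4, 8, 14, 30, 35, 40), c(2, 3, 4, 8, 14, 30, 35, 40))
    bc2 <- bandAverage(sc2)
    expect_equal(unname(bc2@values[2, 1, "delta"]), 2.5)      # 4 Hz belongs to theta
    expect_equal(unname(bc2@values[2, 1, "theta"]), 4)
    expect_equal(unname(bc2@values[2, 1, "gamma"]), mean(c(30, 35, 40)))  # 40 included
    ## a band with no grid point is an error naming the band
    expect_error(bandAverage(mk(seq(5, 40, 5), 1)), "delta")
    ## band mean lies between the in-band extremes
    sc3 <- mk(seq(1, 40, 0.5), runif(79))
    bc3 <- bandAverage(sc3)
    expect_true(all(bc3@values[2, 1, ] >= min(sc3@values[2, 1, ]) &
                    bc3@values[2, 1, ] <= max(sc3@values[2, 1, ])))
})

test_that("an alpha-coupled generator peaks in the alpha band", {
    m <- alphaCoupledModel(seed = 7, duration = 60, order = 9)
    bc <- bandAverage(computeRpdc(m))
    fwd <- bc@values[2, 1, ]
    expect_equal(names(which.max(fwd)), "alpha")
})
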