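# compounds present everywhere on the grid at a fixed abundance
persistentCompounds <- function(n, nLines, nCols, abundance = 5e4) {
    lapply(seq_len(n), function(k) {
        simCompound(
            compound_id = sprintf("p%02d", k), exact_mass = 300 + 10 * k,
            adduct = "[M+H]+",
            peaks = mspeaks(c(160 + k, 200 + k, 250 + k), c(100, 60, 30)),
            mask = matrix(TRUE, nLines, nCols),
            abundance = abundance * (1 + 0.01 * k))
    })
}

test_that("the same seed reproduces the run byte-for-byte", {
    cfg <- smallScene(nLines = 4, nCols = 6, n_cmp = 2, seed = 19)
    s1 <- simulateRun(cfg)
    s2 <- simulateRun(cfg)
    expect_equal(scanInfo(s1$run), scanInfo(s2$run))
    expect_identical(s1$truth, s2$truth)
    f1 <- withr::local_tempfile(fileext = ".mzML")
    f2 <- withr::local_tempfile(fileext = ".mzML")
    writeMzML(s1$run, f1); writeMzML(s2$run, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    # a different seed produces a different stream
    cfg2 <- smallScene(nLines = 4, nCols = 6, n_cmp = 2, seed = 20)
    expect_false(identical(scanInfo(simulateRun(cfg2)$run),
                           scanInfo(s1$run)))
})

test_that("exclusion list suppresses precursor selection entirely", {
    mkcfg <- function(minint, excl = numeric(0)) {
        simConfig(nLines = 2, nCols = 5, compounds = list(),
                  matrixIons = data.frame(mz = 265.96,
                                          off_tissue_intensity = 4e4,
                                          on_tissue_intensity = 4e4),
                  minPrecursorIntensity = minint, exclusionList = excl,
                  dynamicExclusion = NULL, noiseCv = 0.05, seed = 2)
    }
    # matrix ion below the minimum precursor intensity: MS1 scans only
    quiet <- simulateRun(mkcfg(minint = 1e6))
    expect_equal(sum(scanInfo(quiet$run)$ms_level == 2L), 0L)
    # above threshold: matrix MS2 scans appear
    loud <- simulateRun(mkcfg(minint = 1e3))
    expect_gt(sum(scanInfo(loud$run)$ms_level == 2L), 0L)
    # same scene with the matrix m/z on the exclusion list: zero MS2
    masked <- simulateRun(mkcfg(minint = 1e3, excl = 265.96))
    expect_equal(sum(scanInfo(masked$run)$ms_level == 2L), 0L)
})

test_that("sequential mode emits exactly TopN MS2 per cycle when saturated", {
    nL <- 3L; nC <- 10L
    cfg <- simConfig(nLines = nL, nCols = nC,
                     compounds = persistentCompounds(12, nL, nC),
                     mode = "sequential", topN = 4,
                     dynamicExclusion = NULL, seed = 6)
    sim <- simulateRun(cfg)
    si <- scanInfo(sim$run)
    ms1_pos <- which(si$ms_level == 1L)
    # MS2 count between consecutive MS1 scans
    per_cycle <- diff(c(ms1_pos, nrow(si) + 1L)) - 1L
    expect_true(all(per_cycle == 4L))
    expect_equal(length(per_cycle), nL * nC)
})

test_that("sequential MS2 per cycle never exceeds TopN", {
    cfg <- smallScene(nLines = 5, nCols = 8, n_cmp = 4, seed = 14,
                      mode = "sequential")
    sim <- simulateRun(cfg)
    si <- scanInfo(sim$run)
    ms1_pos <- which(si$ms_level == 1L)
    per_cycle <- diff(c(ms1_pos, nrow(si) + 1L)) - 1L
    expect_true(all(per_cycle <= cfg@topN))
})

test_that("parallel MS2 scans are followed by two surveys except at the end", {
    cfg <- smallScene(nLines = 4, nCols = 6, n_cmp = 3, seed = 9,
                      mode = "parallel")
    sim <- simulateRun(cfg)
    si <- scanInfo(sim$run)
    ms2_pos <- which(si$ms_level == 2L)
    n_following_ms1 <- vapply(ms2_pos, function(i)
        sum(si$ms_level[seq_len(nrow(si)) > i] == 1L), integer(1))
    # all but those in the final cycle see >= 2 later surveys
    last_ms1 <- max(which(si$ms_level == 1L))
    expect_true(all(n_following_ms1[ms2_pos < last_ms1 - 1] >= 2))
})

test_that("dynamic exclusion caps selections per window and enforces holdoff", {
    nL <- 2L; nC <- 50L
    de <- c(max_occurrences = 2, occurrence_window_s = 3,
            exclusion_duration_s = 20)
    cfg <- simConfig(nLines = nL, nCols = nC,
                     compounds = persistentCompounds(3, nL, nC),
                     mode = "sequential", topN = 4, dynamicExclusion = de,
                     matrixIons = data.frame(mz = numeric(),
                         off_tissue_intensity = numeric(),
                         on_tissue_intensity = numeric()),
                     seed = 23)
    sim <- simulateRun(cfg)
    m <- merge(sim$truth,
               data.frame(scan_index = scanInfo(sim$run)$index,
                          t = scanInfo(sim$run)$time_s),
               by = "scan_index")
    for (cl in split(m$t, m$compound_id)) {
        t <- sort(cl)
        # (a) no window of occurrence_window_s holds > max_occurrences
        for (i in seq_along(t))
            expect_lte(sum(t >= t[i] - de[["occurrence_window_s"]] &
                           t <= t[i]), de[["max_occurrences"]])
        # (b) after the capping occurrence, silence for the exclusion period
        if (length(t) > 2) {
            trigger <- t[2]
            nxt <- t[t > trigger]
            if (length(nxt))
                expect_gte(min(nxt),
                           trigger + de[["exclusion_duration_s"]] - 1e-9)
        }
    }
})

test_that("parallel acquisition yields at least as many MS2 as sequential", {
    for (seed in c(1, 5, 17)) {
        cmps <- simulatedCompounds(4, 6, 10, seed = seed)
        n_ms2 <- sapply(c("parallel", "sequential"), function(mode) {
            cfg <- simConfig(nLines = 6, nCols = 10, compounds = cmps,
                             mode = mode, seed = seed)
            sum(scanInfo(simulateRun(cfg)$run)$ms_level == 2L)
        })
        expect_gte(n_ms2[["parallel"]], n_ms2[["sequential"]])
    }
})

test_that("all emitted peaks respect the configured mass range", {
    cfg <- smallScene(nLines = 4, nCols = 6, n_cmp = 3, seed = 2,
                      massRange = c(150, 900))
    sim <- simulateRun(cfg)
    for (i in seq_len(nScans(sim$run))) {
        p <- scanPeaks(sim$run, i)
        if (nrow(p))
            expect_true(all(p[, 1] >= 150 & p[, 1] <= 900))
    }
})

test_that("every emitted MS2 scan has a ground-truth row", {
    cfg <- smallScene(nLines = 5, nCols = 7, n_cmp = 3, seed = 33)
    sim <- simulateRun(cfg)
    si <- scanInfo(sim$run)
    expect_setequal(sim$truth$scan_index, si$index[si$ms_level == 2L])
})

test_that("decoy libraries are deterministic and score poorly", {
    cfg <- smallScene(nLines = 8, nCols = 10, n_cmp = 5, seed = 29)
    d1 <- makeLibrary(cfg, decoy = TRUE)
    d2 <- makeLibrary(cfg, decoy = TRUE)
    expect_equal(libraryEntries(d1), libraryEntries(d2))
    for (i in seq_len(length(d1)))
        expect_equal(libraryPeaks(d1, i), libraryPeaks(d2, i))
    # true library entries carry the ground-truth spectra
    lib <- makeLibrary(cfg)
    for (i in seq_along(cfg@compounds))
        expect_equal(libraryPeaks(lib, i), cfg@compounds[[i]]$peaks,
                     ignore_attr = TRUE)
    # decoy fragments share no structure with the true ones
    sim <- simulateRun(cfg)
    ann <- annotateRun(sim$run, cfg@geometry, sim$log, d1, "parallel", 5)
    if (nrow(ann)) expect_lt(stats::median(ann$cosine_score), 0.5)
})

test_that("exclusion-region mask honors the margin in micrometres", {
    roi <- matrix(FALSE, 10, 10)
    roi[4:6, 4:6] <- TRUE
    # margin 0: exact complement of the ROI
    expect_equal(exclusionRegionMask(roi, 0, 100), !roi)
    # brute-force distance check at margin 300 um with 100 um pixels
    m <- exclusionRegionMask(roi, 300, 100)
    idx <- which(roi, arr.ind = TRUE)
    for (r in 1:10) for (cc in 1:10) {
        d <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - cc)^2)) * 100
        expect_equal(m[r, cc], !roi[r, cc] && d >= 300)
    }
    # a 2 mm margin on this small grid excludes everything
    expect_false(any(exclusionRegionMask(roi, 2000, 100)))
    # ROI covering the whole grid leaves nothing
    expect_false(any(exclusionRegionMask(matrix(TRUE, 5, 5), 0, 100)))
})

test_that("writeSimulatedRun emits the three pipeline inputs plus truth", {
    d <- withr::local_tempdir()
    cfg <- smallScene(nLines = 3, nCols = 4, n_cmp = 2, seed = 40)
    writeSimulatedRun(cfg, d)
    expect_true(all(file.exists(file.path(d,
        c("run.mzML", "positions.xml", "truth.tsv", "config.json")))))
    expect_true(file.exists(file.path(d, "library", "true.msp")))
    run <- readMzML(file.path(d, "run.mzML"))
    expect_gt(nScans(run), 0)
    lib <- readLibraryFolder(file.path(d, "library"))
    expect_equal(length(lib), 2L)
})
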