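test_that("mzML round trip preserves scans, times, precursors and peaks", {
    cfg <- smallScene(nLines = 4, nCols = 6, n_cmp = 2)
    sim <- simulateRun(cfg)
    f <- withr::local_tempfile(fileext = ".mzML")
    writeMzML(sim$run, f)
    back <- readMzML(f)
    si1 <- scanInfo(sim$run); si2 <- scanInfo(back)
    expect_equal(nScans(back), nScans(sim$run))
    expect_identical(si2$ms_level, si1$ms_level)
    expect_equal(si2$time_s, si1$time_s, tolerance = 1e-6)
    expect_equal(si2$precursor_mz, si1$precursor_mz, tolerance = 1e-6)
    expect_equal(si2$isolation_width, si1$isolation_width, tolerance = 1e-6)
    expect_equal(polarity(back), polarity(sim$run))
    expect_equal(massRange(back), massRange(sim$run))
    for (i in seq_len(nScans(back)))
        expect_equal(scanPeaks(back, i), scanPeaks(sim$run, i),
                     tolerance = 1e-6, ignore_attr = TRUE)
    ms2 <- si2$ms_level == 2L
    expect_true(all(is.finite(si2$precursor_mz[ms2])))
    expect_true(all(is.na(si2$precursor_mz[!ms2])))
})

test_that("an mzML with zero scans reads as an empty run without error", {
    f <- withr::local_tempfile(fileext = ".mzML")
    writeMzML(MsiRun(data.frame(time_s = numeric(), ms_level = integer()),
                     list()), f)
    run <- readMzML(f)
    expect_s4_class(run, "MsiRun")
    expect_equal(nScans(run), 0L)
})

test_that("malformed XML and out-of-order scan streams are rejected", {
    f <- withr::local_tempfile(fileext = ".mzML")
    writeLines("<mzML><run>", f)
    expect_error(readMzML(f), "malformed")
    expect_error(readMzML(file.path(tempdir(), "does_not_exist.mzML")),
                 "no such file")
    # out-of-order times violate the scan-stream invariant at construction
    expect_error(
        makeRun(list(list(t = 2, level = 1, peaks = mspeaks(200, 5)),
                     list(t = 1, level = 1, peaks = mspeaks(200, 5)))),
        "non-decreasing")
})

test_that("profile-mode spectra are rejected, not silently centroided", {
    cfg <- smallScene(nLines = 2, nCols = 3, n_cmp = 1)
    sim <- simulateRun(cfg)
    f <- withr::local_tempfile(fileext = ".mzML")
    writeMzML(sim$run, f)
    txt <- readLines(f)
    # flip the pwiz centroid-spectrum cvParam into profile spectrum
    txt <- gsub("MS:1000127", "MS:1000128", txt, fixed = TRUE)
    txt <- gsub("centroid spectrum", "profile spectrum", txt, fixed = TRUE)
    f2 <- withr::local_tempfile(fileext = ".mzML")
    writeLines(txt, f2)
    expect_error(readMzML(f2), "profile")
})

test_that("position log round-trips and validates interval sanity", {
    log <- PositionLog(
        lines = data.frame(line_index = 0:1, t_start_s = c(0, 15),
                           t_end_s = c(12, 27), y_um = c(0, 100)),
        laserIntervals = data.frame(t_on_s = c(0, 15),
                                    t_off_s = c(12, 27)))
    f <- withr::local_tempfile(fileext = ".xml")
    writePositionLog(log, f)
    back <- readPositionLog(f)
    expect_equal(logLines(back), logLines(log))
    expect_equal(laserIntervals(back), laserIntervals(log))

    # inverted laser interval
    expect_error(PositionLog(
        lines = data.frame(line_index = 0L, t_start_s = 0, t_end_s = 1,
                           y_um = 0),
        laserIntervals = data.frame(t_on_s = 5, t_off_s = 2)),
        "t_on_s < t_off_s")
    # overlapping laser intervals
    expect_error(PositionLog(
        lines = data.frame(line_index = 0L, t_start_s = 0, t_end_s = 1,
                           y_um = 0),
        laserIntervals = data.frame(t_on_s = c(0, 3), t_off_s = c(5, 8))),
        "non-overlapping")

    # empty laser element: laser never active
    log0 <- PositionLog(
        lines = data.frame(line_index = 0L, t_start_s = 0, t_end_s = 10,
                           y_um = 0),
        laserIntervals = data.frame(t_on_s = numeric(), t_off_s = numeric()))
    f0 <- withr::local_tempfile(fileext = ".xml")
    writePositionLog(log0, f0)
    back0 <- readPositionLog(f0)
    expect_false(any(laserActive(c(0, 5, 9.9), back0)))
})

test_that("MSP and XML library dialects yield identical entries", {
    cfg <- smallScene(n_cmp = 4)
    lib <- makeLibrary(cfg)
    d <- withr::local_tempdir()
    writeMsp(lib, file.path(d, "lib.msp"))
    writeLibraryXml(lib, file.path(d, "lib.xml"))
    msp <- readMsp(file.path(d, "lib.msp"))
    xml <- readLibraryXml(file.path(d, "lib.xml"))
    expect_equal(libraryEntries(msp), libraryEntries(xml))
    for (i in seq_len(length(msp)))
        expect_equal(libraryPeaks(msp, i), libraryPeaks(xml, i),
                     tolerance = 1e-9, ignore_attr = TRUE)
    # folder reader concatenates both files
    both <- readLibraryFolder(d)
    expect_equal(length(both), 2L * length(lib))
})

test_that("library reading keeps duplicates and rejects degenerate entries", {
    d <- withr::local_tempdir()
    # same compound at two collision energies -> two entries retained
    writeLines(c(
        "NAME: alanine", "ID: ala", "EXACTMASS: 89.047679",
        "ADDUCT: [M+H]+", "COLLISIONENERGY: 20", "Num Peaks: 2",
        "44.05 100", "62.06 40", "",
        "NAME: alanine", "ID: ala", "EXACTMASS: 89.047679",
        "ADDUCT: [M+H]+", "COLLISIONENERGY: 40", "Num Peaks: 2",
        "44.05 100", "45.03 80", ""), file.path(d, "dup.msp"))
    lib <- readMsp(file.path(d, "dup.msp"))
    expect_equal(length(lib), 2L)
    expect_equal(libraryEntries(lib)$collision_energy, c(20, 40))

    # empty peak list is a validation error
    writeLines(c("NAME: ghost", "EXACTMASS: 100.0", "Num Peaks: 0", ""),
               file.path(d, "bad.msp"))
    expect_error(readMsp(file.path(d, "bad.msp")), "non-empty")

    # unparseable file names the file and position
    writeLines(c("NAME: broken", "Num Peaks: 2", "not a peak line"),
               file.path(d, "broken.msp"))
    expect_error(readMsp(file.path(d, "broken.msp")), "broken.msp")

    expect_error(readLibraryFolder(withr::local_tempdir()),
                 "no library files")
})

test_that("annotation table round-trips losslessly, including zero rows", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeAnnotationTable(NULL, f)
    expect_equal(length(readLines(f)), 1L)  # header only
    empty <- readAnnotationTable(f)
    expect_equal(nrow(empty), 0L)

    rec <- data.frame(
        scan_index = c(4L, 9L), precursor_mz = c(301.1412, 523.4519),
        adduct = c("[M+H]+", "[M+Na]+"),
        neutral_mass_hypothesis = c(300.1339, 500.4627),
        compound_id = c("cpd001", "cpd002"),
        formula = c("C12H20N2O7", NA),
        ppm_error = c(1.25, -3.5), cosine_score = c(0.97, 0.81),
        provenance = c("experimental", "predicted"),
        pixel_row = c(0L, 3L), pixel_col = c(7L, 2L),
        stringsAsFactors = FALSE)
    writeAnnotationTable(rec, f)
    expect_equal(length(readLines(f)), 3L)
    back <- readAnnotationTable(f)
    expect_equal(back, rec, tolerance = 1e-9)
})
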