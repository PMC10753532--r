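test_that("adduct set per polarity and hypothesis round-trip", {
    pos <- neutralHypotheses(500, "positive")
    expect_setequal(pos$adduct, c("[M+H]+", "[M+Na]+"))
    neg <- neutralHypotheses(500, "negative")
    expect_setequal(neg$adduct, c("[M-H]-", "[M+Cl]-"))
    # re-adding the shift recovers the precursor to 1e-9 Da
    for (h in seq_len(nrow(pos)))
        expect_equal(pos$neutral_mass[h] + pos$mass_shift_da[h], 500,
                     tolerance = 1e-12)
    for (h in seq_len(nrow(neg)))
        expect_equal(neg$neutral_mass[h] + neg$mass_shift_da[h], 500,
                     tolerance = 1e-12)
    # degenerate precursor: all hypotheses non-positive
    expect_equal(nrow(neutralHypotheses(1.007276, "positive")), 0L)
})

test_that("ppm error has the documented sign convention and magnitude", {
    expect_equal(ppmError(500, 500), 0)
    expect_equal(ppmError(500.0025, 500), 5, tolerance = 1e-9)
    expect_equal(ppmError(499.9975, 500), -5, tolerance = 1e-9)
    expect_error(ppmError(500, 0))
    expect_error(ppmError(500, -1))
})

makeTestLib <- function(masses, adducts = NA, ids = NULL) {
    n <- length(masses)
    if (is.null(ids)) ids <- sprintf("c%02d", seq_len(n))
    SpectralLibrary(
        entries = data.frame(
            compound_id = ids, name = ids, formula = NA_character_,
            exact_mass = masses, adduct = rep_len(adducts, n),
            collision_energy = NA_real_, provenance = "experimental",
            stringsAsFactors = FALSE),
        peaks = replicate(n, mspeaks(c(150.5, 200.5), c(100, 50)),
                          simplify = FALSE))
}

test_that("exact-mass matching respects tolerance, adducts and isomers", {
    pm <- 501.00727646          # M = 500 under [M+H]+
    hyp <- neutralHypotheses(pm, "positive")
    # entry exactly at M matches with ppm_error 0
    lib <- makeTestLib(c(500, 500, 500 * (1 + 20e-6), 490),
                       adducts = c(NA, NA, NA, NA))
    m <- matchLibrary(hyp, lib, tol_ppm = 5)
    expect_setequal(m$entry, c(1L, 2L))   # two isomers both matched
    expect_equal(m$ppm_error[m$entry == 1], 0, tolerance = 1e-6)
    # entry 20 ppm away excluded at 5 ppm
    expect_false(3L %in% m$entry)
    # declared adducts restrict eligibility
    lib2 <- makeTestLib(c(500, 500), adducts = c("[M+H]+", "[M+Na]+"))
    m2 <- matchLibrary(hyp, lib2, tol_ppm = 5)
    expect_equal(m2$entry, 1L)
    expect_equal(m2$adduct, "[M+H]+")
})

test_that("matchLibrary agrees with the exhaustive double-loop reference", {
    set.seed(31)
    masses <- runif(500, 150, 900)
    # salt the library with near-duplicates a few ppm apart
    masses <- c(masses, masses[1:50] * (1 + runif(50, -1e-5, 1e-5)))
    lib <- makeTestLib(masses)
    for (rep in 1:20) {
        pm <- runif(1, 160, 900)
        hyp <- neutralHypotheses(pm, sample(c("positive", "negative"), 1))
        mine <- matchLibrary(hyp, lib, tol_ppm = 5)
        ref <- bruteForceMatch(hyp, lib, tol_ppm = 5)
        if (is.null(ref)) {
            expect_equal(nrow(mine), 0L)
        } else {
            key <- function(d) sort(paste(d$entry, d$adduct))
            expect_equal(key(mine), key(ref))
        }
    }
})

test_that("shrinking the tolerance never increases the candidate count", {
    set.seed(13)
    lib <- makeTestLib(runif(300, 150, 900))
    for (rep in 1:10) {
        hyp <- neutralHypotheses(runif(1, 200, 880), "positive")
        n_prev <- Inf
        for (tol in c(20, 10, 5, 2, 1)) {
            n <- nrow(matchLibrary(hyp, lib, tol))
            expect_lte(n, n_prev)
            n_prev <- n
        }
    }
})

test_that("cosine score satisfies its analytic identities", {
    a <- mspeaks(c(100, 200, 300), c(10, 40, 5))
    expect_equal(cosineScore(a, a), 1)
    # disjoint spectra -> 0
    b <- mspeaks(c(150, 250), c(10, 10))
    expect_equal(cosineScore(a, b), 0)
    # hand-computed worked example: (1*2 + 2*1) / (sqrt(5)*sqrt(5)) = 0.8
    e <- mspeaks(c(100, 200), c(1, 2))
    l <- mspeaks(c(100, 200), c(2, 1))
    expect_equal(cosineScore(e, l), 0.8)
    expect_error(cosineScore(a, mspeaks(numeric(0), numeric(0))), "empty")
})

test_that("cosine score is symmetric and scale-invariant", {
    set.seed(9)
    for (rep in 1:20) {
        n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
        a <- mspeaks(sort(runif(n1, 100, 500)), runif(n1, 1, 100))
        b <- mspeaks(sort(runif(n2, 100, 500)), runif(n2, 1, 100))
        s <- cosineScore(a, b)
        expect_gte(s, 0); expect_lte(s, 1)
        expect_equal(cosineScore(b, a), s, tolerance = 1e-12)
        a10 <- a; a10[, 2] <- a10[, 2] * 10
        expect_equal(cosineScore(a10, b), s, tolerance = 1e-12)
    }
})

test_that("fragment pairing tolerates ppm-scale m/z differences", {
    a <- mspeaks(c(100, 200), c(1, 2))
    b <- mspeaks(c(100, 200) * (1 + 3e-6), c(2, 1))  # +3 ppm, under floor
    expect_equal(cosineScore(a, b), 0.8, tolerance = 1e-6)
    # beyond both the ppm window and the Da floor: no pairs
    b2 <- mspeaks(c(100.05, 200.05), c(2, 1))
    expect_equal(cosineScore(a, b2, frag_tol_ppm = 5, frag_tol_da = 0.01), 0)
})

test_that("best-hit retention takes the top score with deterministic ties", {
    lib <- SpectralLibrary(
        entries = data.frame(
            compound_id = c("a", "b", "c", "d"), name = c("a", "b", "c", "d"),
            formula = NA_character_, exact_mass = rep(500, 4),
            adduct = NA_character_, collision_energy = NA_real_,
            provenance = "experimental", stringsAsFactors = FALSE),
        peaks = list(
            mspeaks(c(110, 210), c(5, 1)),    # low score
            mspeaks(c(100, 200), c(10, 20)),  # identical shape -> 1.0
            mspeaks(c(100, 250), c(10, 20)),  # partial
            mspeaks(c(100, 200), c(10, 20)))) # tie with b
    emp <- mspeaks(c(100, 200), c(10, 20))
    cand <- data.frame(entry = 1:4, compound_id = c("a", "b", "c", "d"),
                       adduct = "[M+H]+", neutral_mass_hypothesis = 500,
                       ppm_error = c(1, 3, 0.5, 1), formula = NA,
                       provenance = "experimental",
                       stringsAsFactors = FALSE)
    best <- annotateScan(emp, cand, lib)
    # b and d tie at cosine 1.0; d has the smaller |ppm_error|
    expect_equal(best$compound_id, "d")
    expect_equal(best$cosine_score, 1)
    # equal scores and equal ppm -> lexicographic compound_id
    cand$ppm_error <- c(1, 1, 0.5, 1)
    expect_equal(annotateScan(emp, cand, lib)$compound_id, "b")
    expect_null(annotateScan(emp, cand[0, ], lib))
})

test_that("annotateRun recovers planted compounds on simulated data", {
    cfg <- smallScene(nLines = 10, nCols = 12, n_cmp = 6, seed = 21)
    sim <- simulateRun(cfg)
    lib <- makeLibrary(cfg)
    ann <- annotateRun(sim$run, cfg@geometry, sim$log, lib, "parallel", 5)
    expect_gt(nrow(ann), 0)
    m <- merge(ann, sim$truth, by = "scan_index")
    planted <- m[!grepl("^matrix", m$compound_id.y), ]
    expect_gt(nrow(planted), 0)
    expect_true(all(planted$compound_id.x == planted$compound_id.y))
    # pixel assignment matches the simulator's ground truth
    expect_equal(planted$pixel_row.x, planted$pixel_row.y)
    expect_equal(planted$pixel_col.x, planted$pixel_col.y)
    expect_true(all(abs(ann$ppm_error) <= 5))
    expect_true(all(ann$cosine_score >= 0 & ann$cosine_score <= 1))
})

test_that("per-compound summary aggregates events, scores and adducts", {
    rec <- data.frame(
        scan_index = 1:4, precursor_mz = 1, adduct = c("[M+H]+", "[M+Na]+",
        "[M+H]+", "[M+H]+"), neutral_mass_hypothesis = 1,
        compound_id = c("x", "x", "x", "y"), formula = NA,
        ppm_error = 0, cosine_score = c(0.7, 0.9, 0.8, 0.5),
        provenance = "experimental", pixel_row = 0L, pixel_col = 0L,
        stringsAsFactors = FALSE)
    s <- compoundSummary(rec)
    expect_equal(s$compound_id, c("x", "y"))
    expect_equal(s$n_events, c(3L, 1L))
    expect_equal(s$best_score, c(0.9, 0.5))
    expect_equal(s$adducts[1], "[M+H]+,[M+Na]+")
})
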