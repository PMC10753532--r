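# Fixture builders and independent brute-force oracles shared by the suite.

# hand-build a run from compact scan descriptions:
# list(list(t=, level=, peaks=matrix, prec=, iso=), ...)
makeRun <- function(scans, polarity = "positive", massRange = NULL) {
    si <- data.frame(
        time_s = vapply(scans, `[[`, numeric(1), "t"),
        ms_level = vapply(scans, `[[`, numeric(1), "level"),
        precursor_mz = vapply(scans, function(s)
            if (is.null(s$prec)) NA_real_ else s$prec, numeric(1)),
        isolation_width = vapply(scans, function(s)
            if (is.null(s$iso)) NA_real_ else s$iso, numeric(1)))
    peaks <- lapply(scans, function(s) {
        p <- s$peaks
        if (is.null(p)) p <- matrix(numeric(0), 0, 2)
        as.matrix(p)
    })
    MsiRun(si, peaks, polarity = polarity, massRange = massRange)
}

mspeaks <- function(mz, intensity) cbind(mz = mz, intensity = intensity)

# a log with one line covering [0, t_end) and the laser on throughout
simpleLog <- function(t_end = 100, laser_on = 0, laser_off = t_end) {
    PositionLog(
        lines = data.frame(line_index = 0L, t_start_s = 0, t_end_s = t_end,
                           y_um = 0),
        laserIntervals = data.frame(t_on_s = laser_on, t_off_s = laser_off))
}

# independent brute-force MS2 quality reference: plain loops over the full
# stream, no shared code with assessRun
bruteForceQc <- function(run, log, mode, tol_ppm) {
    si <- scanInfo(run)
    li <- laserIntervals(log)
    window <- if (mode == "parallel") 2L else 1L
    out <- NULL
    for (i in seq_len(nrow(si))) {
        if (si$ms_level[i] != 2) next
        t <- si$time_s[i]
        laser <- FALSE
        for (k in seq_len(nrow(li)))
            if (t >= li$t_on_s[k] && t < li$t_off_s[k]) laser <- TRUE
        pmz <- si$precursor_mz[i]
        found <- 0L
        consistent <- TRUE
        j <- i + 1L
        while (j <= nrow(si) && found < window) {
            if (si$ms_level[j] == 1) {
                found <- found + 1L
                p <- scanPeaks(run, j)
                hit <- FALSE
                for (r in seq_len(nrow(p)))
                    if (abs(p[r, 1] - pmz) * 1e6 / pmz <= tol_ppm)
                        hit <- TRUE
                if (!hit) consistent <- FALSE
            }
            j <- j + 1L
        }
        if (found < window) consistent <- FALSE
        out <- rbind(out, data.frame(scan_index = si$index[i],
                                     laser_ok = laser,
                                     consistency_ok = consistent,
                                     valid = laser && consistent))
    }
    if (is.null(out))
        out <- data.frame(scan_index = integer(), laser_ok = logical(),
                          consistency_ok = logical(), valid = logical())
    out
}

# exhaustive double-loop exact-mass matching reference
bruteForceMatch <- function(hypotheses, lib, tol_ppm) {
    en <- libraryEntries(lib)
    hits <- NULL
    for (h in seq_len(nrow(hypotheses))) {
        for (e in seq_len(nrow(en))) {
            err <- (hypotheses$neutral_mass[h] - en$exact_mass[e]) /
                en$exact_mass[e] * 1e6
            adOk <- is.na(en$adduct[e]) ||
                en$adduct[e] == hypotheses$adduct[h]
            if (abs(err) <= tol_ppm && adOk)
                hits <- rbind(hits, data.frame(
                    entry = e, adduct = hypotheses$adduct[h],
                    ppm_error = err))
        }
    }
    hits
}

# random small run for QC property tests: MS1/MS2 mix, some precursors
# persistent, some not, laser covering part of the run
randomQcRun <- function(n_scans = 60) {
    n <- sample(10:n_scans, 1)
    t <- sort(runif(n, 0, 50))
    level <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.6, 0.4))
    level[1] <- 1L
    basemz <- runif(6, 200, 800)
    peaks <- vector("list", n)
    prec <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (level[i] == 1L) {
            present <- basemz[runif(6) < 0.7]
            jit <- present * (1 + rnorm(length(present), 0, 2e-6))
            o <- order(jit)
            peaks[[i]] <- cbind(jit[o], runif(length(present), 10, 100)[o])
        } else {
            pm <- sample(basemz, 1)
            # sometimes shift the precursor far off so consistency fails
            if (runif(1) < 0.3) pm <- pm * (1 + 30e-6)
            prec[i] <- pm
            peaks[[i]] <- cbind(pm * 0.7, 50)
        }
    }
    run <- makeRun(lapply(seq_len(n), function(i)
        list(t = t[i], level = level[i], peaks = peaks[[i]],
             prec = if (level[i] == 2L) prec[i] else NULL,
             iso = if (level[i] == 2L) 1 else NULL)))
    log <- simpleLog(t_end = 60, laser_on = 0, laser_off = runif(1, 10, 55))
    list(run = run, log = log)
}

# small deterministic simulated scene shared by several test files
smallScene <- function(nLines = 8, nCols = 10, n_cmp = 3, seed = 5,
                       mode = "parallel", ...) {
    cmps <- simulatedCompounds(n_cmp, nLines, nCols, seed = seed)
    simConfig(nLines = nLines, nCols = nCols, compounds = cmps,
              mode = mode, seed = seed, ...)
}
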