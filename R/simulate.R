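#' Define a planted compound for the simulator
#'
#' @param compound_id,name,formula identity of the compound.
#' @param exact_mass neutral monoisotopic mass, Da.
#' @param adduct the adduct under which it ionizes (one of the labels in
#'   \code{\link{adductTable}}).
#' @param peaks fragment spectrum, two-column \code{(mz, relative
#'   intensity)} matrix sorted by m/z.
#' @param mask logical phantom matrix (grid-shaped) giving the compound's
#'   spatial support.
#' @param abundance MS1 peak intensity at full mask (arbitrary counts).
#' @return list describing the compound, for \code{\link{simConfig}}.
#' @export
simCompound <- function(compound_id, name = compound_id, formula = NA,
                        exact_mass, adduct, peaks, mask, abundance) {
    peaks <- as.matrix(peaks)
    colnames(peaks) <- c("mz", "intensity")
    list(compound_id = compound_id, name = name,
         formula = as.character(formula), exact_mass = exact_mass,
         adduct = adduct, peaks = peaks, mask = mask != 0,
         abundance = abundance)
}

#' Configure a simulated MSI-DDA acquisition
#'
#' Defaults reproduce the acquisition regime the pipeline targets: 100 um
#' pixels at a 0.6 s full-scan cycle (plate velocity 166.7 um/s), positive
#' mode, m/z 150-900, isolation window 1 Th, dynamic exclusion after 2
#' occurrences within 3 s for 5400 s, and TopN = 4 MS2 per cycle in
#' sequential mode. Matrix background defaults to two CHCA-type ions
#' (m/z 190.0499 and 265.96) that are brighter off-tissue than on-tissue.
#'
#' @param nLines,nCols pixel grid dimensions.
#' @param compounds list of \code{\link{simCompound}} entries.
#' @param geometry a \linkS4class{RasterGeometry} (defaults as above).
#' @param polarity "positive" or "negative".
#' @param massRange acquisition m/z window.
#' @param mode "parallel" or "sequential".
#' @param topN MS2 per cycle in sequential mode.
#' @param minPrecursorIntensity precursor-eligibility intensity floor.
#' @param isolationWidth precursor isolation window, Th.
#' @param dynamicExclusion named numeric(3) (\code{max_occurrences},
#'   \code{occurrence_window_s}, \code{exclusion_duration_s}), or NULL to
#'   disable.
#' @param exclusionList m/z values never selected as precursors.
#' @param matrixIons data.frame \code{mz}, \code{off_tissue_intensity},
#'   \code{on_tissue_intensity}.
#' @param tissueMask logical grid where matrix ions use their on-tissue
#'   intensity; defaults to the union of compound masks.
#' @param noiseCv CV of multiplicative log-normal intensity noise.
#' @param mzJitterPpm SD of Gaussian m/z jitter, ppm.
#' @param tolPpm ppm tolerance used by the DDA engine for exclusion-list
#'   matching and dynamic-exclusion m/z clustering.
#' @param interLineGap stage retrace time between lines, s.
#' @param laserMargin laser shut-off before each line end, s.
#' @param seed RNG seed.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nLines, nCols, compounds = list(),
                      geometry = rasterGeometry(
                          plateVelocity = 100 / 0.6, cyclePeriod = 0.6,
                          nLines = nLines, nCols = nCols),
                      polarity = "positive", massRange = c(150, 900),
                      mode = c("parallel", "sequential"), topN = 4,
                      minPrecursorIntensity = 500, isolationWidth = 1,
                      dynamicExclusion = c(max_occurrences = 2,
                                           occurrence_window_s = 3,
                                           exclusion_duration_s = 5400),
                      exclusionList = numeric(0),
                      matrixIons = data.frame(
                          mz = c(190.0499, 265.96),
                          off_tissue_intensity = c(8e4, 5e4),
                          on_tissue_intensity = c(3e4, 2e4)),
                      tissueMask = NULL, noiseCv = 0.1, mzJitterPpm = 1,
                      tolPpm = 5, interLineGap = 2, laserMargin = 0,
                      seed = 1) {
    mode <- match.arg(mode)
    if (is.null(tissueMask)) {
        tissueMask <- matrix(FALSE, geometry@nLines, geometry@nCols)
        for (cmp in compounds) tissueMask <- tissueMask | cmp$mask
    }
    if (is.null(dynamicExclusion)) dynamicExclusion <- numeric(0)
    new("SimConfig",
        geometry = geometry, polarity = polarity,
        massRange = as.numeric(massRange), mode = mode,
        topN = as.integer(topN),
        minPrecursorIntensity = as.numeric(minPrecursorIntensity),
        isolationWidth = as.numeric(isolationWidth),
        dynamicExclusion = dynamicExclusion,
        exclusionList = as.numeric(exclusionList),
        compounds = compounds, matrixIons = as.data.frame(matrixIons),
        tissueMask = tissueMask, noiseCv = as.numeric(noiseCv),
        mzJitterPpm = as.numeric(mzJitterPpm), tolPpm = as.numeric(tolPpm),
        interLineGap = as.numeric(interLineGap),
        laserMargin = as.numeric(laserMargin), seed = as.integer(seed))
}

# log-normal multiplier with mean 1 and the given CV
.noiseFactor <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.jitterMz <- function(mz, ppm) {
    if (ppm <= 0) return(mz)
    mz * (1 + stats::rnorm(length(mz), 0, ppm * 1e-6))
}

# enforce strictly increasing m/z after sorting (jitter can tie)
.sortPeaks <- function(mz, intensity, extra = NULL) {
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]
    if (!is.null(extra)) extra <- extra[ord]
    while (length(mz) > 1 && any(diff(mz) <= 0)) {
        i <- which(diff(mz) <= 0)[1] + 1L
        mz[i] <- mz[i - 1L] * (1 + 1e-10)
        ord2 <- order(mz)
        mz <- mz[ord2]; intensity <- intensity[ord2]
        if (!is.null(extra)) extra <- extra[ord2]
    }
    list(mz = mz, intensity = intensity, extra = extra)
}

#' Simulate a complete MSI-DDA acquisition
#'
#' Emits one MS1 scan per pixel in raster order, built from the planted
#' compounds' adduct peaks (abundance x phantom mask, log-normal intensity
#' noise, ppm m/z jitter) plus the matrix background ions (brighter
#' off-tissue). After each MS1 scan the DDA engine ranks eligible peaks by
#' descending intensity — eligible means at or above the minimum precursor
#' intensity, not ppm-matched by the exclusion list, and not dynamically
#' excluded — and schedules MS2 scans: up to \code{topN} per cycle in
#' sequential mode, every eligible precursor in parallel mode (the second
#' analyzer acquires MS2 without consuming cycle time). Dynamic exclusion
#' clusters selected precursor m/z at the engine ppm tolerance; a cluster
#' selected \code{max_occurrences} times within \code{occurrence_window_s}
#' becomes ineligible for \code{exclusion_duration_s}. MS2 spectra are the
#' source compound's fragment spectrum, scaled and noise-perturbed; the run
#' is deterministic for a fixed seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{run} (\linkS4class{MsiRun}), \code{log}
#'   (\linkS4class{PositionLog}) and \code{truth}, a data.frame with one row
#'   per emitted MS2 scan: \code{scan_index}, \code{compound_id},
#'   \code{adduct}, \code{true_mz}, \code{observed_mz}, \code{pixel_row},
#'   \code{pixel_col}.
#' @export
simulateRun <- function(config) {
    validObject(config)
    g <- config@geometry
    set.seed(config@seed)
    tol <- config@tolPpm
    lineDur <- g@nCols * g@cyclePeriod
    t0 <- (seq_len(g@nLines) - 1L) * (lineDur + config@interLineGap)
    lines <- data.frame(line_index = seq_len(g@nLines) - 1L,
                        t_start_s = t0, t_end_s = t0 + lineDur,
                        y_um = (seq_len(g@nLines) - 1L) * g@lineSpacing)
    laser <- data.frame(t_on_s = t0,
                        t_off_s = pmax(t0 + lineDur - config@laserMargin,
                                       t0 + 1e-9))
    log <- PositionLog(lines, laser)

    cmps <- config@compounds
    cmz <- vapply(cmps, function(cmp)
        cmp$exact_mass + .adductShifts[[cmp$adduct]], numeric(1))
    mi <- config@matrixIons
    de <- config@dynamicExclusion
    deOn <- length(de) == 3L
    # dynamic-exclusion cluster state
    cl_mz <- numeric(0); cl_until <- numeric(0); cl_times <- list()

    scanTime <- numeric(0); scanLevel <- integer(0)
    scanPrec <- numeric(0); scanIso <- numeric(0)
    peaks <- list()
    truth <- list()

    for (li in seq_len(g@nLines)) {
        row0 <- li - 1L
        for (ci in seq_len(g@nCols)) {
            colTime <- ci - 1L
            col0 <- if (g@serpentine && row0 %% 2L == 1L)
                g@nCols - 1L - colTime else colTime
            t <- t0[li] + colTime * g@cyclePeriod
            r1 <- row0 + 1L; c1 <- col0 + 1L
            onTissue <- config@tissueMask[r1, c1]
            mz <- numeric(0); int <- numeric(0); src <- integer(0)
            for (k in seq_along(cmps)) {
                a <- cmps[[k]]$abundance * cmps[[k]]$mask[r1, c1]
                if (a <= 0) next
                mz <- c(mz, .jitterMz(cmz[k], config@mzJitterPpm))
                int <- c(int, a * .noiseFactor(1, config@noiseCv))
                src <- c(src, k)
            }
            if (nrow(mi)) {
                base <- if (onTissue) mi$on_tissue_intensity else
                    mi$off_tissue_intensity
                keep <- base > 0
                if (any(keep)) {
                    mz <- c(mz, .jitterMz(mi$mz[keep], config@mzJitterPpm))
                    int <- c(int, base[keep] *
                                 .noiseFactor(sum(keep), config@noiseCv))
                    src <- c(src, -which(keep))
                }
            }
            inR <- mz >= config@massRange[1] & mz <= config@massRange[2]
            mz <- mz[inR]; int <- int[inR]; src <- src[inR]
            sp <- .sortPeaks(mz, int, src)
            peaks[[length(peaks) + 1L]] <-
                cbind(mz = sp$mz, intensity = sp$intensity)
            scanTime <- c(scanTime, t)
            scanLevel <- c(scanLevel, 1L)
            scanPrec <- c(scanPrec, NA_real_)
            scanIso <- c(scanIso, NA_real_)

            ## ---- DDA precursor selection -----------------------------------
            elig <- which(sp$intensity >= config@minPrecursorIntensity)
            if (length(config@exclusionList) && length(elig)) {
                onList <- vapply(sp$mz[elig], function(x)
                    any(abs(x - config@exclusionList) <=
                        x * tol * 1e-6), logical(1))
                elig <- elig[!onList]
            }
            elig <- elig[order(-sp$intensity[elig])]
            nsel <- 0L
            maxsel <- if (config@mode == "sequential")
                config@topN else length(elig)
            selected <- integer(0)
            for (e in elig) {
                if (nsel >= maxsel) break
                x <- sp$mz[e]
                j <- NA_integer_
                if (deOn && length(cl_mz)) {
                    hit <- which(abs(x - cl_mz) <= cl_mz * tol * 1e-6)
                    if (length(hit)) j <- hit[1]
                }
                if (deOn && !is.na(j) && t < cl_until[j]) next
                if (deOn) {
                    if (is.na(j)) {
                        cl_mz <- c(cl_mz, x)
                        cl_until <- c(cl_until, -Inf)
                        cl_times <- c(cl_times, list(numeric(0)))
                        j <- length(cl_mz)
                    }
                    cl_times[[j]] <- c(cl_times[[j]], t)
                    recent <- sum(cl_times[[j]] >=
                                  t - de[["occurrence_window_s"]])
                    if (recent >= de[["max_occurrences"]])
                        cl_until[j] <- t + de[["exclusion_duration_s"]]
                }
                nsel <- nsel + 1L
                selected <- c(selected, e)
            }

            ## ---- emit MS2 scans --------------------------------------------
            for (sidx in seq_along(selected)) {
                e <- selected[sidx]
                dt <- if (config@mode == "sequential")
                    sidx * g@cyclePeriod / (length(selected) + 1L)
                else sidx * 1e-3
                obs_mz <- sp$mz[e]
                source <- sp$extra[e]
                if (source > 0) {
                    cmp <- cmps[[source]]
                    fr <- cmp$peaks
                    fmz <- .jitterMz(fr[, 1], config@mzJitterPpm)
                    fint <- fr[, 2] * (sp$intensity[e] / 100) *
                        .noiseFactor(nrow(fr), config@noiseCv)
                    cid <- cmp$compound_id; cad <- cmp$adduct
                    tmz <- cmz[source]
                } else {
                    mrow <- -source
                    fr_mz <- mi$mz[mrow] * c(0.6, 0.8, 0.95)
                    fmz <- .jitterMz(fr_mz, config@mzJitterPpm)
                    fint <- sp$intensity[e] * c(0.3, 0.5, 0.2) *
                        .noiseFactor(3, config@noiseCv)
                    cid <- sprintf("matrix_%.4f", mi$mz[mrow])
                    cad <- NA_character_
                    tmz <- mi$mz[mrow]
                }
                inR <- fmz >= config@massRange[1] &
                       fmz <= config@massRange[2]
                fsp <- .sortPeaks(fmz[inR], fint[inR])
                peaks[[length(peaks) + 1L]] <-
                    cbind(mz = fsp$mz, intensity = fsp$intensity)
                scanTime <- c(scanTime, t + dt)
                scanLevel <- c(scanLevel, 2L)
                scanPrec <- c(scanPrec, obs_mz)
                scanIso <- c(scanIso, config@isolationWidth)
                truth[[length(truth) + 1L]] <- data.frame(
                    scan_index = length(peaks) - 1L,
                    compound_id = cid, adduct = cad, true_mz = tmz,
                    observed_mz = obs_mz, pixel_row = row0, pixel_col = col0,
                    stringsAsFactors = FALSE)
            }
        }
    }
    run <- MsiRun(
        scanInfo = data.frame(time_s = scanTime, ms_level = scanLevel,
                              precursor_mz = scanPrec,
                              isolation_width = scanIso),
        peaks = peaks, polarity = config@polarity,
        massRange = config@massRange)
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
        scan_index = integer(), compound_id = character(),
        adduct = character(), true_mz = numeric(), observed_mz = numeric(),
        pixel_row = integer(), pixel_col = integer(),
        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(run = run, log = log, truth = truth)
}

#' Build the (true or decoy) spectral library of a simulated scene
#'
#' With \code{decoy = FALSE}, one entry per planted compound carrying its
#' ground-truth fragment spectrum. With \code{decoy = TRUE}, each entry's
#' fragment m/z values are replaced by uniform draws within the mass range
#' (intensities preserved), producing spectra that share nothing with the
#' true fragmentation — the negative control for cosine scoring.
#' Deterministic for a fixed config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param decoy scramble fragment m/z values (default FALSE).
#' @return a \linkS4class{SpectralLibrary}.
#' @export
makeLibrary <- function(config, decoy = FALSE) {
    cmps <- config@compounds
    if (length(cmps) == 0)
        return(SpectralLibrary(.emptyLibraryEntries(), list()))
    entries <- do.call(rbind, lapply(cmps, function(cmp) data.frame(
        compound_id = cmp$compound_id, name = cmp$name,
        formula = cmp$formula, exact_mass = cmp$exact_mass,
        adduct = cmp$adduct, collision_energy = 40,
        provenance = "experimental", stringsAsFactors = FALSE)))
    peaks <- lapply(cmps, function(cmp) cmp$peaks)
    if (decoy) {
        set.seed(config@seed + 7919L)
        lo <- config@massRange[1]
        peaks <- lapply(peaks, function(p) {
            hi <- max(p[, 1])
            mz <- sort(stats::runif(nrow(p), lo, max(hi, lo + 50)))
            cbind(mz = mz, intensity = p[, 2])
        })
    }
    SpectralLibrary(entries, peaks)
}

#' Pixels eligible for exclusion-list acquisition outside an ROI
#'
#' Returns the mask of pixels lying at least \code{margin_um} (center to
#' center) from every ROI pixel — the region where an exclusion-list run
#' can be acquired without picking up analytes delocalized from the tissue.
#' ROI pixels themselves are never part of the mask; with margin 0 the
#' result is the exact complement of the ROI.
#'
#' @param roi_mask logical matrix marking the region of interest.
#' @param margin_um minimum distance from the ROI, um.
#' @param pixel_pitch_um along-track (column) pixel size, um.
#' @param line_spacing_um row spacing, um (default = pitch).
#' @return logical matrix; all-FALSE when the margin exceeds the grid
#'   extent or the ROI covers the whole grid.
#' @export
exclusionRegionMask <- function(roi_mask, margin_um, pixel_pitch_um,
                                line_spacing_um = pixel_pitch_um) {
    if (margin_um < 0) stop("margin_um must be >= 0")
    roi_mask <- roi_mask != 0
    out <- matrix(FALSE, nrow(roi_mask), ncol(roi_mask))
    idx <- which(roi_mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(!roi_mask)
    for (r in seq_len(nrow(roi_mask))) {
        for (cc in seq_len(ncol(roi_mask))) {
            if (roi_mask[r, cc]) next
            d2 <- ((idx[, 1] - r) * line_spacing_um)^2 +
                  ((idx[, 2] - cc) * pixel_pitch_um)^2
            out[r, cc] <- min(d2) >= margin_um^2
        }
    }
    out
}

#' Disc-shaped phantom mask
#'
#' @param nLines,nCols grid dimensions.
#' @param center numeric(2), (row, col) center, 1-based.
#' @param radius radius in pixels.
#' @return logical matrix.
#' @export
phantomDisc <- function(nLines, nCols, center, radius) {
    r <- matrix(seq_len(nLines), nLines, nCols)
    cc <- matrix(seq_len(nCols), nLines, nCols, byrow = TRUE)
    (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Generate a reproducible set of planted compounds
#'
#' Convenience scene builder: \code{n} compounds with well-separated exact
#' masses (about 2.5 Da apart, far beyond any ppm tolerance), distinct
#' pseudo-random fragment spectra of 4-6 peaks inside the mass range, disc
#' phantoms scattered over the grid, and adducts cycling through the
#' polarity's adduct set.
#'
#' @param n number of compounds.
#' @param nLines,nCols grid dimensions.
#' @param polarity "positive" or "negative".
#' @param massRange acquisition window the precursors and fragments must
#'   respect.
#' @param abundance MS1 intensity at full mask (recycled).
#' @param seed RNG seed for the spectra and phantom placement.
#' @return list of \code{\link{simCompound}} entries.
#' @export
simulatedCompounds <- function(n, nLines, nCols, polarity = "positive",
                               massRange = c(150, 900), abundance = 2e4,
                               seed = 42) {
    set.seed(seed)
    ads <- adductTable(polarity)$label
    abundance <- rep_len(abundance, n)
    lapply(seq_len(n), function(k) {
        ad <- ads[(k - 1L) %% length(ads) + 1L]
        exact <- 300 + 2.5 * k + stats::runif(1, 0, 0.8)
        npk <- sample(4:6, 1)
        lo <- massRange[1] + 5
        hi <- min(exact, massRange[2]) - 10
        fmz <- sort(stats::runif(npk, lo, hi))
        while (any(diff(fmz) < 0.5))
            fmz <- sort(stats::runif(npk, lo, hi))
        fint <- stats::runif(npk, 5, 100)
        fint[which.max(fint)] <- 100
        center <- c(sample(seq_len(nLines), 1), sample(seq_len(nCols), 1))
        radius <- max(2, round(min(nLines, nCols) / 4))
        simCompound(
            compound_id = sprintf("cpd%03d", k),
            name = sprintf("compound %d", k),
            formula = NA, exact_mass = exact, adduct = ad,
            peaks = cbind(fmz, fint),
            mask = phantomDisc(nLines, nCols, center, radius),
            abundance = abundance[k])
    })
}

#' Write a complete simulated run to disk
#'
#' Emits the three pipeline inputs plus provenance: \code{run.mzML},
#' \code{positions.xml}, a \code{library/} folder holding the true library
#' as MSP, \code{truth.tsv} and \code{config.json} (grid, engine settings
#' and seed).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSimulatedRun <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateRun(config)
    writeMzML(sim$run, file.path(dir, "run.mzML"))
    writePositionLog(sim$log, file.path(dir, "positions.xml"))
    dir.create(file.path(dir, "library"), showWarnings = FALSE)
    writeMsp(makeLibrary(config), file.path(dir, "library", "true.msp"))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    g <- config@geometry
    cfg <- list(nLines = g@nLines, nCols = g@nCols,
                cyclePeriod = g@cyclePeriod, plateVelocity = g@plateVelocity,
                pixelPitch = g@pixelPitch, polarity = config@polarity,
                massRange = config@massRange, mode = config@mode,
                topN = config@topN,
                minPrecursorIntensity = config@minPrecursorIntensity,
                isolationWidth = config@isolationWidth,
                dynamicExclusion = as.list(config@dynamicExclusion),
                exclusionList = config@exclusionList,
                noiseCv = config@noiseCv, mzJitterPpm = config@mzJitterPpm,
                seed = config@seed)
    writeLines(.toJson(cfg), file.path(dir, "config.json"))
    invisible(dir)
}

# minimal JSON writer (scalars, vectors, named lists) for provenance echo
.toJson <- function(x, indent = "") {
    if (is.list(x) && !is.null(names(x))) {
        inner <- vapply(names(x), function(nm)
            sprintf("%s  \"%s\": %s", indent, nm,
                    .toJson(x[[nm]], paste0(indent, "  "))), character(1))
        paste0("{\n", paste(inner, collapse = ",\n"), "\n", indent, "}")
    } else if (length(x) == 0) {
        "[]"
    } else if (length(x) > 1) {
        paste0("[", paste(vapply(x, .toJson, character(1), ""),
                          collapse = ", "), "]")
    } else if (is.character(x)) {
        sprintf("\"%s\"", x)
    } else if (is.logical(x)) {
        if (x) "true" else "false"
    } else {
        format(x, digits = 15, scientific = FALSE, trim = TRUE)
    }
}
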