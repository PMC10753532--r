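#' Build an MsiRun from scan metadata and peak lists
#'
#' Low-level constructor; computes the TIC column when absent and validates
#' all scan-stream invariants (time order, sorted centroids, MS2 precursor
#' presence).
#'
#' @param scanInfo data.frame with columns \code{time_s}, \code{ms_level},
#'   and for MS2 rows \code{precursor_mz} (optionally
#'   \code{isolation_width}). \code{index} and \code{tic} are filled in.
#' @param peaks list of two-column \code{(mz, intensity)} matrices, one per
#'   scan, m/z ascending.
#' @param polarity "positive" or "negative".
#' @param massRange numeric(2) acquisition window; defaults to the span of
#'   the observed peaks (or c(150, 900) for an empty run).
#' @return an \linkS4class{MsiRun}.
#' @export
MsiRun <- function(scanInfo, peaks, polarity = "positive", massRange = NULL) {
    scanInfo <- as.data.frame(scanInfo)
    n <- nrow(scanInfo)
    if (length(peaks) != n)
        stop("need exactly one peak matrix per scan")
    peaks <- lapply(peaks, function(p) {
        p <- as.matrix(p)
        colnames(p) <- c("mz", "intensity")
        p
    })
    scanInfo$index <- seq_len(n) - 1L
    scanInfo$ms_level <- as.integer(scanInfo$ms_level)
    if (is.null(scanInfo$precursor_mz))
        scanInfo$precursor_mz <- rep(NA_real_, n)
    if (is.null(scanInfo$isolation_width))
        scanInfo$isolation_width <- rep(NA_real_, n)
    scanInfo$tic <- vapply(peaks, function(p) sum(p[, 2]), numeric(1))
    if (is.null(massRange)) {
        allmz <- unlist(lapply(peaks, function(p) p[, 1]), use.names = FALSE)
        massRange <- if (length(allmz)) range(allmz) else c(150, 900)
        if (massRange[1] == massRange[2])
            massRange <- massRange + c(-1, 1)
    }
    scanInfo <- scanInfo[, c("index", "time_s", "ms_level", "precursor_mz",
                             "isolation_width", "tic")]
    rownames(scanInfo) <- NULL
    new("MsiRun", scanInfo = scanInfo, peaks = peaks,
        polarity = polarity, massRange = as.numeric(massRange))
}

#' Build a PositionLog
#'
#' @param lines data.frame with columns \code{line_index}, \code{t_start_s},
#'   \code{t_end_s}, \code{y_um} (records are sorted by start time).
#' @param laserIntervals data.frame with columns \code{t_on_s},
#'   \code{t_off_s}; intervals must be disjoint.
#' @return a \linkS4class{PositionLog}.
#' @export
PositionLog <- function(lines, laserIntervals) {
    lines <- as.data.frame(lines)
    laserIntervals <- as.data.frame(laserIntervals)
    if (nrow(lines)) {
        lines <- lines[order(lines$t_start_s), , drop = FALSE]
        rownames(lines) <- NULL
    }
    if (nrow(laserIntervals)) {
        laserIntervals <- laserIntervals[order(laserIntervals$t_on_s), ,
                                         drop = FALSE]
        rownames(laserIntervals) <- NULL
    }
    new("PositionLog", lines = lines, laserIntervals = laserIntervals)
}

#' Define the raster geometry of a constant-speed MSI acquisition
#'
#' With constant plate velocity, one full-scan cycle sweeps
#' velocity x cyclePeriod micrometres, which is the natural along-track
#' pixel pitch; pass \code{pixelPitch} only to decouple the two.
#'
#' @param plateVelocity stage speed, um/s.
#' @param cyclePeriod full-scan cycle time, s.
#' @param nLines,nCols grid dimensions.
#' @param pixelPitch along-track pixel size, um
#'   (default \code{plateVelocity * cyclePeriod}).
#' @param lineSpacing distance between raster lines, um
#'   (default \code{pixelPitch}).
#' @param serpentine reverse the direction of every other line.
#' @return a \linkS4class{RasterGeometry}.
#' @examples
#' rasterGeometry(plateVelocity = 100 / 0.6, cyclePeriod = 0.6,
#'                nLines = 10, nCols = 20)
#' @export
rasterGeometry <- function(plateVelocity, cyclePeriod, nLines, nCols,
                           pixelPitch = plateVelocity * cyclePeriod,
                           lineSpacing = pixelPitch, serpentine = FALSE) {
    new("RasterGeometry",
        plateVelocity = as.numeric(plateVelocity),
        pixelPitch = as.numeric(pixelPitch),
        lineSpacing = as.numeric(lineSpacing),
        cyclePeriod = as.numeric(cyclePeriod),
        nLines = as.integer(nLines), nCols = as.integer(nCols),
        serpentine = isTRUE(serpentine))
}

#' Derive raster geometry from a position log
#'
#' Uses the log's line records for grid dimensions and timing: the number of
#' lines, and the number of columns implied by the (shortest) line duration
#' at the given cycle period.
#'
#' @param log a \linkS4class{PositionLog} with at least one line.
#' @param plateVelocity stage speed, um/s.
#' @param cyclePeriod full-scan cycle time, s.
#' @param ... further arguments passed to \code{\link{rasterGeometry}}.
#' @return a \linkS4class{RasterGeometry}.
#' @export
geometryFromLog <- function(log, plateVelocity, cyclePeriod, ...) {
    ln <- logLines(log)
    if (nrow(ln) == 0) stop("position log has no line records")
    dur <- min(ln$t_end_s - ln$t_start_s)
    nCols <- max(1L, as.integer(floor(dur / cyclePeriod + 1e-9)))
    ys <- sort(unique(ln$y_um))
    spacing <- if (length(ys) > 1) min(diff(ys)) else plateVelocity * cyclePeriod
    rasterGeometry(plateVelocity = plateVelocity, cyclePeriod = cyclePeriod,
                   nLines = nrow(ln), nCols = nCols,
                   lineSpacing = spacing, ...)
}

#' Build a SpectralLibrary
#'
#' @param entries data.frame with columns \code{compound_id}, \code{name},
#'   \code{formula}, \code{exact_mass}, \code{adduct} (NA = unspecified),
#'   \code{collision_energy} (NA = unspecified), \code{provenance}.
#' @param peaks list of two-column \code{(mz, intensity)} matrices, one per
#'   entry, sorted by m/z, at least one intensity > 0.
#' @return a \linkS4class{SpectralLibrary}.
#' @export
SpectralLibrary <- function(entries, peaks) {
    entries <- as.data.frame(entries)
    for (col in c("compound_id", "name", "formula", "provenance"))
        entries[[col]] <- as.character(entries[[col]])
    entries$adduct <- as.character(entries$adduct)
    entries$collision_energy <- as.numeric(entries$collision_energy)
    entries$exact_mass <- as.numeric(entries$exact_mass)
    rownames(entries) <- NULL
    peaks <- lapply(peaks, function(p) {
        p <- as.matrix(p)
        colnames(p) <- c("mz", "intensity")
        p
    })
    new("SpectralLibrary", entries = entries, peaks = peaks)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn MsiRun-accessors per-scan metadata data.frame
#' @export
scanInfo <- function(run) run@scanInfo

#' Accessors for MsiRun
#'
#' @param run an \linkS4class{MsiRun}.
#' @param i scan number (1-based position in the stream).
#' @name MsiRun-accessors
NULL

#' @describeIn MsiRun-accessors list of centroid peak matrices
#' @export
peaksList <- function(run) run@peaks

#' @describeIn MsiRun-accessors one scan's peak matrix
#' @export
scanPeaks <- function(run, i) run@peaks[[i]]

#' @describeIn MsiRun-accessors run polarity
#' @export
polarity <- function(run) run@polarity

#' @describeIn MsiRun-accessors acquisition m/z window
#' @export
massRange <- function(run) run@massRange

#' @describeIn MsiRun-accessors number of scans
#' @export
nScans <- function(run) nrow(run@scanInfo)

#' Accessors for PositionLog
#'
#' @param log a \linkS4class{PositionLog}.
#' @name PositionLog-accessors
NULL

#' @describeIn PositionLog-accessors raster line records
#' @export
logLines <- function(log) log@lines

#' @describeIn PositionLog-accessors laser-active intervals
#' @export
laserIntervals <- function(log) log@laserIntervals

#' Accessors for SpectralLibrary
#'
#' @param x a \linkS4class{SpectralLibrary}.
#' @param i entry number.
#' @name SpectralLibrary-accessors
NULL

#' @describeIn SpectralLibrary-accessors entry metadata data.frame
#' @export
libraryEntries <- function(x) x@entries

#' @describeIn SpectralLibrary-accessors one entry's fragment spectrum
#' @export
libraryPeaks <- function(x, i) x@peaks[[i]]

#' @describeIn SpectralLibrary-accessors number of entries
#' @export
setMethod("length", "SpectralLibrary", function(x) nrow(x@entries))

#' Concatenate spectral libraries
#'
#' @param x,... \linkS4class{SpectralLibrary} objects.
#' @return a single \linkS4class{SpectralLibrary} with all entries.
#' @export
setMethod("c", "SpectralLibrary", function(x, ...) {
    libs <- c(list(x), list(...))
    SpectralLibrary(
        entries = do.call(rbind, lapply(libs, libraryEntries)),
        peaks = do.call(c, lapply(libs, function(l) l@peaks)))
})

#' Accessors for image grids
#'
#' @param x a \linkS4class{TICMap} or \linkS4class{IonImage}.
#' @name image-accessors
NULL

#' @describeIn image-accessors the per-pixel intensity matrix
#' @export
imageGrid <- function(x) x@grid

#' @describeIn image-accessors the laser-active pixel mask (TICMap only)
#' @export
laserMask <- function(x) x@mask

## ---- show ------------------------------------------------------------------

#' @export
setMethod("show", "MsiRun", function(object) {
    si <- object@scanInfo
    cat("MsiRun:", nrow(si), "scans (",
        sum(si$ms_level == 1L), "MS1 /", sum(si$ms_level == 2L), "MS2 ),",
        object@polarity, "mode\n")
    cat(sprintf("  m/z %g-%g", object@massRange[1], object@massRange[2]))
    if (nrow(si))
        cat(sprintf(", time %.2f-%.2f s", min(si$time_s), max(si$time_s)))
    cat("\n")
})

setMethod("show", "PositionLog", function(object) {
    cat("PositionLog:", nrow(object@lines), "raster lines,",
        nrow(object@laserIntervals), "laser intervals\n")
})

setMethod("show", "RasterGeometry", function(object) {
    cat(sprintf(
        "RasterGeometry: %d x %d pixels, pitch %g um, line spacing %g um\n",
        object@nLines, object@nCols, object@pixelPitch, object@lineSpacing))
    cat(sprintf("  velocity %g um/s, cycle %g s%s\n", object@plateVelocity,
        object@cyclePeriod,
        if (object@serpentine) ", serpentine" else ""))
})

setMethod("show", "SpectralLibrary", function(object) {
    en <- object@entries
    cat("SpectralLibrary:", nrow(en), "entries,",
        length(unique(en$compound_id)), "compounds\n")
    if (nrow(en)) {
        tb <- table(ifelse(is.na(en$adduct), "unspecified", en$adduct))
        cat("  adducts:", paste(names(tb), tb, sep = "=", collapse = ", "),
            "\n")
    }
})

setMethod("show", "TICMap", function(object) {
    cat(sprintf("TICMap: %d x %d pixels, %d visited\n",
        nrow(object@grid), ncol(object@grid), sum(!is.na(object@grid))))
})

setMethod("show", "IonImage", function(object) {
    cat(sprintf("IonImage: m/z %.4f (+/- %g ppm), %d x %d pixels%s\n",
        object@targetMz, object@tolPpm, nrow(object@grid), ncol(object@grid),
        if (object@normalized) ", TIC-normalized" else ""))
})
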