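#' @import methods
NULL

#' MsiRun: a time-ordered MSI scan stream
#'
#' Container for a centroided MS1/MS2 scan stream from a constant-speed
#' raster MSI acquisition. Scan-level metadata live in a data.frame
#' (one row per scan); centroid peak lists are a parallel list of
#' two-column \code{(mz, intensity)} matrices.
#'
#' The \code{scanInfo} data.frame has columns \code{index} (0-based ordinal
#' position), \code{time_s} (acquisition start, seconds from run start),
#' \code{ms_level} (1 or 2), \code{precursor_mz} and \code{isolation_width}
#' (NA for MS1 scans) and \code{tic} (sum of peak intensities).
#'
#' @slot scanInfo data.frame of per-scan metadata (see Details).
#' @slot peaks list of numeric matrices, columns \code{mz}, \code{intensity},
#'   rows sorted by ascending m/z.
#' @slot polarity "positive" or "negative".
#' @slot massRange numeric(2), acquisition m/z window.
#' @aliases MsiRun
#' @exportClass MsiRun
setClass("MsiRun",
    representation(
        scanInfo = "data.frame",
        peaks = "list",
        polarity = "character",
        massRange = "numeric"
    ),
    prototype(
        scanInfo = data.frame(index = integer(), time_s = numeric(),
            ms_level = integer(), precursor_mz = numeric(),
            isolation_width = numeric(), tic = numeric()),
        peaks = list(),
        polarity = "positive",
        massRange = c(150, 900)
    )
)

.validMsiRun <- function(object) {
    msg <- character()
    si <- object@scanInfo
    need <- c("index", "time_s", "ms_level", "precursor_mz",
              "isolation_width", "tic")
    if (!all(need %in% names(si)))
        return(paste("scanInfo must have columns:",
                     paste(need, collapse = ", ")))
    if (length(object@peaks) != nrow(si))
        msg <- c(msg, "length(peaks) must equal nrow(scanInfo)")
    if (!object@polarity %in% c("positive", "negative"))
        msg <- c(msg, "polarity must be 'positive' or 'negative'")
    if (length(object@massRange) != 2L ||
        object@massRange[1] >= object@massRange[2])
        msg <- c(msg, "massRange must be c(low, high) with low < high")
    if (nrow(si) > 0) {
        if (is.unsorted(si$time_s))
            msg <- c(msg, "scan times must be non-decreasing")
        if (!all(si$ms_level %in% c(1L, 2L)))
            msg <- c(msg, "ms_level must be 1 or 2")
        ms2 <- si$ms_level == 2L
        if (any(ms2 & !is.finite(si$precursor_mz)))
            msg <- c(msg, "every MS2 scan must carry precursor_mz")
        for (i in seq_along(object@peaks)) {
            p <- object@peaks[[i]]
            if (!is.matrix(p) || ncol(p) != 2L) {
                msg <- c(msg, sprintf(
                    "peaks[[%d]] must be a 2-column matrix", i))
                break
            }
            if (nrow(p) > 0) {
                if (any(diff(p[, 1]) <= 0)) {
                    msg <- c(msg, sprintf(
                        "peaks[[%d]]: m/z must be strictly increasing", i))
                    break
                }
                if (any(p[, 2] < 0)) {
                    msg <- c(msg, sprintf(
                        "peaks[[%d]]: intensities must be >= 0", i))
                    break
                }
            }
            s <- sum(p[, 2])
            tol <- max(1e-9 * max(s, 1), 1e-9)
            if (abs(s - si$tic[i]) > tol) {
                msg <- c(msg, sprintf(
                    "scan %d: tic does not equal the peak intensity sum", i))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("MsiRun", .validMsiRun)

#' PositionLog: raster line geometry and laser-active intervals
#'
#' Mirrors the stage-control XML log written alongside an MSI acquisition:
#' one record per raster line (0-based index, start/end time in seconds,
#' stage y coordinate in micrometres) and a set of non-overlapping,
#' time-ordered intervals during which the laser fires.
#'
#' @slot lines data.frame with columns \code{line_index}, \code{t_start_s},
#'   \code{t_end_s}, \code{y_um}.
#' @slot laserIntervals data.frame with columns \code{t_on_s}, \code{t_off_s}.
#' @exportClass PositionLog
setClass("PositionLog",
    representation(lines = "data.frame", laserIntervals = "data.frame"),
    prototype(
        lines = data.frame(line_index = integer(), t_start_s = numeric(),
                           t_end_s = numeric(), y_um = numeric()),
        laserIntervals = data.frame(t_on_s = numeric(), t_off_s = numeric())
    )
)

.validPositionLog <- function(object) {
    msg <- character()
    ln <- object@lines
    li <- object@laserIntervals
    if (!all(c("line_index", "t_start_s", "t_end_s", "y_um") %in% names(ln)))
        return("lines must have columns line_index, t_start_s, t_end_s, y_um")
    if (!all(c("t_on_s", "t_off_s") %in% names(li)))
        return("laserIntervals must have columns t_on_s, t_off_s")
    if (nrow(ln) > 0) {
        if (any(ln$t_start_s >= ln$t_end_s))
            msg <- c(msg, "every line needs t_start_s < t_end_s")
        if (is.unsorted(ln$t_start_s, strictly = TRUE) && nrow(ln) > 1)
            msg <- c(msg, "lines must be strictly time-ordered")
    }
    if (nrow(li) > 0) {
        if (any(li$t_on_s >= li$t_off_s))
            msg <- c(msg, "every laser interval needs t_on_s < t_off_s")
        if (nrow(li) > 1 &&
            any(li$t_on_s[-1] < li$t_off_s[-nrow(li)]))
            msg <- c(msg, "laser intervals must be non-overlapping and ordered")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PositionLog", .validPositionLog)

#' RasterGeometry: constant-speed raster acquisition geometry
#'
#' Maps acquisition time onto the 2-D pixel grid. With constant plate
#' velocity the along-track pixel pitch is velocity times the full-scan
#' cycle period unless explicitly overridden.
#'
#' @slot plateVelocity stage speed, um/s.
#' @slot pixelPitch along-track pixel size, um.
#' @slot lineSpacing distance between raster lines, um.
#' @slot cyclePeriod full-scan cycle time, s.
#' @slot nLines,nCols grid dimensions.
#' @slot serpentine if TRUE, even-numbered lines (1, 3, ...) run in the
#'   reverse direction and their column index is mirrored.
#' @exportClass RasterGeometry
setClass("RasterGeometry",
    representation(
        plateVelocity = "numeric", pixelPitch = "numeric",
        lineSpacing = "numeric", cyclePeriod = "numeric",
        nLines = "integer", nCols = "integer", serpentine = "logical"
    )
)

.validRasterGeometry <- function(object) {
    msg <- character()
    for (s in c("plateVelocity", "pixelPitch", "lineSpacing", "cyclePeriod"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
            slot(object, s) <= 0)
            msg <- c(msg, paste(s, "must be a positive scalar"))
    if (object@nLines < 1L) msg <- c(msg, "nLines must be >= 1")
    if (object@nCols < 1L) msg <- c(msg, "nCols must be >= 1")
    if (length(msg)) msg else TRUE
}
setValidity("RasterGeometry", .validRasterGeometry)

#' SpectralLibrary: a set of MS2 reference spectra
#'
#' One row of \code{entries} per library record: compound identity, elemental
#' formula, neutral monoisotopic mass (Da), declared adduct (or NA when the
#' record does not commit to one), normalized collision energy (or NA),
#' provenance ("predicted" or "experimental"). \code{peaks} holds the
#' fragment spectra as \code{(mz, intensity)} matrices in parallel with the
#' rows. Duplicate (compound, adduct, collision energy) tuples are allowed:
#' real libraries carry the same compound at several collision energies.
#'
#' @slot entries data.frame with columns \code{compound_id}, \code{name},
#'   \code{formula}, \code{exact_mass}, \code{adduct}, \code{collision_energy},
#'   \code{provenance}.
#' @slot peaks list of two-column \code{(mz, intensity)} matrices.
#' @exportClass SpectralLibrary
setClass("SpectralLibrary",
    representation(entries = "data.frame", peaks = "list"),
    prototype(
        entries = data.frame(compound_id = character(), name = character(),
            formula = character(), exact_mass = numeric(),
            adduct = character(), collision_energy = numeric(),
            provenance = character()),
        peaks = list()
    )
)

.validSpectralLibrary <- function(object) {
    msg <- character()
    en <- object@entries
    need <- c("compound_id", "name", "formula", "exact_mass", "adduct",
              "collision_energy", "provenance")
    if (!all(need %in% names(en)))
        return(paste("entries must have columns:", paste(need, collapse = ", ")))
    if (length(object@peaks) != nrow(en))
        msg <- c(msg, "length(peaks) must equal nrow(entries)")
    if (nrow(en) > 0) {
        if (any(!is.finite(en$exact_mass) | en$exact_mass <= 0))
            msg <- c(msg, "exact_mass must be > 0 for every entry")
        bad <- !is.na(en$adduct) &
            !en$adduct %in% names(.adductShifts)
        if (any(bad))
            msg <- c(msg, paste("unknown adduct label:",
                paste(unique(en$adduct[bad]), collapse = ", ")))
        for (i in seq_along(object@peaks)) {
            p <- object@peaks[[i]]
            if (!is.matrix(p) || ncol(p) != 2L || nrow(p) == 0) {
                msg <- c(msg, sprintf(
                    "entry %d: peaks must be a non-empty 2-column matrix", i))
                break
            }
            if (is.unsorted(p[, 1])) {
                msg <- c(msg, sprintf("entry %d: peaks must be m/z-sorted", i))
                break
            }
            if (any(p[, 2] < 0) || !any(p[, 2] > 0)) {
                msg <- c(msg, sprintf(
                    "entry %d: intensities must be >= 0 with at least one > 0",
                    i))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("SpectralLibrary", .validSpectralLibrary)

#' TICMap: per-pixel total ion current
#'
#' @slot grid nLines x nCols matrix of summed MS1 TIC per pixel; pixels never
#'   visited by a laser-active MS1 scan are NA, not zero.
#' @slot mask logical matrix, TRUE where the laser was active for at least
#'   one mapped MS1 scan.
#' @exportClass TICMap
setClass("TICMap",
    representation(grid = "matrix", mask = "matrix"))

setValidity("TICMap", function(object) {
    if (!identical(dim(object@grid), dim(object@mask)))
        return("grid and mask dimensions differ")
    v <- object@grid[!is.na(object@grid)]
    if (any(v < 0)) return("TIC values must be >= 0")
    TRUE
})

#' IonImage: an extracted ion map
#'
#' Per-pixel summed intensity of centroid peaks within a symmetric ppm
#' window around a target m/z, optionally divided pixel-wise by the TIC map.
#'
#' @slot targetMz target m/z, Thomson.
#' @slot tolPpm half-window in ppm.
#' @slot grid nLines x nCols intensity matrix (NA = missing pixel).
#' @slot normalized TRUE if TIC-normalized.
#' @exportClass IonImage
setClass("IonImage",
    representation(targetMz = "numeric", tolPpm = "numeric",
                   grid = "matrix", normalized = "logical"))

setValidity("IonImage", function(object) {
    msg <- character()
    if (object@targetMz <= 0) msg <- c(msg, "targetMz must be > 0")
    if (object@tolPpm <= 0) msg <- c(msg, "tolPpm must be > 0")
    v <- object@grid[!is.na(object@grid)]
    if (any(v < 0)) msg <- c(msg, "grid values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' SimConfig: configuration of a simulated MSI-DDA run
#'
#' Full description of a synthetic acquisition: grid and raster geometry,
#' instrument polarity and mass range, DDA engine settings (acquisition
#' mode, TopN, minimum precursor intensity, isolation width, dynamic
#' exclusion, exclusion list) and the scene (planted compounds with phantom
#' masks, matrix background ions, noise model).
#'
#' @slot geometry a \linkS4class{RasterGeometry}.
#' @slot polarity "positive" or "negative".
#' @slot massRange numeric(2), emitted peaks are confined to this window.
#' @slot mode "parallel" or "sequential".
#' @slot topN MS2 scans per full-scan cycle in sequential mode.
#' @slot minPrecursorIntensity minimum MS1 peak intensity eligible for MS2.
#' @slot isolationWidth precursor isolation window, Thomson.
#' @slot dynamicExclusion named numeric(3): \code{max_occurrences},
#'   \code{occurrence_window_s}, \code{exclusion_duration_s}; length-0 to
#'   disable.
#' @slot exclusionList m/z values never selected as precursors.
#' @slot compounds list of planted compounds (see \code{\link{simCompound}}).
#' @slot matrixIons data.frame: \code{mz}, \code{off_tissue_intensity},
#'   \code{on_tissue_intensity}.
#' @slot tissueMask logical matrix; where matrix ions use their on-tissue
#'   intensity. Defaults to the union of compound masks.
#' @slot noiseCv coefficient of variation of multiplicative log-normal
#'   intensity noise.
#' @slot mzJitterPpm standard deviation of Gaussian m/z jitter, ppm.
#' @slot tolPpm ppm tolerance the DDA engine uses for exclusion-list
#'   matching and dynamic-exclusion m/z clustering.
#' @slot interLineGap stage retrace time between raster lines, s.
#' @slot laserMargin seconds before each line end at which the laser shuts
#'   off (0 = laser active for the whole line).
#' @slot seed RNG seed making the run reproducible.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        geometry = "RasterGeometry",
        polarity = "character",
        massRange = "numeric",
        mode = "character",
        topN = "integer",
        minPrecursorIntensity = "numeric",
        isolationWidth = "numeric",
        dynamicExclusion = "numeric",
        exclusionList = "numeric",
        compounds = "list",
        matrixIons = "data.frame",
        tissueMask = "matrix",
        noiseCv = "numeric",
        mzJitterPpm = "numeric",
        tolPpm = "numeric",
        interLineGap = "numeric",
        laserMargin = "numeric",
        seed = "integer"
    )
)

.validSimConfig <- function(object) {
    msg <- character()
    g <- object@geometry
    if (!object@polarity %in% c("positive", "negative"))
        msg <- c(msg, "polarity must be 'positive' or 'negative'")
    if (!object@mode %in% c("parallel", "sequential"))
        msg <- c(msg, "mode must be 'parallel' or 'sequential'")
    if (object@topN < 1L) msg <- c(msg, "topN must be >= 1")
    if (length(object@massRange) != 2L ||
        object@massRange[1] >= object@massRange[2])
        msg <- c(msg, "massRange must be c(low, high) with low < high")
    de <- object@dynamicExclusion
    if (length(de) > 0) {
        need <- c("max_occurrences", "occurrence_window_s",
                  "exclusion_duration_s")
        if (!all(need %in% names(de)) || any(de[need] <= 0))
            msg <- c(msg, paste(
                "dynamicExclusion needs positive", paste(need, collapse = ", ")))
    }
    if (!identical(dim(object@tissueMask), c(g@nLines, g@nCols)))
        msg <- c(msg, "tissueMask dimensions must match the grid")
    for (cmp in object@compounds) {
        if (!identical(dim(cmp$mask), c(g@nLines, g@nCols))) {
            msg <- c(msg, "every compound mask must match the grid dimensions")
            break
        }
    }
    if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
    if (object@tolPpm <= 0) msg <- c(msg, "tolPpm must be > 0")
    if (object@mzJitterPpm < 0) msg <- c(msg, "mzJitterPpm must be >= 0")
    if (object@laserMargin < 0) msg <- c(msg, "laserMargin must be >= 0")
    if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)
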