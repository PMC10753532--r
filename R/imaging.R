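#' Extract an ion image
#'
#' For each MS1 scan, sums the intensities of centroid peaks within a
#' symmetric ppm window around the target m/z and accumulates them into the
#' pixel the scan maps to. With \code{normalize = TRUE} each pixel is
#' divided by that pixel's total ion current (pixels with zero TIC become
#' missing), which cancels pixel-to-pixel ionization-efficiency variation.
#' Pixels never visited by an MS1 scan are missing (NA), not zero.
#'
#' @param run an \linkS4class{MsiRun}.
#' @param geom a \linkS4class{RasterGeometry}.
#' @param log a \linkS4class{PositionLog}.
#' @param target_mz target m/z; must lie inside the run's mass range.
#' @param tol_ppm half-window, ppm (default 5).
#' @param normalize divide pixel-wise by the TIC map (default FALSE).
#' @return an \linkS4class{IonImage}.
#' @export
extractIonImage <- function(run, geom, log, target_mz, tol_ppm = 5,
                            normalize = FALSE) {
    if (tol_ppm <= 0) stop("tol_ppm must be > 0")
    mr <- run@massRange
    if (target_mz < mr[1] || target_mz > mr[2])
        stop(sprintf("target m/z %.4f outside the run mass range %g-%g",
                     target_mz, mr[1], mr[2]))
    si <- run@scanInfo
    tol_da <- target_mz * tol_ppm * 1e-6
    grid <- matrix(NA_real_, geom@nLines, geom@nCols)
    ms1 <- which(si$ms_level == 1L)
    if (length(ms1)) {
        px <- scanToPixel(si$time_s[ms1], geom, log)
        for (j in seq_along(ms1)) {
            r <- px[j, 1]
            if (is.na(r)) next
            p <- run@peaks[[ms1[j]]]
            hit <- abs(p[, 1] - target_mz) <= tol_da
            val <- sum(p[hit, 2])
            r <- r + 1L
            cc <- px[j, 2] + 1L
            grid[r, cc] <- sum(grid[r, cc], val, na.rm = TRUE)
        }
    }
    if (normalize) {
        tic <- buildTicMap(run, geom, log)@grid
        grid <- ifelse(!is.na(tic) & tic > 0, grid / tic, NA_real_)
    }
    new("IonImage", targetMz = as.numeric(target_mz),
        tolPpm = as.numeric(tol_ppm), grid = grid,
        normalized = isTRUE(normalize))
}

#' Extracted-ion chromatogram across MS1 scans
#'
#' Time-ordered extracted-ion intensities over all MS1 scans — the
#' chromatogram view used to diagnose ubiquitous matrix signals (e.g. the
#' CHCA-related ion near m/z 265.96, near-constant wherever the laser hits
#' matrix).
#'
#' @param run an \linkS4class{MsiRun}.
#' @param target_mz target m/z.
#' @param tol_ppm half-window, ppm (default 5).
#' @return data.frame with one row per MS1 scan: \code{scan_index},
#'   \code{time_s}, \code{intensity}.
#' @export
matrixIonTrace <- function(run, target_mz, tol_ppm = 5) {
    si <- run@scanInfo
    ms1 <- which(si$ms_level == 1L)
    tol_da <- target_mz * tol_ppm * 1e-6
    intensity <- vapply(ms1, function(i) {
        p <- run@peaks[[i]]
        sum(p[abs(p[, 1] - target_mz) <= tol_da, 2])
    }, numeric(1))
    data.frame(scan_index = si$index[ms1], time_s = si$time_s[ms1],
               intensity = intensity)
}

#' Composite 2-3 ion images into an RGB overlay
#'
#' Each channel is min-max scaled to [0, 1] independently and placed in the
#' R, G, B planes (a missing third channel is zero-filled). Missing pixels
#' render as 0 (black).
#'
#' @param images list of 2 or 3 \linkS4class{IonImage}s with identical
#'   dimensions.
#' @return numeric array nLines x nCols x 3 with values in [0, 1].
#' @export
mergeChannels <- function(images) {
    if (length(images) < 2 || length(images) > 3)
        stop("mergeChannels needs 2 or 3 images")
    dims <- lapply(images, function(im) dim(im@grid))
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
        stop("all images must have identical dimensions")
    scale01 <- function(g) {
        g[is.na(g)] <- 0
        rng <- range(g)
        if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else g * 0
    }
    out <- array(0, dim = c(dims[[1]], 3))
    for (k in seq_along(images)) out[, , k] <- scale01(images[[k]]@grid)
    out
}

#' Write an image grid as CSV
#'
#' Plain-text matrix export, the bit-exact test surface of the imaging
#' stage. Missing pixels are serialized as empty cells.
#'
#' @param x an \linkS4class{IonImage}, \linkS4class{TICMap} or matrix.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeImageCsv <- function(x, path) {
    g <- if (is.matrix(x)) x else x@grid
    utils::write.table(g, path, sep = ",", na = "", row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read an image grid from CSV
#'
#' @param path CSV written by \code{\link{writeImageCsv}}.
#' @return numeric matrix (empty cells become NA).
#' @export
readImageCsv <- function(path) {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                na.strings = "", colClasses = "numeric"))
}

#' Render an image grid to PNG
#'
#' Display-only transform: intensities are clipped at an upper percentile
#' (hot-pixel suppression), min-max scaled and mapped through a viridis
#' palette; missing pixels render black. The stored grid is never modified
#' — quantitation always uses the CSV/in-memory values.
#'
#' @param x an \linkS4class{IonImage}, \linkS4class{TICMap} or matrix.
#' @param path output PNG path.
#' @param clip_quantile upper percentile for display clipping
#'   (default 0.995).
#' @param palette a palette function taking n, default viridis via
#'   \code{grDevices::hcl.colors}.
#' @return \code{path}, invisibly.
#' @export
writeImagePng <- function(x, path, clip_quantile = 0.995,
                          palette = function(n)
                              grDevices::hcl.colors(n, "viridis")) {
    g <- if (is.matrix(x)) x else x@grid
    if (is.array(g) && length(dim(g)) == 3) {
        png::writePNG(g, path)
        return(invisible(path))
    }
    v <- g[!is.na(g)]
    ncol_pal <- 256L
    cols <- grDevices::col2rgb(palette(ncol_pal)) / 255
    rgb <- array(0, dim = c(dim(g), 3))
    if (length(v)) {
        hi <- stats::quantile(v, clip_quantile, names = FALSE)
        lo <- min(v)
        gg <- pmin(g, hi)
        scale <- if (hi > lo) (gg - lo) / (hi - lo) else gg * 0
        idx <- 1L + as.integer(round(scale * (ncol_pal - 1L)))
        for (k in 1:3) {
            plane <- matrix(0, nrow(g), ncol(g))
            ok <- !is.na(idx)
            plane[ok] <- cols[k, idx[ok]]
            rgb[, , k] <- plane
        }
    }
    png::writePNG(rgb, path)
    invisible(path)
}
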