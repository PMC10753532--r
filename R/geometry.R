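#' Is the laser firing at a given time?
#'
#' Laser intervals are half-open: t = t_on is active, t = t_off is not.
#'
#' @param t time(s) in seconds from run start; vectorized.
#' @param log a \linkS4class{PositionLog}.
#' @return logical vector.
#' @export
laserActive <- function(t, log) {
    li <- log@laserIntervals
    if (nrow(li) == 0) return(rep(FALSE, length(t)))
    vapply(t, function(x) any(x >= li$t_on_s & x < li$t_off_s), logical(1))
}

#' Map acquisition time to a pixel coordinate
#'
#' The row is the raster line whose half-open time window
#' \code{[t_start, t_end)} contains t; the column is
#' \code{floor((t - t_start) * velocity / pitch)}, clipped to the grid.
#' Serpentine geometries mirror the column on odd rows. Times between lines
#' map to no pixel (NA).
#'
#' @param t time(s) in seconds; vectorized.
#' @param geom a \linkS4class{RasterGeometry}.
#' @param log a \linkS4class{PositionLog}.
#' @return integer matrix with columns \code{row}, \code{col} (0-based),
#'   NA rows where t falls outside every line.
#' @export
scanToPixel <- function(t, geom, log) {
    ln <- log@lines
    out <- matrix(NA_integer_, nrow = length(t), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
    if (nrow(ln) == 0) return(out)
    for (k in seq_along(t)) {
        i <- which(t[k] >= ln$t_start_s & t[k] < ln$t_end_s)
        if (length(i) == 0) next
        i <- i[1]
        row <- ln$line_index[i]
        # scans commonly start exactly on a pixel boundary; the epsilon
        # keeps floating-point round-off from landing them one pixel short
        col <- floor((t[k] - ln$t_start_s[i]) * geom@plateVelocity /
                     geom@pixelPitch + 1e-9)
        col <- min(max(col, 0), geom@nCols - 1L)
        if (geom@serpentine && row %% 2L == 1L)
            col <- geom@nCols - 1L - col
        if (row < 0 || row >= geom@nLines) next
        out[k, ] <- c(as.integer(row), as.integer(col))
    }
    out
}

#' Build the total ion map of a run
#'
#' Accumulates (sums) each MS1 scan's TIC into the pixel its acquisition
#' time maps to; MS2 scans are excluded. Pixels never visited by an MS1 scan
#' stay NA (missing), not zero; the mask records where the laser was active
#' at a mapped scan's time.
#'
#' @param run an \linkS4class{MsiRun}.
#' @param geom a \linkS4class{RasterGeometry}.
#' @param log a \linkS4class{PositionLog}.
#' @return a \linkS4class{TICMap}.
#' @export
buildTicMap <- function(run, geom, log) {
    si <- run@scanInfo
    grid <- matrix(NA_real_, geom@nLines, geom@nCols)
    mask <- matrix(FALSE, geom@nLines, geom@nCols)
    ms1 <- which(si$ms_level == 1L)
    if (length(ms1)) {
        px <- scanToPixel(si$time_s[ms1], geom, log)
        las <- laserActive(si$time_s[ms1], log)
        for (j in seq_along(ms1)) {
            r <- px[j, 1]
            if (is.na(r)) next
            r <- r + 1L
            cc <- px[j, 2] + 1L
            grid[r, cc] <- sum(grid[r, cc], si$tic[ms1[j]], na.rm = TRUE)
            mask[r, cc] <- mask[r, cc] || las[j]
        }
    }
    new("TICMap", grid = grid, mask = mask)
}
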