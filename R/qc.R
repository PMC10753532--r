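#' Precursor-consistency window for an acquisition mode
#'
#' In parallel (multi-analyzer) acquisition the selected precursor must
#' re-appear in the next two survey scans; in sequential acquisition, in the
#' next one.
#'
#' @param mode "parallel" or "sequential".
#' @return 2L for parallel, 1L for sequential.
#' @export
consistencyWindow <- function(mode = c("parallel", "sequential")) {
    mode <- match.arg(mode)
    if (mode == "parallel") 2L else 1L
}

#' Check precursor persistence after an MS2 scan
#'
#' The second validity criterion of the MS2 quality filter: each of the next
#' \code{window} MS1 full scans strictly after the MS2 scan must contain a
#' centroid peak matching the precursor m/z within \code{tol_ppm}.
#' Interleaved MS2 scans are skipped when counting the window (a precursor
#' can only be re-observed in a survey scan). If fewer than \code{window}
#' MS1 scans remain in the run the criterion fails (conservative end-of-run
#' policy).
#'
#' @param run an \linkS4class{MsiRun}.
#' @param i 1-based position of the MS2 scan in the stream.
#' @param window number of following MS1 scans to check (see
#'   \code{\link{consistencyWindow}}).
#' @param tol_ppm match tolerance in ppm.
#' @param min_intensity minimum centroid intensity counting as present
#'   (default 0: any matching centroid).
#' @return list with \code{ok} (logical) and \code{checked} (0-based indices
#'   of the MS1 scans inspected).
#' @export
precursorConsistent <- function(run, i, window, tol_ppm = 5,
                                min_intensity = 0) {
    si <- run@scanInfo
    if (si$ms_level[i] != 2L) stop("scan ", i, " is not an MS2 scan")
    pmz <- si$precursor_mz[i]
    following <- which(si$ms_level == 1L & seq_len(nrow(si)) > i)
    checked <- utils::head(following, window)
    if (length(checked) < window)
        return(list(ok = FALSE, checked = si$index[checked]))
    tol_da <- pmz * tol_ppm * 1e-6
    ok <- all(vapply(checked, function(j) {
        p <- run@peaks[[j]]
        nrow(p) > 0 && any(abs(p[, 1] - pmz) <= tol_da &
                           p[, 2] >= min_intensity)
    }, logical(1)))
    list(ok = ok, checked = si$index[checked])
}

#' Two-criterion MS2 quality assessment of a run
#'
#' Separates usable fragmentation spectra from artifacts with the two
#' validity criteria: (i) the laser must be active at the MS2 scan's start
#' time, and (ii) the selected precursor must re-appear, within
#' \code{tol_ppm}, in the MS1 scans following the one in which it was chosen
#' (two scans for parallel acquisition, one for sequential). A spectrum is
#' valid only if both hold.
#'
#' @param run an \linkS4class{MsiRun}.
#' @param log a \linkS4class{PositionLog}.
#' @param mode "parallel" or "sequential".
#' @param tol_ppm precursor-consistency tolerance, ppm (default 5).
#' @param min_intensity minimum centroid intensity counting as present.
#' @return list with \code{verdicts}, a data.frame with one row per MS2 scan
#'   (columns \code{scan_index}, \code{laser_ok}, \code{consistency_ok},
#'   \code{valid}, \code{checked_scan_indices} as a comma-joined string),
#'   and \code{counts}, the named vector \code{c(total, laser_active,
#'   valid)} behind the quality-assessment Venn diagram.
#' @export
assessRun <- function(run, log, mode = c("parallel", "sequential"),
                      tol_ppm = 5, min_intensity = 0) {
    mode <- match.arg(mode)
    if (tol_ppm <= 0) stop("tol_ppm must be > 0")
    window <- consistencyWindow(mode)
    si <- run@scanInfo
    ms2 <- which(si$ms_level == 2L)
    verdicts <- data.frame(
        scan_index = integer(length(ms2)), laser_ok = logical(length(ms2)),
        consistency_ok = logical(length(ms2)), valid = logical(length(ms2)),
        checked_scan_indices = character(length(ms2)),
        stringsAsFactors = FALSE)
    for (k in seq_along(ms2)) {
        i <- ms2[k]
        las <- laserActive(si$time_s[i], log)
        cons <- precursorConsistent(run, i, window, tol_ppm, min_intensity)
        verdicts$scan_index[k] <- si$index[i]
        verdicts$laser_ok[k] <- las
        verdicts$consistency_ok[k] <- cons$ok
        verdicts$valid[k] <- las && cons$ok
        verdicts$checked_scan_indices[k] <- paste(cons$checked, collapse = ",")
    }
    counts <- c(total = length(ms2),
                laser_active = sum(verdicts$laser_ok),
                valid = sum(verdicts$valid))
    list(verdicts = verdicts, counts = counts)
}

#' Write a QC report
#'
#' Per-MS2 verdict TSV plus a summary block (as comment lines) with the
#' three Venn counts: total MS2, laser-active, fully valid.
#'
#' @param qc result of \code{\link{assessRun}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeQcReport <- function(qc, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# total_ms2\t%d", qc$counts[["total"]]), con)
    writeLines(sprintf("# laser_active\t%d", qc$counts[["laser_active"]]), con)
    writeLines(sprintf("# valid\t%d", qc$counts[["valid"]]), con)
    utils::write.table(qc$verdicts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
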