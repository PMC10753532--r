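# Workflow wrappers behind the command-line entry point
# (inst/scripts/msidda.R). Each takes the three pipeline inputs — mzML scan
# stream, position/laser log, library folder — plus the three user
# parameters (acquisition mode, TIC normalization, ppm tolerance), and
# writes its outputs under an output directory. All outputs are
# deterministic for fixed inputs.

.checkRunConfig <- function(mzml_path, log_path, library_dir, tol_ppm) {
    if (!file.exists(mzml_path)) stop("mzML file not found: ", mzml_path)
    if (!file.exists(log_path)) stop("position log not found: ", log_path)
    if (!dir.exists(library_dir))
        stop("library folder not found: ", library_dir)
    if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0)
        stop("tol_ppm must be a positive number")
    invisible(TRUE)
}

#' Quality-assess a run from its files
#'
#' Reads the scan stream and position log, runs the two-criterion MS2
#' quality filter, writes \code{qc_report.tsv} and returns the three Venn
#' counts (total MS2, laser-active, fully valid).
#'
#' @param mzml_path mzML scan stream.
#' @param log_path position/laser XML log.
#' @param out_dir output directory, created if needed.
#' @param mode "parallel" or "sequential".
#' @param tol_ppm precursor-consistency tolerance, ppm.
#' @return the \code{\link{assessRun}} result, invisibly.
#' @export
runQc <- function(mzml_path, log_path, out_dir = ".",
                  mode = c("parallel", "sequential"), tol_ppm = 5) {
    mode <- match.arg(mode)
    if (tol_ppm <= 0) stop("tol_ppm must be a positive number")
    run <- readMzML(mzml_path)
    log <- readPositionLog(log_path)
    qc <- assessRun(run, log, mode, tol_ppm)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeQcReport(qc, file.path(out_dir, "qc_report.tsv"))
    message(sprintf("MS2 scans: %d total, %d laser-active, %d valid",
                    qc$counts[["total"]], qc$counts[["laser_active"]],
                    qc$counts[["valid"]]))
    invisible(qc)
}

#' Annotate a run from its files
#'
#' The full workflow: read the three inputs, quality-filter the MS2 scans,
#' annotate every valid spectrum against the libraries, and write
#' \code{annotations.tsv}, \code{qc_report.tsv}, a per-compound
#' \code{compound_summary.tsv} and one extracted-ion image
#' (\code{eim_<compound>_<adduct>.csv/.png}) per annotated compound/adduct
#' pair. A run with zero valid MS2 scans yields an empty annotation table
#' with a warning, not an error.
#'
#' @param mzml_path mzML scan stream.
#' @param log_path position/laser XML log.
#' @param library_dir folder of MSP/XML spectral libraries.
#' @param out_dir output directory.
#' @param geom a \linkS4class{RasterGeometry}; NULL derives it from the log
#'   via \code{\link{geometryFromLog}} at \code{cycle_period}.
#' @param mode "parallel" or "sequential".
#' @param tol_ppm ppm tolerance for QC and exact-mass matching (default 5).
#' @param tic_normalize TIC-normalize the exported ion images
#'   (default FALSE).
#' @param cycle_period full-scan cycle period used when deriving geometry
#'   from the log, s.
#' @param write_images write per-compound EIMs (default TRUE).
#' @return the annotation data.frame, invisibly.
#' @export
runAnnotate <- function(mzml_path, log_path, library_dir, out_dir = ".",
                        geom = NULL, mode = c("parallel", "sequential"),
                        tol_ppm = 5, tic_normalize = FALSE,
                        cycle_period = 0.6, write_images = TRUE) {
    mode <- match.arg(mode)
    .checkRunConfig(mzml_path, log_path, library_dir, tol_ppm)
    run <- readMzML(mzml_path)
    log <- readPositionLog(log_path)
    lib <- readLibraryFolder(library_dir)
    if (is.null(geom))
        geom <- geometryFromLog(log, plateVelocity = 100 / cycle_period,
                                cyclePeriod = cycle_period)
    qc <- assessRun(run, log, mode, tol_ppm)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeQcReport(qc, file.path(out_dir, "qc_report.tsv"))
    if (qc$counts[["valid"]] == 0)
        warning("no MS2 scan passed the quality filter; ",
                "writing an empty annotation table")
    ann <- annotateRun(run, geom, log, lib, mode, tol_ppm, qc = qc)
    writeAnnotationTable(ann, file.path(out_dir, "annotations.tsv"))
    smry <- compoundSummary(ann)
    utils::write.table(smry, file.path(out_dir, "compound_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_images && nrow(ann)) {
        pairs <- unique(ann[, c("compound_id", "adduct", "precursor_mz")])
        pairs <- pairs[!duplicated(pairs[, c("compound_id", "adduct")]), ,
                       drop = FALSE]
        for (i in seq_len(nrow(pairs))) {
            img <- extractIonImage(run, geom, log, pairs$precursor_mz[i],
                                   tol_ppm, normalize = tic_normalize)
            stem <- file.path(out_dir, sprintf("eim_%s_%s",
                gsub("[^A-Za-z0-9._-]", "_", pairs$compound_id[i]),
                gsub("[^A-Za-z0-9._+-]", "", pairs$adduct[i])))
            writeImageCsv(img, paste0(stem, ".csv"))
            writeImagePng(img, paste0(stem, ".png"))
        }
    }
    message(sprintf("annotated %d of %d valid MS2 scans (%d compounds)",
                    nrow(ann), qc$counts[["valid"]], nrow(smry)))
    invisible(ann)
}

#' Extract and export one ion image from files
#'
#' @param mzml_path mzML scan stream.
#' @param log_path position/laser XML log.
#' @param target_mz target m/z (must be inside the run's mass range).
#' @param out_dir output directory.
#' @param geom a \linkS4class{RasterGeometry}; NULL derives it from the log.
#' @param tol_ppm half-window, ppm.
#' @param tic_normalize divide pixel-wise by the TIC map.
#' @param cycle_period cycle period for geometry derivation, s.
#' @return the \linkS4class{IonImage}, invisibly; writes
#'   \code{image_<mz>.csv} and \code{.png}.
#' @export
runImage <- function(mzml_path, log_path, target_mz, out_dir = ".",
                     geom = NULL, tol_ppm = 5, tic_normalize = FALSE,
                     cycle_period = 0.6) {
    run <- readMzML(mzml_path)
    log <- readPositionLog(log_path)
    if (is.null(geom))
        geom <- geometryFromLog(log, plateVelocity = 100 / cycle_period,
                                cyclePeriod = cycle_period)
    img <- extractIonImage(run, geom, log, target_mz, tol_ppm,
                           normalize = tic_normalize)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- file.path(out_dir, sprintf("image_%.4f", target_mz))
    writeImageCsv(img, paste0(stem, ".csv"))
    writeImagePng(img, paste0(stem, ".png"))
    invisible(img)
}
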