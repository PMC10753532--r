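.annotationCols <- c("scan_index", "precursor_mz", "adduct",
    "neutral_mass_hypothesis", "compound_id", "formula", "ppm_error",
    "cosine_score", "provenance", "pixel_row", "pixel_col")

#' Write an annotation table
#'
#' One TSV row per annotated MS2 scan, stable column order, lossless
#' round-trip via \code{\link{readAnnotationTable}}. Zero records give a
#' header-only file.
#'
#' @param records annotation data.frame as returned by
#'   \code{\link{annotateRun}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationTable <- function(records, path) {
    if (is.null(records) || nrow(records) == 0) {
        records <- as.data.frame(
            setNames(rep(list(character(0)), length(.annotationCols)),
                     .annotationCols))
    }
    missing <- setdiff(.annotationCols, names(records))
    if (length(missing))
        stop("annotation records lack columns: ",
             paste(missing, collapse = ", "))
    out <- records[, .annotationCols, drop = FALSE]
    for (col in c("precursor_mz", "neutral_mass_hypothesis", "ppm_error",
                  "cosine_score"))
        if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.9g", out[[col]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Read an annotation table
#'
#' @param path TSV written by \code{\link{writeAnnotationTable}}.
#' @return annotation data.frame.
#' @export
readAnnotationTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = "",
                            colClasses = "character")
    for (col in c("precursor_mz", "neutral_mass_hypothesis", "ppm_error",
                  "cosine_score"))
        df[[col]] <- as.numeric(df[[col]])
    for (col in c("scan_index", "pixel_row", "pixel_col"))
        df[[col]] <- as.integer(df[[col]])
    df
}
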