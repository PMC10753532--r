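#' Read a centroided mzML scan stream
#'
#' Reads all MS1 and MS2 scans in acquisition order with times in seconds.
#' Precursor m/z and isolation width are populated for MS2 scans; run
#' polarity is taken from the scan metadata. Profile-mode spectra are
#' rejected explicitly rather than silently centroided.
#'
#' @param path path to an mzML file.
#' @return an \linkS4class{MsiRun}.
#' @export
readMzML <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    # xml2 first: it reports the location of malformed XML, which mzR does not
    tryCatch(invisible(xml2::read_xml(path)),
             error = function(e) stop("malformed mzML in '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
    h <- NULL
    ms <- mzR::openMSfile(path, backend = "pwiz")
    on.exit(mzR::close(ms), add = TRUE)
    n <- length(ms)
    if (n == 0L) {
        return(MsiRun(
            scanInfo = data.frame(time_s = numeric(), ms_level = integer(),
                                  precursor_mz = numeric(),
                                  isolation_width = numeric()),
            peaks = list()))
    }
    h <- mzR::header(ms)
    if (any(!is.na(h$centroided) & !h$centroided))
        stop("profile-mode spectra are not supported; ",
             "centroid the data during mzML conversion")
    pk <- mzR::peaks(ms)
    if (n == 1L) pk <- list(pk)
    pol <- h$polarity[!is.na(h$polarity) & h$polarity >= 0]
    polarity <- if (length(pol) && pol[1] == 0L) "negative" else "positive"
    iw <- h$isolationWindowLowerOffset + h$isolationWindowUpperOffset
    prec <- ifelse(h$msLevel == 2L, h$precursorMZ, NA_real_)
    prec[!is.na(prec) & prec == 0] <- NA_real_
    si <- data.frame(
        time_s = h$retentionTime,
        ms_level = as.integer(h$msLevel),
        precursor_mz = prec,
        isolation_width = ifelse(h$msLevel == 2L, iw, NA_real_))
    mr <- NULL
    lo <- suppressWarnings(min(h$scanWindowLowerLimit, na.rm = TRUE))
    hi <- suppressWarnings(max(h$scanWindowUpperLimit, na.rm = TRUE))
    if (is.finite(lo) && is.finite(hi) && lo > 0 && hi > lo) mr <- c(lo, hi)
    MsiRun(scanInfo = si, peaks = pk, polarity = polarity, massRange = mr)
}

#' Write an MsiRun to mzML
#'
#' Emits a PSI-standard mzML file (centroid spectra) that round-trips
#' through \code{\link{readMzML}}: scan times, levels, precursor and
#' isolation-window metadata and peak lists are preserved.
#'
#' @param run an \linkS4class{MsiRun}.
#' @param path output file path (conventionally \code{.mzML}).
#' @return \code{path}, invisibly.
#' @export
writeMzML <- function(run, path) {
    validObject(run)
    si <- run@scanInfo
    n <- nrow(si)
    if (n == 0L) {
        # mzR cannot write a spectrum-less file; emit a minimal valid mzML
        cvuri <- paste0("https://raw.githubusercontent.com/HUPO-PSI/",
                        "psi-ms-CV/master/psi-ms.obo")
        writeLines(c(
            '<?xml version="1.0" encoding="utf-8"?>',
            '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
            '  <cvList count="1">',
            sprintf('    <cv id="MS" fullName="PSI-MS" URI="%s"/>', cvuri),
            '  </cvList>',
            '  <fileDescription>',
            '    <fileContent>',
            paste0('      <cvParam cvRef="MS" accession="MS:1000579" ',
                   'name="MS1 spectrum" value=""/>'),
            '    </fileContent>',
            '  </fileDescription>',
            '  <softwareList count="1">',
            '    <software id="sw" version="0.1">',
            paste0('      <cvParam cvRef="MS" accession="MS:1000799" ',
                   'name="custom unreleased software tool" value=""/>'),
            '    </software>',
            '  </softwareList>',
            '  <instrumentConfigurationList count="1">',
            '    <instrumentConfiguration id="IC">',
            paste0('      <cvParam cvRef="MS" accession="MS:1000031" ',
                   'name="instrument model" value=""/>'),
            '    </instrumentConfiguration>',
            '  </instrumentConfigurationList>',
            '  <dataProcessingList count="1">',
            '    <dataProcessing id="dp">',
            '      <processingMethod order="0" softwareRef="sw">',
            paste0('        <cvParam cvRef="MS" accession="MS:1000544" ',
                   'name="Conversion to mzML" value=""/>'),
            '      </processingMethod>',
            '    </dataProcessing>',
            '  </dataProcessingList>',
            '  <run id="run" defaultInstrumentConfigurationRef="IC">',
            '    <spectrumList count="0" defaultDataProcessingRef="dp">',
            '    </spectrumList>',
            '  </run>',
            '</mzML>'), path)
        return(invisible(path))
    }
    pol <- if (run@polarity == "positive") 1L else 0L
    basemz <- vapply(run@peaks, function(p)
        if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1))
    baseint <- vapply(run@peaks, function(p)
        if (nrow(p)) max(p[, 2]) else 0, numeric(1))
    lowmz <- vapply(run@peaks, function(p)
        if (nrow(p)) p[1, 1] else 0, numeric(1))
    highmz <- vapply(run@peaks, function(p)
        if (nrow(p)) p[nrow(p), 1] else 0, numeric(1))
    ms2 <- si$ms_level == 2L
    # precursorScanNum: most recent preceding MS1 scan (0 if none)
    lastms1 <- 0L
    pscan <- integer(n)
    for (i in seq_len(n)) {
        pscan[i] <- if (ms2[i]) lastms1 else 0L
        if (!ms2[i]) lastms1 <- i
    }
    hdr <- data.frame(
        seqNum = seq_len(n), acquisitionNum = seq_len(n),
        msLevel = si$ms_level, polarity = rep(pol, n),
        peaksCount = vapply(run@peaks, nrow, integer(1)),
        totIonCurrent = si$tic, retentionTime = si$time_s,
        basePeakMZ = basemz, basePeakIntensity = baseint,
        collisionEnergy = ifelse(ms2, 40, 0), ionisationEnergy = 0,
        lowMZ = lowmz, highMZ = highmz,
        precursorScanNum = pscan,
        precursorMZ = ifelse(ms2, si$precursor_mz, 0),
        precursorCharge = ifelse(ms2, 1L, 0L),
        precursorIntensity = 0,
        mergedScan = 0L, mergedResultScanNum = 0L,
        mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
        injectionTime = 0, filterString = NA_character_,
        spectrumId = paste0("scan=", seq_len(n)),
        centroided = TRUE, ionMobilityDriftTime = NA_real_,
        isolationWindowTargetMZ = ifelse(ms2, si$precursor_mz, NA_real_),
        isolationWindowLowerOffset = ifelse(ms2, si$isolation_width / 2,
                                            NA_real_),
        isolationWindowUpperOffset = ifelse(ms2, si$isolation_width / 2,
                                            NA_real_),
        scanWindowLowerLimit = run@massRange[1],
        scanWindowUpperLimit = run@massRange[2],
        stringsAsFactors = FALSE)
    pk <- lapply(run@peaks, function(p) {
        storage.mode(p) <- "double"
        p
    })
    suppressWarnings(
        mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml"))
    invisible(path)
}
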