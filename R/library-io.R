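# Two on-disk library dialects are supported and produce identical
# SpectralLibrary content from equivalent records:
#
# 1. NIST-style MSP text, one block per entry:
#      NAME: palmitic acid
#      ID: cpd0001
#      FORMULA: C16H32O2
#      EXACTMASS: 256.240230
#      ADDUCT: [M+H]+
#      COLLISIONENERGY: 40
#      PROVENANCE: predicted
#      Num Peaks: 3
#      57.0699 100
#      ...
#    (blank line between entries; unknown headers are ignored; ADDUCT,
#    COLLISIONENERGY and PROVENANCE are optional.)
#
# 2. A minimal XML dialect, one <compound> per entry, emulating the shape of
#    HMDB "MS-MS Spectra Files (XML)" exports:
#      <library>
#        <compound id="cpd0001" name="..." formula="..."
#                  exact_mass="256.240230" adduct="[M+H]+"
#                  collision_energy="40" provenance="predicted">
#          <peak mz="57.0699" intensity="100"/>
#          ...
#        </compound>
#      </library>

.emptyLibraryEntries <- function(n = 0) {
    data.frame(compound_id = character(n), name = character(n),
               formula = character(n), exact_mass = numeric(n),
               adduct = character(n), collision_energy = numeric(n),
               provenance = character(n), stringsAsFactors = FALSE)
}

#' Read an MSP spectral library file
#'
#' @param path path to an MSP text file.
#' @return a \linkS4class{SpectralLibrary}.
#' @export
readMsp <- function(path) {
    txt <- readLines(path, warn = FALSE)
    entries <- .emptyLibraryEntries()
    peaks <- list()
    i <- 1L
    n <- length(txt)
    while (i <= n) {
        while (i <= n && !nzchar(trimws(txt[i]))) i <- i + 1L
        if (i > n) break
        fields <- list()
        while (i <= n && grepl("^[A-Za-z][A-Za-z0-9_ ]*:", txt[i])) {
            key <- toupper(trimws(sub(":.*$", "", txt[i])))
            val <- trimws(sub("^[^:]*:", "", txt[i]))
            fields[[key]] <- val
            i <- i + 1L
        }
        if (is.null(fields[["NAME"]]))
            stop("MSP parse error in '", path, "' near line ", i,
                 ": entry without NAME")
        npk <- fields[["NUM PEAKS"]]
        if (is.null(npk))
            stop("MSP parse error in '", path, "' near line ", i,
                 ": entry without 'Num Peaks'")
        npk <- as.integer(npk)
        pk <- matrix(numeric(0), 0, 2)
        if (npk > 0) {
            if (i + npk - 1L > n)
                stop("MSP parse error in '", path, "' near line ", i,
                     ": fewer peak lines than 'Num Peaks'")
            rows <- strsplit(trimws(txt[i:(i + npk - 1L)]), "[\t ;]+")
            pk <- t(vapply(rows, function(r) as.numeric(r[1:2]), numeric(2)))
            if (any(!is.finite(pk)))
                stop("MSP parse error in '", path, "' near line ", i,
                     ": unreadable peak line")
            i <- i + npk
        }
        num <- function(key) {
            v <- fields[[key]]
            if (is.null(v)) NA_real_ else as.numeric(v)
        }
        chr <- function(key, default = NA_character_) {
            v <- fields[[key]]
            if (is.null(v) || !nzchar(v)) default else v
        }
        exact_mass <- num("EXACTMASS")
        if (!is.finite(exact_mass))
            stop("MSP parse error in '", path, "' near line ", i,
                 ": entry '", fields[["NAME"]], "' without EXACTMASS")
        entries <- rbind(entries, data.frame(
            compound_id = chr("ID", default = fields[["NAME"]]),
            name = fields[["NAME"]],
            formula = chr("FORMULA"),
            exact_mass = exact_mass,
            adduct = chr("ADDUCT", chr("PRECURSORTYPE")),
            collision_energy = num("COLLISIONENERGY"),
            provenance = chr("PROVENANCE", "experimental"),
            stringsAsFactors = FALSE))
        pk <- pk[order(pk[, 1]), , drop = FALSE]
        peaks[[length(peaks) + 1L]] <- pk
    }
    SpectralLibrary(entries, peaks)
}

#' Write a spectral library as MSP text
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMsp <- function(lib, path) {
    validObject(lib)
    en <- lib@entries
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(en))) {
        pk <- lib@peaks[[i]]
        lines <- c(
            paste0("NAME: ", en$name[i]),
            paste0("ID: ", en$compound_id[i]),
            if (!is.na(en$formula[i])) paste0("FORMULA: ", en$formula[i]),
            sprintf("EXACTMASS: %.9f", en$exact_mass[i]),
            if (!is.na(en$adduct[i])) paste0("ADDUCT: ", en$adduct[i]),
            if (!is.na(en$collision_energy[i]))
                sprintf("COLLISIONENERGY: %g", en$collision_energy[i]),
            paste0("PROVENANCE: ", en$provenance[i]),
            paste0("Num Peaks: ", nrow(pk)),
            sprintf("%.9f %.9g", pk[, 1], pk[, 2]),
            "")
        writeLines(lines, con)
    }
    invisible(path)
}

#' Read a spectral library in the XML dialect
#'
#' @param path path to an XML library file.
#' @return a \linkS4class{SpectralLibrary}.
#' @export
readLibraryXml <- function(path) {
    doc <- tryCatch(xml2::read_xml(path),
        error = function(e) stop("library parse error in '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    cmp <- xml2::xml_find_all(doc, ".//compound")
    attror <- function(nodes, a, default = NA_character_) {
        v <- xml2::xml_attr(nodes, a)
        ifelse(is.na(v) | !nzchar(v), default, v)
    }
    entries <- data.frame(
        compound_id = xml2::xml_attr(cmp, "id"),
        name = attror(cmp, "name"),
        formula = attror(cmp, "formula"),
        exact_mass = as.numeric(xml2::xml_attr(cmp, "exact_mass")),
        adduct = attror(cmp, "adduct"),
        collision_energy = as.numeric(attror(cmp, "collision_energy")),
        provenance = attror(cmp, "provenance", "experimental"),
        stringsAsFactors = FALSE)
    if (nrow(entries) && any(!is.finite(entries$exact_mass)))
        stop("library parse error in '", path,
             "': compound without numeric exact_mass")
    peaks <- lapply(cmp, function(node) {
        pn <- xml2::xml_find_all(node, "./peak")
        pk <- cbind(mz = as.numeric(xml2::xml_attr(pn, "mz")),
                    intensity = as.numeric(xml2::xml_attr(pn, "intensity")))
        if (any(!is.finite(pk)))
            stop("library parse error in '", path, "': non-numeric peak")
        pk[order(pk[, 1]), , drop = FALSE]
    })
    SpectralLibrary(entries, peaks)
}

#' Write a spectral library in the XML dialect
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLibraryXml <- function(lib, path) {
    validObject(lib)
    en <- lib@entries
    doc <- xml2::xml_new_root("library")
    for (i in seq_len(nrow(en))) {
        at <- list(id = en$compound_id[i], name = en$name[i],
                   exact_mass = sprintf("%.9f", en$exact_mass[i]),
                   provenance = en$provenance[i])
        if (!is.na(en$formula[i])) at$formula <- en$formula[i]
        if (!is.na(en$adduct[i])) at$adduct <- en$adduct[i]
        if (!is.na(en$collision_energy[i]))
            at$collision_energy <- sprintf("%g", en$collision_energy[i])
        node <- do.call(xml2::xml_add_child,
                        c(list(doc, "compound"), at))
        pk <- lib@peaks[[i]]
        for (j in seq_len(nrow(pk)))
            xml2::xml_add_child(node, "peak",
                mz = sprintf("%.9f", pk[j, 1]),
                intensity = sprintf("%.9g", pk[j, 2]))
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

#' Read every spectral library in a folder
#'
#' Reads all \code{*.msp} and \code{*.xml} files and concatenates their
#' entries. Duplicate (compound, adduct, collision energy) tuples are kept:
#' libraries legitimately hold the same compound at several collision
#' energies.
#'
#' @param path folder containing at least one library file.
#' @return a \linkS4class{SpectralLibrary}.
#' @export
readLibraryFolder <- function(path) {
    if (!dir.exists(path)) stop("no such folder: ", path)
    files <- list.files(path, pattern = "\\.(msp|xml)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0)
        stop("no library files (*.msp, *.xml) in folder: ", path)
    libs <- lapply(sort(files), function(f) {
        if (grepl("\\.msp$", f, ignore.case = TRUE)) readMsp(f)
        else readLibraryXml(f)
    })
    do.call(c, libs)
}
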