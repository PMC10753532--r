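# Position-log XML dialect (the stage-control software's line/laser log):
#   <msi_position_log>
#     <lines>
#       <line index="0" t_start="0.0" t_end="12.0" y_um="0.0"/>
#       ...
#     </lines>
#     <laser>
#       <interval t_on="0.0" t_off="12.0"/>
#       ...
#     </laser>
#   </msi_position_log>
# Times in seconds from run start, y in micrometres.

#' Read a position/laser log
#'
#' Parses the XML stage log documented above into a
#' \linkS4class{PositionLog}: one record per raster line plus the intervals
#' during which the laser fired. Records are returned time-ordered;
#' overlapping laser intervals or inverted line times are validation errors.
#'
#' @param path path to the XML log.
#' @return a \linkS4class{PositionLog}.
#' @export
readPositionLog <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    doc <- tryCatch(xml2::read_xml(path),
        error = function(e) stop("malformed position log '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    lnodes <- xml2::xml_find_all(doc, ".//lines/line")
    attrnum <- function(nodes, a)
        as.numeric(xml2::xml_attr(nodes, a))
    lines <- data.frame(
        line_index = as.integer(xml2::xml_attr(lnodes, "index")),
        t_start_s = attrnum(lnodes, "t_start"),
        t_end_s = attrnum(lnodes, "t_end"),
        y_um = attrnum(lnodes, "y_um"))
    if (nrow(lines) && any(!is.finite(as.matrix(lines))))
        stop("position log '", path, "': line record with missing attribute")
    inodes <- xml2::xml_find_all(doc, ".//laser/interval")
    laser <- data.frame(
        t_on_s = attrnum(inodes, "t_on"),
        t_off_s = attrnum(inodes, "t_off"))
    if (nrow(laser) && any(!is.finite(as.matrix(laser))))
        stop("position log '", path, "': laser interval missing attribute")
    PositionLog(lines = lines, laserIntervals = laser)
}

#' Write a position/laser log
#'
#' @param log a \linkS4class{PositionLog}.
#' @param path output XML path.
#' @return \code{path}, invisibly.
#' @export
writePositionLog <- function(log, path) {
    validObject(log)
    fmt <- function(x) sprintf("%.9g", x)
    doc <- xml2::xml_new_root("msi_position_log")
    lines <- xml2::xml_add_child(doc, "lines")
    ln <- log@lines
    for (i in seq_len(nrow(ln)))
        xml2::xml_add_child(lines, "line",
            index = as.character(ln$line_index[i]),
            t_start = fmt(ln$t_start_s[i]),
            t_end = fmt(ln$t_end_s[i]),
            y_um = fmt(ln$y_um[i]))
    laser <- xml2::xml_add_child(doc, "laser")
    li <- log@laserIntervals
    for (i in seq_len(nrow(li)))
        xml2::xml_add_child(laser, "interval",
            t_on = fmt(li$t_on_s[i]), t_off = fmt(li$t_off_s[i]))
    xml2::write_xml(doc, path)
    invisible(path)
}
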