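## Annotation XML dialect
## ----------------------
## ImageScope-compatible structure:
##   <Annotations SpotId Role>
##     <Annotation Name="POSITIVE" Type="Marks"> <Regions>
##        <Region Type="Point" Provenance="AUTO"> <Vertices> <Vertex X Y/> ...
##     <Annotation Name="NEGATIVE" Type="Marks"> ...
##     <Annotation Name="GRID" Type="Grid" SpacingX SpacingY OffsetX OffsetY
##                 ImageWidth ImageHeight Seed>
##        <Regions> <Region Type="Rectangle" FrameId> <Vertices>
##            <Vertex X=x0 Y=y0/> <Vertex X=x0+w Y=y0+h/>
## Point regions carry exactly one vertex; rectangles exactly two with
## corner1 < corner2 on both axes. Coordinates are 0-based integer pixels.
## Labels are carried by the layer, not per-region color.

#' Write marks (and optionally a grid) to annotation XML
#'
#' Serializes a \code{\linkS4class{MarkSet}} — and, if given, a
#' \code{\linkS4class{FrameGrid}} — to the package's ImageScope-style
#' annotation dialect: one layer per mark label plus one grid layer of
#' two-vertex rectangle regions. Output is byte-stable: identical inputs
#' produce identical files.
#'
#' @param markset a \code{\linkS4class{MarkSet}}.
#' @param path output file path.
#' @param grid optional \code{\linkS4class{FrameGrid}}.
#' @return invisibly, \code{path}.
#' @seealso \code{\link{readAnnotations}}
#' @export
writeAnnotations <- function(markset, path, grid = NULL) {
    stopifnot(is(markset, "MarkSet"))
    doc <- xml2::xml_new_root("Annotations",
                              SpotId = spotId(markset), Role = role(markset))
    m <- marks(markset)
    for (lab in .MARK_LABELS) {
        ann <- xml2::xml_add_child(doc, "Annotation", Name = lab, Type = "Marks")
        regs <- xml2::xml_add_child(ann, "Regions")
        sub <- m[m$label == lab, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
            reg <- xml2::xml_add_child(regs, "Region", Type = "Point",
                                       Provenance = sub$provenance[i])
            verts <- xml2::xml_add_child(reg, "Vertices")
            xml2::xml_add_child(verts, "Vertex",
                                X = as.character(sub$x[i]),
                                Y = as.character(sub$y[i]))
        }
    }
    if (!is.null(grid)) {
        stopifnot(is(grid, "FrameGrid"))
        ann <- xml2::xml_add_child(doc, "Annotation", Name = "GRID", Type = "Grid",
                                   SpacingX = as.character(grid@spacingX),
                                   SpacingY = as.character(grid@spacingY),
                                   OffsetX = as.character(grid@offsetX),
                                   OffsetY = as.character(grid@offsetY),
                                   ImageWidth = as.character(grid@imageWidth),
                                   ImageHeight = as.character(grid@imageHeight),
                                   Seed = as.character(grid@seed))
        regs <- xml2::xml_add_child(ann, "Regions")
        f <- frames(grid)
        for (i in seq_len(nrow(f))) {
            reg <- xml2::xml_add_child(regs, "Region", Type = "Rectangle",
                                       FrameId = as.character(f$frameId[i]))
            verts <- xml2::xml_add_child(reg, "Vertices")
            xml2::xml_add_child(verts, "Vertex",
                                X = as.character(f$x0[i]), Y = as.character(f$y0[i]))
            xml2::xml_add_child(verts, "Vertex",
                                X = as.character(f$x0[i] + f$width[i]),
                                Y = as.character(f$y0[i] + f$height[i]))
        }
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

.regionVertices <- function(reg) {
    vs <- xml2::xml_find_all(reg, "./Vertices/Vertex")
    cbind(x = as.numeric(xml2::xml_attr(vs, "X")),
          y = as.numeric(xml2::xml_attr(vs, "Y")))
}

#' Read annotation XML
#'
#' Parses a file written in the package's annotation dialect and recovers
#' the mark set (labels from their layer, provenance from the optional
#' per-region attribute, default \code{AUTO}) and, when a grid layer is
#' present, the counting-frame grid. Layers with unrecognized names are
#' ignored with a warning. Malformed XML raises a parse error naming the
#' line; regions with the wrong vertex count raise a schema error.
#'
#' @param path file path.
#' @return list with elements \code{marks} (a \code{MarkSet}) and
#'   \code{grid} (a \code{FrameGrid}, or \code{NULL} when absent).
#' @seealso \code{\link{writeAnnotations}}
#' @export
readAnnotations <- function(path) {
    doc <- xml2::read_xml(path)
    sid <- xml2::xml_attr(doc, "SpotId"); if (is.na(sid)) sid <- "spot"
    rl <- xml2::xml_attr(doc, "Role");    if (is.na(rl)) rl <- "dD"
    dfs <- list(); grid <- NULL
    for (ann in xml2::xml_find_all(doc, "./Annotation")) {
        nm <- xml2::xml_attr(ann, "Name")
        regs <- xml2::xml_find_all(ann, "./Regions/Region")
        if (nm %in% .MARK_LABELS) {
            rows <- lapply(regs, function(reg) {
                v <- .regionVertices(reg)
                if (nrow(v) != 1L)
                    stop("schema error: point region must have exactly 1 vertex, found ",
                         nrow(v))
                prov <- xml2::xml_attr(reg, "Provenance")
                data.frame(x = v[1, "x"], y = v[1, "y"], label = nm,
                           provenance = if (is.na(prov)) "AUTO" else prov)
            })
            dfs <- c(dfs, rows)
        } else if (identical(nm, "GRID")) {
            att <- function(a) as.numeric(xml2::xml_attr(ann, a))
            fr <- lapply(regs, function(reg) {
                v <- .regionVertices(reg)
                if (nrow(v) != 2L)
                    stop("schema error: rectangle region must have exactly 2 vertices, found ",
                         nrow(v))
                if (v[1, "x"] >= v[2, "x"] || v[1, "y"] >= v[2, "y"])
                    stop("schema error: rectangle corner1 must be < corner2 on both axes")
                data.frame(frameId = as.integer(xml2::xml_attr(reg, "FrameId")),
                           x0 = v[1, "x"], y0 = v[1, "y"],
                           width = v[2, "x"] - v[1, "x"],
                           height = v[2, "y"] - v[1, "y"])
            })
            fr <- if (length(fr)) do.call(rbind, fr) else
                data.frame(frameId = integer(0), x0 = numeric(0), y0 = numeric(0),
                           width = numeric(0), height = numeric(0))
            fr <- fr[order(fr$frameId), , drop = FALSE]
            rownames(fr) <- NULL
            grid <- new("FrameGrid", frames = fr,
                        spacingX = att("SpacingX"), spacingY = att("SpacingY"),
                        offsetX = att("OffsetX"), offsetY = att("OffsetY"),
                        imageWidth = att("ImageWidth"), imageHeight = att("ImageHeight"),
                        seed = as.integer(xml2::xml_attr(ann, "Seed")))
        } else {
            warning("ignoring unknown annotation layer: ", nm)
        }
    }
    df <- if (length(dfs)) do.call(rbind, dfs) else .emptyMarks()
    list(marks = MarkSet(sid, rl, df), grid = grid)
}
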