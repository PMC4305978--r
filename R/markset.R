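#' Construct a MarkSet
#'
#' Builds a \code{\linkS4class{MarkSet}} from a marks data.frame, coercing
#' coordinates to integer pixels and sorting marks into canonical raster
#' order (by \code{y}, then \code{x}). Missing \code{provenance} defaults
#' to \code{"AUTO"}.
#'
#' @param spotId character(1) spot identifier.
#' @param role one of \code{"mD"}, \code{"dD"}, \code{"cD"}, \code{"TRUTH"}.
#' @param marks data.frame with columns \code{x}, \code{y}, \code{label}
#'   and optionally \code{provenance}. Coordinates are 0-based pixels and
#'   must be whole numbers.
#' @return a \code{MarkSet}.
#' @examples
#' MarkSet("spot1", "dD",
#'         data.frame(x = c(10, 40), y = c(20, 5),
#'                    label = c("POSITIVE", "NEGATIVE")))
#' @export
MarkSet <- function(spotId, role, marks = .emptyMarks()) {
    marks <- as.data.frame(marks, stringsAsFactors = FALSE)
    if (!"provenance" %in% names(marks))
        marks$provenance <- rep("AUTO", nrow(marks))
    if (nrow(marks)) {
        for (k in c("x", "y")) {
            v <- marks[[k]]
            if (any(v != floor(v)))
                stop("mark coordinates must be whole pixel numbers")
            marks[[k]] <- as.integer(v)
        }
        marks$label <- as.character(marks$label)
        marks$provenance <- as.character(marks$provenance)
        marks <- marks[order(marks$y, marks$x), c("x", "y", "label", "provenance"),
                       drop = FALSE]
        rownames(marks) <- NULL
    } else {
        marks <- .emptyMarks()
    }
    new("MarkSet", spotId = as.character(spotId), role = as.character(role),
        marks = marks)
}

#' @rdname accessors
setMethod("marks", "MarkSet", function(object) object@marks)
#' @rdname accessors
setMethod("spotId", "MarkSet", function(object) object@spotId)
#' @rdname accessors
setMethod("role", "MarkSet", function(object) object@role)
#' @rdname accessors
setMethod("nMarks", "MarkSet", function(object) nrow(object@marks))

setMethod("show", "MarkSet", function(object) {
    m <- object@marks
    cat(sprintf("MarkSet '%s' (role %s): %d marks (%d positive, %d negative, %d expert-added)\n",
                object@spotId, object@role, nrow(m),
                sum(m$label == "POSITIVE"), sum(m$label == "NEGATIVE"),
                sum(m$provenance == "EXPERT_ADDED")))
})

#' Keep only marks counted by a grid
#'
#' Restricts a \code{MarkSet} to the marks counted by some frame of the
#' grid under the forbidden-line rule (\code{\link{isCounted}}).
#'
#' @param object a \code{MarkSet}.
#' @param grid a \code{\linkS4class{FrameGrid}}.
#' @return a \code{MarkSet} with the uncounted marks removed.
#' @export
restrictToGrid <- function(object, grid) {
    stopifnot(is(object, "MarkSet"), is(grid, "FrameGrid"))
    m <- marks(object)
    keep <- !is.na(.assignFrames(grid, m$x, m$y))
    MarkSet(spotId(object), role(object), m[keep, , drop = FALSE])
}

#' Export marks to CSV
#'
#' Writes one row per mark with columns \code{spot_id}, \code{x}, \code{y},
#' \code{label}, \code{provenance} for spreadsheet review.
#'
#' @param object a \code{MarkSet}.
#' @param path output file path.
#' @return invisibly, the written data.frame.
#' @export
writeMarksCSV <- function(object, path) {
    stopifnot(is(object, "MarkSet"))
    m <- marks(object)
    out <- data.frame(spot_id = rep(spotId(object), nrow(m)),
                      x = m$x, y = m$y, label = m$label,
                      provenance = m$provenance, stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(out)
}
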