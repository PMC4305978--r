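#' Excess-RGB channel decomposition
#'
#' Computes the three excess color channels of an RGB raster in exact
#' integer arithmetic, without clipping: excess red \code{2R - G - B},
#' excess green \code{2G - R - B} and excess blue \code{2B - R - G}. The
#' three channels sum to zero at every pixel and each lies in [-510, 510].
#' Class-coded DIA markup colors become strongly positive in exactly one
#' channel, which is what the mark extraction thresholds.
#'
#' @param image numeric array (height, width, 3) with channel values 0-255.
#' @return list with matrices \code{exR}, \code{exG}, \code{exB}.
#' @examples
#' px <- array(c(200, 100, 50), c(1, 1, 3))
#' excessRGB(px)  # exR 250, exG -50, exB -200
#' @export
excessRGB <- function(image) {
    stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
    d <- dim(image)
    r <- matrix(image[, , 1], d[1], d[2])
    g <- matrix(image[, , 2], d[1], d[2])
    b <- matrix(image[, , 3], d[1], d[2])
    list(exR = 2 * r - g - b, exG = 2 * g - r - b, exB = 2 * b - r - g)
}

#' Threshold excess channels into class masks
#'
#' Applies fixed thresholds to the excess channels to isolate the
#' positively (immunostained) and negatively (counterstained) labeled
#' nuclear profiles of a DIA markup mask: \code{positive = exR >= tPos},
#' \code{negative = exB >= tNeg}. A pixel passing both thresholds is
#' assigned to the class with the larger excess, ties to positive, so the
#' returned masks are disjoint.
#'
#' @param channels list as returned by \code{\link{excessRGB}}.
#' @param tPos,tNeg positive thresholds on the excess-red and excess-blue
#'   channels (default 80).
#' @return list with logical matrices \code{positive}, \code{negative}.
#' @export
thresholdClassMasks <- function(channels, tPos = 80, tNeg = 80) {
    stopifnot(tPos > 0, tNeg > 0)
    pos <- channels$exR >= tPos
    neg <- channels$exB >= tNeg
    both <- pos & neg
    if (any(both)) {
        toPos <- channels$exR[both] >= channels$exB[both]   # tie -> positive
        pos[both] <- toPos
        neg[both] <- !toPos
    }
    list(positive = pos, negative = neg)
}

## 8-connected component labeling of a logical matrix via the pixel
## adjacency graph. Returns an integer matrix of labels (0 = background).
.labelComponents <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    idx <- which(mask)
    if (!length(idx)) return(lab)
    nr <- nrow(mask); nc <- ncol(mask)
    vid <- integer(nr * nc); vid[idx] <- seq_along(idx)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    edges <- list()
    ## neighbor offsets in column-major linear indexing (forward half of the
    ## 8-neighborhood): down (+1), right (+nr), down-right (+nr+1), up-right (+nr-1)
    offs <- list(c(1L,  rows < nr),
                 c(nr,  cols < nc),
                 c(nr + 1L, rows < nr & cols < nc),
                 c(nr - 1L, rows > 1L & cols < nc))
    for (k in seq_along(offs)) {
        d <- offs[[k]][1]
        ok <- as.logical(offs[[k]][-1])
        nb <- idx[ok] + d
        has <- vid[nb] > 0L
        if (any(has))
            edges[[length(edges) + 1L]] <- cbind(vid[idx[ok]][has], vid[nb][has])
    }
    if (length(edges)) {
        g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
        memb <- igraph::components(g)$membership
    } else {
        memb <- seq_along(idx)
    }
    lab[idx] <- memb
    lab
}

## Centroids of labeled components with area >= minArea, as 0-based (x, y)
## rounded half-up, with the component pixel count.
.componentCentroids <- function(lab, minArea) {
    idx <- which(lab > 0L)
    if (!length(idx))
        return(data.frame(x = integer(0), y = integer(0), area = integer(0)))
    nr <- nrow(lab)
    memb <- lab[idx]
    xs <- (idx - 1L) %/% nr      # 0-based column = x
    ys <- (idx - 1L) %% nr       # 0-based row = y
    area <- tabulate(memb)
    keep <- which(area >= minArea)
    if (!length(keep))
        return(data.frame(x = integer(0), y = integer(0), area = integer(0)))
    cx <- .roundHalfUp(tapply(xs, memb, mean)[as.character(keep)])
    cy <- .roundHalfUp(tapply(ys, memb, mean)[as.character(keep)])
    data.frame(x = as.integer(cx), y = as.integer(cy), area = area[keep])
}

#' Extract centroid marks from class masks
#'
#' Labels the 8-connected components of the positive and negative class
#' masks, drops components smaller than \code{minArea} pixels, and places
#' one mark at each remaining component's centroid (mean pixel coordinate,
#' rounded half-up to integer pixels). Marks are returned in raster order
#' (row-major by centroid) with provenance \code{AUTO}.
#'
#' @param positiveMask,negativeMask logical matrices of equal dimensions.
#' @param minArea minimum component area in pixels (default 20).
#' @param spotId spot identifier for the resulting set.
#' @param role role of the resulting set (default \code{"dD"}).
#' @return a \code{\linkS4class{MarkSet}}.
#' @export
extractMarks <- function(positiveMask, negativeMask, minArea = 20,
                         spotId = "spot", role = "dD") {
    stopifnot(identical(dim(positiveMask), dim(negativeMask)))
    cpos <- .componentCentroids(.labelComponents(positiveMask), minArea)
    cneg <- .componentCentroids(.labelComponents(negativeMask), minArea)
    df <- rbind(
        if (nrow(cpos)) data.frame(x = cpos$x, y = cpos$y, label = "POSITIVE"),
        if (nrow(cneg)) data.frame(x = cneg$x, y = cneg$y, label = "NEGATIVE"))
    if (is.null(df)) df <- .emptyMarks()
    df$provenance <- rep("AUTO", nrow(df))
    MarkSet(spotId, role, df)
}

#' Markup mask to machine marks (dD)
#'
#' Convenience pipeline: \code{\link{excessRGB}} then
#' \code{\link{thresholdClassMasks}} then \code{\link{extractMarks}}.
#'
#' @param image markup raster, numeric array (height, width, 3) in 0-255.
#' @param tPos,tNeg excess-channel thresholds (default 80).
#' @param minArea minimum component area in pixels (default 20).
#' @param spotId spot identifier.
#' @return a \code{\linkS4class{MarkSet}} with role \code{dD}.
#' @export
markupToMarks <- function(image, tPos = 80, tNeg = 80, minArea = 20,
                          spotId = "spot") {
    m <- thresholdClassMasks(excessRGB(image), tPos, tNeg)
    extractMarks(m$positive, m$negative, minArea, spotId, "dD")
}
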