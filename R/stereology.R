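#' Generate a systematic uniform random counting-frame grid
#'
#' Places rectangular counting frames on a regular lattice whose offset is
#' drawn uniformly on \code{[0, spacing)} from the seeded generator, one
#' offset per grid (systematic uniform random sampling). Frames are laid at
#' \code{offset + i * spacing} for every \code{i} such that the frame lies
#' fully inside the image; frames crossing the border are dropped, not
#' clipped, so the sampling fraction stays unbiased.
#'
#' @param imageWidth,imageHeight image extent in pixels.
#' @param frameWidth,frameHeight frame size in pixels (default 150).
#' @param spacingX,spacingY lattice period in pixels; must be >= the frame
#'   size (frames may not overlap). Default twice the frame size.
#' @param seed integer seed for the offset draw; identical seeds give
#'   identical grids.
#' @return a \code{\linkS4class{FrameGrid}}.
#' @examples
#' g <- generateGrid(1000, 1000, 100, 100, 500, 500, seed = 7)
#' nFrames(g)
#' @export
generateGrid <- function(imageWidth, imageHeight,
                         frameWidth = 150, frameHeight = 150,
                         spacingX = 2 * frameWidth, spacingY = 2 * frameHeight,
                         seed = 1L) {
    stopifnot(imageWidth > 0, imageHeight > 0,
              frameWidth > 0, frameHeight > 0, spacingX > 0, spacingY > 0)
    if (frameWidth > spacingX || frameHeight > spacingY)
        stop("frame larger than spacing: frames would overlap")
    if (frameWidth > imageWidth || frameHeight > imageHeight)
        stop("frame exceeds image: no frame fits")
    spacingX <- as.integer(spacingX); spacingY <- as.integer(spacingY)
    off <- withr::with_seed(seed, c(sample.int(spacingX, 1L) - 1L,
                                    sample.int(spacingY, 1L) - 1L))
    .buildGrid(imageWidth, imageHeight, frameWidth, frameHeight,
               spacingX, spacingY, off[1], off[2], as.integer(seed))
}

.buildGrid <- function(imageWidth, imageHeight, frameWidth, frameHeight,
                       spacingX, spacingY, offsetX, offsetY, seed) {
    xs <- seq.int(offsetX, by = spacingX,
                  length.out = max(0L, 1L + (imageWidth - frameWidth - offsetX) %/% spacingX))
    ys <- seq.int(offsetY, by = spacingY,
                  length.out = max(0L, 1L + (imageHeight - frameHeight - offsetY) %/% spacingY))
    if (offsetX > imageWidth - frameWidth) xs <- integer(0)
    if (offsetY > imageHeight - frameHeight) ys <- integer(0)
    grid <- expand.grid(x0 = xs, y0 = ys)        # row-major: x fastest
    frames <- data.frame(frameId = seq_len(nrow(grid)) - 1L,
                         x0 = grid$x0, y0 = grid$y0,
                         width = rep(frameWidth, nrow(grid)),
                         height = rep(frameHeight, nrow(grid)))
    new("FrameGrid", frames = frames,
        spacingX = spacingX, spacingY = spacingY,
        offsetX = offsetX, offsetY = offsetY,
        imageWidth = imageWidth, imageHeight = imageHeight, seed = seed)
}

#' @rdname accessors
setMethod("frames", "FrameGrid", function(object) object@frames)
#' @rdname accessors
setMethod("nFrames", "FrameGrid", function(object) nrow(object@frames))

setMethod("show", "FrameGrid", function(object) {
    f <- object@frames
    cat(sprintf(paste0("FrameGrid: %d frames of %gx%g px, spacing %gx%g, ",
                       "offset (%g,%g), image %gx%g, seed %d\n"),
                nrow(f), if (nrow(f)) f$width[1] else NA, if (nrow(f)) f$height[1] else NA,
                object@spacingX, object@spacingY, object@offsetX, object@offsetY,
                object@imageWidth, object@imageHeight, object@seed))
})

#' Unbiased counting-frame rule
#'
#' Decides whether a point mark is counted by a frame under the classical
#' forbidden-line rule, applied in y-down image coordinates: the left and
#' bottom edges (and their extensions through the corners) are forbidden;
#' the top and right edges accept. A point is counted iff
#' \code{x0 < x <= x0 + width} and \code{y0 <= y < y0 + height}.
#' Adjacent frames of a tiling therefore count every point at most once.
#'
#' @param frame a one-row data.frame or list with fields \code{x0},
#'   \code{y0}, \code{width}, \code{height} (e.g. one row of
#'   \code{frames(grid)}).
#' @param x,y point coordinates (vectorized).
#' @return logical vector.
#' @examples
#' f <- list(x0 = 0, y0 = 0, width = 100, height = 100)
#' isCounted(f, 50, 50)   # interior: counted
#' isCounted(f, 0, 50)    # on the left forbidden line: not counted
#' @export
isCounted <- function(frame, x, y) {
    (x > frame$x0) & (x <= frame$x0 + frame$width) &
    (y >= frame$y0) & (y < frame$y0 + frame$height)
}

## Frame id counting each point, or NA if no frame counts it. Frames are
## disjoint under the counting rule, so the lattice position can be used
## directly; fall back to a frame scan only for tiny grids.
.assignFrames <- function(grid, x, y) {
    f <- frames(grid)
    out <- rep(NA_integer_, length(x))
    for (i in seq_len(nrow(f))) {
        hit <- isCounted(f[i, ], x, y)
        out[hit] <- f$frameId[i]
    }
    out
}

#' Count marks per frame
#'
#' Tallies the marks of a set counted by each frame of the grid, split by
#' Ki67 label. Each mark is counted by at most one frame (frames are
#' disjoint under the forbidden-line rule); marks in no frame are ignored.
#'
#' @param grid a \code{\linkS4class{FrameGrid}}.
#' @param markset a \code{\linkS4class{MarkSet}} whose coordinates lie
#'   within the grid's image bounds.
#' @return data.frame with columns \code{frameId}, \code{nPositive},
#'   \code{nNegative}, one row per frame.
#' @export
countInGrid <- function(grid, markset) {
    stopifnot(is(grid, "FrameGrid"), is(markset, "MarkSet"))
    m <- marks(markset)
    if (nrow(m) && (any(m$x >= grid@imageWidth) || any(m$y >= grid@imageHeight)))
        stop("mark coordinates outside the image bounds")
    id <- .assignFrames(grid, m$x, m$y)
    f <- frames(grid)
    pos <- table(factor(id[m$label == "POSITIVE"], levels = f$frameId))
    neg <- table(factor(id[m$label == "NEGATIVE"], levels = f$frameId))
    data.frame(frameId = f$frameId,
               nPositive = as.integer(pos), nNegative = as.integer(neg))
}

#' Resize the grid to a target review workload
#'
#' Chooses the lattice spacing so that, of \code{nMarksDetected} marks
#' spread over the spot, about \code{targetMarks} fall inside counting
#' frames. The sampling fraction is \code{f = min(1, targetMarks /
#' nMarksDetected)} and the spacing is \code{frameSize / sqrt(f)} on both
#' axes, rounded up to integer pixels and floored at the frame size (full
#' tiling when the target saturates). The grid itself is drawn by
#' \code{\link{generateGrid}}.
#'
#' @param imageWidth,imageHeight image extent in pixels.
#' @param frameWidth,frameHeight frame size in pixels.
#' @param nMarksDetected number of marks the image analysis detected (> 0).
#' @param targetMarks desired number of marks to review (> 0).
#' @param seed integer seed for the offset draw.
#' @return a \code{\linkS4class{FrameGrid}}.
#' @examples
#' g <- autosizeGrid(1000, 1000, 100, 100, nMarksDetected = 1000,
#'                   targetMarks = 250, seed = 3)
#' g@spacingX  # 200 = 100 / sqrt(0.25)
#' @export
autosizeGrid <- function(imageWidth, imageHeight, frameWidth, frameHeight,
                         nMarksDetected, targetMarks, seed = 1L) {
    if (nMarksDetected <= 0 || targetMarks <= 0)
        stop("nMarksDetected and targetMarks must be positive")
    f <- min(1, targetMarks / nMarksDetected)
    sx <- max(frameWidth, ceiling(frameWidth / sqrt(f)))
    sy <- max(frameHeight, ceiling(frameHeight / sqrt(f)))
    generateGrid(imageWidth, imageHeight, frameWidth, frameHeight, sx, sy, seed)
}

#' Serialize a grid to JSON
#'
#' Writes the frame list and lattice parameters as JSON.
#'
#' @param grid a \code{\linkS4class{FrameGrid}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGridJSON <- function(grid, path) {
    stopifnot(is(grid, "FrameGrid"))
    obj <- list(imageWidth = grid@imageWidth, imageHeight = grid@imageHeight,
                spacingX = grid@spacingX, spacingY = grid@spacingY,
                offsetX = grid@offsetX, offsetY = grid@offsetY,
                seed = grid@seed, frames = frames(grid))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
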