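#' Construct an ErrorModel
#'
#' The default rates mirror the error composition the audit taxonomy is
#' designed to measure in Ki67 TMA material: a small fraction of tumour
#' nuclei outside the detected epithelial mask, a substantial
#' nuclear-segmentation miss rate, roughly one spurious component per ten
#' nuclei, and rare label flips. Pass zeros for an error-free spot.
#'
#' @param pMissTissue probability a true nucleus lies outside the simulated
#'   tissue mask (default 0.028).
#' @param pMissNuclear probability a within-mask nucleus is absent from the
#'   markup (default 0.234).
#' @param rateFalseDetection expected spurious components per spot
#'   (Poisson; default 51).
#' @param pLabelFlipPos probability a positive nucleus is rendered negative
#'   (default 0.008).
#' @param pLabelFlipNeg probability a negative nucleus is rendered positive
#'   (default 0.013).
#' @param seed integer seed (default 1).
#' @return an \code{\linkS4class{ErrorModel}}.
#' @export
ErrorModel <- function(pMissTissue = 0.028, pMissNuclear = 0.234,
                       rateFalseDetection = 51, pLabelFlipPos = 0.008,
                       pLabelFlipNeg = 0.013, seed = 1L) {
    new("ErrorModel", pMissTissue = pMissTissue, pMissNuclear = pMissNuclear,
        rateFalseDetection = rateFalseDetection, pLabelFlipPos = pLabelFlipPos,
        pLabelFlipNeg = pLabelFlipNeg, seed = as.integer(seed))
}

setMethod("show", "ErrorModel", function(object) {
    cat(sprintf(paste0("ErrorModel: pMissTissue %.3f, pMissNuclear %.3f, ",
                       "rateFalseDetection %.1f, pLabelFlipPos %.3f, ",
                       "pLabelFlipNeg %.3f, seed %d\n"),
                object@pMissTissue, object@pMissNuclear, object@rateFalseDetection,
                object@pLabelFlipPos, object@pLabelFlipNeg, object@seed))
})

## Class palettes. The markup palette is saturated so the excess channels
## separate classes by a wide margin; the spot image uses stain-like hues.
.PALETTE <- list(
    markupBackground = c(40, 40, 40),     # non-epithelium
    markupTissue     = c(128, 128, 128),  # epithelial mask (zero excess)
    markupPositive   = c(255, 0, 0),
    markupNegative   = c(0, 0, 255),
    spotBackground   = c(245, 242, 238),
    spotDisc         = c(238, 222, 226),
    spotTissue       = c(230, 205, 212),
    spotPositive     = c(150, 90, 45),    # DAB brown
    spotNegative     = c(70, 80, 150))    # hematoxylin blue

## Linear (column-major) pixel indices of a filled axis-aligned ellipse.
## Center (cx0, cy0) is 0-based; the pixel set is symmetric about it, so
## its centroid equals the center exactly.
.ellipseIdx <- function(S, cx0, cy0, a, b) {
    dx <- seq.int(-floor(a), floor(a))
    dy <- seq.int(-floor(b), floor(b))
    inside <- outer(dy / b, dx / a, function(v, u) u^2 + v^2 <= 1)
    sel <- which(inside, arr.ind = TRUE)
    rows <- cy0 + dy[sel[, 1]] + 1L
    cols <- cx0 + dx[sel[, 2]] + 1L
    (cols - 1L) * S + rows
}

## Rejection-sample one nucleus center: inside the disc with margin,
## tissue-mask condition on the center pixel, and a clearance of
## r + r_other + 3 px to every already placed center. Errors out when the
## attempt budget is exhausted (infeasible packing).
.placeCenter <- function(S, cx, cy, R, r, wantTissue, tissue, px, py, pr,
                         budget) {
    for (att in seq_len(budget)) {
        th <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * max(0, R - r - 2)
        x <- round(cx + rad * cos(th)); y <- round(cy + rad * sin(th))
        if (x < r + 2 || y < r + 2 || x > S - 1 - r - 2 || y > S - 1 - r - 2) next
        if (tissue[y + 1, x + 1] != wantTissue) next
        if (length(px) && any((x - px)^2 + (y - py)^2 < (r + pr + 3)^2)) next
        return(c(x, y))
    }
    stop("infeasible packing: could not place a nucleus after ", budget,
         " attempts")
}

#' Generate a synthetic TMA spot with logged errors
#'
#' Emulates one circular tissue-microarray spot: an irregular epithelial
#' tissue region (union of random discs clipped to the spot disc, diameter
#' 0.9 of the image), non-overlapping elliptical nuclei (axes 4-8 px)
#' placed by rejection sampling, Ki67 labels drawn to match
#' \code{trueKi67Pct} in expectation, and a DIA-style markup mask rendered
#' under the error model: nuclei outside the tissue mask or missed by the
#' simulated nuclear segmentation are absent from the markup, spurious
#' components are added inside the tissue region with random class, and
#' label flips repaint a nucleus in the other class color. Every injected
#' error is recorded once in the event log with its audit category and the
#' nucleus center coordinate. All draws derive from the error model's
#' seed, so output is fully deterministic.
#'
#' @param nNuclei number of true nuclei (>= 0).
#' @param trueKi67Pct expected Ki67 percentage in [0, 100] (default 25).
#' @param imageSize image side length in pixels (>= 64; default 1024).
#' @param errorModel an \code{\linkS4class{ErrorModel}}.
#' @return a \code{\linkS4class{SyntheticSpot}}.
#' @export
generateSpot <- function(nNuclei = 500, trueKi67Pct = 25, imageSize = 1024,
                         errorModel = ErrorModel()) {
    stopifnot(nNuclei >= 0, trueKi67Pct >= 0, trueKi67Pct <= 100,
              imageSize >= 64)
    validObject(errorModel)
    em <- errorModel
    S <- as.integer(imageSize)
    withr::with_seed(em@seed, {
        cx <- (S - 1) / 2; cy <- (S - 1) / 2
        R <- 0.45 * S
        X <- matrix(0:(S - 1), S, S, byrow = TRUE)   # 0-based x per column
        Y <- matrix(0:(S - 1), S, S)                 # 0-based y per row
        disc <- (X - cx)^2 + (Y - cy)^2 <= R^2
        ## epithelial region: union of random discs clipped to the spot
        ## disc, redrawn until it covers 40-85% of the disc so both tissue
        ## and non-tissue nuclei can be placed
        nBlob <- 10L
        for (try in 1:50) {
            tissue <- matrix(FALSE, S, S)
            bth <- stats::runif(nBlob, 0, 2 * pi)
            brad <- sqrt(stats::runif(nBlob)) * 0.7 * R
            br <- stats::runif(nBlob, 0.10, 0.18) * S
            for (k in seq_len(nBlob)) {
                bx <- cx + brad[k] * cos(bth[k]); by <- cy + brad[k] * sin(bth[k])
                tissue <- tissue | ((X - bx)^2 + (Y - by)^2 <= br[k]^2)
            }
            tissue <- tissue & disc
            frac <- mean(tissue[disc])
            if (frac >= 0.4 && frac <= 0.85) break
        }
        if (frac < 0.4 || frac > 0.85)
            stop("could not draw a tissue region covering 40-85% of the disc")

        n <- as.integer(nNuclei)
        isOut  <- stats::runif(n) < em@pMissTissue
        aAxis  <- stats::runif(n, 4, 8)
        bAxis  <- stats::runif(n, 4, 8)
        isPos  <- stats::runif(n) < trueKi67Pct / 100
        px <- integer(0); py <- integer(0); pr <- numeric(0)
        budget <- 2000L
        for (i in seq_len(n)) {
            r <- max(aAxis[i], bAxis[i])
            p <- .placeCenter(S, cx, cy, R, r, !isOut[i], tissue,
                              px, py, pr, budget)
            px <- c(px, p[1]); py <- c(py, p[2]); pr <- c(pr, r)
        }

        ## detection and label rendering
        missNuc <- !isOut & (stats::runif(n) < em@pMissNuclear)
        detected <- !isOut & !missNuc
        flip <- logical(n)
        u <- stats::runif(n)
        flip[detected & isPos]  <- u[detected & isPos]  < em@pLabelFlipPos
        flip[detected & !isPos] <- u[detected & !isPos] < em@pLabelFlipNeg
        renderedPos <- ifelse(flip, !isPos, isPos)

        ## spurious markup components
        nFalse <- stats::rpois(1, em@rateFalseDetection)
        fa <- stats::runif(nFalse, 4, 8); fb <- stats::runif(nFalse, 4, 8)
        fPos <- stats::runif(nFalse) < 0.5
        fx <- integer(0); fy <- integer(0)
        for (i in seq_len(nFalse)) {
            r <- max(fa[i], fb[i])
            p <- .placeCenter(S, cx, cy, R, r, TRUE, tissue,
                              px, py, pr, budget)
            px <- c(px, p[1]); py <- c(py, p[2]); pr <- c(pr, r)
            fx <- c(fx, p[1]); fy <- c(fy, p[2])
        }
        tx <- px[seq_len(n)]; ty <- py[seq_len(n)]   # true nucleus centers

        ## render spot image (all true nuclei) and markup mask (detected +
        ## spurious components, in rendered-class colors); ellipse pixel
        ## sets are collected per class and assigned in one pass
        nucIdx <- lapply(seq_len(n), function(i)
            .ellipseIdx(S, tx[i], ty[i], aAxis[i], bAxis[i]))
        falseIdx <- lapply(seq_len(nFalse), function(i)
            .ellipseIdx(S, fx[i], fy[i], fa[i], fb[i]))
        catIdx <- function(idxList, sel)
            if (any(sel)) unlist(idxList[sel], use.names = FALSE) else integer(0)
        spotCh <- lapply(.PALETTE$spotBackground, function(v) matrix(v, S, S))
        markCh <- lapply(.PALETTE$markupBackground, function(v) matrix(v, S, S))
        markupPosIdx <- c(catIdx(nucIdx, detected & renderedPos),
                          catIdx(falseIdx, fPos))
        markupNegIdx <- c(catIdx(nucIdx, detected & !renderedPos),
                          catIdx(falseIdx, !fPos))
        for (k in 1:3) {
            spotCh[[k]][disc]   <- .PALETTE$spotDisc[k]
            spotCh[[k]][tissue] <- .PALETTE$spotTissue[k]
            spotCh[[k]][catIdx(nucIdx, isPos)]  <- .PALETTE$spotPositive[k]
            spotCh[[k]][catIdx(nucIdx, !isPos)] <- .PALETTE$spotNegative[k]
            markCh[[k]][tissue] <- .PALETTE$markupTissue[k]
            markCh[[k]][markupPosIdx] <- .PALETTE$markupPositive[k]
            markCh[[k]][markupNegIdx] <- .PALETTE$markupNegative[k]
        }

        events <- rbind(
            data.frame(category = rep("UNDETECTED_BY_TISSUE_MASK", sum(isOut)),
                       x = tx[isOut], y = ty[isOut]),
            data.frame(category = rep("UNDETECTED_BY_NUCLEAR", sum(missNuc)),
                       x = tx[missNuc], y = ty[missNuc]),
            data.frame(category = rep("FALSE_NEGATIVE_LABEL", sum(flip & isPos)),
                       x = tx[flip & isPos], y = ty[flip & isPos]),
            data.frame(category = rep("FALSE_POSITIVE_LABEL", sum(flip & !isPos)),
                       x = tx[flip & !isPos], y = ty[flip & !isPos]),
            data.frame(category = rep("FALSE_DETECTION", nFalse),
                       x = fx, y = fy))
        rownames(events) <- NULL

        truth <- MarkSet("synthetic", "TRUTH",
                         data.frame(x = tx, y = ty,
                                    label = ifelse(isPos, "POSITIVE", "NEGATIVE"),
                                    provenance = rep("AUTO", n)))
        new("SyntheticSpot",
            spotImage = .stackChannels(spotCh),
            markupMask = .stackChannels(markCh),
            tissueMask = tissue, truth = truth, eventLog = events,
            imageSize = S, ki67Target = trueKi67Pct)
    })
}

.stackChannels <- function(ch) {
    array(c(ch[[1]], ch[[2]], ch[[3]]), c(nrow(ch[[1]]), ncol(ch[[1]]), 3L))
}

#' @rdname accessors
setMethod("truthMarks", "SyntheticSpot", function(object) object@truth)
#' @rdname accessors
setMethod("eventLog", "SyntheticSpot", function(object) object@eventLog)

setMethod("show", "SyntheticSpot", function(object) {
    cat(sprintf("SyntheticSpot: %dx%d px, %d truth nuclei (Ki67%% target %.1f), %d logged events\n",
                object@imageSize, object@imageSize, nMarks(object@truth),
                object@ki67Target, nrow(object@eventLog)))
})

#' Simulate a perfect expert correction
#'
#' Produces the cD a flawless expert would derive from the machine marks of
#' a synthetic spot: every truth nucleus is present (misses are added with
#' provenance \code{EXPERT_ADDED}), every spurious dD mark is removed, and
#' every label is corrected to the truth. Deterministic.
#'
#' @param spot the \code{\linkS4class{SyntheticSpot}} the dD was derived
#'   from.
#' @param dd \code{\linkS4class{MarkSet}} produced from the spot's markup
#'   mask (see \code{\link{markupToMarks}}).
#' @return a \code{\linkS4class{MarkSet}} with role \code{cD}.
#' @export
simulateCd <- function(spot, dd) {
    stopifnot(is(spot, "SyntheticSpot"), is(dd, "MarkSet"))
    tm <- marks(truthMarks(spot))
    dm <- marks(dd)
    detected <- paste(tm$x, tm$y) %in% paste(dm$x, dm$y)
    MarkSet(spotId(dd), "cD",
            data.frame(x = tm$x, y = tm$y, label = tm$label,
                       provenance = ifelse(detected, "AUTO", "EXPERT_ADDED")))
}

#' Restrict an event log to grid-counted coordinates
#'
#' Keeps the events whose coordinate is counted by some frame of the grid
#' under the forbidden-line rule — the subset an audit restricted to the
#' same grid can see.
#'
#' @param events event-log data.frame (columns \code{category}, \code{x},
#'   \code{y}), e.g. \code{eventLog(spot)}.
#' @param grid a \code{\linkS4class{FrameGrid}}.
#' @return the filtered data.frame.
#' @export
eventsInGrid <- function(events, grid) {
    keep <- !is.na(.assignFrames(grid, events$x, events$y))
    out <- events[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a synthetic fixture bundle
#'
#' Writes the spot image, markup mask, binary tissue mask, ground-truth
#' annotation XML and event-log JSON of one synthetic spot to a directory,
#' using the \code{<spotId>.<kind>.<ext>} naming convention consumed by
#' \code{\link{runAudit}}.
#'
#' @param spot a \code{\linkS4class{SyntheticSpot}}.
#' @param dir output directory (created if needed).
#' @param spotId file-name stem.
#' @return invisibly, the named character vector of written paths.
#' @export
writeSpotBundle <- function(spot, dir, spotId = "spot") {
    stopifnot(is(spot, "SyntheticSpot"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(spot   = file.path(dir, paste0(spotId, ".spot.png")),
               markup = file.path(dir, paste0(spotId, ".markup.png")),
               tissue = file.path(dir, paste0(spotId, ".tissue.png")),
               truth  = file.path(dir, paste0(spotId, ".truth.xml")),
               events = file.path(dir, paste0(spotId, ".events.json")))
    writeRasterImage(spot@spotImage, paths["spot"])
    writeRasterImage(spot@markupMask, paths["markup"])
    writeRasterImage(matrix(255 * spot@tissueMask, nrow(spot@tissueMask)),
                     paths["tissue"])
    tr <- truthMarks(spot)
    writeAnnotations(MarkSet(spotId, role(tr), marks(tr)), paths["truth"])
    jsonlite::write_json(eventLog(spot), paths["events"], digits = NA)
    invisible(paths)
}
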