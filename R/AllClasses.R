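#' @import methods
NULL

## Controlled vocabularies used across the package.
.MARK_LABELS     <- c("POSITIVE", "NEGATIVE")
.MARK_PROVENANCE <- c("AUTO", "EXPERT_ADDED")
.MARK_ROLES      <- c("mD", "dD", "cD", "TRUTH")

## Categories a cD mark can fall into (first six) plus the dD-only category.
.CD_CATEGORIES <- c("TRUE_POSITIVE", "TRUE_NEGATIVE",
                    "FALSE_POSITIVE_LABEL", "FALSE_NEGATIVE_LABEL",
                    "UNDETECTED_BY_TISSUE_MASK", "UNDETECTED_BY_NUCLEAR")
.EDIT_CATEGORIES <- c("TRUE_POSITIVE", "TRUE_NEGATIVE",
                      "FALSE_POSITIVE_LABEL", "FALSE_NEGATIVE_LABEL",
                      "FALSE_DETECTION",
                      "UNDETECTED_BY_TISSUE_MASK", "UNDETECTED_BY_NUCLEAR")
.EDIT_KINDS <- c(TRUE_POSITIVE = "NONE", TRUE_NEGATIVE = "NONE",
                 FALSE_POSITIVE_LABEL = "RELABEL", FALSE_NEGATIVE_LABEL = "RELABEL",
                 FALSE_DETECTION = "DELETE",
                 UNDETECTED_BY_TISSUE_MASK = "ADD", UNDETECTED_BY_NUCLEAR = "ADD")

.emptyMarks <- function() {
    data.frame(x = integer(0), y = integer(0),
               label = character(0), provenance = character(0),
               stringsAsFactors = FALSE)
}

#' MarkSet: labeled point annotations for one TMA spot
#'
#' A \code{MarkSet} holds the point marks of one tissue-microarray spot:
#' each mark is a single pixel coordinate (0-based, x rightward, y downward)
#' with a Ki67 label (\code{POSITIVE} = immunostained, \code{NEGATIVE} =
#' counterstained) and a provenance flag (\code{AUTO} for machine-generated
#' marks, \code{EXPERT_ADDED} for marks added during expert correction).
#' The role distinguishes manual (\code{mD}), machine (\code{dD}),
#' expert-corrected (\code{cD}) and generator ground-truth (\code{TRUTH})
#' sets. Marks are kept in canonical raster order (by y, then x), so two
#' sets with the same marks compare identical regardless of construction
#' order.
#'
#' @slot spotId character(1), identifier of the spot.
#' @slot role one of \code{"mD"}, \code{"dD"}, \code{"cD"}, \code{"TRUTH"}.
#' @slot marks data.frame with integer columns \code{x}, \code{y} and
#'   character columns \code{label}, \code{provenance}.
#' @aliases MarkSet
#' @exportClass MarkSet
setClass("MarkSet",
         representation(spotId = "character", role = "character",
                        marks = "data.frame"))

setValidity("MarkSet", function(object) {
    m <- object@marks
    msgs <- character(0)
    if (length(object@spotId) != 1L) msgs <- c(msgs, "spotId must be character(1)")
    if (length(object@role) != 1L || !object@role %in% .MARK_ROLES)
        msgs <- c(msgs, sprintf("role must be one of %s",
                                paste(.MARK_ROLES, collapse = ", ")))
    need <- c("x", "y", "label", "provenance")
    if (!all(need %in% names(m)))
        return(sprintf("marks must have columns %s", paste(need, collapse = ", ")))
    if (nrow(m)) {
        if (!is.integer(m$x) || !is.integer(m$y))
            msgs <- c(msgs, "mark coordinates must be integer pixels")
        if (any(m$x < 0L) || any(m$y < 0L))
            msgs <- c(msgs, "mark coordinates must be >= 0")
        if (!all(m$label %in% .MARK_LABELS))
            msgs <- c(msgs, "labels must be POSITIVE or NEGATIVE")
        if (!all(m$provenance %in% .MARK_PROVENANCE))
            msgs <- c(msgs, "provenance must be AUTO or EXPERT_ADDED")
        if (anyDuplicated(m[, c("x", "y")]))
            msgs <- c(msgs, "duplicate mark coordinates within one set")
    }
    if (length(msgs)) msgs else TRUE
})

#' FrameGrid: systematic uniform random grid of unbiased counting frames
#'
#' Rectangular counting frames placed on a regular lattice with one uniformly
#' random offset per grid (systematic uniform random sampling). Frames that
#' would cross the image border are dropped, never clipped. Each frame
#' carries the classical unbiased counting-frame semantics: the left and
#' bottom edges are forbidden lines, the top and right edges accept (see
#' \code{\link{isCounted}}).
#'
#' @slot frames data.frame with columns \code{frameId}, \code{x0}, \code{y0},
#'   \code{width}, \code{height}, in row-major placement order.
#' @slot spacingX,spacingY lattice period in pixels (>= frame size).
#' @slot offsetX,offsetY random lattice offset in \code{[0, spacing)}.
#' @slot imageWidth,imageHeight image extent in pixels.
#' @slot seed integer seed the offsets were drawn from.
#' @aliases FrameGrid
#' @exportClass FrameGrid
setClass("FrameGrid",
         representation(frames = "data.frame",
                        spacingX = "numeric", spacingY = "numeric",
                        offsetX = "numeric", offsetY = "numeric",
                        imageWidth = "numeric", imageHeight = "numeric",
                        seed = "integer"))

setValidity("FrameGrid", function(object) {
    f <- object@frames
    msgs <- character(0)
    need <- c("frameId", "x0", "y0", "width", "height")
    if (!all(need %in% names(f)))
        return(sprintf("frames must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(f$frameId)) msgs <- c(msgs, "frameId must be unique")
    if (nrow(f)) {
        if (any(f$width <= 0) || any(f$height <= 0))
            msgs <- c(msgs, "frame dimensions must be > 0")
        if (any(f$x0 < 0) || any(f$y0 < 0) ||
            any(f$x0 + f$width > object@imageWidth) ||
            any(f$y0 + f$height > object@imageHeight))
            msgs <- c(msgs, "every frame must lie fully inside the image")
        if (any((f$x0 - object@offsetX) %% object@spacingX != 0) ||
            any((f$y0 - object@offsetY) %% object@spacingY != 0))
            msgs <- c(msgs, "frame positions must equal offset + i * spacing")
        if (object@spacingX < max(f$width) || object@spacingY < max(f$height))
            msgs <- c(msgs, "spacing must be >= frame size (frames would overlap)")
    }
    if (object@offsetX < 0 || object@offsetX >= object@spacingX ||
        object@offsetY < 0 || object@offsetY >= object@spacingY)
        msgs <- c(msgs, "offsets must lie in [0, spacing)")
    if (length(msgs)) msgs else TRUE
})

#' SpotAudit: per-spot tally of expert edits
#'
#' Result of auditing one spot's machine marks (dD) against the
#' expert-corrected marks (cD), restricted to marks counted by the grid.
#' Every cD mark is classified exactly once, so the six cD categories sum
#' to \code{nCdNuclei}; \code{FALSE_DETECTION} records correspond to dD-only
#' marks the expert deleted.
#'
#' @slot spotId character(1).
#' @slot nCdNuclei number of grid-counted cD marks.
#' @slot tallies named integer vector over the seven edit categories.
#' @slot nEdits number of RELABEL + DELETE + ADD actions.
#' @slot ki67Dd,ki67Cd Ki67 percentages of the grid-counted dD and cD marks
#'   (\code{NA} when a set has no counted marks).
#' @slot edits data.frame of individual \code{EditRecord}s with columns
#'   \code{x}, \code{y}, \code{category}, \code{editKind}.
#' @aliases SpotAudit
#' @exportClass SpotAudit
setClass("SpotAudit",
         representation(spotId = "character", nCdNuclei = "integer",
                        tallies = "integer", nEdits = "integer",
                        ki67Dd = "numeric", ki67Cd = "numeric",
                        edits = "data.frame"))

setValidity("SpotAudit", function(object) {
    msgs <- character(0)
    if (!identical(sort(names(object@tallies)), sort(.EDIT_CATEGORIES)))
        return("tallies must be named over the seven edit categories")
    if (sum(object@tallies[.CD_CATEGORIES]) != object@nCdNuclei)
        msgs <- c(msgs, "cD categories must sum to nCdNuclei (conservation)")
    kinds <- .EDIT_KINDS[names(object@tallies)]
    if (sum(object@tallies[kinds != "NONE"]) != object@nEdits)
        msgs <- c(msgs, "nEdits must equal RELABEL + DELETE + ADD tally")
    for (k in c("ki67Dd", "ki67Cd")) {
        v <- slot(object, k)
        if (!is.na(v) && (v < 0 || v > 100))
            msgs <- c(msgs, sprintf("%s must be in [0, 100] or NA", k))
    }
    if (length(msgs)) msgs else TRUE
})

#' ErrorModel: detection and labeling error rates for the spot generator
#'
#' Parameterizes the errors injected when a synthetic markup mask is
#' rendered from the ground truth, mirroring the error taxonomy of the
#' audit: nuclei lying outside the simulated epithelial tissue mask (missed
#' by the tissue classifier), within-mask nuclei absent from the markup
#' (missed by nuclear segmentation), spurious components, and label flips.
#'
#' @slot pMissTissue probability in [0,1] that a true nucleus falls outside
#'   the simulated tissue mask (and is therefore not in the markup).
#' @slot pMissNuclear probability in [0,1] that a within-mask nucleus is
#'   absent from the markup.
#' @slot rateFalseDetection expected number of spurious markup components
#'   per spot (Poisson rate, >= 0).
#' @slot pLabelFlipPos probability a positive nucleus is rendered negative.
#' @slot pLabelFlipNeg probability a negative nucleus is rendered positive.
#' @slot seed integer seed; every generator draw derives from it.
#' @aliases ErrorModel
#' @exportClass ErrorModel
setClass("ErrorModel",
         representation(pMissTissue = "numeric", pMissNuclear = "numeric",
                        rateFalseDetection = "numeric",
                        pLabelFlipPos = "numeric", pLabelFlipNeg = "numeric",
                        seed = "integer"))

setValidity("ErrorModel", function(object) {
    p <- c(object@pMissTissue, object@pMissNuclear,
           object@pLabelFlipPos, object@pLabelFlipNeg)
    msgs <- character(0)
    if (any(p < 0) || any(p > 1)) msgs <- c(msgs, "probabilities must be in [0, 1]")
    if (object@rateFalseDetection < 0) msgs <- c(msgs, "rateFalseDetection must be >= 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, "seed must be a single integer")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticSpot: generated TMA spot with full error log
#'
#' One synthetic tissue-microarray spot: the rendered RGB spot image, the
#' DIA-style multicolor markup mask, the binary epithelial tissue mask, the
#' ground-truth mark set, and an event log holding one row for every
#' injected error (category + coordinate). The log is the oracle the audit
#' is validated against.
#'
#' @slot spotImage numeric array (height x width x 3), channel values 0-255.
#' @slot markupMask numeric array (height x width x 3), class-palette colors.
#' @slot tissueMask logical matrix (height x width), TRUE inside epithelium.
#' @slot truth \code{MarkSet} with role \code{TRUTH}.
#' @slot eventLog data.frame with columns \code{category}, \code{x}, \code{y}.
#' @slot imageSize integer(1), image side length in pixels.
#' @slot ki67Target numeric(1), the Ki67 percentage labels were drawn at.
#' @aliases SyntheticSpot
#' @exportClass SyntheticSpot
setClass("SyntheticSpot",
         representation(spotImage = "array", markupMask = "array",
                        tissueMask = "matrix", truth = "MarkSet",
                        eventLog = "data.frame", imageSize = "integer",
                        ki67Target = "numeric"))

setValidity("SyntheticSpot", function(object) {
    msgs <- character(0)
    if (!all(c("category", "x", "y") %in% names(object@eventLog)))
        msgs <- c(msgs, "eventLog must have columns category, x, y")
    if (nrow(object@eventLog) &&
        !all(object@eventLog$category %in% .EDIT_CATEGORIES))
        msgs <- c(msgs, "eventLog categories must come from the edit taxonomy")
    if (length(msgs)) msgs else TRUE
})
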