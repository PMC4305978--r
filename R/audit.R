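#' Match machine and corrected marks
#'
#' One-to-one greedy nearest-neighbor assignment between the marks of the
#' machine set (dD) and the corrected set (cD): candidate pairs are all
#' (dd, cd) index pairs within \code{tolerance} pixels (Euclidean); they
#' are accepted in ascending distance order, ties broken by (dd index,
#' cd index); each mark ends up in at most one pair. Unmoved marks have
#' distance zero and always pair first.
#'
#' @param dd,cd \code{\linkS4class{MarkSet}} objects.
#' @param tolerance maximum pairing distance in pixels (default 5).
#' @return list with \code{pairs} (data.frame of columns \code{dd},
#'   \code{cd}: 1-based row indices into \code{marks(dd)} /
#'   \code{marks(cd)}), \code{ddOnly} and \code{cdOnly} (integer indices of
#'   unmatched marks).
#' @export
matchMarks <- function(dd, cd, tolerance = 5) {
    stopifnot(is(dd, "MarkSet"), is(cd, "MarkSet"), tolerance >= 0)
    A <- marks(dd); B <- marks(cd)
    nA <- nrow(A); nB <- nrow(B)
    pairs <- data.frame(dd = integer(0), cd = integer(0))
    if (nA && nB) {
        D <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2)
        cand <- which(D <= tolerance, arr.ind = TRUE)
        if (nrow(cand)) {
            ord <- order(D[cand], cand[, 1], cand[, 2])
            cand <- cand[ord, , drop = FALSE]
            freeA <- rep(TRUE, nA); freeB <- rep(TRUE, nB)
            keep <- logical(nrow(cand))
            for (k in seq_len(nrow(cand))) {
                i <- cand[k, 1]; j <- cand[k, 2]
                if (freeA[i] && freeB[j]) {
                    keep[k] <- TRUE
                    freeA[i] <- FALSE; freeB[j] <- FALSE
                }
            }
            pairs <- data.frame(dd = cand[keep, 1], cd = cand[keep, 2])
        }
    }
    list(pairs = pairs,
         ddOnly = setdiff(seq_len(nA), pairs$dd),
         cdOnly = setdiff(seq_len(nB), pairs$cd))
}

#' Classify every dD/cD difference
#'
#' Turns a matching into edit records, attributing each difference to its
#' DIA component: paired marks with equal labels are
#' \code{TRUE_POSITIVE}/\code{TRUE_NEGATIVE} (no edit); paired marks with
#' differing labels are label corrections (\code{FALSE_POSITIVE_LABEL}
#' when the machine said positive and the expert negative,
#' \code{FALSE_NEGATIVE_LABEL} for the converse); dD-only marks are
#' \code{FALSE_DETECTION} deletions; cD-only marks (expert additions) are
#' attributed by position — inside the epithelial tissue mask the nuclear
#' segmentation missed them (\code{UNDETECTED_BY_NUCLEAR}), outside it the
#' tissue classifier did (\code{UNDETECTED_BY_TISSUE_MASK}). Without a
#' tissue mask all additions are charged to the nuclear component.
#'
#' @param match result of \code{\link{matchMarks}}.
#' @param dd,cd the matched \code{\linkS4class{MarkSet}} objects.
#' @param tissueMask logical matrix (height x width) covering the image, or
#'   \code{NULL}.
#' @return data.frame of edit records with columns \code{x}, \code{y},
#'   \code{category}, \code{editKind}.
#' @export
classifyEdits <- function(match, dd, cd, tissueMask = NULL) {
    A <- marks(dd); B <- marks(cd)
    recs <- list()
    p <- match$pairs
    if (nrow(p)) {
        la <- A$label[p$dd]; lb <- B$label[p$cd]
        cat_ <- ifelse(la == lb,
                       ifelse(lb == "POSITIVE", "TRUE_POSITIVE", "TRUE_NEGATIVE"),
                       ifelse(la == "POSITIVE", "FALSE_POSITIVE_LABEL",
                                                "FALSE_NEGATIVE_LABEL"))
        recs$paired <- data.frame(x = B$x[p$cd], y = B$y[p$cd], category = cat_)
    }
    if (length(match$ddOnly))
        recs$deleted <- data.frame(x = A$x[match$ddOnly], y = A$y[match$ddOnly],
                                   category = "FALSE_DETECTION")
    if (length(match$cdOnly)) {
        x <- B$x[match$cdOnly]; y <- B$y[match$cdOnly]
        inTissue <- if (is.null(tissueMask)) rep(TRUE, length(x))
                    else .maskLookup(tissueMask, x, y)
        recs$added <- data.frame(x = x, y = y,
                                 category = ifelse(inTissue,
                                                   "UNDETECTED_BY_NUCLEAR",
                                                   "UNDETECTED_BY_TISSUE_MASK"))
    }
    out <- if (length(recs)) do.call(rbind, recs) else
        data.frame(x = integer(0), y = integer(0), category = character(0))
    out$editKind <- unname(.EDIT_KINDS[out$category])
    rownames(out) <- NULL
    out
}

#' Ki67 percentage
#'
#' \code{100 * nPositive / (nPositive + nNegative)}; \code{NA} when both
#' counts are zero (undefined, excluded from downstream regression).
#'
#' @param nPositive,nNegative non-negative counts (vectorized).
#' @return numeric percentage in [0, 100], or \code{NA}.
#' @examples
#' ki67Percent(3, 1)  # 75
#' @export
ki67Percent <- function(nPositive, nNegative) {
    if (any(nPositive < 0) || any(nNegative < 0))
        stop("counts must be >= 0")
    tot <- nPositive + nNegative
    ifelse(tot == 0, NA_real_, 100 * nPositive / tot)
}

#' Audit one spot
#'
#' Full per-spot audit: both mark sets are first restricted to the marks
#' counted by the grid (so effort metrics reflect only reviewed marks),
#' then matched (\code{\link{matchMarks}}) and every difference classified
#' (\code{\link{classifyEdits}}). Ki67 percentages are computed over the
#' grid-counted marks of each set.
#'
#' @param dd machine \code{\linkS4class{MarkSet}} (role dD).
#' @param cd corrected \code{\linkS4class{MarkSet}} (role cD).
#' @param grid a \code{\linkS4class{FrameGrid}}.
#' @param tissueMask logical matrix or \code{NULL} (see
#'   \code{\link{classifyEdits}}).
#' @param tolerance pairing tolerance in pixels (default 5).
#' @return a \code{\linkS4class{SpotAudit}}.
#' @export
auditSpot <- function(dd, cd, grid, tissueMask = NULL, tolerance = 5) {
    ddG <- restrictToGrid(dd, grid)
    cdG <- restrictToGrid(cd, grid)
    match <- matchMarks(ddG, cdG, tolerance)
    recs <- classifyEdits(match, ddG, cdG, tissueMask)
    tal <- table(factor(recs$category, levels = .EDIT_CATEGORIES))
    tal <- stats::setNames(as.integer(tal), .EDIT_CATEGORIES)
    mdd <- marks(ddG); mcd <- marks(cdG)
    new("SpotAudit", spotId = spotId(dd),
        nCdNuclei = nMarks(cdG), tallies = tal,
        nEdits = sum(tal[.EDIT_KINDS[names(tal)] != "NONE"]),
        ki67Dd = ki67Percent(sum(mdd$label == "POSITIVE"), sum(mdd$label == "NEGATIVE")),
        ki67Cd = ki67Percent(sum(mcd$label == "POSITIVE"), sum(mcd$label == "NEGATIVE")),
        edits = recs)
}

#' @rdname accessors
setMethod("tallies", "SpotAudit", function(object) object@tallies)
#' @rdname accessors
setMethod("edits", "SpotAudit", function(object) object@edits)
#' @rdname accessors
setMethod("nEdits", "SpotAudit", function(object) object@nEdits)
#' @rdname accessors
setMethod("spotId", "SpotAudit", function(object) object@spotId)
#' @rdname accessors
setMethod("ki67Values", "SpotAudit",
          function(object) c(dD = object@ki67Dd, cD = object@ki67Cd))

setMethod("show", "SpotAudit", function(object) {
    cat(sprintf("SpotAudit '%s': %d cD nuclei, %d edits (Ki67%% dD %.1f, cD %.1f)\n",
                object@spotId, object@nCdNuclei, object@nEdits,
                object@ki67Dd, object@ki67Cd))
    print(object@tallies)
})

#' Tabulate a list of spot audits
#'
#' One row per spot with the per-category tallies, edit count and Ki67
#' percentages; the input format of \code{\link{summarizeEffort}} and the
#' per-spot CSV written by \code{\link{runAudit}}.
#'
#' @param audits list of \code{\linkS4class{SpotAudit}} objects.
#' @return data.frame with columns \code{spot_id}, \code{n_cd_nuclei}, one
#'   column per edit category, \code{n_edits}, \code{ki67_dd}, \code{ki67_cd}.
#' @export
auditTable <- function(audits) {
    stopifnot(length(audits) >= 1)
    rows <- lapply(audits, function(a) {
        stopifnot(is(a, "SpotAudit"))
        cbind(data.frame(spot_id = spotId(a), n_cd_nuclei = a@nCdNuclei),
              as.data.frame(as.list(tallies(a))),
              data.frame(n_edits = nEdits(a), ki67_dd = a@ki67Dd, ki67_cd = a@ki67Cd))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
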