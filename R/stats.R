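#' Ordinary least-squares regression between two Ki67 series
#'
#' Fits \code{y ~ x} by OLS (via \code{\link[stats]{lm}}) after pairwise
#' removal of undefined (NA) entries, and reports slope, intercept,
#' coefficient of determination \code{R^2 = 1 - SS_res/SS_tot} and the
#' slope's t-test p-value. Zero variance in \code{x} is an error; zero
#' variance in \code{y} yields \code{R^2 = 0} with a warning.
#'
#' @param x,y numeric vectors of equal length (percentages), n >= 3 after
#'   NA removal.
#' @return list with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{n}, \code{pValue}.
#' @examples
#' linearRegression(c(0, 10, 20), c(1, 11, 21))  # slope 1, intercept 1
#' @export
linearRegression <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    nDropped <- sum(!ok)
    if (nDropped) message(nDropped, " undefined pair(s) removed from regression")
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("regression needs at least 3 defined pairs")
    if (stats::var(x) == 0) stop("zero variance in x: regression undefined")
    fit <- stats::lm(y ~ x)
    if (stats::var(y) == 0) {
        warning("zero variance in y: r_squared set to 0")
        r2 <- 0
        pv <- NA_real_
    } else {
        r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
        ## slope t-test computed directly; an exact fit gives p = 0 rather
        ## than summary.lm's perfect-fit warning
        n <- length(x)
        se2 <- sum(stats::residuals(fit)^2) / (n - 2) / sum((x - mean(x))^2)
        pv <- if (se2 == 0) 0 else
            2 * stats::pt(abs(stats::coef(fit)["x"]) / sqrt(se2),
                          df = n - 2, lower.tail = FALSE)
        pv <- unname(pv)
    }
    list(slope = unname(stats::coef(fit)["x"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         rSquared = r2, n = length(x), pValue = pv)
}

#' Bland-Altman agreement analysis
#'
#' Computes the differences \code{y - x}, their mean (bias), sample
#' standard deviation (n-1 denominator) and the 95 percent limits of
#' agreement \code{bias +/- 1.96 sd}.
#'
#' @param x,y numeric vectors of equal length, n >= 2 after pairwise NA
#'   removal.
#' @return list with \code{bias}, \code{sdDiff}, \code{loaLow},
#'   \code{loaHigh}, \code{n}.
#' @examples
#' blandAltman(c(10, 20, 30), c(15, 25, 35))  # bias 5, sd 0
#' @export
blandAltman <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) stop("Bland-Altman needs at least 2 defined pairs")
    d <- y - x
    bias <- mean(d)
    s <- stats::sd(d)
    list(bias = bias, sdDiff = s,
         loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s, n = length(d))
}

#' Summarize expert editing effort over a spot series
#'
#' Aggregates per-spot audit tallies into series totals: total cD nuclei,
#' total edits and their percentage, per-category counts and percentages
#' (all relative to the cD nucleus total), mean cD marks per spot, and the
#' manual-work-savings fraction \code{1 - total_edits/total_cd_nuclei}
#' (floored at 0) — a reviewed mark that needed no edit is manual marking
#' saved.
#'
#' @param audits either a list of \code{\linkS4class{SpotAudit}} objects or
#'   a data.frame in the \code{\link{auditTable}} layout (columns
#'   \code{n_cd_nuclei} and one per edit category).
#' @return list of class \code{effortSummary} with fields \code{nSpots},
#'   \code{totalCdNuclei}, \code{totalEdits}, \code{pctEdits},
#'   \code{perCategoryCounts}, \code{perCategoryPct},
#'   \code{meanMarksPerSpot}, \code{savingsFraction}. Raw (unrounded)
#'   values are stored; \code{print} rounds percentages to one decimal.
#' @export
summarizeEffort <- function(audits) {
    tab <- if (is.data.frame(audits)) audits else auditTable(audits)
    if (!nrow(tab)) stop("no spots to summarize")
    stopifnot(all(c("n_cd_nuclei", .EDIT_CATEGORIES) %in% names(tab)))
    counts <- vapply(.EDIT_CATEGORIES, function(k) sum(tab[[k]]), numeric(1))
    totalCd <- sum(tab$n_cd_nuclei)
    editCats <- .EDIT_CATEGORIES[.EDIT_KINDS[.EDIT_CATEGORIES] != "NONE"]
    totalEdits <- sum(counts[editCats])
    out <- list(nSpots = nrow(tab),
                totalCdNuclei = totalCd,
                totalEdits = totalEdits,
                pctEdits = 100 * totalEdits / totalCd,
                perCategoryCounts = counts,
                perCategoryPct = 100 * counts / totalCd,
                meanMarksPerSpot = totalCd / nrow(tab),
                savingsFraction = max(0, 1 - totalEdits / totalCd))
    class(out) <- "effortSummary"
    out
}

#' @export
print.effortSummary <- function(x, ...) {
    cat(sprintf("Effort over %d spots: %d cD nuclei, %d edits (%.1f%%), savings %.3f\n",
                x$nSpots, x$totalCdNuclei, x$totalEdits, x$pctEdits,
                x$savingsFraction))
    pct <- round(x$perCategoryPct, 1)
    for (k in names(pct))
        cat(sprintf("  %-26s %8d (%.1f%%)\n", k, x$perCategoryCounts[[k]], pct[[k]]))
    invisible(x)
}

#' Scatter plot with the fitted regression line
#'
#' @param x,y the two Ki67 series.
#' @param reg optional result of \code{\link{linearRegression}} (fitted if
#'   missing).
#' @param xlab,ylab,main plot annotation.
#' @return invisibly, the regression result.
#' @export
plotRegression <- function(x, y, reg = NULL, xlab = "Ki67% (dD)",
                           ylab = "Ki67% (cD)", main = "") {
    if (is.null(reg)) reg <- linearRegression(x, y)
    graphics::plot(x, y, pch = 19, col = "grey30", xlab = xlab, ylab = ylab,
                   main = main)
    graphics::abline(reg$intercept, reg$slope, col = "red3", lwd = 2)
    graphics::abline(0, 1, col = "grey60", lty = 2)
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("y = %.2f + %.2f x,  R² = %.3f (n = %d)",
                                      reg$intercept, reg$slope, reg$rSquared, reg$n))
    invisible(reg)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias and 95 percent limits of
#' agreement drawn as horizontal lines.
#'
#' @param x,y the two Ki67 series.
#' @param ba optional result of \code{\link{blandAltman}}.
#' @param main plot title.
#' @return invisibly, the Bland-Altman result.
#' @export
plotBlandAltman <- function(x, y, ba = NULL, main = "") {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (is.null(ba)) ba <- blandAltman(x, y)
    graphics::plot((x + y) / 2, y - x, pch = 19, col = "grey30",
                   xlab = "Mean Ki67%", ylab = "Difference (cD - dD)", main = main)
    graphics::abline(h = ba$bias, col = "red3", lwd = 2)
    graphics::abline(h = c(ba$loaLow, ba$loaHigh), col = "red3", lty = 2)
    invisible(ba)
}
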