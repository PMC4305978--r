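#' Markup mask to reviewable annotations
#'
#' End-to-end wizard flow for one spot: read the multicolor DIA markup
#' raster, extract the machine (dD) marks by Excess-RGB thresholding and
#' centroid extraction, lay a counting-frame grid over the image (sized to
#' \code{targetMarks} when given, otherwise with the fixed spacing), and
#' write both to one annotation XML file ready for expert editing.
#'
#' @param markupPath path to the markup raster (PNG/TIFF).
#' @param outPath output annotation XML path.
#' @param spotId spot identifier (default: file-name stem).
#' @param tPos,tNeg excess-channel thresholds (default 80).
#' @param minArea minimum component area in pixels (default 20).
#' @param frameWidth,frameHeight counting-frame size (default 150).
#' @param spacingX,spacingY lattice spacing (default twice the frame size);
#'   ignored when \code{targetMarks} is given.
#' @param targetMarks optional review workload target passed to
#'   \code{\link{autosizeGrid}}.
#' @param seed integer seed for the grid offset.
#' @param writeMasks if TRUE, also write the thresholded class masks next
#'   to \code{outPath} as debug PNGs.
#' @return invisibly, a list with \code{marks} (the dD
#'   \code{\linkS4class{MarkSet}}) and \code{grid} (the
#'   \code{\linkS4class{FrameGrid}}).
#' @export
runWizard <- function(markupPath, outPath, spotId = NULL,
                      tPos = 80, tNeg = 80, minArea = 20,
                      frameWidth = 150, frameHeight = 150,
                      spacingX = 2 * frameWidth, spacingY = 2 * frameHeight,
                      targetMarks = NULL, seed = 1L, writeMasks = FALSE) {
    if (is.null(spotId))
        spotId <- sub("\\.(markup|mask)$", "",
                      tools::file_path_sans_ext(basename(markupPath)))
    ok <- FALSE
    on.exit(if (!ok && file.exists(outPath)) unlink(outPath))
    img <- readRasterImage(markupPath)
    cls <- thresholdClassMasks(excessRGB(img), tPos, tNeg)
    dd <- extractMarks(cls$positive, cls$negative, minArea, spotId, "dD")
    if (nMarks(dd) == 0L)
        warning("no marks extracted from ", markupPath)
    w <- dim(img)[2]; h <- dim(img)[1]
    grid <- if (!is.null(targetMarks) && nMarks(dd) > 0L)
        autosizeGrid(w, h, frameWidth, frameHeight, nMarks(dd), targetMarks, seed)
    else
        generateGrid(w, h, frameWidth, frameHeight, spacingX, spacingY, seed)
    writeAnnotations(dd, outPath, grid)
    if (writeMasks) {
        stem <- tools::file_path_sans_ext(outPath)
        writeRasterImage(matrix(255 * cls$positive, h), paste0(stem, ".pos.png"))
        writeRasterImage(matrix(255 * cls$negative, h), paste0(stem, ".neg.png"))
    }
    ok <- TRUE
    tab <- table(factor(marks(dd)$label, levels = .MARK_LABELS))
    message(sprintf("%s: %d dD marks (%d positive, %d negative), %d frames",
                    spotId, nMarks(dd), tab["POSITIVE"], tab["NEGATIVE"],
                    nFrames(grid)))
    invisible(list(marks = dd, grid = grid))
}

#' Audit a directory of dD/cD annotation pairs
#'
#' Discovers spots by the \code{<spotId>.dd.xml} / \code{<spotId>.cd.xml}
#' naming convention (tissue masks \code{<spotId>.tissue.png} are used when
#' present), audits every pair against the grid stored in the dD file, and
#' writes per-spot and per-edit CSVs, a series summary JSON, and
#' regression / Bland-Altman PNGs (when at least 3 spots have defined Ki67
#' percentages). Unpaired files are listed and skipped with a warning.
#'
#' @param dir directory holding the annotation pairs.
#' @param outDir output directory (created if needed).
#' @param tolerance mark-pairing tolerance in pixels (default 5).
#' @return invisibly, a list with \code{audits} (list of
#'   \code{\linkS4class{SpotAudit}}), \code{table}
#'   (\code{\link{auditTable}}), \code{summary}
#'   (\code{\link{summarizeEffort}}), \code{regression} and
#'   \code{blandAltman} (or \code{NULL} when skipped).
#' @export
runAudit <- function(dir, outDir, tolerance = 5) {
    ddFiles <- sort(list.files(dir, pattern = "\\.dd\\.xml$", full.names = TRUE))
    if (!length(ddFiles)) stop("no .dd.xml files found in ", dir)
    ids <- sub("\\.dd\\.xml$", "", basename(ddFiles))
    cdFiles <- file.path(dir, paste0(ids, ".cd.xml"))
    missing <- !file.exists(cdFiles)
    if (any(missing)) {
        warning("skipping unpaired spots (no .cd.xml): ",
                paste(ids[missing], collapse = ", "))
        ddFiles <- ddFiles[!missing]; cdFiles <- cdFiles[!missing]
        ids <- ids[!missing]
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    audits <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        ddDoc <- readAnnotations(ddFiles[i])
        cdDoc <- readAnnotations(cdFiles[i])
        if (is.null(ddDoc$grid))
            stop("no grid layer in ", ddFiles[i])
        maskPath <- file.path(dir, paste0(ids[i], ".tissue.png"))
        tissue <- if (file.exists(maskPath)) readTissueMask(maskPath) else NULL
        if (is.null(tissue))
            warning("no tissue mask for spot ", ids[i],
                    ": all additions attributed to the nuclear component")
        audits[[i]] <- auditSpot(ddDoc$marks, cdDoc$marks, ddDoc$grid,
                                 tissue, tolerance)
    }
    tab <- auditTable(audits)
    utils::write.csv(tab, file.path(outDir, "spot_audits.csv"), row.names = FALSE)
    perEdit <- do.call(rbind, lapply(audits, function(a) {
        e <- edits(a)
        if (nrow(e)) cbind(spot_id = spotId(a), e) else NULL
    }))
    if (is.null(perEdit))
        perEdit <- data.frame(spot_id = character(0), x = integer(0),
                              y = integer(0), category = character(0),
                              editKind = character(0))
    utils::write.csv(perEdit, file.path(outDir, "edits.csv"), row.names = FALSE)
    eff <- summarizeEffort(tab)
    reg <- ba <- NULL
    defined <- !is.na(tab$ki67_dd) & !is.na(tab$ki67_cd)
    if (sum(defined) >= 3) {
        reg <- linearRegression(tab$ki67_dd, tab$ki67_cd)
        ba <- blandAltman(tab$ki67_dd, tab$ki67_cd)
        grDevices::png(file.path(outDir, "regression.png"), 600, 600)
        plotRegression(tab$ki67_dd, tab$ki67_cd, reg, main = "Ki67% cD vs dD")
        grDevices::dev.off()
        grDevices::png(file.path(outDir, "bland_altman.png"), 600, 600)
        plotBlandAltman(tab$ki67_dd, tab$ki67_cd, ba, main = "Ki67% agreement")
        grDevices::dev.off()
    } else {
        warning("fewer than 3 spots with defined Ki67%: regression and ",
                "Bland-Altman skipped")
    }
    summary <- list(effort = unclass(eff), regression = reg, blandAltman = ba)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(list(audits = audits, table = tab, summary = eff,
                   regression = reg, blandAltman = ba))
}

#' Generate a batch of synthetic fixture bundles
#'
#' Generates \code{nSpots} synthetic spots (per-spot seed = \code{seed + i})
#' and writes for each the fixture bundle (\code{\link{writeSpotBundle}})
#' plus the derived machine annotations \code{<id>.dd.xml} (marks + grid,
#' via the wizard parameters) and the perfect-expert \code{<id>.cd.xml} —
#' a directory \code{\link{runAudit}} can consume directly.
#'
#' @param outDir output directory.
#' @param nSpots number of spots (default 10).
#' @param nNuclei true nuclei per spot (default 500).
#' @param trueKi67Pct expected Ki67 percentage (default 25).
#' @param imageSize image side in pixels (default 1024).
#' @param errorModel an \code{\linkS4class{ErrorModel}}; its seed is
#'   re-derived per spot as \code{seed + i}.
#' @param frameWidth,frameHeight,spacingX,spacingY grid parameters (defaults
#'   as in \code{\link{generateGrid}}).
#' @param seed base integer seed.
#' @return invisibly, the character vector of spot ids written.
#' @export
runSynth <- function(outDir, nSpots = 10, nNuclei = 500, trueKi67Pct = 25,
                     imageSize = 1024, errorModel = ErrorModel(),
                     frameWidth = 150, frameHeight = 150,
                     spacingX = 2 * frameWidth, spacingY = 2 * frameHeight,
                     seed = 1L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ids <- sprintf("spot%03d", seq_len(nSpots))
    for (i in seq_len(nSpots)) {
        em <- errorModel
        em@seed <- as.integer(seed + i)
        spot <- generateSpot(nNuclei, trueKi67Pct, imageSize, em)
        writeSpotBundle(spot, outDir, ids[i])
        dd <- markupToMarks(spot@markupMask, spotId = ids[i])
        grid <- generateGrid(imageSize, imageSize, frameWidth, frameHeight,
                             spacingX, spacingY, seed = seed + i)
        writeAnnotations(dd, file.path(outDir, paste0(ids[i], ".dd.xml")), grid)
        writeAnnotations(simulateCd(spot, dd),
                         file.path(outDir, paste0(ids[i], ".cd.xml")))
    }
    invisible(ids)
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and lines starting
#' with \code{#} are ignored. Values that parse as numbers are returned
#' numeric. Used by the command-line wrapper (\code{inst/scripts}); flags
#' override file values.
#'
#' @param path config file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    out <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2) stop("malformed config line: ", ln)
        key <- trimws(kv[1])
        val <- trimws(paste(kv[-1], collapse = "="))
        num <- suppressWarnings(as.numeric(val))
        out[[key]] <- if (!is.na(num)) num else val
    }
    out
}
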