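#' Read / write a SarStack as multi-page TIFF plus sidecar CSV
#'
#' One 32-bit float TIFF page per acquisition (values affine-scaled to
#' [0, 1]; the scale, acquisition dates and pixel spacing live in a
#' sidecar CSV next to the TIFF). Nodata cells, if any, go to a companion
#' 8-bit mask TIFF. This is a plain raster interchange format: the
#' classifier needs dates and spacing, not a map projection.
#'
#' @param stack a \linkS4class{SarStack}.
#' @param path path of the TIFF to write / read.
#' @return \code{readSarStack}: the restored \linkS4class{SarStack}.
#' @export
writeSarStack <- function(stack, path) {
    v <- sigmaValues(stack)
    nd <- nodataMask(stack)
    lo <- min(v[!nd], -30); hi <- max(v[!nd], 0)
    sc <- (v - lo) / (hi - lo)
    sc[nd] <- 0
    T <- dim(v)[3L]
    tiff::writeTIFF(lapply(seq_len(T), function(t) sc[, , t]), path,
        bits.per.sample = 32L)
    meta <- data.frame(band = seq_len(T), date = format(acqDates(stack)),
        scale_lo = lo, scale_hi = hi,
        spacing_x = pixelSpacing(stack)[1L],
        spacing_y = pixelSpacing(stack)[2L])
    utils::write.csv(meta, .sidecarPath(path), row.names = FALSE)
    if (any(nd))
        tiff::writeTIFF(lapply(seq_len(T), function(t) (nd[, , t]) + 0),
            .maskPath(path), bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeSarStack
#' @export
readSarStack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    meta <- utils::read.csv(.sidecarPath(path))
    v <- array(0, c(dim(pages[[1L]]), length(pages)))
    for (t in seq_along(pages))
        v[, , t] <- pages[[t]] * (meta$scale_hi[t] - meta$scale_lo[t]) +
            meta$scale_lo[t]
    nd <- array(FALSE, dim(v))
    if (file.exists(.maskPath(path))) {
        mp <- tiff::readTIFF(.maskPath(path), all = TRUE)
        for (t in seq_along(mp)) nd[, , t] <- mp[[t]] > 0.5
    }
    sarStack(v, as.Date(meta$date), nd,
        c(meta$spacing_x[1L], meta$spacing_y[1L]))
}

.sidecarPath <- function(path) sub("\\.tiff?$", "_dates.csv", path)
.maskPath <- function(path) sub("\\.tiff?$", "_mask.tif", path)

#' Read / write small categorical rasters as 8-bit TIFF
#'
#' Byte rasters for rice maps (0 non-rice, 1 rice, 255 unclassifiable),
#' class labels or SoS indices (255 = no SoS).
#'
#' @param m integer matrix with values in 0..254 and NA.
#' @param path TIFF path.
#' @param naValue byte encoding NA (default 255).
#' @return \code{readByteRaster}: the integer matrix with NA restored.
#' @export
writeByteRaster <- function(m, path, naValue = 255L) {
    m[is.na(m)] <- naValue
    tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeByteRaster
#' @export
readByteRaster <- function(path, naValue = 255L) {
    m <- round(tiff::readTIFF(path) * 255)
    m[m == naValue] <- NA
    storage.mode(m) <- "integer"
    m
}

#' Read / write ground-truth points as CSV
#'
#' Columns: id, x, y (map metres), label (rice/nonrice) and optionally
#' split (train/validate).
#'
#' @param points data.frame of points.
#' @param path CSV path.
#' @return \code{readGroundTruth}: the points data.frame.
#' @export
writeGroundTruth <- function(points, path) {
    utils::write.csv(points, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) utils::read.csv(path)
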