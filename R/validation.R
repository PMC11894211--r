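#' Sample ground-truth points from a simulated scene
#'
#' Emulates a field survey: points are placed at the centres of pixels
#' whose 3x3 neighbourhood is a single class, because GPS ground truth is
#' collected inside fields (rice or otherwise), never on bunds or field
#' boundaries. Labels are rice / nonrice (all non-rice classes pooled).
#' Map coordinates are metres from the top-left corner of the scene.
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param n number of points.
#' @param seed optional integer seed.
#' @return data.frame(id, x, y, label).
#' @export
makeGroundTruth <- function(truth, n = 200L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    cls <- classRaster(truth)
    H <- nrow(cls); W <- ncol(cls)
    interior <- .interiorMask(cls)
    pool <- which(interior)
    if (length(pool) < n)
        stop("scene too fragmented: only ", length(pool),
            " interior pixels for ", n, " points")
    px <- sample(pool, n)
    sp <- pixelSpacing(truth)
    r <- (px - 1L) %% H + 1L
    cc <- (px - 1L) %/% H + 1L
    data.frame(id = seq_len(n),
        x = (cc - 0.5) * sp[1L], y = (r - 0.5) * sp[2L],
        label = ifelse(cls[px] == 1L, "rice", "nonrice"))
}

## TRUE where the 3x3 neighbourhood (clipped at edges) is one class.
.interiorMask <- function(cls) {
    H <- nrow(cls); W <- ncol(cls)
    same <- matrix(TRUE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- pmin(pmax(seq_len(H) + dr, 1L), H)
        cc <- pmin(pmax(seq_len(W) + dc, 1L), W)
        same <- same & (cls == cls[r, cc])
    }
    same
}

#' Stratified train/validation split of ground-truth points
#'
#' Splits points into training and validation sets, stratified by label so
#' each class contributes the same fraction (default 60/40). The split
#' depends only on the points and the seed, never on any classification.
#'
#' @param points data.frame with a \code{label} column.
#' @param trainFraction fraction used for training, in (0, 1).
#' @param seed optional integer seed.
#' @return List with data.frames \code{train} and \code{validate}.
#' @export
splitGroundTruth <- function(points, trainFraction = 0.6, seed = NULL) {
    if (trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must be in (0, 1)")
    if (!is.null(seed)) set.seed(seed)
    counts <- table(points$label)
    if (any(counts < 2L))
        stop("labels with fewer than 2 points: ",
            paste(names(counts)[counts < 2L], collapse = ", "))
    trainIdx <- unlist(lapply(split(seq_len(nrow(points)), points$label),
        function(i) sample(i, round(trainFraction * length(i)))),
        use.names = FALSE)
    list(train = points[sort(trainIdx), , drop = FALSE],
        validate = points[setdiff(seq_len(nrow(points)), trainIdx), ,
            drop = FALSE])
}

## Map coordinates -> linear pixel index (pixel containing the point).
.pointPixels <- function(points, dims, pixelSpacing) {
    cc <- floor(points$x / pixelSpacing[1L]) + 1L
    r <- floor(points$y / pixelSpacing[2L]) + 1L
    bad <- r < 1L | r > dims[1L] | cc < 1L | cc > dims[2L]
    if (any(bad))
        stop("points outside the raster: ",
            paste(points$id[bad], collapse = ", "))
    (cc - 1L) * dims[1L] + r
}

#' Error matrix of a rice map against validation points
#'
#' Tallies mapped vs reference labels at validation points (each point is
#' assigned to the pixel containing it; no neighbourhood majority). Points
#' falling on unclassifiable pixels are excluded and reported via a
#' message.
#'
#' @param map a \linkS4class{RiceMap}.
#' @param points validation points, data.frame(id, x, y, label).
#' @return Integer matrix, rows = mapped class, columns = reference class.
#' @export
errorMatrix <- function(map, points) {
    rice <- riceRaster(map)
    px <- .pointPixels(points, dim(rice), pixelSpacing(map))
    mapped <- rice[px]
    drop <- is.na(mapped)
    if (any(drop))
        message(sum(drop), " point(s) on unclassifiable pixels excluded")
    lev <- c("rice", "nonrice")
    cm <- table(
        mapped = factor(ifelse(mapped[!drop] == 1L, "rice", "nonrice"), lev),
        reference = factor(points$label[!drop], lev))
    m <- matrix(as.integer(cm), 2L, 2L,
        dimnames = list(mapped = lev, reference = lev))
    m
}

#' Thematic-map accuracy measures from an error matrix
#'
#' \code{overallAccuracy}: percentage of cases on the diagonal.
#' \code{producerUserAccuracy}: per-class producer's accuracy (diagonal /
#' column total; complement of omission error) and user's accuracy
#' (diagonal / row total; complement of commission error), \code{NA} where
#' the marginal is zero. \code{kappaCoefficient}: chance-corrected
#' agreement (N A - B) / (N^2 - B), where A is the diagonal sum and B the
#' sum over classes of row total x column total.
#'
#' @param cm square integer matrix, rows = mapped, columns = reference.
#' @return Percent (overall), data.frame (producer/user), or coefficient
#'   (kappa).
#' @examples
#' cm <- matrix(c(80, 10, 20, 90), 2)  # rows mapped, cols reference
#' overallAccuracy(cm)                 # 85
#' kappaCoefficient(cm)                # 0.7
#' @export
overallAccuracy <- function(cm) {
    cm <- as.matrix(cm)
    N <- sum(cm)
    if (N <= 0) stop("empty error matrix")
    100 * sum(diag(cm)) / N
}

#' @rdname overallAccuracy
#' @export
producerUserAccuracy <- function(cm) {
    cm <- as.matrix(cm)
    rs <- rowSums(cm); cs <- colSums(cm)
    cls <- if (!is.null(rownames(cm))) rownames(cm) else
        paste0("class_", seq_len(nrow(cm)))
    data.frame(class = cls,
        producer_pct = ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_),
        user_pct = ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_),
        row.names = NULL)
}

#' @rdname overallAccuracy
#' @export
kappaCoefficient <- function(cm) {
    cm <- as.matrix(cm)
    N <- sum(cm)
    A <- sum(diag(cm))
    B <- sum(rowSums(cm) * colSums(cm))
    if (N^2 == B)
        stop("kappa undefined: N^2 equals the chance-agreement term")
    (N * A - B) / (N^2 - B)
}
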