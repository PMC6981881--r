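#' Pearson correlation with strict input checks
#'
#' Standard product-moment coefficient; unlike \code{stats::cor} this
#' refuses vectors of fewer than 3 points or zero variance instead of
#' returning NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y differ in length")
    if (length(x) < 3L) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: zero variance input")
    stats::cor(x, y)
}

#' Trans-acting lncRNA target screen
#'
#' All (lncRNA, gene) pairs whose expression profiles across the shared
#' conditions correlate with |r| at or above the threshold (0.9 by default,
#' matching the screen criterion; use 0.99 to reproduce the stricter
#' reported shortlist).  The boundary is inclusive by default; set
#' \code{strict} for a strict inequality.
#'
#' @param lncExpr numeric matrix, lncRNA features x conditions.
#' @param geneExpr numeric matrix, gene features x conditions.
#' @param rMin absolute-correlation threshold.
#' @param strict use |r| > rMin instead of >=?
#' @return data.frame (\code{lncrna_id}, \code{gene_id}, \code{r}) sorted by
#'   |r| descending.
#' @export
transCandidates <- function(lncExpr, geneExpr, rMin = 0.9, strict = FALSE) {
    lncExpr <- as.matrix(lncExpr); geneExpr <- as.matrix(geneExpr)
    shared <- intersect(colnames(lncExpr), colnames(geneExpr))
    if (is.null(colnames(lncExpr)) || is.null(colnames(geneExpr)))
        shared <- if (ncol(lncExpr) == ncol(geneExpr))
            seq_len(ncol(lncExpr)) else character(0)
    if (length(shared) < 3L)
        stop("fewer than 3 shared conditions between the two matrices")
    r <- stats::cor(t(lncExpr[, shared, drop = FALSE]),
                    t(geneExpr[, shared, drop = FALSE]))
    hit <- if (strict) abs(r) > rMin else abs(r) >= rMin
    idx <- which(hit, arr.ind = TRUE)
    res <- data.frame(
        lncrna_id = rownames(lncExpr)[idx[, 1]],
        gene_id = rownames(geneExpr)[idx[, 2]],
        r = r[idx], stringsAsFactors = FALSE)
    res <- res[order(-abs(res$r)), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Assemble a qPCR Ct table
#'
#' Long-format cycle-threshold table with the reference gene and calibrator
#' sample recorded as attributes.  An optional \code{replicate} column keeps
#' biological replicates apart.
#'
#' @param df data.frame with columns \code{sample}, \code{gene}, \code{ct}
#'   (and optionally \code{replicate}).
#' @param referenceGene internal-control gene id.
#' @param calibratorSample calibrator (baseline) sample id.
#' @return the validated data.frame, classed \code{"CtTable"}.
#' @export
ctTable <- function(df, referenceGene, calibratorSample) {
    stopifnot(all(c("sample", "gene", "ct") %in% names(df)))
    if (!referenceGene %in% df$gene)
        stop(sprintf("reference gene '%s' absent from table", referenceGene))
    if (!calibratorSample %in% df$sample)
        stop(sprintf("calibrator sample '%s' absent from table",
                     calibratorSample))
    attr(df, "referenceGene") <- referenceGene
    attr(df, "calibratorSample") <- calibratorSample
    class(df) <- c("CtTable", class(df))
    df
}

.ctLookup <- function(ct, sample, gene, replicate = NULL) {
    rows <- ct$sample == sample & ct$gene == gene
    if (!is.null(replicate) && "replicate" %in% names(ct))
        rows <- rows & ct$replicate == replicate
    v <- ct$ct[rows]
    if (!length(v))
        stop(sprintf("missing Ct for (sample '%s', gene '%s')", sample, gene))
    v
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct(target) - Ct(reference) within each sample; ddCt = dCt(sample) -
#' dCt(calibrator); the fold change is 2^-ddCt.  With a \code{replicate}
#' column the fold change is computed per replicate (replicate i of the
#' sample against replicate i of the calibrator) and the mean is returned,
#' with \code{sd} and \code{n} attributes.
#'
#' @param ct a \code{\link{ctTable}}.
#' @param targetGene gene to quantify.
#' @param sample sample to quantify.
#' @return fold change (numeric scalar; attributes \code{sd}, \code{n} when
#'   replicated).
#' @export
ddctFoldChange <- function(ct, targetGene, sample) {
    stopifnot(inherits(ct, "CtTable"))
    ref <- attr(ct, "referenceGene")
    cal <- attr(ct, "calibratorSample")
    if ("replicate" %in% names(ct)) {
        reps <- sort(unique(ct$replicate[ct$sample == sample &
                                         ct$gene == targetGene]))
    } else reps <- list(NULL)
    fc <- vapply(reps, function(rep) {
        dctS <- .ctLookup(ct, sample, targetGene, rep)[1] -
            .ctLookup(ct, sample, ref, rep)[1]
        dctC <- .ctLookup(ct, cal, targetGene, rep)[1] -
            .ctLookup(ct, cal, ref, rep)[1]
        2^-(dctS - dctC)
    }, numeric(1))
    out <- mean(fc)
    if (length(fc) > 1L) {
        attr(out, "sd") <- stats::sd(fc)
        attr(out, "n") <- length(fc)
    }
    out
}

#' Circadian profile relative to a baseline timepoint
#'
#' Divides an expression row by its value at the baseline condition (ZT2 by
#' convention), so the baseline fold change is exactly 1.
#'
#' @param exprRow named numeric vector; names like "ZT2", "ZT6", ... (or
#'   bare hours).
#' @param baseline name of the baseline condition.
#' @param photoperiod light:dark descriptor carried in the result.
#' @return a \linkS4class{CircadianProfile}.
#' @export
relativeProfile <- function(exprRow, baseline = "ZT2", photoperiod = "12:12") {
    if (is.null(names(exprRow))) stop("exprRow must be named by condition")
    if (!baseline %in% names(exprRow))
        stop(sprintf("baseline condition '%s' absent", baseline))
    b <- exprRow[[baseline]]
    if (b == 0) stop("zero baseline value")
    tp <- suppressWarnings(as.numeric(sub("^ZT", "", names(exprRow))))
    if (anyNA(tp)) stop("conditions must be ZT<hours> or numeric hours")
    o <- order(tp)
    new("CircadianProfile", timepoints = tp[o],
        foldChanges = as.numeric(exprRow)[o] / b,
        photoperiod = photoperiod)
}

setMethod("show", "CircadianProfile", function(object) {
    cat(sprintf("CircadianProfile (L:D %s): %d timepoints ZT%g-ZT%g\n",
                object@photoperiod, length(object@timepoints),
                min(object@timepoints), max(object@timepoints)))
})

#' Peak and periodicity summary of a circadian profile
#'
#' Local maxima above a prominence floor (via \code{pracma::findpeaks});
#' the profile is called periodic at \code{period} hours when it has at
#' least two peaks and every consecutive peak spacing is within
#' \code{toleranceH} of the period (default 4 h, one sampling interval).
#'
#' @param profile a \linkS4class{CircadianProfile}.
#' @param minProminence minimum rise of a peak above its flanking minima.
#' @param period candidate period, hours.
#' @param toleranceH allowed deviation of peak spacing from the period.
#' @return list with \code{peakTimes}, \code{interPeakIntervals} and
#'   \code{hasPeriodicity}.
#' @export
peakSummary <- function(profile, minProminence = 0.1, period = 24,
                        toleranceH = 4) {
    stopifnot(is(profile, "CircadianProfile"))
    y <- profile@foldChanges
    t <- profile@timepoints
    if (length(y) < 4L) stop("need at least 4 timepoints")
    pk <- pracma::findpeaks(y)
    peakTimes <- numeric(0)
    if (!is.null(pk)) {
        prom <- pmin(pk[, 1] - y[pk[, 3]], pk[, 1] - y[pk[, 4]])
        keep <- prom >= minProminence
        peakTimes <- sort(t[pk[keep, 2]])
    }
    gaps <- diff(peakTimes)
    list(peakTimes = peakTimes,
         interPeakIntervals = gaps,
         hasPeriodicity = length(peakTimes) >= 2L &&
             all(abs(gaps - period) <= toleranceH))
}

#' Cluster expression profiles by correlation
#'
#' Agglomerative clustering with distance 1 - Pearson r and average linkage
#' (the package's declared convention for pattern-similarity grouping).
#' Deterministic given the input row order.  Constant rows have no defined
#' correlation and are reported as an error naming the features.
#'
#' @param expr numeric matrix, features x conditions (>= 2 features).
#' @param k number of clusters (or use \code{cutHeight}).
#' @param cutHeight dendrogram cut height on the 1 - r scale.
#' @return named integer cluster labels.
#' @export
clusterProfiles <- function(expr, k = NULL, cutHeight = NULL) {
    expr <- as.matrix(expr)
    if (nrow(expr) < 2L) stop("need at least 2 features")
    sds <- apply(expr, 1, stats::sd)
    if (any(sds == 0))
        stop(sprintf("constant feature row(s): %s",
                     paste(rownames(expr)[sds == 0], collapse = ", ")))
    d <- stats::as.dist(1 - stats::cor(t(expr)))
    hc <- stats::hclust(d, method = "average")
    if (is.null(k) && is.null(cutHeight))
        stop("supply k or cutHeight")
    if (!is.null(k)) stats::cutree(hc, k = k)
    else stats::cutree(hc, h = cutHeight)
}
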