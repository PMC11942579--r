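## Chromatographic common-peak handling: relative retention time / relative
## peak area metrics, common-peak matching across samples, and fingerprint
## similarity against a mean reference chromatogram.

#' Construct a PeakTable
#'
#' @param areas numeric matrix of non-negative peak areas with samples in
#'   rows and peaks in columns (dimnames required).
#' @param batch sample-to-batch map as in [BandMatrix()].
#' @param rrt optional per-peak relative retention times (positive,
#'   length = number of peaks).
#' @param label optional per-peak compound labels (e.g. \code{"Rg1"},
#'   \code{"Re"}, \code{"Rb1"}; \code{NA} for unidentified peaks).
#' @param referencePeak optional id of the reference peak used for relative
#'   metrics.
#' @return A validated \linkS4class{PeakTable}.
#' @export
PeakTable <- function(areas, batch, rrt = NULL, label = NULL,
                      referencePeak = NULL) {
    if (is.null(rownames(areas)) || is.null(colnames(areas)))
        stop("area matrix needs sample row names and peak column names")
    batch <- .asBatchMap(batch, rownames(areas))
    rd <- DataFrame(row.names = colnames(areas))
    if (!is.null(rrt)) rd$rrt <- rrt
    if (!is.null(label)) rd$label <- label
    se <- SummarizedExperiment(
        assays = list(area = t(areas)),
        rowData = rd,
        colData = DataFrame(batch = unname(batch),
                            row.names = rownames(areas)))
    out <- new("PeakTable", se)
    if (!is.null(referencePeak)) metadata(out)$reference_peak <- referencePeak
    validObject(out)
    out
}

#' Read a peak table from CSV/TSV
#'
#' Expects a header of peak ids and one row per sample, first column the
#' sample id, cells the peak areas.
#'
#' @param path file path.
#' @param batch sample-to-batch map as in [BandMatrix()].
#' @param sep optional separator override.
#' @inheritParams PeakTable
#' @return A \linkS4class{PeakTable}.
#' @export
readPeakTable <- function(path, batch, rrt = NULL, label = NULL,
                          referencePeak = NULL, sep = NULL) {
    tab <- .readTable(path, sep)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "numeric"
    rownames(m) <- as.character(tab[[1L]])
    PeakTable(m, batch = batch, rrt = rrt, label = label,
              referencePeak = referencePeak)
}

#' Write a peak table as samples-by-peaks CSV
#'
#' @param pt a \linkS4class{PeakTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(pt, path) {
    m <- t(assay(pt, "area"))
    out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Subset a PeakTable by compound label
#'
#' Restricts the table to the peaks carrying one of the given labels — for
#' instance the three pharmacopoeia marker ginsenosides Rg1, Re, Rb1 as a
#' reduced chemical panel.
#'
#' @param pt a \linkS4class{PeakTable} with \code{rowData(pt)$label}.
#' @param labels character vector of labels to keep.
#' @return A \linkS4class{PeakTable} over the selected peaks.
#' @export
selectPeaks <- function(pt, labels) {
    lab <- rowData(pt)$label
    if (is.null(lab)) stop("peak table carries no labels")
    keep <- !is.na(lab) & lab %in% labels
    if (!any(keep)) stop("no peak matches the requested labels")
    out <- pt[keep, ]
    validObject(out)
    out
}

#' Relative retention time and relative peak area of one peak list
#'
#' Method-validation metrics against a designated reference peak S:
#' RRT_i = rt_i / rt_S and RPA_i = area_i / area_S, so the reference peak
#' itself scores (1, 1).  RRT is invariant to a uniform multiplicative
#' shift of all retention times, RPA to a uniform rescaling of all areas.
#'
#' @param peaks data frame with columns \code{rt} (minutes, strictly
#'   increasing) and \code{area} (non-negative) for one sample.
#' @param referencePeak index of the reference peak; its area must be
#'   positive.
#' @return Data frame with columns \code{rt}, \code{area}, \code{rrt},
#'   \code{rpa}.
#' @export
relativeMetrics <- function(peaks, referencePeak) {
    stopifnot(is.data.frame(peaks), all(c("rt", "area") %in% names(peaks)))
    if (is.unsorted(peaks$rt, strictly = TRUE))
        stop("retention times must be strictly increasing")
    if (referencePeak < 1L || referencePeak > nrow(peaks))
        stop("reference peak index out of range")
    if (peaks$area[referencePeak] <= 0)
        stop("reference peak has zero area")
    data.frame(peaks[c("rt", "area")],
               rrt = peaks$rt / peaks$rt[referencePeak],
               rpa = peaks$area / peaks$area[referencePeak])
}

#' Match common peaks across samples
#'
#' Aligns per-sample peak lists on relative retention time: each sample's
#' RTs are divided by the RT of its own reference peak (the peak nearest in
#' raw RT to the first sample's reference), then every peak of the first
#' sample is greedily matched to the nearest unused RRT in each other
#' sample.  A peak is \emph{common} iff it is matched in every sample
#' within \code{rrtTolerance}; the result contains only common peaks,
#' ordered by RRT.  Matching on raw RT is available via \code{on = "rt"}.
#'
#' @param peakLists named list (one element per sample) of data frames with
#'   columns \code{rt} and \code{area}.
#' @param batch sample-to-batch map as in [BandMatrix()].
#' @param referencePeak index of the reference peak in the first sample's
#'   list; default the largest-area peak of the first sample.
#' @param rrtTolerance maximum |RRT difference| for a match (default 0.02;
#'   RRT repeatability in validated methods is far tighter).
#' @param on \code{"rrt"} (default) or \code{"rt"} for raw retention times.
#' @return A \linkS4class{PeakTable} of the common peaks (rowData carries
#'   the first sample's RRT), or an error with per-sample match diagnostics
#'   when no peak is common.
#' @export
matchCommonPeaks <- function(peakLists, batch, referencePeak = NULL,
                             rrtTolerance = 0.02, on = c("rrt", "rt")) {
    on <- match.arg(on)
    stopifnot(is.list(peakLists), length(peakLists) >= 2L)
    if (is.null(names(peakLists)))
        stop("peakLists must be named by sample id")
    for (nm in names(peakLists)) {
        pl <- peakLists[[nm]]
        if (!is.data.frame(pl) || !all(c("rt", "area") %in% names(pl)) ||
            nrow(pl) == 0L)
            stop("sample '", nm, "': need a non-empty data frame with rt, area")
        if (is.unsorted(pl$rt, strictly = TRUE))
            stop("sample '", nm, "': retention times must be strictly increasing")
    }
    first <- peakLists[[1L]]
    if (is.null(referencePeak)) referencePeak <- which.max(first$area)
    refRt <- first$rt[referencePeak]
    coord <- lapply(peakLists, function(pl) {
        if (on == "rt") return(pl$rt)
        own <- which.min(abs(pl$rt - refRt))
        pl$rt / pl$rt[own]
    })
    target <- coord[[1L]]
    matched <- matrix(NA_integer_, length(target), length(peakLists),
                      dimnames = list(NULL, names(peakLists)))
    matched[, 1L] <- seq_along(target)
    for (s in seq_along(peakLists)[-1L]) {
        free <- rep(TRUE, length(coord[[s]]))
        for (p in seq_along(target)) {
            dd <- abs(coord[[s]] - target[p])
            dd[!free] <- Inf
            hit <- which.min(dd)
            if (length(hit) && dd[hit] <= rrtTolerance) {
                matched[p, s] <- hit
                free[hit] <- FALSE
            }
        }
    }
    common <- which(rowSums(!is.na(matched)) == length(peakLists))
    if (!length(common)) {
        diag_ <- colSums(!is.na(matched))
        stop("no common peak across all samples; per-sample matches: ",
             paste(sprintf("%s=%d", names(diag_), diag_), collapse = ", "))
    }
    common <- common[order(target[common])]
    areas <- vapply(seq_along(peakLists), function(s)
        peakLists[[s]]$area[matched[common, s]],
        numeric(length(common)))
    areas <- matrix(areas, nrow = length(common),
                    dimnames = list(sprintf("P%02d", seq_along(common)),
                                    names(peakLists)))
    PeakTable(t(areas), batch = batch, rrt = target[common],
              referencePeak = if (referencePeak %in% common)
                  rownames(areas)[match(referencePeak, common)] else NULL)
}

#' Convert a PeakTable back into per-sample peak lists
#'
#' Uses the stored RRT as the retention-time coordinate, enabling
#' re-matching of an already-common table.
#'
#' @param pt a \linkS4class{PeakTable} with \code{rowData(pt)$rrt}.
#' @return Named list of data frames with columns \code{rt}, \code{area}.
#' @export
asPeakLists <- function(pt) {
    rrt <- rowData(pt)$rrt
    if (is.null(rrt)) stop("peak table carries no rrt coordinates")
    a <- assay(pt, "area")
    stats::setNames(lapply(colnames(pt), function(s)
        data.frame(rt = rrt, area = a[, s])), colnames(pt))
}

#' Fingerprint similarity against a reference chromatogram
#'
#' The congruence (cosine) coefficient between common-peak area vectors,
#' \deqn{sim(x, y) = \sum_i x_i y_i / (\lVert x\rVert \lVert y\rVert),}
#' which lies in [0, 1] for non-negative areas and equals 1 iff the vectors
#' are proportional.  Each sample is scored against a reference vector —
#' by default the arithmetic mean chromatogram of the cohort, the
#' generated-reference convention of pharmacopoeia fingerprint similarity
#' software — and the full pairwise matrix is returned for heatmaps.
#'
#' @param pt a \linkS4class{PeakTable} with at least two peaks.
#' @param reference \code{"mean"} (default) or the id of a sample to use as
#'   reference.
#' @return List with elements \code{sample} (named per-sample similarity to
#'   the reference), \code{pairwise} (a \linkS4class{SimilarityMatrix},
#'   method \code{"cosine"}) and \code{reference} (the reference area
#'   vector).
#' @export
fingerprintSimilarity <- function(pt, reference = "mean") {
    stopifnot(is(pt, "PeakTable"))
    if (nrow(pt) < 2L) stop("need at least two peaks")
    X <- t(assay(pt, "area"))            # samples x peaks
    ref <- if (identical(reference, "mean")) colMeans(X)
           else if (reference %in% rownames(X)) X[reference, ]
           else stop("unknown reference sample: ", reference)
    if (sum(ref^2) == 0) stop("reference vector is all zero")
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0))
        stop("zero area vector(s): ",
             paste(rownames(X)[nrm == 0], collapse = ", "))
    perSample <- as.vector(X %*% ref) / (nrm * sqrt(sum(ref^2)))
    perSample <- pmin(perSample, 1)
    list(sample = stats::setNames(perSample, rownames(X)),
         pairwise = .cosineMatrix(X),
         reference = ref)
}

#' Within-batch fingerprint similarity summaries
#'
#' Convenience wrapper: computes the pairwise cosine similarity matrix of
#' \code{pt} and summarizes it per batch with [withinBatchSimilarity()].
#'
#' @param pt a \linkS4class{PeakTable}.
#' @param reference passed to [fingerprintSimilarity()].
#' @return Data frame as in [withinBatchSimilarity()].
#' @export
withinBatchFingerprintSimilarity <- function(pt, reference = "mean") {
    fs <- fingerprintSimilarity(pt, reference = reference)
    withinBatchSimilarity(fs$pairwise, batchMap(pt))
}
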