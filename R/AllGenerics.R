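#' @rdname bandCounts
#' @export
setGeneric("bandCounts", function(x) standardGeneric("bandCounts"))

#' @rdname panelSize
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))

#' @rdname primerIds
#' @export
setGeneric("primerIds", function(x) standardGeneric("primerIds"))

#' @rdname batchMap
#' @export
setGeneric("batchMap", function(x) standardGeneric("batchMap"))

#' @rdname excludePrimer
#' @export
setGeneric("excludePrimer",
    function(x, primerId) standardGeneric("excludePrimer"))

#' @rdname simMethod
#' @export
setGeneric("simMethod", function(x) standardGeneric("simMethod"))

#' @rdname foldResults
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))

#' @rdname loocvSummary
#' @export
setGeneric("loocvSummary", function(x) standardGeneric("loocvSummary"))

## ---- accessor methods ---------------------------------------------------

#' Per-sample observed band counts (m2)
#'
#' @param x a \linkS4class{BandMatrix}.
#' @return Named integer vector: for each sample, its number of amplified
#'   bands (1-entries).
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 1))
#' head(bandCounts(bm))
#' @export
setMethod("bandCounts", "BandMatrix", function(x) {
    cs <- colSums(SummarizedExperiment::assay(x, "bands"))
    as.integer(cs) |> stats::setNames(colnames(x))
})

#' Panel-wide band total (m1)
#'
#' @param x a \linkS4class{BandMatrix}.
#' @return Integer: total number of bands scored across all primers of the
#'   (possibly primer-excluded) panel.
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 1))
#' panelSize(bm)
#' @export
setMethod("panelSize", "BandMatrix", function(x) nrow(x))

#' Owning primer of each band
#'
#' @param x a \linkS4class{BandMatrix}.
#' @return Character vector, one primer_id per band, named by band id.
#' @export
setMethod("primerIds", "BandMatrix", function(x) {
    stats::setNames(as.character(SummarizedExperiment::rowData(x)$primer_id),
                    rownames(x))
})

#' Sample-to-batch map
#'
#' @param x a \linkS4class{BandMatrix} or \linkS4class{PeakTable}.
#' @return Named character vector mapping sample id to batch id.
#' @export
setMethod("batchMap", "BandMatrix", function(x) {
    stats::setNames(as.character(SummarizedExperiment::colData(x)$batch),
                    colnames(x))
})

#' @rdname batchMap
#' @export
setMethod("batchMap", "PeakTable", function(x) {
    stats::setNames(as.character(SummarizedExperiment::colData(x)$batch),
                    colnames(x))
})

#' Similarity coefficient of a SimilarityMatrix
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @return Single string naming the coefficient.
#' @export
setMethod("simMethod", "SimilarityMatrix", function(x) x@method)

#' Per-fold HWEP reports of a cross-validation
#'
#' @param x a \linkS4class{LoocvResult}.
#' @return Named list (one element per retained fold) of per-batch HWEP
#'   report data frames; the name is the excluded primer or peak.
#' @export
setMethod("foldResults", "LoocvResult", function(x) {
    x@folds[setdiff(names(x@folds), x@excludedFolds)]
})

#' Cross-validation summary table
#'
#' @param x a \linkS4class{LoocvResult}.
#' @return Data frame with one row per batch: mean and standard error of the
#'   HWEP size n and of the MQS mass across folds, plus the fold count.
#' @export
setMethod("loocvSummary", "LoocvResult", function(x) x@summary)
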