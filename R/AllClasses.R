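#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' BandMatrix: binary dominant-marker band profiles
#'
#' A \linkS4class{SummarizedExperiment} holding a binary presence/absence
#' matrix of amplified bands.  Rows are bands (with their owning primer in
#' \code{rowData(x)$primer_id}), columns are samples (with their batch in
#' \code{colData(x)$batch}).  The assay is named \code{"bands"} and contains
#' only 0/1 with no missing entries.  An optional primer panel table
#' (primer_id, sequence) is kept in \code{metadata(x)$panel}.
#'
#' Dominant markers such as ISSR are scored per band: 1 when the band is
#' present on the gel, 0 when absent, with no heterozygote resolution.  The
#' panel-wide band total m1 is \code{panelSize(x)} and the per-sample
#' observed band count m2 is \code{bandCounts(x)}.
#'
#' @seealso [BandMatrix()], [readBandMatrix()], [primerBandStats()],
#'   [excludePrimer()]
#' @export
setClass("BandMatrix", contains = "SummarizedExperiment")

setValidity("BandMatrix", function(object) {
    msg <- character()
    if (!"bands" %in% SummarizedExperiment::assayNames(object))
        return("assay 'bands' is missing")
    m <- assay(object, "bands")
    if (anyNA(m))
        msg <- c(msg, "band matrix contains missing entries")
    else if (!all(m == 0L | m == 1L))
        msg <- c(msg, "band matrix entries must all be 0 or 1")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "band ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    pid <- rowData(object)$primer_id
    if (is.null(pid) || anyNA(pid) || any(!nzchar(pid)))
        msg <- c(msg, "every band needs a non-empty rowData primer_id")
    bt <- colData(object)$batch
    if (is.null(bt) || anyNA(bt) || any(!nzchar(as.character(bt))))
        msg <- c(msg, "every sample needs a non-empty colData batch")
    panel <- metadata(object)$panel
    if (!is.null(panel) && !is.null(pid)) {
        if (anyDuplicated(panel$primer_id))
            msg <- c(msg, "panel primer_ids must be unique")
        if (!all(pid %in% panel$primer_id))
            msg <- c(msg, "band assigned to a primer absent from the panel")
    }
    if (length(msg)) msg else TRUE
})

#' PeakTable: aligned common-peak areas of chromatographic fingerprints
#'
#' A \linkS4class{SummarizedExperiment} with one row per common peak and one
#' column per sample; the \code{"area"} assay holds non-negative peak areas
#' in detector response units.  \code{rowData} carries the peak's relative
#' retention time (\code{rrt}) and an optional compound \code{label} (for
#' instance the ginsenosides Rg1, Re, Rb1); \code{colData$batch} maps samples
#' to batches and \code{metadata(x)$reference_peak} names the reference peak
#' used for relative metrics.
#'
#' @seealso [PeakTable()], [matchCommonPeaks()], [fingerprintSimilarity()],
#'   [selectPeaks()]
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
    msg <- character()
    if (!"area" %in% SummarizedExperiment::assayNames(object))
        return("assay 'area' is missing")
    a <- assay(object, "area")
    if (anyNA(a))
        msg <- c(msg, "peak areas contain missing cells")
    else if (any(a < 0))
        msg <- c(msg, "peak areas must be non-negative")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "peak ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    bt <- colData(object)$batch
    if (is.null(bt) || anyNA(bt))
        msg <- c(msg, "every sample needs a colData batch")
    rrt <- rowData(object)$rrt
    if (!is.null(rrt) && (anyNA(rrt) || any(rrt <= 0)))
        msg <- c(msg, "rowData rrt must be positive when present")
    if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: pairwise similarity among samples
#'
#' A square symmetric matrix of similarities in [0, 1] with unit diagonal,
#' carrying the coefficient used (\code{"dice"}, \code{"jaccard"},
#' \code{"simple_matching"} for binary band profiles; \code{"cosine"} for
#' fingerprint area vectors) in its \code{method} slot.
#'
#' @seealso [pairwiseSimilarity()], [fingerprintSimilarity()], [upgma()],
#'   [withinBatchSimilarity()]
#' @export
setClass("SimilarityMatrix",
    contains = "matrix",
    representation(method = "character"))

setValidity("SimilarityMatrix", function(object) {
    m <- object@.Data
    msg <- character()
    if (nrow(m) != ncol(m))
        return("similarity matrix must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "row and column sample ids must be present and equal")
    if (anyNA(m) || any(m < -1e-8) || any(m > 1 + 1e-8))
        msg <- c(msg, "similarities must lie in [0, 1]")
    if (max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, "similarity matrix must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8)
        msg <- c(msg, "diagonal must equal 1")
    if (length(object@method) != 1L)
        msg <- c(msg, "method must be a single string")
    if (length(msg)) msg else TRUE
})

#' HwepConfig: constants of the entropy-to-HWEP model
#'
#' Bundles the tunable constants of the Hardy-Weinberg equilibrium
#' population (HWEP) sizing model:
#' \describe{
#'   \item{C}{entropy conversion constant in \eqn{H = -C \ln(m_2/m_1)}.
#'     The default 1/ln 2 expresses band entropy in bits.}
#'   \item{tPlusU}{the quantile sum \eqn{t_{\alpha,n-1} + u_\beta} of the
#'     sizing formula; 10.8 corresponds to \eqn{\alpha = \beta = 0.05}.}
#'   \item{formulaMode}{\code{"table_consistent"} uses
#'     \eqn{n = 100 (t+u)^2 RSD^2} with RSD as a fraction for both genetic
#'     and chemical data; \code{"eq5_literal"} uses the alternative
#'     formulation-control form \eqn{n = K \cdot RSD^2}.}
#'   \item{K}{formulation control coefficient of the literal mode
#'     (default 25.6).}
#'   \item{unitMass}{mass of one equilibrium unit in grams (default 1.000 g);
#'     MQS is reported in kilograms.}
#' }
#'
#' @seealso [HwepConfig()], [hwepSize()], [mqs()], [batchHwepReport()]
#' @export
setClass("HwepConfig",
    representation(C = "numeric", tPlusU = "numeric",
                   formulaMode = "character", K = "numeric",
                   unitMass = "numeric"),
    prototype(C = 1 / log(2), tPlusU = 10.8,
              formulaMode = "table_consistent", K = 25.6, unitMass = 1))

setValidity("HwepConfig", function(object) {
    msg <- character()
    for (s in c("C", "tPlusU", "K", "unitMass")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("%s must be a single positive number", s))
    }
    if (length(object@formulaMode) != 1L ||
        !object@formulaMode %in% c("table_consistent", "eq5_literal"))
        msg <- c(msg,
            "formulaMode must be 'table_consistent' or 'eq5_literal'")
    if (length(msg)) msg else TRUE
})

#' Create an HwepConfig
#'
#' @param C entropy conversion constant (> 0); default \code{1/log(2)}
#'   (entropy in bits).
#' @param tPlusU quantile sum \eqn{t_{\alpha,n-1} + u_\beta}; default 10.8.
#' @param formulaMode \code{"table_consistent"} (default) or
#'   \code{"eq5_literal"}; see \linkS4class{HwepConfig}.
#' @param K formulation control coefficient for the literal mode.
#' @param unitMass mass of one equilibrium unit in grams.
#' @return An \linkS4class{HwepConfig} object.
#' @examples
#' cfg <- HwepConfig()
#' hwepSize(0.0616, cfg)
#' @export
HwepConfig <- function(C = 1 / log(2), tPlusU = 10.8,
                       formulaMode = c("table_consistent", "eq5_literal"),
                       K = 25.6, unitMass = 1) {
    formulaMode <- match.arg(formulaMode)
    ## slot name "C" would partially match new()'s Class argument, so fill
    ## slots explicitly
    out <- new("HwepConfig")
    out@C <- C; out@tPlusU <- tPlusU; out@formulaMode <- formulaMode
    out@K <- K; out@unitMass <- unitMass
    validObject(out)
    out
}

#' LoocvResult: leave-one-unit-out cross-validation of HWEP sizing
#'
#' Holds, for every fold (one excluded primer or one excluded common peak),
#' the per-batch HWEP report recomputed on the remaining data, plus
#' mean +/- standard-error summaries of n and MQS per batch across folds.
#' Folds in which some sample was left without any observed band (or with an
#' all-zero area vector) are flagged in \code{excludedFolds} and do not enter
#' the summaries.
#'
#' @seealso [loocvGenetic()], [loocvChemical()], [foldResults()],
#'   [loocvSummary()]
#' @export
setClass("LoocvResult",
    representation(unit = "character", folds = "list",
                   excludedFolds = "character", summary = "data.frame"))

setValidity("LoocvResult", function(object) {
    msg <- character()
    if (!object@unit %in% c("primer", "peak"))
        msg <- c(msg, "unit must be 'primer' or 'peak'")
    if (is.null(names(object@folds)) || anyDuplicated(names(object@folds)))
        msg <- c(msg, "folds must be uniquely named by excluded unit")
    if (!all(object@excludedFolds %in% names(object@folds)))
        msg <- c(msg, "excludedFolds must name existing folds")
    if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "BandMatrix", function(object) {
    cat(sprintf("BandMatrix: %d bands x %d samples\n",
                nrow(object), ncol(object)))
    pid <- rowData(object)$primer_id
    cat(sprintf("  primers (%d): %s\n", length(unique(pid)),
                paste(unique(pid), collapse = ", ")))
    bt <- as.character(colData(object)$batch)
    cat(sprintf("  batches (%d): %s\n", length(unique(bt)),
                paste(unique(bt), collapse = ", ")))
    zero <- sum(rowSums(assay(object, "bands")) == 0)
    if (zero > 0)
        cat(sprintf("  note: %d band(s) absent from every sample\n", zero))
    invisible(NULL)
})

setMethod("show", "PeakTable", function(object) {
    cat(sprintf("PeakTable: %d common peaks x %d samples\n",
                nrow(object), ncol(object)))
    lab <- rowData(object)$label
    if (!is.null(lab) && any(!is.na(lab)))
        cat(sprintf("  labelled peaks: %s\n",
                    paste(lab[!is.na(lab)], collapse = ", ")))
    ref <- metadata(object)$reference_peak
    if (!is.null(ref)) cat(sprintf("  reference peak: %s\n", ref))
    cat(sprintf("  batches: %s\n",
                paste(unique(as.character(colData(object)$batch)),
                      collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix (%s): %d samples\n",
                object@method, nrow(object)))
    off <- object@.Data[upper.tri(object@.Data)]
    if (length(off))
        cat(sprintf("  off-diagonal range: [%.4f, %.4f]\n",
                    min(off), max(off)))
    invisible(NULL)
})

setMethod("show", "HwepConfig", function(object) {
    cat("HwepConfig\n")
    cat(sprintf("  C        = %.6f %s\n", object@C,
                if (isTRUE(all.equal(object@C, 1 / log(2)))) "(bits)" else ""))
    cat(sprintf("  t + u    = %.2f\n", object@tPlusU))
    cat(sprintf("  mode     = %s\n", object@formulaMode))
    cat(sprintf("  K        = %.2f\n", object@K))
    cat(sprintf("  unitMass = %.3f g\n", object@unitMass))
    invisible(NULL)
})

setMethod("show", "LoocvResult", function(object) {
    cat(sprintf("LoocvResult: leave-one-%s-out, %d fold(s)\n",
                object@unit, length(object@folds)))
    if (length(object@excludedFolds))
        cat(sprintf("  flagged/excluded folds: %s\n",
                    paste(object@excludedFolds, collapse = ", ")))
    print(object@summary, row.names = FALSE)
    invisible(NULL)
})
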