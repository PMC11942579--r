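## Reading, validating and summarizing dominant-marker band matrices.
##
## File dialect: delimited text, header row of band ids, first column the
## sample id, entries 0/1.  Band ids follow "<primer>:<label>" so that a
## band's owning primer is recoverable from its id and primer exclusion is a
## pure column filter; an explicit band->primer map may override this.

.detectSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else ","
}

.readTable <- function(path, sep = NULL) {
    if (is.null(sep)) sep <- .detectSep(path)
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "\"", colClasses = "character")
}

.primerFromBandId <- function(bandIds) {
    hit <- regexpr(":", bandIds, fixed = TRUE)
    if (any(hit < 0))
        stop("band id(s) without a '<primer>:<label>' structure and no ",
             "explicit primer map: ",
             paste(bandIds[hit < 0], collapse = ", "))
    substr(bandIds, 1L, hit - 1L)
}

.asBatchMap <- function(batch, sampleIds) {
    if (is.character(batch) && length(batch) == 1L && file.exists(batch)) {
        tab <- .readTable(batch)
        if (ncol(tab) < 2L)
            stop("batch map file needs two columns: sample_id, batch_id")
        batch <- stats::setNames(as.character(tab[[2L]]),
                                 as.character(tab[[1L]]))
    } else if (is.data.frame(batch)) {
        batch <- stats::setNames(as.character(batch[[2L]]),
                                 as.character(batch[[1L]]))
    }
    if (is.null(names(batch)))
        stop("batch map must be named by sample id")
    miss <- setdiff(sampleIds, names(batch))
    if (length(miss))
        stop("samples missing from the batch map: ",
             paste(miss, collapse = ", "))
    batch[sampleIds]
}

#' Construct a BandMatrix
#'
#' @param bands numeric/integer matrix of 0/1 calls with samples in rows and
#'   bands in columns (the orientation band matrices are tabulated in);
#'   dimnames required.  Internally stored with bands as
#'   SummarizedExperiment rows.
#' @param batch sample-to-batch assignment: a named vector
#'   (sample id -> batch id), a two-column data frame, or the path of a
#'   two-column delimited file.
#' @param primers optional character vector giving the owning primer of each
#'   band column; when omitted, primers are parsed from band ids of the form
#'   \code{"<primer>:<label>"}.
#' @param panel optional primer panel data frame with columns
#'   \code{primer_id} and (optionally) \code{sequence}; every band's primer
#'   must appear in it.
#' @return A validated \linkS4class{BandMatrix}.  Bands that are absent from
#'   every sample are legal but reported with a message, since a band that
#'   never appears would not have been scored on a gel.
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("P1:01", "P1:02", "P2:01")))
#' bm <- BandMatrix(m, batch = c(s1 = "A", s2 = "A"))
#' panelSize(bm)
#' @export
BandMatrix <- function(bands, batch, primers = NULL, panel = NULL) {
    if (is.null(rownames(bands)) || is.null(colnames(bands)))
        stop("band matrix needs sample row names and band column names")
    storage.mode(bands) <- "integer"
    if (is.null(primers)) primers <- .primerFromBandId(colnames(bands))
    if (length(primers) != ncol(bands))
        stop("one primer_id per band column is required")
    batch <- .asBatchMap(batch, rownames(bands))
    if (is.null(panel))
        panel <- data.frame(primer_id = unique(primers),
                            sequence = NA_character_)
    se <- SummarizedExperiment(
        assays = list(bands = t(bands)),
        rowData = DataFrame(primer_id = as.character(primers),
                            row.names = colnames(bands)),
        colData = DataFrame(batch = unname(batch),
                            row.names = rownames(bands)))
    out <- new("BandMatrix", se)
    metadata(out)$panel <- panel
    validObject(out)
    zero <- rownames(out)[rowSums(assay(out, "bands")) == 0]
    if (length(zero))
        message("band(s) absent from every sample: ",
                paste(zero, collapse = ", "))
    out
}

#' Read a band matrix from delimited text
#'
#' Expects a header row of band ids and one row per sample, first column the
#' sample id, entries 0/1.  Non-binary entries are a parse error naming the
#' offending sample and band.
#'
#' @param path file path (TSV or CSV; the separator is sniffed from the
#'   header unless \code{sep} is given).
#' @param batch sample-to-batch map as in [BandMatrix()].
#' @param primers,panel,sep see [BandMatrix()]; \code{sep} overrides
#'   separator detection.
#' @param missing policy for \code{NA}/empty cells: \code{"fail"} (default,
#'   strict) or \code{"as-absent"} (missing calls scored 0).
#' @return A validated \linkS4class{BandMatrix}; a message reports the
#'   sample, band, and per-primer band counts read.
#' @seealso [writeBandMatrix()]
#' @export
readBandMatrix <- function(path, batch, primers = NULL, panel = NULL,
                           sep = NULL, missing = c("fail", "as-absent")) {
    missing <- match.arg(missing)
    tab <- .readTable(path, sep)
    if (ncol(tab) < 2L) stop("no band columns found in ", path)
    sampleIds <- as.character(tab[[1L]])
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id(s): ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    bandIds <- colnames(tab)[-1L]
    if (anyDuplicated(bandIds))
        stop("duplicate band id(s): ",
             paste(unique(bandIds[duplicated(bandIds)]), collapse = ", "))
    raw <- as.matrix(tab[, -1L, drop = FALSE])
    raw[raw == "" | raw == "NA"] <- NA_character_
    if (anyNA(raw)) {
        if (missing == "fail") {
            bad <- which(is.na(raw), arr.ind = TRUE)[1L, ]
            stop(sprintf(
                "missing band call at sample '%s', band '%s' (set missing = \"as-absent\" to score as 0)",
                sampleIds[bad[1L]], bandIds[bad[2L]]))
        }
        raw[is.na(raw)] <- "0"
    }
    ok <- raw %in% c("0", "1")
    if (!all(ok)) {
        bad <- which(matrix(!ok, nrow(raw)), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-binary entry '%s' at sample '%s', band '%s'",
                     raw[bad[1L], bad[2L]], sampleIds[bad[1L]],
                     bandIds[bad[2L]]))
    }
    m <- matrix(as.integer(raw), nrow = nrow(raw),
                dimnames = list(sampleIds, bandIds))
    bm <- BandMatrix(m, batch = batch, primers = primers, panel = panel)
    perPrimer <- table(primerIds(bm))
    message(sprintf("read %d samples x %d bands (%s)",
                    ncol(bm), nrow(bm),
                    paste(sprintf("%s: %d", names(perPrimer), perPrimer),
                          collapse = ", ")))
    bm
}

#' Write a band matrix to delimited text
#'
#' Inverse of [readBandMatrix()]: header of band ids, first column
#' \code{sample_id}, entries 0/1.
#'
#' @param bm a \linkS4class{BandMatrix}.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeBandMatrix <- function(bm, path, sep = "\t") {
    m <- t(assay(bm, "bands"))
    out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Per-primer polymorphism statistics
#'
#' For each primer: TNB (total number of bands), NPB (number of polymorphic
#' bands) and PPB (percentage of polymorphic bands).  A band is polymorphic
#' when it is neither present in all samples nor absent in all samples.  A
#' final \code{"Total"} row pools the panel: pooled PPB =
#' 100 * sum(NPB) / sum(TNB).
#'
#' @param bm a \linkS4class{BandMatrix} with at least two samples
#'   (polymorphism is undefined on one sample).
#' @return Data frame with columns \code{primer_id}, \code{TNB}, \code{NPB},
#'   \code{PPB}; last row is the pooled panel total.
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 1))
#' primerBandStats(bm)
#' @export
primerBandStats <- function(bm) {
    stopifnot(is(bm, "BandMatrix"))
    if (ncol(bm) < 2L)
        stop("polymorphism is undefined for a single-sample matrix")
    pid <- primerIds(bm)
    prs <- rowSums(assay(bm, "bands"))
    poly <- prs > 0 & prs < ncol(bm)
    primers <- unique(pid)
    tnb <- vapply(primers, function(p) sum(pid == p), integer(1))
    npb <- vapply(primers, function(p) sum(poly[pid == p]), integer(1))
    out <- data.frame(primer_id = c(primers, "Total"),
                      TNB = c(tnb, sum(tnb)),
                      NPB = c(npb, sum(npb)),
                      row.names = NULL)
    out$PPB <- 100 * out$NPB / out$TNB
    out
}

#' Drop all bands of one primer
#'
#' Leave-one-primer-out subsetting: returns a new
#' \linkS4class{BandMatrix} without the excluded primer's band rows.  The
#' panel band total shrinks by that primer's TNB; sample order is preserved
#' and the panel metadata keeps bookkeeping of the exclusion.
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param primerId primer to exclude; must own at least one band in
#'   \code{x}'s panel.
#' @return A \linkS4class{BandMatrix} on the reduced panel.
#' @seealso [loocvGenetic()]
#' @export
setMethod("excludePrimer", "BandMatrix", function(x, primerId) {
    panel <- metadata(x)$panel
    known <- union(unique(primerIds(x)),
                   if (!is.null(panel)) panel$primer_id else character())
    if (!primerId %in% known)
        stop("unknown primer_id: ", primerId)
    keep <- primerIds(x) != primerId
    out <- x[keep, ]
    if (!is.null(panel))
        metadata(out)$panel <- panel[panel$primer_id != primerId, ,
                                     drop = FALSE]
    metadata(out)$excluded_primers <-
        c(metadata(x)$excluded_primers, primerId)
    validObject(out)
    out
})
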