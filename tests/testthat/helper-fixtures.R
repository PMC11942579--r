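# Small in-code fixtures shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# 4 samples x 5 bands over two primers, two batches; hand-checkable.
toyBandMatrix <- function() {
    m <- matrix(c(
        1, 0, 1, 1, 0,
        1, 0, 0, 1, 1,
        0, 1, 1, 0, 0,
        0, 1, 1, 0, 1), nrow = 4, byrow = TRUE,
        dimnames = list(c("a1", "a2", "b1", "b2"),
                        c("P1:01", "P1:02", "P1:03", "P2:01", "P2:02")))
    suppressMessages(BandMatrix(
        m, batch = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")))
}

# BandMatrix from explicit profile rows (list of 0/1 vectors).
profileBandMatrix <- function(profiles, primers, batch) {
    m <- do.call(rbind, profiles)
    colnames(m) <- paste0(primers, ":",
                          stats::ave(seq_along(primers), primers,
                                     FUN = seq_along))
    rownames(m) <- names(profiles)
    suppressMessages(BandMatrix(m, batch = batch, primers = primers))
}

# Similarity matrix from an explicit symmetric matrix.
simFrom <- function(m, method = "dice") {
    new("SimilarityMatrix", m, method = method)
}

# Peak table from a samples x peaks matrix; auto-names unnamed peaks.
toyPeakTable <- function(areas, batch, ...) {
    if (is.null(colnames(areas)))
        colnames(areas) <- sprintf("P%02d", seq_len(ncol(areas)))
    PeakTable(areas, batch = batch, ...)
}

refData <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- ginsengReferenceData()
        cache
    }
})
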