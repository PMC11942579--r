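## Pairwise binary similarity, UPGMA clustering and within-batch summaries.

#' Pairwise similarity among band profiles
#'
#' For two binary profiles let a, b, c, d count the bands scored (1,1),
#' (1,0), (0,1) and (0,0) respectively.  Supported coefficients:
#' \describe{
#'   \item{dice}{2a / (2a + b + c) (default; the prevalent choice for
#'     dominant-marker data).}
#'   \item{jaccard}{a / (a + b + c).}
#'   \item{simple_matching}{(a + d) / (a + b + c + d).}
#' }
#' Two all-zero profiles (a + b + c = 0) are defined as identical
#' (similarity 1) under dice/jaccard, with a warning.
#'
#' @param bm a \linkS4class{BandMatrix} with at least two samples.
#' @param method coefficient name.
#' @return A \linkS4class{SimilarityMatrix} over the samples of \code{bm}.
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 1))
#' sim <- pairwiseSimilarity(bm)
#' withinBatchSimilarity(sim, batchMap(bm))
#' @export
pairwiseSimilarity <- function(bm,
        method = c("dice", "simple_matching", "jaccard")) {
    method <- match.arg(method)
    stopifnot(is(bm, "BandMatrix"))
    if (ncol(bm) < 2L) stop("need at least two samples")
    X <- t(assay(bm, "bands"))          # samples x bands
    nb <- ncol(X)
    a <- X %*% t(X)
    ones <- rowSums(X)
    b <- outer(ones, rep(1, length(ones))) - a   # 1 in x, 0 in y
    c_ <- t(b)
    s <- switch(method,
        simple_matching = (a + (nb - a - b - c_)) / nb,
        dice = {
            den <- 2 * a + b + c_
            out <- ifelse(den == 0, 1, 2 * a / ifelse(den == 0, 1, den))
            if (any(den == 0 & upper.tri(den)))
                warning("all-zero profile pair(s): similarity defined as 1")
            out
        },
        jaccard = {
            den <- a + b + c_
            out <- ifelse(den == 0, 1, a / ifelse(den == 0, 1, den))
            if (any(den == 0 & upper.tri(den)))
                warning("all-zero profile pair(s): similarity defined as 1")
            out
        })
    diag(s) <- 1
    dimnames(s) <- list(rownames(X), rownames(X))
    new("SimilarityMatrix", s, method = method)
}

#' Coerce a SimilarityMatrix to a plain base matrix
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @param ... ignored.
#' @return The underlying numeric matrix, without the S4 wrapper.
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@.Data)

#' Cosine similarity matrix of non-negative vectors
#' @noRd
.cosineMatrix <- function(X, method = "cosine") {
    ## X: samples x features, non-negative
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0))
        stop("zero area vector(s): cosine similarity undefined for ",
             paste(rownames(X)[nrm == 0], collapse = ", "))
    s <- (X %*% t(X)) / outer(nrm, nrm)
    s[s > 1] <- 1
    diag(s) <- 1
    new("SimilarityMatrix", s, method = method)
}

#' UPGMA dendrogram of a similarity matrix
#'
#' Agglomerates samples by average linkage (unweighted pair group method
#' with arithmetic mean) on distances d = 1 - similarity.  Merge height is
#' half the merged average distance, so the tree is ultrametric with
#' cophenetic distance equal to the UPGMA-averaged distance.  Equal-height
#' merge candidates are resolved deterministically: the pair whose sorted,
#' concatenated leaf ids sort first lexicographically is merged.
#'
#' @param sim a \linkS4class{SimilarityMatrix} (or square symmetric
#'   similarity matrix with dimnames) over at least two samples.
#' @return An ultrametric [ape::phylo] tree with branch lengths; serialize
#'   with [exportNewick()] or \code{ape::write.tree}.
#' @examples
#' s <- matrix(c(1, .9, .6, .9, 1, .6, .6, .6, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(new("SimilarityMatrix", s, method = "dice"))
#' @export
upgma <- function(sim) {
    D <- 1 - as.matrix(sim)
    n <- nrow(D)
    if (n < 2L) stop("need at least two samples to cluster")
    labels <- rownames(D)
    size <- rep(1, n)
    members <- as.list(labels)            # leaf ids per active cluster
    id <- -(seq_len(n))                   # hclust convention: leaves < 0
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    active <- seq_len(n)
    d <- D
    for (step in seq_len(n - 1L)) {
        ut <- which(upper.tri(d[active, active, drop = FALSE]), arr.ind = TRUE)
        vals <- d[active, active, drop = FALSE][upper.tri(
            d[active, active, drop = FALSE])]
        dmin <- min(vals)
        cand <- ut[vals <= dmin + 1e-12, , drop = FALSE]
        if (nrow(cand) > 1L) {
            keys <- apply(cand, 1L, function(p) paste(
                sort(c(members[[active[p[1L]]]], members[[active[p[2L]]]])),
                collapse = "\r"))
            cand <- cand[order(keys)[1L], , drop = FALSE]
        }
        i <- active[cand[1L, 1L]]; j <- active[cand[1L, 2L]]
        merge[step, ] <- sort(c(id[i], id[j]))
        height[step] <- d[i, j]
        ## Lance-Williams average-linkage update into slot i
        for (k in setdiff(active, c(i, j))) {
            d[i, k] <- d[k, i] <-
                (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
        }
        members[[i]] <- c(members[[i]], members[[j]])
        size[i] <- size[i] + size[j]
        id[i] <- step
        active <- setdiff(active, j)
    }
    ordr <- local({
        rec <- function(k) if (k < 0) -k else c(rec(merge[k, 1L]),
                                                rec(merge[k, 2L]))
        rec(n - 1L)
    })
    hc <- structure(list(merge = merge, height = height, order = ordr,
                         labels = labels, method = "average",
                         call = match.call(),
                         dist.method = "1 - similarity"),
                    class = "hclust")
    ape::as.phylo(hc)
}

#' Write a tree to a Newick file
#'
#' @param tree an [ape::phylo] tree, e.g. from [upgma()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Write a similarity matrix as square CSV
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path) {
    utils::write.csv(as.matrix(sim), path, quote = FALSE)
    invisible(path)
}

#' Within-batch similarity summaries
#'
#' For each batch, the mean and sample standard deviation of the pairwise
#' similarity values among its samples (off-diagonal entries only).
#' Batches with a single sample carry no pairwise value and are excluded
#' with a warning.
#'
#' @param sim a \linkS4class{SimilarityMatrix} (or plain symmetric matrix
#'   with sample dimnames).
#' @param batch named character vector mapping sample id to batch id, e.g.
#'   [batchMap()] of the source object.
#' @return Data frame with columns \code{batch}, \code{n_samples},
#'   \code{n_pairs}, \code{mean}, \code{sd} (sd is \code{NA} for a single
#'   pair).
#' @export
withinBatchSimilarity <- function(sim, batch) {
    m <- as.matrix(sim)
    ids <- rownames(m)
    miss <- setdiff(ids, names(batch))
    if (length(miss))
        stop("samples missing from the batch map: ",
             paste(miss, collapse = ", "))
    batch <- batch[ids]
    batches <- unique(unname(batch))
    singles <- batches[vapply(batches, function(b) sum(batch == b),
                              integer(1)) < 2L]
    if (length(singles)) {
        warning("singleton batch(es) excluded: ",
                paste(singles, collapse = ", "))
        batches <- setdiff(batches, singles)
    }
    rows <- lapply(batches, function(b) {
        sub <- m[batch == b, batch == b, drop = FALSE]
        vals <- sub[upper.tri(sub)]
        data.frame(batch = b, n_samples = nrow(sub),
                   n_pairs = length(vals), mean = mean(vals),
                   sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_)
    })
    do.call(rbind, rows)
}
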