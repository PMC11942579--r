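# Oracle for the three binary coefficients via literal count enumeration.
coefOracle <- function(x, y, method) {
    a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
    c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
    switch(method,
        simple_matching = (a + d) / (a + b + c_ + d),
        dice = 2 * a / (2 * a + b + c_),
        jaccard = a / (a + b + c_))
}

test_that("binary similarity coefficients match count-based enumeration", {
    x <- c(1, 0, 1, 1, 0); y <- c(1, 0, 0, 1, 1)
    bm <- profileBandMatrix(list(s1 = x, s2 = y),
                            primers = rep("P", 5),
                            batch = c(s1 = "X", s2 = "X"))
    expected <- c(simple_matching = 0.6, dice = 2 * 2 / 6, jaccard = 0.5)
    for (m in names(expected)) {
        s <- pairwiseSimilarity(bm, method = m)
        expect_equal(s["s1", "s2"], expected[[m]], info = m)
        expect_equal(s["s1", "s2"], coefOracle(x, y, m), info = m)
        expect_identical(simMethod(s), m)
    }

    # randomized profiles agree with the oracle for every pair and method
    set.seed(42)
    profs <- lapply(1:5, function(i) rbinom(12, 1, 0.5))
    names(profs) <- paste0("r", 1:5)
    bm2 <- profileBandMatrix(profs, primers = rep("P", 12),
                             batch = setNames(rep("X", 5), names(profs)))
    for (m in names(expected)) {
        s <- pairwiseSimilarity(bm2, method = m)
        for (i in 1:4) for (j in (i + 1):5)
            expect_equal(s[i, j], coefOracle(profs[[i]], profs[[j]], m))
        expect_true(all(diag(as.matrix(s)) == 1))
        expect_equal(as.matrix(s), t(as.matrix(s)))
    }
})

test_that("identical, complementary and all-zero profiles hit the limits", {
    ident <- profileBandMatrix(list(s1 = c(1, 0, 1), s2 = c(1, 0, 1)),
                               primers = rep("P", 3),
                               batch = c(s1 = "X", s2 = "X"))
    for (m in c("dice", "simple_matching", "jaccard"))
        expect_equal(unname(pairwiseSimilarity(ident, m)["s1", "s2"]), 1)

    compl <- profileBandMatrix(list(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1)),
                               primers = rep("P", 4),
                               batch = c(s1 = "X", s2 = "X"))
    expect_equal(unname(pairwiseSimilarity(compl, "jaccard")["s1", "s2"]), 0)
    expect_equal(unname(pairwiseSimilarity(compl, "dice")["s1", "s2"]), 0)

    zeros <- profileBandMatrix(list(s1 = c(0, 0), s2 = c(0, 0)),
                               primers = rep("P", 2),
                               batch = c(s1 = "X", s2 = "X"))
    expect_warning(s <- pairwiseSimilarity(zeros, "jaccard"), "all-zero")
    expect_equal(unname(s["s1", "s2"]), 1)
})

test_that("permuting samples permutes but does not change pairwise values", {
    bm <- generateBandMatrix(bandDesign(seed = 8))
    s <- pairwiseSimilarity(bm)
    perm <- sample(ncol(bm))
    s2 <- pairwiseSimilarity(bm[, perm])
    expect_equal(as.matrix(s2), as.matrix(s)[colnames(bm)[perm],
                                             colnames(bm)[perm]])
})

test_that("UPGMA reproduces the three-taxon hand computation", {
    d <- matrix(c(0, 0.1, 0.4,
                  0.1, 0, 0.4,
                  0.4, 0.4, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- upgma(simFrom(1 - d))
    coph <- as.matrix(stats::cophenetic(tr))
    expect_equal(coph["A", "B"], 0.1)
    expect_equal(coph["A", "C"], 0.4)
    expect_equal(coph["B", "C"], 0.4)
    # leaf depths: A,B merge at 0.05, root at 0.2
    depth <- ape::node.depth.edgelength(tr)[seq_len(3)]
    expect_equal(unname(depth), rep(0.2, 3))
    expect_true(ape::is.ultrametric(tr))
    expect_true(ape::is.monophyletic(tr, c("A", "B")))
})

test_that("equal-distance ties break lexicographically by leaf ids", {
    ids <- c("D", "B", "C", "A")
    d <- matrix(0.3, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
    tr <- upgma(simFrom(1 - d))
    expect_true(ape::is.monophyletic(tr, c("A", "B")))
    expect_true(ape::is.monophyletic(tr, c("A", "B", "C")))
    coph <- as.matrix(stats::cophenetic(tr))
    expect_equal(max(abs(coph[upper.tri(coph)] - 0.3)), 0)
})

test_that("UPGMA matches average-linkage hclust on tie-free distances", {
    set.seed(99)
    for (rep in 1:3) {
        n <- 7
        D <- as.matrix(stats::dist(matrix(runif(n * 3), n)))
        D <- D / max(D)
        dimnames(D) <- list(letters[1:n], letters[1:n])
        tr <- upgma(simFrom(1 - D))
        hc <- stats::hclust(stats::as.dist(D), method = "average")
        cop1 <- as.matrix(stats::cophenetic(tr))
        cop2 <- as.matrix(stats::cophenetic(hc))
        expect_equal(cop1[rownames(cop2), colnames(cop2)], cop2)
        expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    }
})

test_that("UPGMA is idempotent on its own cophenetic distances", {
    bm <- generateBandMatrix(bandDesign(seed = 21))
    tr <- upgma(pairwiseSimilarity(bm))
    coph <- as.matrix(stats::cophenetic(tr))
    tr2 <- upgma(simFrom(1 - coph))
    coph2 <- as.matrix(stats::cophenetic(tr2))
    expect_equal(coph2[rownames(coph), colnames(coph)], coph)
})

test_that("trees export as Newick with branch lengths", {
    bm <- generateBandMatrix(bandDesign(seed = 2))
    tr <- upgma(pairwiseSimilarity(bm))
    f <- withr::local_tempfile(fileext = ".nwk")
    exportNewick(tr, f)
    back <- ape::read.tree(f)
    expect_setequal(back$tip.label, colnames(bm))
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
})

test_that("within-batch similarity summarizes off-diagonal pairs", {
    ids <- c("x1", "x2", "x3", "y1")
    m <- diag(4); dimnames(m) <- list(ids, ids)
    m["x1", "x2"] <- m["x2", "x1"] <- 0.9
    m["x1", "x3"] <- m["x3", "x1"] <- 0.8
    m["x2", "x3"] <- m["x3", "x2"] <- 0.7
    m["y1", c("x1", "x2", "x3")] <- m[c("x1", "x2", "x3"), "y1"] <- 0.2
    bmap <- c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y")
    expect_warning(out <- withinBatchSimilarity(simFrom(m), bmap),
                   "singleton")
    expect_identical(out$batch, "X")
    expect_equal(out$mean, 0.8)
    expect_equal(out$sd, 0.1)

    ident <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    out2 <- withinBatchSimilarity(simFrom(ident),
                                  setNames(rep("Z", 3), letters[1:3]))
    expect_equal(out2$mean, 1)
    expect_equal(out2$sd, 0)
})

test_that("heterogeneous batches score lower within-batch similarity and
           clean two-batch structure is recovered by the dendrogram", {
    des <- bandDesign(
        primers = c(P1 = 20L, P2 = 20L),
        batches = data.frame(batch_id = c("lo", "hi"), n_samples = 4L,
                             founder_presence_prob = 0.5,
                             flip_prob = c(0.02, 0.15)),
        seed = 17)
    means <- replicate(20, {
        des$seed <- des$seed + 1
        bm <- generateBandMatrix(des)
        out <- withinBatchSimilarity(pairwiseSimilarity(bm), batchMap(bm))
        out$mean[match(c("lo", "hi"), out$batch)]
    })
    expect_gt(mean(means[1, ] > means[2, ]), 0.9)

    sep <- profileBandMatrix(
        list(g1 = c(1, 1, 1, 1, 0, 0, 0, 0), g2 = c(1, 1, 1, 0, 0, 0, 0, 0),
             h1 = c(0, 0, 0, 0, 1, 1, 1, 1), h2 = c(0, 0, 0, 1, 1, 1, 1, 0)),
        primers = rep("P", 8),
        batch = c(g1 = "G", g2 = "G", h1 = "H", h2 = "H"))
    tr <- upgma(pairwiseSimilarity(sep))
    expect_true(ape::is.monophyletic(tr, c("g1", "g2")))
    expect_true(ape::is.monophyletic(tr, c("h1", "h2")))
})
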