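test_that("leave-one-primer-out produces one fold per primer", {
    bm <- generateBandMatrix(bandDesign(seed = 13))
    res <- loocvGenetic(bm)
    folds <- foldResults(res)
    expect_length(folds, 8L)
    expect_setequal(names(folds), unique(primerIds(bm)))
    smry <- loocvSummary(res)
    expect_setequal(smry$batch, unique(batchMap(bm)))
    expect_true(all(smry$folds == 8L))
    # SE is recomputable from the stored folds: sd over sqrt(fold count)
    for (b in smry$batch) {
        nv <- vapply(folds, function(f) f$n[f$batch == b], numeric(1))
        expect_equal(smry$se_n[smry$batch == b], sd(nv) / sqrt(length(nv)))
        expect_equal(smry$mean_n[smry$batch == b], mean(nv))
    }
})

test_that("duplicated-information primers give identical folds", {
    prof <- list(s1 = c(1, 0, 1, 0), s2 = c(1, 1, 0, 0), s3 = c(0, 1, 1, 0))
    # primer B duplicates primer A's two bands exactly
    dup <- lapply(prof, function(p) c(p[1:2], p[1:2]))
    bm <- profileBandMatrix(dup, primers = c("A", "A", "B", "B"),
                            batch = c(s1 = "X", s2 = "X", s3 = "X"))
    res <- loocvGenetic(bm)
    folds <- foldResults(res)
    expect_length(folds, 2L)
    expect_equal(folds[["A"]]$n, folds[["B"]]$n)
    expect_equal(loocvSummary(res)$se_n, 0)
})

test_that("a fold leaving a sample bandless is flagged and skipped", {
    # sample s1 is supported only by primer A's bands: dropping A zeroes it
    prof <- list(s1 = c(1, 1, 0, 0), s2 = c(1, 0, 1, 1), s3 = c(1, 1, 0, 1))
    bm <- profileBandMatrix(prof, primers = c("A", "A", "B", "B"),
                            batch = c(s1 = "X", s2 = "X", s3 = "X"))
    expect_warning(res <- loocvGenetic(bm), "no band; fold flagged")
    expect_length(foldResults(res), 1L)
    expect_identical(names(foldResults(res)), "B")
})

test_that("a primer carrying all variation collapses RSD in its fold", {
    # primer V varies between samples; primer C is identical in every sample
    prof <- list(s1 = c(1, 0, 1, 1, 0), s2 = c(0, 1, 1, 1, 0),
                 s3 = c(1, 1, 1, 1, 0))
    bm <- profileBandMatrix(prof, primers = c("V", "V", "C", "C", "C"),
                            batch = c(s1 = "X", s2 = "X", s3 = "X"))
    res <- loocvGenetic(bm)
    folds <- foldResults(res)
    expect_equal(folds[["V"]]$RSD, 0)     # constant profiles remain
    expect_gt(folds[["C"]]$RSD, 0)
})

test_that("leave-one-peak-out produces one fold per peak", {
    pt <- generatePeakTable(peakDesign(seed = 14))
    res <- loocvChemical(pt)
    folds <- foldResults(res)
    expect_length(folds, 6L)
    expect_setequal(names(folds), rownames(pt))
    smry <- loocvSummary(res)
    expect_true(all(smry$folds == 6L))
    for (b in smry$batch) {
        mv <- vapply(folds, function(f) f$MQS_kg[f$batch == b], numeric(1))
        expect_equal(smry$se_MQS_kg[smry$batch == b],
                     sd(mv) / sqrt(length(mv)))
    }
})

test_that("an everywhere-zero peak does not influence the chemical result", {
    areas <- rbind(s1 = c(5, 3, 0, 2), s2 = c(4, 4, 0, 2),
                   s3 = c(6, 2, 0, 3))
    colnames(areas) <- c("p1", "p2", "pz", "p4")
    pt <- toyPeakTable(areas, batch = c(s1 = "X", s2 = "X", s3 = "X"))
    full <- batchHwepReport(batchEntropiesChemical(pt))
    res <- loocvChemical(pt)
    zeroFold <- foldResults(res)[["pz"]]
    expect_equal(zeroFold$n, full$n)
    expect_equal(zeroFold$RSD, full$RSD)
})

test_that("equal-area peaks make all chemical folds identical", {
    areas <- matrix(rep(c(7, 7, 7), each = 3), nrow = 3,
                    dimnames = list(c("s1", "s2", "s3"), c("p1", "p2", "p3")))
    areas <- areas * c(1, 1.2, 0.9)     # sample-level scale, peak-equal
    pt <- toyPeakTable(areas, batch = c(s1 = "X", s2 = "X", s3 = "X"))
    res <- loocvChemical(pt)
    ns <- vapply(foldResults(res), function(f) f$n, numeric(1))
    expect_equal(max(ns) - min(ns), 0, tolerance = 1e-12)
})

test_that("group comparisons handle separation and degeneracy", {
    same <- groupCompare(rep(2.5, 8), rep(c("a", "b"), each = 4))
    expect_equal(same$p.value, 1)

    set.seed(7)
    sep <- groupCompare(c(rnorm(4, 0, 1e-3), rnorm(4, 1, 1e-3)),
                        rep(c("a", "b"), each = 4))
    expect_lt(sep$p.value, 1e-6)

    # hand-computed Welch statistic on a small fixture
    x <- c(3.1, 2.8, 3.6, 3.0); y <- c(2.1, 2.6, 2.2)
    got <- groupCompare(c(x, y), rep(c("a", "b"), c(4, 3)))
    sx <- var(x) / 4; sy <- var(y) / 3
    tW <- (mean(x) - mean(y)) / sqrt(sx + sy)
    dfW <- (sx + sy)^2 / (sx^2 / 3 + sy^2 / 2)
    expect_equal(got$statistic, tW)
    expect_equal(got$df, dfW)
    expect_equal(got$p.value, 2 * pt(-abs(tW), dfW))

    paired <- groupCompare(c(x, x + 0.5), rep(c("a", "b"), each = 4),
                           design = "paired_t")
    expect_lt(paired$p.value, 1e-6)
})

test_that("two-group ANOVA reproduces the squared pooled t statistic", {
    set.seed(15)
    v <- c(rnorm(5, 0), rnorm(6, 0.8))
    g <- rep(c("a", "b"), c(5, 6))
    aovOut <- groupCompare(v, g, design = "one_way_anova_lsd")
    tPooled <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
    expect_equal(aovOut$statistic, unname(tPooled$statistic)^2)
    expect_equal(aovOut$p.value, tPooled$p.value)
})

test_that("LSD letters separate clearly distinct groups only", {
    set.seed(16)
    v <- c(rnorm(4, 0, 0.05), rnorm(4, 0.05, 0.05), rnorm(4, 3, 0.05))
    g <- rep(c("low1", "low2", "high"), each = 4)
    out <- groupCompare(v, g, design = "one_way_anova_lsd")
    expect_lt(out$p.value, 1e-6)
    lt <- out$letters
    expect_identical(unname(lt["high"] == lt["low1"]), FALSE)
    expect_identical(unname(lt["low1"]), unname(lt["low2"]))
    expect_true(all(out$pairwise_p[c("low1", "low2"), "high"] < 0.05))
})

test_that("spearmanExact matches hand limits and the exact-p oracle", {
    expect_equal(unname(spearmanExact(1:5, c(2, 4, 6, 8, 10))$estimate), 1)
    expect_equal(unname(spearmanExact(1:5, 5:1)$estimate), -1)
    expect_error(spearmanExact(rep(1, 5), 1:5), "constant")

    set.seed(23)
    for (i in 1:5) {
        x <- sample(100, 7); y <- sample(100, 7)
        got <- spearmanExact(x, y)
        oracle <- suppressWarnings(
            cor.test(x, y, method = "spearman", exact = TRUE))
        expect_equal(unname(got$estimate), unname(oracle$estimate))
        expect_equal(got$p.value, oracle$p.value, tolerance = 1e-10)
        expect_match(got$method, "exact permutation")
        # the enumeration is over all 7! = 5040 rank permutations
        expect_equal(got$p.value * 5040, round(got$p.value * 5040))
    }
})

test_that("large samples fall back to the asymptotic t approximation", {
    set.seed(29)
    x <- rnorm(25); y <- x + rnorm(25)
    got <- spearmanExact(x, y)
    expect_match(got$method, "asymptotic t")
    oracle <- cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(unname(got$estimate), unname(oracle$estimate))
    rho <- unname(got$estimate)
    tstat <- rho * sqrt((25 - 2) / (1 - rho^2))
    expect_equal(got$p.value, 2 * pt(-abs(tstat), 23))
})

test_that("LOOCV results serialize to JSON and CSV", {
    bm <- generateBandMatrix(bandDesign(seed = 19))
    res <- loocvGenetic(bm)
    f <- withr::local_tempfile(fileext = ".json")
    writeLoocvResult(res, f)
    js <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_identical(js$unit, "primer")
    expect_length(js$folds, 8L)
    expect_true(file.exists(paste0(f, ".csv")))
})
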