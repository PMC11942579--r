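## Leave-one-primer-out / leave-one-peak-out cross-validation of HWEP
## sizing, group-difference tests, and exact small-sample Spearman
## correlation.

.loocvSummarize <- function(folds, keep) {
    reps <- folds[keep]
    batches <- unique(unlist(lapply(reps, `[[`, "batch")))
    k <- length(reps)
    rows <- lapply(batches, function(b) {
        nv <- vapply(reps, function(r) r$n[r$batch == b], numeric(1))
        mv <- vapply(reps, function(r) r$MQS_kg[r$batch == b], numeric(1))
        data.frame(batch = b, folds = k,
                   mean_n = mean(nv), se_n = stats::sd(nv) / sqrt(k),
                   mean_MQS_kg = mean(mv),
                   se_MQS_kg = stats::sd(mv) / sqrt(k))
    })
    do.call(rbind, rows)
}

#' Leave-one-primer-out cross-validation of genetic HWEP sizing
#'
#' For each primer of the panel, its bands are excluded, the panel total m1
#' and every sample's m2 are recomputed, and the per-batch entropies, RSD,
#' HWEP size n and MQS are rederived on the reduced panel — one fold per
#' primer, probing primer-specific bias of the sizing.  A fold in which
#' some sample retains no band at all cannot yield finite entropy; such
#' folds are flagged, excluded from the summaries, and reported with a
#' warning.
#'
#' @param bm a \linkS4class{BandMatrix} with at least two primers and at
#'   least two samples per batch.
#' @param cfg an \linkS4class{HwepConfig}.
#' @return A \linkS4class{LoocvResult} (unit \code{"primer"}).
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 1))
#' loocvSummary(loocvGenetic(bm))
#' @export
loocvGenetic <- function(bm, cfg = HwepConfig()) {
    primers <- unique(primerIds(bm))
    if (length(primers) < 2L) stop("need at least two primers")
    folds <- list(); bad <- character()
    for (p in primers) {
        sub <- excludePrimer(bm, p)
        m2 <- bandCounts(sub)
        if (any(m2 == 0L)) {
            warning("fold without primer ", p, " leaves sample(s) ",
                    paste(names(m2)[m2 == 0L], collapse = ", "),
                    " with no band; fold flagged and excluded")
            bad <- c(bad, p)
            folds[[p]] <- NULL
            next
        }
        folds[[p]] <- batchHwepReport(batchEntropiesGenetic(sub, cfg), cfg)
    }
    keep <- setdiff(primers, bad)
    if (!length(keep)) stop("every fold was flagged; no summary possible")
    new("LoocvResult", unit = "primer", folds = folds,
        excludedFolds = character(),
        summary = .loocvSummarize(folds, keep))
}

#' Leave-one-peak-out cross-validation of chemical HWEP sizing
#'
#' For each common peak, that peak is excluded and the fingerprint entropy
#' Sp, per-batch RSD, HWEP size n and MQS are recomputed on the remaining
#' peaks — one fold per peak.  A fold leaving a sample with an all-zero
#' area vector is flagged and excluded with a warning.
#'
#' @param pt a \linkS4class{PeakTable} with at least two peaks.
#' @param cfg an \linkS4class{HwepConfig}.
#' @return A \linkS4class{LoocvResult} (unit \code{"peak"}).
#' @export
loocvChemical <- function(pt, cfg = HwepConfig()) {
    if (nrow(pt) < 2L) stop("need at least two peaks")
    peaks <- rownames(pt)
    folds <- list(); bad <- character()
    for (p in peaks) {
        sub <- pt[rownames(pt) != p, ]
        a <- assay(sub, "area")
        if (any(colSums(a) == 0)) {
            warning("fold without peak ", p, " leaves sample(s) ",
                    paste(colnames(a)[colSums(a) == 0], collapse = ", "),
                    " with an all-zero profile; fold flagged and excluded")
            bad <- c(bad, p)
            next
        }
        folds[[p]] <- batchHwepReport(batchEntropiesChemical(sub), cfg)
    }
    keep <- setdiff(peaks, bad)
    if (!length(keep)) stop("every fold was flagged; no summary possible")
    new("LoocvResult", unit = "peak", folds = folds,
        excludedFolds = character(),
        summary = .loocvSummarize(folds, keep))
}

#' Write a LoocvResult as JSON plus a CSV summary
#'
#' @param x a \linkS4class{LoocvResult}.
#' @param path JSON output path; the CSV summary is \code{paste0(path,
#'   ".csv")}.
#' @return \code{path}, invisibly.
#' @export
writeLoocvResult <- function(x, path) {
    jsonlite::write_json(
        list(unit = x@unit, folds = x@folds,
             excluded_folds = x@excludedFolds, summary = x@summary),
        path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
    utils::write.csv(x@summary, paste0(path, ".csv"), row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Group-difference tests for batch comparisons
#'
#' Standard statistical plumbing behind batch contrasts:
#' \describe{
#'   \item{two_sample_welch}{Welch's unequal-variance t-test on two groups.}
#'   \item{paired_t}{paired t-test on two equal-length groups.}
#'   \item{one_way_anova_lsd}{one-way ANOVA followed by unadjusted pairwise
#'     t-tests on the pooled SD (Fisher's LSD), with a compact letter
#'     display: groups sharing a letter are not significantly different at
#'     \code{alpha}.}
#' }
#' Degenerate data (all values identical across groups) report p = 1
#' rather than erroring.
#'
#' @param values numeric vector of observations.
#' @param group grouping labels, same length as \code{values}; every group
#'   needs at least two values.
#' @param design one of \code{"two_sample_welch"},
#'   \code{"one_way_anova_lsd"}, \code{"paired_t"}.
#' @param alpha significance level for the LSD letter display.
#' @return List with \code{design}, \code{statistic}, \code{df},
#'   \code{p.value}; for the ANOVA design additionally \code{pairwise_p}
#'   (matrix of unadjusted pairwise p-values) and \code{letters} (named
#'   letter groupings, ordered by decreasing group mean).
#' @export
groupCompare <- function(values, group,
        design = c("two_sample_welch", "one_way_anova_lsd", "paired_t"),
        alpha = 0.05) {
    design <- match.arg(design)
    group <- as.character(group)
    stopifnot(length(values) == length(group))
    sizes <- table(group)
    if (any(sizes < 2L)) stop("every group needs at least two values")
    degenerate <- stats::var(values) == 0
    if (design %in% c("two_sample_welch", "paired_t")) {
        if (length(sizes) != 2L) stop(design, " needs exactly two groups")
        g <- names(sizes)
        x <- values[group == g[1L]]; y <- values[group == g[2L]]
        if (degenerate)
            return(list(design = design, statistic = 0,
                        df = NA_real_, p.value = 1))
        tt <- tryCatch(
            if (design == "paired_t") stats::t.test(x, y, paired = TRUE)
            else stats::t.test(x, y, var.equal = FALSE),
            error = function(e) {
                ## constant within groups (or constant differences): report
                ## the exact-equality case instead of failing
                delta <- mean(x) - mean(y)
                list(statistic = if (delta == 0) 0 else Inf * sign(delta),
                     parameter = NA_real_,
                     p.value = if (delta == 0) 1 else 0)
            })
        return(list(design = design, statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p.value = tt$p.value))
    }
    ## one-way ANOVA + LSD
    if (degenerate) {
        lv <- names(sort(tapply(values, group, mean), decreasing = TRUE))
        return(list(design = design, statistic = 0, df = NA_real_,
                    p.value = 1,
                    pairwise_p = matrix(1, length(lv), length(lv),
                                        dimnames = list(lv, lv)),
                    letters = stats::setNames(rep("a", length(lv)), lv)))
    }
    fit <- stats::aov(values ~ factor(group))
    at <- stats::anova(fit)
    pw <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    lv <- names(sort(tapply(values, group, mean), decreasing = TRUE))
    pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    for (i in rownames(pw)) for (j in colnames(pw))
        if (!is.na(pw[i, j])) pmat[i, j] <- pmat[j, i] <- pw[i, j]
    letters <- .lsdLetters(pmat, lv, alpha)
    list(design = design, statistic = at$`F value`[1L],
         df = at$Df[seq_len(2L)], p.value = at$`Pr(>F)`[1L],
         pairwise_p = pmat, letters = letters)
}

## Compact letter display by the line (sweep) method: walk groups in mean
## order, extend each run while all pairs inside stay non-significant,
## drop runs contained in an earlier one.  Presentational only.
.lsdLetters <- function(pmat, orderedGroups, alpha) {
    k <- length(orderedGroups)
    runs <- list()
    i <- 1L
    while (i <= k) {
        j <- i
        while (j < k && all(pmat[orderedGroups[i:(j + 1L)],
                                 orderedGroups[i:(j + 1L)]][
                                 upper.tri(diag(j + 2L - i))] >= alpha))
            j <- j + 1L
        runs[[length(runs) + 1L]] <- i:j
        i <- if (j == k) k + 1L else i + 1L
    }
    keep <- !vapply(seq_along(runs), function(r) any(vapply(
        seq_along(runs)[-r], function(s) all(runs[[r]] %in% runs[[s]]),
        logical(1))), logical(1))
    runs <- runs[keep]
    out <- stats::setNames(rep("", k), orderedGroups)
    for (r in seq_along(runs))
        out[runs[[r]]] <- paste0(out[runs[[r]]], letters[r])
    out
}

## All permutations of 1..n as an n! x n matrix (row-wise).
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- .permutations(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    for (pos in seq_len(n)) {
        rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
        out[rows, pos] <- n
        out[rows, -pos] <- sub
    }
    out
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' rho is the Pearson correlation of the (average-tie) ranks, equivalently
#' \eqn{1 - 6\sum d_i^2 / (n(n^2-1))} without ties.  The two-sided p-value
#' is computed by full enumeration of all n! rank permutations when
#' \code{n <= exactMax} (counting permutations with |rho| at least the
#' observed), and by the asymptotic t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} otherwise; the method used is
#' recorded.
#'
#' @param x,y equal-length numeric vectors, length >= 3, neither constant.
#' @param exactMax largest n for which the full permutation enumeration is
#'   used (default 9; 9! = 362880 permutations).
#' @return An object of class \code{"htest"} with \code{estimate} (rho),
#'   \code{p.value}, \code{parameter} (n pairs), and a \code{method} string
#'   naming \code{exact permutation} or \code{asymptotic t}.
#' @examples
#' spearmanExact(1:7, c(2, 1, 4, 3, 6, 5, 7))
#' @export
spearmanExact <- function(x, y, exactMax = 9L) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 3L) stop("need at least three pairs")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("correlation undefined for a constant vector")
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= exactMax) {
        P <- .permutations(n)
        xc <- rx - mean(rx); yc <- ry - mean(ry)
        num <- matrix(yc[P], nrow(P)) %*% xc
        rhos <- as.vector(num) / sqrt(sum(xc^2) * sum(yc^2))
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
        meth <- "Spearman rank correlation, exact permutation p"
    } else {
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
        meth <- "Spearman rank correlation, asymptotic t approximation"
    }
    structure(list(estimate = c(rho = rho), p.value = p,
                   parameter = c(n = n), method = meth,
                   data.name = paste(deparse1(substitute(x)), "and",
                                     deparse1(substitute(y)))),
              class = "htest")
}
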