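## Information entropy of band profiles and fingerprints, batch RSD,
## HWEP size n and MQS mass.  This is the core statistic of the package:
## within-batch fluctuation of per-sample entropy, expressed as a relative
## standard deviation, is converted into the number of 1-g equilibrium
## units a sampling must cover for that fluctuation to be balanced.

#' Band-profile information entropy
#'
#' \deqn{H = -C \ln(m_2 / m_1)}
#' where m1 is the total number of bands the full primer panel can amplify
#' and m2 the number actually observed for the sample.  With the default
#' C = 1/ln 2 this is \eqn{-\log_2(m_2/m_1)} and H is in bits; H = 0 iff
#' the sample shows the full panel.
#'
#' @param m2 observed band count(s), 0 < m2 <= m1 (vectorized).
#' @param m1 panel band total.
#' @param C conversion constant, default \code{1/log(2)}.
#' @return Numeric entropy value(s).
#' @examples
#' bandEntropy(70, 92)   # 0.3943
#' bandEntropy(46, 92)   # exactly 1 bit
#' @export
bandEntropy <- function(m2, m1, C = 1 / log(2)) {
    stopifnot(length(m1) == 1L, m1 > 0, C > 0)
    if (any(m2 > m1))
        stop("m2 > m1: a sample cannot show more bands than the panel holds")
    if (any(m2 <= 0))
        stop("m2 = 0 gives infinite entropy (sample amplified no band)")
    -C * log(m2 / m1)
}

#' Chromatographic fingerprint information entropy
#'
#' \deqn{S_p = -\sum_i a_i \ln(a_i / \sum_j a_j)}
#' the peak-area-weighted entropy of one sample's common-peak profile, in
#' response units times nats.  The sign is chosen so that Sp >= 0;
#' zero-area peaks contribute 0 (the x ln x -> 0 limit).
#'
#' @param areas non-negative peak areas of one sample; at least one must be
#'   positive.
#' @return Single numeric Sp value.
#' @examples
#' fingerprintEntropy(c(2, 1, 1))   # 4 * log(2)
#' fingerprintEntropy(rep(10, 6))   # 60 * log(6)
#' @export
fingerprintEntropy <- function(areas) {
    if (length(areas) < 1L) stop("need at least one peak")
    if (anyNA(areas) || any(areas < 0)) stop("areas must be non-negative")
    tot <- sum(areas)
    if (tot == 0) stop("all-zero area vector: entropy undefined")
    pos <- areas > 0
    -sum(areas[pos] * log(areas[pos] / tot))
}

#' Relative standard deviation of a batch
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' returned as a fraction.
#'
#' @param values at least two per-sample entropy values with non-zero mean.
#' @return RSD as a fraction (multiply by 100 for percent).
#' @examples
#' batchRSD(c(0.3943, 0.3536, 0.3943))   # 0.0616...
#' @export
batchRSD <- function(values) {
    if (length(values) < 2L) stop("RSD needs at least two values")
    m <- mean(values)
    if (m == 0) stop("RSD undefined for zero mean")
    stats::sd(values) / m
}

#' HWEP size from a batch RSD
#'
#' In \code{table_consistent} mode (the default),
#' \deqn{n = 100 \, (t_{\alpha,n-1} + u_\beta)^2 \, RSD^2}
#' with RSD as a fraction — equivalently \eqn{(10.8 \cdot RSD\%)^2 / 100}.
#' This form reproduces the published genetic and chemical batch tables and
#' is used for both data types.  \code{eq5_literal} mode instead applies the
#' formulation-control form \eqn{n = K \cdot RSD^2} (K = 25.6 by default),
#' which yields values on a very different scale; it is retained for
#' fidelity to that formulation and announces itself with a message.
#'
#' n scales quadratically in RSD and is 0 at RSD 0.
#'
#' @param rsd batch RSD as a fraction (>= 0); vectorized.
#' @param cfg an \linkS4class{HwepConfig}.
#' @return HWEP size(s) n (number of equilibrium units, dimensionless).
#' @examples
#' hwepSize(0.0616)    # ~44.3
#' hwepSize(0.1099)    # ~141
#' @export
hwepSize <- function(rsd, cfg = HwepConfig()) {
    if (any(rsd < 0)) stop("rsd must be non-negative")
    switch(cfg@formulaMode,
        table_consistent = 100 * cfg@tPlusU^2 * rsd^2,
        eq5_literal = {
            message("eq5_literal mode: n = K * RSD^2 does not reproduce ",
                    "the tabulated batch sizes")
            cfg@K * rsd^2
        })
}

#' Minimum quantity for one sampling (MQS)
#'
#' MQS = n equilibrium units times the per-unit mass, expressed in
#' kilograms: \code{n * unitMass / 1000}.
#'
#' @param n HWEP size(s), >= 0.
#' @param cfg an \linkS4class{HwepConfig} (supplies \code{unitMass} in g).
#' @return Mass(es) in kg.
#' @examples
#' mqs(44.30)   # 0.0443 kg
#' @export
mqs <- function(n, cfg = HwepConfig()) {
    if (any(n < 0)) stop("n must be non-negative")
    n * cfg@unitMass / 1000
}

#' Per-sample genetic entropies of a band matrix
#'
#' For every sample: m2 = its observed band count, m1 = the panel band
#' total of \code{bm} (which shrinks after [excludePrimer()]), and
#' H = [bandEntropy()].
#'
#' @param bm a \linkS4class{BandMatrix}.
#' @param cfg an \linkS4class{HwepConfig} (supplies C).
#' @return Data frame with columns \code{sample}, \code{batch}, \code{m2},
#'   \code{m1}, \code{H}, in sample order.
#' @export
batchEntropiesGenetic <- function(bm, cfg = HwepConfig()) {
    stopifnot(is(bm, "BandMatrix"))
    m2 <- bandCounts(bm)
    data.frame(sample = colnames(bm),
               batch = unname(batchMap(bm)),
               m2 = unname(m2),
               m1 = panelSize(bm),
               H = bandEntropy(unname(m2), panelSize(bm), C = cfg@C),
               row.names = NULL)
}

#' Per-sample fingerprint entropies of a peak table
#'
#' Applies [fingerprintEntropy()] to every sample's common-peak area
#' vector.
#'
#' @param pt a \linkS4class{PeakTable}.
#' @return Data frame with columns \code{sample}, \code{batch}, \code{Sp}.
#' @export
batchEntropiesChemical <- function(pt) {
    stopifnot(is(pt, "PeakTable"))
    a <- assay(pt, "area")
    data.frame(sample = colnames(pt),
               batch = unname(batchMap(pt)),
               Sp = apply(a, 2L, fingerprintEntropy),
               row.names = NULL)
}

#' Per-batch HWEP report
#'
#' Groups per-sample entropies by batch and derives, for each batch, the
#' RSD of its entropies, the HWEP size n, and the MQS mass in kg — the
#' layout of the published genetic and chemical batch tables.  Values are
#' carried at full precision; round for display with
#' [formatHwepReport()].
#'
#' @param entropies data frame with a \code{batch} column and one entropy
#'   column (\code{H}, \code{Sp} or \code{entropy}), e.g. from
#'   [batchEntropiesGenetic()] or [batchEntropiesChemical()].
#' @param cfg an \linkS4class{HwepConfig}.
#' @return Data frame with one row per batch (input order):
#'   \code{batch}, \code{n_samples}, \code{mean_entropy}, \code{RSD}
#'   (fraction), \code{n}, \code{MQS_kg}.
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 1))
#' batchHwepReport(batchEntropiesGenetic(bm))
#' @export
batchHwepReport <- function(entropies, cfg = HwepConfig()) {
    stopifnot(is.data.frame(entropies), "batch" %in% names(entropies))
    vcol <- intersect(c("H", "Sp", "entropy"), names(entropies))[1L]
    if (is.na(vcol))
        stop("no entropy column (H, Sp or entropy) found")
    batches <- unique(entropies$batch)
    rows <- lapply(batches, function(b) {
        v <- entropies[entropies$batch == b, vcol]
        if (length(v) < 2L)
            stop("batch '", b, "' has fewer than two samples")
        r <- batchRSD(v)
        n <- hwepSize(r, cfg)
        data.frame(batch = b, n_samples = length(v), mean_entropy = mean(v),
                   RSD = r, n = n, MQS_kg = mqs(n, cfg))
    })
    do.call(rbind, rows)
}

#' Round an HWEP report to display precision
#'
#' Mirrors the conventional table layout: entropy to 4 decimals, RSD as
#' percent to 2 decimals, n to 2 decimals, MQS to 3 decimals (kg).
#'
#' @param report output of [batchHwepReport()].
#' @return Data frame with rounded display columns.
#' @export
formatHwepReport <- function(report) {
    data.frame(batch = report$batch,
               n_samples = report$n_samples,
               mean_entropy = round(report$mean_entropy, 4L),
               RSD_pct = round(100 * report$RSD, 2L),
               n = round(report$n, 2L),
               MQS_kg = round(report$MQS_kg, 3L))
}

#' Write an HWEP report as CSV plus a full-precision JSON sidecar
#'
#' The CSV mirrors the display layout of [formatHwepReport()]; the JSON
#' variant carries full-precision values together with the configuration
#' block used, for machine consumption.
#'
#' @param report output of [batchHwepReport()].
#' @param path CSV output path; the JSON sidecar is \code{paste0(path,
#'   ".json")}.
#' @param cfg the \linkS4class{HwepConfig} the report was computed with.
#' @return \code{path}, invisibly.
#' @export
writeHwepReport <- function(report, path, cfg = HwepConfig()) {
    utils::write.csv(formatHwepReport(report), path, row.names = FALSE,
                     quote = FALSE)
    payload <- list(
        config = list(C = cfg@C, tPlusU = cfg@tPlusU,
                      formulaMode = cfg@formulaMode, K = cfg@K,
                      unitMass_g = cfg@unitMass),
        batches = report)
    jsonlite::write_json(payload, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE, dataframe = "rows")
    invisible(path)
}
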