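## Seeded generators for band matrices and peak tables with the statistical
## structure the analysis assumes: per-batch founder band profiles with
## independent band flips (genetic heterogeneity), and log-normal
## multiplicative area noise of stated CV (chemical heterogeneity).  The
## defaults emulate the reference study design: an 8-primer / 92-band ISSR
## panel and six-peak fingerprints over seven batches (five decoction-piece
## batches PG01-PG05, garden ginseng GG, forest-grown FG) of three samples
## each, with per-batch heterogeneity graded to the published batch
## contrasts (homogeneous GG-like vs heterogeneous FG-like).

.studyPrimerCounts <- c(UBC807 = 14L, UBC808 = 12L, UBC809 = 5L,
                        UBC823 = 13L, UBC834 = 13L, UBC840 = 10L,
                        UBC842 = 11L, UBC873 = 14L)

.studyBandBatches <- data.frame(
    batch_id = c("PG01", "PG02", "PG03", "PG04", "PG05", "GG", "FG"),
    n_samples = 3L,
    founder_presence_prob = c(0.77, 0.38, 0.48, 0.42, 0.42, 0.88, 0.54),
    flip_prob = c(0.02, 0.03, 0.07, 0.02, 0.06, 0.01, 0.06))

.studyPeakBatches <- data.frame(
    batch_id = c("PG01", "PG02", "PG03", "PG04", "PG05", "GG", "FG"),
    n_samples = 3L,
    cv = c(0.10, 0.25, 0.35, 0.05, 0.18, 0.08, 0.45))

.studyMeanAreas <- c(5e4, 8e4, 2e4, 1.2e5, 3e4, 6e4)
.studyPeakRt <- c(4.5, 6.2, 8.0, 10.3, 13.1, 16.8)   # minutes
.studyPeakLabels <- c("Rg1", "Re", NA, "Rb1", NA, NA)

#' Design of a synthetic band matrix
#'
#' Each batch draws one founder band profile (each band present with
#' \code{founder_presence_prob}); each sample of the batch then flips every
#' band independently with \code{flip_prob}, so \code{flip_prob} is the
#' within-batch heterogeneity dial the HWEP statistic should recover.
#'
#' Defaults reproduce the reference study conditions: the 8-primer, 92-band
#' panel and seven batches of three samples, with founder presence set to
#' each batch's observed band fraction and flip probabilities graded to the
#' published within-batch heterogeneity contrast.
#'
#' @param primers named integer vector of band counts per primer.
#' @param batches data frame with columns \code{batch_id},
#'   \code{n_samples} (>= 2), \code{founder_presence_prob} and
#'   \code{flip_prob} (both in [0, 1]).
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @return A \code{"BandDesign"} list understood by
#'   [generateBandMatrix()].
#' @export
bandDesign <- function(primers = .studyPrimerCounts,
                       batches = .studyBandBatches, seed = 1L) {
    stopifnot(is.numeric(primers), length(primers) >= 1L,
              !is.null(names(primers)), all(primers >= 1))
    need <- c("batch_id", "n_samples", "founder_presence_prob", "flip_prob")
    stopifnot(is.data.frame(batches), all(need %in% names(batches)),
              all(batches$n_samples >= 2L),
              all(batches$founder_presence_prob >= 0),
              all(batches$founder_presence_prob <= 1),
              all(batches$flip_prob >= 0), all(batches$flip_prob <= 1),
              !anyDuplicated(batches$batch_id))
    structure(list(primers = as.integer(primers) |>
                       stats::setNames(names(primers)),
                   batches = batches, seed = as.integer(seed)),
              class = "BandDesign")
}

#' Design of a synthetic peak table
#'
#' Sample areas are \code{mean_areas[i] * LogNormal} with the log-normal
#' parameterized so each peak's multiplicative noise has expectation 1 and
#' coefficient of variation \code{cv} — guaranteeing positive areas and
#' mapping \code{cv} directly onto the RSD scale of fingerprint
#' fluctuation.
#'
#' Defaults emulate the reference study conditions: six common peaks with
#' areas on the 1e4-1e5 response-unit scale (three of them labelled Rg1,
#' Re, Rb1; the largest-area peak is the reference), seven batches of three
#' samples with per-batch CVs graded to the published chemical contrast.
#'
#' @param nPeaks number of common peaks.
#' @param meanAreas positive per-peak mean areas (length \code{nPeaks}).
#' @param batches data frame with columns \code{batch_id}, \code{n_samples}
#'   (>= 2) and \code{cv} (>= 0).
#' @param rt per-peak retention times in minutes (strictly increasing),
#'   used when peak lists are generated.
#' @param labels optional per-peak compound labels.
#' @param seed integer seed.
#' @return A \code{"PeakDesign"} list understood by
#'   [generatePeakTable()].
#' @export
peakDesign <- function(nPeaks = 6L, meanAreas = .studyMeanAreas,
                       batches = .studyPeakBatches, rt = .studyPeakRt,
                       labels = .studyPeakLabels, seed = 1L) {
    stopifnot(length(meanAreas) == nPeaks, all(meanAreas > 0),
              length(rt) == nPeaks, !is.unsorted(rt, strictly = TRUE))
    need <- c("batch_id", "n_samples", "cv")
    stopifnot(is.data.frame(batches), all(need %in% names(batches)),
              all(batches$n_samples >= 2L), all(batches$cv >= 0),
              !anyDuplicated(batches$batch_id))
    if (!is.null(labels)) stopifnot(length(labels) == nPeaks)
    structure(list(nPeaks = as.integer(nPeaks), meanAreas = meanAreas,
                   batches = batches, rt = rt, labels = labels,
                   seed = as.integer(seed)),
              class = "PeakDesign")
}

## Run fn under a private RNG stream without disturbing the caller's.
.withSeed <- function(seed, fn) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    fn()
}

#' Generate a synthetic band matrix
#'
#' Draws, per batch, a founder profile and per-sample band flips as
#' described in [bandDesign()].  A design whose founder draw comes out
#' all-zero is retried a bounded number of times, then errors.  Output is
#' bit-identical for identical design + seed.
#'
#' @param design a [bandDesign()] object.
#' @return A validated \linkS4class{BandMatrix}; band ids are
#'   \code{"<primer>:<ordinal>"}, sample ids \code{"<batch>-<i>"}.
#' @examples
#' bm <- generateBandMatrix(bandDesign(seed = 42))
#' panelSize(bm)
#' @export
generateBandMatrix <- function(design) {
    stopifnot(inherits(design, "BandDesign"))
    bandIds <- unlist(lapply(names(design$primers), function(p)
        sprintf("%s:%02d", p, seq_len(design$primers[[p]]))),
        use.names = FALSE)
    m1 <- length(bandIds)
    .withSeed(design$seed, function() {
        rows <- list(); batchOf <- character()
        for (b in seq_len(nrow(design$batches))) {
            bb <- design$batches[b, ]
            founder <- integer(m1)
            for (try in seq_len(100L)) {
                founder <- stats::rbinom(m1, 1L, bb$founder_presence_prob)
                if (sum(founder) > 0L) break
                if (try == 100L)
                    stop("batch '", bb$batch_id,
                         "': founder profile all zero after 100 draws")
            }
            for (s in seq_len(bb$n_samples)) {
                flip <- stats::runif(m1) < bb$flip_prob
                prof <- ifelse(flip, 1L - founder, founder)
                rows[[paste0(bb$batch_id, "-", s)]] <- prof
                batchOf[paste0(bb$batch_id, "-", s)] <- bb$batch_id
            }
        }
        m <- do.call(rbind, rows)
        colnames(m) <- bandIds
        suppressMessages(BandMatrix(m, batch = batchOf))
    })
}

#' Generate a synthetic peak table (and optional peak lists)
#'
#' Areas follow the log-normal multiplicative noise model of
#' [peakDesign()]: \code{area = meanArea * exp(rnorm(sdlog) - sdlog^2/2)}
#' with \code{sdlog = sqrt(log(1 + cv^2))}, so the expected area is the
#' design mean and the multiplicative CV is the design CV.  With
#' \code{peakLists = TRUE} the per-sample peak lists additionally receive
#' multiplicative retention-time jitter, for exercising
#' [matchCommonPeaks()].
#'
#' @param design a [peakDesign()] object.
#' @param peakLists also return raw per-sample peak lists with jittered
#'   retention times.
#' @param rtJitterCV multiplicative CV of the retention-time jitter
#'   (default 0.002, i.e. RRT repeatability well below the matching
#'   tolerance).
#' @return A \linkS4class{PeakTable}; with \code{peakLists = TRUE}, a list
#'   with elements \code{table} and \code{lists}.
#' @examples
#' pt <- generatePeakTable(peakDesign(seed = 42))
#' batchHwepReport(batchEntropiesChemical(pt))
#' @export
generatePeakTable <- function(design, peakLists = FALSE, rtJitterCV = 0.002) {
    stopifnot(inherits(design, "PeakDesign"))
    .withSeed(design$seed, function() {
        samples <- character(); batchOf <- character()
        areas <- NULL; rts <- list()
        for (b in seq_len(nrow(design$batches))) {
            bb <- design$batches[b, ]
            sdlog <- sqrt(log(1 + bb$cv^2))
            for (s in seq_len(bb$n_samples)) {
                id <- paste0(bb$batch_id, "-", s)
                noise <- exp(stats::rnorm(design$nPeaks, 0, sdlog) -
                             sdlog^2 / 2)
                areas <- rbind(areas, design$meanAreas * noise)
                rts[[id]] <- design$rt *
                    exp(stats::rnorm(design$nPeaks, 0, rtJitterCV))
                samples <- c(samples, id)
                batchOf[id] <- bb$batch_id
            }
        }
        rownames(areas) <- samples
        colnames(areas) <- sprintf("P%02d", seq_len(design$nPeaks))
        pt <- PeakTable(areas, batch = batchOf,
                        rrt = design$rt / design$rt[which.max(design$meanAreas)],
                        label = design$labels,
                        referencePeak = sprintf("P%02d",
                                                which.max(design$meanAreas)))
        if (!peakLists) return(pt)
        lists <- stats::setNames(lapply(samples, function(id) {
            o <- order(rts[[id]])
            data.frame(rt = rts[[id]][o], area = unname(areas[id, o]))
        }), samples)
        list(table = pt, lists = lists)
    })
}

#' Reference dataset of the ginseng quality-consistency study
#'
#' Machine-readable copies of the published study tables shipped with the
#' package: the 8-primer ISSR panel with per-primer band counts, the
#' per-sample amplified band counts (TNB) of the 21 samples over seven
#' batches, the per-sample fingerprint entropies of the six-common-peak and
#' three-ginsenoside panels, and the published per-batch summary columns
#' (RSD, HWEP n, MQS) for comparison.  All analysis values are recomputed
#' by the package from the TNB and entropy inputs; the published summaries
#' are provided as printed, including the PG05 genetic MQS misprint
#' (0.998 kg for n = 99.80, where the 1 g unit mass implies 0.100 kg).
#'
#' @return Named list of data frames: \code{primers} (primer_id, sequence,
#'   TNB, NPB), \code{bandCounts} (batch, sample, tnb, published per-sample
#'   entropy), \code{geneticSummary} (batch, published RSD %, n, MQS kg),
#'   \code{fingerprintEntropies} (batch, replicate, entropy of both
#'   panels), \code{fingerprintSummary} (batch, panel, published RSD %, n,
#'   MQS kg).
#' @examples
#' ref <- ginsengReferenceData()
#' ref$primers
#' @export
ginsengReferenceData <- function() {
    dir <- system.file("extdata", package = "BatchHWEP", mustWork = TRUE)
    rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                        header = TRUE, check.names = FALSE,
                                        stringsAsFactors = FALSE)
    list(primers = rd("ginseng_issr_primers.tsv"),
         bandCounts = rd("ginseng_band_counts.tsv"),
         geneticSummary = rd("ginseng_genetic_summary.tsv"),
         fingerprintEntropies = rd("ginseng_fingerprint_entropy.tsv"),
         fingerprintSummary = rd("ginseng_fingerprint_summary.tsv"))
}
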