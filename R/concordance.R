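#' Construct a demultiplexing call table
#'
#' @param barcode character vector of unique droplet barcodes.
#' @param call character vector of calls: sample identifiers or the
#'   reserved tokens `MULTIPLET`, `UNLABELLED`, `UNASSIGNED`.
#' @param samples the sample vocabulary; inferred from the non-reserved
#'   calls when omitted.
#' @param extra optional data.frame of additional per-droplet columns.
#'
#' @return A [CallTable].
#' @examples
#' callTable(c("AAAC", "AAAG", "AAAT"), c("S1", "MULTIPLET", "S2"))
#' @export
callTable <- function(barcode, call, samples = NULL, extra = NULL) {
    df <- data.frame(barcode = as.character(barcode),
                     call = as.character(call),
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df <- cbind(df, extra)
    if (is.null(samples))
        samples <- sort(setdiff(unique(df$call), RESERVED_TOKENS))
    new("CallTable", calls = df, samples = as.character(samples))
}

#' @describeIn CallTable-class the underlying data.frame of calls.
#' @param x a `CallTable`.
#' @export
calls <- function(x) x@calls

#' @describeIn CallTable-class the declared sample vocabulary.
#' @export
sampleVocabulary <- function(x) x@samples

#' Classify droplets into the five concordance categories
#'
#' Compares two demultiplexing call sets droplet by droplet over their
#' common barcodes. With the reference taken as ground truth (in
#' practice the better-validated call set, e.g. oligo-barcode based)
#' and the test set under audit (e.g. SNP based), each droplet is:
#'
#' * **singlet** — identical sample call in both sets;
#' * **partial_stealth** — a singlet call in the test set but a
#'   `MULTIPLET` call in the reference: a multiplet the test
#'   demultiplexer let through as a singlet;
#' * **multiplet** — `MULTIPLET` in both;
#' * **unassigned** — `UNASSIGNED` in the test set;
#' * **discordant** — everything else (sample mismatches, reference
#'   `UNLABELLED` rows, ...), the catch-all, with a subtype breakdown
#'   retained in the result for diagnostics.
#'
#' Barcodes present in only one table are excluded and counted
#' separately.
#'
#' @param ref,test [CallTable] objects (reference and audited set).
#' @return A [ConcordanceResult].
#' @examples
#' ref  <- callTable(c("b1", "b2"), c("S1", "MULTIPLET"))
#' test <- callTable(c("b1", "b2"), c("S1", "S1"), samples = "S1")
#' classifyConcordance(ref, test)
#' @export
classifyConcordance <- function(ref, test) {
    stopifnot(is(ref, "CallTable"), is(test, "CallTable"))
    if (nrow(ref@calls) == 0L || nrow(test@calls) == 0L)
        stop("both call tables must be non-empty")
    common <- intersect(ref@calls$barcode, test@calls$barcode)
    if (length(common) == 0L)
        stop("the two call tables share no barcodes")
    rc <- ref@calls$call[match(common, ref@calls$barcode)]
    tc <- test@calls$call[match(common, test@calls$barcode)]
    samples <- union(ref@samples, test@samples)
    refIsSample <- rc %in% samples
    testIsSample <- tc %in% samples

    cls <- rep("discordant", length(common))
    cls[testIsSample & refIsSample & tc == rc] <- "singlet"
    cls[testIsSample & rc == "MULTIPLET"] <- "partial_stealth"
    cls[tc == "MULTIPLET" & rc == "MULTIPLET"] <- "multiplet"
    cls[tc == "UNASSIGNED"] <- "unassigned"

    counts <- vapply(CONCORDANCE_CLASSES,
                     function(cl) sum(cls == cl), integer(1))

    perSample <- data.frame(
        sample = samples,
        singlet = vapply(samples, function(sm)
            sum(cls == "singlet" & tc == sm), integer(1)),
        partial_stealth = vapply(samples, function(sm)
            sum(cls == "partial_stealth" & tc == sm), integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)

    disc <- cls == "discordant"
    sub <- character(0)
    if (any(disc)) {
        subtype <- ifelse(refIsSample & testIsSample, "sample_mismatch",
                   ifelse(rc == "UNLABELLED", "ref_unlabelled",
                   ifelse(tc == "UNLABELLED", "test_unlabelled",
                   ifelse(rc == "UNASSIGNED", "ref_unassigned",
                          "other"))))
        sub <- table(subtype[disc])
    }
    new("ConcordanceResult", counts = counts, perSample = perSample,
        discordantBreakdown =
            stats::setNames(as.integer(sub), names(sub)),
        nCommon = length(common),
        nRefOnly = length(setdiff(ref@calls$barcode, common)),
        nTestOnly = length(setdiff(test@calls$barcode, common)))
}

#' @describeIn ConcordanceResult-class named counts of the five
#'   concordance classes.
#' @param res a `ConcordanceResult`.
#' @export
concordanceCounts <- function(res) res@counts

#' Summarise a concordance classification
#'
#' Converts the five class counts into the audit's headline
#' proportions: each class as a fraction of the common barcodes; the
#' partial-stealth burden among monolabelled droplets,
#' `partial_stealth / (singlet + partial_stealth)`; and its complement,
#' the singlet-to-monolabelled ratio. The latter differs from the model
#' [trueSingletRatio()] in that homogeneous stealth multiplets —
#' invisible to both call sets — still count as singlets here.
#'
#' @param res a [ConcordanceResult].
#' @return A list with `fractions` (named numeric over the five
#'   classes), `partialStealthAmongMonolabelled`,
#'   `singletToMonolabelled`, and `nCommon`. The two ratios are `NA`
#'   (with a `flag`) when no droplet is monolabelled in the test set.
#' @examples
#' # printed-count arithmetic: 4285 / (24433 + 4285) is about 15%
#' res <- new("ConcordanceResult",
#'            counts = c(singlet = 24433L, partial_stealth = 4285L,
#'                       multiplet = 3561L, unassigned = 88L,
#'                       discordant = 302L),
#'            perSample = data.frame(), discordantBreakdown = integer(0),
#'            nCommon = 32669L, nRefOnly = 0L, nTestOnly = 0L)
#' summariseConcordance(res)$partialStealthAmongMonolabelled
#' @export
summariseConcordance <- function(res) {
    stopifnot(is(res, "ConcordanceResult"))
    if (res@nCommon == 0L)
        stop("no common barcodes to summarise")
    cnt <- res@counts
    mono <- cnt[["singlet"]] + cnt[["partial_stealth"]]
    out <- list(fractions = cnt / res@nCommon,
                partialStealthAmongMonolabelled =
                    if (mono > 0) cnt[["partial_stealth"]] / mono
                    else NA_real_,
                singletToMonolabelled =
                    if (mono > 0) cnt[["singlet"]] / mono else NA_real_,
                nCommon = res@nCommon)
    if (mono == 0) out$flag <- "no monolabelled droplets; ratios undefined"
    out
}

## One EM fit of a two-component univariate Gaussian mixture from given
## starting responsibilities; returns parameters and log-likelihood.
.emTwoGaussians <- function(x, z1, maxIter = 500L, tol = 1e-8) {
    n <- length(x)
    ll_old <- -Inf
    for (iter in seq_len(maxIter)) {
        w1 <- mean(z1)
        if (w1 <= 0 || w1 >= 1) return(NULL)
        mu1 <- sum(z1 * x) / sum(z1)
        mu2 <- sum((1 - z1) * x) / sum(1 - z1)
        s1 <- sqrt(sum(z1 * (x - mu1)^2) / sum(z1))
        s2 <- sqrt(sum((1 - z1) * (x - mu2)^2) / sum(1 - z1))
        if (!is.finite(s1) || !is.finite(s2) ||
            s1 < 1e-10 * stats::sd(x) || s2 < 1e-10 * stats::sd(x))
            return(NULL)
        d1 <- w1 * stats::dnorm(x, mu1, s1)
        d2 <- (1 - w1) * stats::dnorm(x, mu2, s2)
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        ll <- sum(log(tot))
        z1 <- d1 / tot
        if (is.finite(ll) && abs(ll - ll_old) < tol)
            return(list(w = c(w1, 1 - w1), mu = c(mu1, mu2),
                        sigma = c(s1, s2), loglik = ll,
                        iterations = iter, converged = TRUE))
        ll_old <- ll
    }
    list(w = c(w1, 1 - w1), mu = c(mu1, mu2), sigma = c(s1, s2),
         loglik = ll_old, iterations = maxIter, converged = FALSE)
}

#' Two-Gaussian null threshold for marker scores
#'
#' Separates a high-scoring (marker-positive) population from the bulk
#' by fitting a two-component Gaussian mixture to a per-droplet score
#' distribution (expectation-maximisation, k = 2) and thresholding on
#' the upper tail of the lower-mean (null) component: the threshold is
#' the smallest score whose null-component upper-tail probability —
#' optionally Benjamini-Yekutieli-adjusted across the observed scores —
#' is at most `p`. Scores above the threshold are called positive.
#'
#' EM is initialised by a split at the median plus random restarts
#' (deterministic given `seed`); the best log-likelihood fit wins.
#'
#' @param scores numeric vector of at least 20 scores.
#' @param p tail significance level in (0, 0.5); scores whose
#'   (adjusted) null tail probability is below this are positive.
#' @param adjust `"none"` (raw tail probability; threshold equals the
#'   null quantile `mu0 + z_(1-p) * sigma0`) or `"BY"`
#'   (Benjamini-Yekutieli adjustment of the per-score tail
#'   probabilities, the conservative multiple-testing variant).
#' @param nRestarts random EM restarts beyond the median split.
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed seed for the restarts.
#'
#' @return The threshold (numeric scalar), with the winning mixture fit
#'   attached as attribute `"fit"` (`w`, `mu`, `sigma`, `loglik`,
#'   `iterations`, `converged`).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0, 1), rnorm(200, 10, 1))
#' twoGaussianThreshold(x, p = 1e-4)  # about 3.7
#' @export
twoGaussianThreshold <- function(scores, p = 1e-4,
                                 adjust = c("none", "BY"),
                                 nRestarts = 10L, maxIter = 500L,
                                 tol = 1e-8, seed = 1L) {
    adjust <- match.arg(adjust)
    scores <- scores[is.finite(scores)]
    if (length(scores) < 20L)
        stop("at least 20 finite scores are required")
    if (p <= 0 || p >= 0.5)
        stop("'p' must lie in (0, 0.5)")
    if (stats::sd(scores) == 0)
        stop("degenerate score distribution: all scores are identical")

    fits <- .withSeed(seed, function() {
        starts <- c(list(as.numeric(scores <= stats::median(scores))),
                    lapply(seq_len(nRestarts), function(i)
                        stats::runif(length(scores))))
        lapply(starts, function(z1)
            .emTwoGaussians(scores, z1, maxIter = maxIter, tol = tol))
    })
    fits <- Filter(function(f) !is.null(f) && f$converged, fits)
    if (length(fits) == 0L)
        stop("EM failed to converge for every start; score distribution may be degenerate")
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    null <- which.min(best$mu)
    mu0 <- best$mu[null]
    s0 <- best$sigma[null]

    thr <- if (adjust == "none") {
        mu0 + stats::qnorm(1 - p) * s0
    } else {
        pvals <- stats::pnorm(scores, mu0, s0, lower.tail = FALSE)
        padj <- stats::p.adjust(pvals, method = "BY")
        ok <- padj <= p
        if (!any(ok))
            stop(sprintf("no score reaches BY-adjusted tail probability %g", p))
        min(scores[ok])
    }
    structure(thr, fit = best)
}

#' Call double-positive droplets from per-lineage marker scores
#'
#' A droplet scoring above threshold for more than one cell lineage is
#' transcriptomically a multiplet. Given a per-barcode score table (one
#' column per lineage) and per-lineage thresholds — typically from
#' [twoGaussianThreshold()] — this returns the double-positive
#' barcodes. Intersected with the monolabelled droplets of a
#' demultiplexing [CallTable] (via `against`), the double positives
#' that the labelling called a single sample are reported as partial
#' stealth multiplet candidates.
#'
#' @param scoreTable data.frame with a `barcode` column and one numeric
#'   column per lineage.
#' @param thresholds named numeric, one threshold per lineage column.
#' @param against optional [CallTable] against which to intersect.
#'
#' @return Character vector of double-positive barcodes, or — when
#'   `against` is given — a list with `doublePositive`,
#'   `partialStealthCandidates` (double positives called as a single
#'   sample) and `nSkipped` (rows dropped for missing scores, with a
#'   warning when nonzero).
#' @examples
#' tab <- data.frame(barcode = c("b1", "b2"), ES = c(5, 0.1),
#'                   NIH3T3 = c(4, 0.2))
#' callDoublePositives(tab, c(ES = 1, NIH3T3 = 1))  # "b1"
#' @export
callDoublePositives <- function(scoreTable, thresholds, against = NULL) {
    if (!"barcode" %in% names(scoreTable))
        stop("'scoreTable' must have a 'barcode' column")
    lineages <- names(thresholds)
    missing <- setdiff(lineages, names(scoreTable))
    if (length(missing))
        stop(sprintf("score table lacks lineage column(s): %s",
                     paste(missing, collapse = ", ")))
    sc <- as.matrix(scoreTable[, lineages, drop = FALSE])
    complete <- stats::complete.cases(sc)
    nSkipped <- sum(!complete)
    if (nSkipped > 0)
        warning(sprintf("%d row(s) skipped for missing scores", nSkipped))
    above <- sweep(sc[complete, , drop = FALSE], 2L, thresholds, `>`)
    dp <- scoreTable$barcode[complete][rowSums(above) >= 2L]
    if (is.null(against))
        return(dp)
    cl <- against@calls
    mono <- cl$barcode[cl$call %in% against@samples]
    list(doublePositive = dp,
         partialStealthCandidates = intersect(dp, mono),
         nSkipped = nSkipped)
}

#' @rdname ConcordanceResult-class
#' @param object a `ConcordanceResult`.
#' @export
setMethod("show", "ConcordanceResult", function(object) {
    cat(sprintf("ConcordanceResult over %d common barcodes\n",
                object@nCommon))
    for (cl in CONCORDANCE_CLASSES)
        cat(sprintf("  %-16s %d\n", cl, object@counts[[cl]]))
    if (object@nRefOnly || object@nTestOnly)
        cat(sprintf("  excluded: %d reference-only, %d test-only barcodes\n",
                    object@nRefOnly, object@nTestOnly))
})

#' @rdname CallTable-class
#' @param object a `CallTable`.
#' @export
setMethod("show", "CallTable", function(object) {
    cat(sprintf("CallTable: %d droplets, %d samples (%s)\n",
                nrow(object@calls), length(object@samples),
                paste(utils::head(object@samples, 6), collapse = ", ")))
    tb <- sort(table(object@calls$call), decreasing = TRUE)
    for (nm in utils::head(names(tb), 8))
        cat(sprintf("  %-16s %d\n", nm, tb[[nm]]))
})
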