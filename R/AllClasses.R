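#' @import methods
NULL

RESERVED_TOKENS <- c("MULTIPLET", "UNLABELLED", "UNASSIGNED")

DROPLET_CLASSES <- c("empty", "singlet_labelled", "singlet_unlabelled",
                     "hs", "ps", "mu", "un")

MULTIPLET_CLASSES <- c("hs", "ps", "mu", "un")

PROB_CONVENTIONS <- c("per_droplet", "per_cell_droplet", "per_monolabelled")

#' ExperimentDesign: the full parameter set of a multiplexed droplet run
#'
#' An `ExperimentDesign` holds the parameters of a sample-multiplexed
#' droplet experiment: the pooling fractions `r_i` of the `s` samples,
#' their labelling efficiencies `a_i`, and the Poisson loading rate
#' `lambda` (mean cells per droplet). All model quantities — the four
#' multiplet-class probabilities, the true singlet ratio, simulated
#' droplet pools — are functions of this object.
#'
#' @slot r numeric vector of pooling fractions, one per sample; each in
#'   (0, 1] and summing to 1.
#' @slot a numeric vector of per-sample labelling efficiencies in \[0, 1\]:
#'   the probability that a cell of sample i carries a detectable barcode.
#' @slot lam positive scalar, the Poisson mean number of cells per droplet.
#'
#' @seealso [experimentDesign()], [equalDesign()], [multipletProbabilities()]
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
         representation(r = "numeric", a = "numeric", lam = "numeric"))

setValidity("ExperimentDesign", function(object) {
    msg <- character()
    s <- length(object@r)
    if (s < 1L)
        msg <- c(msg, "at least one sample is required")
    if (length(object@a) != s)
        msg <- c(msg, "'r' and 'a' must have equal length")
    if (any(!is.finite(object@r)) || any(object@r <= 0) || any(object@r > 1))
        msg <- c(msg, "all pooling fractions must lie in (0, 1]")
    if (abs(sum(object@r) - 1) > 1e-9)
        msg <- c(msg, "pooling fractions must sum to 1 (tolerance 1e-9)")
    if (any(!is.finite(object@a)) || any(object@a < 0) || any(object@a > 1))
        msg <- c(msg, "labelling efficiencies must lie in [0, 1]")
    if (length(object@lam) != 1L || !is.finite(object@lam) || object@lam <= 0)
        msg <- c(msg, "'lam' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' MultipletProbabilities: droplet-class probabilities under the model
#'
#' Holds the probabilities of the seven droplet classes — empty droplet,
#' labelled singlet, unlabelled singlet, and the four multiplet classes
#' (homogeneous stealth `hs`, partial stealth `ps`, multilabelled `mu`,
#' unlabelled `un`) — for one [ExperimentDesign]. Probabilities are
#' stored per droplet (empty droplets included), the convention under
#' which the seven entries sum to exactly 1; accessors convert to
#' per-cell-droplet or per-monolabelled-droplet scales on request.
#'
#' @slot probs named numeric of length 7 (per-droplet canonical form).
#' @slot convention character, the default reporting convention.
#' @slot lam,abar numeric scalars retained for convention conversions.
#'
#' @seealso [multipletProbabilities()], [classProbabilities()],
#'   [multipletFractions()]
#' @exportClass MultipletProbabilities
setClass("MultipletProbabilities",
         representation(probs = "numeric", convention = "character",
                        lam = "numeric", abar = "numeric"))

setValidity("MultipletProbabilities", function(object) {
    msg <- character()
    p <- object@probs
    if (!identical(names(p), DROPLET_CLASSES))
        msg <- c(msg, "'probs' must be named by the seven droplet classes")
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-12)
        msg <- c(msg, "per-droplet class probabilities must sum to 1")
    mult <- -expm1(-object@lam) - object@lam * exp(-object@lam)
    if (abs(sum(p[MULTIPLET_CLASSES]) - mult) > 1e-12)
        msg <- c(msg, "multiplet classes must carry the total multiplet mass")
    if (!object@convention %in% PROB_CONVENTIONS)
        msg <- c(msg, sprintf("convention must be one of: %s",
                              paste(PROB_CONVENTIONS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ObservedCounts: per-class droplet tallies from a demultiplexed run
#'
#' Per-class droplet counts as exported by a demultiplexer: droplets
#' called a single sample (monolabelled), droplets with no detected
#' label, and droplets called multiplets. The per-sample breakdown is
#' optional; the total is the number of cell-droplets.
#'
#' @slot monoPerSample named numeric of per-sample monolabelled counts
#'   (length 0 when only the total is known).
#' @slot monoTotal,unlabelled,multilabelled,total numeric scalars; `NA`
#'   where a class was not reported.
#'
#' @seealso [observedCounts()], [readObservedCounts()],
#'   [estimateLabellingEfficiency()], [estimateLambda()]
#' @exportClass ObservedCounts
setClass("ObservedCounts",
         representation(monoPerSample = "numeric", monoTotal = "numeric",
                        unlabelled = "numeric", multilabelled = "numeric",
                        total = "numeric"))

setValidity("ObservedCounts", function(object) {
    msg <- character()
    cnt <- c(object@monoPerSample, object@monoTotal, object@unlabelled,
             object@multilabelled, object@total)
    if (any(cnt < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be nonnegative")
    if (length(object@monoPerSample) &&
        !is.na(object@monoTotal) &&
        abs(sum(object@monoPerSample) - object@monoTotal) > 1e-9)
        msg <- c(msg, "per-sample monolabelled counts must sum to 'monoTotal'")
    if (!is.na(object@total) && !is.na(object@monoTotal) &&
        !is.na(object@unlabelled) && !is.na(object@multilabelled) &&
        abs(object@monoTotal + object@unlabelled + object@multilabelled -
            object@total) > 1e-9)
        msg <- c(msg, "class counts must sum to 'total'")
    if (length(msg)) msg else TRUE
})

#' ParameterEstimate: an inverse-model estimate of abar or lambda
#'
#' Result container for the inverse-estimation routines: the estimated
#' average labelling efficiency and/or Poisson loading rate, the method
#' used, and diagnostics (observed vs fitted fractions, the bracket and
#' residual of any root solve, boundary flags).
#'
#' @slot abar,lam numeric scalars (`NA` for the quantity not estimated).
#' @slot method character tag identifying the estimator.
#' @slot diagnostics named list.
#'
#' @seealso [estimateLabellingEfficiency()], [estimateLambda()]
#' @exportClass ParameterEstimate
setClass("ParameterEstimate",
         representation(abar = "numeric", lam = "numeric",
                        method = "character", diagnostics = "list"))

setValidity("ParameterEstimate", function(object) {
    msg <- character()
    if (!is.na(object@abar) && (object@abar < 0 || object@abar > 1))
        msg <- c(msg, "'abar' must lie in [0, 1]")
    if (!is.na(object@lam) && object@lam <= 0)
        msg <- c(msg, "'lam' must be positive")
    if (length(msg)) msg else TRUE
})

#' DropletPoolTally: a simulated droplet pool and its class tally
#'
#' Output of the Monte-Carlo droplet simulator: per-class droplet counts
#' for one simulated pool, the design and seed that generated it (the
#' same seed regenerates identical tallies), the per-sample breakdown of
#' labelled singlets, and optionally the per-droplet records needed to
#' derive demultiplexing call tables.
#'
#' @slot nDroplets integer, droplets simulated (empty droplets included).
#' @slot tally named integer over the seven droplet classes.
#' @slot singletPerSample named integer, labelled singlets per sample.
#' @slot design the generating [ExperimentDesign].
#' @slot seed integer seed used.
#' @slot droplets data.frame of per-droplet records (0 rows unless
#'   requested): barcode, n_cells, composition, latent_class,
#'   apparent_call.
#'
#' @seealso [simulatePool()], [degradeCalls()]
#' @exportClass DropletPoolTally
setClass("DropletPoolTally",
         representation(nDroplets = "integer", tally = "integer",
                        singletPerSample = "integer",
                        design = "ExperimentDesign", seed = "integer",
                        droplets = "data.frame"))

setValidity("DropletPoolTally", function(object) {
    msg <- character()
    if (!identical(names(object@tally), DROPLET_CLASSES))
        msg <- c(msg, "'tally' must be named by the seven droplet classes")
    if (sum(object@tally) != object@nDroplets)
        msg <- c(msg, "class tallies must sum to the droplet count")
    if (sum(object@singletPerSample) != object@tally[["singlet_labelled"]])
        msg <- c(msg, "per-sample singlets must sum to the singlet tally")
    if (length(msg)) msg else TRUE
})

#' CallTable: per-droplet demultiplexing calls
#'
#' A table of droplet barcodes and their demultiplexing calls, as
#' exported by any HTO/CMO/SNP demultiplexer. Calls are either a sample
#' identifier from the declared vocabulary or one of the reserved tokens
#' `MULTIPLET`, `UNLABELLED`, `UNASSIGNED`. Extra columns (e.g. the
#' latent class of a simulated droplet) are carried along untouched.
#'
#' @slot calls data.frame with at least columns `barcode` and `call`;
#'   barcodes unique.
#' @slot samples character vector, the sample vocabulary.
#'
#' @seealso [callTable()], [readCallTable()], [classifyConcordance()]
#' @exportClass CallTable
setClass("CallTable",
         representation(calls = "data.frame", samples = "character"))

setValidity("CallTable", function(object) {
    msg <- character()
    if (!all(c("barcode", "call") %in% names(object@calls)))
        msg <- c(msg, "'calls' must have columns 'barcode' and 'call'")
    else {
        if (anyDuplicated(object@calls$barcode))
            msg <- c(msg, "barcodes must be unique within a call table")
        bad <- setdiff(unique(object@calls$call),
                       c(object@samples, RESERVED_TOKENS))
        if (length(bad)) {
            row <- which(object@calls$call == bad[1L])[1L]
            msg <- c(msg, sprintf(
                "unknown call token '%s' (first at row %d); declare it in the sample vocabulary or map it to a reserved token",
                bad[1L], row))
        }
    }
    if (length(msg)) msg else TRUE
})

#' ConcordanceResult: five-way classification of two paired call sets
#'
#' Result of comparing a reference and a test demultiplexing call table
#' droplet by droplet: counts of Singlet, Partial stealth multiplet,
#' Multiplet, Unassigned and Discordant/Others over the barcodes common
#' to both tables, plus a per-sample singlet/partial-stealth breakdown
#' and a breakdown of the discordant catch-all.
#'
#' @slot counts named integer over the five concordance classes.
#' @slot perSample data.frame: sample, singlet and partial-stealth
#'   counts per sample.
#' @slot discordantBreakdown named integer over discordant subtypes.
#' @slot nCommon integer, barcodes present in both tables.
#' @slot nRefOnly,nTestOnly integer, barcodes found in only one table
#'   (excluded from classification).
#'
#' @seealso [classifyConcordance()], [summariseConcordance()]
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
         representation(counts = "integer", perSample = "data.frame",
                        discordantBreakdown = "integer", nCommon = "integer",
                        nRefOnly = "integer", nTestOnly = "integer"))

CONCORDANCE_CLASSES <- c("singlet", "partial_stealth", "multiplet",
                         "unassigned", "discordant")

setValidity("ConcordanceResult", function(object) {
    msg <- character()
    if (!identical(names(object@counts), CONCORDANCE_CLASSES))
        msg <- c(msg, "'counts' must be named by the five concordance classes")
    if (sum(object@counts) != object@nCommon)
        msg <- c(msg, "the five class counts must sum to 'nCommon'")
    if (length(msg)) msg else TRUE
})
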