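## Run `fun()` under a fixed, named RNG (Mersenne-Twister / Inversion),
## restoring the caller's RNG state afterwards so simulations are
## reproducible without clobbering the session stream.
.withSeed <- function(seed, fun) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    fun()
}

#' Classify a droplet from its cell composition
#'
#' Applies the droplet classification rule to one composition: counts of
#' labelled cells per sample plus a count of unlabelled cells (whose
#' sample of origin is irrelevant to — and unrecoverable from — the
#' observed label status). With `k` total cells, `L` distinct labelled
#' samples and `U` unlabelled cells:
#'
#' * `k = 0` — empty droplet;
#' * `k = 1` — labelled or unlabelled singlet;
#' * `k >= 2`, `L >= 2` — multilabelled multiplet (`mu`);
#' * `k >= 2`, `L = 1`, `U = 0` — homogeneous stealth multiplet (`hs`);
#' * `k >= 2`, `L = 1`, `U >= 1` — partial stealth multiplet (`ps`);
#' * `k >= 2`, `L = 0` — unlabelled multiplet (`un`).
#'
#' Note the boundary the closed forms dictate: labelled cells of one
#' sample plus an unlabelled cell **of that same sample** is still a
#' partial stealth multiplet — label status, not sample of origin,
#' drives the classification.
#'
#' @param labelled integer vector, labelled-cell count per sample.
#' @param unlabelled integer scalar, unlabelled-cell count.
#' @return One of `"empty"`, `"singlet_labelled"`,
#'   `"singlet_unlabelled"`, `"hs"`, `"ps"`, `"mu"`, `"un"`.
#' @examples
#' classifyDroplet(c(2, 0), 0)  # homogeneous stealth
#' classifyDroplet(c(1, 0), 1)  # partial stealth
#' classifyDroplet(c(1, 1), 0)  # multilabelled
#' @export
classifyDroplet <- function(labelled, unlabelled) {
    if (any(labelled < 0) || unlabelled < 0)
        stop("cell counts must be nonnegative")
    k <- sum(labelled) + unlabelled
    L <- sum(labelled > 0)
    if (k == 0) return("empty")
    if (k == 1) return(if (unlabelled == 1) "singlet_unlabelled"
                       else "singlet_labelled")
    if (L >= 2) return("mu")
    if (L == 1) return(if (unlabelled >= 1) "ps" else "hs")
    "un"
}

## Vectorised classification of a pool: `lab` is an nDroplets x s matrix
## of labelled-cell counts, `unlab` the unlabelled counts.
.classifyPool <- function(lab, unlab) {
    k <- rowSums(lab) + unlab
    L <- rowSums(lab > 0)
    cls <- character(length(unlab))
    cls[k == 0] <- "empty"
    cls[k == 1 & unlab == 1] <- "singlet_unlabelled"
    cls[k == 1 & unlab == 0] <- "singlet_labelled"
    multi <- k >= 2
    cls[multi & L >= 2] <- "mu"
    cls[multi & L == 1 & unlab == 0] <- "hs"
    cls[multi & L == 1 & unlab >= 1] <- "ps"
    cls[multi & L == 0] <- "un"
    cls
}

.sampleNames <- function(design) {
    nm <- names(design@r)
    if (is.null(nm)) nm <- paste0("S", seq_along(design@r))
    nm
}

#' Simulate a droplet pool under the loading/labelling model
#'
#' Seeded Monte-Carlo generator of a droplet pool: each droplet captures
#' `k ~ Poisson(lam)` cells, each cell belongs to sample `i` with
#' probability `r_i` and carries a detectable label with probability
#' `a_i`. The implementation draws the equivalent independent Poisson
#' thinning — labelled cells of sample `i` as `Poisson(r_i a_i lam)` and
#' unlabelled cells (pooled across samples) as
#' `Poisson((1 - abar) lam)` per droplet — which is distributionally
#' identical to the per-cell draw. Droplets are classified with the
#' [classifyDroplet()] rule and tallied.
#'
#' This simulator is the package's independent oracle for the closed
#' forms of [multipletProbabilities()] and the fixture factory for the
#' concordance auditor.
#'
#' @param design an [ExperimentDesign].
#' @param nDroplets number of droplets to simulate (>= 1).
#' @param seed integer seed; the same seed reproduces identical tallies.
#' @param keepDroplets logical; keep per-droplet records (needed by
#'   [degradeCalls()]; off by default to bound memory at large pools).
#'
#' @return A [DropletPoolTally].
#' @examples
#' pool <- simulatePool(equalDesign(4, 0.9, 0.5), 1e4, seed = 1)
#' poolTally(pool)
#' @export
simulatePool <- function(design, nDroplets, seed, keepDroplets = FALSE) {
    stopifnot(is(design, "ExperimentDesign"))
    nDroplets <- as.integer(nDroplets)
    if (is.na(nDroplets) || nDroplets < 1L)
        stop("'nDroplets' must be >= 1")
    s <- nSamples(design)
    lam <- design@lam
    abar <- overallLabellingEfficiency(design)
    .withSeed(seed, function() {
        lab <- matrix(stats::rpois(nDroplets * s,
                                   rep(design@r * design@a * lam,
                                       each = nDroplets)),
                      nrow = nDroplets, ncol = s)
        unlab <- stats::rpois(nDroplets, (1 - abar) * lam)
        cls <- .classifyPool(lab, unlab)
        tally <- vapply(DROPLET_CLASSES,
                        function(cl) sum(cls == cl), integer(1))
        sn <- .sampleNames(design)
        singletIdx <- cls == "singlet_labelled"
        perSample <- if (any(singletIdx)) {
            who <- max.col(lab[singletIdx, , drop = FALSE],
                           ties.method = "first")
            vapply(seq_len(s), function(i) sum(who == i), integer(1))
        } else integer(s)
        names(perSample) <- sn
        droplets <- if (keepDroplets) {
            who <- max.col(lab, ties.method = "first")
            apparent <- rep(NA_character_, nDroplets)
            apparent[cls %in% c("singlet_labelled", "hs", "ps")] <-
                sn[who[cls %in% c("singlet_labelled", "hs", "ps")]]
            apparent[cls == "mu"] <- "MULTIPLET"
            apparent[cls %in% c("singlet_unlabelled", "un")] <- "UNLABELLED"
            data.frame(
                barcode = sprintf("BC%08d", seq_len(nDroplets)),
                n_cells = rowSums(lab) + unlab,
                composition = paste0(apply(lab, 1L, paste, collapse = ","),
                                     "+", unlab),
                latent_class = cls,
                apparent_call = apparent,
                stringsAsFactors = FALSE)
        } else {
            data.frame()
        }
        new("DropletPoolTally", nDroplets = nDroplets, tally = tally,
            singletPerSample = perSample, design = design,
            seed = as.integer(seed), droplets = droplets)
    })
}

#' @describeIn DropletPoolTally-class named per-class droplet counts.
#' @param pool a `DropletPoolTally`.
#' @export
poolTally <- function(pool) pool@tally

#' @describeIn DropletPoolTally-class per-droplet records (0 rows unless
#'   the pool was simulated with `keepDroplets = TRUE`).
#' @export
poolDroplets <- function(pool) pool@droplets

#' @describeIn DropletPoolTally-class observed per-class frequencies
#'   (per droplet, summing to 1).
#' @export
poolFrequencies <- function(pool) pool@tally / pool@nDroplets

#' Derive truth and degraded demultiplexing call tables from a pool
#'
#' Turns the per-droplet records of a simulated pool into a pair of
#' demultiplexing call tables over the cell-droplets (empty droplets
#' carry no barcode and are dropped): a *truth* table holding each
#' droplet's apparent call under a perfect demultiplexer — stealth
#' multiplets (`hs`, `ps`) present as their monolabelled sample call,
#' multilabelled multiplets as `MULTIPLET`, label-free droplets as
#' `UNLABELLED` — with the latent generative class retained in a side
#' column, and a *degraded* table in which each call is independently
#' replaced by `UNASSIGNED` with probability `pUnassign` or by a
#' uniformly chosen different sample with probability `pMisassign`,
#' emulating an imperfect demultiplexer.
#'
#' @param pool a [DropletPoolTally] simulated with
#'   `keepDroplets = TRUE`.
#' @param pUnassign,pMisassign degradation probabilities in \[0, 1\]
#'   with `pUnassign + pMisassign <= 1`.
#' @param seed integer seed for the degradation draws.
#'
#' @return A list with [CallTable] elements `truth` and `degraded`.
#' @examples
#' pool <- simulatePool(equalDesign(3, 0.9, 0.4), 1e3, seed = 7,
#'                      keepDroplets = TRUE)
#' tabs <- degradeCalls(pool, pUnassign = 0.05, pMisassign = 0.02,
#'                      seed = 8)
#' @export
degradeCalls <- function(pool, pUnassign = 0, pMisassign = 0, seed) {
    stopifnot(is(pool, "DropletPoolTally"))
    if (nrow(pool@droplets) == 0L)
        stop("'pool' has no per-droplet records; simulate with keepDroplets = TRUE")
    if (pUnassign < 0 || pMisassign < 0 || pUnassign + pMisassign > 1)
        stop("'pUnassign' and 'pMisassign' must be in [0, 1] and sum to at most 1")
    rec <- pool@droplets[pool@droplets$latent_class != "empty", ,
                         drop = FALSE]
    sn <- .sampleNames(pool@design)
    truth <- callTable(barcode = rec$barcode, call = rec$apparent_call,
                       samples = sn,
                       extra = data.frame(latent_class = rec$latent_class,
                                          stringsAsFactors = FALSE))
    degradedCall <- .withSeed(seed, function() {
        n <- nrow(rec)
        u <- stats::runif(n)
        out <- rec$apparent_call
        out[u < pUnassign] <- "UNASSIGNED"
        mis <- which(u >= pUnassign & u < pUnassign + pMisassign)
        if (length(mis)) {
            if (length(sn) == 1L) {
                out[mis] <- sn
            } else {
                out[mis] <- vapply(rec$apparent_call[mis], function(cur) {
                    pickFrom <- setdiff(sn, cur)
                    pickFrom[sample.int(length(pickFrom), 1L)]
                }, character(1))
            }
        }
        out
    })
    degraded <- callTable(barcode = rec$barcode, call = degradedCall,
                          samples = sn)
    list(truth = truth, degraded = degraded)
}

#' @rdname DropletPoolTally-class
#' @param object a `DropletPoolTally`.
#' @export
setMethod("show", "DropletPoolTally", function(object) {
    cat(sprintf("DropletPoolTally: %d droplets (seed %d)\n",
                object@nDroplets, object@seed))
    for (cl in DROPLET_CLASSES)
        cat(sprintf("  %-18s %d\n", cl, object@tally[[cl]]))
    if (nrow(object@droplets))
        cat(sprintf("  per-droplet records kept: %d rows\n",
                    nrow(object@droplets)))
})
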