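#' Construct an experiment design
#'
#' Builds an [ExperimentDesign] from pooling fractions, labelling
#' efficiencies and the Poisson loading rate. A scalar `a` is recycled
#' across samples.
#'
#' @param r numeric vector of pooling fractions (one per sample, summing
#'   to 1). The number of samples `s` is `length(r)`.
#' @param a numeric vector of labelling efficiencies in \[0, 1\], length 1
#'   or `length(r)`.
#' @param lam positive scalar: mean cells per droplet (Poisson
#'   expectation); in practice set by the cell loading rate of the chip.
#'
#' @return An [ExperimentDesign].
#' @examples
#' experimentDesign(r = c(0.5, 0.3, 0.2), a = c(0.9, 0.8, 0.7), lam = 0.5)
#' @export
experimentDesign <- function(r, a, lam) {
    if (length(a) == 1L) a <- rep(a, length(r))
    new("ExperimentDesign", r = as.numeric(r), a = as.numeric(a),
        lam = as.numeric(lam))
}

#' Construct the equal design (equal pooling, equal labelling)
#'
#' The simplifying design in which all `s` samples are pooled in equal
#' proportion with a common labelling efficiency, i.e. `r_i a_i = abar/s`
#' for every sample. Under this design the general class-probability
#' formulas reduce to closed forms in `(s, abar, lam)` alone, which is
#' the parameterisation used for design curves and for inference from
#' aggregate count tables.
#'
#' @param s integer number of samples, `s >= 1`.
#' @param abar common labelling efficiency in \[0, 1\] (equal to the
#'   pool-average efficiency for this design).
#' @param lam positive scalar, mean cells per droplet.
#'
#' @return An [ExperimentDesign] with `r_i = 1/s`, `a_i = abar`.
#' @examples
#' equalDesign(s = 8, abar = 0.995, lam = 0.369)
#' @export
equalDesign <- function(s, abar, lam) {
    s <- as.integer(s)
    if (is.na(s) || s < 1L)
        stop("'s' must be an integer >= 1")
    experimentDesign(r = rep(1 / s, s), a = abar, lam = lam)
}

#' @describeIn experimentDesign number of samples in the design.
#' @param design an [ExperimentDesign].
#' @export
nSamples <- function(design) length(design@r)

#' @describeIn experimentDesign pooling fractions `r_i`.
#' @export
poolingFractions <- function(design) design@r

#' @describeIn experimentDesign labelling efficiencies `a_i`.
#' @export
labellingEfficiencies <- function(design) design@a

#' @describeIn experimentDesign Poisson loading rate `lambda`.
#' @export
loadingRate <- function(design) design@lam

#' Overall (pool-averaged) labelling efficiency
#'
#' The probability that a random cell of the pooled suspension carries a
#' detectable sample barcode: the pooling-fraction-weighted average of
#' the per-sample labelling efficiencies, `abar = sum(r_i * a_i)`.
#'
#' @param design an [ExperimentDesign].
#' @return A probability in \[0, 1\].
#' @examples
#' d <- experimentDesign(c(0.5, 0.3, 0.2), c(0.9, 0.8, 0.7), lam = 0.5)
#' overallLabellingEfficiency(d)  # 0.83
#' @export
overallLabellingEfficiency <- function(design) {
    stopifnot(is(design, "ExperimentDesign"))
    sum(design@r * design@a)
}

#' Poisson droplet occupancy probability
#'
#' Probability that a droplet captures exactly `k` cells under Poisson
#' loading with mean `lam` cells per droplet.
#'
#' @param lam positive scalar, mean cells per droplet.
#' @param k nonnegative integer vector of cell counts.
#' @return `P(k) = exp(-lam) * lam^k / k!`, vectorised over `k`.
#' @examples
#' dropletOccupancyPmf(0.369, 1)  # about 0.2551
#' @export
dropletOccupancyPmf <- function(lam, k) {
    if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
        stop("'lam' must be a single positive number")
    if (any(k < 0) || any(k != floor(k)))
        stop("'k' must contain nonnegative integers")
    stats::dpois(k, lam)
}

## Shared core of the closed forms. Sum_i exp(r_i a_i lam) - s is
## evaluated as sum(expm1(r_i a_i lam)) to avoid cancellation at small
## lam; likewise exp(-abar*lam) - exp(-lam) = exp(-lam)*expm1((1-abar)*lam).
.classProbsPerDroplet <- function(design) {
    lam <- design@lam
    abar <- sum(design@r * design@a)
    S <- sum(expm1(design@r * design@a * lam))  # sum exp(r_i a_i lam) - s
    e <- exp(-lam)
    p_hs <- e * (S - abar * lam)
    p_ps <- e * expm1((1 - abar) * lam) * S
    p_mu <- 1 - exp(-abar * lam) * (S + 1)
    p_un <- e * (expm1((1 - abar) * lam) - (1 - abar) * lam)
    p <- c(empty = e,
           singlet_labelled = lam * e * abar,
           singlet_unlabelled = lam * e * (1 - abar),
           hs = p_hs, ps = p_ps, mu = p_mu, un = p_un)
    ## clamp parts-per-1e16 negative zeros from cancellation
    p[p < 0 & p > -1e-12] <- 0
    p
}

#' Closed-form droplet-class probabilities
#'
#' Evaluates, for one [ExperimentDesign], the probability of every
#' droplet class under the Poisson loading model: empty droplet,
#' labelled singlet, unlabelled singlet, and the four multiplet classes
#' — homogeneous stealth (all cells labelled, one sample), partial
#' stealth (labelled cells of one sample plus unlabelled cell(s)),
#' multilabelled (cells of two or more samples labelled) and unlabelled
#' (no cell labelled). The four multiplet probabilities are
#'
#' \deqn{p_{HS} = e^{-\lambda}\left(\sum_i e^{r_i a_i \lambda} -
#'   \bar a \lambda - s\right)}
#' \deqn{p_{PS} = (e^{-\bar a\lambda} - e^{-\lambda})
#'   \left(\sum_i e^{r_i a_i \lambda} - s\right)}
#' \deqn{p_{Mu} = 1 - e^{-\bar a\lambda}
#'   \left(\sum_i e^{r_i a_i \lambda} - s + 1\right)}
#' \deqn{p_{Un} = e^{-\lambda}(e^{(1-\bar a)\lambda} -
#'   (1-\bar a)\lambda - 1)}
#'
#' Probabilities are stored per droplet (the seven classes sum to 1 and
#' the four multiplet classes to `1 - exp(-lam) - lam*exp(-lam)`);
#' `convention` selects the default reporting scale of the accessors.
#'
#' @param design an [ExperimentDesign].
#' @param convention `"per_droplet"` (probabilities over all droplets,
#'   the canonical form), `"per_cell_droplet"` (conditional on at least
#'   one cell: divide by `1 - exp(-lam)`), or `"per_monolabelled"`
#'   (conditional on presenting as monolabelled: divide by
#'   `p_singlet_labelled + p_hs + p_ps`).
#'
#' @return A [MultipletProbabilities].
#' @examples
#' mp <- multipletProbabilities(equalDesign(8, 0.995, 0.369))
#' classProbabilities(mp, "per_cell_droplet")["ps"]  # < 0.002
#' @export
multipletProbabilities <- function(design, convention = "per_droplet") {
    stopifnot(is(design, "ExperimentDesign"))
    convention <- match.arg(convention, PROB_CONVENTIONS)
    new("MultipletProbabilities",
        probs = .classProbsPerDroplet(design),
        convention = convention,
        lam = design@lam,
        abar = sum(design@r * design@a))
}

.conventionDenominator <- function(x, convention) {
    switch(convention,
           per_droplet = 1,
           per_cell_droplet = -expm1(-x@lam),
           per_monolabelled = sum(x@probs[c("singlet_labelled", "hs", "ps")]))
}

#' Droplet-class probabilities under a reporting convention
#'
#' @param x a [MultipletProbabilities].
#' @param convention reporting scale; defaults to the one the object was
#'   created with. See [multipletProbabilities()].
#' @return Named numeric over the seven droplet classes, rescaled by the
#'   convention's denominator. Under `"per_monolabelled"` only the
#'   monolabelled-presenting classes (`singlet_labelled`, `hs`, `ps`)
#'   are fractions of the same observable stratum.
#' @export
classProbabilities <- function(x, convention = x@convention) {
    stopifnot(is(x, "MultipletProbabilities"))
    convention <- match.arg(convention, PROB_CONVENTIONS)
    x@probs / .conventionDenominator(x, convention)
}

#' Multiplet-class probabilities or fractions
#'
#' The four multiplet-class values of a [MultipletProbabilities] under a
#' reporting convention; `"among_multiplets"` additionally normalises
#' the four classes to sum to 1 (the scale used for the design curves of
#' class composition).
#'
#' @param x a [MultipletProbabilities].
#' @param convention one of `"per_droplet"`, `"per_cell_droplet"`,
#'   `"per_monolabelled"`, `"among_multiplets"`.
#' @return Named numeric over `hs`, `ps`, `mu`, `un`.
#' @export
multipletFractions <- function(x, convention = x@convention) {
    stopifnot(is(x, "MultipletProbabilities"))
    convention <- match.arg(convention, c(PROB_CONVENTIONS, "among_multiplets"))
    m <- x@probs[MULTIPLET_CLASSES]
    if (convention == "among_multiplets")
        m / sum(m)
    else
        m / .conventionDenominator(x, convention)
}

#' True singlet ratio
#'
#' The fraction of monolabelled droplets that are genuine singlets. A
#' monolabelled droplet — exactly one sample's barcode detected — is
#' either a true labelled singlet, a homogeneous stealth multiplet, or a
#' partial stealth multiplet, so
#'
#' \deqn{TSR = \frac{P(1)\,\bar a}{P(1)\,\bar a + p_{HS} + p_{PS}}
#'   = \frac{\bar a \lambda e^{-\lambda(1-\bar a)}}
#'          {\sum_i e^{r_i a_i \lambda} - s}}
#'
#' @param design an [ExperimentDesign] with `abar > 0` (with nothing
#'   labelled there are no monolabelled droplets and the ratio is
#'   undefined).
#' @return A probability in (0, 1\].
#' @examples
#' trueSingletRatio(equalDesign(1, 1, 0.5))  # 0.5 / (exp(0.5) - 1)
#' @export
trueSingletRatio <- function(design) {
    stopifnot(is(design, "ExperimentDesign"))
    abar <- sum(design@r * design@a)
    if (abar <= 0)
        stop("the true singlet ratio is undefined when no sample is labelled (abar = 0)")
    lam <- design@lam
    S <- sum(expm1(design@r * design@a * lam))
    abar * lam * exp(-lam * (1 - abar)) / S
}

#' Parameter-sweep table of multiplet composition and TSR
#'
#' Evaluates the model along a grid of one design parameter, holding the
#' others fixed at an equal design, and returns one row per grid point
#' with the four multiplet-class fractions among multiplets (the scale
#' of class-composition design curves) and the true singlet ratio.
#'
#' @param axis which parameter to sweep: `"labelling_efficiency"`,
#'   `"sample_count"`, or `"lam"`.
#' @param grid numeric (or integer, for `sample_count`) vector of grid
#'   values within the parameter's domain.
#' @param s,abar,lam the fixed values of the parameters not swept.
#'
#' @return A data.frame with columns `axis`, `value`, `frac_hs`,
#'   `frac_ps`, `frac_mu`, `frac_un` (fractions among multiplets,
#'   summing to 1 per row), `p_multiplet` (total multiplet probability
#'   per droplet) and `tsr`.
#' @examples
#' sweepClassProportions("labelling_efficiency",
#'                       grid = seq(0.1, 1, by = 0.1), s = 5, lam = 0.3)
#' @export
sweepClassProportions <- function(axis = c("labelling_efficiency",
                                           "sample_count", "lam"),
                                  grid, s = 5L, abar = 0.9, lam = 0.3) {
    axis <- match.arg(axis)
    if (length(grid) == 0L)
        stop("'grid' must not be empty")
    rows <- lapply(grid, function(v) {
        d <- switch(axis,
                    labelling_efficiency = equalDesign(s, v, lam),
                    sample_count = equalDesign(v, abar, lam),
                    lam = equalDesign(s, abar, v))
        mp <- multipletProbabilities(d)
        fr <- multipletFractions(mp, "among_multiplets")
        ab <- overallLabellingEfficiency(d)
        data.frame(axis = axis, value = v,
                   frac_hs = fr[["hs"]], frac_ps = fr[["ps"]],
                   frac_mu = fr[["mu"]], frac_un = fr[["un"]],
                   p_multiplet = sum(mp@probs[MULTIPLET_CLASSES]),
                   tsr = if (ab > 0) trueSingletRatio(d) else NA_real_)
    })
    do.call(rbind, rows)
}

#' @rdname ExperimentDesign-class
#' @param object an `ExperimentDesign`.
#' @export
setMethod("show", "ExperimentDesign", function(object) {
    s <- nSamples(object)
    cat(sprintf("ExperimentDesign: %d sample%s, lambda = %g\n",
                s, if (s == 1L) "" else "s", object@lam))
    cat(sprintf("  pooling fractions:      %s\n",
                paste(signif(object@r, 4), collapse = ", ")))
    cat(sprintf("  labelling efficiencies: %s\n",
                paste(signif(object@a, 4), collapse = ", ")))
    cat(sprintf("  overall labelling efficiency (abar): %.4g\n",
                overallLabellingEfficiency(object)))
})

#' @rdname MultipletProbabilities-class
#' @param object a `MultipletProbabilities`.
#' @export
setMethod("show", "MultipletProbabilities", function(object) {
    cat(sprintf("MultipletProbabilities (lambda = %g, abar = %.4g)\n",
                object@lam, object@abar))
    cat(sprintf("  convention: %s\n", object@convention))
    p <- classProbabilities(object)
    for (cl in DROPLET_CLASSES)
        cat(sprintf("  %-18s %.6g\n", cl, p[[cl]]))
})
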