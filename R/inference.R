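#' Construct an observed-counts object
#'
#' @param mono per-sample monolabelled droplet counts (a named or
#'   unnamed vector), or a single total monolabelled count.
#' @param unlabelled count of droplets with no detected label (`NA` if
#'   not reported).
#' @param multilabelled count of droplets called multiplets (`NA` if not
#'   reported).
#' @param total total cell-droplets; computed from the other classes
#'   when all are present.
#'
#' @return An [ObservedCounts].
#' @examples
#' observedCounts(mono = c(A = 1918, B = 2001), unlabelled = 10,
#'                multilabelled = 250)
#' @export
observedCounts <- function(mono = NA_real_, unlabelled = NA_real_,
                           multilabelled = NA_real_, total = NA_real_) {
    perSample <- numeric(0)
    if (length(mono) > 1L || !is.null(names(mono))) {
        perSample <- as.numeric(mono)
        names(perSample) <- names(mono)
        monoTotal <- sum(perSample)
    } else {
        monoTotal <- as.numeric(mono)
    }
    if (is.na(total) && !is.na(monoTotal) && !is.na(unlabelled) &&
        !is.na(multilabelled))
        total <- monoTotal + unlabelled + multilabelled
    if (is.na(total) && !is.na(monoTotal) && is.na(unlabelled) &&
        !is.na(multilabelled))
        total <- monoTotal + multilabelled
    new("ObservedCounts", monoPerSample = perSample, monoTotal = monoTotal,
        unlabelled = as.numeric(unlabelled),
        multilabelled = as.numeric(multilabelled), total = as.numeric(total))
}

#' @describeIn ParameterEstimate-class estimated average labelling
#'   efficiency.
#' @param x a `ParameterEstimate`.
#' @export
abarHat <- function(x) x@abar

#' @describeIn ParameterEstimate-class estimated loading rate.
#' @export
lamHat <- function(x) x@lam

#' @describeIn ParameterEstimate-class diagnostics list of the
#'   estimator (observed vs fitted fractions, bracket, residual, flags).
#' @export
estimateDiagnostics <- function(x) x@diagnostics

#' Estimate the average labelling efficiency from observed counts
#'
#' Inverts the model for the pool-average labelling efficiency `abar`
#' from the observed monolabelled and unlabelled droplet counts.
#'
#' The default `"ratio"` estimator is the fraction of label-positive
#' cell-droplets among droplets presenting a label status,
#' `abar = n_mono / (n_mono + n_unlabelled)`. Its bias is of order
#' `lam * (1 - abar)` because stealth multiplets inflate the
#' monolabelled class slightly; the `"model_consistent"` estimator
#' removes it by solving, at a known `lam`,
#' \deqn{\frac{P(1)\bar a + p_{HS} + p_{PS}}{P(1)(1-\bar a) + p_{Un}}
#'   = \frac{n_{mono}}{n_{unlab}}}
#' for `abar` by bracketed root-finding on \[0, 1\] (equal design).
#'
#' @param counts an [ObservedCounts] with monolabelled and unlabelled
#'   counts.
#' @param method `"ratio"` (default) or `"model_consistent"`.
#' @param lam loading rate, required for `"model_consistent"`.
#' @param s sample count for the `"model_consistent"` equal design.
#'
#' @return A [ParameterEstimate] with `abarHat()` set. When no
#'   unlabelled droplets were observed the estimate is the boundary
#'   value 1 and `estimateDiagnostics(x)$boundary` is `TRUE`.
#' @examples
#' cnt <- observedCounts(mono = 14266, unlabelled = 72)
#' abarHat(estimateLabellingEfficiency(cnt))  # 0.995 after rounding
#' @export
estimateLabellingEfficiency <- function(counts,
                                        method = c("ratio",
                                                   "model_consistent"),
                                        lam = NULL, s = 2L) {
    stopifnot(is(counts, "ObservedCounts"))
    method <- match.arg(method)
    n_mono <- counts@monoTotal
    n_un <- counts@unlabelled
    if (is.na(n_mono) || is.na(n_un))
        stop("monolabelled and unlabelled counts are both required")
    if (n_mono + n_un <= 0)
        stop("monolabelled and unlabelled counts are both zero; abar is unidentifiable")
    if (n_un == 0) {
        return(new("ParameterEstimate", abar = 1, lam = NA_real_,
                   method = method,
                   diagnostics = list(boundary = TRUE,
                                      observed_ratio = Inf)))
    }
    if (method == "ratio") {
        ab <- n_mono / (n_mono + n_un)
        return(new("ParameterEstimate", abar = ab, lam = NA_real_,
                   method = "ratio",
                   diagnostics = list(boundary = FALSE,
                                      n_mono = n_mono, n_unlabelled = n_un)))
    }
    if (is.null(lam))
        stop("'lam' is required for the model-consistent estimator")
    target <- n_mono / n_un
    f <- function(ab) {
        p <- .classProbsPerDroplet(equalDesign(s, ab, lam))
        mono <- p[["singlet_labelled"]] + p[["hs"]] + p[["ps"]]
        unl <- p[["singlet_unlabelled"]] + p[["un"]]
        mono / unl - target
    }
    ## mono/unl is 0 at abar=0 and +Inf at abar=1: root is bracketed
    root <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)
    new("ParameterEstimate", abar = root$root, lam = NA_real_,
        method = "model_consistent",
        diagnostics = list(boundary = FALSE, lam = lam, s = s,
                           observed_ratio = target,
                           residual = f(root$root)))
}

#' Estimate the loading rate from the multilabelled droplet count
#'
#' Inverts the model for the Poisson loading rate `lambda` from the
#' observed fraction of multilabelled (detected-multiplet) droplets
#' among cell-droplets, at a known labelling efficiency and sample
#' count: solves
#' \deqn{\frac{p_{Mu}(\lambda)}{1 - e^{-\lambda}} =
#'   \frac{n_{multi}}{n_{total}}}
#' by bracketed root-finding on `lambda` in \[1e-9, 10\]. The left-hand
#' side is strictly increasing in `lambda`, so the root is unique.
#'
#' @param counts an [ObservedCounts] with `multilabelled` and `total`.
#' @param abar average labelling efficiency (> 0).
#' @param s sample count (>= 2; with one sample no droplet can be
#'   multilabelled and `lambda` is unidentifiable from this count).
#' @param r optional pooling fractions; the equal design is assumed when
#'   omitted.
#' @param a optional per-sample labelling efficiencies paired with `r`.
#'
#' @return A [ParameterEstimate] with `lamHat()` set; plugging the
#'   estimate back into the model reproduces the observed multilabelled
#'   fraction to the solver tolerance (recorded in the diagnostics).
#' @examples
#' cnt <- observedCounts(mono = 14266, unlabelled = 72,
#'                       multilabelled = 2578)
#' round(lamHat(estimateLambda(cnt, abar = 0.995, s = 8)), 3)  # 0.369
#' @export
estimateLambda <- function(counts, abar, s, r = NULL, a = NULL) {
    stopifnot(is(counts, "ObservedCounts"))
    n_mu <- counts@multilabelled
    n_tot <- counts@total
    if (is.na(n_mu) || n_mu < 1)
        stop("lambda is unidentifiable without observed multilabelled droplets")
    if (is.na(n_tot) || n_tot <= n_mu)
        stop("'total' must exceed the multilabelled count")
    if (abar <= 0)
        stop("'abar' must be positive")
    s <- as.integer(s)
    if (s < 2L)
        stop("with a single sample no droplet can be multilabelled; lambda is unidentifiable")
    target <- n_mu / n_tot
    designAt <- function(lam) {
        if (is.null(r)) equalDesign(s, abar, lam)
        else experimentDesign(r, if (is.null(a)) abar else a, lam)
    }
    muFrac <- function(lam)
        .classProbsPerDroplet(designAt(lam))[["mu"]] / -expm1(-lam)
    bracket <- c(1e-9, 10)
    if (muFrac(bracket[2L]) <= target)
        stop(sprintf(
            "observed multilabelled fraction %.4g is not attainable for lambda <= %g at abar = %g, s = %d",
            target, bracket[2L], abar, s))
    root <- stats::uniroot(function(l) muFrac(l) - target, bracket,
                           tol = 1e-12)
    new("ParameterEstimate", abar = abar, lam = root$root,
        method = "multilabelled_fraction",
        diagnostics = list(observed_fraction = target,
                           fitted_fraction = muFrac(root$root),
                           residual = muFrac(root$root) - target,
                           bracket = bracket, s = s))
}

#' Theoretical multiplet-class proportions for given parameters
#'
#' Convenience wrapper evaluating the closed forms on the equal design
#' for one or more labelling efficiencies at a fixed loading rate — the
#' computation behind theoretical class-composition estimates for a
#' dataset once `abar` and `lambda` have been inferred from its counts.
#'
#' @param abar labelling efficiency, possibly a vector (one row
#'   returned per value, e.g. one per downsampling level).
#' @param lam loading rate.
#' @param s sample count.
#' @param convention reporting scale for the four class proportions;
#'   defaults to `"per_cell_droplet"`, the scale of observed class
#'   fractions among cell-droplets.
#'
#' @return A data.frame with columns `abar`, `lam`, `s`, `p_hs`, `p_ps`,
#'   `p_mu`, `p_un`.
#' @examples
#' theoreticalCategoryProportions(abar = c(1, 0.95, 0.9), lam = 0.369,
#'                                s = 8)
#' @export
theoreticalCategoryProportions <- function(abar, lam, s,
                                           convention = c("per_cell_droplet",
                                                          "per_droplet",
                                                          "per_monolabelled",
                                                          "among_multiplets")) {
    convention <- match.arg(convention)
    rows <- lapply(abar, function(ab) {
        mp <- multipletProbabilities(equalDesign(s, ab, lam))
        fr <- multipletFractions(mp, convention)
        data.frame(abar = ab, lam = lam, s = as.integer(s),
                   p_hs = fr[["hs"]], p_ps = fr[["ps"]],
                   p_mu = fr[["mu"]], p_un = fr[["un"]])
    })
    do.call(rbind, rows)
}

#' @rdname ParameterEstimate-class
#' @param object a `ParameterEstimate`.
#' @export
setMethod("show", "ParameterEstimate", function(object) {
    cat(sprintf("ParameterEstimate (method: %s)\n", object@method))
    if (!is.na(object@abar))
        cat(sprintf("  abar_hat:   %.6g\n", object@abar))
    if (!is.na(object@lam))
        cat(sprintf("  lambda_hat: %.6g\n", object@lam))
    if (isTRUE(object@diagnostics$boundary))
        cat("  note: boundary estimate (no unlabelled droplets observed)\n")
})

#' @rdname ObservedCounts-class
#' @param object an `ObservedCounts`.
#' @export
setMethod("show", "ObservedCounts", function(object) {
    cat("ObservedCounts\n")
    if (length(object@monoPerSample))
        cat(sprintf("  monolabelled (per sample): %s\n",
                    paste(object@monoPerSample, collapse = ", ")))
    cat(sprintf("  monolabelled total: %s\n", object@monoTotal))
    cat(sprintf("  unlabelled:         %s\n", object@unlabelled))
    cat(sprintf("  multilabelled:      %s\n", object@multilabelled))
    cat(sprintf("  total cell-droplets: %s\n", object@total))
})
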