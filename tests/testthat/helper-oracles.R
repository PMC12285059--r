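# Independent oracles used across the suite. These re-derive model
# quantities by routes disjoint from the package implementation
# (enumeration over explicit cell records, truncated-Poisson
# combinatorics), so agreement is evidence, not tautology.

# Classify a droplet from an explicit list of cell records, following
# the verbal class definitions directly. `cells` is a data.frame with
# columns sample (integer) and labelled (logical); unlabelled cells
# keep their sample of origin but it must not influence the class.
oracleClassify <- function(cells) {
  if (nrow(cells) == 0L) return("empty")
  if (nrow(cells) == 1L)
    return(if (cells$labelled) "singlet_labelled" else "singlet_unlabelled")
  labSamples <- unique(cells$sample[cells$labelled])
  if (length(labSamples) >= 2L) return("mu")
  if (length(labSamples) == 0L) return("un")
  if (any(!cells$labelled)) return("ps")
  "hs"
}

# All ways of placing exactly k cells into m channels.
compositionsOf <- function(k, m) {
  if (m == 1L) return(matrix(k, 1L, 1L))
  do.call(rbind, lapply(0:k, function(i)
    cbind(i, compositionsOf(k - i, m - 1L))))
}

# Cell records for an allocation over the 2s channels
# (sample 1..s labelled, then sample 1..s unlabelled).
cellsFromAllocation <- function(cnt, s) {
  lab <- cnt[seq_len(s)]
  unl <- cnt[(s + 1L):(2L * s)]
  data.frame(sample = c(rep(seq_len(s), lab), rep(seq_len(s), unl)),
             labelled = rep(c(TRUE, FALSE), c(sum(lab), sum(unl))))
}

# Closed-form-free class probabilities: truncated Poisson occupancy
# against multinomial allocation of each cell into the 2s channels,
# classified per allocation by the cell-record oracle. Truncation error
# is below the Poisson tail beyond kMax (< 1e-10 for lam <= 0.6,
# kMax = 12).
oracleClassProbs <- function(r, a, lam, kMax = 12L) {
  s <- length(r)
  chan <- c(r * a, r * (1 - a))
  classes <- c("empty", "singlet_labelled", "singlet_unlabelled",
               "hs", "ps", "mu", "un")
  p <- setNames(numeric(7L), classes)
  for (k in 0:kMax) {
    pk <- dpois(k, lam)
    if (k == 0L) { p[["empty"]] <- p[["empty"]] + pk; next }
    alloc <- compositionsOf(k, 2L * s)
    for (j in seq_len(nrow(alloc))) {
      cnt <- as.numeric(alloc[j, ])
      cl <- oracleClassify(cellsFromAllocation(cnt, s))
      p[[cl]] <- p[[cl]] + pk * dmultinom(cnt, prob = chan)
    }
  }
  p
}

# Simplified equal-design closed forms (common labelling efficiency,
# equal pooling), coded from their own algebraic form.
equalCaseFormulas <- function(s, abar, lam) {
  e <- exp(-lam)
  grow <- s * (exp(abar * lam / s) - 1)
  c(hs = e * grow - abar * lam * e,
    ps = (exp(-abar * lam) - e) * grow,
    mu = 1 - exp(-abar * lam) * (grow + 1),
    un = e * (exp((1 - abar) * lam) - (1 - abar) * lam - 1))
}

# Draw a random valid design (caller controls the RNG seed).
randomDesign <- function(sMax = 8L, lamMax = 1.5) {
  s <- sample.int(sMax, 1L)
  r <- runif(s, 0.05, 1); r <- r / sum(r)
  experimentDesign(r = r, a = runif(s), lam = runif(1, 0.05, lamMax))
}

# Row-by-row concordance oracle following the class definitions
# verbatim for one droplet. The five conditions are mutually exclusive,
# so the cascade order is immaterial.
oracleConcordanceRow <- function(refCall, testCall, samples) {
  if (testCall == "UNASSIGNED") {
    "unassigned"
  } else if (refCall == "MULTIPLET" && testCall == "MULTIPLET") {
    "multiplet"
  } else if (refCall == "MULTIPLET" && testCall %in% samples) {
    "partial_stealth"
  } else if (refCall %in% samples && refCall == testCall) {
    "singlet"
  } else {
    "discordant"
  }
}

# 3-sigma binomial tolerance for an empirical frequency.
binomTol <- function(p, n) 3 * sqrt(pmax(p * (1 - p), 1e-12) / n)
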