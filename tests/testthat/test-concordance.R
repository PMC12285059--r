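test_that("call tables validate barcodes and tokens", {
  expect_s4_class(callTable(c("b1", "b2"), c("S1", "MULTIPLET")),
                  "CallTable")
  expect_error(callTable(c("b1", "b1"), c("S1", "S2")), "unique")
  expect_error(callTable("b1", "Doublet", samples = "S1"),
               "unknown call token 'Doublet'")
})

test_that("concordance matches the enumeration oracle on all call pairs", {
  samples <- c("A", "B")
  vocab <- c(samples, "MULTIPLET", "UNLABELLED", "UNASSIGNED")
  pairs <- expand.grid(ref = vocab, test = vocab,
                       stringsAsFactors = FALSE)
  ref <- callTable(sprintf("b%02d", seq_len(nrow(pairs))), pairs$ref,
                   samples = samples)
  test <- callTable(sprintf("b%02d", seq_len(nrow(pairs))), pairs$test,
                    samples = samples)
  res <- classifyConcordance(ref, test)
  want <- table(factor(mapply(oracleConcordanceRow, pairs$ref, pairs$test,
                              MoreArgs = list(samples = samples)),
                       levels = names(concordanceCounts(res))))
  expect_identical(unname(concordanceCounts(res)), as.integer(want))
  expect_identical(sum(concordanceCounts(res)), nrow(pairs))
})

test_that("concordance on a large random pair equals row-by-row enumeration", {
  set.seed(55)
  samples <- c("S1", "S2", "S3")
  vocab <- c(samples, "MULTIPLET", "UNLABELLED", "UNASSIGNED")
  n <- 1e4
  bc <- sprintf("BC%05d", seq_len(n))
  rc <- sample(vocab, n, replace = TRUE, prob = c(0.3, 0.25, 0.2, 0.15, 0.05, 0.05))
  tc <- sample(vocab, n, replace = TRUE)
  res <- classifyConcordance(callTable(bc, rc, samples),
                             callTable(bc, tc, samples))
  want <- vapply(seq_len(n), function(i)
    oracleConcordanceRow(rc[i], tc[i], samples), character(1))
  expect_identical(unname(concordanceCounts(res)),
                   as.integer(table(factor(want,
                                           levels = names(concordanceCounts(res))))))
  # row order is immaterial
  perm <- sample.int(n)
  res2 <- classifyConcordance(callTable(bc[perm], rc[perm], samples),
                              callTable(bc, tc, samples))
  expect_identical(concordanceCounts(res), concordanceCounts(res2))
})

test_that("barcodes present in only one table are excluded but counted", {
  ref <- callTable(c("b1", "b2", "b3"), c("A", "A", "MULTIPLET"), "A")
  test <- callTable(c("b2", "b3", "b4"), c("A", "A", "A"), "A")
  res <- classifyConcordance(ref, test)
  expect_identical(res@nCommon, 2L)
  expect_identical(res@nRefOnly, 1L)
  expect_identical(res@nTestOnly, 1L)
  expect_identical(concordanceCounts(res)[["singlet"]], 1L)
  expect_identical(concordanceCounts(res)[["partial_stealth"]], 1L)
  expect_error(classifyConcordance(ref, callTable("zz", "A", "A")),
               "no barcodes")
})

test_that("identical pure-sample tables are all singlets", {
  tab <- callTable(sprintf("b%d", 1:50), rep(c("A", "B"), 25), c("A", "B"))
  res <- classifyConcordance(tab, tab)
  expect_identical(concordanceCounts(res)[["singlet"]], 50L)
  expect_identical(sum(concordanceCounts(res)), 50L)
  expect_equal(summariseConcordance(res)$singletToMonolabelled, 1)
})

test_that("summary ratios reproduce the published count arithmetic", {
  mk <- function(cnt) new("ConcordanceResult",
                          counts = setNames(as.integer(cnt),
                                            c("singlet", "partial_stealth",
                                              "multiplet", "unassigned",
                                              "discordant")),
                          perSample = data.frame(),
                          discordantBreakdown = integer(0),
                          nCommon = as.integer(sum(cnt)),
                          nRefOnly = 0L, nTestOnly = 0L)
  nsclc <- summariseConcordance(mk(c(24433, 4285, 3561, 88, 302)))
  expect_equal(nsclc$partialStealthAmongMonolabelled, 4285 / 28718)
  expect_equal(round(nsclc$partialStealthAmongMonolabelled, 2), 0.15)
  cite <- summariseConcordance(mk(c(13588, 624, 1759, 680, 265)))
  expect_equal(cite$partialStealthAmongMonolabelled, 624 / 14212,
               tolerance = 1e-12)
  expect_equal(round(cite$partialStealthAmongMonolabelled, 4), 0.0439)
  degenerate <- summariseConcordance(mk(c(0, 0, 5, 1, 1)))
  expect_true(is.na(degenerate$partialStealthAmongMonolabelled))
  expect_match(degenerate$flag, "undefined")
})

test_that("two-Gaussian threshold separates well-split mixtures", {
  set.seed(8)
  x <- c(rnorm(250, 0, 1), rnorm(250, 10, 1))
  thr <- twoGaussianThreshold(x, p = 1e-4)
  expect_gt(thr, 3.5)
  expect_lt(thr, 6.5)
  expect_true(all(x[x > 8] > thr))       # high component all positive
  fit <- attr(thr, "fit")
  expect_equal(sort(fit$mu), c(0, 10), tolerance = 0.3)
  thrBY <- twoGaussianThreshold(x, p = 1e-4, adjust = "BY")
  expect_gte(thrBY, thr - 1e-9)          # BY is the conservative variant
  expect_true(all(x[x > 8] > thrBY))
})

test_that("two-Gaussian EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(21)
  x <- c(rnorm(300, 0, 1), rnorm(150, 4, 1.5))
  fit <- attr(twoGaussianThreshold(x, p = 1e-3), "fit")
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("unadjusted threshold converges to the null quantile", {
  set.seed(33)
  mu <- 2; sigma <- 0.5
  x <- c(rnorm(20000, mu, sigma), rnorm(20000, 12, 1))
  thr <- twoGaussianThreshold(x, p = 1e-4)
  expect_equal(as.numeric(thr), mu + qnorm(1 - 1e-4) * sigma,
               tolerance = 0.05)
})

test_that("degenerate or insufficient scores are rejected", {
  expect_error(twoGaussianThreshold(rep(1, 100)), "identical")
  expect_error(twoGaussianThreshold(rnorm(10)), "at least 20")
  expect_error(twoGaussianThreshold(rnorm(100), p = 0.7), "0, 0.5")
})

test_that("double positives and partial-stealth candidates are recovered exactly", {
  set.seed(71)
  n <- 200
  bc <- sprintf("BC%04d", seq_len(n))
  scores <- data.frame(barcode = bc,
                       ES = rnorm(n, 0, 0.2),
                       NIH3T3 = rnorm(n, 0, 0.2))
  planted <- sample(bc, 5)
  scores$ES[scores$barcode %in% planted] <- 5
  scores$NIH3T3[scores$barcode %in% planted] <- 5
  thr <- c(ES = 2, NIH3T3 = 2)
  expect_setequal(callDoublePositives(scores, thr), planted)
  expect_length(callDoublePositives(
    data.frame(barcode = bc, ES = rnorm(n, 0, 0.1), NIH3T3 = rnorm(n, 0, 0.1)),
    thr), 0L)

  # intersect with a call table: only monolabelled double-positives remain
  callSet <- rep("ES", n)
  callSet[bc %in% planted[1:2]] <- "MULTIPLET"
  tab <- callTable(bc, callSet, samples = c("ES", "NIH3T3"))
  out <- callDoublePositives(scores, thr, against = tab)
  expect_setequal(out$partialStealthCandidates, planted[3:5])
  expect_identical(out$nSkipped, 0L)

  scores$ES[1] <- NA
  expect_warning(callDoublePositives(scores, thr), "skipped")
  expect_error(callDoublePositives(scores, c(ES = 1, missing = 1)),
               "lacks lineage")
})

test_that("simulate -> degrade -> audit recovers the planted degradation", {
  d <- equalDesign(4, 0.95, 0.5)
  pool <- simulatePool(d, 5e4, seed = 12, keepDroplets = TRUE)
  tabs <- degradeCalls(pool, pUnassign = 0.08, pMisassign = 0.02, seed = 13)
  res <- classifyConcordance(tabs$truth, tabs$degraded)
  n <- res@nCommon
  unassignedRate <- concordanceCounts(res)[["unassigned"]] / n
  expect_lt(abs(unassignedRate - 0.08), binomTol(0.08, n))
  # misassigned MULTIPLET rows surface as partial stealth
  nMu <- poolTally(pool)[["mu"]]
  psRate <- concordanceCounts(res)[["partial_stealth"]] / nMu
  expect_lt(abs(psRate - 0.02), binomTol(0.02, nMu))
})
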