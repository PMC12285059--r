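## File plumbing. Dialect: tab-separated UTF-8 text with a mandatory
## header row and '.' as decimal separator; JSON reports with stable key
## ordering so runs can be diffed.

#' Read a per-class droplet count table
#'
#' Reads a two-column delimited file with header `class<TAB>count`,
#' where `class` is `sample:<name>` (monolabelled droplets called
#' `<name>`), `unlabelled`, or `multilabelled`.
#'
#' @param path path to a tab-separated file.
#' @return An [ObservedCounts].
#' @examples
#' f <- system.file("extdata", "citeseq_demux_counts.tsv",
#'                  package = "stealthmx")
#' readObservedCounts(f)
#' @export
readObservedCounts <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("class", "count") %in% names(df)))
        stop(sprintf("'%s' must have columns 'class' and 'count'", path))
    isSample <- startsWith(df$class, "sample:")
    known <- isSample | df$class %in% c("unlabelled", "multilabelled")
    if (!all(known))
        stop(sprintf("unknown class token '%s' in '%s'",
                     df$class[!known][1L], path))
    mono <- df$count[isSample]
    names(mono) <- sub("^sample:", "", df$class[isSample])
    pick <- function(cl)
        if (any(df$class == cl)) sum(df$count[df$class == cl]) else NA_real_
    observedCounts(mono = if (length(mono)) mono else NA_real_,
                   unlabelled = pick("unlabelled"),
                   multilabelled = pick("multilabelled"))
}

#' Read a demultiplexing call table
#'
#' Reads a delimited file with header columns `barcode` and `call`.
#' Demultiplexer dialect tokens are normalised through `tokenMap`
#' before validation; any call containing a `+` (a multiplet call that
#' names its constituent samples, e.g. `"A+B"`) is normalised to
#' `MULTIPLET`.
#'
#' @param path path to a tab-separated file.
#' @param samples sample vocabulary; inferred from the file when
#'   omitted.
#' @param tokenMap named character vector mapping dialect tokens to
#'   calls; the default covers common demultiplexer vocabularies
#'   (`Doublet`/`doublet`/`Multiplet` to `MULTIPLET`,
#'   `Negative`/`negative`/`Unlabelled` to `UNLABELLED`,
#'   `unassigned`/`Unassigned`/`ambiguous` to `UNASSIGNED`).
#' @return A [CallTable].
#' @export
readCallTable <- function(path, samples = NULL,
                          tokenMap = defaultTokenMap()) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("barcode", "call") %in% names(df)))
        stop(sprintf("'%s' must have columns 'barcode' and 'call'", path))
    cl <- as.character(df$call)
    hit <- cl %in% names(tokenMap)
    cl[hit] <- tokenMap[cl[hit]]
    cl[grepl("+", cl, fixed = TRUE)] <- "MULTIPLET"
    extra <- df[, setdiff(names(df), c("barcode", "call")), drop = FALSE]
    callTable(df$barcode, cl, samples = samples,
              extra = if (ncol(extra)) extra else NULL)
}

#' @describeIn readCallTable the default dialect-token mapping.
#' @export
defaultTokenMap <- function() {
    c(Doublet = "MULTIPLET", doublet = "MULTIPLET",
      Multiplet = "MULTIPLET", multiplet = "MULTIPLET",
      Negative = "UNLABELLED", negative = "UNLABELLED",
      Unlabelled = "UNLABELLED", unlabelled = "UNLABELLED",
      Unassigned = "UNASSIGNED", unassigned = "UNASSIGNED",
      ambiguous = "UNASSIGNED")
}

#' Write a call table as tab-separated text
#'
#' @param x a [CallTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCallTable <- function(x, path) {
    stopifnot(is(x, "CallTable"))
    utils::write.table(x@calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a per-barcode marker-score table
#'
#' Delimited text with a `barcode` column and one numeric column per
#' lineage.
#'
#' @param path path to a tab-separated file.
#' @return A data.frame.
#' @export
readScoreTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"barcode" %in% names(df))
        stop(sprintf("'%s' must have a 'barcode' column", path))
    df
}

#' Read an experiment design from a config file
#'
#' YAML (or plain `key: value`) config with keys `samples`, `fractions`,
#' `efficiencies`, `lam`. `fractions` may be omitted for equal pooling;
#' a scalar `efficiencies` is recycled.
#'
#' @param path config path.
#' @return An [ExperimentDesign].
#' @export
readDesignConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    s <- if (!is.null(cfg$samples)) as.integer(cfg$samples)
         else length(cfg$fractions)
    r <- if (!is.null(cfg$fractions)) as.numeric(cfg$fractions)
         else rep(1 / s, s)
    if (is.null(cfg$efficiencies))
        stop(sprintf("'%s' must set 'efficiencies'", path))
    if (is.null(cfg$lam))
        stop(sprintf("'%s' must set 'lam'", path))
    experimentDesign(r = r, a = as.numeric(cfg$efficiencies),
                     lam = as.numeric(cfg$lam))
}

#' Write a sweep table as tab-separated text
#'
#' @param x a data.frame from [sweepClassProportions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSweepTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a JSON run report
#'
#' Serialises a named list to JSON with stable key ordering, stamping
#' the package version and, when given, the seed and configuration so
#' every report is self-describing.
#'
#' @param report named list.
#' @param path output path.
#' @param seed optional integer recorded in the report.
#' @param config optional named list of run configuration.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, seed = NULL, config = NULL) {
    stamp <- list(package = "stealthmx",
                  version = as.character(utils::packageVersion("stealthmx")))
    if (!is.null(seed)) stamp$seed <- as.integer(seed)
    if (!is.null(config)) stamp$config <- config
    jsonlite::write_json(c(stamp, report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
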