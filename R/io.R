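#' Read a gene-expression time-series matrix
#'
#' Expects tab- or comma-separated text with a header row of time labels, the
#' first column holding gene identifiers and the remaining columns holding
#' expression values in temporal order (column order is the time order; no
#' timestamps are required because the supported designs are equally spaced).
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; guessed from the first line when NULL.
#' @return an \code{\link{ExpressionSeries}}.
#' @export
readExpression <- function(path, sep = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3L)
        stop("expression file needs a header and at least 2 gene rows: ", path)
    if (is.null(sep))
        sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
    tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             comment.char = "")
    if (ncol(tab) < 3L)
        stop("fewer than 2 time-point columns in ", path)
    ids <- tab[[1L]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicated gene identifier(s): ", paste(dup, collapse = ", "))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric value at gene '%s', time column '%s'",
                     ids[bad[1L]], colnames(vals)[bad[2L]]))
    }
    rownames(num) <- ids
    colnames(num) <- colnames(vals)
    ExpressionSeries(num)
}

#' Write an expression matrix as tab-separated text
#'
#' @param es an \code{\link{ExpressionSeries}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(es, path) {
    v <- exprValues(es)
    labs <- timeLabels(es)
    if (is.null(labs)) labs <- paste0("t", seq_len(ncol(v)))
    df <- data.frame(gene = rownames(v), v, check.names = FALSE)
    colnames(df) <- c("gene", labs)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a directed edge list
#'
#' Two-column (regulator, target) whitespace/tab-separated text; an optional
#' third column (e.g. a lag) is ignored on input. Self-loops are retained and
#' flagged. Lines that are empty or start with \code{#} are skipped.
#'
#' @param path path to the edge-list file.
#' @return a \code{\link{GoldNetwork}}.
#' @export
readEdgeList <- function(path) {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    lines <- lines[keep]
    lineno <- which(keep)
    if (!length(lines)) return(GoldNetwork())
    parts <- strsplit(trimws(lines), "[\t ,]+")
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad))
        stop(sprintf("malformed edge at line %d of %s: '%s'",
                     lineno[bad[1L]], path, lines[bad[1L]]))
    GoldNetwork(regulator = vapply(parts, `[[`, "", 1L),
                target = vapply(parts, `[[`, "", 2L))
}

#' Write an inferred network as tab-separated text
#'
#' Columns: regulator, target, lag, score.
#'
#' @param net an \code{\link{InferredNetwork}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path) {
    utils::write.table(edges(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Normalise expression per gene
#'
#' \code{minmax} maps each gene row onto [0,1] (a constant row maps to 0.5 by
#' convention); \code{zscore} centres and scales each row (a constant row maps
#' to 0); \code{none} returns the input unchanged. Min-max is the default
#' upstream of scoring and modelling because the complex Elliot activation
#' saturates and the mutual-information binning is scale-sensitive.
#'
#' @param es an \code{\link{ExpressionSeries}}.
#' @param mode one of \code{"minmax"}, \code{"zscore"}, \code{"none"}.
#' @return a new \code{ExpressionSeries}; the input is untouched.
#' @export
normalizeExpression <- function(es, mode = c("minmax", "zscore", "none")) {
    mode <- match.arg(mode)
    if (mode == "none") return(es)
    v <- exprValues(es)
    out <- t(apply(v, 1L, function(row) {
        rng <- range(row)
        if (mode == "minmax") {
            if (rng[1L] == rng[2L]) rep(0.5, length(row))
            else (row - rng[1L]) / (rng[2L] - rng[1L])
        } else {
            s <- stats::sd(row)
            if (s == 0) rep(0, length(row)) else (row - mean(row)) / s
        }
    }))
    dimnames(out) <- dimnames(v)
    ExpressionSeries(out)
}

#' Read a flat key-value run configuration
#'
#' One \code{key = value} (or \code{key: value}) pair per line, keys mirroring
#' the \code{\link{RunConfig}} fields (\code{tauMax}, \code{L}, \code{minLag},
#' \code{normalization}, \code{encoding}, \code{seed}, \code{nRuns}) plus
#' optional optimizer fields prefixed \code{optimizer.} or \code{bat.}
#' (e.g. \code{optimizer.popSize}, \code{bat.nBats}). Unknown keys error.
#'
#' @param path path to the configuration file.
#' @return a \code{\link{RunConfig}}.
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, "[=:]", fixed = FALSE)
    keys <- trimws(vapply(kv, `[[`, "", 1L))
    vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"), ""))
    args <- list(); opt <- list(); bat <- list()
    numKeys <- c("tauMax", "L", "minLag", "seed", "nRuns")
    for (i in seq_along(keys)) {
        k <- keys[i]; v <- vals[i]
        if (k %in% numKeys) args[[k]] <- as.integer(v)
        else if (k %in% c("normalization", "encoding")) args[[k]] <- v
        else if (startsWith(k, "optimizer."))
            opt[[sub("^optimizer\\.", "", k)]] <- as.numeric(v)
        else if (startsWith(k, "bat."))
            bat[[sub("^bat\\.", "", k)]] <- as.numeric(v)
        else stop("unknown configuration key: ", k)
    }
    if (length(bat)) opt$bat <- do.call(batConfig, bat)
    args$optimizer <- do.call(optimizerConfig, opt)
    do.call(RunConfig, args)
}
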