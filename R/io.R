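# Readers/writers for the plain-text formats the package consumes and emits:
# delimited expression matrices (TSV/CSV/GCT 1.2), gene sets (one id per
# line, or GMT), and ranking tables.

#' Read an expression matrix
#'
#' Accepts tab- or comma-delimited text (first column gene ids, header row of
#' sample ids) and the GCT 1.2 dialect (two header lines; the Description
#' column is ignored). Duplicate gene ids and ragged rows are errors.
#'
#' @param path file path.
#' @param format `"auto"` (default: GCT if the first line is `#1.2` or the
#'   extension is .gct, else by extension), `"tsv"`, `"csv"`, or `"gct"`.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
readExpression <- function(path, format = c("auto", "tsv", "csv", "gct")) {
    format <- match.arg(format)
    if (format == "auto") {
        first <- readLines(path, n = 1L)
        format <- if (startsWith(first, "#1.2") ||
                      grepl("\\.gct$", path, ignore.case = TRUE)) {
            "gct"
        } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
            "csv"
        } else {
            "tsv"
        }
    }
    if (format == "gct") {
        ln <- readLines(path)
        if (length(ln) < 3L) stop("truncated GCT file: ", path)
        body <- ln[-(1:2)]
        parts <- strsplit(body, "\t", fixed = TRUE)
        widths <- lengths(parts)
        if (any(widths != widths[1L])) {
            stop("ragged GCT row at line ",
                 2L + which(widths != widths[1L])[1L])
        }
        header <- parts[[1L]]
        samples <- header[-(1:2)]            # drop Name, Description
        rows <- parts[-1L]
        ids <- vapply(rows, `[`, character(1L), 1L)
        vals <- t(vapply(rows, function(p) as.numeric(p[-(1:2)]),
                         numeric(length(samples))))
        dimnames(vals) <- list(ids, samples)
        m <- vals
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
            check.names = FALSE, stringsAsFactors = FALSE,
            colClasses = "character", fill = FALSE, quote = "\"")
        ids <- df[[1L]]
        m <- as.matrix(df[, -1L, drop = FALSE])
        storage.mode(m) <- "double"
        rownames(m) <- ids
    }
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    if (length(dup)) {
        stop("duplicate gene ids in ", path, ": ",
             paste(utils::head(dup, 10L), collapse = ", "))
    }
    .asExpressionMatrix(m)
}

#' Write an expression matrix as TSV
#'
#' @param x genes x samples matrix.
#' @param path output path.
#' @param idColumn name of the first (gene id) column.
#' @return Invisibly, `path`.
#' @export
writeExpression <- function(x, path, idColumn = "gene_id") {
    x <- .asExpressionMatrix(x)
    header <- paste(c(idColumn, colnames(x)), collapse = "\t")
    body <- vapply(seq_len(nrow(x)), function(i) {
        paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
    }, character(1L))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a gene set
#'
#' Plain lists (one id per line; blank lines and `#` comments skipped) and
#' GMT records (tab-delimited: name, description, then ids) are accepted. A
#' GMT file with several records returns a named list unless `set` picks one.
#'
#' @param path file path.
#' @param set for GMT input, the record name (or index) to return.
#' @return Character vector of gene ids, or a named list of such vectors for
#'   a multi-record GMT with `set = NULL`.
#' @export
readGeneSet <- function(path, set = NULL) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
    if (!length(ln)) stop("no gene ids in ", path)
    isGmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
        all(vapply(strsplit(ln, "\t", fixed = TRUE), length, 1L) >= 3L)
    if (!isGmt) {
        return(unique(trimws(ln)))
    }
    recs <- strsplit(ln, "\t", fixed = TRUE)
    sets <- lapply(recs, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(recs, `[`, character(1L), 1L)
    if (!is.null(set)) {
        return(sets[[set]])
    }
    if (length(sets) == 1L) sets[[1L]] else sets
}

#' Write a ranking table as TSV
#'
#' Emits the standard ranking schema (`rank`, `gene_id`, `score`,
#' `abs_score`, `sd`, `method`); numeric columns are written at full
#' precision so a write/read round trip is exact.
#'
#' @param ranking a ranking data.frame (from the baseline rankers) or a
#'   [ParticipationResult-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRanking <- function(ranking, path) {
    if (methods::is(ranking, "ParticipationResult")) {
        ranking <- rankingTable(ranking)
    }
    if (!"sd" %in% names(ranking)) {
        ranking$sd <- NA_real_
    }
    header <- "rank\tgene_id\tscore\tabs_score\tsd\tmethod"
    num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
    body <- paste(ranking$rank, ranking$gene, num(ranking$score),
                  num(ranking$abs_score), num(ranking$sd), ranking$method,
                  sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a ranking table written by [writeRanking()]
#'
#' @param path file path.
#' @return data.frame with columns `rank`, `gene`, `score`, `abs_score`,
#'   `sd`, `method`.
#' @export
readRanking <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, fill = FALSE)
    names(df)[names(df) == "gene_id"] <- "gene"
    df
}

#' Write a reproducibility manifest
#'
#' JSON record of the parameters, seed and package version of a run, written
#' beside its outputs.
#'
#' @param path output path (.json).
#' @param params named list of run parameters.
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(path, params = list()) {
    manifest <- c(list(
        package = "cocaRank",
        version = as.character(utils::packageVersion("cocaRank")),
        r_version = R.version.string,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ), params)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
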