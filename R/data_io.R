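## Readers/writers for the external text formats and the cohort container.
## Expression travels as a plain genes x samples numeric matrix until it is
## paired with phenotype data in a SummarizedExperiment via makeCohort().

.validateExpr <- function(values, what = "expression matrix") {
    if (!is.matrix(values) || !is.numeric(values))
        stop(what, " must be a numeric matrix")
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop(what, " must carry gene rownames and sample colnames")
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene ids: ",
             paste(unique(rownames(values)[duplicated(rownames(values))]),
                   collapse = ", "))
    if (anyDuplicated(colnames(values)))
        stop("duplicate sample ids: ",
             paste(unique(colnames(values)[duplicated(colnames(values))]),
                   collapse = ", "))
    if (anyNA(values)) {
        idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
        stop("missing value at gene '", rownames(values)[idx[1L]],
             "', sample '", colnames(values)[idx[2L]], "'")
    }
    invisible(values)
}

#' Read a gene x sample expression matrix from delimited text
#'
#' Reads tab- or comma-separated text with a header row and identifiers in
#' the first column. Values are expected on log2 scale after preprocessing,
#' but no scale check is applied here. Duplicate gene rows (e.g. multiple
#' probes mapping to one symbol) are collapsed; duplicate sample ids are
#' rejected.
#'
#' @param path file path.
#' @param orientation \code{"rows-are-genes"} (default) or
#'   \code{"rows-are-samples"}; the latter transposes after reading.
#' @param collapse how to collapse duplicate gene rows:
#'   \code{"max-variance"} keeps the most variable row (a common microarray
#'   convention), \code{"mean"} averages.
#' @param sep field separator; \code{NULL} auto-detects tab vs comma from
#'   the header line.
#' @return numeric matrix, genes x samples, with unique dimnames.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("rows-are-genes",
                                                 "rows-are-samples"),
                                 collapse = c("max-variance", "mean"),
                                 sep = NULL) {
    orientation <- match.arg(orientation)
    collapse <- match.arg(collapse)
    if (!file.exists(path)) stop("no such file: ", path)
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) stop("empty file: ", path)
    if (is.null(sep))
        sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "")
    if (nrow(df) == 0L || ncol(df) < 2L) stop("no data rows in ", path)
    ids <- df[[1L]]
    body <- df[, -1L, drop = FALSE]
    # data.frame subsetting uniquifies duplicated column names; recover the
    # raw header so duplicate sample ids are caught, not silently renamed
    rawNames <- gsub("^\"|\"$", "",
                     strsplit(header, sep, fixed = TRUE)[[1L]])[-1L]
    if (length(rawNames) == ncol(body)) colnames(body) <- make.unique(rawNames)
    # locate non-numeric / blank cells before coercion so we can name them
    for (j in seq_along(body)) {
        cell <- body[[j]]
        bad <- which(is.na(cell) | cell == "" |
                     is.na(suppressWarnings(as.numeric(cell))))
        if (length(bad))
            stop("non-numeric or blank cell at row '", ids[bad[1L]],
                 "', column '", colnames(body)[j], "'")
    }
    values <- vapply(body, as.numeric, numeric(nrow(df)))
    if (nrow(df) == 1L) values <- matrix(values, nrow = 1L,
                                         dimnames = list(NULL, colnames(body)))
    if (length(rawNames) == ncol(values)) colnames(values) <- rawNames
    rownames(values) <- ids
    if (orientation == "rows-are-samples") values <- t(values)
    if (anyDuplicated(colnames(values)))
        stop("duplicate sample ids: ",
             paste(unique(colnames(values)[duplicated(colnames(values))]),
                   collapse = ", "))
    if (anyDuplicated(rownames(values)))
        values <- .collapseDuplicateGenes(values, collapse)
    .validateExpr(values)
    values
}

.collapseDuplicateGenes <- function(values, collapse) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    message(length(dup), " duplicated gene id(s) collapsed by ", collapse)
    keep <- !rownames(values) %in% dup
    collapsed <- lapply(dup, function(g) {
        block <- values[rownames(values) == g, , drop = FALSE]
        if (collapse == "mean") colMeans(block)
        else block[which.max(apply(block, 1L, stats::var)), ]
    })
    collapsed <- do.call(rbind, collapsed)
    rownames(collapsed) <- dup
    out <- rbind(values[keep, , drop = FALSE], collapsed)
    out[order(match(rownames(out), unique(rownames(values)))), , drop = FALSE]
}

#' Write an expression matrix as TSV (genes as rows)
#'
#' Full \code{write}/\code{read} round trips reproduce values to printed
#' precision (15 significant digits) with identical id ordering.
#'
#' @param x genes x samples numeric matrix.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
    .validateExpr(x)
    df <- data.frame(gene_id = rownames(x),
                     format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", colnames(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a per-sample phenotype table (CSV)
#'
#' Expected columns: \code{sample_id}, \code{recurrence} (0/1),
#' \code{who_grade} (1-3); optional: \code{simpson_grade} (1-5),
#' \code{time_to_recurrence} (years), \code{follow_up} (years),
#' \code{batch}, plus any extra annotation columns which are carried along
#' unused. Samples with missing optional covariates are retained and
#' flagged; the modeling stage decides exclusion.
#'
#' @param path CSV path.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readPhenotypeTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("sample_id", "recurrence", "who_grade")
    miss <- setdiff(required, colnames(df))
    if (length(miss)) stop("phenotype table lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    bad <- which(!df$recurrence %in% c(0, 1))
    if (length(bad))
        stop("recurrence outside {0,1} at row ", bad[1L],
             " (sample '", df$sample_id[bad[1L]], "')")
    bad <- which(!is.na(df$who_grade) & !df$who_grade %in% 1:3)
    if (length(bad))
        stop("who_grade outside {1,2,3} at row ", bad[1L],
             " (sample '", df$sample_id[bad[1L]], "')")
    if ("simpson_grade" %in% colnames(df)) {
        bad <- which(!is.na(df$simpson_grade) & !df$simpson_grade %in% 1:5)
        if (length(bad))
            stop("simpson_grade outside {1..5} at row ", bad[1L])
    }
    if ("time_to_recurrence" %in% colnames(df)) {
        stray <- !is.na(df$time_to_recurrence) & df$recurrence == 0
        if (any(stray)) {
            message(sum(stray),
                    " non-recurrent sample(s) had time_to_recurrence; cleared")
            df$time_to_recurrence[stray] <- NA_real_
        }
    }
    if (anyNA(df$who_grade))
        message(sum(is.na(df$who_grade)),
                " sample(s) with missing who_grade retained (flagged)")
    rownames(df) <- df$sample_id
    df
}

#' Read a gene-set library in GMT format
#'
#' One term per line: term name, description, then member gene symbols,
#' tab-separated. Member symbols are de-duplicated per term (case
#' preserved; matching elsewhere is case-insensitive).
#'
#' @param path GMT path.
#' @return named list of character vectors; term descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty GMT file: ", path)
    sets <- vector("list", length(lines))
    desc <- character(length(lines))
    nm <- character(length(lines))
    ndup <- 0L
    for (i in seq_along(lines)) {
        # count fields by separators: strsplit drops trailing empties, and a
        # term with an empty gene column must be told apart from a 2-field line
        nf <- length(gregexpr("\t", lines[i], fixed = TRUE)[[1L]]) + 1L
        if (!grepl("\t", lines[i], fixed = TRUE)) nf <- 1L
        if (nf < 3L)
            stop("GMT line ", i, " has fewer than 3 fields")
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (length(genes) == 0L)
            stop("GMT line ", i, " ('", f[1L], "') has an empty gene list")
        u <- unique(genes)
        ndup <- ndup + (length(genes) - length(u))
        nm[i] <- f[1L]; desc[i] <- f[2L]; sets[[i]] <- u
    }
    if (ndup > 0L) message(ndup, " duplicated member gene(s) removed")
    if (anyDuplicated(nm)) stop("duplicate term names in GMT")
    names(sets) <- nm
    attr(sets, "description") <- stats::setNames(desc, nm)
    sets
}

#' Read gene genomic coordinates (BED-like TSV)
#'
#' Columns: chrom, start, end, gene_id (no header). One record per gene.
#'
#' @param path file path.
#' @return data.frame with \code{gene_id}, \code{chromosome}, \code{start}.
#' @export
readGeneAnnotation <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chromosome", "start", "end",
                                          "gene_id"))
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id in annotation")
    if (any(df$start < 0)) stop("negative start position")
    data.frame(gene_id = df$gene_id, chromosome = df$chromosome,
               start = as.integer(df$start), stringsAsFactors = FALSE)
}

#' Bundle expression and phenotype into a cohort object
#'
#' @param expr genes x samples numeric matrix (log2 scale).
#' @param pheno phenotype data.frame keyed by \code{sample_id}; must cover
#'   every expression sample.
#' @return \code{SummarizedExperiment} with assay \code{"exprs"} and the
#'   phenotype in \code{colData}.
#' @export
makeCohort <- function(expr, pheno) {
    .validateExpr(expr)
    miss <- setdiff(colnames(expr), pheno$sample_id)
    if (length(miss))
        stop("samples missing from phenotype table: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    pheno <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = expr),
        colData = S4Vectors::DataFrame(pheno, row.names = colnames(expr)))
    S4Vectors::metadata(se)$stages <- attr(expr, "stages")
    se
}

## Extract the expression matrix from a cohort or pass a matrix through.
.exprs <- function(x) {
    if (is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, "exprs"))
    .validateExpr(x)
    x
}

## Extract phenotype: cohort colData, or a supplied data.frame.
.pheno <- function(x, pheno = NULL) {
    if (is.null(pheno) && is(x, "SummarizedExperiment"))
        pheno <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(pheno)) stop("phenotype table required")
    pheno
}
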