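#' Read a gene-by-cell-line expression matrix
#'
#' Reads a delimited expression table with genes in rows (CCLE-style
#' orientation): the first column holds gene symbols (header \code{"gene"}
#' or any label), the remaining columns are cell lines. Values are treated
#' as opaque real expression levels; no normalization is applied.
#'
#' Duplicate gene rows are collapsed to the first occurrence with a warning.
#' By default any non-numeric cell is an error naming its position; with
#' \code{allowMissing = TRUE}, rows containing missing values are dropped
#' with a warning instead.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param allowMissing logical; drop rows with missing values instead of
#'   failing (default \code{FALSE}).
#' @return numeric matrix with gene-symbol rownames and cell-line colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("TP53", "EGFR"), c("A", "B", "C"))), tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path, dialect = c("tsv", "csv"),
                                 allowMissing = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(df) < 2L)
    stop("malformed expression file: need a gene column plus >= 1 cell line")
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  cells <- colnames(vals)
  if (anyDuplicated(cells))
    stop("malformed header: duplicated cell-line identifiers")
  # coerce column-wise so a bad cell can be named
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(genes, cells))
  for (j in seq_along(cells)) {
    col <- vals[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !(toupper(trimws(col)) %in% c("NA", "NAN", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', cell line '%s'",
                   col[bad[1L]], genes[bad[1L]], cells[j]))
    m[, j] <- num
  }
  if (anyNA(m)) {
    if (!allowMissing) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at gene '%s', cell line '%s' (set allowMissing = TRUE to drop such rows)",
                   genes[idx[1L]], cells[idx[2L]]))
    }
    drop <- rowSums(is.na(m)) > 0L
    warning(sprintf("dropping %d gene row(s) containing missing values",
                    sum(drop)))
    m <- m[!drop, , drop = FALSE]
    genes <- rownames(m)
  }
  if (anyDuplicated(genes)) {
    warning(sprintf("collapsing %d duplicated gene row(s) to first occurrence",
                    sum(duplicated(genes))))
    m <- m[!duplicated(genes), , drop = FALSE]
  }
  m
}

#' Write an expression matrix
#'
#' Inverse of \code{\link{readExpressionMatrix}}: genes in rows, first
#' column header \code{"gene"}. Values are written with full precision so a
#' tsv round-trip reproduces the matrix bit-exactly.
#'
#' @param expr numeric matrix with gene rownames and cell-line colnames.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(expr, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-response table
#'
#' CSV with header-named columns \code{cell_line}, \code{drug},
#' \code{ec50_um} (any column order). EC50 values are concentrations in uM
#' and must be strictly positive; rows with non-positive or non-numeric
#' EC50 are dropped with a warning. A duplicated (cell line, drug) pair is
#' a validation error.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns \code{cell_line}, \code{drug},
#'   \code{ec50_um}.
#' @export
readDrugResponse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "ec50_um")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("drug-response table lacks required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, need]
  ec <- suppressWarnings(as.numeric(df$ec50_um))
  bad <- is.na(ec) | ec <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with non-positive or non-numeric EC50",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
    ec <- ec[!bad]
  }
  df$ec50_um <- ec
  key <- paste(df$cell_line, df$drug, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (cell_line, drug) pair(s): ",
         paste(unique(df$cell_line[duplicated(key)]), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Read a gene list
#'
#' Plain text, one gene symbol per line; blank lines and lines starting
#' with \code{#} are ignored. Duplicates are removed.
#'
#' @param path path to the file.
#' @param name label for the list (defaults to the file name).
#' @return a list with elements \code{name} and \code{symbols}.
#' @export
readGeneList <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  symbols <- unique(lines)
  if (!length(symbols)) stop("gene list is empty: ", path)
  list(name = if (is.null(name)) basename(path) else name, symbols = symbols)
}

#' Align an expression matrix with a drug's response records
#'
#' Restricts the expression matrix to the cell lines that have an EC50
#' record for \code{drug}, in deterministic lexicographic order, and
#' returns the EC50 vector aligned to the columns.
#'
#' @param expr expression matrix (genes x cell lines).
#' @param resp drug-response data.frame from \code{\link{readDrugResponse}}.
#' @param drug drug name to align on.
#' @return list with \code{expr} (column-subset matrix) and \code{ec50}
#'   (named numeric vector in uM, aligned to the columns).
#' @export
alignDataset <- function(expr, resp, drug) {
  stopifnot(is.matrix(expr))
  rec <- resp[resp$drug == drug, , drop = FALSE]
  shared <- sort(intersect(colnames(expr), rec$cell_line))
  if (length(shared) == 0L)
    stop("alignment error: no cell line shared between expression matrix ",
         "and response records for drug '", drug, "'")
  if (length(shared) < 2L)
    stop("alignment error: fewer than 2 shared cell lines for drug '",
         drug, "'")
  ec50 <- setNames(rec$ec50_um[match(shared, rec$cell_line)], shared)
  list(expr = expr[, shared, drop = FALSE], ec50 = ec50)
}
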