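#' Log-scale expression matrix with sample metadata
#'
#' Thin container around a genes x samples numeric matrix of log-scale
#' expression values plus optional per-sample metadata (tumor type, survival
#' time/event). Duplicate gene symbols must be collapsed before construction
#' (see [read_expression()]); all values must be finite.
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = identifiers).
#' @param metadata Optional data.frame, one row per sample, rownames matching
#'   `colnames(values)`; typically columns `tumor_type`, `time`, `event`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    fail("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    fail("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    fail("duplicate gene symbols: collapse duplicates before construction (see read_expression)")
  }
  if (anyDuplicated(colnames(values))) fail("duplicate sample identifiers")
  if (!all(is.finite(values))) fail("expression values must be finite")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!setequal(rownames(metadata), colnames(values))) {
      fail("metadata rows do not match sample identifiers")
    }
    metadata <- metadata[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$metadata)) {
    cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Upper-quartile normalize a count matrix and log-transform
#'
#' Scales each sample so that the 75th percentile of its nonzero counts
#' equals `reference`, then applies `log2(x + 1)`. This is the normalization
#' conventionally applied to pan-cancer RNA-seq compendia before signature
#' scoring.
#'
#' @param counts Nonnegative genes x samples count matrix.
#' @param reference Target value for the per-sample upper quartile
#'   (default 1000).
#' @param metadata Optional sample metadata passed through.
#' @return An [expression_matrix()] of log2-scale values.
#' @export
upper_quartile_normalize <- function(counts, reference = 1000, metadata = NULL) {
  if (any(counts < 0)) fail("counts must be nonnegative")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) return(NA_real_)
    stats::quantile(nz, 0.75, names = FALSE)
  })
  bad <- colnames(counts)[is.na(uq)]
  if (length(bad) > 0L) {
    fail("all-zero sample(s): %s", paste(bad, collapse = ", "))
  }
  scaled <- sweep(counts, 2, reference / uq, `*`)
  expression_matrix(log2(scaled + 1), metadata = metadata)
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV layout: first column gene symbols, header row of sample identifiers.
#' GCT 1.2 layout: `#1.2` version line, dimensions line, then `Name`,
#' `Description` and sample columns. Duplicate gene symbols are collapsed by
#' keeping, for each symbol, the row with the largest median absolute
#' deviation (the most variable measurement); collapse actions are reported
#' via `message()`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`; default guesses from the extension.
#' @param metadata Optional sample metadata data.frame.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (!file.exists(path)) fail("file not found: %s", path)
  if (file.size(path) == 0L) fail("empty file: %s", path)
  if (format == "gct") {
    lines <- readLines(path, n = 2L)
    if (length(lines) < 2L || !startsWith(lines[1], "#1.2")) {
      fail("'%s' is not a GCT 1.2 file", path)
    }
    dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
    body <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                              quote = "", check.names = FALSE,
                              stringsAsFactors = FALSE, comment.char = "")
    if (nrow(body) != dims[1] || ncol(body) - 2L != dims[2]) {
      fail("GCT header dimensions (%d x %d) do not match body (%d x %d)",
           dims[1], dims[2], nrow(body), ncol(body) - 2L)
    }
    genes <- as.character(body[[1]])
    vals <- as.matrix(body[, -(1:2), drop = FALSE])
  } else {
    body <- read_tsv_plain(path)
    if (ncol(body) < 2L) fail("expression TSV needs a gene column plus samples")
    genes <- as.character(body[[1]])
    vals <- as.matrix(body[, -1, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  vals <- collapse_duplicate_genes(vals)
  expression_matrix(vals, metadata = metadata)
}

# keep, per duplicated symbol, the row with the largest median absolute
# deviation; ties broken by first occurrence
collapse_duplicate_genes <- function(vals) {
  dup <- unique(rownames(vals)[duplicated(rownames(vals))])
  if (length(dup) == 0L) return(vals)
  keep <- rep(TRUE, nrow(vals))
  for (g in dup) {
    idx <- which(rownames(vals) == g)
    mads <- apply(vals[idx, , drop = FALSE], 1, stats::mad)
    keep[idx] <- FALSE
    keep[idx[which.max(mads)]] <- TRUE
  }
  message(sprintf("collapsed %d duplicate symbol(s) by max MAD: %s",
                  length(dup), paste(dup, collapse = ", ")))
  vals[keep, , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' Genes sorted by symbol, samples in their stored order, so repeated writes
#' of the same object are byte-identical.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values[order(rownames(expr$values)), , drop = FALSE]
  df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}
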