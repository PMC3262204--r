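#' Expression matrix container
#'
#' A light S3 container for a probe-by-sample expression grid together with a
#' tag recording which value space it lives in: raw scanner intensities,
#' quantile-normalized intensities, or log2 ratios to the per-probe mean.
#' Probes are rows, samples are columns; row and column names are the probe
#' and sample identifiers and must be unique.
#'
#' @param values numeric matrix with unique, non-empty rownames (probe IDs)
#'   and colnames (sample IDs).
#' @param value_space one of `"raw"`, `"normalized"`, `"log2ratio"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, value_space = c("raw", "normalized", "log2ratio")) {
  value_space <- match.arg(value_space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe IDs as rownames and sample IDs as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  if (value_space %in% c("raw", "normalized") && any(values < 0))
    stop("negative values are not allowed in ", value_space, " intensity space",
         call. = FALSE)
  structure(list(values = values, value_space = value_space),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [%s space]\n",
              nrow(x$values), ncol(x$values), x$value_space))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr_matrix
#' @export
value_space <- function(x) x$value_space

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read / write expression matrices as tab-delimited text
#'
#' The on-disk format is a TSV with probe IDs in the first column (header
#' `probe_id`) and one column per sample.
#'
#' @param path file path.
#' @param value_space value-space tag to attach on read (the text format does
#'   not store it).
#' @return `read_expr_matrix` returns an [expr_matrix()];
#'   `write_expr_matrix` returns `path` invisibly.
#' @export
read_expr_matrix <- function(path, value_space = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("expected first column 'probe_id' in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  expr_matrix(m, value_space)
}

#' @rdname read_expr_matrix
#' @param x an `expr_matrix`.
#' @export
write_expr_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probe_id = probe_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probe-to-gene annotation tables
#'
#' An annotation is a data frame with columns `probe_id` and `gene_symbol`
#' (symbols upper-cased, one symbol per probe). Stored as two-column TSV.
#'
#' @param probe_id character vector of probe identifiers.
#' @param gene_symbol character vector of gene symbols, same length.
#' @return a `data.frame` with validated columns.
#' @export
probe_annotation <- function(probe_id, gene_symbol) {
  probe_id <- as.character(probe_id)
  gene_symbol <- toupper(as.character(gene_symbol))
  if (length(probe_id) != length(gene_symbol))
    stop("probe_id and gene_symbol lengths differ", call. = FALSE)
  if (anyDuplicated(probe_id))
    stop("duplicate probe IDs in annotation", call. = FALSE)
  if (any(!nzchar(gene_symbol)) || anyNA(gene_symbol))
    stop("empty gene symbols in annotation", call. = FALSE)
  data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
             stringsAsFactors = FALSE)
}

#' @rdname probe_annotation
#' @param path file path.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_annotation(df$probe_id, df$gene_symbol)
}

#' @rdname probe_annotation
#' @param annotation an annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene signatures (named gene-symbol sets)
#'
#' @param name signature name.
#' @param genes character vector of gene symbols (upper-cased, de-duplicated).
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  if (!nzchar(name)) stop("signature name must be non-empty", call. = FALSE)
  if (length(genes) == 0) stop("signature '", name, "' is empty", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @rdname gene_signature
#' @param path file path; the on-disk format is one gene symbol per line.
#' @export
read_signature <- function(path, name = basename(path)) {
  gene_signature(name, readLines(path, warn = FALSE))
}

#' @rdname gene_signature
#' @param x a `gene_signature`.
#' @export
write_signature <- function(x, path) {
  writeLines(x$genes, path)
  invisible(path)
}
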