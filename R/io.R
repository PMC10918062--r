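# On-disk formats. Everything is tab-separated UTF-8 with Unix newlines;
# count matrices are integer, feature x sample, first column = feature id.

#' Validate a count matrix
#'
#' Checks the invariants of a count matrix: a numeric matrix with unique,
#' non-empty feature (row) and sample (column) identifiers and nonnegative
#' integer-valued cells, no missing values.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, if valid; otherwise a classed error.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    value_error("count matrix must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    value_error("count matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    duplicate_error("duplicate feature identifiers in count matrix")
  if (anyDuplicated(colnames(counts)))
    duplicate_error("duplicate sample identifiers in count matrix")
  if (any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts))))
    value_error("empty identifier in count matrix")
  if (anyNA(counts))
    value_error("missing values are not permitted in count matrices")
  if (any(counts < 0) || any(counts != floor(counts)))
    value_error("counts must be nonnegative integers")
  invisible(counts)
}

split_tsv_lines <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) format_error(sprintf("empty file: %s", path))
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a count matrix from TSV
#'
#' The first row is the sample header; each remaining row is a feature
#' identifier followed by one integer count per sample. In the
#' `"named-first-column"` dialect (the canonical output format) the header
#' carries a name for the identifier column; in the `"plain"` dialect the
#' header holds only the sample identifiers.
#'
#' @param path path to a TSV file.
#' @param dialect header dialect, see Details.
#' @return integer matrix with feature rownames and sample colnames, row and
#'   column order as in the file.
#' @seealso [write_count_matrix()] for the byte-stable inverse.
#' @export
read_count_matrix <- function(path, dialect = c("named-first-column", "plain")) {
  dialect <- match.arg(dialect)
  fields <- split_tsv_lines(path)
  header <- fields[[1L]]
  samples <- if (dialect == "named-first-column") header[-1L] else header
  if (length(samples) < 1L) format_error(sprintf("no sample columns in %s", path))
  if (anyDuplicated(samples))
    duplicate_error(sprintf("duplicate sample identifier in header of %s", path))
  body <- fields[-1L]
  nf <- lengths(body)
  bad <- which(nf != length(samples) + 1L)
  if (length(bad))
    format_error(sprintf("line %d of %s has %d fields, expected %d",
                         bad[1L] + 1L, path, nf[bad[1L]], length(samples) + 1L))
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids))
    duplicate_error(sprintf("duplicate feature identifier '%s' in %s",
                            ids[duplicated(ids)][1L], path))
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad)) {
    line <- (bad[1L] - 1L) %/% length(samples) + 2L
    value_error(sprintf("negative or non-integer count '%s' at line %d of %s",
                        raw[bad[1L]], line, path))
  }
  m <- matrix(num, nrow = length(ids), ncol = length(samples), byrow = TRUE,
              dimnames = list(ids, samples))
  validate_count_matrix(m)
  m
}

#' Write a count matrix to TSV
#'
#' Canonical serialization: `"named-first-column"` header, tab separators,
#' Unix newlines, UTF-8. Writing the result of [read_count_matrix()] on a
#' canonical file reproduces the file byte for byte.
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @param id_name name of the identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_name = "feature") {
  validate_count_matrix(counts)
  header <- paste(c(id_name, colnames(counts)), collapse = "\t")
  rows <- paste(rownames(counts),
                apply(counts, 1L, function(r)
                  paste(format(r, scientific = FALSE, trim = TRUE),
                        collapse = "\t")),
                sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a miRNA-to-target map
#'
#' Two dialects are supported. `"two-column"`: a header `mirna<TAB>gene`
#' followed by one pair per line. `"targetscan-export"`: a wider table in the
#' style of TargetScan's downloadable predicted-target files, from which the
#' miRNA and gene-symbol columns are extracted by name (`mirna_col`,
#' `gene_col`); all other columns are ignored. Duplicate pairs are collapsed
#' and the number of unique pairs is reported via `message()`.
#'
#' @param path path to a TSV file.
#' @param dialect input dialect.
#' @param mirna_col,gene_col column names holding the miRNA identifier and
#'   gene symbol in the `"targetscan-export"` dialect.
#' @param strip_prefix optional species prefix (e.g. `"mmu-"`) stripped from
#'   miRNA identifiers before matching; identifiers are otherwise matched
#'   exactly and case-sensitively.
#' @return data.frame with character columns `mirna` and `gene`, one row per
#'   unique pair.
#' @export
read_target_map <- function(path,
                            dialect = c("two-column", "targetscan-export"),
                            mirna_col = "miRNA", gene_col = "Gene Symbol",
                            strip_prefix = NULL) {
  dialect <- match.arg(dialect)
  fields <- split_tsv_lines(path)
  header <- fields[[1L]]
  if (dialect == "two-column") {
    if (length(header) < 2L || header[1L] != "mirna" || header[2L] != "gene")
      format_error(sprintf("expected header 'mirna\\tgene' in %s", path))
    i_mir <- 1L; i_gene <- 2L
  } else {
    i_mir <- match(mirna_col, header)
    i_gene <- match(gene_col, header)
    if (is.na(i_mir))
      format_error(sprintf("column '%s' not found in %s", mirna_col, path))
    if (is.na(i_gene))
      format_error(sprintf("column '%s' not found in %s", gene_col, path))
  }
  body <- fields[-1L]
  need <- max(i_mir, i_gene)
  bad <- which(lengths(body) < need)
  if (length(bad))
    format_error(sprintf("line %d of %s has fewer than %d fields",
                         bad[1L] + 1L, path, need))
  mirna <- vapply(body, `[[`, "", i_mir)
  gene <- vapply(body, `[[`, "", i_gene)
  if (any(!nzchar(mirna)) || any(!nzchar(gene)))
    value_error(sprintf("empty identifier in target map %s", path))
  if (!is.null(strip_prefix))
    mirna <- sub(paste0("^", strip_prefix), "", mirna)
  pairs <- data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE)
  n_in <- nrow(pairs)
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  message(sprintf("target map: %d unique pairs (%d duplicate rows collapsed)",
                  nrow(pairs), n_in - nrow(pairs)))
  pairs
}

#' Read sample metadata
#'
#' TSV with header `sample<TAB>group`; sample order in the file is preserved.
#'
#' @param path path to a TSV file.
#' @return data.frame with character columns `sample` and `group`.
#' @export
read_metadata <- function(path) {
  fields <- split_tsv_lines(path)
  header <- fields[[1L]]
  if (length(header) < 2L || header[1L] != "sample" || header[2L] != "group")
    format_error(sprintf("expected header 'sample\\tgroup' in %s", path))
  body <- fields[-1L]
  if (length(body) == 0L) format_error(sprintf("no samples in %s", path))
  bad <- which(lengths(body) < 2L)
  if (length(bad))
    format_error(sprintf("line %d of %s has fewer than 2 fields",
                         bad[1L] + 1L, path))
  meta <- data.frame(sample = vapply(body, `[[`, "", 1L),
                     group = vapply(body, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample))
    duplicate_error(sprintf("duplicate sample '%s' in %s",
                            meta$sample[duplicated(meta$sample)][1L], path))
  meta
}

#' Write a results table to TSV
#'
#' Deterministic serialization of a data.frame: declared column order, reals
#' at 6 significant digits, Unix newlines. The same table always produces
#' identical bytes.
#'
#' @param table data.frame; list columns are not supported.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path) {
  if (!is.data.frame(table)) value_error("'table' must be a data.frame")
  cols <- lapply(table, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  header <- paste(names(table), collapse = "\t")
  lines <- if (nrow(table) == 0L) header else
    c(header, do.call(paste, c(cols, sep = "\t")))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) io_error(sprintf("cannot write %s", path)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# read back a results table (stage plumbing)
read_results_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# read a real-valued feature x sample matrix written by write_norm_matrix()
read_norm_matrix <- function(path, log2 = FALSE, pseudocount = if (log2) 1 else 0) {
  df <- read_results_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  new_norm_matrix(m, log2 = log2, pseudocount = pseudocount)
}

write_norm_matrix <- function(norm, path, id_name = "feature") {
  m <- unclass(norm)
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_name
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_results_table(df, path)
}
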