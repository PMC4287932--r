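#' Read a gene-by-sample expression matrix
#'
#' Supports plain TSV (first column gene identifiers, header row of sample
#' identifiers) and GCT 1.2 (a `#1.2` version line, a `nrow TAB ncol`
#' dimension line, then a table with `Name` and `Description` columns).
#' Values are assumed to be on a log2 scale; the package never re-normalizes.
#'
#' Duplicate gene rows are collapsed by their arithmetic mean on the log2
#' scale with a warning, matching common probe-collapse practice. Rows that
#' are missing in every sample are dropped. Sample order is never changed;
#' gene order follows the file (after collapsing duplicates at the position
#' of first occurrence).
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (default: by extension), `"tsv"`, `"gct"`.
#' @return A numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  mat <- if (format == "gct") .read_gct(path) else .read_tsv_matrix(path)
  validate_expression(mat, collapse_duplicates = TRUE)
}

.parse_numeric_cells <- function(df, path) {
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "" & col != "NA" & is.na(suppress))
      if (length(bad))
        stop("non-numeric value '", col[bad[1L]], "' in ", path,
             " at data row ", bad[1L], ", sample column '", names(df)[j], "'")
      df[[j]] <- suppress
    }
  }
  df
}

.read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("malformed TSV header in ", path,
         ": need a gene column plus at least one sample column")
  genes <- trimws(df[[1L]])
  vals <- .parse_numeric_cells(df[-1L], path)
  m <- as.matrix(vals)
  rownames(m) <- genes
  colnames(m) <- trimws(names(vals))
  m
}

.read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[[1L]]) != "#1.2")
    stop("malformed GCT: first line must be '#1.2' in ", path)
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[[2L]]),
                                               "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("malformed GCT: second line must declare 'nrow TAB ncol' in ", path)
  df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L || !identical(tolower(names(df)[1:2]),
                                  c("name", "description")))
    stop("malformed GCT: expected 'Name' and 'Description' columns in ", path)
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
    stop("GCT dimension mismatch in ", path, ": declared ", dims[1L], " x ",
         dims[2L], " but found ", nrow(df), " x ", ncol(df) - 2L)
  genes <- trimws(df[[1L]])
  vals <- .parse_numeric_cells(df[-(1:2)], path)
  m <- as.matrix(vals)
  rownames(m) <- genes
  colnames(m) <- trimws(names(vals))
  m
}

#' Validate (and optionally tidy) an expression matrix
#'
#' Checks the invariants every downstream computation relies on: a numeric
#' matrix with at least 2 genes and 1 sample, unique gene and sample
#' identifiers, and no infinite values. `NA` values are permitted and are
#' excluded per sample at ranking time.
#'
#' @param mat Numeric matrix with rownames (genes) and colnames (samples).
#' @param collapse_duplicates Collapse duplicate gene rows by mean (with a
#'   warning) instead of failing.
#' @return The validated matrix.
#' @export
validate_expression <- function(mat, collapse_duplicates = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must have gene rownames and sample colnames")
  rownames(mat) <- trimws(rownames(mat))
  colnames(mat) <- trimws(colnames(mat))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "))
  if (anyDuplicated(rownames(mat))) {
    if (!collapse_duplicates)
      stop("duplicate gene identifiers: ",
           paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                 collapse = ", "))
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning("collapsing ", length(dup),
            " duplicated gene identifier(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    first <- !duplicated(rownames(mat))
    collapsed <- mat[first, , drop = FALSE]
    for (g in dup)
      collapsed[g, ] <- colMeans(mat[rownames(mat) == g, , drop = FALSE],
                                 na.rm = TRUE)
    collapsed[is.nan(collapsed)] <- NA_real_
    mat <- collapsed
  }
  all_missing <- rowSums(!is.na(mat)) == 0L
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " gene row(s) missing in every sample")
    mat <- mat[!all_missing, , drop = FALSE]
  }
  if (nrow(mat) < 2L || ncol(mat) < 1L)
    stop("expression matrix must have at least 2 genes and 1 sample")
  if (any(is.infinite(mat)))
    stop("expression matrix contains infinite values")
  mat
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param mat Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"gct"`.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must have dimnames")
  if (format == "tsv") {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
    df <- data.frame(Name = rownames(mat), Description = "na", mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
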