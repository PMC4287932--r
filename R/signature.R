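#' Construct an EMT signature
#'
#' An EMT signature is a pair of disjoint gene lists: epithelial (Epi) genes,
#' expected to be expressed in epithelial-like samples, and mesenchymal (Mes)
#' genes, expected in mesenchymal-like samples. Signatures may carry
#' non-negative per-gene weights produced by signature combination; the
#' two-sample KS score itself is unweighted and ignores them.
#'
#' Gene identifiers are matched by exact string comparison after trimming
#' surrounding whitespace; no alias resolution is attempted.
#'
#' @param epi_genes Character vector of epithelial gene identifiers.
#' @param mes_genes Character vector of mesenchymal gene identifiers.
#' @param weights Optional named numeric vector of non-negative weights, one
#'   per signature gene. Missing genes default to weight 1.
#' @param source Free-text provenance string.
#' @return An object of class `emt_signature`: a list with elements
#'   `epi_genes`, `mes_genes`, `weights` (always fully populated, default 1)
#'   and `source`.
#' @examples
#' sig <- emt_signature(c("CDH1", "KRT19"), c("VIM", "ZEB1", "SNAI1"))
#' sig
#' @export
emt_signature <- function(epi_genes, mes_genes, weights = NULL, source = "") {
  epi_genes <- trimws(as.character(epi_genes))
  mes_genes <- trimws(as.character(mes_genes))
  if (length(epi_genes) == 0L || length(mes_genes) == 0L)
    stop("both 'epi_genes' and 'mes_genes' must be non-empty")
  if (anyDuplicated(epi_genes)) {
    warning("duplicate Epi genes removed: ",
            paste(unique(epi_genes[duplicated(epi_genes)]), collapse = ", "))
    epi_genes <- unique(epi_genes)
  }
  if (anyDuplicated(mes_genes)) {
    warning("duplicate Mes genes removed: ",
            paste(unique(mes_genes[duplicated(mes_genes)]), collapse = ", "))
    mes_genes <- unique(mes_genes)
  }
  both <- intersect(epi_genes, mes_genes)
  if (length(both))
    stop("genes assigned to both Epi and Mes: ", paste(both, collapse = ", "))
  all_genes <- c(epi_genes, mes_genes)
  w <- stats::setNames(rep(1, length(all_genes)), all_genes)
  if (!is.null(weights)) {
    if (is.null(names(weights)))
      stop("'weights' must be a named numeric vector")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("'weights' must be finite and non-negative")
    unknown <- setdiff(names(weights), all_genes)
    if (length(unknown))
      stop("weights given for genes not in the signature: ",
           paste(unknown, collapse = ", "))
    w[names(weights)] <- weights
  }
  structure(
    list(epi_genes = epi_genes, mes_genes = mes_genes,
         weights = w, source = as.character(source)[1L]),
    class = "emt_signature")
}

#' @export
print.emt_signature <- function(x, ...) {
  cat("EMT signature: ", length(x$epi_genes), " Epi genes, ",
      length(x$mes_genes), " Mes genes\n", sep = "")
  if (nzchar(x$source)) cat("source: ", x$source, "\n", sep = "")
  show <- function(g) paste(utils::head(g, 6),
                            collapse = ", ")
  cat("Epi: ", show(x$epi_genes),
      if (length(x$epi_genes) > 6) ", ..." else "", "\n", sep = "")
  cat("Mes: ", show(x$mes_genes),
      if (length(x$mes_genes) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Parses the standard MSigDB GMT dialect: one set per line, with fields
#' `name TAB description TAB gene1 TAB gene2 ...`. The description field is
#' discarded. Duplicate genes within a set are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per gene set), in file
#'   order. An empty file yields an empty list.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L)
      stop("GMT parse error at line ", i,
           ": expected at least 3 tab-separated fields (name, description, genes)")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " ('", fields[1L],
              "'): duplicate genes removed")
      genes <- unique(genes)
    }
    nms[i] <- fields[1L]
    sets[[i]] <- genes
  }
  stats::setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a fully named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an EMT signature from a TSV table
#'
#' The table must carry columns `gene` and `direction` (tokens `Epi` or
#' `Mes`) and may carry a numeric `weight` column; when `weight` is absent
#' every gene receives weight 1.
#'
#' @param path Path to a tab-separated signature table.
#' @return An [emt_signature()].
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("signature table missing column(s): ", paste(miss, collapse = ", "))
  df$gene <- trimws(df$gene)
  df$direction <- trimws(df$direction)
  bad <- setdiff(unique(df$direction), c("Epi", "Mes"))
  if (length(bad))
    stop("invalid direction token(s): ", paste(bad, collapse = ", "),
         " (expected 'Epi' or 'Mes')")
  dup <- unique(df$gene[duplicated(df$gene)])
  conflict <- dup[vapply(dup, function(g)
    length(unique(df$direction[df$gene == g])) > 1L, logical(1L))]
  if (length(conflict))
    stop("gene(s) listed with both directions: ",
         paste(conflict, collapse = ", "))
  df <- df[!duplicated(df$gene), , drop = FALSE]
  w <- if ("weight" %in% names(df)) {
    if (!is.numeric(df$weight)) stop("'weight' column must be numeric")
    stats::setNames(df$weight, df$gene)
  } else NULL
  emt_signature(df$gene[df$direction == "Epi"],
                df$gene[df$direction == "Mes"],
                weights = w,
                source = path)
}

#' Write an EMT signature to a TSV table
#'
#' Writes columns `gene`, `direction`, `weight`; `read_signature()` on the
#' result reproduces the gene lists and weights exactly.
#'
#' @param sig An [emt_signature()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "emt_signature"))
  genes <- c(sig$epi_genes, sig$mes_genes)
  df <- data.frame(
    gene = genes,
    direction = c(rep("Epi", length(sig$epi_genes)),
                  rep("Mes", length(sig$mes_genes))),
    weight = unname(sig$weights[genes]),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
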