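#' Single-sample GSEA enrichment score
#'
#' Computes the single-sample gene set enrichment score of one gene set in
#' one sample: genes are ordered by descending expression, an in-set
#' cumulative mass `P_in` (each in-set gene weighted by its ascending
#' expression rank raised to `alpha`, normalized to total 1) and a uniform
#' out-of-set cumulative mass `P_out` are accumulated along the ordering,
#' and the score is the running sum of their differences,
#' `sum_i (P_in(i) - P_out(i))`. With `alpha = 0` every in-set gene carries
#' equal weight, and the score is positive when the set concentrates at high
#' expression, negative at low expression.
#'
#' Ties in expression are broken by current gene order (stable), which only
#' matters for tied genes straddling the set boundary.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param sample_id Sample to score.
#' @param gene_set Character vector of gene identifiers.
#' @param alpha Rank-weight exponent in `[0, 1]` (default 0.25).
#' @param set_name Label stored in the result (defaults to a deparse of the
#'   set argument when unnamed).
#' @return One-row data.frame with columns `sample_id`, `set_name`, `es`.
#' @export
ssgsea_es <- function(mat, sample_id, gene_set, alpha = 0.25,
                      set_name = "set") {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]")
  if (!sample_id %in% colnames(mat))
    stop("unknown sample id: ", sample_id)
  x <- mat[, sample_id]
  x <- x[!is.na(x)]
  gene_set <- unique(trimws(gene_set))
  inset <- names(x) %in% gene_set
  n_in <- sum(inset)
  if (n_in == 0L) stop("gene set '", set_name,
                       "' has no genes in the matrix")
  if (n_in == length(x))
    stop("gene set '", set_name, "' covers every gene; complement is empty")
  r <- rank(x, ties.method = "average")      # ascending rank = weight base
  ord <- order(x, decreasing = TRUE)         # descending expression walk
  in_ord <- inset[ord]
  w <- ifelse(in_ord, r[ord]^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (length(x) - n_in)
  data.frame(sample_id = sample_id, set_name = set_name,
             es = sum(p_in - p_out), stringsAsFactors = FALSE)
}

#' ssGSEA scores for all samples and gene sets
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param alpha Rank-weight exponent, see [ssgsea_es()].
#' @return Long-format data.frame with columns `sample_id`, `set_name`,
#'   `es`, ordered set-major then sample.
#' @export
ssgsea <- function(mat, gene_sets, alpha = 0.25) {
  mat <- validate_expression(mat)
  if (!length(gene_sets)) stop("'gene_sets' is empty")
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  out <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    do.call(rbind, lapply(colnames(mat), function(s)
      ssgsea_es(mat, s, gene_sets[[nm]], alpha = alpha, set_name = nm)))
  }))
  rownames(out) <- NULL
  out
}

#' Correlate enrichment scores with marker-gene expression
#'
#' Spearman correlation of a per-sample enrichment score with each marker
#' gene's expression across samples. Canonical EMT markers are mesenchymal
#' TWIST1, SNAI1, SNAI2, VIM, CDH2, ZEB1 and epithelial CDH1, DDR1, ERBB2,
#' ERBB3, KRT19; markers absent from the matrix are reported as missing,
#' not errors.
#'
#' @param es Named numeric vector of enrichment scores (names = sample ids).
#' @param mat Numeric gene-by-sample matrix containing those samples.
#' @param markers Character vector of marker gene identifiers.
#' @return data.frame with columns `marker`, `rho`, `pvalue`, `present`.
#' @export
marker_correlation <- function(es, mat, markers) {
  if (is.null(names(es))) stop("'es' must be named by sample id")
  samples <- intersect(names(es), colnames(mat))
  if (length(samples) < 3L)
    stop("need at least 3 samples shared between 'es' and 'mat'")
  markers <- unique(trimws(markers))
  present <- markers %in% rownames(mat)
  if (!any(present)) stop("none of the markers are present in the matrix")
  rows <- lapply(seq_along(markers), function(i) {
    if (!present[i])
      return(data.frame(marker = markers[i], rho = NA_real_,
                        pvalue = NA_real_, present = FALSE,
                        stringsAsFactors = FALSE))
    sa <- spearman_association(es[samples], mat[markers[i], samples])
    data.frame(marker = markers[i], rho = sa$rho, pvalue = sa$pvalue,
               present = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Canonical EMT marker genes used to orient published sets.
.default_mes_markers <- c("TWIST1", "SNAI1", "SNAI2", "VIM", "CDH2", "ZEB1")
.default_epi_markers <- c("CDH1", "DDR1", "ERBB2", "ERBB3", "KRT19")
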