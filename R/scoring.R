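#' Rank the genes of one sample
#'
#' Ranks are ascending in expression (1 = lowest) with mid-ranks for ties.
#' Genes with a missing value in this sample are excluded from this sample's
#' ranking only; other samples are unaffected.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param sample_id Column identifier of the sample.
#' @return Named numeric vector of ranks over the genes observed in the
#'   sample.
#' @export
rank_sample <- function(mat, sample_id) {
  if (!sample_id %in% colnames(mat))
    stop("unknown sample id: ", sample_id)
  x <- mat[, sample_id]
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop("sample '", sample_id, "' has fewer than 2 observed genes")
  rank(x, ties.method = "average")
}

# Signed supremum deviation between the Epi and Mes rank ECDFs evaluated on
# the shared rank axis. Returns the signed score, the KS statistic D and the
# two one-sided sups.
.ks_signed <- function(epi_ranks, mes_ranks) {
  pts <- sort(unique(c(epi_ranks, mes_ranks)))
  fe <- findInterval(pts, sort(epi_ranks)) / length(epi_ranks)
  fm <- findInterval(pts, sort(mes_ranks)) / length(mes_ranks)
  d_plus <- max(fe - fm, 0)   # ECDF_Epi above ECDF_Mes -> Mes-like
  d_minus <- max(fm - fe, 0)
  score <- if (d_plus > d_minus) d_plus else if (d_minus > d_plus) -d_minus else 0
  list(score = score, d = max(d_plus, d_minus),
       d_plus = d_plus, d_minus = d_minus)
}

#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Two-sided p-value for an observed two-sample KS statistic `d_stat` with
#' group sizes `n_epi` and `n_mes`. The default is the asymptotic Kolmogorov
#' distribution evaluated at `sqrt(n_eff) * d` with effective size
#' `n_epi * n_mes / (n_epi + n_mes)`. With `exact = TRUE` (available for
#' `n_epi + n_mes <= 20`) the p-value is computed by exhaustive enumeration
#' of all label assignments of untied rank positions, i.e. the permutation
#' null `P(D >= d_stat)`.
#'
#' @param d_stat KS statistic in `[0, 1]`.
#' @param n_epi,n_mes Gene-set sizes used to form the two ECDFs.
#' @param exact Use the exhaustive permutation null (small sets only).
#' @return A p-value in `[0, 1]`.
#' @export
ks_pvalue <- function(d_stat, n_epi, n_mes, exact = FALSE) {
  if (!is.finite(d_stat) || d_stat < 0 || d_stat > 1)
    stop("'d_stat' must lie in [0, 1]")
  if (n_epi < 1L || n_mes < 1L) stop("'n_epi' and 'n_mes' must be >= 1")
  if (exact) {
    n <- n_epi + n_mes
    if (n > 20L)
      stop("exact p-value supported only for n_epi + n_mes <= 20")
    splits <- utils::combn(n, n_epi)
    dperm <- apply(splits, 2L, function(idx)
      .ks_signed(idx, setdiff(seq_len(n), idx))$d)
    return(mean(dperm >= d_stat - 1e-12))
  }
  lambda <- sqrt(n_epi * n_mes / (n_epi + n_mes)) * d_stat
  if (lambda < 1e-3) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Classify samples by EMT score and KS p-value
#'
#' Follows the four-way segregation into `Mes` (positive score, significant),
#' `intermediate-Mes` (positive, not significant), `intermediate-Epi`
#' (non-positive, not significant) and `Epi` (negative, significant). A score
#' of exactly 0 is assigned `intermediate-Epi` (documented tie rule). The
#' conventional threshold is 0.05; a stricter 0.001 cut is sometimes used to
#' call only extreme phenotypes.
#'
#' @param emt_score Numeric vector of signed EMT scores.
#' @param ks_pvalue Numeric vector of KS p-values (recycled if length 1).
#' @param p_threshold Significance threshold in (0, 1).
#' @return Character vector over
#'   `c("Epi", "intermediate-Epi", "intermediate-Mes", "Mes")`.
#' @export
classify <- function(emt_score, ks_pvalue, p_threshold = 0.05) {
  if (!is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop("'p_threshold' must lie strictly inside (0, 1)")
  n <- max(length(emt_score), length(ks_pvalue))
  s <- rep_len(emt_score, n)
  p <- rep_len(ks_pvalue, n)
  out <- ifelse(is.na(s) | is.na(p), NA_character_,
         ifelse(s > 0,
                ifelse(p < p_threshold, "Mes", "intermediate-Mes"),
         ifelse(s < 0,
                ifelse(p < p_threshold, "Epi", "intermediate-Epi"),
                "intermediate-Epi")))
  out
}

#' EMT score of one sample
#'
#' The EMT score is the signed two-sample Kolmogorov-Smirnov statistic
#' comparing the empirical cumulative distribution functions of the Epi and
#' Mes signature genes over the sample's ascending-expression gene ranks.
#' When Mes genes sit at high ranks, `ECDF_Epi` rises first and exceeds
#' `ECDF_Mes`, giving a positive score: positive = mesenchymal-like,
#' negative = epithelial-like, with extremes at +1 and -1. `|score|` is the
#' classical KS statistic `D`, from which the p-value is computed; in the
#' measure-zero event that the two one-sided suprema tie exactly, the score
#' is 0 (and the sample is intermediate).
#'
#' @param mat Numeric gene-by-sample matrix (log2 scale).
#' @param sample_id Sample to score.
#' @param signature An [emt_signature()].
#' @param p_threshold Significance threshold for classification.
#' @param exact_p Use the exhaustive permutation p-value (small signatures).
#' @param min_genes Minimum number of genes of each set that must be present
#'   in the matrix (default 3); below this the sample cannot be scored.
#' @return One-row data.frame with columns `sample_id`, `emt_score`,
#'   `ks_pvalue`, `class`, `n_epi_used`, `n_mes_used`.
#' @examples
#' m <- matrix(1:10, nrow = 10,
#'             dimnames = list(paste0("g", 1:10), "s1"))
#' m <- cbind(m, s2 = 11:20)
#' sig <- emt_signature(paste0("g", 1:3), paste0("g", 8:10))
#' emt_score(m, "s1", sig)
#' @export
emt_score <- function(mat, sample_id, signature, p_threshold = 0.05,
                      exact_p = FALSE, min_genes = 3L) {
  stopifnot(inherits(signature, "emt_signature"))
  r <- rank_sample(mat, sample_id)
  epi <- intersect(signature$epi_genes, names(r))
  mes <- intersect(signature$mes_genes, names(r))
  if (length(epi) < min_genes || length(mes) < min_genes)
    stop("signature coverage too low in sample '", sample_id, "': ",
         length(epi), " of ", length(signature$epi_genes), " Epi and ",
         length(mes), " of ", length(signature$mes_genes),
         " Mes genes present (need >= ", min_genes, " each)")
  if (length(epi) < 0.5 * length(signature$epi_genes) ||
      length(mes) < 0.5 * length(signature$mes_genes))
    warning("less than 50% of the signature found in sample '", sample_id, "'")
  ks <- .ks_signed(r[epi], r[mes])
  p <- ks_pvalue(ks$d, length(epi), length(mes), exact = exact_p)
  data.frame(sample_id = sample_id,
             emt_score = ks$score,
             ks_pvalue = p,
             class = classify(ks$score, p, p_threshold),
             n_epi_used = length(epi),
             n_mes_used = length(mes),
             stringsAsFactors = FALSE)
}

#' EMT scores for every sample of a matrix
#'
#' Applies [emt_score()] to each sample in column order. Samples whose
#' signature coverage is below `min_genes` yield a flagged record (`NA`
#' score, message in `note`) rather than aborting the whole matrix.
#'
#' @inheritParams emt_score
#' @return A data.frame of class `emt_scores`, one row per sample, with the
#'   columns of [emt_score()] plus `note` (empty when scoring succeeded).
#' @export
score_matrix <- function(mat, signature, p_threshold = 0.05,
                         exact_p = FALSE, min_genes = 3L) {
  mat <- validate_expression(mat)
  rows <- lapply(colnames(mat), function(s) {
    res <- tryCatch(
      emt_score(mat, s, signature, p_threshold, exact_p, min_genes),
      error = function(e) {
        epi <- intersect(signature$epi_genes, rownames(mat))
        mes <- intersect(signature$mes_genes, rownames(mat))
        data.frame(sample_id = s, emt_score = NA_real_,
                   ks_pvalue = NA_real_, class = NA_character_,
                   n_epi_used = length(epi), n_mes_used = length(mes),
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
    if (is.null(res$note)) res$note <- ""
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("emt_scores", "data.frame")
  out
}

#' @export
print.emt_scores <- function(x, ...) {
  cat("EMT scores for ", nrow(x), " sample(s)\n", sep = "")
  cls <- table(factor(x$class,
                      c("Epi", "intermediate-Epi", "intermediate-Mes", "Mes")))
  cat("classes: ", paste(names(cls), cls, sep = "=", collapse = "  "), "\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

#' Spearman association between EMT scores and a covariate
#'
#' Used, e.g., to relate EMT scores to drug response (IC50) across samples.
#' Pairs with a missing value in either vector are dropped.
#'
#' @param scores Named or plain numeric vector.
#' @param covariate Numeric vector of equal length (pairing by position).
#' @return List with elements `rho`, `pvalue`, `n`.
#' @export
spearman_association <- function(scores, covariate) {
  if (length(scores) != length(covariate))
    stop("'scores' and 'covariate' must have equal length")
  keep <- is.finite(scores) & is.finite(covariate)
  if (sum(keep) < 3L)
    stop("need at least 3 complete pairs; got ", sum(keep))
  ct <- suppressWarnings(
    stats::cor.test(scores[keep], covariate[keep], method = "spearman"))
  list(rho = unname(ct$estimate), pvalue = ct$p.value, n = sum(keep))
}

#' Mann-Whitney comparison of EMT scores between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, e.g. spindle vs
#' non-spindle morphology groups. With complete ties across the two groups
#' the reported p-value is the maximal tie-corrected value (1).
#'
#' @param scores Numeric vector.
#' @param labels Two-level grouping vector of the same length.
#' @return List with `u_stat` (U of the first level), `pvalue`, `groups`.
#' @export
mannwhitney_groups <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.factor(as.character(labels[keep]))
  lev <- levels(labels)
  if (length(lev) != 2L)
    stop("'labels' must have exactly 2 levels; got ", length(lev))
  x <- scores[labels == lev[1L]]
  y <- scores[labels == lev[2L]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # complete ties: no evidence either way
  list(u_stat = unname(wt$statistic), pvalue = p, groups = lev)
}
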