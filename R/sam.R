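#' Significance Analysis of Microarrays (SAM) between Epi and Mes groups
#'
#' Computes the SAM moderated difference statistic for every gene,
#' `d_g = (mean_Mes - mean_Epi) / (s_g + s0)`, where `s_g` is the pooled
#' standard error of the group-mean difference and `s0` a small positive
#' "fudge factor" stabilizing genes with tiny variance, together with a
#' permutation-based false discovery rate per gene expressed as a q-value in
#' percent (0-100).
#'
#' Group labels are permuted (exhaustively when the number of distinct
#' assignments does not exceed `n_perm`, excluding the observed labeling and
#' its mirror; otherwise `n_perm` seeded random assignments). At the cut
#' `|d| >= |d_g|` the q-value is `100 * F / max(1, C)` where `C` is the
#' observed number of genes called and `F` the expected number of false
#' calls across permutations: the mean per-permutation count by default
#' (`fdr = "mean"`, calibrated so that a pure null yields no q = 0 calls),
#' or the Tusher-style median count (`fdr = "median"`). q-values are capped
#' at 100 and made monotone non-increasing in `|d|`.
#'
#' @param mat Numeric gene-by-sample matrix (log2 scale).
#' @param epi_ids,mes_ids Disjoint sample identifier vectors, each of
#'   size >= 2.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation draw.
#' @param s0 Either a number >= 0, `"p05"` (default: 5th percentile of the
#'   per-gene standard errors) or `"tusher"` (coefficient-of-variation
#'   minimization over the percentile candidates 0, 5, ..., 100).
#' @param fdr `"mean"` (default) or `"median"` false-call count across
#'   permutations.
#' @return Object of class `sam_result`: list with `table` (data.frame
#'   `gene`, `d`, `s`, `fc_log2`, `q_pct`), `s0`, `n_perm_used`,
#'   `exhaustive`, `seed`, `fdr`, `groups`.
#' @export
sam <- function(mat, epi_ids, mes_ids, n_perm = 1000L, seed = 1L,
                s0 = "p05", fdr = c("mean", "median")) {
  fdr <- match.arg(fdr)
  mat <- validate_expression(mat)
  .check_groups(mat, epi_ids, mes_ids, min_size = 2L)
  if (nrow(mat) < 2L) stop("need at least 2 genes")
  # canonical (sorted) sample order, so the permutation universe and the
  # resulting q-values are identical when the two labels are swapped
  ids <- sort(c(epi_ids, mes_ids))
  X <- mat[, ids, drop = FALSE]
  if (anyNA(X)) stop("SAM requires complete values for the selected samples")
  n1 <- length(epi_ids); n2 <- length(mes_ids); n <- n1 + n2
  is_mes <- ids %in% mes_ids

  obs <- .sam_d(X, is_mes, s0 = NULL)
  s0_val <- .sam_s0(obs$d_raw, obs$s, s0)
  d_obs <- obs$num / (obs$s + s0_val)

  # Permute which samples are labeled "group 2" with group sizes fixed;
  # the observed assignment and its mirror are excluded (they reproduce
  # |d| exactly and would bias the false-call count).
  k <- min(n1, n2)
  n_assign <- choose(n, k)
  exhaustive <- n_assign <= n_perm + 2
  obs_idx <- which(if (n2 <= n1) is_mes else !is_mes)
  if (exhaustive) {
    splits <- utils::combn(n, k)
    keep <- apply(splits, 2L, function(s) !identical(s, obs_idx))
    if (n1 == n2)
      keep <- keep & apply(splits, 2L, function(s)
        !identical(setdiff(seq_len(n), s), as.vector(obs_idx)))
    splits <- splits[, keep, drop = FALSE]
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    splits <- replicate(n_perm, sort(sample.int(n, k)))
  }
  B <- ncol(splits)
  # splits mark the smaller group; orient so the sign convention matches
  dperm <- .sam_d_perm(X, splits, s0_val, small_is_mes = (n2 <= n1))

  q <- .sam_q(abs(d_obs), abs(dperm), fdr)
  tab <- data.frame(gene = rownames(X), d = d_obs, s = obs$s,
                    fc_log2 = obs$num, q_pct = q,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, s0 = s0_val, n_perm_used = B,
                 exhaustive = exhaustive, seed = seed, fdr = fdr,
                 groups = list(epi_ids = epi_ids, mes_ids = mes_ids)),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM result: ", nrow(x$table), " genes, groups ",
      length(x$groups$epi_ids), " Epi vs ", length(x$groups$mes_ids),
      " Mes\n", sep = "")
  cat("s0 = ", format(x$s0, digits = 4), "; ", x$n_perm_used,
      if (x$exhaustive) " exhaustive" else " random",
      " permutations (seed ", x$seed, "); fdr = ", x$fdr, "\n", sep = "")
  cat(sum(x$table$q_pct == 0), " gene(s) at q = 0\n", sep = "")
  invisible(x)
}

.check_groups <- function(mat, epi_ids, mes_ids, min_size = 1L) {
  if (length(intersect(epi_ids, mes_ids)))
    stop("'epi_ids' and 'mes_ids' overlap")
  missing <- setdiff(c(epi_ids, mes_ids), colnames(mat))
  if (length(missing))
    stop("sample id(s) not in the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(epi_ids) < min_size || length(mes_ids) < min_size)
    stop("each group needs at least ", min_size, " samples")
  invisible(TRUE)
}

# Observed SAM ingredients for one labeling: numerator mean_Mes - mean_Epi,
# pooled standard error s, and d without fudge factor.
.sam_d <- function(X, is_mes, s0 = NULL) {
  n1 <- sum(!is_mes); n2 <- sum(is_mes)
  m1 <- rowMeans(X[, !is_mes, drop = FALSE])
  m2 <- rowMeans(X[, is_mes, drop = FALSE])
  ss <- rowSums((X[, !is_mes, drop = FALSE] - m1)^2) +
        rowSums((X[, is_mes, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  num <- m2 - m1
  list(num = num, s = s, d_raw = num / s)
}

# Vectorized permutation statistics: splits is a k x B matrix of column
# indices (the smaller group) into X; returns the G x B matrix of permuted
# d values, oriented so the split plays the Mes role when small_is_mes.
.sam_d_perm <- function(X, splits, s0_val, small_is_mes = TRUE) {
  n <- ncol(X); k <- nrow(splits); B <- ncol(splits)
  A <- matrix(0, n, B)
  A[cbind(as.vector(splits), rep(seq_len(B), each = k))] <- 1
  X2 <- X^2
  Ssp <- X %*% A                 # per-perm sums over the split
  Srt <- rowSums(X) - Ssp
  Qsp <- X2 %*% A
  Qrt <- rowSums(X2) - Qsp
  Msp <- Ssp / k; Mrt <- Srt / (n - k)
  ss <- pmax(Qrt - (n - k) * Mrt^2, 0) + pmax(Qsp - k * Msp^2, 0)
  s <- sqrt((1 / k + 1 / (n - k)) * ss / (n - 2))
  if (small_is_mes) (Msp - Mrt) / (s + s0_val)
  else (Mrt - Msp) / (s + s0_val)
}

.sam_s0 <- function(d_raw, s, s0) {
  if (is.numeric(s0)) {
    if (!is.finite(s0) || s0 < 0) stop("numeric 's0' must be >= 0")
    return(s0)
  }
  if (identical(s0, "p05"))
    return(unname(stats::quantile(s, 0.05, names = FALSE)))
  if (identical(s0, "tusher")) return(.sam_s0_tusher(d_raw * s, s))
  stop("'s0' must be a number, \"p05\" or \"tusher\"")
}

# Tusher-style s0: pick the s-quantile candidate minimizing the coefficient
# of variation of the MAD of d across s-percentile bins.
.sam_s0_tusher <- function(num, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE)
  qbins <- cut(s, breaks = unique(stats::quantile(s, seq(0, 1, 0.01))),
               include.lowest = TRUE)
  cv <- vapply(cand, function(s0c) {
    d <- num / (s + s0c)
    v <- tapply(d, qbins, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  cand[which.min(cv)]
}

# q-values in percent at the per-gene cuts |d| >= |d_g|.
.sam_q <- function(abs_d, abs_dperm, fdr) {
  B <- ncol(abs_dperm)
  obs_sorted <- sort(abs_d)
  calls <- length(abs_d) - findInterval(abs_d - 1e-12, obs_sorted)
  if (fdr == "mean") {
    pool <- sort(as.vector(abs_dperm))
    false <- (length(pool) - findInterval(abs_d - 1e-12, pool)) / B
  } else {
    counts <- apply(abs_dperm, 2L, function(col) {
      sc <- sort(col)
      length(sc) - findInterval(abs_d - 1e-12, sc)
    })  # genes x B
    false <- apply(counts, 1L, stats::median)
  }
  q <- 100 * false / pmax(calls, 1L)
  q <- pmin(q, 100)
  ord <- order(abs_d, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q
}

#' Per-gene ROC area for Mes-vs-Epi discrimination
#'
#' For every gene, the area under the ROC curve for discriminating Mes from
#' Epi samples by that gene's expression:
#' `AUC = P(Mes value > Epi value) + 0.5 * P(tie)`, the normalized
#' Mann-Whitney U. Genes higher in Mes score above 0.5, genes higher in Epi
#' below 0.5, constant genes exactly 0.5.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param epi_ids,mes_ids Disjoint non-empty sample identifier vectors.
#' @return data.frame with columns `gene`, `roc`.
#' @export
roc_per_gene <- function(mat, epi_ids, mes_ids) {
  mat <- validate_expression(mat)
  .check_groups(mat, epi_ids, mes_ids, min_size = 1L)
  X <- mat[, c(epi_ids, mes_ids), drop = FALSE]
  if (anyNA(X)) stop("ROC computation requires complete values")
  n1 <- length(epi_ids); n2 <- length(mes_ids)
  R <- t(apply(X, 1L, rank, ties.method = "average"))
  u <- rowSums(R[, n1 + seq_len(n2), drop = FALSE]) - n2 * (n2 + 1) / 2
  data.frame(gene = rownames(X), roc = as.numeric(u / (n1 * n2)),
             stringsAsFactors = FALSE)
}
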