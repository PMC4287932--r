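# Independent brute-force oracles. These deliberately share no code with the
# package internals: everything is computed by explicit scans or loops.

# Two-sample KS by scanning every rank threshold; returns the two one-sided
# suprema and the signed score under the positive-when-Epi-ECDF-leads rule.
brute_ks <- function(epi_ranks, mes_ranks) {
  pts <- sort(unique(c(epi_ranks, mes_ranks)))
  d_plus <- 0; d_minus <- 0
  for (t in pts) {
    fe <- sum(epi_ranks <= t) / length(epi_ranks)
    fm <- sum(mes_ranks <= t) / length(mes_ranks)
    d_plus <- max(d_plus, fe - fm)
    d_minus <- max(d_minus, fm - fe)
  }
  score <- if (d_plus > d_minus) d_plus else if (d_minus > d_plus) -d_minus else 0
  list(d = max(d_plus, d_minus), score = score)
}

# Per-gene ROC AUC by counting all (Mes, Epi) pairs.
brute_auc <- function(epi_vals, mes_vals) {
  wins <- 0
  for (m in mes_vals) for (e in epi_vals)
    wins <- wins + (m > e) + 0.5 * (m == e)
  wins / (length(epi_vals) * length(mes_vals))
}

# Spearman rho by the direct sum-of-squared-rank-differences formula
# (valid for untied data).
brute_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# ssGSEA enrichment score by an explicit position-by-position walk down the
# descending-expression list.
ssgsea_unrolled <- function(x, set, alpha) {
  ord <- order(x, decreasing = TRUE)
  r <- rank(x, ties.method = "average")
  inset <- names(x) %in% set
  denom_in <- sum(r[inset]^alpha)
  n_out <- sum(!inset)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in ord) {
    if (inset[i]) p_in <- p_in + unname(r[i])^alpha / denom_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# SAM d statistic for one labeling, written independently of the package.
brute_sam_d <- function(X, epi_idx, mes_idx, s0) {
  vapply(seq_len(nrow(X)), function(g) {
    xe <- X[g, epi_idx]; xm <- X[g, mes_idx]
    ne <- length(xe); nm <- length(xm)
    sp <- sqrt((1 / ne + 1 / nm) *
               (sum((xe - mean(xe))^2) + sum((xm - mean(xm))^2)) /
               (ne + nm - 2))
    (mean(xm) - mean(xe)) / (sp + s0)
  }, numeric(1))
}

# SAM q-values in percent by explicit loops over all exhaustive label
# assignments (excluding the observed one and its mirror), for either
# false-call rule.
brute_sam_q <- function(X, epi_idx, mes_idx, s0, fdr = "mean") {
  n <- length(epi_idx) + length(mes_idx)
  d_obs <- abs(brute_sam_d(X, epi_idx, mes_idx, s0))
  splits <- combn(n, length(mes_idx))
  cols <- c(epi_idx, mes_idx)
  perm_abs <- list()
  for (b in seq_len(ncol(splits))) {
    mes_b <- cols[splits[, b]]
    epi_b <- setdiff(cols, mes_b)
    if (setequal(mes_b, mes_idx) || setequal(mes_b, epi_idx)) next
    perm_abs[[length(perm_abs) + 1L]] <-
      abs(brute_sam_d(X, epi_b, mes_b, s0))
  }
  q <- numeric(length(d_obs))
  for (g in seq_along(d_obs)) {
    cut <- d_obs[g]
    calls <- sum(d_obs >= cut - 1e-12)
    false_b <- vapply(perm_abs, function(v) sum(v >= cut - 1e-12),
                      numeric(1))
    f <- if (fdr == "mean") mean(false_b) else median(false_b)
    q[g] <- min(100, 100 * f / max(1, calls))
  }
  ord <- order(d_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q
}

# Small labelled expression matrix from a vector/matrix of values.
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  usable <- function(x) !is.null(x) && all(nzchar(x)) && !anyDuplicated(x)
  if (is.null(genes))
    genes <- if (usable(rownames(m))) rownames(m)
             else sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples))
    samples <- if (usable(colnames(m))) colnames(m)
               else sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# A two-group matrix with planted per-gene shifts, for SAM/ROC tests.
toy_groups <- function(n_genes, n_epi, n_mes, shift = 0, sd = 1,
                       seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * (n_epi + n_mes), sd = sd), n_genes)
  X[, n_epi + seq_len(n_mes)] <- X[, n_epi + seq_len(n_mes)] + shift
  dimnames(X) <- list(sprintf("g%03d", seq_len(n_genes)),
                      c(sprintf("e%02d", seq_len(n_epi)),
                        sprintf("m%02d", seq_len(n_mes))))
  X
}
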