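#' Select extreme samples from a phenotype ranking
#'
#' Picks the most mesenchymal and most epithelial samples from a per-sample
#' ranking value (higher = more Mes). In `cell_line` mode the extreme
#' fraction `frac` of each end is taken (`ceiling(frac * n)` per end, capped
#' at `floor(n / 2)` so the groups never overlap); in `tumour` mode a fixed
#' count `n_each` per end (again capped at `floor(n / 2)`).
#'
#' @param ranking Named numeric vector (names = sample ids), higher = Mes.
#' @param mode `"cell_line"` (fraction of each end, default 25%) or
#'   `"tumour"` (fixed count per end, default 100).
#' @param frac Extreme fraction per end in (0, 0.5], cell-line mode.
#' @param n_each Extreme count per end, tumour mode.
#' @return List with character vectors `epi_ids` and `mes_ids` (disjoint).
#' @export
select_extremes <- function(ranking, mode = c("cell_line", "tumour"),
                            frac = 0.25, n_each = 100L) {
  mode <- match.arg(mode)
  if (is.null(names(ranking))) stop("'ranking' must be named by sample id")
  ranking <- ranking[is.finite(ranking)]
  n <- length(ranking)
  if (n < 4L) stop("need at least 4 ranked samples; got ", n)
  if (mode == "cell_line") {
    if (!is.finite(frac) || frac <= 0 || frac > 0.5)
      stop("'frac' must lie in (0, 0.5]")
    m <- min(ceiling(frac * n), floor(n / 2))
  } else {
    if (n_each < 1L) stop("'n_each' must be >= 1")
    m <- min(as.integer(n_each), floor(n / 2))
  }
  ord <- order(ranking, decreasing = TRUE)
  list(epi_ids = names(ranking)[ord[(n - m + 1L):n]],
       mes_ids = names(ranking)[ord[seq_len(m)]])
}

#' Fit an SVD-metagene probit phenotype predictor
#'
#' A deterministic approximation to Bayesian binary regression on metagenes:
#' genes are standardized on the training samples, the top `k` left singular
#' vectors of the standardized training matrix define the metagenes (each
#' vector's sign is fixed so its loading on the Mes-group mean is positive),
#' and a ridge-penalized probit regression of phenotype (Mes = 1, Epi = 0)
#' on the metagene coordinates is fitted by iteratively reweighted least
#' squares. The ridge penalty keeps the fit finite even when the training
#' groups are linearly separable, which is the typical case for extreme
#' phenotype panels.
#'
#' @param mat Numeric gene-by-sample matrix containing the training samples.
#' @param epi_ids,mes_ids Disjoint training sample identifiers, each group
#'   of size >= `k + 1`.
#' @param k Number of metagenes (default 2).
#' @param ridge Ridge penalty on the non-intercept coefficients
#'   (default 1e-3).
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return Object of class `metagene_probit` with the training genes,
#'   per-gene centers/scales, metagene basis `u` (genes x k), probit
#'   coefficients, per-training-sample fitted probabilities and convergence
#'   diagnostics.
#' @seealso [predict.metagene_probit()]
#' @export
fit_metagene_probit <- function(mat, epi_ids, mes_ids, k = 2L, ridge = 1e-3,
                                max_iter = 100L, tol = 1e-8) {
  mat <- validate_expression(mat)
  .check_groups(mat, epi_ids, mes_ids, min_size = k + 1L)
  ids <- c(epi_ids, mes_ids)
  X <- mat[, ids, drop = FALSE]
  if (anyNA(X)) stop("training samples must have complete values")
  if (k < 1L || k > min(dim(X)) - 1L)
    stop("'k' must lie in [1, min(genes, samples) - 1]")
  ctr <- rowMeans(X)
  scl <- apply(X, 1L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- (X - ctr) / scl
  sv <- svd(Xs, nu = k, nv = k)
  if (sv$d[k] < 1e-10 * sv$d[1L])
    stop("'k' = ", k, " exceeds the effective rank of the training matrix")
  u <- sv$u
  mes_mean <- rowMeans(Xs[, mes_ids, drop = FALSE])
  flip <- drop(crossprod(u, mes_mean)) < 0
  u[, flip] <- -u[, flip]
  coords <- crossprod(u, Xs)                 # k x n_train
  rownames(coords) <- paste0("metagene", seq_len(k))
  y <- as.numeric(ids %in% mes_ids)
  fit <- .probit_ridge_irls(t(coords), y, ridge, max_iter, tol)
  structure(list(genes = rownames(X), center = ctr, scale = scl, u = u,
                 k = k, ridge = ridge, coef = fit$coef,
                 converged = fit$converged, iterations = fit$iterations,
                 training = list(epi_ids = epi_ids, mes_ids = mes_ids),
                 fitted = stats::setNames(fit$fitted, ids)),
            class = "metagene_probit")
}

# Ridge-penalized probit IRLS; Z gets an intercept column, the penalty
# applies to the slope coefficients only.
.probit_ridge_irls <- function(Z, y, ridge, max_iter, tol) {
  Z <- cbind(`(Intercept)` = 1, Z)
  p <- ncol(Z)
  P <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- rep(0, p)
  eps <- 1e-10
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Z %*% beta), -8), 8)
    mu <- pmin(pmax(stats::pnorm(eta), eps), 1 - eps)
    phi <- pmax(stats::dnorm(eta), eps)
    w <- phi^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / phi
    ZW <- Z * w
    beta_new <- drop(solve(crossprod(Z, ZW) + P, crossprod(ZW, z)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * (1 + max(abs(beta)))) {
      eta <- pmin(pmax(drop(Z %*% beta), -8), 8)
      return(list(coef = stats::setNames(beta, colnames(Z)),
                  fitted = stats::pnorm(eta),
                  converged = TRUE, iterations = it))
    }
  }
  stop("probit IRLS did not converge after ", max_iter,
       " iterations (last max coefficient change ",
       format(delta, digits = 3), "); increase 'ridge' or 'max_iter'")
}

#' Predict mesenchymal phenotype probability for new samples
#'
#' Projects samples onto the fitted metagene basis (after standardization
#' with the training centers/scales) and applies the fitted probit. Genes
#' absent from `mat` are imputed at the training mean (0 after
#' standardization) with a warning; more than 50% missing is an error.
#'
#' @param object A [fit_metagene_probit()] result.
#' @param mat Numeric gene-by-sample matrix.
#' @param sample_ids Samples to predict (default: all columns).
#' @param ... Unused.
#' @return Named numeric vector of Mes probabilities in `[0, 1]`.
#' @export
predict.metagene_probit <- function(object, mat,
                                    sample_ids = colnames(mat), ...) {
  missing_samples <- setdiff(sample_ids, colnames(mat))
  if (length(missing_samples))
    stop("sample id(s) not in the matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  genes <- object$genes
  absent <- setdiff(genes, rownames(mat))
  if (length(absent) > 0.5 * length(genes))
    stop(length(absent), " of ", length(genes),
         " predictor genes missing from the matrix (> 50%)")
  if (length(absent))
    warning("imputing ", length(absent),
            " missing predictor gene(s) at the training mean")
  Xs <- matrix(0, length(genes), length(sample_ids),
               dimnames = list(genes, sample_ids))
  found <- intersect(genes, rownames(mat))
  vals <- mat[found, sample_ids, drop = FALSE]
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- object$center[found][idx[, 1L]]
  }
  Xs[found, ] <- (vals - object$center[found]) / object$scale[found]
  coords <- crossprod(object$u, Xs)
  eta <- drop(object$coef[1L] + crossprod(coords, object$coef[-1L]))
  stats::setNames(stats::pnorm(pmin(pmax(eta, -8), 8)), sample_ids)
}

#' @export
print.metagene_probit <- function(x, ...) {
  cat("Metagene probit predictor: ", length(x$genes), " genes, k = ", x$k,
      " metagenes, ridge = ", format(x$ridge), "\n", sep = "")
  cat("training: ", length(x$training$epi_ids), " Epi vs ",
      length(x$training$mes_ids), " Mes; IRLS ",
      if (x$converged) "converged" else "did not converge", " in ",
      x$iterations, " iteration(s)\n", sep = "")
  cat("coefficients: ",
      paste(names(x$coef), format(x$coef, digits = 3), sep = "=",
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Select signature genes from SAM and ROC statistics
#'
#' Applies the selection thresholds: a gene joins the Mes list when its
#' q-value is at most `q_max_pct`, its ROC exceeds `roc_hi` and its SAM `d`
#' is positive; it joins the Epi list when q is at most `q_max_pct`, ROC is
#' below `roc_lo` and `d` is negative. Genes whose `d` and ROC disagree in
#' direction are excluded with a warning. Relaxing any threshold can only
#' grow the selection.
#'
#' @param sam_res A [sam()] result (or its `table`).
#' @param roc_res A [roc_per_gene()] result over the same gene universe.
#' @param q_max_pct Maximum q-value percent (default 0).
#' @param roc_hi,roc_lo ROC thresholds (defaults 0.8 and 0.2).
#' @return An [emt_signature()] (unweighted).
#' @export
select_signature_genes <- function(sam_res, roc_res, q_max_pct = 0,
                                   roc_hi = 0.8, roc_lo = 0.2) {
  st <- if (inherits(sam_res, "sam_result")) sam_res$table else sam_res
  if (!setequal(st$gene, roc_res$gene))
    stop("'sam_res' and 'roc_res' must cover the same gene universe")
  if (roc_lo >= roc_hi) stop("'roc_lo' must be below 'roc_hi'")
  m <- merge(st, roc_res, by = "gene", sort = FALSE)
  pass_q <- m$q_pct <= q_max_pct
  mes_dir <- m$roc > roc_hi
  epi_dir <- m$roc < roc_lo
  conflict <- pass_q & ((mes_dir & m$d < 0) | (epi_dir & m$d > 0))
  if (any(conflict))
    warning(sum(conflict),
            " gene(s) excluded for conflicting d/ROC directions: ",
            paste(utils::head(m$gene[conflict], 5), collapse = ", "))
  mes <- m$gene[pass_q & mes_dir & m$d > 0]
  epi <- m$gene[pass_q & epi_dir & m$d < 0]
  if (!length(epi) || !length(mes))
    stop("signature empty on the ",
         paste(c("Epi", "Mes")[!c(length(epi), length(mes))],
               collapse = " and "),
         " side; consider relaxing q_max_pct or the ROC thresholds")
  emt_signature(epi, mes, source = "SAM/ROC selection")
}

#' Derive a cancer-specific EMT signature from a cohort
#'
#' Runs the six-step derivation scheme on one expression cohort:
#' \enumerate{
#'   \item ssGSEA scores for each published EMT gene set;
#'   \item correlation of each set's scores with canonical Mes and Epi
#'     marker expression, choosing the best-agreeing set (the ranking is
#'     flipped when the set is epithelial-oriented);
#'   \item the `n_seed` most Mes and most Epi samples by that ranking train
#'     an SVD-metagene probit predictor;
#'   \item the predictor assigns every sample a Mes probability (steps 1-3
#'     may be repeated, re-seeding from the probabilities, up to
#'     `max_iter` passes or until the seed membership stabilizes);
#'   \item the extreme samples by probability (fraction `frac` per end for
#'     cell lines, `n_each` per end for tumours) enter SAM and per-gene ROC,
#'     and genes passing `q_max_pct` / `roc_hi` / `roc_lo` form the
#'     signature;
#'   \item per-gene statistics (log2 fold-change, q%, ROC, cohort size) are
#'     attached for downstream cross-disease combination.
#' }
#'
#' @param mat Numeric gene-by-sample matrix (log2 scale).
#' @param published_sets Named list of character vectors (published EMT
#'   gene sets, e.g. from [read_gene_sets()]).
#' @param disease Disease label recorded in the per-gene statistics.
#' @param markers_mes,markers_epi Marker genes used to orient and choose the
#'   published set (defaults: canonical EMT markers).
#' @param mode,frac,n_each Extreme-sample selection, see [select_extremes()].
#' @param n_seed Seed samples per end for probit training (clamped to
#'   10-20).
#' @param q_max_pct,roc_hi,roc_lo Gene-selection thresholds, see
#'   [select_signature_genes()].
#' @param k,ridge Metagene probit settings, see [fit_metagene_probit()].
#' @param alpha ssGSEA exponent.
#' @param n_perm,seed SAM permutation settings.
#' @param max_iter Maximum number of step 1-3 passes (default 1).
#' @return Object of class `emt_derivation`: list with `signature`
#'   ([emt_signature()]), `stats` (data.frame `gene`, `direction`,
#'   `fc_log2`, `q_pct`, `roc`, `n_samples`, `disease`), `best_set`,
#'   `orientation`, `marker_tables`, `es`, `probabilities`, `extremes`,
#'   `sam`, `roc`, `fit`, `iterations`.
#' @export
derive_cancer_signature <- function(mat, published_sets, disease = "",
                                    markers_mes = .default_mes_markers,
                                    markers_epi = .default_epi_markers,
                                    mode = c("cell_line", "tumour"),
                                    frac = 0.25, n_each = 100L,
                                    n_seed = 15L, q_max_pct = 0,
                                    roc_hi = 0.8, roc_lo = 0.2,
                                    k = 2L, ridge = 1e-3, alpha = 0.25,
                                    n_perm = 1000L, seed = 1L,
                                    max_iter = 1L) {
  mode <- match.arg(mode)
  mat <- validate_expression(mat)
  if (!length(published_sets)) stop("step 1: 'published_sets' is empty")
  if (ncol(mat) < 30L)
    warning("fewer than 30 samples; derived signatures may be unstable")
  n_seed_eff <- min(max(as.integer(n_seed), 10L), 20L, floor(ncol(mat) / 2))
  if (n_seed_eff != n_seed)
    warning("n_seed adjusted to ", n_seed_eff, " (allowed range 10-20, ",
            "at most half the cohort)")

  # Steps 1-2: ssGSEA of published sets, marker agreement, best set.
  es_long <- ssgsea(mat, published_sets, alpha = alpha)
  marker_tables <- list()
  agreement <- stats::setNames(numeric(length(published_sets)),
                               names(published_sets))
  for (nm in names(published_sets)) {
    es <- stats::setNames(es_long$es[es_long$set_name == nm],
                          es_long$sample_id[es_long$set_name == nm])
    tab <- tryCatch(
      marker_correlation(es, mat, c(markers_mes, markers_epi)),
      error = function(e) stop("step 2 (", nm, "): ",
                               conditionMessage(e), call. = FALSE))
    tab$role <- ifelse(tab$marker %in% markers_mes, "Mes", "Epi")
    marker_tables[[nm]] <- tab
    rho_mes <- tab$rho[tab$role == "Mes" & tab$present]
    rho_epi <- tab$rho[tab$role == "Epi" & tab$present]
    agreement[nm] <- mean(c(rho_mes, -rho_epi))
  }
  best_set <- names(which.max(abs(agreement)))
  orientation <- if (agreement[best_set] >= 0) 1 else -1
  es_best <- stats::setNames(
    es_long$es[es_long$set_name == best_set],
    es_long$sample_id[es_long$set_name == best_set])
  ranking <- orientation * es_best

  # Steps 3-4 (optionally recursive): seed extremes -> probit -> probabilities.
  seeds_prev <- NULL
  fit <- NULL
  prob <- NULL
  iterations <- 0L
  for (it in seq_len(max(1L, as.integer(max_iter)))) {
    seeds <- select_extremes(ranking, mode = "tumour", n_each = n_seed_eff)
    if (!is.null(seeds_prev) &&
        setequal(seeds$epi_ids, seeds_prev$epi_ids) &&
        setequal(seeds$mes_ids, seeds_prev$mes_ids)) break
    seeds_prev <- seeds
    fit <- tryCatch(
      fit_metagene_probit(mat, seeds$epi_ids, seeds$mes_ids,
                          k = k, ridge = ridge),
      error = function(e) stop("step 3: ", conditionMessage(e),
                               call. = FALSE))
    prob <- predict(fit, mat)
    ranking <- prob
    iterations <- it
  }

  # Step 5: extremes by probability, SAM + ROC, threshold selection.
  extremes <- select_extremes(prob, mode = mode, frac = frac,
                              n_each = n_each)
  sam_res <- tryCatch(
    sam(mat, extremes$epi_ids, extremes$mes_ids, n_perm = n_perm,
        seed = seed),
    error = function(e) stop("step 5 (SAM): ", conditionMessage(e),
                             call. = FALSE))
  roc_res <- roc_per_gene(mat, extremes$epi_ids, extremes$mes_ids)
  sig <- tryCatch(
    select_signature_genes(sam_res, roc_res, q_max_pct = q_max_pct,
                           roc_hi = roc_hi, roc_lo = roc_lo),
    error = function(e) stop("step 5 (selection): ", conditionMessage(e),
                             call. = FALSE))
  sig$source <- paste0("derived", if (nzchar(disease))
    paste0(" (", disease, ")") else "")

  # Step 6: per-gene statistics for the generic combination.
  genes <- c(sig$epi_genes, sig$mes_genes)
  st <- sam_res$table[match(genes, sam_res$table$gene), ]
  rc <- roc_res$roc[match(genes, roc_res$gene)]
  stats_df <- data.frame(
    gene = genes,
    direction = c(rep("Epi", length(sig$epi_genes)),
                  rep("Mes", length(sig$mes_genes))),
    fc_log2 = st$fc_log2,
    q_pct = st$q_pct,
    roc = rc,
    n_samples = ncol(mat),
    disease = disease,
    stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL

  structure(list(signature = sig, stats = stats_df, best_set = best_set,
                 orientation = orientation, agreement = agreement,
                 marker_tables = marker_tables, es = es_long,
                 probabilities = prob, extremes = extremes,
                 sam = sam_res, roc = roc_res, fit = fit,
                 iterations = iterations),
            class = "emt_derivation")
}

#' @export
print.emt_derivation <- function(x, ...) {
  cat("EMT signature derivation\n")
  cat("best published set: ", x$best_set, " (orientation ",
      if (x$orientation > 0) "Mes-up" else "Epi-up", "), ",
      x$iterations, " seeding pass(es)\n", sep = "")
  cat("extremes: ", length(x$extremes$epi_ids), " Epi vs ",
      length(x$extremes$mes_ids), " Mes samples\n", sep = "")
  print(x$signature)
  invisible(x)
}
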