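test_that("extreme-sample selection honours both modes and stays disjoint", {
  r <- setNames(seq_len(40), sprintf("s%02d", 1:40))
  ex <- select_extremes(r, "cell_line", frac = 0.25)
  expect_length(ex$mes_ids, 10)
  expect_length(ex$epi_ids, 10)
  expect_length(intersect(ex$epi_ids, ex$mes_ids), 0)
  expect_setequal(ex$mes_ids, sprintf("s%02d", 31:40))
  expect_setequal(ex$epi_ids, sprintf("s%02d", 1:10))

  r2 <- setNames(rnorm(1000), sprintf("t%04d", 1:1000))
  ex2 <- select_extremes(r2, "tumour", n_each = 100)
  expect_length(ex2$mes_ids, 100)
  expect_length(ex2$epi_ids, 100)

  expect_error(select_extremes(setNames(1:3, c("a", "b", "c"))),
               "at least 4")
  # odd n with a large fraction still cannot overlap
  r3 <- setNames(1:5, letters[1:5])
  ex3 <- select_extremes(r3, "cell_line", frac = 0.5)
  expect_length(intersect(ex3$epi_ids, ex3$mes_ids), 0)
})

test_that("metagene probit separates separable training groups", {
  co <- generate_cohort(n_samples = 80, n_background = 100, n_epi = 20,
                        n_mes = 20, b = 3, sigma = 0.3,
                        phi_dist = "two_cluster", seed = 41)
  tr <- co$truth$samples
  epi <- tr$sample_id[order(tr$phi)][1:20]
  mes <- tr$sample_id[order(-tr$phi)][1:20]
  fit <- fit_metagene_probit(co$matrix, epi, mes)
  expect_true(fit$converged)
  expect_true(all(fit$fitted[mes] > 0.5))
  expect_true(all(fit$fitted[epi] < 0.5))
  # Mes training mean probability exceeds the Epi mean
  expect_gt(mean(fit$fitted[mes]), mean(fit$fitted[epi]))

  # a sample at the grand training centroid is maximally uncertain
  cm <- cbind(co$matrix,
              CENTROID = rowMeans(co$matrix[, c(epi, mes)]))
  expect_lt(abs(predict(fit, cm, "CENTROID") - 0.5), 0.05)
})

test_that("ridge probit IRLS agrees with direct penalized-likelihood optimization", {
  set.seed(42)
  # k = 1 toy: one metagene coordinate at +/-1 plus jitter
  x <- c(-1, -1.1, -0.9, -1.05, 1, 1.1, 0.95, 1.02)
  genes <- sprintf("g%02d", 1:12)
  base <- outer(rnorm(12), x) + rnorm(12 * 8, sd = 0.05)
  # plant a strong coordinate so the top singular vector tracks x
  base[1:6, ] <- base[1:6, ] + outer(rep(2, 6), x)
  m <- toy_matrix(base, genes = genes, samples = sprintf("s%d", 1:8))
  epi <- sprintf("s%d", 1:4); mes <- sprintf("s%d", 5:8)
  fit <- fit_metagene_probit(m, epi, mes, k = 1, ridge = 0.05,
                             max_iter = 500, tol = 1e-10)

  # recompute the coordinate exactly as documented and compare against a
  # direct optimizer of the ridge-penalized probit log-likelihood
  ctr <- rowMeans(m[, c(epi, mes)])
  scl <- apply(m[, c(epi, mes)], 1, sd)
  Xs <- (m[, c(epi, mes)] - ctr) / scl
  z <- drop(crossprod(fit$u, Xs))
  y <- as.numeric(c(epi, mes) %in% mes)
  negll <- function(b) {
    eta <- b[1] + b[2] * z
    -sum(y * pnorm(eta, log.p = TRUE) +
           (1 - y) * pnorm(-eta, log.p = TRUE)) + 0.05 * b[2]^2 / 2
  }
  opt <- optim(c(0, 0), negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit$coef), opt$par, tolerance = 1e-4)
  # predictions are the closed-form probit of the linear predictor
  expect_equal(unname(predict(fit, m, c(epi, mes))),
               unname(pnorm(fit$coef[1] + fit$coef[2] * z)),
               tolerance = 1e-8)
})

test_that("phenotype prediction is idempotent and handles missing genes", {
  co <- generate_cohort(n_samples = 50, n_background = 80, n_epi = 15,
                        n_mes = 15, phi_dist = "two_cluster", seed = 43)
  tr <- co$truth$samples
  epi <- tr$sample_id[order(tr$phi)][1:12]
  mes <- tr$sample_id[order(-tr$phi)][1:12]
  fit <- fit_metagene_probit(co$matrix, epi, mes)
  pr <- predict(fit, co$matrix)
  expect_equal(pr[names(fit$fitted)], fit$fitted, tolerance = 1e-12)

  # duplicated sample gets the same probability
  m2 <- cbind(co$matrix, DUP = co$matrix[, epi[1]])
  pr2 <- predict(fit, m2)
  expect_equal(unname(pr2["DUP"]), unname(pr2[epi[1]]))

  # recovery of the planted axis
  expect_gt(cor(pr, tr$phi, method = "spearman"), 0.9)

  # missing predictor genes: warn below 50%, error above
  drop_few <- co$matrix[-(1:10), ]
  expect_warning(pr3 <- predict(fit, drop_few), "imputing")
  expect_gt(cor(pr3, tr$phi, method = "spearman"), 0.85)
  drop_most <- co$matrix[1:30, ]
  expect_error(predict(fit, drop_most), "> 50%")
})

test_that("threshold selection follows the q/ROC rules and is monotone", {
  st <- data.frame(
    gene = c("m_good", "q_bad", "roc_mid", "e_good", "confl"),
    d = c(2, 2.5, 1.5, -2, -1.8),
    s = 1, fc_log2 = c(2, 2.5, 1.5, -2, -1.8),
    q_pct = c(0, 5, 0, 0, 0))
  roc <- data.frame(gene = st$gene, roc = c(0.9, 0.9, 0.5, 0.1, 0.85))
  expect_warning(sig <- select_signature_genes(st, roc), "conflicting")
  expect_identical(sig$mes_genes, "m_good")
  expect_identical(sig$epi_genes, "e_good")

  # relaxing thresholds never removes a selected gene
  sig2 <- suppressWarnings(
    select_signature_genes(st, roc, q_max_pct = 5, roc_hi = 0.7,
                           roc_lo = 0.3))
  expect_true(all(sig$mes_genes %in% sig2$mes_genes))
  expect_true(all(sig$epi_genes %in% sig2$epi_genes))
  expect_true("q_bad" %in% sig2$mes_genes)

  expect_error(select_signature_genes(st[1:3, ], roc),
               "same gene universe")
  expect_error(
    suppressWarnings(
      select_signature_genes(st, transform(roc, roc = 0.5))),
    "relaxing")
})

test_that("the six-step derivation recovers a planted signature", {
  co <- generate_cohort(phi_dist = "two_cluster", seed = 44)
  der <- derive_cancer_signature(
    co$matrix, co$gene_sets["planted_mes"], disease = "synthetic",
    markers_mes = co$gene_sets$planted_mes[1:3],
    markers_epi = co$gene_sets$planted_epi[1:3],
    n_perm = 500, seed = 45)
  truth <- co$truth$genes
  planted <- truth$gene[truth$role != "background"]
  background <- truth$gene[truth$role == "background"]
  got <- c(der$signature$epi_genes, der$signature$mes_genes)
  expect_gte(mean(planted %in% got), 0.9)
  expect_lte(mean(background %in% got), 0.01)
  # directions match the planted blocks
  expect_true(all(der$signature$mes_genes %in%
                  truth$gene[truth$role == "mes_block"] |
                  der$signature$mes_genes %in% background))
  expect_identical(unique(der$stats$disease), "synthetic")
  expect_identical(unique(der$stats$n_samples), ncol(co$matrix))

  # the orientation flip: an Epi-oriented published set ranks the same way
  der2 <- derive_cancer_signature(
    co$matrix, co$gene_sets["planted_epi"], disease = "synthetic",
    markers_mes = co$gene_sets$planted_mes[1:3],
    markers_epi = co$gene_sets$planted_epi[1:3],
    n_perm = 200, seed = 45)
  expect_identical(der2$orientation, -1)
  expect_gt(cor(der2$probabilities, co$truth$samples$phi,
                method = "spearman"), 0.9)
})

test_that("derivation validates inputs and clamps the seed count", {
  co <- generate_cohort(n_samples = 40, n_background = 60, n_epi = 10,
                        n_mes = 10, phi_dist = "two_cluster", seed = 46)
  expect_error(derive_cancer_signature(co$matrix, list()), "empty")
  expect_warning(
    der <- derive_cancer_signature(
      co$matrix, co$gene_sets["planted_mes"],
      markers_mes = co$gene_sets$planted_mes[1:3],
      markers_epi = co$gene_sets$planted_epi[1:3],
      n_seed = 50, n_perm = 100, seed = 4),
    "n_seed adjusted")
  expect_length(der$fit$training$mes_ids, 20)
})
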