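test_that("rank_sample ranks ascending with mid-rank ties and is rank-invariant", {
  m <- toy_matrix(cbind(c(1, 3, 2), c(5, 5, 1)),
                  genes = c("A", "B", "C"))
  expect_equal(rank_sample(m, "s1"), c(A = 1, B = 3, C = 2))
  expect_equal(rank_sample(m, "s2"), c(A = 2.5, B = 2.5, C = 1))
  expect_error(rank_sample(m, "nope"), "unknown sample")

  # strictly monotone transform leaves ranks identical
  m2 <- m; m2[, "s1"] <- exp(m[, "s1"])
  expect_identical(rank_sample(m2, "s1"), rank_sample(m, "s1"))
})

test_that("emt_score hits the documented extreme and derived values", {
  g <- sprintf("g%02d", 1:10)
  m <- toy_matrix(cbind(1:10, 10:1), genes = g)
  sig <- emt_signature(g[1:3], g[8:10])
  up <- emt_score(m, "s1", sig)
  expect_equal(up$emt_score, 1)            # Mes genes at the top -> +1
  expect_match(up$class, "Mes")            # 3v3: maximal D, p above 0.05
  expect_equal(emt_score(m, "s2", sig)$emt_score, -1)

  # swapping the lists negates the score exactly
  swapped <- emt_signature(g[8:10], g[1:3])
  expect_equal(emt_score(m, "s1", swapped)$emt_score, -1)

  # 6 genes g1<...<g6, Epi={g1,g4}, Mes={g2,g5}: sup(Fe-Fm)=0.5, sup(Fm-Fe)=0
  m6 <- toy_matrix(cbind(1:6, 1:6), genes = paste0("g", 1:6))
  s6 <- emt_signature(c("g1", "g4"), c("g2", "g5"))
  expect_equal(emt_score(m6, "s1", s6, min_genes = 2)$emt_score, 0.5)
})

test_that("|emt_score| equals the brute-force KS statistic with the right sign", {
  set.seed(11)
  g_all <- sprintf("g%03d", 1:50)
  for (rep in 1:200) {
    n <- sample(10:50, 1)
    genes <- g_all[1:n]
    vals <- sample(1000, n)                 # untied
    m <- toy_matrix(cbind(vals, vals), genes = genes)
    ne <- sample(3:floor(n / 2), 1)
    nm <- sample(3:floor(n / 2), 1)
    pick <- sample(genes, ne + nm)
    sig <- emt_signature(pick[1:ne], pick[ne + 1:nm])
    got <- emt_score(m, "s1", sig)
    r <- rank_sample(m, "s1")
    oracle <- brute_ks(r[sig$epi_genes], r[sig$mes_genes])
    expect_equal(got$emt_score, oracle$score)
    # |score| is the KS D except when the two one-sided sups tie exactly
    # (documented score-0 rule)
    if (oracle$score != 0)
      expect_equal(abs(got$emt_score), oracle$d)
  }
})

test_that("antisymmetry and rank invariance hold on random instances", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:40)
  for (rep in 1:25) {
    m <- toy_matrix(cbind(rnorm(40), rnorm(40)), genes = genes)
    pick <- sample(genes, 16)
    sig <- emt_signature(pick[1:8], pick[9:16])
    swp <- emt_signature(pick[9:16], pick[1:8])
    a <- emt_score(m, "s1", sig)
    b <- emt_score(m, "s1", swp)
    expect_equal(b$emt_score, -a$emt_score)
    expect_equal(b$ks_pvalue, a$ks_pvalue)

    # strictly increasing transform leaves the whole record identical
    m2 <- m; m2[, "s1"] <- 2 * m[, "s1"]^3 + exp(m[, "s1"] / 4)
    a2 <- emt_score(m2, "s1", sig)
    expect_identical(a2$emt_score, a$emt_score)
    expect_identical(a2$ks_pvalue, a$ks_pvalue)
    expect_identical(a2$class, a$class)
  }
})

test_that("non-signature genes that do not interleave leave the score unchanged", {
  g <- sprintf("g%02d", 1:12)
  base <- toy_matrix(cbind(1:6, 1:6), genes = g[1:6])
  sig <- emt_signature(c("g01", "g03"), c("g04", "g06"))
  s0 <- emt_score(base, "s1", sig, min_genes = 2)
  # append genes strictly above every signature gene: relative order kept
  ext <- toy_matrix(cbind(c(1:6, 101:106), c(1:6, 101:106)), genes = g)
  s1 <- emt_score(ext, "s1", sig, min_genes = 2)
  expect_equal(s1$emt_score, s0$emt_score)
})

test_that("ks_pvalue matches stats::ks.test and the permutation enumeration", {
  # asymptotic branch against ks.test's asymptotic two-sample p-value
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(25, 0.4)
    d <- as.numeric(suppressWarnings(stats::ks.test(y, x))$statistic)
    ours <- ks_pvalue(d, n_epi = 30, n_mes = 25)
    ref <- suppressWarnings(stats::ks.test(y, x, exact = FALSE))$p.value
    expect_equal(ours, ref, tolerance = 1e-4)
  }
  expect_equal(ks_pvalue(0, 10, 10), 1)
  expect_lt(ks_pvalue(1, 100, 100), 1e-10)

  # exact branch against ks.test's exact small-sample p-value
  for (rep in 1:10) {
    x <- sample(1000, 5); y <- sample(1000, 6)
    while (length(intersect(x, y))) y <- sample(1000, 6)
    d <- as.numeric(stats::ks.test(y, x)$statistic)
    expect_equal(ks_pvalue(d, 5, 6, exact = TRUE),
                 stats::ks.test(y, x, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(ks_pvalue(1.2, 5, 5), "\\[0, 1\\]")
  expect_error(ks_pvalue(0.5, 15, 15, exact = TRUE), "<= 20")
})

test_that("classification partitions score/p space with the documented tie rule", {
  expect_identical(classify(0.5, 0.01), "Mes")
  expect_identical(classify(-0.1, 0.4), "intermediate-Epi")
  expect_identical(classify(0, 1), "intermediate-Epi")
  expect_identical(classify(0.3, 0.4), "intermediate-Mes")
  expect_identical(classify(-0.6, 0.001), "Epi")
  # stricter threshold flips borderline calls to intermediate
  expect_identical(classify(0.5, 0.01, p_threshold = 0.001),
                   "intermediate-Mes")
  expect_error(classify(0.1, 0.5, p_threshold = 0), "strictly inside")

  # partition: every (sign, p) combination lands in exactly one class
  set.seed(14)
  s <- runif(200, -1, 1); p <- runif(200)
  k <- classify(s, p)
  expect_true(all(k %in% c("Epi", "intermediate-Epi",
                           "intermediate-Mes", "Mes")))
  expect_identical(k[s > 0 & p < 0.05], rep("Mes", sum(s > 0 & p < 0.05)))
})

test_that("score_matrix scores every sample, flags low coverage, is deterministic", {
  set.seed(15)
  genes <- sprintf("g%02d", 1:30)
  m <- toy_matrix(cbind(rnorm(30), rnorm(30), rep(5, 30)), genes = genes)
  colnames(m) <- c("a", "b", "const")
  m <- cbind(m, a_copy = m[, "a"])
  sig <- emt_signature(genes[1:5], genes[6:10])
  res <- score_matrix(m, sig)
  expect_s3_class(res, "emt_scores")
  expect_identical(res$sample_id, colnames(m))
  # duplicate sample values give identical results
  expect_equal(res$emt_score[res$sample_id == "a_copy"],
               res$emt_score[res$sample_id == "a"])
  # constant sample: complete ties, mid-ranks make the ECDFs equal
  expect_equal(res$emt_score[res$sample_id == "const"], 0)

  # coverage failure yields a flagged record, not an abort
  sig_absent <- emt_signature(c("x1", "x2", "x3", genes[1:2]),
                              genes[6:10])
  res2 <- suppressWarnings(score_matrix(m, sig_absent))
  expect_true(all(is.na(res2$emt_score)))
  expect_match(res2$note[1], "coverage")
})

test_that("spearman association matches the direct rank formula", {
  s <- c(0.1, -0.5, 0.9, 0.3, -0.2)
  expect_equal(spearman_association(s, s)$rho, 1)
  expect_equal(spearman_association(s, -s)$rho, -1)
  set.seed(16)
  for (rep in 1:10) {
    x <- sample(100, 5); y <- sample(100, 5)
    expect_equal(spearman_association(x, y)$rho, brute_spearman(x, y))
  }
  expect_error(spearman_association(c(1, 2), c(3, 4)), "at least 3")
  # missing pairs dropped before the n >= 3 check
  expect_error(spearman_association(c(1, 2, NA, 4), c(1, NA, 3, 4)),
               "at least 3")
})

test_that("Mann-Whitney comparison behaves at ties, separation and label swaps", {
  expect_equal(mannwhitney_groups(rep(1, 6), rep(c("a", "b"), 3))$pvalue, 1)

  # fully separated 5 vs 5: exact two-sided p = 2 / choose(10, 5)
  x <- c(1:5, 11:15)
  lab <- rep(c("lo", "hi"), each = 5)
  res <- mannwhitney_groups(x, lab)
  expect_equal(res$pvalue, 2 / choose(10, 5))

  # swapping level order preserves the p-value
  res2 <- mannwhitney_groups(x, factor(lab, levels = c("lo", "hi")))
  expect_equal(res2$pvalue, res$pvalue)
  expect_error(mannwhitney_groups(1:4, rep("a", 4)), "2 levels")
})
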