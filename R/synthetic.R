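#' Generate a synthetic cohort with a planted EMT axis
#'
#' Simulates a log2-scale gene-by-sample matrix under a linear single-factor
#' model: each sample carries a latent EMT position `phi` in `[-1, +1]`
#' (uniform, or two clusters at -0.8 and +0.8 with sd 0.1, clamped), and
#' each gene is `x_gs = mu_g + beta_g * phi_s + eps_gs` with baseline
#' `mu_g ~ Normal(7, 1)`, `beta_g = +b` for mesenchymal block genes, `-b`
#' for epithelial block genes, `0` for background genes, and noise
#' `eps ~ Normal(0, sigma^2)`. The defaults (200 samples, 500 background
#' genes, 50 + 50 block genes, `b = 2`, `sigma = 0.5`) define the study
#' conditions used throughout the test-suite recovery experiments.
#'
#' @param n_samples Number of samples (default 200).
#' @param n_background Background (non-signature) genes (default 500).
#' @param n_epi,n_mes Epithelial / mesenchymal block sizes (default 50
#'   each).
#' @param b Effect size in log2 units (default 2).
#' @param sigma Noise standard deviation (default 0.5).
#' @param phi_dist `"uniform"` or `"two_cluster"`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param gene_prefix Prefixes for generated gene names.
#' @return Object of class `emt_cohort`: list with `matrix` (genes x
#'   samples), `truth` (list with per-sample `samples$phi`, per-gene
#'   `genes$role`, `b`, `sigma`, `phi_dist`, `seed`), `signature` (the
#'   planted [emt_signature()]) and `gene_sets` (planted Mes and Epi sets,
#'   usable as "published" sets).
#' @export
generate_cohort <- function(n_samples = 200L, n_background = 500L,
                            n_epi = 50L, n_mes = 50L, b = 2.0, sigma = 0.5,
                            phi_dist = c("uniform", "two_cluster"),
                            seed = 1L,
                            gene_prefix = c(epi = "EPI", mes = "MES",
                                            bg = "BG")) {
  phi_dist <- match.arg(phi_dist)
  if (min(n_samples, n_background, n_epi, n_mes) < 1L)
    stop("all counts must be >= 1")
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (!is.finite(b) || b <= 0) stop("'b' must be > 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  phi <- switch(phi_dist,
    uniform = stats::runif(n_samples, -1, 1),
    two_cluster = {
      centre <- sample(rep(c(-0.8, 0.8), length.out = n_samples))
      pmin(pmax(centre + stats::rnorm(n_samples, 0, 0.1), -1), 1)
    })
  samples <- sprintf("S%04d", seq_len(n_samples))
  genes <- c(sprintf("%s%04d", gene_prefix[["epi"]], seq_len(n_epi)),
             sprintf("%s%04d", gene_prefix[["mes"]], seq_len(n_mes)),
             sprintf("%s%04d", gene_prefix[["bg"]], seq_len(n_background)))
  role <- c(rep("epi_block", n_epi), rep("mes_block", n_mes),
            rep("background", n_background))
  beta <- c(rep(-b, n_epi), rep(b, n_mes), rep(0, n_background))
  g <- length(genes)
  mu <- stats::rnorm(g, 7, 1)
  eps <- matrix(stats::rnorm(g * n_samples, 0, sigma), g, n_samples)
  X <- mu + outer(beta, phi) + eps
  dimnames(X) <- list(genes, samples)

  structure(list(
    matrix = X,
    truth = list(
      samples = data.frame(sample_id = samples, phi = phi,
                           stringsAsFactors = FALSE),
      genes = data.frame(gene = genes, role = role,
                         stringsAsFactors = FALSE),
      b = b, sigma = sigma, phi_dist = phi_dist, seed = as.integer(seed)),
    signature = emt_signature(genes[role == "epi_block"],
                              genes[role == "mes_block"],
                              source = "planted"),
    gene_sets = list(
      planted_mes = genes[role == "mes_block"],
      planted_epi = genes[role == "epi_block"])),
    class = "emt_cohort")
}

#' @export
print.emt_cohort <- function(x, ...) {
  tr <- x$truth
  cat("Synthetic EMT cohort: ", ncol(x$matrix), " samples x ",
      nrow(x$matrix), " genes\n", sep = "")
  cat("blocks: ", sum(tr$genes$role == "epi_block"), " Epi / ",
      sum(tr$genes$role == "mes_block"), " Mes / ",
      sum(tr$genes$role == "background"), " background; b = ", tr$b,
      ", sigma = ", tr$sigma, ", phi ~ ", tr$phi_dist,
      ", seed ", tr$seed, "\n", sep = "")
  invisible(x)
}

#' Generate related synthetic cohorts for several diseases
#'
#' Builds `D` cohorts sharing a consensus block of Epi and Mes genes while
#' each disease additionally plants its own private signature genes (half
#' Epi, half Mes). Private genes of one disease are absent from the other
#' cohorts' matrices, so a gene's disease membership mirrors the situation
#' the cross-disease combination addresses: consensus genes recur in all
#' `D` signatures, private genes in exactly one. Per-disease seeds are
#' derived as `seed + d`.
#'
#' @param D Number of diseases (default 6).
#' @param n_shared_epi,n_shared_mes Consensus block sizes (default 10
#'   each).
#' @param n_private_per_disease Private signature genes per disease, split
#'   evenly Epi/Mes (default 40).
#' @param n_samples,n_background,b,sigma Per-cohort generator settings; the
#'   default `phi_dist = "two_cluster"` gives each cohort distinct Epi and
#'   Mes groups, the regime the SAM/ROC selection expects.
#' @param phi_dist Passed to [generate_cohort()].
#' @param seed Base integer seed.
#' @return Object of class `emt_multidisease`: list with `cohorts` (named
#'   list of `emt_cohort`), `consensus` (list `epi`, `mes`), `private`
#'   (per-disease list), `D`, `seed`.
#' @export
generate_multidisease <- function(D = 6L, n_shared_epi = 10L,
                                  n_shared_mes = 10L,
                                  n_private_per_disease = 40L,
                                  n_samples = 200L, n_background = 500L,
                                  b = 2.0, sigma = 0.5,
                                  phi_dist = "two_cluster", seed = 1L) {
  if (D < 2L) stop("'D' must be >= 2")
  if (n_private_per_disease %% 2L)
    stop("'n_private_per_disease' must be even (split Epi/Mes)")
  npriv <- n_private_per_disease %/% 2L
  if (min(n_shared_epi, n_shared_mes, npriv) < 1L)
    stop("all block sizes must be >= 1")
  shared_epi <- sprintf("CONSEPI%03d", seq_len(n_shared_epi))
  shared_mes <- sprintf("CONSMES%03d", seq_len(n_shared_mes))
  cohorts <- list()
  private <- list()
  for (d in seq_len(D)) {
    dis <- sprintf("disease%d", d)
    co <- generate_cohort(
      n_samples = n_samples, n_background = n_background,
      n_epi = n_shared_epi + npriv, n_mes = n_shared_mes + npriv,
      b = b, sigma = sigma, phi_dist = phi_dist,
      seed = as.integer(seed) + d,
      gene_prefix = c(epi = "EPI", mes = "MES", bg = "BG"))
    # Rename block genes: shared consensus names first, then private names.
    priv_epi <- sprintf("PRIV%s_EPI%03d", d, seq_len(npriv))
    priv_mes <- sprintf("PRIV%s_MES%03d", d, seq_len(npriv))
    map <- rownames(co$matrix)
    map[seq_len(n_shared_epi)] <- shared_epi
    map[n_shared_epi + seq_len(npriv)] <- priv_epi
    map[n_shared_epi + npriv + seq_len(n_shared_mes)] <- shared_mes
    map[n_shared_epi + npriv + n_shared_mes + seq_len(npriv)] <- priv_mes
    rownames(co$matrix) <- map
    co$truth$genes$gene <- map
    co$signature <- emt_signature(c(shared_epi, priv_epi),
                                  c(shared_mes, priv_mes),
                                  source = paste0("planted (", dis, ")"))
    co$gene_sets <- list(planted_mes = c(shared_mes, priv_mes),
                         planted_epi = c(shared_epi, priv_epi))
    cohorts[[dis]] <- co
    private[[dis]] <- list(epi = priv_epi, mes = priv_mes)
  }
  structure(list(cohorts = cohorts,
                 consensus = list(epi = shared_epi, mes = shared_mes),
                 private = private, D = D, seed = as.integer(seed)),
            class = "emt_multidisease")
}

#' @export
print.emt_multidisease <- function(x, ...) {
  cat("Synthetic multi-disease collection: D = ", x$D, " cohorts\n",
      sep = "")
  cat("consensus genes: ", length(x$consensus$epi), " Epi / ",
      length(x$consensus$mes), " Mes; ",
      length(x$private[[1L]]$epi) + length(x$private[[1L]]$mes),
      " private genes per disease\n", sep = "")
  invisible(x)
}
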