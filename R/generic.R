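#' Cross-disease weight of a single gene
#'
#' The weight of gene `g` over a collection of disease-specific signature
#' statistics is
#' `w_g = sum_d |fc_gd| * (1 - q_gd/100) * 2*|ROC_gd - 0.5| * sqrt(n_d)`,
#' summed over the diseases whose signature contains the gene. Each factor
#' is monotone in the stated direction: larger absolute fold-change, smaller
#' q-value%, ROC further from chance and larger cohorts all increase the
#' weight; a disease where the gene is absent contributes 0, as does a
#' disease where its ROC equals 0.5. The `sqrt(n_d)` damping prevents one
#' very large cohort from dominating the sum. The z-transformed weight is
#' computed against the population of all genes appearing in at least one
#' disease signature.
#'
#' @param stats_list List of per-disease statistics data.frames (columns
#'   `gene`, `direction`, `fc_log2`, `q_pct`, `roc`, `n_samples`), as
#'   produced by [derive_cancer_signature()].
#' @param gene Gene identifier.
#' @return List with `gene`, `w`, `z`, `diseases_present`,
#'   `direction_consensus` (`"Epi"`, `"Mes"` or `"conflict"`).
#' @export
gene_weight <- function(stats_list, gene) {
  tab <- .weight_table(stats_list)
  row <- tab[tab$gene == gene, ]
  if (!nrow(row)) stop("gene '", gene, "' appears in no disease signature")
  list(gene = gene, w = row$w, z = row$z,
       diseases_present = row$diseases_present,
       direction_consensus = row$direction)
}

.check_stats_df <- function(df, i) {
  need <- c("gene", "direction", "fc_log2", "q_pct", "roc", "n_samples")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("disease stats ", i, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$q_pct < 0 | df$q_pct > 100, na.rm = TRUE))
    stop("disease stats ", i, ": q_pct outside [0, 100]")
  if (any(df$roc < 0 | df$roc > 1, na.rm = TRUE))
    stop("disease stats ", i, ": roc outside [0, 1]")
  if (any(df$n_samples < 1)) stop("disease stats ", i, ": n_samples < 1")
  invisible(TRUE)
}

# Population weight table over all genes in >= 1 disease signature.
.weight_table <- function(stats_list) {
  if (!length(stats_list)) stop("'stats_list' is empty")
  for (i in seq_along(stats_list)) .check_stats_df(stats_list[[i]], i)
  all <- do.call(rbind, lapply(stats_list, function(df)
    df[, c("gene", "direction", "fc_log2", "q_pct", "roc", "n_samples")]))
  all$contrib <- abs(all$fc_log2) * (1 - all$q_pct / 100) *
    2 * abs(all$roc - 0.5) * sqrt(all$n_samples)
  genes <- unique(all$gene)
  w <- vapply(genes, function(g) sum(all$contrib[all$gene == g]),
              numeric(1L))
  npres <- vapply(genes, function(g) sum(all$gene == g), integer(1L))
  dir <- vapply(genes, function(g) {
    d <- unique(all$direction[all$gene == g])
    if (length(d) == 1L) d else "conflict"
  }, character(1L))
  sdw <- stats::sd(w)
  z <- if (length(w) > 1L && isTRUE(sdw > 0)) (w - mean(w)) / sdw
       else rep(NA_real_, length(w))
  data.frame(gene = genes, w = unname(w), z = unname(z),
             diseases_present = unname(npres), direction = unname(dir),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine disease-specific signatures into a generic EMT signature
#'
#' Computes the cross-disease weight of every gene appearing in at least one
#' disease signature (see [gene_weight()]), z-transforms the weights over
#' that population, and selects the genes that (i) satisfy the membership
#' rule (`"all"`: present in all `D` disease signatures; `"at_least_k"`:
#' present in at least `k`), (ii) have a z-transformed weight strictly above
#' `z_threshold` (default 3.09, the upper 0.001 standard-normal quantile),
#' and (iii) carry a consistent Epi/Mes direction across diseases (genes
#' with conflicting directions are excluded with a warning).
#'
#' @param stats_list List of `D >= 2` per-disease statistics data.frames
#'   (see [gene_weight()]).
#' @param z_threshold Strict lower bound on the z-transformed weight.
#' @param membership `"all"` (default) or `"at_least_k"`.
#' @param k Minimum number of diseases for `membership = "at_least_k"`.
#' @return An [emt_signature()] whose weights are the combined `w_g`; the
#'   full population table is attached as attribute `"weight_table"`.
#' @export
combine_signatures <- function(stats_list, z_threshold = 3.09,
                               membership = c("all", "at_least_k"),
                               k = NULL) {
  membership <- match.arg(membership)
  if (length(stats_list) < 2L) stop("need stats for at least 2 diseases")
  D <- length(stats_list)
  if (membership == "at_least_k") {
    if (is.null(k) || k < 1L || k > D)
      stop("'k' must lie in [1, ", D, "] for membership = \"at_least_k\"")
  } else k <- D
  tab <- .weight_table(stats_list)
  if (all(is.na(tab$z)))
    stop("weights have zero variance; z-transform undefined")
  conflict <- tab$direction == "conflict"
  if (any(conflict))
    warning(sum(conflict), " gene(s) excluded for conflicting directions: ",
            paste(utils::head(tab$gene[conflict], 5), collapse = ", "))
  sel <- tab$diseases_present >= k & tab$z > z_threshold & !conflict
  if (!any(sel))
    stop("no gene passes membership + z > ", z_threshold,
         "; consider membership = \"at_least_k\" or a lower threshold")
  chosen <- tab[sel, ]
  epi <- chosen$gene[chosen$direction == "Epi"]
  mes <- chosen$gene[chosen$direction == "Mes"]
  if (!length(epi) || !length(mes))
    stop("combined signature empty on the ",
         paste(c("Epi", "Mes")[!c(length(epi), length(mes))],
               collapse = " and "),
         " side; consider relaxing the selection")
  sig <- emt_signature(epi, mes,
                       weights = stats::setNames(chosen$w, chosen$gene),
                       source = paste0("generic signature over ", D,
                                       " diseases (membership ", membership,
                                       ", z > ", z_threshold, ")"))
  attr(sig, "weight_table") <- tab
  sig
}

#' Pairwise overlap between EMT signatures
#'
#' For every pair of signatures, counts the shared Epi genes, shared Mes
#' genes and genes assigned discordant directions (Epi in one, Mes in the
#' other).
#'
#' @param signatures Named list of at least two [emt_signature()] objects.
#' @return data.frame with columns `sig_a`, `sig_b`, `shared_epi`,
#'   `shared_mes`, `discordant`.
#' @export
signature_overlap_report <- function(signatures) {
  if (length(signatures) < 2L) stop("need at least 2 signatures")
  if (is.null(names(signatures)))
    names(signatures) <- paste0("sig", seq_along(signatures))
  stopifnot(all(vapply(signatures, inherits, logical(1L), "emt_signature")))
  pairs <- utils::combn(names(signatures), 2L)
  rows <- apply(pairs, 2L, function(p) {
    a <- signatures[[p[1L]]]; b <- signatures[[p[2L]]]
    data.frame(sig_a = p[1L], sig_b = p[2L],
               shared_epi = length(intersect(a$epi_genes, b$epi_genes)),
               shared_mes = length(intersect(a$mes_genes, b$mes_genes)),
               discordant = length(intersect(a$epi_genes, b$mes_genes)) +
                            length(intersect(a$mes_genes, b$epi_genes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write per-disease signature statistics tables
#'
#' TSV with columns `gene`, `direction`, `fc_log2`, `q_pct`, `roc`,
#' `n_samples` and optionally `disease`.
#'
#' @param path File path.
#' @return `read_disease_stats`: the validated data.frame.
#' @export
read_disease_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  .check_stats_df(df, path)
  df
}

#' @rdname read_disease_stats
#' @param stats A per-disease statistics data.frame.
#' @export
write_disease_stats <- function(stats, path) {
  .check_stats_df(stats, "stats")
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
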