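#' Global significance score of a gene set
#'
#' The square root of the mean squared per-gene t-statistic: the
#' cumulative evidence for differential expression in the set,
#' regardless of direction.
#'
#' @param t Vector of per-gene t-statistics (genes in the set).
#' @return Non-negative scalar; `NA` for an empty set.
#' @export
global_significance <- function(t) {
  if (length(t) == 0) return(NA_real_)
  sqrt(mean(t^2))
}

#' Directed significance score of a gene set
#'
#' Signed companion of [global_significance()]: the signed mean of
#' signed squared t-statistics, mapped back to the t scale. It equals
#' plus or minus the global score when every gene moves the same way and
#' collapses to zero under perfect cancellation, so a set full of
#' strongly regulated genes can still score near zero when they move in
#' both directions.
#'
#' @param t Vector of per-gene t-statistics.
#' @return Signed scalar with `|directed| <= global`; `NA` for an empty
#'   set.
#' @export
directed_significance <- function(t) {
  if (length(t) == 0) return(NA_real_)
  s <- mean(sign(t) * t^2)
  sign(s) * sqrt(abs(s))
}

#' Per-sample pathway Z-score
#'
#' Summarises a gene set's normalized expression into one score per
#' sample: each gene is Z-scaled across samples, the first principal
#' component of the samples is extracted, its sign oriented so that the
#' mean gene loading is positive (higher score = higher average pathway
#' expression), and the scores are Z-scaled again.
#'
#' @param mat Log2 normalized expression, set genes by samples.
#' @return Named numeric vector of per-sample scores (mean 0, sd 1), or
#'   `NULL` when no gene has variance.
#' @export
pathway_z <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) {
    abort("pathway_z needs at least 3 samples",
          class = "immunopanel_validation_error")
  }
  v <- apply(mat, 1, sd)
  if (any(v == 0)) {
    inform(paste0("dropping zero-variance gene(s) from pathway: ",
                  paste(rownames(mat)[v == 0], collapse = ", ")))
    mat <- mat[v > 0, , drop = FALSE]
  }
  if (nrow(mat) == 0) return(NULL)
  z <- (mat - rowMeans(mat)) / apply(mat, 1, sd)
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (mean(pc$rotation[, 1]) < 0) scores <- -scores
  scores <- (scores - mean(scores)) / sd(scores)
  setNames(scores, colnames(mat))
}

#' Score every gene set against DE results and expression
#'
#' Produces, per set and contrast, the global and directed significance
#' scores of the set's tested genes, and per set and sample the pathway
#' Z-score. Genes belonging to several sets are scored in each set
#' independently; sets with no gene on the panel yield a warning and no
#' rows.
#'
#' @param de A `de_result` tibble (possibly several contrasts).
#' @param x A normalized `panel_experiment`.
#' @param gene_sets Named list of gene symbol vectors.
#' @param pseudocount Log-guard for expression.
#' @return List with `significance` (tibble: `set`, `contrast`,
#'   `n_genes`, `global`, `directed`) and `pathway_z` (tibble: `set`,
#'   `sample_id`, `z`).
#' @export
score_gene_sets <- function(de, x, gene_sets, pseudocount = 0.5) {
  stopifnot(inherits(x, "panel_experiment"))
  expr <- gene_matrix(x, classes = "endogenous", log2 = TRUE,
                      pseudocount = pseudocount)
  sig <- purrr::imap_dfr(gene_sets, function(genes, set) {
    de |>
      filter(.data$gene_symbol %in% genes) |>
      group_by(.data$contrast) |>
      summarise(set = set, n_genes = n(),
                global = global_significance(.data$t),
                directed = directed_significance(.data$t),
                .groups = "drop")
  }) |>
    select("set", "contrast", "n_genes", "global", "directed")
  pz <- purrr::imap_dfr(gene_sets, function(genes, set) {
    present <- intersect(genes, rownames(expr))
    if (length(present) == 0) {
      warn(paste0("gene set has no panel genes: ", set))
      return(tibble())
    }
    z <- pathway_z(expr[present, , drop = FALSE])
    if (is.null(z)) return(tibble())
    tibble(set = set, sample_id = names(z), z = unname(z))
  })
  list(significance = sig, pathway_z = pz)
}

#' Pivot per-sample pathway Z-scores to a sets-by-samples matrix
#'
#' @param pathway_z Tibble `set`, `sample_id`, `z` from
#'   [score_gene_sets()].
#' @return Numeric matrix, sets by samples.
#' @export
pathway_z_matrix <- function(pathway_z) {
  wide <- pathway_z |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "z")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$set
  m
}
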