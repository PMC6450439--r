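#' Marker-based immune cell-type scores
#'
#' The score of a cell type in a sample is the mean log2 normalized
#' expression of the type's marker genes: a relative-abundance proxy.
#' Scores can be compared within a cell type across samples or groups,
#' never across cell types.
#'
#' @param x A normalized `panel_experiment`.
#' @param marker_map Tibble `cell_type`, `gene_symbol` (e.g.
#'   [default_marker_map()]).
#' @param exclude Marker genes removed by the background filter.
#' @param pseudocount Log-guard.
#' @return Tibble `sample_id`, `cell_type`, `score`, `n_markers`. Types
#'   with every marker excluded are dropped with a warning.
#' @export
cell_scores <- function(x, marker_map, exclude = character(),
                        pseudocount = 0.5) {
  stopifnot(inherits(x, "panel_experiment"))
  expr <- gene_matrix(x, classes = "endogenous", log2 = TRUE,
                      pseudocount = pseudocount)
  types <- split(marker_map$gene_symbol, marker_map$cell_type)
  purrr::imap_dfr(types, function(markers, type) {
    usable <- setdiff(intersect(markers, rownames(expr)), exclude)
    if (length(usable) == 0) {
      warn(paste0("all markers of ", type, " are excluded or absent"))
      return(tibble())
    }
    sub <- expr[usable, , drop = FALSE]
    tibble(sample_id = colnames(sub), cell_type = type,
           score = colMeans(sub), n_markers = length(usable))
  })
}

#' Marker-coherence confidence p-value
#'
#' For a multi-marker cell type, tests whether the markers co-vary
#' across samples as a common abundance signal would make them: the
#' statistic is the mean pairwise Pearson correlation among markers, and
#' its null distribution is built by independently permuting each
#' marker's values across samples. One-sided p with the +1 correction.
#'
#' @param mat Log2 normalized expression, the type's markers by samples
#'   (at least 2 markers, 4 samples).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return List with `p`, `statistic` (observed mean pairwise
#'   correlation) and `n_perm`.
#' @export
marker_confidence <- function(mat, n_perm = 10000, seed = 1) {
  mat <- as.matrix(mat)
  g <- nrow(mat); s <- ncol(mat)
  if (g < 2) {
    abort("marker confidence needs at least 2 markers",
          class = "immunopanel_validation_error")
  }
  if (s < 4) {
    abort("marker confidence needs at least 4 samples",
          class = "immunopanel_validation_error")
  }
  z <- (mat - rowMeans(mat)) / apply(mat, 1, sd)
  # mean pairwise correlation via sums of per-sample column totals:
  # sum over pairs of z_j . z_k = (colsum^2 - sum of squares) / 2
  pair_stat <- function(zz) {
    cs <- colSums(zz)
    (sum(cs^2) - sum(zz^2)) / 2 / (s - 1) / (g * (g - 1) / 2)
  }
  obs <- pair_stat(z)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    zp <- z
    for (j in seq_len(g)) zp[j, ] <- z[j, sample.int(s)]
    pair_stat(zp)
  }, 0)
  list(p = (1 + sum(perm >= obs)) / (n_perm + 1), statistic = obs,
       n_perm = n_perm)
}

#' Confidence p-values for every multi-marker cell type
#'
#' @param x A normalized `panel_experiment`.
#' @param marker_map Tibble `cell_type`, `gene_symbol`.
#' @param exclude Excluded marker genes.
#' @param n_perm,seed Permutation settings (see [marker_confidence()]).
#' @param pseudocount Log-guard.
#' @return Tibble `cell_type`, `n_markers`, `statistic`, `confidence_p`;
#'   single-marker types are reported with `confidence_p = NA`.
#' @export
cell_confidence <- function(x, marker_map, exclude = character(),
                            n_perm = 10000, seed = 1, pseudocount = 0.5) {
  expr <- gene_matrix(x, classes = "endogenous", log2 = TRUE,
                      pseudocount = pseudocount)
  types <- split(marker_map$gene_symbol, marker_map$cell_type)
  purrr::imap_dfr(types, function(markers, type) {
    usable <- setdiff(intersect(markers, rownames(expr)), exclude)
    if (length(usable) == 0) return(tibble())
    if (length(usable) == 1) {
      return(tibble(cell_type = type, n_markers = 1L,
                    statistic = NA_real_, confidence_p = NA_real_))
    }
    mc <- marker_confidence(expr[usable, , drop = FALSE], n_perm = n_perm,
                            seed = seed)
    tibble(cell_type = type, n_markers = length(usable),
           statistic = mc$statistic, confidence_p = mc$p)
  })
}

#' Two-group rank-sum comparison of values
#'
#' Two-sided Wilcoxon rank-sum p-value: exact enumeration when the total
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with continuity correction. Fully tied data gives
#' p = 1.
#'
#' @param case,reference Numeric vectors (each of length >= 2).
#' @return List with `p` and `direction` (sign of the median
#'   difference).
#' @export
rank_sum_test <- function(case, reference) {
  if (length(case) < 2 || length(reference) < 2) {
    abort("need at least 2 samples per group",
          class = "immunopanel_validation_error")
  }
  direction <- sign(median(case) - median(reference))
  if (length(unique(c(case, reference))) == 1) {
    return(list(p = 1, direction = 0))
  }
  total <- length(case) + length(reference)
  ties <- anyDuplicated(c(case, reference)) > 0
  p <- if (total <= 20 && !ties) {
    suppressWarnings(
      wilcox.test(case, reference, exact = TRUE)$p.value)
  } else if (total <= 20) {
    # exact enumeration over group assignments, valid under ties
    r <- rank(c(case, reference))
    m <- length(case)
    w_obs <- sum(r[seq_len(m)])
    w_all <- utils::combn(total, m, function(idx) sum(r[idx]))
    min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  } else {
    suppressWarnings(
      wilcox.test(case, reference, exact = FALSE, correct = TRUE)$p.value)
  }
  list(p = p, direction = direction)
}

#' Compare cell-type scores between contrast groups
#'
#' One rank-sum test per cell type; results stay within the cell type
#' and are never ranked across types.
#'
#' @param scores Tibble from [cell_scores()].
#' @param contrast A [contrast()].
#' @return Tibble `cell_type`, `n_case`, `n_reference`, `direction`,
#'   `p`.
#' @export
compare_cell_groups <- function(scores, contrast) {
  stopifnot(inherits(contrast, "contrast"))
  scores |>
    group_by(.data$cell_type) |>
    summarise({
      case <- .data$score[.data$sample_id %in% contrast$case]
      ref <- .data$score[.data$sample_id %in% contrast$reference]
      rs <- rank_sum_test(case, ref)
      tibble(n_case = length(case), n_reference = length(ref),
             direction = rs$direction, p = rs$p)
    }, .groups = "drop")
}
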