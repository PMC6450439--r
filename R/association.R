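#' Pathway-phenotype Spearman correlation screen
#'
#' Correlates every pathway's per-sample Z-score with every phenotype
#' endpoint over the shared samples, using average-rank tie handling and
#' a two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. A cell is significant when
#' `rho > 0.5` or `rho < -0.5` *and* `p < 0.05`; non-significant cells
#' can be masked downstream (blank-cell convention). Constant endpoints
#' give an undefined rho and are masked.
#'
#' @param pathway_z Tibble `set`, `sample_id`, `z` (from
#'   [score_gene_sets()]).
#' @param phenotypes Wide phenotype tibble with `sample_id`.
#' @param rho_cutoff,p_cutoff Significance rule thresholds.
#' @return Tibble `set`, `endpoint`, `n`, `rho`, `p`, `significant`.
#' @export
spearman_screen <- function(pathway_z, phenotypes, rho_cutoff = 0.5,
                            p_cutoff = 0.05) {
  endpoints <- setdiff(names(phenotypes), "sample_id")
  sets <- split(pathway_z, pathway_z$set)
  purrr::imap_dfr(sets, function(pz, set) {
    joined <- pz |> inner_join(phenotypes, by = "sample_id")
    purrr::map_dfr(endpoints, function(e) {
      keep <- stats::complete.cases(joined$z, joined[[e]])
      zz <- joined$z[keep]; yy <- joined[[e]][keep]
      n <- length(zz)
      if (n < 4 || sd(yy) == 0 || sd(zz) == 0) {
        return(tibble(set = set, endpoint = e, n = n, rho = NA_real_,
                      p = NA_real_, significant = FALSE))
      }
      rho <- cor(zz, yy, method = "spearman")
      p <- if (abs(rho) == 1) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tt), df = n - 2)
      }
      tibble(set = set, endpoint = e, n = n, rho = rho, p = p,
             significant = abs(rho) > rho_cutoff & p < p_cutoff)
    })
  })
}

#' Hierarchical clustering with Euclidean distance and average linkage
#'
#' Agglomerative (UPGMA) clustering of the rows or columns of a matrix.
#'
#' @param mat Numeric matrix.
#' @param axis Cluster `"rows"` or `"columns"`.
#' @return List with the `hclust` object, `leaf_order` (labels in
#'   dendrogram order) and `heights`.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "columns") t(mat) else as.matrix(mat)
  if (nrow(m) < 2) {
    abort("need at least 2 items to cluster",
          class = "immunopanel_validation_error")
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    abort(paste0("non-finite entries at rows: ",
                 paste(unique(bad[, 1]), collapse = ", ")),
          class = "immunopanel_validation_error")
  }
  hc <- hclust(dist(m), method = "average")
  list(hclust = hc, leaf_order = hc$labels[hc$order], heights = hc$height)
}

#' PCA summary with per-group confidence ellipses
#'
#' Column-centred (optionally unit-variance-scaled) PCA of a
#' samples-by-variables matrix, reporting PC1/PC2 coordinates, variance
#' explained, and a 95% normal-quantile ellipse per group (centre,
#' semi-axes from the chi-square quantile of the group covariance
#' eigenvalues, and orientation). Principal-component signs are oriented
#' so the mean loading is positive.
#'
#' @param mat Numeric matrix, samples by variables.
#' @param grouping Factor-like vector of group labels per sample (or
#'   `NULL`).
#' @param scale. Scale variables to unit variance (constant variables
#'   are dropped first).
#' @param level Ellipse coverage level.
#' @return List with `coordinates` (tibble `sample_id`, `group`, `PC1`,
#'   `PC2`), `variance_explained`, `ellipses` (tibble per group) and the
#'   `prcomp` fit.
#' @export
pca_summary <- function(mat, grouping = NULL, scale. = TRUE, level = 0.95) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) {
    abort("PCA summary needs at least 3 samples",
          class = "immunopanel_validation_error")
  }
  if (ncol(mat) < 2) {
    abort("PCA summary needs at least 2 variables",
          class = "immunopanel_validation_error")
  }
  if (scale.) {
    v <- apply(mat, 2, sd)
    mat <- mat[, v > 0, drop = FALSE]
  }
  pc <- prcomp(mat, center = TRUE, scale. = scale.)
  flip <- ifelse(colMeans(pc$rotation) < 0, -1, 1)
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  k <- min(2, ncol(pc$x))
  coords <- tibble(
    sample_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    group = if (is.null(grouping)) NA_character_ else as.character(grouping),
    PC1 = pc$x[, 1],
    PC2 = if (k >= 2) pc$x[, 2] else 0
  )
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ellipses <- NULL
  if (!is.null(grouping)) {
    r2 <- qchisq(level, df = 2)
    ellipses <- coords |>
      group_by(.data$group) |>
      summarise({
        xy <- cbind(.data$PC1, .data$PC2)
        ctr <- colMeans(xy)
        if (nrow(xy) >= 3 && sum(apply(xy, 2, sd) > 0) == 2) {
          ei <- eigen(stats::cov(xy), symmetric = TRUE)
          ang <- atan2(ei$vectors[2, 1], ei$vectors[1, 1])
          tibble(center_x = ctr[1], center_y = ctr[2],
                 semi_major = sqrt(max(ei$values, 0) * r2),
                 semi_minor = sqrt(max(min(ei$values), 0) * r2),
                 angle = ang)
        } else {
          tibble(center_x = ctr[1], center_y = ctr[2],
                 semi_major = NA_real_, semi_minor = NA_real_,
                 angle = NA_real_)
        }
      }, .groups = "drop")
  }
  list(coordinates = coords, variance_explained = ve, ellipses = ellipses,
       fit = pc)
}

#' Exact Venn region cardinalities of named gene sets
#'
#' For 2 to 5 named sets, counts and lists the members of every
#' exclusive region (each combination of "in these sets, not in those").
#' Region sizes sum exactly to the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return Tibble `region` (e.g. `"A&B"`), `n_sets`, `size`, `members`
#'   (list column).
#' @export
venn_overlaps <- function(sets) {
  if (length(sets) < 2) {
    abort("need at least 2 sets", class = "immunopanel_validation_error")
  }
  if (length(sets) > 5) {
    abort("more than 5 sets is unsupported",
          class = "immunopanel_validation_error")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be named", class = "immunopanel_validation_error")
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  combos <- purrr::map(seq_along(sets), ~ utils::combn(names(sets), .x,
                                                       simplify = FALSE)) |>
    purrr::flatten()
  purrr::map_dfr(combos, function(cmb) {
    rkey <- paste(cmb, collapse = "&")
    members <- universe[key == rkey]
    tibble(region = rkey, n_sets = length(cmb), size = length(members),
           members = list(members))
  })
}
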