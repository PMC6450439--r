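#' Fit the negative-control background model
#'
#' Pools the negative-probe counts across all lanes and summarises them
#' as a mean, a sample standard deviation (n-1 denominator), and the
#' exclusion threshold `mean + 2 * sd` used to flag genes indistinguishable
#' from background.
#'
#' @param x A `panel_experiment` (negative probes are extracted), or a
#'   numeric vector/matrix of negative-probe counts.
#' @return A `background_model`: list with `mean_background`,
#'   `sd_background`, `threshold`.
#' @export
fit_background <- function(x) {
  neg <- if (inherits(x, "panel_experiment")) class_counts(x, "negative") else x
  neg <- as.numeric(neg)
  if (length(neg) < 2) {
    abort("need at least 2 negative-probe observations",
          class = "immunopanel_validation_error")
  }
  m <- mean(neg)
  s <- sd(neg)
  structure(list(mean_background = m, sd_background = s,
                 threshold = m + 2 * s),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> mean %.3f, sd %.3f, threshold %.3f\n",
              x$mean_background, x$sd_background, x$threshold))
  invisible(x)
}

#' @export
tidy.background_model <- function(x, ...) {
  tibble(mean_background = x$mean_background,
         sd_background = x$sd_background, threshold = x$threshold)
}

#' Subtract background from endogenous and housekeeping counts
#'
#' Reduces every endogenous and housekeeping count by the mean
#' background and floors at zero; control probes are left untouched.
#'
#' @param x A raw-stage `panel_experiment`.
#' @param background A `background_model` from [fit_background()].
#' @return The experiment at stage `background_subtracted`.
#' @export
subtract_background <- function(x, background) {
  stopifnot(inherits(x, "panel_experiment"),
            inherits(background, "background_model"))
  if (x$stage != "raw") {
    abort("background subtraction expects a raw-stage experiment",
          class = "immunopanel_validation_error")
  }
  target <- x$panel$probe_class %in% c("endogenous", "housekeeping")
  counts <- x$counts
  counts[target, ] <- pmax(counts[target, ] - background$mean_background, 0)
  out <- x
  out$counts <- counts
  out$stage <- "background_subtracted"
  out$background <- background
  out
}

#' Flag genes expressed below background
#'
#' A gene is excluded from an analysis unit when its mean raw count over
#' that unit's samples falls strictly below the background threshold
#' (`mean + 2 * sd` of the negative probes). Analysis units default to
#' tissue-by-regimen cells so each contrast keeps a consistent gene
#' universe.
#'
#' @param x A `panel_experiment` holding raw counts.
#' @param background A `background_model`.
#' @param by Metadata columns defining the analysis unit.
#' @return Tibble with the unit columns, `gene_symbol`, `mean_count`
#'   and `excluded`.
#' @export
flag_low_expression <- function(x, background, by = c("tissue", "regimen")) {
  stopifnot(inherits(x, "panel_experiment"))
  m <- gene_matrix(x, classes = "endogenous")
  units <- interaction(x$samples[by], drop = TRUE, sep = ":")
  purrr::map_dfr(levels(units), function(u) {
    cols <- x$samples$sample_id[units == u]
    mc <- rowMeans(m[, cols, drop = FALSE])
    meta <- x$samples[match(cols[1], x$samples$sample_id), by]
    tibble(meta, gene_symbol = rownames(m), mean_count = unname(mc),
           excluded = unname(mc) < background$threshold)
  })
}

#' Excluded genes for one analysis unit
#'
#' @param flags Output of [flag_low_expression()].
#' @param ... Filters identifying the unit (e.g. `tissue == "lung"`).
#' @return Character vector of excluded gene symbols.
#' @export
excluded_genes <- function(flags, ...) {
  flags |>
    filter(..., .data$excluded) |>
    distinct(.data$gene_symbol) |>
    pull("gene_symbol")
}

geomean <- function(x) exp(mean(log(x)))

#' Positive-control normalization factors
#'
#' Each lane's factor is the arithmetic mean (over lanes) of the lane
#' geometric means of the positive probes, divided by that lane's
#' geometric mean. Applying the factor multiplicatively equalises the
#' spike-in signal across lanes.
#'
#' @param x A `panel_experiment`.
#' @return Tibble of `sample_id` and `positive_factor`.
#' @export
positive_control_factors <- function(x) {
  pos <- class_counts(x, "positive")
  if (any(pos == 0)) {
    abort("zero positive-control count: geometric mean undefined",
          class = "immunopanel_validation_error")
  }
  g <- apply(pos, 2, geomean)
  tibble(sample_id = colnames(pos), positive_factor = unname(mean(g) / g))
}

#' geNorm housekeeping stability analysis
#'
#' Computes, for each candidate reference gene, the geNorm stability
#' measure M: the mean over all other candidates of the standard
#' deviation across samples of the pairwise log2 expression ratio.
#' The least stable gene (highest M, ties broken lexicographically by
#' symbol) is removed and M recomputed until two genes remain. The
#' pairwise variation `V(k, k+1)` is the standard deviation across
#' samples of the log2 ratio of normalization factors (geometric means)
#' built from the k and k+1 most stable genes; the selected set is the
#' smallest `k >= 3` with `V < v_cutoff`, falling back to the k with
#' minimal V.
#'
#' @param x A `panel_experiment` (housekeeping probes are used) or a
#'   log2 expression matrix, genes by samples.
#' @param pseudocount Added before log2 when `x` is an experiment.
#' @param v_cutoff Pairwise-variation cutoff (conventional 0.15).
#' @return A `genorm_result`: `stability` tibble (gene, M at first
#'   round), `removal_order`, `ranking` (most to least stable),
#'   `pairwise_variation` tibble (k, V), `selected` genes.
#' @export
genorm_stability <- function(x, pseudocount = 0.5, v_cutoff = 0.15) {
  mat <- if (inherits(x, "panel_experiment")) {
    log2(class_counts(x, "housekeeping") + pseudocount)
  } else {
    as.matrix(x)
  }
  if (inherits(x, "panel_experiment")) {
    rownames(mat) <-
      x$panel$gene_symbol[x$panel$probe_class == "housekeeping"]
  }
  if (nrow(mat) < 3) {
    abort("geNorm needs at least 3 candidate housekeeping genes",
          class = "immunopanel_validation_error")
  }
  if (ncol(mat) < 2) {
    abort("geNorm needs at least 2 samples",
          class = "immunopanel_validation_error")
  }

  m_values <- function(sub) {
    vapply(seq_len(nrow(sub)), function(j) {
      others <- setdiff(seq_len(nrow(sub)), j)
      mean(vapply(others, function(k) sd(sub[j, ] - sub[k, ]), 0))
    }, 0)
  }

  removal <- character()
  current <- mat
  first_m <- NULL
  while (nrow(current) > 2) {
    m <- m_values(current)
    if (is.null(first_m)) {
      first_m <- tibble(gene = rownames(current), M = m)
    }
    worst <- max(m)
    # lexicographic tie-break keeps removal deterministic
    drop_gene <- sort(rownames(current)[m == worst])[1]
    removal <- c(removal, drop_gene)
    current <- current[setdiff(rownames(current), drop_gene), , drop = FALSE]
  }
  ranking <- c(sort(rownames(current)), rev(removal))

  n <- length(ranking)
  vk <- purrr::map_dfr(2:(n - 1), function(k) {
    nf_k <- colMeans(mat[ranking[1:k], , drop = FALSE])
    nf_k1 <- colMeans(mat[ranking[1:(k + 1)], , drop = FALSE])
    tibble(k = k, V = sd(nf_k - nf_k1))
  })
  eligible <- vk |> filter(.data$k >= 3, .data$V < v_cutoff)
  k_sel <- if (nrow(eligible) > 0) min(eligible$k) else vk$k[which.min(vk$V)]
  structure(list(
    stability = first_m,
    removal_order = removal,
    ranking = ranking,
    pairwise_variation = vk,
    selected = ranking[seq_len(k_sel)]
  ), class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result>", length(x$ranking), "candidates;",
      length(x$selected), "selected:",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.genorm_result <- function(x, ...) {
  x$stability |>
    mutate(rank = match(.data$gene, x$ranking),
           selected = .data$gene %in% x$selected) |>
    arrange(.data$rank)
}

#' @export
glance.genorm_result <- function(x, ...) {
  tibble(n_candidates = length(x$ranking), n_selected = length(x$selected),
         min_V = min(x$pairwise_variation$V))
}

#' Positive-control and housekeeping normalization
#'
#' Multiplies each lane first by its positive-control factor and then by
#' a housekeeping factor computed the same way from the selected
#' housekeeping genes (after positive-control scaling). After
#' normalization the per-lane geometric mean of the selected
#' housekeeping genes is identical across lanes.
#'
#' @param x A `background_subtracted` `panel_experiment`.
#' @param housekeeping Character vector of selected housekeeping gene
#'   symbols (e.g. from [genorm_stability()]).
#' @param pseudocount Replaces zero housekeeping counts before geometric
#'   means (logged when triggered).
#' @return The experiment at stage `normalized`, with a `norm_factors`
#'   tibble (`sample_id`, `positive_factor`, `housekeeping_factor`).
#' @export
normalize_counts <- function(x, housekeeping, pseudocount = 0.5) {
  stopifnot(inherits(x, "panel_experiment"))
  if (x$stage != "background_subtracted") {
    abort("normalize_counts expects a background_subtracted experiment",
          class = "immunopanel_validation_error")
  }
  if (length(housekeeping) == 0) {
    abort("selected housekeeping set is empty",
          class = "immunopanel_validation_error")
  }
  hk_ids <- x$panel$probe_id[x$panel$gene_symbol %in% housekeeping &
                               x$panel$probe_class == "housekeeping"]
  if (length(hk_ids) == 0) {
    abort("no housekeeping probes match the selected genes",
          class = "immunopanel_validation_error")
  }
  pf <- positive_control_factors(x)
  counts <- sweep(x$counts, 2, pf$positive_factor, `*`)

  hk <- counts[hk_ids, , drop = FALSE]
  if (any(hk == 0)) {
    inform("zero housekeeping count: applying pseudocount before geometric mean")
    hk <- hk + pseudocount
  }
  g <- apply(hk, 2, geomean)
  hf <- mean(g) / g
  counts <- sweep(counts, 2, hf, `*`)

  out <- x
  out$counts <- counts
  out$stage <- "normalized"
  out$norm_factors <- tibble(sample_id = colnames(counts),
                             positive_factor = pf$positive_factor,
                             housekeeping_factor = unname(hf))
  out$housekeeping_used <- sort(intersect(
    housekeeping, x$panel$gene_symbol[x$panel$probe_class == "housekeeping"]))
  out
}
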