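#' Define a case-vs-reference contrast
#'
#' @param name Contrast label (e.g. `"Acute.4x"`, `"Lung.W13"`).
#' @param case,reference Disjoint sample-id vectors, each with at least
#'   two samples.
#' @return A `contrast` object.
#' @export
contrast <- function(name, case, reference) {
  if (length(intersect(case, reference)) > 0) {
    abort("case and reference samples overlap",
          class = "immunopanel_validation_error")
  }
  if (length(case) < 2 || length(reference) < 2) {
    abort("each contrast side needs at least 2 samples",
          class = "immunopanel_validation_error")
  }
  structure(list(name = name, case = case, reference = reference),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("<contrast> %s: %d case vs %d reference samples\n",
              x$name, length(x$case), length(x$reference)))
  invisible(x)
}

#' Build the study's standard treated-vs-vehicle contrasts
#'
#' One contrast per regimen-by-time-by-tissue cell that contains both
#' treated and vehicle samples, each treated group matched to its
#' dosing-, time- and tissue-matched vehicle. Acute cells (sampled at
#' `day1`) are named `Acute.1x` / `Acute.4x`; chronic cells are named
#' `<Tissue>.<Week>`.
#'
#' @param samples Sample metadata tibble.
#' @return Named list of `contrast` objects.
#' @export
build_contrasts <- function(samples) {
  samples <- validate_samples(samples)
  cells <- samples |>
    distinct(.data$regimen, .data$time_point, .data$tissue)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    in_cell <- samples |>
      filter(.data$regimen == cell$regimen,
             .data$time_point == cell$time_point,
             .data$tissue == cell$tissue)
    case <- in_cell$sample_id[in_cell$treatment == "cSiO2"]
    ref <- in_cell$sample_id[in_cell$treatment == "VEH"]
    if (length(case) < 2 || length(ref) < 2) next
    nm <- if (cell$time_point == "day1") {
      if (cell$regimen == "single") "Acute.1x" else "Acute.4x"
    } else {
      paste0(toupper(substring(cell$tissue, 1, 1)),
             substring(cell$tissue, 2), ".", cell$time_point)
    }
    out[[nm]] <- contrast(nm, case, ref)
  }
  out
}

#' Per-gene and per-sample log2 ratios for a contrast
#'
#' The per-gene ratio is `log2(mean_case / mean_reference)` of
#' normalized counts (pseudocount-guarded); the per-sample ratio, used
#' for heatmap exports, is `log2(sample / mean_reference)` for every
#' case and reference sample.
#'
#' @param x A normalized `panel_experiment`.
#' @param contrast A [contrast()].
#' @param pseudocount Added to means before the log.
#' @param per_sample If `TRUE`, also return per-sample ratios.
#' @return Tibble `gene_symbol`, `log2_ratio`; with `per_sample = TRUE`
#'   a list with `per_gene` and `per_sample` tibbles.
#' @export
log2_ratio <- function(x, contrast, pseudocount = 0.5, per_sample = FALSE) {
  stopifnot(inherits(x, "panel_experiment"), inherits(contrast, "contrast"))
  if (x$stage != "normalized") {
    abort("log2_ratio expects a normalized experiment",
          class = "immunopanel_validation_error")
  }
  m <- gene_matrix(x, classes = "endogenous")
  mc <- rowMeans(m[, contrast$case, drop = FALSE])
  mr <- rowMeans(m[, contrast$reference, drop = FALSE])
  per_gene <- tibble(gene_symbol = rownames(m),
                     log2_ratio = unname(log2(mc + pseudocount) -
                                           log2(mr + pseudocount)))
  if (!per_sample) return(per_gene)
  samp <- m[, c(contrast$case, contrast$reference), drop = FALSE]
  ps <- log2(samp + pseudocount) - log2(mr + pseudocount)
  list(per_gene = per_gene,
       per_sample = as_tibble(ps, rownames = "gene_symbol") |>
         tidyr::pivot_longer(-"gene_symbol", names_to = "sample_id",
                             values_to = "log2_ratio"))
}

#' Log-linear per-gene test
#'
#' Ordinary least squares of `log2(normalized count + pseudocount)` on a
#' case indicator; for a two-group design this is the pooled-variance
#' t-test with `n - 2` degrees of freedom. Genes with zero residual
#' variance are flagged degenerate (p = 0 when the group means differ,
#' p = 1 when they do not).
#'
#' @param x A normalized `panel_experiment` (or a log2 expression matrix
#'   with gene rownames).
#' @param contrast A [contrast()].
#' @param pseudocount Added before the log when `x` is an experiment.
#' @return Tibble `gene_symbol`, `estimate` (log2 units), `t`, `p`,
#'   `degenerate`.
#' @export
fit_log_linear <- function(x, contrast, pseudocount = 0.5) {
  y <- if (inherits(x, "panel_experiment")) {
    gene_matrix(x, classes = "endogenous", log2 = TRUE,
                pseudocount = pseudocount)
  } else {
    as.matrix(x)
  }
  y1 <- y[, contrast$case, drop = FALSE]
  y0 <- y[, contrast$reference, drop = FALSE]
  n1 <- ncol(y1); n0 <- ncol(y0); n <- n1 + n0
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  ss <- rowSums((y1 - m1)^2) + rowSums((y0 - m0)^2)
  s2 <- ss / (n - 2)
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  est <- m1 - m0
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, ifelse(est == 0, 0, sign(est) * Inf), est / se)
  p <- ifelse(degenerate, ifelse(est == 0, 1, 0),
              2 * pt(-abs(est / se), df = n - 2))
  tibble(gene_symbol = rownames(y), estimate = unname(est),
         t = unname(t_stat), p = unname(p), degenerate = unname(degenerate))
}

#' Simplified negative-binomial per-gene test
#'
#' Negative-binomial regression of raw counts on a case indicator with a
#' log link and a lane offset equal to the log of the inverse combined
#' normalization factor (so coefficients are on the normalized scale).
#' The gene dispersion is estimated by the method of moments on Poisson
#' residuals (`alpha = sum((y - mu)^2 - mu) / sum(mu^2)`, floored at
#' 1e-8) and held fixed in a final weighted fit; the Wald t on the case
#' coefficient is referenced to `n - 2` degrees of freedom. Fit failures
#' fall back to the log-linear model, recorded in `model_used`.
#'
#' @param x A raw-stage (or background-subtracted) `panel_experiment`
#'   holding counts.
#' @param contrast A [contrast()].
#' @param factors Tibble with `sample_id` and combined normalization
#'   factor column `factor` (e.g. positive x housekeeping factor).
#' @return Tibble `gene_symbol`, `estimate` (log2 units), `t`, `p`,
#'   `dispersion`, `model_used`.
#' @export
fit_simplified_nb <- function(x, contrast, factors) {
  stopifnot(inherits(x, "panel_experiment"), inherits(contrast, "contrast"))
  m <- gene_matrix(x, classes = "endogenous")
  samples <- c(contrast$case, contrast$reference)
  f <- factors$factor[match(samples, factors$sample_id)]
  if (anyNA(f)) {
    abort("missing normalization factor for contrast samples",
          class = "immunopanel_validation_error")
  }
  group <- as.integer(samples %in% contrast$case)
  offset <- log(1 / f)
  n <- length(samples)
  ll <- NULL
  res <- purrr::map_dfr(rownames(m), function(g) {
    y <- round(m[g, samples])
    fit <- tryCatch({
      pois <- suppressWarnings(
        glm(y ~ group, family = poisson(), offset = offset))
      mu <- pois$fitted.values
      alpha <- max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-8)
      nb <- suppressWarnings(
        glm(y ~ group, family = MASS::negative.binomial(theta = 1 / alpha),
            offset = offset))
      # dispersion pinned at 1: the NB family already carries the
      # mean-variance relation, so the Wald SE must not be rescaled
      sm <- summary(nb, dispersion = 1)$coefficients
      est_ln <- sm["group", "Estimate"]
      se <- sm["group", "Std. Error"]
      tibble(gene_symbol = g, estimate = est_ln / log(2),
             t = est_ln / se, p = 2 * pt(-abs(est_ln / se), df = n - 2),
             dispersion = alpha, model_used = "simplified_nb")
    }, error = function(e) NULL)
    if (!is.null(fit)) return(fit)
    # fall back to the log-linear model for this gene
    if (is.null(ll)) {
      ll <<- fit_log_linear(
        log2(sweep(m[, samples, drop = FALSE], 2, f, `*`) + 0.5), contrast)
    }
    ll |>
      filter(.data$gene_symbol == g) |>
      mutate(dispersion = NA_real_, model_used = "log_linear") |>
      select("gene_symbol", "estimate", "t", "p", "dispersion", "model_used")
  })
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH q-values with monotonicity enforcement.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]",
          class = "immunopanel_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' The differential-expression calling rule
#'
#' A gene is significant when `q < 0.05` and `log2_ratio > 1` or
#' `< -1` (strict inequalities: a two-fold change exactly at the
#' boundary is not called).
#'
#' @param q BH q-values.
#' @param log2_ratio Per-gene log2 ratios.
#' @param q_cutoff,lfc_cutoff Thresholds of the rule.
#' @return Logical vector.
#' @export
call_de <- function(q, log2_ratio, q_cutoff = 0.05, lfc_cutoff = 1) {
  q < q_cutoff & abs(log2_ratio) > lfc_cutoff
}

#' Run differential expression for one contrast
#'
#' Combines the log2 ratio of group means, the chosen per-gene model's
#' t and p, BH adjustment within the contrast, and the calling rule.
#'
#' @param x A normalized `panel_experiment`.
#' @param contrast A [contrast()].
#' @param model `"log_linear"` (default) or `"nb"`; the model is chosen
#'   globally per run and recorded per gene.
#' @param exclude Gene symbols excluded by the background filter.
#' @param raw For `model = "nb"`, the raw-stage experiment.
#' @param q_cutoff,lfc_cutoff Calling-rule thresholds.
#' @param pseudocount Log-guard for ratios and the log-linear model.
#' @return A `de_result` tibble: `contrast`, `gene_symbol`,
#'   `log2_ratio`, `t`, `p`, `q`, `significant`, `model_used`.
#' @export
run_de <- function(x, contrast, model = c("log_linear", "nb"),
                   exclude = character(), raw = NULL,
                   q_cutoff = 0.05, lfc_cutoff = 1, pseudocount = 0.5) {
  model <- match.arg(model)
  ratios <- log2_ratio(x, contrast, pseudocount = pseudocount)
  if (model == "log_linear") {
    fit <- fit_log_linear(x, contrast, pseudocount = pseudocount) |>
      mutate(model_used = ifelse(.data$degenerate, "log_linear_degenerate",
                                 "log_linear"))
  } else {
    if (is.null(raw)) {
      abort("model = 'nb' needs the raw-stage experiment via `raw`",
            class = "immunopanel_validation_error")
    }
    f <- x$norm_factors
    if (is.null(f)) {
      abort("normalized experiment carries no norm_factors",
            class = "immunopanel_validation_error")
    }
    fit <- fit_simplified_nb(raw, contrast,
                             tibble(sample_id = f$sample_id,
                                    factor = f$positive_factor *
                                      f$housekeeping_factor))
  }
  out <- ratios |>
    inner_join(fit |> select("gene_symbol", "t", "p", "model_used"),
               by = "gene_symbol") |>
    filter(!(.data$gene_symbol %in% exclude))
  out |>
    mutate(q = bh_adjust(.data$p),
           significant = call_de(.data$q, .data$log2_ratio,
                                 q_cutoff, lfc_cutoff),
           contrast = contrast$name, .before = 1) |>
    select("contrast", "gene_symbol", "log2_ratio", "t", "p", "q",
           "significant", "model_used")
}

#' Sequential within-treatment time contrasts
#'
#' Compares consecutive time points within the treated arm (later vs
#' earlier), with the same per-gene machinery and calling rule as the
#' treated-vs-vehicle contrasts.
#'
#' @param x A normalized `panel_experiment`.
#' @param treatment Treated arm to follow over time.
#' @param time_points Ordered time points (at least two).
#' @param tissue Tissue to restrict to.
#' @param ... Passed to [run_de()].
#' @return A `de_result` tibble with one block per consecutive pair
#'   (e.g. `W5-vs-W1`).
#' @export
sequential_contrasts <- function(x, treatment = "cSiO2",
                                 time_points = c("W1", "W5", "W9", "W13"),
                                 tissue = "lung", ...) {
  stopifnot(inherits(x, "panel_experiment"))
  if (length(time_points) < 2) {
    abort("need at least two time points for sequential contrasts",
          class = "immunopanel_validation_error")
  }
  bad <- setdiff(time_points, unique(x$samples$time_point))
  if (length(bad) > 0) {
    abort(paste0("unknown time point(s): ", paste(bad, collapse = ", ")),
          class = "immunopanel_validation_error")
  }
  ids <- function(tp) {
    x$samples$sample_id[x$samples$treatment == treatment &
                          x$samples$time_point == tp &
                          x$samples$tissue == tissue]
  }
  purrr::map_dfr(seq_len(length(time_points) - 1), function(i) {
    earlier <- time_points[i]; later <- time_points[i + 1]
    cn <- contrast(paste0(later, "-vs-", earlier), ids(later), ids(earlier))
    run_de(x, cn, ...)
  })
}
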