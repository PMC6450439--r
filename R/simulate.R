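#' Default study design for simulated experiments
#'
#' Emulates a two-arm instillation study: a single-dose cohort sampled one
#' day after dosing (lung), a four-weekly-dose cohort sampled one day
#' after the last dose (lung), and a chronic four-weekly cohort sampled
#' 1, 5, 9 and 13 weeks after the last dose (lung at every time point;
#' kidney and spleen at week 13). Each treatment-by-time-by-tissue cell
#' has `n_per_group` replicates of vehicle (VEH) and particle (cSiO2)
#' exposed animals.
#'
#' @param n_per_group Replicates per design cell (default 8).
#' @return A sample-metadata tibble (see [validate_samples()]).
#' @export
default_design <- function(n_per_group = 8) {
  cells <- tibble(
    regimen    = c("single", "four_weekly", rep("four_weekly", 4),
                   "four_weekly", "four_weekly"),
    time_point = c("day1", "day1", "W1", "W5", "W9", "W13", "W13", "W13"),
    tissue     = c("lung", "lung", "lung", "lung", "lung", "lung",
                   "kidney", "spleen")
  )
  tidyr::crossing(cells, treatment = c("VEH", "cSiO2"),
                  replicate = seq_len(n_per_group)) |>
    mutate(sample_id = sprintf("%s_%s_%s_%s_r%d", .data$treatment,
                               .data$regimen, .data$time_point, .data$tissue,
                               .data$replicate)) |>
    select("sample_id", "treatment", "regimen", "time_point", "tissue",
           "replicate") |>
    validate_samples()
}

#' Simulate a panel annotation with gene sets and a cell-marker map
#'
#' Builds a targeted panel: endogenous genes, housekeeping genes, a
#' geometric positive-control concentration ladder, and negative
#' background probes. Endogenous genes are assigned to overlapping gene
#' sets (every gene has a primary set; a fraction is shared into a second
#' set, since genes can serve several immune pathways). Cell-type marker
#' genes are disjoint across cell types.
#'
#' @param n_endogenous,n_housekeeping,n_positive,n_negative Probe counts
#'   per class (defaults mirror a 770/40/6/8 immune panel).
#' @param n_sets Number of gene sets.
#' @param n_cell_types Number of cell types in the marker map.
#' @param markers_per_type Markers per cell type.
#' @param overlap_fraction Fraction of each set's genes shared into a
#'   second set.
#' @param marker_map Optional marker-map tibble (`cell_type`,
#'   `gene_symbol`) whose genes are embedded verbatim among the
#'   endogenous genes; overrides `n_cell_types`/`markers_per_type`.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return List with `panel` (annotation tibble), `gene_sets` (named
#'   list) and `marker_map` (tibble).
#' @export
simulate_panel <- function(n_endogenous = 770, n_housekeeping = 40,
                           n_positive = 6, n_negative = 8, n_sets = 10,
                           n_cell_types = 6, markers_per_type = 3,
                           overlap_fraction = 0.1, marker_map = NULL,
                           seed = 1) {
  if (n_endogenous < 1 || n_housekeeping < 1 || n_positive < 1 ||
      n_sets < 1 || n_cell_types < 1) {
    abort("all panel class sizes must be >= 1",
          class = "immunopanel_validation_error")
  }
  if (n_negative < 2) {
    abort("need at least 2 negative probes to model background",
          class = "immunopanel_validation_error")
  }
  if (is.null(marker_map) && n_cell_types * markers_per_type > n_endogenous) {
    abort("marker map would need more genes than the panel holds",
          class = "immunopanel_validation_error")
  }
  set.seed(seed)
  genes <- sprintf("Gene%04d", seq_len(n_endogenous))
  if (!is.null(marker_map)) {
    mgenes <- unique(marker_map$gene_symbol)
    if (length(mgenes) > n_endogenous) {
      abort("marker map has more genes than the panel holds",
            class = "immunopanel_validation_error")
    }
    genes[seq_along(mgenes)] <- mgenes
  }
  hk <- sprintf("Hk%02d", seq_len(n_housekeeping))
  pos <- paste0("POS_", LETTERS[seq_len(n_positive)])
  neg <- paste0("NEG_", LETTERS[seq_len(n_negative)])
  ladder <- 128 * (1 / 4)^(seq_len(n_positive) - 1)
  symbol <- c(genes, hk, pos, neg)
  panel <- tibble(
    probe_id = sprintf("PRB%05d", seq_along(symbol)),
    gene_symbol = symbol,
    probe_class = rep(probe_classes,
                      c(n_endogenous, n_housekeeping, n_positive, n_negative)),
    ladder_concentration = c(rep(NA_real_, n_endogenous + n_housekeeping),
                             ladder, rep(NA_real_, n_negative))
  )

  # primary membership: contiguous blocks; overlap: borrow from the next set
  block <- split(genes, cut(seq_along(genes), breaks = n_sets, labels = FALSE))
  gene_sets <- purrr::map(seq_len(n_sets), function(i) {
    nxt <- block[[if (i == n_sets) 1 else i + 1]]
    extra <- nxt[seq_len(max(0, round(overlap_fraction * length(nxt))))]
    unique(c(block[[i]], extra))
  })
  names(gene_sets) <- sprintf("pathway_%02d", seq_len(n_sets))

  if (is.null(marker_map)) {
    picked <- sample(genes, n_cell_types * markers_per_type)
    marker_map <- tibble(
      cell_type = rep(sprintf("cell_type_%02d", seq_len(n_cell_types)),
                      each = markers_per_type),
      gene_symbol = picked
    )
  }
  marker_map <- marker_map |>
    group_by(.data$cell_type) |>
    mutate(multi_marker = n() >= 2) |>
    ungroup()
  list(panel = validate_panel(panel), gene_sets = gene_sets,
       marker_map = marker_map)
}

#' Simulation configuration
#'
#' Tunable parameters of the count simulator. Counts are negative
#' binomial with variance `mu + mu^2 * dispersion`. Baseline means are
#' log-normal on the log2 scale; per-gene dispersions are gamma
#' distributed. A `responder_fraction` of single-dose treated samples are
#' "high responders" carrying the full planted log2 effect; the rest
#' carry `attenuation` times the effect. All four-weekly treated samples
#' respond fully. Latent disease severity grows linearly with time for
#' treated samples and stays 0 for vehicle.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of simulation parameters.
#' @export
sim_config <- function(...) {
  defaults <- list(
    baseline_log2_mean = 7,    # log2 counts
    baseline_log2_sd = 2,
    dispersion_shape = 2,      # gamma, mean shape/rate = 0.1
    dispersion_rate = 20,
    hk_baseline_log2_mean = 9, # housekeeping genes are high and tight
    hk_baseline_log2_sd = 0.8,
    hk_dispersion = 0.005,
    n_unstable_housekeeping = 0,
    unstable_sd = 1,           # extra per-sample log2 noise for planted
                               # unstable housekeeping genes
    de_fraction = 0.1,
    effect_size = 2,           # |log2 effect| of planted DE genes
    prop_up = 0.8,             # most induced genes go up in this model
    responder_fraction = 3 / 8,
    attenuation = 0.25,
    lane_scale_sd = 0.1,       # sdlog of per-lane scale factors
    background_mean = 10,      # Poisson mean of negative probes
    positive_scale = 150,      # counts per fM for the positive ladder
    tissue_scale = c(lung = 1, kidney = 1, spleen = 0.4),
    time_scale = c(day1 = 1, W1 = 1, W5 = 1, W9 = 1, W13 = 1),
    severity_max = 3
  )
  utils::modifyList(defaults, list(...))
}

time_weeks <- c(day1 = 1 / 7, W1 = 1, W5 = 5, W9 = 9, W13 = 13)

#' Simulate raw counts for a design
#'
#' Draws a raw-stage count matrix with known ground truth: planted
#' differentially expressed endogenous genes, stable (and optionally
#' planted-unstable) housekeeping genes, Poisson background on the
#' negative probes, and positive probes scaling linearly with the ladder
#' concentration times the lane scale factor.
#'
#' @param panel_sim Result of [simulate_panel()] (or a list with `panel`).
#' @param design Sample metadata tibble (e.g. [default_design()]).
#' @param config Parameters from [sim_config()].
#' @param seed Integer seed.
#' @return List with `experiment` (raw `panel_experiment`) and `truth`
#'   (class `sim_truth`): planted effects, baselines and dispersions,
#'   responder status, per-sample effect multipliers, latent severity,
#'   lane scale factors and unstable housekeeping genes.
#' @export
simulate_counts <- function(panel_sim, design, config = sim_config(),
                            seed = 1) {
  panel <- if (is.data.frame(panel_sim)) panel_sim else panel_sim$panel
  panel <- validate_panel(panel)
  design <- validate_samples(design)
  cfg <- config
  if (any(unlist(cfg[c("hk_dispersion", "background_mean",
                       "positive_scale")]) <= 0)) {
    abort("dispersion, background and ladder scale must be positive",
          class = "immunopanel_validation_error")
  }
  set.seed(seed)
  n_s <- nrow(design)
  genes <- panel$gene_symbol[panel$probe_class == "endogenous"]
  hk <- panel$gene_symbol[panel$probe_class == "housekeeping"]
  n_g <- length(genes)

  baseline <- 2^rnorm(n_g, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  dispersion <- pmax(rgamma(n_g, cfg$dispersion_shape,
                            rate = cfg$dispersion_rate), 1e-4)
  if (any(baseline <= 0)) {
    abort("baseline means must be positive",
          class = "immunopanel_validation_error")
  }
  n_de <- round(cfg$de_fraction * n_g)
  de_genes <- if (n_de > 0) sample(genes, n_de) else character()
  effect <- setNames(numeric(n_g), genes)
  if (n_de > 0) {
    sign_up <- ifelse(runif(n_de) < cfg$prop_up, 1, -1)
    effect[de_genes] <- cfg$effect_size * sign_up
  }

  # responder assignment: single-regimen treated samples split into
  # high/low responders; four-weekly treated samples all respond fully
  responder <- rep(NA_character_, n_s)
  modifier <- numeric(n_s)
  treated <- design$treatment == "cSiO2"
  for (cell in split(seq_len(n_s)[treated],
                     interaction(design$regimen, design$time_point,
                                 design$tissue, drop = TRUE)[treated])) {
    if (length(cell) == 0) next
    if (design$regimen[cell[1]] == "single") {
      n_high <- round(cfg$responder_fraction * length(cell))
      # full permutation: RNG consumption is independent of the fraction
      perm <- sample.int(length(cell))
      high <- cell[perm[seq_len(n_high)]]
      responder[high] <- "high"
      responder[setdiff(cell, high)] <- "low"
    } else {
      responder[cell] <- "high"
    }
  }
  modifier[treated] <- ifelse(responder[treated] == "high", 1,
                              cfg$attenuation)
  modifier <- modifier * unname(cfg$tissue_scale[design$tissue]) *
    unname(cfg$time_scale[design$time_point])
  modifier[!treated] <- 0

  severity <- ifelse(treated,
                     cfg$severity_max * time_weeks[design$time_point] / 13 *
                       ifelse(responder == "low" & !is.na(responder),
                              cfg$attenuation, 1),
                     0)

  lane_scale <- exp(rnorm(n_s, 0, cfg$lane_scale_sd))

  mu_endo <- outer(baseline, lane_scale) * 2^outer(effect, modifier)
  endo <- matrix(rnbinom(n_g * n_s, mu = mu_endo,
                         size = rep(1 / dispersion, n_s)),
                 nrow = n_g)

  hk_base <- 2^rnorm(length(hk), cfg$hk_baseline_log2_mean,
                     cfg$hk_baseline_log2_sd)
  unstable <- if (cfg$n_unstable_housekeeping > 0) {
    sample(hk, cfg$n_unstable_housekeeping)
  } else character()
  mu_hk <- outer(hk_base, lane_scale)
  if (length(unstable) > 0) {
    idx <- match(unstable, hk)
    mu_hk[idx, ] <- mu_hk[idx, ] *
      2^matrix(rnorm(length(idx) * n_s, 0, cfg$unstable_sd), nrow = length(idx))
  }
  hk_counts <- matrix(rnbinom(length(hk) * n_s, mu = mu_hk,
                              size = rep(1 / cfg$hk_dispersion, n_s)),
                      nrow = length(hk))

  ladder <- panel$ladder_concentration[panel$probe_class == "positive"]
  mu_pos <- outer(ladder * cfg$positive_scale, lane_scale)
  pos <- matrix(rpois(length(ladder) * n_s, mu_pos), nrow = length(ladder))

  n_neg <- sum(panel$probe_class == "negative")
  neg <- matrix(rpois(n_neg * n_s, cfg$background_mean), nrow = n_neg)

  counts <- matrix(0L, nrow = nrow(panel), ncol = n_s,
                   dimnames = list(panel$probe_id, design$sample_id))
  counts[panel$probe_class == "endogenous", ] <- endo
  counts[panel$probe_class == "housekeeping", ] <- hk_counts
  counts[panel$probe_class == "positive", ] <- pos
  counts[panel$probe_class == "negative", ] <- neg

  truth <- structure(list(
    effects = tibble(gene_symbol = genes, log2_effect = unname(effect)),
    de_genes = de_genes,
    baselines = tibble(gene_symbol = genes, baseline = baseline,
                       dispersion = dispersion),
    responders = tibble(sample_id = design$sample_id, responder = responder),
    sample_modifier = tibble(sample_id = design$sample_id,
                             effect_multiplier = modifier),
    severity = tibble(sample_id = design$sample_id,
                      severity = unname(severity)),
    lane_scale = tibble(sample_id = design$sample_id,
                        lane_scale = lane_scale),
    unstable_housekeeping = unstable,
    config = cfg
  ), class = "sim_truth")

  list(experiment = panel_experiment(counts, panel, design, stage = "raw"),
       truth = truth)
}

#' Simulate phenotype endpoints from latent severity
#'
#' Ordinal histopathology endpoints are noisy, discretised monotone
#' transforms of each sample's latent severity, clipped to 0..4; percent
#' positive staining endpoints are logistic transforms of severity on a
#' 0-100 scale. At zero noise every endpoint is a strictly monotone
#' function of severity.
#'
#' @param design Sample metadata tibble.
#' @param truth A `sim_truth` from [simulate_counts()] (supplies severity).
#' @param noise_sd Gaussian noise on the latent scale before transform.
#' @param seed Integer seed.
#' @return Wide phenotype tibble (see [read_phenotypes()]).
#' @export
simulate_phenotypes <- function(design, truth, noise_sd = 0.3, seed = 1) {
  design <- validate_samples(design)
  sev <- truth$severity$severity[match(design$sample_id,
                                       truth$severity$sample_id)]
  if (anyNA(sev)) {
    abort("truth has no severity for some design samples",
          class = "immunopanel_validation_error")
  }
  set.seed(seed)
  smax <- truth$config$severity_max %||% 3
  out <- tibble(sample_id = design$sample_id)
  ord_slope <- seq(0.9, 1.4, length.out = length(phenotype_endpoints$ordinal))
  for (i in seq_along(phenotype_endpoints$ordinal)) {
    e <- phenotype_endpoints$ordinal[i]
    latent <- sev * ord_slope[i] * 4 / smax + rnorm(nrow(design), 0, noise_sd)
    out[[e]] <- pmax(0, pmin(4, round(latent)))
  }
  pct_a <- c(1.2, 1.4, 1.6)
  pct_b <- smax * c(0.5, 0.45, 0.55)
  for (i in seq_along(phenotype_endpoints$percent)) {
    e <- phenotype_endpoints$percent[i]
    out[[e]] <- 100 * plogis(pct_a[i] * (sev - pct_b[i]) +
                               rnorm(nrow(design), 0, noise_sd))
  }
  validate_phenotypes(out)
}

#' Simulate a gene-interaction edge list with planted modules
#'
#' Splits the supplied genes into `n_modules` modules. Within-module
#' pairs are fully connected with scores drawn from `within_range`
#' (above the conventional 0.7 confidence cut); between-module pairs are
#' connected with probability `between_density` and scores from
#' `between_range`.
#'
#' @param gene_symbols Genes to place in the network.
#' @param n_modules Number of planted modules.
#' @param within_range,between_range Uniform score ranges.
#' @param between_density Probability of a between-module edge.
#' @param seed Integer seed.
#' @return Canonical edge tibble with a `planted_modules` attribute
#'   (list of gene sets).
#' @export
simulate_edge_list <- function(gene_symbols, n_modules = 3,
                               within_range = c(0.85, 0.95),
                               between_range = c(0.2, 0.5),
                               between_density = 0.1, seed = 1) {
  if (n_modules < 1) {
    abort("n_modules must be >= 1", class = "immunopanel_validation_error")
  }
  if (length(gene_symbols) < n_modules) {
    abort("fewer genes than modules", class = "immunopanel_validation_error")
  }
  set.seed(seed)
  membership <- ceiling(seq_along(gene_symbols) * n_modules /
                          length(gene_symbols))
  modules <- split(gene_symbols, membership)
  pairs <- utils::combn(gene_symbols, 2)
  m_a <- membership[match(pairs[1, ], gene_symbols)]
  m_b <- membership[match(pairs[2, ], gene_symbols)]
  within <- m_a == m_b
  keep_between <- !within & runif(ncol(pairs)) < between_density
  score <- numeric(ncol(pairs))
  score[within] <- runif(sum(within), within_range[1], within_range[2])
  score[keep_between] <- runif(sum(keep_between), between_range[1],
                               between_range[2])
  keep <- within | keep_between
  edges <- as_edge_list(tibble(gene_a = pairs[1, keep],
                               gene_b = pairs[2, keep],
                               combined_score = score[keep]))
  attr(edges, "planted_modules") <- unname(modules)
  edges
}
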