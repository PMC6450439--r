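#' Pipeline run configuration
#'
#' Collects every tunable of a seeded end-to-end run: the simulated
#' study design and panel sizes, the count-simulator parameters, the
#' analysis thresholds (BH q 0.05, |log2 ratio| 1, Spearman |rho| 0.5,
#' edge confidence 0.7, MCL inflation 1.5), the per-gene model, and the
#' seed every stochastic step derives from.
#'
#' @param ... Named overrides. Nested lists (`panel`, `sim`,
#'   `thresholds`) are merged element-wise.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_per_group = 8,
    panel = list(n_endogenous = 770, n_housekeeping = 40, n_positive = 6,
                 n_negative = 8, n_sets = 10),
    sim = sim_config(),
    thresholds = list(q = 0.05, lfc = 1, rho = 0.5, edge = 0.7,
                      inflation = 1.5),
    model = "log_linear",
    cells_n_perm = 2000,
    phenotype_noise_sd = 0.3,
    network = list(n_modules = 3, between_density = 0.1),
    seed = 1
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  th <- defaults$thresholds
  if (th$q <= 0 || th$q >= 1 || th$lfc < 0 || th$rho < 0 || th$rho > 1 ||
      th$edge <= 0 || th$edge > 1 || th$inflation <= 1) {
    abort("pipeline thresholds out of range",
          class = "immunopanel_validation_error")
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full simulated analysis pipeline
#'
#' Simulate panel and counts, fit and subtract background, flag
#' below-background genes, select housekeeping genes with geNorm,
#' normalize, run differential expression for every treated-vs-vehicle
#' contrast, score gene sets (significance scores and pathway
#' Z-scores), profile immune cell types (scores, marker confidence,
#' per-contrast rank-sum comparisons), correlate chronic lung pathway
#' Z-scores with simulated phenotypes, compute Venn overlaps of the
#' chronic lung DE gene lists, and cluster a simulated interaction
#' network of significant genes with MCL. All randomness derives from
#' `config$seed`; identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written
#'   as TSV plus a `manifest.json` (package version, seed, config hash,
#'   per-stage counts).
#' @return A `pipeline_bundle` list of tibbles: `de`, `significance`,
#'   `pathway_z`, `cell_scores`, `cell_confidence`, `cell_comparisons`,
#'   `correlations`, `venn`, `clusters`, `excluded`, `phenotypes`, plus
#'   `truth` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  marker_map <- default_marker_map()
  panel_sim <- rlang::exec(simulate_panel, !!!config$panel,
                           marker_map = marker_map, seed = seed)
  design <- default_design(config$n_per_group)
  sim <- simulate_counts(panel_sim, design, config = config$sim,
                         seed = seed + 1L)
  pe <- sim$experiment

  bg <- fit_background(pe)
  flags <- flag_low_expression(pe, bg)
  pe_bs <- subtract_background(pe, bg)
  gn <- genorm_stability(pe_bs)
  pe_norm <- normalize_counts(pe_bs, gn$selected)

  contrasts <- build_contrasts(design)
  th <- config$thresholds
  de <- purrr::map_dfr(contrasts, function(cn) {
    unit <- pe$samples |>
      filter(.data$sample_id == cn$case[1]) |>
      select("tissue", "regimen")
    excl <- excluded_genes(flags, .data$tissue == unit$tissue,
                           .data$regimen == unit$regimen)
    run_de(pe_norm, cn, model = if (config$model == "nb") "nb"
           else "log_linear",
           exclude = excl, raw = pe, q_cutoff = th$q, lfc_cutoff = th$lfc)
  })

  scores <- score_gene_sets(de, pe_norm, panel_sim$gene_sets)

  cs <- suppressWarnings(cell_scores(pe_norm, marker_map))
  cc <- suppressWarnings(
    cell_confidence(pe_norm, marker_map, n_perm = config$cells_n_perm,
                    seed = seed + 2L))
  comparisons <- purrr::map_dfr(contrasts, function(cn) {
    compare_cell_groups(cs, cn) |> mutate(contrast = cn$name, .before = 1)
  })

  phen <- simulate_phenotypes(design, sim$truth,
                              noise_sd = config$phenotype_noise_sd,
                              seed = seed + 3L)
  chronic_lung <- design$sample_id[design$tissue == "lung" &
                                     design$time_point != "day1"]
  correlations <- spearman_screen(
    scores$pathway_z |> filter(.data$sample_id %in% chronic_lung),
    phen |> filter(.data$sample_id %in% chronic_lung),
    rho_cutoff = th$rho)

  lung_chronic_names <- intersect(c("Lung.W1", "Lung.W5", "Lung.W9",
                                    "Lung.W13"), unique(de$contrast))
  de_sets <- purrr::map(lung_chronic_names, function(nm) {
    de$gene_symbol[de$contrast == nm & de$significant]
  })
  names(de_sets) <- lung_chronic_names
  de_sets <- de_sets[lengths(de_sets) > 0]
  venn <- if (length(de_sets) >= 2) {
    venn_overlaps(de_sets) |> select(-"members")
  } else {
    tibble(region = character(), n_sets = integer(), size = integer())
  }

  sig_counts <- de |>
    group_by(.data$contrast) |>
    summarise(n_significant = sum(.data$significant), .groups = "drop")
  ref_contrast <- sig_counts$contrast[order(-sig_counts$n_significant,
                                            sig_counts$contrast)][1]
  sig_genes <- sort(de$gene_symbol[de$contrast == ref_contrast &
                                     de$significant])
  clusters <- if (length(sig_genes) >= max(2, config$network$n_modules)) {
    net_edges <- simulate_edge_list(
      sig_genes, n_modules = config$network$n_modules,
      between_density = config$network$between_density, seed = seed + 4L)
    kept <- filter_edges(net_edges, threshold = th$edge,
                         universe = sig_genes)
    if (nrow(kept) > 0) {
      tidy(mcl_cluster(kept, inflation = th$inflation))
    } else {
      tibble(gene = character(), cluster = integer())
    }
  } else {
    tibble(gene = character(), cluster = integer())
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("immunopanel")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    thresholds = th,
    model = config$model,
    n_samples = nrow(design),
    n_probes = nrow(pe$counts),
    background = tidy(bg),
    housekeeping_selected = gn$selected,
    n_excluded_by_unit = flags |>
      group_by(.data$tissue, .data$regimen) |>
      summarise(n_excluded = sum(.data$excluded), .groups = "drop"),
    de_counts = sig_counts,
    network_reference_contrast = ref_contrast
  )

  bundle <- structure(list(
    de = de, significance = scores$significance,
    pathway_z = scores$pathway_z, cell_scores = cs, cell_confidence = cc,
    cell_comparisons = comparisons, correlations = correlations,
    venn = venn, clusters = clusters,
    excluded = flags |> filter(.data$excluded),
    phenotypes = phen, truth = sim$truth, manifest = manifest
  ), class = "pipeline_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

bundle_tables <- c("de", "significance", "pathway_z", "cell_scores",
                   "cell_confidence", "cell_comparisons", "correlations",
                   "venn", "clusters", "excluded", "phenotypes")

#' Write a pipeline bundle to disk
#'
#' One TSV per table plus `manifest.json`.
#'
#' @param bundle A `pipeline_bundle`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in bundle_tables) {
    readr::write_tsv(bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  manifest <- bundle$manifest
  manifest$background <- as.list(manifest$background)
  manifest$n_excluded_by_unit <- as.list(manifest$n_excluded_by_unit)
  manifest$de_counts <- as.list(manifest$de_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable run summary
#'
#' Counts of DE genes per contrast, the top gene sets by absolute
#' directed score, the significant pathway-phenotype correlations, and
#' the cluster sizes; ordering is deterministic (by |score| then name).
#'
#' @param bundle A `pipeline_bundle`.
#' @param n_top Number of top sets to show.
#' @return Character vector of summary lines (also printed).
#' @export
report_summary <- function(bundle, n_top = 5) {
  missing <- setdiff(bundle_tables, names(bundle))
  if (length(missing) > 0) {
    abort(paste0("bundle is missing tables: ",
                 paste(missing, collapse = ", ")),
          class = "immunopanel_validation_error")
  }
  lines <- character()
  de_counts <- bundle$de |>
    group_by(.data$contrast) |>
    summarise(n = sum(.data$significant), .groups = "drop") |>
    arrange(.data$contrast)
  lines <- c(lines, "Differentially expressed genes per contrast:",
             sprintf("  %s: %d genes", de_counts$contrast, de_counts$n))
  top <- bundle$significance |>
    mutate(abs_directed = abs(.data$directed)) |>
    arrange(dplyr::desc(.data$abs_directed), .data$set) |>
    head(n_top)
  lines <- c(lines, sprintf("Top %d gene sets by |directed score|:", n_top),
             sprintf("  %s (%s): directed %.2f, global %.2f", top$set,
                     top$contrast, top$directed, top$global))
  sig_cor <- bundle$correlations |> filter(.data$significant)
  lines <- c(lines,
             sprintf("Significant pathway-phenotype correlations: %d",
                     nrow(sig_cor)))
  if (nrow(bundle$clusters) > 0) {
    sizes <- bundle$clusters |>
      group_by(.data$cluster) |>
      summarise(n = n(), .groups = "drop")
    lines <- c(lines, sprintf("Network clusters: %d (sizes %s)",
                              nrow(sizes),
                              paste(sizes$n, collapse = ", ")))
  } else {
    lines <- c(lines, "Network clusters: none (no significant genes)")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
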