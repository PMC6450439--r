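# Small builders used across the suite.

two_group_design <- function(n = 8, treatmenta = "VEH", treatmentb = "cSiO2",
                             regimen = "four_weekly", time_point = "day1",
                             tissue = "lung") {
  tibble::tibble(
    sample_id = sprintf("%s_r%d", rep(c(treatmenta, treatmentb), each = n),
                        rep(seq_len(n), 2)),
    treatment = rep(c(treatmenta, treatmentb), each = n),
    regimen = regimen, time_point = time_point, tissue = tissue,
    replicate = rep(seq_len(n), 2)
  )
}

tiny_panel <- function(n_endogenous = 4, n_housekeeping = 3, n_positive = 6,
                       n_negative = 8) {
  n <- n_endogenous + n_housekeeping + n_positive + n_negative
  tibble::tibble(
    probe_id = sprintf("P%03d", seq_len(n)),
    gene_symbol = c(sprintf("G%02d", seq_len(n_endogenous)),
                    sprintf("HK%02d", seq_len(n_housekeeping)),
                    paste0("POS_", LETTERS[seq_len(n_positive)]),
                    paste0("NEG_", LETTERS[seq_len(n_negative)])),
    probe_class = rep(c("endogenous", "housekeeping", "positive", "negative"),
                      c(n_endogenous, n_housekeeping, n_positive, n_negative)),
    ladder_concentration = c(rep(NA, n_endogenous + n_housekeeping),
                             128 * 0.25^(seq_len(n_positive) - 1),
                             rep(NA, n_negative))
  )
}

# experiment with counts supplied for endogenous (and optionally "HK"-named
# housekeeping) genes plus flat control probes, for hand-arithmetic tests
manual_experiment <- function(gene_counts, design,
                              positive = 500, negative = 10,
                              stage = "raw") {
  gene_counts <- as.matrix(gene_counts)
  is_hk <- grepl("^HK", rownames(gene_counts))
  gene_counts <- gene_counts[order(is_hk), , drop = FALSE]
  is_hk <- sort(is_hk)
  n_pos <- 6; n_neg <- 8
  panel <- tibble::tibble(
    probe_id = sprintf("P%03d", seq_len(nrow(gene_counts) + n_pos + n_neg)),
    gene_symbol = c(rownames(gene_counts),
                    paste0("POS_", LETTERS[seq_len(n_pos)]),
                    paste0("NEG_", LETTERS[seq_len(n_neg)])),
    probe_class = c(ifelse(is_hk, "housekeeping", "endogenous"),
                    rep("positive", n_pos), rep("negative", n_neg)),
    ladder_concentration = c(rep(NA, nrow(gene_counts)),
                             128 * 0.25^(seq_len(n_pos) - 1), rep(NA, n_neg))
  )
  counts <- rbind(gene_counts,
                  matrix(positive, n_pos, ncol(gene_counts)),
                  matrix(negative, n_neg, ncol(gene_counts)))
  dimnames(counts) <- list(panel$probe_id, design$sample_id)
  panel_experiment(counts, panel, design, stage = stage)
}

simulated_normalized <- function(n_genes = 50, n = 4, seed = 1,
                                 config = sim_config(de_fraction = 0)) {
  ps <- simulate_panel(n_genes, 5, 6, 8, n_sets = 2, n_cell_types = 1,
                       seed = seed)
  sim <- simulate_counts(ps, two_group_design(n), config, seed = seed + 500)
  pe <- sim$experiment
  bg <- fit_background(pe)
  pn <- normalize_counts(subtract_background(pe, bg),
                         genorm_stability(pe)$selected)
  list(panel_sim = ps, sim = sim, raw = pe, norm = pn,
       contrast = build_contrasts(pe$samples)[[1]])
}
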