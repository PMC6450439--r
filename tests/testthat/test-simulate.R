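test_that("simulated panels have the study's composition and a decreasing ladder", {
  ps <- simulate_panel(770, 40, 6, 8, n_sets = 10, n_cell_types = 6, seed = 1)
  expect_equal(nrow(ps$panel), 824)
  counts <- table(ps$panel$probe_class)
  expect_equal(unname(counts[c("endogenous", "housekeeping", "positive",
                               "negative")]), c(770L, 40L, 6L, 8L),
               ignore_attr = TRUE)
  ladder <- ps$panel$ladder_concentration[ps$panel$probe_class == "positive"]
  expect_true(all(diff(ladder) < 0))
  # markers disjoint across cell types
  expect_equal(anyDuplicated(ps$marker_map$gene_symbol), 0L)
})

test_that("panel simulation is deterministic under the seed and validates", {
  a <- simulate_panel(10, 3, 6, 2, n_sets = 2, n_cell_types = 2,
                      markers_per_type = 2, seed = 7)
  b <- simulate_panel(10, 3, 6, 2, n_sets = 2, n_cell_types = 2,
                      markers_per_type = 2, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_panel(10, 3, 6, 1), # too few negatives
               class = "immunopanel_validation_error")
  expect_error(
    simulate_panel(5, 3, 6, 8, n_cell_types = 3, markers_per_type = 2),
    class = "immunopanel_validation_error")
})

test_that("count simulation is deterministic and respects the mixture degeneracy", {
  ps <- simulate_panel(30, 4, 6, 8, n_sets = 2, n_cell_types = 2, seed = 2)
  d <- two_group_design(4, regimen = "single")
  s1 <- simulate_counts(ps, d, sim_config(), seed = 9)
  s2 <- simulate_counts(ps, d, sim_config(), seed = 9)
  expect_identical(s1$experiment$counts, s2$experiment$counts)

  # responder fraction 0 and 1 coincide when attenuation is 1
  f0 <- simulate_counts(ps, d, sim_config(responder_fraction = 0,
                                          attenuation = 1), seed = 9)
  f1 <- simulate_counts(ps, d, sim_config(responder_fraction = 1,
                                          attenuation = 1), seed = 9)
  expect_identical(f0$experiment$counts, f1$experiment$counts)
})

test_that("planted effects are recovered in the empirical log2 ratios", {
  ps <- simulate_panel(500, 4, 6, 8, n_sets = 2, n_cell_types = 2, seed = 3)
  d <- two_group_design(8)
  means <- replicate(20, {
    sim <- simulate_counts(ps, d, sim_config(de_fraction = 0.1,
                                             effect_size = 2, prop_up = 1),
                           seed = sample.int(1e6, 1))
    m <- gene_matrix(sim$experiment)
    planted <- sim$truth$de_genes
    case <- d$sample_id[d$treatment == "cSiO2"]
    veh <- d$sample_id[d$treatment == "VEH"]
    mean(log2(rowMeans(m[planted, case]) / rowMeans(m[planted, veh])))
  })
  expect_lt(abs(mean(means) - 2), 0.2)
})

test_that("negative probes are Poisson-like background and positives track the ladder", {
  ps <- simulate_panel(20, 4, 6, 8, n_sets = 2, n_cell_types = 2, seed = 5)
  d <- two_group_design(8)
  sim <- simulate_counts(ps, d, seed = 11)
  neg <- class_counts(sim$experiment, "negative")
  expect_lt(abs(mean(neg) - 10), 2)
  expect_lt(abs(var(as.numeric(neg)) / mean(neg) - 1), 0.35)

  pos <- class_counts(sim$experiment, "positive")
  conc <- ps$panel$ladder_concentration[ps$panel$probe_class == "positive"]
  fit <- lm(rowMeans(pos) ~ conc)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("phenotypes are monotone in severity and flat for vehicle", {
  ps <- simulate_panel(20, 4, 6, 8, n_sets = 2, n_cell_types = 2, seed = 6)
  d <- default_design(4)
  sim <- simulate_counts(ps, d, sim_config(responder_fraction = 1), seed = 13)
  phen0 <- simulate_phenotypes(d, sim$truth, noise_sd = 0, seed = 1)
  sev <- sim$truth$severity$severity
  for (e in phenotype_endpoints$percent) {
    expect_equal(cor(sev, phen0[[e]], method = "spearman"), 1)
  }
  veh <- d$treatment == "VEH"
  for (e in phenotype_endpoints$ordinal) {
    expect_true(all(phen0[[e]][veh] == 0))
  }
  expect_error(simulate_phenotypes(two_group_design(2),
                                   list(severity = sim$truth$severity[0, ],
                                        config = sim$truth$config)),
               class = "immunopanel_validation_error")
})

test_that("phenotype noise keeps severity strongly rank-correlated", {
  # the correlation screen's population: chronic lung, 2 arms x 4 weeks x 8
  ps <- simulate_panel(10, 4, 6, 8, n_sets = 2, n_cell_types = 1, seed = 8)
  d <- default_design(8)
  sim <- simulate_counts(ps, d, sim_config(), seed = 21)
  keep <- d$tissue == "lung" & d$time_point != "day1"
  expect_equal(sum(keep), 64)
  rhos <- vapply(1:10, function(s) {
    ph <- simulate_phenotypes(d, sim$truth, noise_sd = 0.3, seed = s)
    cor(sim$truth$severity$severity[keep], ph$CD45R[keep],
        method = "spearman")
  }, 0)
  expect_true(all(rhos > 0.8))
})

test_that("planted edge-list modules split into components above the cut", {
  el <- simulate_edge_list(sprintf("g%02d", 1:10), n_modules = 2,
                           between_range = c(0.3, 0.3),
                           between_density = 1, seed = 2)
  kept <- filter_edges(el, 0.7)
  mc <- mcl_cluster(kept)
  expect_equal(length(mc$clusters), 2)
  expect_equal(partition_key(mc$clusters),
               partition_key(attr(el, "planted_modules")))

  single <- simulate_edge_list(sprintf("g%02d", 1:6), n_modules = 1, seed = 3)
  expect_equal(length(mcl_cluster(filter_edges(single, 0.7))$clusters), 1)

  expect_error(simulate_edge_list(c("a", "b"), n_modules = 3),
               class = "immunopanel_validation_error")
})

test_that("severity is strictly increasing in time for treated samples", {
  ps <- simulate_panel(10, 4, 6, 8, n_sets = 2, n_cell_types = 1, seed = 9)
  d <- default_design(2)
  sim <- simulate_counts(ps, d, sim_config(responder_fraction = 1), seed = 2)
  sev <- dplyr::left_join(d, sim$truth$severity, by = "sample_id") |>
    dplyr::filter(treatment == "cSiO2", tissue == "lung",
                  regimen == "four_weekly") |>
    dplyr::group_by(time_point) |>
    dplyr::summarise(s = mean(severity))
  ord <- c("day1", "W1", "W5", "W9", "W13")
  expect_true(all(diff(sev$s[match(ord, sev$time_point)]) > 0))
  veh <- dplyr::left_join(d, sim$truth$severity, by = "sample_id") |>
    dplyr::filter(treatment == "VEH")
  expect_true(all(veh$severity == 0))
})
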