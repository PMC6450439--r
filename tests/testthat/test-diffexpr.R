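test_that("log2 ratios of group means match hand arithmetic and antisymmetry", {
  d <- two_group_design(2)
  gc <- rbind(Gup = c(10, 10, 40, 40),    # VEH then cSiO2 columns
              Gflat = c(20, 20, 20, 20),
              Gdown = c(40, 40, 10, 10))
  pe <- manual_experiment(gc, d, stage = "normalized")
  cn <- build_contrasts(d)[[1]]
  r <- log2_ratio(pe, cn, pseudocount = 0)
  expect_equal(r$log2_ratio[r$gene_symbol == "Gup"], 2)
  expect_equal(r$log2_ratio[r$gene_symbol == "Gflat"], 0)
  expect_equal(r$log2_ratio[r$gene_symbol == "Gdown"], -2)

  flipped <- contrast("rev", cn$reference, cn$case)
  r2 <- log2_ratio(pe, flipped, pseudocount = 0)
  expect_equal(r2$log2_ratio, -r$log2_ratio)

  ps <- log2_ratio(pe, cn, pseudocount = 0, per_sample = TRUE)
  expect_equal(
    ps$per_sample$log2_ratio[ps$per_sample$gene_symbol == "Gup" &
                               ps$per_sample$sample_id == cn$case[1]], 2)
})

test_that("the log-linear model is the pooled t-test with degenerate flags", {
  d <- two_group_design(3)
  cn <- build_contrasts(d)[[1]]
  y <- rbind(same = c(1, 2, 3, 1, 2, 3),
             const = c(3, 3, 3, 5, 5, 5),
             noisy = c(1.2, 1.9, 3.4, 4.1, 5.2, 5.9))
  colnames(y) <- c(cn$reference, cn$case)
  fit <- fit_log_linear(y, cn)
  expect_equal(fit$t[fit$gene_symbol == "same"], 0)
  expect_equal(fit$p[fit$gene_symbol == "same"], 1)
  expect_true(fit$degenerate[fit$gene_symbol == "const"])
  expect_equal(fit$p[fit$gene_symbol == "const"], 0)

  tt <- t.test(y["noisy", cn$case], y["noisy", cn$reference],
               var.equal = TRUE)
  expect_equal(fit$t[fit$gene_symbol == "noisy"], unname(tt$statistic))
  expect_equal(fit$p[fit$gene_symbol == "noisy"], tt$p.value)

  rev <- fit_log_linear(y, contrast("rev", cn$reference, cn$case))
  expect_equal(rev$t, -fit$t)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(42)
  for (i in 1:100) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "immunopanel_validation_error")
})

test_that("the DE calling rule uses strict inequalities on both thresholds", {
  expect_true(call_de(0.04, 1.5))
  expect_false(call_de(0.04, 1.0))
  expect_false(call_de(0.05, 3))
  expect_false(call_de(0.04, -1.0))
  expect_true(call_de(0.04, -1.01))
})

test_that("the simplified NB model recovers planted effects and the Poisson limit", {
  d <- two_group_design(8)
  cn <- build_contrasts(d)[[1]]
  ps <- simulate_panel(40, 4, 6, 8, n_sets = 2, n_cell_types = 1, seed = 71)
  ests <- replicate(20, {
    sim <- simulate_counts(ps, d, sim_config(de_fraction = 0.5,
                                             effect_size = 2, prop_up = 1,
                                             lane_scale_sd = 0),
                           seed = sample.int(1e6, 1))
    f <- tibble::tibble(sample_id = d$sample_id, factor = 1)
    fit <- fit_simplified_nb(sim$experiment, cn, f)
    mean(fit$estimate[fit$gene_symbol %in% sim$truth$de_genes])
  })
  expect_gte(mean(ests), 1.8)
  expect_lte(mean(ests), 2.2)

  # dispersion -> 0 limit (underdispersed fixture floors the moment
  # estimate): Wald t agrees with Poisson regression
  y <- c(60, 59, 61, 60, 60, 61, 59, 60,
         100, 99, 101, 100, 100, 101, 99, 100)
  pe_counts <- rbind(Gx = y)
  colnames(pe_counts) <- c(d$sample_id[d$treatment == "VEH"],
                           d$sample_id[d$treatment == "cSiO2"])
  pe <- manual_experiment(pe_counts, d)
  f <- tibble::tibble(sample_id = d$sample_id, factor = 1)
  fit <- fit_simplified_nb(pe, cn, f)
  group <- as.integer(colnames(pe_counts) %in% cn$case)
  pois <- glm(y ~ group, family = poisson())
  t_pois <- coef(summary(pois))["group", "z value"]
  expect_lt(abs(fit$t - t_pois) / abs(t_pois), 0.05)
})

test_that("identical groups give a near-zero NB estimate", {
  d <- two_group_design(4)
  cn <- build_contrasts(d)[[1]]
  gc <- rbind(Ga = rep(c(50, 52, 48, 50), 2))
  colnames(gc) <- c(cn$reference, cn$case)
  pe <- manual_experiment(gc, d)
  fit <- fit_simplified_nb(pe, cn,
                           tibble::tibble(sample_id = d$sample_id, factor = 1))
  expect_lt(abs(fit$estimate), 1e-8)
  expect_gt(fit$p, 0.99)
})

test_that("run_de assembles ratios, model stats, BH and calls per contrast", {
  fx <- simulated_normalized(n_genes = 60, n = 8, seed = 81,
                             config = sim_config(de_fraction = 0.3,
                                                 effect_size = 2.5))
  de <- run_de(fx$norm, fx$contrast)
  expect_named(de, c("contrast", "gene_symbol", "log2_ratio", "t", "p", "q",
                     "significant", "model_used"))
  expect_equal(de$q, bh_adjust(de$p))
  expect_equal(de$significant, call_de(de$q, de$log2_ratio))
  planted <- fx$sim$truth$de_genes
  expect_gt(mean(de$significant[de$gene_symbol %in% planted]), 0.5)
  # excluded genes are absent from the result
  de2 <- run_de(fx$norm, fx$contrast, exclude = de$gene_symbol[1])
  expect_false(de$gene_symbol[1] %in% de2$gene_symbol)
})

test_that("sequential time contrasts run pairwise and validate inputs", {
  ps <- simulate_panel(30, 4, 6, 8, n_sets = 2, n_cell_types = 1, seed = 91)
  d <- default_design(4)
  frac <- vapply(1:5, function(s) {
    sim <- simulate_counts(ps, d, sim_config(de_fraction = 0), seed = 92 + s)
    pe <- sim$experiment
    pn <- normalize_counts(subtract_background(pe, fit_background(pe)),
                           genorm_stability(pe)$selected)
    seq_de <- sequential_contrasts(pn)
    if (s == 1) {
      expect_setequal(unique(seq_de$contrast),
                      c("W5-vs-W1", "W9-vs-W5", "W13-vs-W9"))
    }
    mean(seq_de$significant)
  }, 0)
  # null time course: essentially nothing called
  expect_lte(mean(frac), 0.01)
  sim <- simulate_counts(ps, d, sim_config(de_fraction = 0), seed = 92)
  pe <- sim$experiment
  pn <- normalize_counts(subtract_background(pe, fit_background(pe)),
                         genorm_stability(pe)$selected)
  expect_error(sequential_contrasts(pn, time_points = "W1"),
               class = "immunopanel_validation_error")
  expect_error(sequential_contrasts(pn, time_points = c("W1", "W99")),
               class = "immunopanel_validation_error")
})

test_that("contrasts validate disjointness and minimum size", {
  expect_error(contrast("x", c("a", "b"), c("b", "c")),
               class = "immunopanel_validation_error")
  expect_error(contrast("x", "a", c("b", "c")),
               class = "immunopanel_validation_error")
})
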