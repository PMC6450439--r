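test_that("background model matches hand arithmetic on pooled negatives", {
  bg <- fit_background(c(10, 12, 8, 10, 10))
  expect_equal(bg$mean_background, 10)
  expect_equal(bg$sd_background, sqrt(2))
  expect_equal(bg$threshold, 10 + 2 * sqrt(2))

  flat <- fit_background(c(7, 7, 7, 7))
  expect_equal(flat$threshold, 7)

  expect_error(fit_background(5), class = "immunopanel_validation_error")
})

test_that("pooled background threshold brackets the Poisson truth", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    neg <- matrix(rpois(8 * 16, 10), 8)
    th <- fit_background(neg)$threshold
    th >= 10 + 2 * sqrt(10) * 0.6 && th <= 10 + 2 * sqrt(10) * 1.4
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("background subtraction floors at zero and spares control probes", {
  d <- two_group_design(2)
  gc <- matrix(c(100, 5, 100, 5, 100, 5, 100, 5), nrow = 2,
               dimnames = list(c("Ga", "Gb"), NULL))
  pe <- manual_experiment(gc, d, positive = 500, negative = 10)
  bg <- structure(list(mean_background = 10, sd_background = 0,
                       threshold = 10), class = "background_model")
  sub <- subtract_background(pe, bg)
  m <- gene_matrix(sub, "endogenous")
  expect_true(all(m["Ga", ] == 90))
  expect_true(all(m["Gb", ] == 0))
  expect_true(all(class_counts(sub, "positive") == 500))
  expect_true(all(class_counts(sub, "negative") == 10))
  expect_error(subtract_background(sub, bg),
               class = "immunopanel_validation_error")

  zero_bg <- structure(list(mean_background = 0, sd_background = 0,
                            threshold = 0), class = "background_model")
  ident <- subtract_background(pe, zero_bg)
  expect_equal(ident$counts, pe$counts, ignore_attr = TRUE)
})

test_that("low-expression flagging uses a strict 'below threshold' rule", {
  d <- two_group_design(2)
  gc <- rbind(Glow = rep(11, 4), Gedge = rep(12, 4), Ghigh = rep(40, 4))
  pe <- manual_experiment(gc, d)
  bg <- structure(list(mean_background = 10, sd_background = 1,
                       threshold = 12), class = "background_model")
  flags <- flag_low_expression(pe, bg)
  expect_true(flags$excluded[flags$gene_symbol == "Glow"])
  expect_false(flags$excluded[flags$gene_symbol == "Gedge"]) # boundary kept
  expect_false(flags$excluded[flags$gene_symbol == "Ghigh"])

  zero <- structure(list(mean_background = 0, sd_background = 0,
                         threshold = 0), class = "background_model")
  expect_false(any(flag_low_expression(pe, zero)$excluded))
})

test_that("flagging is monotone in the threshold", {
  fx <- simulated_normalized(n_genes = 40, n = 4, seed = 31)
  bg <- fit_background(fx$raw)
  low <- flag_low_expression(fx$raw, structure(
    list(mean_background = bg$mean_background, sd_background = bg$sd_background,
         threshold = bg$threshold), class = "background_model"))
  high <- flag_low_expression(fx$raw, structure(
    list(mean_background = bg$mean_background, sd_background = bg$sd_background,
         threshold = bg$threshold * 2), class = "background_model"))
  excl_low <- low$gene_symbol[low$excluded]
  excl_high <- high$gene_symbol[high$excluded]
  expect_true(all(excl_low %in% excl_high))
})

test_that("positive-control factors follow the geometric-mean convention", {
  d <- two_group_design(1)
  gc <- matrix(50, 1, 2, dimnames = list("Ga", NULL))
  pe <- manual_experiment(gc, d, positive = 1, negative = 5)
  # overwrite positives so lane geometric means are 100 and 200
  pos_ids <- pe$panel$probe_id[pe$panel$probe_class == "positive"]
  pe$counts[pos_ids, 1] <- 100
  pe$counts[pos_ids, 2] <- 200
  f <- positive_control_factors(pe)
  expect_equal(f$positive_factor, c(1.5, 0.75))

  pe$counts[pos_ids, 2] <- 100
  expect_equal(positive_control_factors(pe)$positive_factor, c(1, 1))

  pe$counts[pos_ids[1], 1] <- 0
  expect_error(positive_control_factors(pe),
               class = "immunopanel_validation_error")
})

test_that("doubling one lane's counts halves its positive factor", {
  fx <- simulated_normalized(n_genes = 10, n = 2, seed = 41)
  pe <- fx$raw
  f0 <- positive_control_factors(pe)
  pe$counts[, 1] <- pe$counts[, 1] * 2
  f1 <- positive_control_factors(pe)
  ratio <- f1$positive_factor[1] / f0$positive_factor[1]
  other_mean_ratio <- mean(f1$positive_factor[-1] / f0$positive_factor[-1])
  # factor_1 scales with (new pooled mean)/(2 x lane geomean)
  expect_equal(ratio * 2 / other_mean_ratio, 1, tolerance = 1e-12)
})

test_that("geNorm stability behaves on degenerate and proportional genes", {
  samples <- paste0("s", 1:6)
  base <- rnorm(6)
  mat <- rbind(a = base, b = base + 1, c = base - 2, d = rnorm(6))
  colnames(mat) <- samples
  res <- genorm_stability(mat)
  # a, b, c are mutually proportional on the log scale: the ratio sd terms
  # among them vanish, so d must be removed first
  expect_equal(res$removal_order[1], "d")
  m <- res$stability
  expect_true(all(m$M >= 0))

  const <- matrix(5, 4, 5, dimnames = list(letters[1:4], paste0("s", 1:5)))
  res_c <- genorm_stability(const)
  expect_true(all(res_c$stability$M == 0))
  # ties remove the lexicographically smallest symbol first: deterministic
  expect_equal(res_c$removal_order, c("a", "b"))

  expect_error(genorm_stability(mat[1:2, ]),
               class = "immunopanel_validation_error")
})

test_that("geNorm is invariant to sample and gene order", {
  set.seed(5)
  mat <- matrix(rnorm(7 * 10), 7,
                dimnames = list(paste0("hk", 1:7), paste0("s", 1:10)))
  a <- genorm_stability(mat)
  b <- genorm_stability(mat[sample(7), sample(10)])
  expect_equal(sort(a$ranking), sort(b$ranking))
  expect_equal(a$removal_order, b$removal_order)
  expect_equal(a$selected, b$selected)
  expect_equal(a$pairwise_variation$V, b$pairwise_variation$V)
})

test_that("planted unstable housekeeping genes are removed first", {
  d <- two_group_design(8)
  hits <- vapply(1:30, function(s) {
    ps <- simulate_panel(10, 7, 6, 8, n_sets = 2, n_cell_types = 1, seed = s)
    sim <- simulate_counts(ps, d,
                           sim_config(de_fraction = 0,
                                      n_unstable_housekeeping = 2),
                           seed = 7000 + s)
    gn <- genorm_stability(sim$experiment)
    setequal(gn$removal_order[1:2], sim$truth$unstable_housekeeping)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("housekeeping normalization equalises lane geometric means", {
  d <- two_group_design(1)
  gc <- rbind(Ga = c(30, 60), HK01 = c(10, 20), HK02 = c(10, 20),
              HK03 = c(10, 20))
  pe <- manual_experiment(gc, d, positive = 500, negative = 0)
  bs <- subtract_background(pe, structure(
    list(mean_background = 0, sd_background = 0, threshold = 0),
    class = "background_model"))
  norm <- normalize_counts(bs, c("HK01", "HK02", "HK03"))
  # single housekeeping profile {10, 20}: factors 1.5 and 0.75
  expect_equal(norm$norm_factors$housekeeping_factor, c(1.5, 0.75))
  hk <- gene_matrix(norm, "housekeeping")
  gm <- apply(hk, 2, function(x) exp(mean(log(x))))
  expect_equal(gm[1], gm[2], tolerance = 1e-9, ignore_attr = TRUE)
  # identical lanes -> identity
  gc2 <- rbind(Ga = c(40, 40), HK01 = c(10, 10), HK02 = c(12, 12),
               HK03 = c(9, 9))
  pe2 <- manual_experiment(gc2, d, positive = 500, negative = 0)
  bs2 <- subtract_background(pe2, structure(
    list(mean_background = 0, sd_background = 0, threshold = 0),
    class = "background_model"))
  norm2 <- normalize_counts(bs2, c("HK01", "HK02", "HK03"))
  expect_equal(unname(norm2$counts), unname(pe2$counts))
})

test_that("normalization is invariant to scaling one lane", {
  # the pooled-mean numerator of the factor convention rescales every lane
  # by one shared constant when a lane is scaled, so invariance holds up
  # to that single global factor, and exactly for all ratio quantities
  fx <- simulated_normalized(n_genes = 30, n = 3, seed = 51)
  bs <- subtract_background(fx$raw, fit_background(fx$raw))
  hk <- genorm_stability(bs)$selected
  ref <- normalize_counts(bs, hk)
  scaled <- bs
  scaled$counts[, 2] <- scaled$counts[, 2] * 3.7
  got <- normalize_counts(scaled, hk)
  ratio <- got$counts / ref$counts
  ratio <- ratio[is.finite(ratio)]
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-9)
  r_ref <- log2_ratio(ref, fx$contrast)
  r_got <- log2_ratio(got, fx$contrast, pseudocount = 0.5 * ratio[1])
  expect_equal(r_got$log2_ratio, r_ref$log2_ratio, tolerance = 1e-9)
})

test_that("normalize_counts validates stage and housekeeping selection", {
  fx <- simulated_normalized(n_genes = 10, n = 2, seed = 61)
  expect_error(normalize_counts(fx$raw, "Hk01"),
               class = "immunopanel_validation_error")
  bs <- subtract_background(fx$raw, fit_background(fx$raw))
  expect_error(normalize_counts(bs, character()),
               class = "immunopanel_validation_error")
  expect_error(normalize_counts(bs, "not_a_gene"),
               class = "immunopanel_validation_error")
})
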