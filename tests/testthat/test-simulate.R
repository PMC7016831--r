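test_that("generator is deterministic given its seed", {
  a <- generate_dataset(sim_config(n_features = 200L, rng_seed = 9))
  b <- generate_dataset(sim_config(n_features = 200L, rng_seed = 9))
  c_ <- generate_dataset(sim_config(n_features = 200L, rng_seed = 10))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts$counts, c_$counts$counts))
})

test_that("with no effects and zero dispersion, sample means track expected means", {
  # law-of-large-numbers check: Poisson counts, proportional packaging
  cfg <- sim_config(n_features = 400L, de_fraction = 0, nb_dispersion = 0,
                    packaging_mode = "proportional",
                    dropout_midpoint = -Inf,
                    library_size_range = c(2e6, 2e6), rng_seed = 5)
  ds <- generate_dataset(cfg)
  counts <- ds$counts$counts
  # cell & EV of one model share one expected-mean vector; 12 draws per model
  for (m in c("NSCLC", "CML")) {
    ab <- 2^ds$truth[[paste0("base_log2_", m)]]
    mu <- 2e6 * ab / sum(ab)
    sel <- ds$counts$samples$model == m
    obs <- rowMeans(counts[, sel, drop = FALSE])
    hi <- mu >= 1000          # 12 replicate draws per model: sd/mean < 1%
    expect_true(sum(hi) > 50)
    expect_lt(max(abs(obs[hi] - mu[hi]) / mu[hi]), 0.05)
  }
})

test_that("every EV-detected feature has positive cell-side abundance", {
  ds <- generate_dataset(sim_config(n_features = 300L, rng_seed = 2))
  tr <- ds$truth
  expect_true(all(2^tr$base_log2_NSCLC[tr$detected_NSCLC] > 0))
  expect_true(all(2^tr$base_log2_CML[tr$detected_CML] > 0))
  # one truth row per emitted feature
  expect_identical(tr$feature_id, rownames(ds$counts$counts))
})

test_that("packaging model honors its degenerate and moment contracts", {
  cfg_prop <- sim_config(n_features = 10L, packaging_mode = "proportional",
                         dropout_midpoint = -Inf)
  ab <- c(0.5, 1, 2, 4, 8)
  set.seed(1)
  pk <- apply_packaging(ab, cfg_prop)
  expect_identical(pk$ev_abundance, ab)         # no dropout, factors 1
  expect_identical(pk$factors, rep(1, 5))

  cfg_deg <- sim_config(n_features = 10L, packaging_mode = "selective",
                        selective_fraction = 1, packaging_log_sd = 0,
                        dropout_midpoint = -Inf)
  set.seed(1)
  expect_identical(apply_packaging(ab, cfg_deg)$factors, rep(1, 5))

  # moment check: sd of log factors among perturbed features ~ packaging_log_sd
  cfg_sel <- sim_config(n_features = 5000L, packaging_mode = "selective",
                        selective_fraction = 0.3, packaging_log_sd = 1.5,
                        dropout_midpoint = -Inf)
  set.seed(42)
  pk <- apply_packaging(rep(16, 5000), cfg_sel)
  perturbed <- pk$factors != 1
  expect_gt(sum(perturbed), 1000)
  expect_lt(abs(sd(log(pk$factors[perturbed])) - 1.5) / 1.5, 0.05)
  expect_error(apply_packaging(c(-1, 2), cfg_sel), ">= 0")
})

test_that("dropout probability follows the logistic detection curve", {
  cfg <- sim_config(n_features = 10L, packaging_mode = "proportional",
                    dropout_midpoint = 3, dropout_slope = 1)
  set.seed(7)
  ab <- rep(2^3, 20000)                        # at the midpoint: p = 0.5
  det_rate <- mean(apply_packaging(ab, cfg)$detected)
  expect_lt(abs(det_rate - 0.5), 0.02)
  set.seed(7)
  ab_hi <- rep(2^8, 20000)                     # 5 log2 units above: p ~ 0.993
  expect_gt(mean(apply_packaging(ab_hi, cfg)$detected), 0.98)
})

test_that("simulated Ct tables obey the log2 arithmetic of the assay", {
  cfg <- sim_config(n_features = 20L, de_fraction = 0, rng_seed = 1)
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  tr$logfc_NSCLC[1] <- -1                      # halve abundance in MDR
  ct <- simulate_ct_table(tr, tr$feature_id[1], reference_feature = tr$feature_id[2],
                          model = "NSCLC", ct_noise_sd = 0, rng_seed = 1)
  t_sens <- ct$ct[ct$feature_id == tr$feature_id[1] & ct$condition == "sensitive"]
  t_mdr <- ct$ct[ct$feature_id == tr$feature_id[1] & ct$condition == "MDR"]
  expect_equal(unique(t_mdr - t_sens), 1)      # halving abundance costs one cycle

  # no effect + no noise -> flat downstream ddCt
  ct0 <- simulate_ct_table(tr, tr$feature_id[3], reference_feature = tr$feature_id[2],
                           model = "NSCLC", ct_noise_sd = 0, rng_seed = 1)
  fc <- delta_delta_ct(ct0, tr$feature_id[3], tr$feature_id[2])
  expect_equal(fc$delta_delta_ct, 0)
  expect_equal(fc$fold_change, 1)

  # reproducibility and reference-stability guard
  ct_a <- simulate_ct_table(tr, tr$feature_id[4], tr$feature_id[2], rng_seed = 3)
  ct_b <- simulate_ct_table(tr, tr$feature_id[4], tr$feature_id[2], rng_seed = 3)
  expect_identical(ct_a, ct_b)
  expect_error(simulate_ct_table(tr, tr$feature_id[2], reference_feature = tr$feature_id[1],
                                 model = "NSCLC"),
               "not expression-stable")
})

test_that("invalid simulation configurations fail before sampling", {
  expect_error(sim_config(biotype_proportions = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(sim_config(nb_dispersion = -1), ">= 0")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(library_size_range = c(5e6, 1e6)), "library_size_range")
  expect_error(sim_config(n_features = 10L,
                          forced_effects = data.frame(feature = 11, base_log2 = 5)),
               "outside")
})
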