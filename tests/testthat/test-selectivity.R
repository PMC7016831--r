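test_that("pairs are built from replicate-summed RPM with hand-checked arithmetic", {
  # 4 features; feature 3 absent from EVs, feature 4 absent everywhere
  cell_counts <- matrix(c(6, 2, 2, 0), 4, 3)     # summed: 18, 6, 6, 0
  ev_counts <- matrix(c(9, 3, 0, 0), 4, 3)       # summed: 27, 9, 0, 0
  cellm <- count_matrix(cell_counts, toy_meta("NSCLC", "cell")[1:3, ],
                        feature_ids = paste0("f", 1:4))
  evm <- count_matrix(ev_counts, toy_meta("NSCLC", "EV")[1:3, ],
                      feature_ids = paste0("f", 1:4))
  pairs <- build_pairs(cellm, evm)
  expect_equal(pairs$pairs$feature_id, c("f1", "f2"))
  expect_equal(pairs$pairs$x, log2(c(18, 6) / 30 * 1e6))
  expect_equal(pairs$pairs$y, log2(c(27, 9) / 36 * 1e6))
  expect_equal(pairs$n_unique_cell, 1)           # f3: counts in cells only
  expect_equal(pairs$n_unique_ev, 0)

  # identical compartments land exactly on y = x
  same <- build_pairs(cellm, count_matrix(cell_counts, toy_meta("NSCLC", "EV")[1:3, ],
                                          feature_ids = paste0("f", 1:4)))
  expect_equal(same$pairs$x, same$pairs$y)
  expect_error(build_pairs(cellm, count_matrix(matrix(0L, 4, 3),
                                               toy_meta("NSCLC", "EV")[1:3, ],
                                               feature_ids = paste0("f", 1:4))),
               "zero total")
})

test_that("OLS fit matches the closed-form normal equations and flags degeneracy", {
  x <- c(1, 2, 4, 7, 9); y <- 2 * x + 1
  fit <- fit_regression(abundance_pairs(x, y), threshold = 0)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(14)
  x2 <- runif(5, 1, 9); y2 <- 1.3 * x2 - 0.4 + rnorm(5)
  fit2 <- fit_regression(abundance_pairs(x2, y2), threshold = 0)
  X <- cbind(1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y2)         # normal-equations oracle
  expect_equal(fit2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit2$r_squared, cor(x2, y2)^2, tolerance = 1e-12)

  none <- fit_regression(abundance_pairs(x, y), threshold = 99)
  expect_false(none$defined)
  expect_true(is.na(none$r_squared))
})

test_that("the default grid enumerates 101 thresholds and ties break to the smallest", {
  x <- seq(0.5, 9.5, length.out = 40); y <- x   # exactly collinear
  res <- grid_search_threshold(abundance_pairs(x, y))
  expect_equal(nrow(res$grid), 101L)
  expect_equal(res$grid$threshold, seq(0, 10, by = 0.1))
  defined <- !is.na(res$grid$r_squared)
  expect_true(all(abs(res$grid$r_squared[defined] - 1) < 1e-12))
  expect_equal(res$t_max, 0)                     # tie-break: least data discarded
})

test_that("grid search finds the planted noise floor", {
  # pure line above x = 3; +/-2 alternating noise below
  x_noise <- c(seq(0.5, 2.75, by = 0.25), 2.95)
  y_noise <- x_noise + c(2, -2)[rep_len(1:2, length(x_noise))]
  x_line <- seq(3.05, 9.95, by = 0.1)
  pairs <- abundance_pairs(c(x_noise, x_line), c(y_noise, x_line))
  res <- grid_search_threshold(pairs, lo = 0, hi = 10, step = 0.1)
  expect_equal(res$t_max, 3.0)
  expect_equal(res$r_squared_at_tmax, 1.0, tolerance = 1e-12)
  # maximal over the defined grid entries, by exhaustive re-scan
  expect_equal(res$r_squared_at_tmax,
               max(res$grid$r_squared, na.rm = TRUE), tolerance = 1e-12)
  expect_gte(res$r_squared_at_tmax, res$fit0$r_squared)
})

test_that("the packaging verdict applies a strict ceiling", {
  low <- list(grid = data.frame(threshold = 0, n_points = 10, r_squared = 0.62))
  class(low) <- "selectivity_result"
  expect_equal(selectivity_report(low)$verdict, "selective")
  high <- low; high$grid$r_squared <- 0.95
  expect_equal(selectivity_report(high)$verdict, "proportional")
  boundary <- low; boundary$grid$r_squared <- 0.8
  expect_equal(selectivity_report(boundary)$verdict, "proportional")
})

test_that("proportional packaging with vanishing dispersion approaches perfect correlation", {
  r2 <- sapply(c(0.4, 0.05, 0), function(phi) {
    ds <- generate_dataset(sim_config(n_features = 600L, de_fraction = 0,
                                      packaging_mode = "proportional",
                                      nb_dispersion = phi, rng_seed = 77))
    p <- build_pairs(subset_samples(ds$counts, "NSCLC", "cell", "sensitive"),
                     subset_samples(ds$counts, "NSCLC", "EV", "sensitive"))
    fit_regression(p, 0)$r_squared
  })
  expect_true(all(diff(r2) > 0))
  expect_gt(r2[3], 0.99)
})

test_that("selective packaging depresses the best grid R^2 below the proportional run", {
  for (seed in 1:5) {
    r2 <- sapply(c("proportional", "selective"), function(mode) {
      ds <- generate_dataset(sim_config(n_features = 1000L, packaging_mode = mode,
                                        rng_seed = seed))
      p <- build_pairs(subset_samples(ds$counts, "NSCLC", "cell", "sensitive"),
                       subset_samples(ds$counts, "NSCLC", "EV", "sensitive"))
      max(grid_search_threshold(p)$grid$r_squared, na.rm = TRUE)
    })
    expect_lt(r2["selective"], r2["proportional"])
  }
})

test_that("EV species are a subset of cell species on generator output", {
  for (seed in 1:3) {
    ds <- generate_dataset(sim_config(n_features = 500L, rng_seed = seed))
    for (ph in c("sensitive", "MDR")) {
      p <- build_pairs(subset_samples(ds$counts, "CML", "cell", ph),
                       subset_samples(ds$counts, "CML", "EV", ph))
      expect_equal(p$n_unique_ev, 0)
    }
  }
})
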