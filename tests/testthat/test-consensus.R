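# brute-force Venn oracle: scan every feature's membership pattern
venn_oracle <- function(sets) {
  nm <- names(sets)
  out <- table(factor(character(0)))
  universe <- unique(unlist(sets, use.names = FALSE))
  keys <- vapply(universe, function(f)
    paste(nm[vapply(sets, function(s) f %in% s, logical(1))], collapse = "&"),
    character(1))
  as.list(table(keys))
}

fake_de <- function(ids, logfc, p, tested = rep(TRUE, length(ids))) {
  d <- data.frame(feature_id = ids, logfc = logfc, p_value = p,
                  adjusted_p = bh_adjust(p), mean_log2_cpm = 5, tested = tested,
                  stringsAsFactors = FALSE)
  d$p_value[!tested] <- NA; d$adjusted_p[!tested] <- NA; d$logfc[!tested] <- NA
  class(d) <- c("de_result", "data.frame")
  d
}

test_that("Venn partition covers hand-enumerable cases", {
  sets <- list(A = c("1", "2"), B = "2", C = character(0), D = character(0))
  v <- venn_partition(sets)
  expect_equal(nrow(v), 15L)
  expect_equal(v$n[v$region == "A"], 1L)
  expect_equal(v$n[v$region == "A&B"], 1L)
  expect_equal(sum(v$n), 2L)

  disjoint <- list(A = c("a", "b"), B = c("c"), C = c("d", "e", "f"), D = character(0))
  v2 <- venn_partition(disjoint)
  expect_equal(v2$n[v2$region == "A"], 2L)
  expect_equal(v2$n[v2$region == "C"], 3L)
  expect_equal(sum(v2$n), 6L)
  expect_true(all(v2$n[grepl("&", v2$region)] == 0L))
})

test_that("Venn counts equal a per-feature membership scan on random sets", {
  set.seed(19)
  for (rep_ in 1:10) {
    pool <- sprintf("f%03d", 1:100)
    sets <- setNames(lapply(1:4, function(i) sample(pool, rpois(1, 30))),
                     c("NSCLC_cell", "NSCLC_EV", "CML_cell", "CML_EV"))
    v <- venn_partition(sets)
    oracle <- venn_oracle(sets)
    for (region in v$region) {
      expect_equal(v$n[v$region == region],
                   if (is.null(oracle[[region]])) 0L else as.integer(oracle[[region]]),
                   info = region)
    }
    expect_equal(sum(v$n), length(unique(unlist(sets))))
  }
})

test_that("directional consensus keeps concordant significant features only", {
  ids <- c("miR-383", "up_dis", "p_fail", "concord2")
  de1 <- fake_de(ids, logfc = c(-8.83, 2, 2, 3.1), p = c(1e-5, 0.01, 0.2, 0.001))
  de2 <- fake_de(ids, logfc = c(-5.46, -2, 2, 2.2), p = c(1e-5, 0.01, 0.01, 0.002))
  cons <- directional_consensus(de1, de2, alpha = 0.05)
  expect_setequal(cons$feature_id, c("miR-383", "concord2"))
  expect_equal(cons$direction[cons$feature_id == "miR-383"], "down_in_MDR")
  expect_equal(cons$direction[cons$feature_id == "concord2"], "up_in_MDR")
  expect_true(all(cons$logfc_NSCLC * cons$logfc_CML > 0))

  # symmetric in model order up to column swap
  swapped <- directional_consensus(de2, de1, alpha = 0.05,
                                   model_names = c("CML", "NSCLC"))
  expect_setequal(swapped$feature_id, cons$feature_id)
  expect_equal(swapped$logfc_NSCLC, cons$logfc_NSCLC)
  expect_equal(swapped$logfc_CML, cons$logfc_CML)

  # features tested in only one model are excluded but counted
  de3 <- fake_de(ids, logfc = c(2, 2, 2, 2), p = rep(0.001, 4),
                 tested = c(TRUE, FALSE, TRUE, TRUE))
  de4 <- fake_de(ids, logfc = rep(2, 4), p = rep(0.001, 4))
  cons2 <- directional_consensus(de3, de4)
  expect_false("up_dis" %in% cons2$feature_id)
  expect_equal(attr(cons2, "n_tested_one_model"), 1L)
})

test_that("biotype composition is conserved and recovers a single-biotype extreme", {
  cm <- toy_matrix(n_features = 8, seed = 6)
  ann_one <- data.frame(feature_id = rownames(cm$counts), name = "x",
                        biotype = "miRNA", stringsAsFactors = FALSE)
  comp <- biotype_composition(cm, ann_one)
  expect_equal(unname(comp["miRNA", ]), rep(1, 6))

  ann_mix <- ann_one; ann_mix$biotype <- rep(c("miRNA", "pseudogene"), 4)
  comp2 <- biotype_composition(cm, ann_mix)
  expect_equal(unname(colSums(comp2)), rep(1, 6))

  # unannotated features fall into "other"
  comp3 <- biotype_composition(cm, ann_mix[1:4, ])
  expect_true("other" %in% rownames(comp3))
  zero <- cm$counts; zero[, 1] <- 0L
  expect_error(biotype_composition(count_matrix(zero, cm$samples), ann_one),
               "zero-count sample")
})

test_that("planted biotype proportions are recovered within sampling error", {
  ds <- generate_dataset(sim_config(n_features = 2000L, de_fraction = 0,
                                    packaging_mode = "proportional", rng_seed = 13))
  comp <- biotype_composition(ds$counts, ds$annotation)
  expect_true(all(comp["pseudogene", ] > 0.13 & comp["pseudogene", ] < 0.17))
  expect_true(all(abs(comp["protein_coding", ] - 0.55) < 0.04))
})

test_that("target mapping is an inner join with unmapped miRs reported", {
  cons <- fake_de(c("miR-1", "miR-2", "miR-9"), c(2, -2, 1), rep(0.01, 3))
  cons <- directional_consensus(cons, cons)       # trivially self-concordant
  empty <- map_targets(cons, data.frame(mir = character(0), gene = character(0)))
  expect_equal(nrow(empty$joined), 0L)
  expect_setequal(empty$unmapped, cons$feature_id)

  mapping <- data.frame(mir = c("miR-1", "miR-1", "miR-2"),
                        gene = c("TP53INP1", "E2F7", "NCKAP1"))
  res <- map_targets(cons, mapping)
  expect_equal(nrow(res$joined), 3L)
  expect_equal(sum(res$joined$feature_id == "miR-1"), 2L)
  expect_setequal(res$unmapped, "miR-9")

  # equals a brute-force nested-loop join
  brute <- do.call(rbind, lapply(seq_len(nrow(cons)), function(i)
    do.call(rbind, lapply(seq_len(nrow(mapping)), function(j)
      if (cons$feature_id[i] == mapping$mir[j])
        data.frame(feature_id = cons$feature_id[i], target = mapping$gene[j])))))
  expect_equal(res$joined[, c("feature_id", "target")],
               brute[order(brute$feature_id, brute$target), ],
               ignore_attr = TRUE)
  expect_error(map_targets(cons, data.frame(x = 1)), "two columns")
})
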