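# Small in-code fixtures shared across test files.

# metadata for one model/compartment, 3+3 replicates
toy_meta <- function(model = "NSCLC", compartment = "cell") {
  data.frame(label = paste0("s", 1:6), model = model, compartment = compartment,
             phenotype = rep(c("sensitive", "MDR"), each = 3),
             replicate = rep(1:3, 2), stringsAsFactors = FALSE)
}

toy_matrix <- function(counts = NULL, n_features = 10, model = "NSCLC",
                       compartment = "cell", seed = 1) {
  meta <- toy_meta(model, compartment)
  if (is.null(counts)) {
    set.seed(seed)
    counts <- matrix(rpois(n_features * 6, 50), n_features, 6)
  }
  dimnames(counts) <- list(sprintf("f%03d", seq_len(nrow(counts))), meta$label)
  count_matrix(counts, meta)
}

# NB matrix with per-feature means and common dispersion, 3 vs 3
nb_matrix <- function(n, mu, phi, seed, delta = rep(0, n)) {
  set.seed(seed)
  mu_mat <- cbind(mu, mu, mu, mu * 2^delta, mu * 2^delta, mu * 2^delta)
  counts <- matrix(
    if (phi > 0) rnbinom(n * 6, size = 1 / phi, mu = mu_mat)
    else rpois(n * 6, mu_mat), n, 6)
  toy_matrix(counts)
}
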