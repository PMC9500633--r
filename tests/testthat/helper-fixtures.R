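# Small fixtures built in code; nothing is stored on disk.

# two-component panel with clean round numbers
tiny_panel <- function() {
  rbind(
    derive_electronic_descriptors("A", homo = -6, lumo = -2,
                                  molecular_energy = -100,
                                  adsorption_energy = -1),
    derive_electronic_descriptors("B", homo = -8, lumo = -4,
                                  molecular_energy = -200,
                                  adsorption_energy = -3))
}

# deterministic small regression split with linear signal
linear_split <- function(n = 24, p = 3, noise = 0, seed = 42,
                         beta = seq_len(p)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  split_train_test(X, y, seed = seed)
}

# quick synthetic study with a small grid budget for model fitting
small_grid <- list(estimator_range = 1:10, seed_range = 1:3)

# exhaustive minimum within-cluster sum of squares over all 2-partitions
brute_force_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {     # fix point 1 in cluster 1; skip empty
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    ss <- 0
    for (g in 1:2) {
      Xg <- X[lab == g, , drop = FALSE]
      ss <- ss + sum(sweep(Xg, 2, colMeans(Xg))^2)
    }
    best <- min(best, ss)
  }
  best
}
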