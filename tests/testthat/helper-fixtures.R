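# Fixtures built in code: tiny track sets, bedGraph writers, and cached
# medium-size simulations shared across tests in a file.

# A track_set built directly from vectors: `values` is a named list
# (channel -> named list of per-chromosome bin vectors).
make_tracks <- function(values, bin_bp = 10) {
  chrom_sizes <- vapply(values[[1]], function(v) length(v) * bin_bp,
                        numeric(1))
  track_set(values, names(values), bin_bp, chrom_sizes)
}

# Constant-signal track set with `m` channels named mod_tp over one
# chromosome of `n_bins` bins.
make_flat_tracks <- function(channel_names, n_bins = 2000, bin_bp = 10,
                             value = 1) {
  values <- setNames(
    lapply(channel_names, function(ch) list(chrT = rep(value, n_bins))),
    channel_names
  )
  make_tracks(values, bin_bp)
}

# Write a bedGraph file from a data frame of (chrom, start, end, value).
write_bedgraph <- function(df, path = tempfile(fileext = ".bedGraph")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Small promoter-only simulation (asymmetric class), for orientation tests.
sim_promoters <- function(n = 100, noise_sd = 0.1, seed = 1, ...) {
  simulate_tracks(sim_config(n_promoter = n, n_enhancer = 0, n_flat = 0,
                             noise_sd = noise_sd, seed = seed, ...))
}

# Small three-class simulation.
sim_three_class <- function(n_per = 30, noise_sd = 0.1, seed = 1, ...) {
  simulate_tracks(sim_config(n_promoter = n_per, n_enhancer = n_per,
                             n_flat = n_per, noise_sd = noise_sd,
                             seed = seed, ...))
}

truth_labels <- function(truth) {
  as.integer(factor(truth$class, levels = c("promoter", "enhancer", "flat")))
}

# Fraction of loci whose orientation matches the planted one, up to the
# unidentifiable global sign.
orientation_agreement <- function(est, planted) {
  a <- mean(est == planted)
  max(a, 1 - a)
}

# Exhaustive minimum-normalized-cut bipartition for small graphs.
min_ncut_partition <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 14)
  best <- NULL
  bestv <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    A <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    B <- setdiff(seq_len(n), A)
    cut <- sum(W[A, B])
    v <- cut / sum(W[A, ]) + cut / sum(W[B, ])
    if (v < bestv) {
      bestv <- v
      best <- A
    }
  }
  list(members = best, ncut = bestv)
}

# Planted two-block adjacency with weak random inter-block weights.
planted_two_block <- function(n1, n2, seed, p_within = 1, p_between = 0.05) {
  set.seed(seed)
  n <- n1 + n2
  blk <- rep(1:2, c(n1, n2))
  W <- matrix(p_between * (0.5 + runif(n * n)), n, n)
  W[blk == 1, blk == 1] <- p_within * (0.9 + 0.2 * runif(n1 * n1))
  W[blk == 2, blk == 2] <- p_within * (0.9 + 0.2 * runif(n2 * n2))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  list(W = W, labels = blk)
}
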