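# Height prior, window scoring and the genome-wide template scan.

# Signature set whose channel rows are constants, so window heights are
# exactly the given values.
const_height_sigs <- function(heights, channel = "ch_c14", L = 50) {
  data <- array(rep(heights, each = L), dim = c(1, L, length(heights)),
                dimnames = list(channel, NULL, NULL))
  chromsig:::new_signature_set(
    data, chromsig:::as_channel_table(channel),
    tibble::tibble(chrom = "chrT", summit = seq_along(heights),
                   orientation = "+"),
    window_bp = L * 10, bin_bp = 10
  )
}

test_that("height prior is a smoothed relative-frequency histogram", {
  # all heights equal: all mass in one bin (up to smoothing)
  sigs <- const_height_sigs(rep(2, 20))
  pr <- fit_height_prior(sigs, n_bins = 10, pseudo = 0.5)
  expect_equal(sum(pr$table$ch_c14$prob), 1, tolerance = 1e-12)
  expect_gt(prior_prob(pr, "ch_c14", 2), 0.75)
  # far above the training support: pseudo-count floor
  expect_equal(prior_prob(pr, "ch_c14", 100), pr$table$ch_c14$floor)
  expect_lt(prior_prob(pr, "ch_c14", 100), 0.03)

  # uniform heights on [0, 1], 10 equal-width bins over [0, 1.1]:
  # interior bins each hold ~ bin width (0.11) of the mass
  set.seed(31)
  u <- runif(10000)
  pru <- fit_height_prior(const_height_sigs(u), n_bins = 10)
  p_interior <- pru$table$ch_c14$prob[1:9]
  expect_true(all(abs(p_interior - 0.11 * max(u)) < 0.02))

  expect_error(fit_height_prior(const_height_sigs(rep(1, 5))),
               "at least 10", class = "chromsig_data_error")
})

test_that("window scores combine correlation and height prior per channel", {
  sim <- sim_three_class(n_per = 12, noise_sd = 0.05, seed = 8)
  sigs <- extract_signatures(sim$tracks, sim$peaks)
  enh <- subset_signatures(sigs, sim$truth$class == "enhancer")
  tmpl <- chromsig:::new_scan_template(
    mean_signature(enh), enh$channels, enh$window_bp, enh$bin_bp
  )
  prior <- fit_height_prior(enh)

  # a training locus at modal height: correlation ~ 1, score ~ sum of priors
  w <- signature_matrix(enh, 1)
  sc <- window_score(w, tmpl, prior)
  expect_equal(sc$total, sum(sc$per_channel))
  expect_gt(sc$total, 0)

  # flat window: every channel has zero variance -> total 0
  flat <- matrix(3, nrow(w), ncol(w), dimnames = dimnames(w))
  expect_equal(window_score(flat, tmpl, prior)$total, 0)

  # same shape at 100x height: correlation unchanged, but every channel's
  # height falls outside the training support so the prior collapses to
  # the pseudo-count floor
  sc100 <- window_score(100 * w, tmpl, prior)
  floors <- vapply(rownames(w), function(ch) prior$table[[ch]]$floor,
                   numeric(1))
  for (ch in rownames(w)) {
    expect_equal(prior_prob(prior, ch, mean(100 * w[ch, ])),
                 prior$table[[ch]]$floor)
  }
  expect_lte(sc100$total, sum(floors) + 1e-12)
  expect_lt(sc100$total, 0.2 * sc$total)
  # without the prior the magnitude mismatch goes unpunished
  sc100_np <- window_score(100 * w, tmpl, NULL)
  expect_gt(sc100_np$total, 0.8 * nrow(w))
})

test_that("scan finds implants in both orientations and decomposes scores", {
  g <- simulate_scan_genome(genome_bp = 2e6, n_implant = 12, seed = 5)
  sim <- sim_three_class(n_per = 20, noise_sd = 0.1, seed = 6)
  train <- extract_signatures(sim$tracks, sim$peaks)
  enh <- subset_signatures(train, sim$truth$class == "enhancer")
  tmpl <- chromsig:::new_scan_template(mean_signature(enh), enh$channels,
                                       enh$window_bp, enh$bin_bp)
  prior <- fit_height_prior(enh)
  hits <- scan_genome(g$tracks, tmpl, prior, top_n = 12)
  expect_gte(evaluate_recall(hits, g$truth, tolerance_bp = 200), 0.9)
  # both planted orientations are present among the recovered implants
  expect_true(all(c("+", "-") %in% g$truth$orientation))
  # per-channel scores sum to the total exactly
  per <- rowSums(as.matrix(hits[, grep("^score_", names(hits))]))
  expect_equal(per, hits$score, tolerance = 1e-12, ignore_attr = TRUE)
  # non-maximum suppression: hit centres >= window/2 apart
  cent <- sort(hits$center)
  expect_true(all(diff(cent) >= tmpl$window_bp / 2))
})

test_that("asymmetric templates report the planted implant orientation", {
  g <- simulate_scan_genome(genome_bp = 2e6, n_implant = 12,
                            class = "promoter", seed = 9)
  sim <- sim_promoters(n = 25, noise_sd = 0.1, seed = 10)
  train <- extract_signatures(sim$tracks, sim$peaks)
  train <- flip(train, which = sim$truth$orientation == "-")
  tmpl <- chromsig:::new_scan_template(mean_signature(train), train$channels,
                                       train$window_bp, train$bin_bp)
  # broad promoter-like features give a flat correlation peak, so hit
  # centres localize less sharply than narrow enhancer flanks: use a wider
  # matching tolerance and focus on the reported orientation
  hits <- scan_genome(g$tracks, tmpl, fit_height_prior(train), top_n = 12)
  m <- vapply(seq_len(nrow(g$truth)), function(i) {
    j <- which(hits$chrom == g$truth$chrom[i] &
                 abs(hits$center - g$truth$summit[i]) <= 600)[1]
    if (is.na(j)) NA_character_ else hits$orientation[j]
  }, character(1))
  found <- !is.na(m)
  expect_gte(mean(found), 0.9)
  expect_gte(mean((m == g$truth$orientation)[found]), 0.9)
})

test_that("scan is shift-equivariant and mirror-consistent", {
  # asymmetric template: orientations are identifiable, so mirroring the
  # genome must invert every reported orientation
  g <- simulate_scan_genome(genome_bp = 1e6, n_implant = 6,
                            class = "promoter", seed = 3)
  tmpl <- chromsig:::new_scan_template(
    g$templates$promoter, attr(g$templates, "channels"), 10000, 10
  )
  hits <- scan_genome(g$tracks, tmpl, NULL, top_n = 6)

  # translate all tracks by s bins: hits translate with identical scores
  s <- 30L
  shifted <- g$tracks
  for (ch in names(shifted$signal)) {
    v <- shifted$signal[[ch]]$chrS1
    shifted$signal[[ch]]$chrS1 <- c(numeric(s), v[seq_len(length(v) - s)])
  }
  hs <- scan_genome(shifted, tmpl, NULL, top_n = 6)
  o1 <- order(hits$center)
  o2 <- order(hs$center)
  expect_equal(hs$center[o2], hits$center[o1] + s * 10)
  expect_equal(hs$score[o2], hits$score[o1], tolerance = 1e-9)

  # mirrored genome: same hits at mirrored coordinates, orientations flipped
  mir <- g$tracks
  n_bins <- length(mir$signal[[1]]$chrS1)
  for (ch in names(mir$signal)) {
    mir$signal[[ch]]$chrS1 <- rev(mir$signal[[ch]]$chrS1)
  }
  hm <- scan_genome(mir, tmpl, NULL, top_n = 6)
  om <- order(n_bins * 10 - hm$center)
  expect_equal(n_bins * 10 - hm$center[om], hits$center[o1])
  expect_equal(hm$score[om], hits$score[o1], tolerance = 1e-9)
  expect_true(all(hm$orientation[om] != hits$orientation[o1]))
})

test_that("recall evaluator matches by centre distance per chromosome", {
  hits <- tibble::tibble(chrom = c("c1", "c1"), center = c(1000, 5000))
  ref <- tibble::tibble(chrom = c("c1", "c1"), summit = c(1100, 9000))
  expect_equal(evaluate_recall(hits, ref, tolerance_bp = 200), 0.5)
  expect_equal(evaluate_recall(hits, hits, tolerance_bp = 0), 1)
  ref2 <- tibble::tibble(chrom = "c2", summit = 1000)
  expect_equal(evaluate_recall(hits, ref2, tolerance_bp = 1e6), 0)
  expect_error(evaluate_recall(hits[0, ], ref), "non-empty",
               class = "chromsig_data_error")
})
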