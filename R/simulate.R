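# Synthetic multichannel tracks with planted signature classes.  The
# generator emulates the study conditions end to end: promoter-like,
# enhancer-like and featureless loci implanted at known centres and
# orientations into noisy genome-wide tracks, so orientation recovery,
# cluster recovery and scan recall can all be measured against ground
# truth.

#' Template shape parameters for the synthetic signature classes
#'
#' Heights are in arbitrary ChIP enrichment units; offsets/widths in bp
#' relative to the locus centre.  Defaults are heuristic shapes chosen to
#' resemble typical promoter-like and enhancer-like chromatin profiles:
#' the promoter class carries a one-sided H3K4me3 domain (downstream of the
#' summit) with flanking H3K4me1/H3K27ac/H3K18ac nucleosomes, the enhancer
#' class two narrow symmetric H3K4me1 nucleosomes inside a broad H3K27me3
#' domain with a central dip, and the flat class no signal.  The earlier
#' time point is a scaled-down copy of the later one (chromatin marks
#' strengthen over time).
#'
#' @param k4me3_height,k4me3_offset_bp,k4me3_sd_bp One-sided promoter
#'   H3K4me3 bump.
#' @param prom_k4me1_height,prom_k4me1_offset_bp,prom_k4me1_sd_bp Broad
#'   promoter H3K4me1 flanks.
#' @param prom_k27me3_height,prom_k27me3_halfwidth_bp Weak broad polycomb
#'   context domain around promoter loci.
#' @param enh_k4me1_height,enh_k4me1_offset_bp,enh_k4me1_sd_bp Narrow
#'   enhancer H3K4me1 flanking nucleosomes.
#' @param enh_k4me3_height,enh_k4me3_halfwidth_bp Weak broad enhancer
#'   H3K4me3 domain (active enhancers carry H3K4me3 at a fraction of
#'   promoter level).
#' @param k27me3_height,k27me3_halfwidth_bp,k27me3_edge_bp,k27me3_dip_sd_bp
#'   Broad enhancer H3K27me3 domain with smooth edges and a central dip.
#' @param early_scale Multiplier applied to every channel at the earlier
#'   time point (default 0.5).
#' @return A named list of parameters.
#' @export
template_params <- function(k4me3_height = 8, k4me3_offset_bp = 1200,
                            k4me3_sd_bp = 1000,
                            prom_k4me1_height = 8, prom_k4me1_offset_bp = 1200,
                            prom_k4me1_sd_bp = 600,
                            prom_k27me3_height = 2.5,
                            prom_k27me3_halfwidth_bp = 4000,
                            enh_k4me1_height = 10, enh_k4me1_offset_bp = 400,
                            enh_k4me1_sd_bp = 200,
                            enh_k4me3_height = 4.5,
                            enh_k4me3_halfwidth_bp = 2500,
                            k27me3_height = 5, k27me3_halfwidth_bp = 3500,
                            k27me3_edge_bp = 200, k27me3_dip_sd_bp = 400,
                            early_scale = 0.5) {
  as.list(environment())
}

sim_channel_table <- function() {
  mods <- c("H3K4me1", "H3K4me3", "H3K27me3")
  tps <- c("c14", "c13")
  tibble(
    name = paste(rep(mods, times = length(tps)), rep(tps, each = length(mods)),
                 sep = "_"),
    modification = rep(mods, times = length(tps)),
    timepoint = rep(tps, each = length(mods))
  )
}

#' Class templates for the synthetic signature generator
#'
#' @param window_bp,bin_bp Window and bin geometry (defaults 10 Kb / 10 bp,
#'   so each template row has 1000 bins).
#' @param params Shape parameters from [template_params()].
#' @return Named list of M x L matrices (`promoter`, `enhancer`, `flat`)
#'   with the channel table attached as `attr(, "channels")`.
#' @export
signature_templates <- function(window_bp = 10000, bin_bp = 10,
                                params = template_params()) {
  p <- params
  L <- as.integer(window_bp / bin_bp)
  pos <- (seq_len(L) - 0.5) * bin_bp - window_bp / 2
  channels <- sim_channel_table()
  gauss <- function(mu, sd, h) h * exp(-(pos - mu)^2 / (2 * sd^2))
  flanks <- function(off, sd, h) gauss(-off, sd, h) + gauss(off, sd, h)
  domain <- function(h, halfwidth, edge, dip_sd) {
    h * (1 / (1 + exp(-(pos + halfwidth) / edge))) *
      (1 / (1 + exp((pos - halfwidth) / edge))) *
      (1 - exp(-pos^2 / (2 * dip_sd^2)))
  }
  zero <- numeric(L)

  late <- list(
    promoter = rbind(
      H3K4me1 = flanks(p$prom_k4me1_offset_bp, p$prom_k4me1_sd_bp,
                       p$prom_k4me1_height),
      H3K4me3 = gauss(p$k4me3_offset_bp, p$k4me3_sd_bp, p$k4me3_height),
      H3K27me3 = domain(p$prom_k27me3_height, p$prom_k27me3_halfwidth_bp,
                        400, 1500)
    ),
    enhancer = rbind(
      H3K4me1 = flanks(p$enh_k4me1_offset_bp, p$enh_k4me1_sd_bp,
                       p$enh_k4me1_height),
      H3K4me3 = domain(p$enh_k4me3_height, p$enh_k4me3_halfwidth_bp,
                       300, 500),
      H3K27me3 = domain(p$k27me3_height, p$k27me3_halfwidth_bp,
                        p$k27me3_edge_bp, p$k27me3_dip_sd_bp)
    ),
    flat = rbind(
      H3K4me1 = zero, H3K4me3 = zero, H3K27me3 = zero
    )
  )
  out <- lapply(late, function(m) {
    full <- rbind(m, p$early_scale * m)
    rownames(full) <- channels$name
    full
  })
  attr(out, "channels") <- channels
  attr(out, "window_bp") <- window_bp
  attr(out, "bin_bp") <- bin_bp
  out
}

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 2000 loci split
#' 620/660/720 into promoter-like, enhancer-like and flat classes, 10 Kb
#' windows at 10 bp bins, additive truncated-Gaussian noise with standard
#' deviation `noise_sd` times each channel's peak template height (each
#' track has its own signal-to-noise, like separate ChIP libraries) and a
#' 150 bp correlation length (fragment-scale smoothness; `noise_corr_bp =
#' 0` gives i.i.d. noise per bin).
#'
#' @param n_promoter,n_enhancer,n_flat Loci per class.
#' @param noise_sd Noise standard deviation as a fraction of each
#'   channel's peak template height.
#' @param noise_corr_bp Noise correlation length in bp (0 = white noise).
#' @param bin_bp,window_bp Track geometry.
#' @param spacing_bp Centre-to-centre distance between consecutive loci
#'   (must be at least `window_bp`).
#' @param n_chrom Number of chromosomes the loci are spread over.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @param params Template shape parameters ([template_params()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_promoter = 620, n_enhancer = 660, n_flat = 720,
                       noise_sd = 0.1, noise_corr_bp = 150,
                       bin_bp = 10, window_bp = 10000, spacing_bp = 12000,
                       n_chrom = 4, seed = 1, params = template_params()) {
  stopifnot(noise_sd >= 0, spacing_bp >= window_bp, n_chrom >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate multichannel tracks with planted signature classes
#'
#' Loci are placed on a regular grid (`spacing_bp` apart, so windows never
#' collide), assigned a class and an orientation at random, and each
#' locus's class template (flipped for `"-"` orientations) is added to the
#' tracks; truncated-at-zero Gaussian noise is added everywhere.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `tracks` ([track_set]), `peaks` (anchor tibble with
#'   `chrom`, `summit`), `truth` (per-locus class label, planted
#'   orientation, implant centre) and `templates`.
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  templates <- signature_templates(cfg$window_bp, cfg$bin_bp, cfg$params)
  counts <- c(promoter = cfg$n_promoter, enhancer = cfg$n_enhancer,
              flat = cfg$n_flat)
  n <- sum(counts)
  per_chrom <- ceiling(n / cfg$n_chrom)
  chrom <- paste0("chrS", rep(seq_len(cfg$n_chrom), each = per_chrom))[seq_len(n)]
  slot <- unlist(lapply(table(chrom)[unique(chrom)], seq_len), use.names = FALSE)
  summit <- slot * cfg$spacing_bp - cfg$spacing_bp / 2
  chrom_sizes <- setNames(
    as.integer(table(chrom)[unique(chrom)] * cfg$spacing_bp),
    unique(chrom)
  )
  set.seed(derive_seed(cfg$seed, "simulate"))
  class <- sample(rep(names(counts), counts))
  orientation <- sample(c("+", "-"), n, replace = TRUE)
  truth <- tibble(chrom = chrom, summit = summit, class = class,
                  orientation = orientation)
  tracks <- implant_tracks(templates, truth, chrom_sizes, cfg$bin_bp,
                           cfg$window_bp, cfg$noise_sd, cfg$noise_corr_bp)
  list(
    tracks = tracks,
    peaks = truth |> select("chrom", "summit"),
    truth = truth,
    templates = templates,
    config = cfg
  )
}

# Per-channel noise scale: noise_sd times that channel's maximum template
# height over the reference classes (each track has its own signal-to-noise,
# as separate ChIP libraries do).  A channel with no signal in any reference
# class falls back to the global maximum (pure-background track).
channel_noise_sd <- function(templates, noise_sd, ref_classes = NULL) {
  ref <- if (is.null(ref_classes)) templates else templates[ref_classes]
  per_ch <- apply(vapply(ref, function(t) apply(t, 1, max),
                         numeric(nrow(ref[[1]]))), 1, max)
  global <- max(per_ch, 1e-12)
  per_ch[per_ch <= 0] <- global
  noise_sd * per_ch
}

# Adds class templates (flipped for "-" loci) at each truth row's summit,
# then truncated Gaussian noise.  Loci whose windows overlap raise an
# error.  Assumes the RNG has already been seeded by the caller.
implant_tracks <- function(templates, truth, chrom_sizes, bin_bp, window_bp,
                           noise_sd, noise_corr_bp, noise_ref = NULL) {
  channels <- attr(templates, "channels")
  L <- ncol(templates[[1]])
  half <- window_bp / 2
  sd_by_channel <- channel_noise_sd(templates, noise_sd, noise_ref)
  by_chrom <- split(seq_len(nrow(truth)), truth$chrom)
  for (cr in names(by_chrom)) {
    s <- sort(truth$summit[by_chrom[[cr]]])
    if (length(s) > 1 && any(diff(s) < window_bp)) {
      abort("loci collide: centres closer than one window",
            class = "chromsig_data_error")
    }
  }
  signal <- list()
  for (ci in seq_len(nrow(channels))) {
    ch <- channels$name[ci]
    signal[[ch]] <- list()
    for (cr in names(chrom_sizes)) {
      nb <- as.integer(ceiling(chrom_sizes[[cr]] / bin_bp))
      v <- numeric(nb)
      rows <- by_chrom[[cr]]
      for (i in rows) {
        row <- templates[[truth$class[i]]][ci, ]
        if (truth$orientation[i] == "-") row <- rev(row)
        b0 <- as.integer(floor((truth$summit[i] - half) / bin_bp))
        v[(b0 + 1L):(b0 + L)] <- v[(b0 + 1L):(b0 + L)] + row
      }
      if (sd_by_channel[[ci]] > 0) {
        v <- v + sd_by_channel[[ci]] * correlated_noise(nb, noise_corr_bp / bin_bp)
        v <- pmax(v, 0)
      }
      signal[[ch]][[cr]] <- v
    }
  }
  track_set(signal, channels, bin_bp, chrom_sizes)
}

# Unit-variance Gaussian noise with an approximately Gaussian
# autocorrelation of scale sd_bins (0 = white), via circular FFT smoothing.
correlated_noise <- function(n, sd_bins) {
  z <- rnorm(n)
  if (sd_bins <= 0) return(z)
  half_k <- ceiling(4 * sd_bins)
  k <- exp(-(seq(-half_k, half_k))^2 / (2 * sd_bins^2))
  k <- k / sum(k)
  nfft <- stats::nextn(n + length(k), c(2L, 3L, 5L))
  zp <- c(z, numeric(nfft - n))
  kp <- c(k, numeric(nfft - length(k)))
  sm <- Re(stats::fft(stats::fft(zp) * stats::fft(kp), inverse = TRUE)) / nfft
  sm <- sm[(half_k + 1L):(half_k + n)]
  sm / sqrt(sum(k^2)) # restore unit marginal variance
}

#' Simulate a genome for scan benchmarking
#'
#' Implants `n_implant` enhancer-like signatures (random orientations) and
#' optionally `n_decoy` shape-matched decoys whose signal is scaled by
#' `decoy_scale` (right shape, wrong ChIP magnitude) into a noisy genome.
#'
#' @param genome_bp Total genome length (one chromosome; default 10 Mb).
#' @param n_implant Number of true enhancer-like implants (default 50).
#' @param n_decoy Number of height-skewed decoys (default 0).
#' @param decoy_scale Height multiplier for decoys (default 5).
#' @param class Template class to implant (default `"enhancer"`).
#' @param noise_sd,noise_corr_bp,bin_bp,window_bp,seed,params As in
#'   [sim_config()].
#' @return A list like [simulate_tracks()]; `truth$class` distinguishes
#'   implants from `"decoy"` rows.
#' @export
simulate_scan_genome <- function(genome_bp = 1e7, n_implant = 50,
                                 n_decoy = 0, decoy_scale = 5,
                                 class = "enhancer", noise_sd = 0.1,
                                 noise_corr_bp = 150, bin_bp = 10,
                                 window_bp = 10000, seed = 1,
                                 params = template_params()) {
  templates <- signature_templates(window_bp, bin_bp, params)
  templates$decoy <- decoy_scale * templates[[class]]
  n <- n_implant + n_decoy
  n_slots <- floor(genome_bp / (1.2 * window_bp)) - 1
  if (n > n_slots) abort("genome too small for the requested implants",
                         class = "chromsig_config_error")
  set.seed(derive_seed(seed, "simulate_scan"))
  slots <- sort(sample.int(n_slots, n))
  summit <- slots * 1.2 * window_bp
  summit <- round(summit / 100) * 100
  truth <- tibble(
    chrom = "chrS1",
    summit = summit,
    class = sample(rep(c(class, "decoy"), c(n_implant, n_decoy))),
    orientation = sample(c("+", "-"), n, replace = TRUE)
  )
  chrom_sizes <- c(chrS1 = as.integer(genome_bp))
  tracks <- implant_tracks(templates, truth, chrom_sizes, bin_bp, window_bp,
                           noise_sd, noise_corr_bp,
                           noise_ref = setdiff(names(templates), "decoy"))
  list(tracks = tracks, truth = truth, templates = templates)
}
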