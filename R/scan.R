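# Genome-wide template matching: slide a cluster's mean signature across
# binned tracks in both orientations, score windows by Pearson correlation
# times an empirical signal-height prior, and report local score maxima.

#' Build a scan template from a cluster fit
#'
#' @param fit A `cluster_fit`.
#' @param cluster Cluster label to use as the template (e.g. the
#'   enhancer-like cluster).
#' @param channels Optional channel subset (e.g. only the later time
#'   point's channels).
#' @return A `scan_template`: the M x L `matrix` with channel rownames,
#'   the channel table, `window_bp` and `bin_bp`.
#' @export
cluster_template <- function(fit, cluster, channels = NULL) {
  stopifnot(inherits(fit, "cluster_fit"))
  m <- fit$cluster_signatures[[as.character(cluster)]]
  if (is.null(m)) abort(paste0("no cluster '", cluster, "' in fit"),
                        class = "chromsig_config_error")
  sigs <- fit$signatures
  new_scan_template(m, sigs$channels, sigs$window_bp, sigs$bin_bp, channels)
}

new_scan_template <- function(mat, channels, window_bp, bin_bp,
                              keep_channels = NULL) {
  channels <- as_channel_table(channels)
  rownames(mat) <- channels$name
  if (!is.null(keep_channels)) {
    missing <- setdiff(keep_channels, channels$name)
    if (length(missing)) {
      abort(paste0("unknown channel(s): ", paste(missing, collapse = ", ")),
            class = "chromsig_config_error")
    }
    mat <- mat[keep_channels, , drop = FALSE]
    channels <- channels[match(keep_channels, channels$name), , drop = FALSE]
  }
  structure(
    list(matrix = mat, channels = channels, window_bp = window_bp,
         bin_bp = as.integer(bin_bp)),
    class = "scan_template"
  )
}

#' @export
print.scan_template <- function(x, ...) {
  cat("<scan_template> ", nrow(x$matrix), " channels x ", ncol(x$matrix),
      " bins (", x$window_bp, " bp at ", x$bin_bp, " bp)\n", sep = "")
  invisible(x)
}

#' Fit the empirical signal-height prior
#'
#' For each channel, the relative-frequency histogram of the mean window
#' signal ("height") among the training signatures, lightly smoothed with a
#' pseudo-count so near-miss heights are penalized rather than annihilated.
#' Queries outside the padded support return the pseudo-count floor.
#' Correlation alone is scale-invariant, so without this prior a window
#' with the right shape but a wildly wrong ChIP magnitude would score as
#' well as a true match.
#'
#' @param sigs A `signature_set` of training loci (e.g. one cluster's
#'   members; at least 10).
#' @param n_bins Number of equal-width histogram bins spanning
#'   `[0, 1.1 * max training height]` (default 25).
#' @param pseudo Pseudo-count added to every bin (default 0.5).
#' @param channels Optional channel subset.
#' @return A `height_prior`.
#' @export
fit_height_prior <- function(sigs, n_bins = 25, pseudo = 0.5, channels = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  channels <- channels %||% sigs$channels$name
  N <- dim(sigs$data)[3]
  if (N < 10) abort("need at least 10 training signatures",
                    class = "chromsig_data_error")
  L <- dim(sigs$data)[2]
  heights <- colSums(aperm(sigs$data, c(2, 1, 3))) / L # M x N
  rownames(heights) <- sigs$channels$name
  per_channel <- lapply(channels, function(ch) {
    h <- heights[ch, ]
    top <- 1.1 * max(h, .Machine$double.eps)
    breaks <- seq(0, top, length.out = n_bins + 1)
    counts <- tabulate(findInterval(h, breaks, rightmost.closed = TRUE),
                       nbins = n_bins)
    prob <- (counts + pseudo) / (N + pseudo * n_bins)
    list(breaks = breaks, prob = prob,
         floor = pseudo / (N + pseudo * n_bins))
  })
  structure(
    list(channels = channels, table = setNames(per_channel, channels),
         n_bins = n_bins, pseudo = pseudo, n_train = N),
    class = "height_prior"
  )
}

#' Look up prior probabilities for window heights
#'
#' @param prior A `height_prior`.
#' @param channel Channel name.
#' @param height Numeric vector of mean window signals.
#' @return Relative frequencies; the pseudo-count floor outside the
#'   training support.
#' @export
prior_prob <- function(prior, channel, height) {
  stopifnot(inherits(prior, "height_prior"))
  tab <- prior$table[[channel]]
  if (is.null(tab)) abort(paste0("no prior for channel '", channel, "'"),
                          class = "chromsig_config_error")
  idx <- findInterval(height, tab$breaks, rightmost.closed = TRUE)
  out <- rep(tab$floor, length(height))
  inside <- idx >= 1 & idx <= length(tab$prob)
  out[inside] <- tab$prob[idx[inside]]
  out
}

#' @export
print.height_prior <- function(x, ...) {
  cat("<height_prior> ", length(x$channels), " channels, ", x$n_bins,
      " bins, ", x$n_train, " training loci\n", sep = "")
  invisible(x)
}

#' @export
tidy.height_prior <- function(x, ...) {
  bind_rows(purrr::imap(x$table, function(tab, ch) {
    mids <- (head(tab$breaks, -1) + tab$breaks[-1]) / 2
    tibble(channel = ch, height = mids, prob = tab$prob)
  }))
}

#' Score one window against a template
#'
#' Per channel, the Pearson correlation between the window's and the
#' template's positional vectors, multiplied by the prior probability of
#' the window's mean signal in that channel; the total score is the sum
#' over channels.  A zero-variance channel (in window or template)
#' contributes 0.
#'
#' @param window M x L matrix with channel rownames (or a `signature_set`
#'   locus via [signature_matrix()]).
#' @param template A `scan_template`.
#' @param prior A `height_prior`, or `NULL` to disable the prior
#'   (correlation-only scoring).
#' @return List with `per_channel` (named vector) and `total`.
#' @export
window_score <- function(window, template, prior = NULL) {
  stopifnot(inherits(template, "scan_template"))
  tmat <- template$matrix
  if (is.null(rownames(window))) rownames(window) <- rownames(tmat)
  if (!all(rownames(tmat) %in% rownames(window)) ||
      ncol(window) != ncol(tmat)) {
    abort("window shape/channels do not match template",
          class = "chromsig_data_error")
  }
  per <- vapply(rownames(tmat), function(ch) {
    x <- window[ch, ]
    t <- tmat[ch, ]
    if (sd(x) == 0 || sd(t) == 0) return(0)
    r <- cor(x, t)
    p <- if (is.null(prior)) 1 else prior_prob(prior, ch, mean(x))
    r * p
  }, numeric(1))
  list(per_channel = per, total = sum(per))
}

#' Scan a genome for windows matching a template signature
#'
#' Slides the template across every chromosome at `stride_bp`, scoring each
#' window in both orientations (the window is flipped, scored, and the
#' better orientation kept).  Reported hits are non-maximum-suppressed: a
#' hit must be the score maximum within half a window on each side, so hit
#' centres are at least `window_bp / 2` apart.  Correlations are computed
#' for all positions by FFT cross-correlation, which is exact up to
#' floating-point error.
#'
#' @param tracks A [track_set] binned at the template's bin size.
#' @param template A `scan_template`.
#' @param prior A `height_prior` or `NULL` (correlation-only ablation).
#' @param stride_bp Stride between evaluated windows (default 100 bp; must
#'   be a multiple of the bin size).
#' @param top_n Number of top-ranked hits to return (default 2500).
#' @param min_sd Variance guard: windows with signal standard deviation at
#'   or below this score 0 in that channel.
#' @return A tibble of hits: `chrom`, `start`, `end`, `center`,
#'   `orientation`, per-channel `score_*` columns, `score` and `rank`,
#'   ordered by decreasing score.
#' @export
scan_genome <- function(tracks, template, prior = NULL, stride_bp = 100,
                        top_n = 2500, min_sd = 1e-9) {
  stopifnot(inherits(tracks, "track_set"), inherits(template, "scan_template"))
  bin <- tracks$bin_bp
  if (bin != template$bin_bp) {
    abort("tracks and template bin sizes differ", class = "chromsig_config_error")
  }
  if (stride_bp %% bin != 0) {
    abort("`stride_bp` must be a multiple of the bin size",
          class = "chromsig_config_error")
  }
  missing <- setdiff(rownames(template$matrix), tracks$channels$name)
  if (length(missing)) {
    abort(paste0("template channels absent from tracks: ",
                 paste(missing, collapse = ", ")),
          class = "chromsig_config_error")
  }
  L <- ncol(template$matrix)
  stride <- as.integer(stride_bp / bin)
  radius <- as.integer(floor((template$window_bp / 2) / stride_bp))
  chroms <- names(tracks$chrom_sizes)
  ch_names <- rownames(template$matrix)

  hits <- list()
  for (cr in chroms) {
    nb <- length(tracks$signal[[ch_names[1]]][[cr]])
    if (nb < L) {
      warn(paste0("chromosome '", cr, "' shorter than the window; skipped"))
      next
    }
    n_pos <- nb - L + 1L
    starts <- seq(1L, n_pos, by = stride)
    ns <- length(starts)
    s_plus <- matrix(0, ns, length(ch_names),
                     dimnames = list(NULL, ch_names))
    s_minus <- s_plus
    for (ch in ch_names) {
      x <- tracks$signal[[ch]][[cr]]
      t_row <- template$matrix[ch, ]
      tc <- t_row - mean(t_row)
      tss <- sum(tc^2)
      cs <- c(0, cumsum(x))
      cs2 <- c(0, cumsum(x^2))
      S1 <- (cs[starts + L] - cs[starts])
      S2 <- (cs2[starts + L] - cs2[starts])
      v <- pmax(S2 - S1^2 / L, 0)
      sd_x <- sqrt(v)
      p <- if (is.null(prior)) 1 else prior_prob(prior, ch, S1 / L)
      if (tss > min_sd^2) {
        den <- sd_x * sqrt(tss)
        bad <- sd_x <= min_sd
        r_p <- (sliding_cross(x, t_row)[starts] - S1 * mean(t_row)) / den
        r_m <- (sliding_cross(x, rev(t_row))[starts] - S1 * mean(t_row)) / den
        r_p[bad] <- 0
        r_m[bad] <- 0
        s_plus[, ch] <- r_p * p
        s_minus[, ch] <- r_m * p
      }
    }
    tot_p <- rowSums(s_plus)
    tot_m <- rowSums(s_minus)
    best <- pmax(tot_p, tot_m)
    is_minus <- tot_m > tot_p
    keep <- best >= running_max(best, radius)
    if (!any(keep)) next
    idx <- which(keep)
    sc <- s_plus[idx, , drop = FALSE]
    sc[is_minus[idx], ] <- s_minus[idx, , drop = FALSE][is_minus[idx], ]
    colnames(sc) <- paste0("score_", ch_names)
    start_bp <- (starts[idx] - 1L) * bin
    hits[[cr]] <- bind_cols(
      tibble(
        chrom = cr,
        start = start_bp,
        end = start_bp + template$window_bp,
        center = start_bp + template$window_bp / 2,
        orientation = ifelse(is_minus[idx], "-", "+"),
        score = best[idx]
      ),
      as_tibble(sc)
    )
  }
  if (!length(hits)) {
    abort("no scannable chromosome (all shorter than the window)",
          class = "chromsig_data_error")
  }
  out <- bind_rows(hits) |>
    arrange(desc(.data$score)) |>
    slice_head(n = top_n) |>
    mutate(rank = row_number())
  attr(out, "window_bp") <- template$window_bp
  attr(out, "bin_bp") <- bin
  out
}

#' Fraction of reference loci recovered by scan hits
#'
#' A reference locus counts as recovered when at least one hit centre lies
#' within `tolerance_bp` of it on the same chromosome.
#'
#' @param hits Scan hit tibble (needs `chrom` and `center`).
#' @param reference Data frame of reference loci with `chrom` and `summit`
#'   (or `center`).
#' @param tolerance_bp Matching tolerance in bp (default 200).
#' @return Fraction in `[0, 1]`.
#' @export
evaluate_recall <- function(hits, reference, tolerance_bp = 200) {
  hits <- as_tibble(hits)
  reference <- as_tibble(reference)
  if (!nrow(hits) || !nrow(reference)) {
    abort("hits and reference must be non-empty", class = "chromsig_data_error")
  }
  ref_pos <- if ("summit" %in% names(reference)) {
    reference$summit
  } else {
    reference$center
  }
  hit_by_chrom <- split(hits$center, hits$chrom)
  recovered <- vapply(seq_len(nrow(reference)), function(i) {
    hc <- hit_by_chrom[[reference$chrom[i]]]
    if (is.null(hc)) return(FALSE)
    any(abs(hc - ref_pos[i]) <= tolerance_bp)
  }, logical(1))
  mean(recovered)
}
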