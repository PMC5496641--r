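#' Extract multichannel signatures around anchor loci
#'
#' For each locus, takes the binned signal of every channel over the window
#' `[summit - window_bp/2, summit + window_bp/2)`, giving an M x L matrix
#' per locus (M channels, L = window_bp / bin_bp positional bins; the
#' defaults, a 10 Kb window at 10 bp, give L = 1000).  Loci whose window
#' overhangs a chromosome end are skipped with a warning rather than
#' zero-padded: padding would fabricate a flat chromatin signal.
#'
#' @param tracks A [track_set].
#' @param loci Data frame with columns `chrom` and `summit` (0-based bp);
#'   optional `score`.
#' @param window_bp Window width in bp (default 10000); `window_bp / 2` must
#'   be a multiple of the track bin size.
#' @return A `signature_set`: list with a `M x L x N` array `data`, the
#'   channel table, a `loci` tibble (including the current `orientation`,
#'   initialized to `"+"`), `window_bp` and `bin_bp`.
#' @export
extract_signatures <- function(tracks, loci, window_bp = 10000) {
  stopifnot(inherits(tracks, "track_set"))
  loci <- as_tibble(loci)
  stopifnot(all(c("chrom", "summit") %in% names(loci)))
  bin <- tracks$bin_bp
  half <- window_bp / 2
  if (half %% bin != 0) {
    abort("`window_bp / 2` must be a multiple of the bin size",
          class = "chromsig_config_error")
  }
  L <- as.integer(window_bp / bin)
  M <- nrow(tracks$channels)
  sizes <- tracks$chrom_sizes[loci$chrom]
  ok <- !is.na(sizes) & loci$summit - half >= 0 & loci$summit + half <= sizes
  if (any(!ok)) {
    warn(paste0("skipping ", sum(!ok),
                " locus/loci whose window overhangs a chromosome end"))
  }
  loci <- loci[ok, , drop = FALSE]
  N <- nrow(loci)
  if (N == 0) abort("no loci left after filtering", class = "chromsig_data_error")
  start_bin <- as.integer(floor((loci$summit - half) / bin)) + 1L
  data <- array(0, dim = c(M, L, N),
                dimnames = list(tracks$channels$name, NULL, NULL))
  for (m in seq_len(M)) {
    per_chrom <- tracks$signal[[m]]
    for (i in seq_len(N)) {
      data[m, , i] <- per_chrom[[loci$chrom[i]]][start_bin[i]:(start_bin[i] + L - 1L)]
    }
  }
  loci$orientation <- rep("+", N)
  new_signature_set(data, tracks$channels, loci, window_bp, bin)
}

new_signature_set <- function(data, channels, loci, window_bp, bin_bp) {
  structure(
    list(data = data, channels = channels, loci = as_tibble(loci),
         window_bp = window_bp, bin_bp = as.integer(bin_bp)),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<signature_set> ", d[3], " loci x ", d[1], " channels x ", d[2],
      " bins (", x$window_bp, " bp window, ", x$bin_bp, " bp bins)\n", sep = "")
  invisible(x)
}

#' Flip signatures along the positional axis
#'
#' Reverses every channel row of the selected loci (channels are not
#' permuted) and toggles their orientation flag.  `flip(flip(x))` is the
#' identity.
#'
#' @param x A `signature_set` or a plain channel-by-position matrix.
#' @param ... Passed to methods.
#' @export
flip <- function(x, ...) UseMethod("flip")

#' @rdname flip
#' @param which Logical or integer index of loci to flip (default: all).
#' @export
flip.signature_set <- function(x, which = TRUE, ...) {
  idx <- seq_len(dim(x$data)[3])[which]
  L <- dim(x$data)[2]
  x$data[, , idx] <- x$data[, L:1, idx, drop = FALSE]
  x$loci$orientation[idx] <- ifelse(x$loci$orientation[idx] == "+", "-", "+")
  x
}

#' @rdname flip
#' @export
flip.matrix <- function(x, ...) {
  x[, rev(seq_len(ncol(x))), drop = FALSE]
}

#' Mean signature over loci
#'
#' Element-wise arithmetic mean of the per-locus matrices, in each locus's
#' current orientation.
#'
#' @param sigs A `signature_set`.
#' @return An M x L matrix with channel rownames.
#' @export
mean_signature <- function(sigs) {
  stopifnot(inherits(sigs, "signature_set"))
  rowMeans(sigs$data, dims = 2)
}

#' Subset a signature set by locus
#'
#' @param sigs A `signature_set`.
#' @param i Locus index (logical or integer).
#' @return A `signature_set` with the selected loci.
#' @export
subset_signatures <- function(sigs, i) {
  idx <- seq_len(dim(sigs$data)[3])[i]
  new_signature_set(sigs$data[, , idx, drop = FALSE], sigs$channels,
                    sigs$loci[idx, , drop = FALSE], sigs$window_bp, sigs$bin_bp)
}

#' Extract a single locus matrix
#'
#' @param sigs A `signature_set`.
#' @param i Locus index.
#' @return An M x L matrix.
#' @export
signature_matrix <- function(sigs, i) {
  m <- sigs$data[, , i, drop = FALSE]
  dim(m) <- dim(sigs$data)[1:2]
  rownames(m) <- sigs$channels$name
  m
}

# Per-channel mean squared deviation of every locus from a template matrix.
# Returns an M x N matrix.  A - mu recycles mu across the locus dimension.
channel_msd_to <- function(data, mu) {
  d2 <- (data - as.vector(mu))^2
  L <- dim(data)[2]
  colSums(aperm(d2, c(2, 1, 3))) / L
}

#' Multichannel distance between a signature and a template
#'
#' Per channel, the root-mean-square deviation between the two positional
#' vectors; channels are then combined either by an unweighted sum
#' (`method = "sum"`, the default) or by treating all channels as one
#' concatenated vector (`method = "concat"`).
#'
#' @param sig,template M x L numeric matrices with matching shape.
#' @param method `"sum"` or `"concat"`.
#' @return A single non-negative number.
#' @export
orientation_distance <- function(sig, template, method = c("sum", "concat")) {
  method <- match.arg(method)
  if (!all(dim(sig) == dim(template))) {
    abort("shape mismatch between signature and template",
          class = "chromsig_data_error")
  }
  msd <- rowMeans((sig - template)^2)
  switch(method,
         sum = sum(sqrt(msd)),
         concat = sqrt(mean(msd)))
}

#' @export
autoplot.signature_set <- function(object, ...) {
  plot_signature_matrix(mean_signature(object), object$channels,
                        object$bin_bp, object$window_bp) +
    ggplot2::labs(title = "Mean chromatin signature")
}

# Long tibble for a channel x position matrix, positions centred on 0.
signature_long <- function(mat, channels, bin_bp, window_bp) {
  L <- ncol(mat)
  pos <- (seq_len(L) - 0.5) * bin_bp - window_bp / 2
  tibble(
    channel = rep(rownames(mat) %||% channels$name, times = L),
    position_bp = rep(pos, each = nrow(mat)),
    value = as.vector(mat)
  ) |>
    left_join(channels, by = c(channel = "name"))
}

plot_signature_matrix <- function(mat, channels, bin_bp, window_bp) {
  df <- signature_long(mat, channels, bin_bp, window_bp)
  ggplot2::ggplot(df, ggplot2::aes(.data$position_bp, .data$value,
                                   colour = .data$timepoint)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$modification), scales = "free_y") +
    ggplot2::labs(x = "position relative to summit (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}
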