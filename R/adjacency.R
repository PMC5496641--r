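# Per-channel distance matrices, bandwidth calibration, Gaussian kernel and
# combined adjacency.  These are the building blocks of the spectral
# clustering; build_adjacency() streams channel by channel so that at most
# two N x N matrices are resident at once.

#' Per-channel pairwise RMSD distance matrices
#'
#' For each channel m, `dist[i, j]` is the root-mean-square deviation
#' between the positional vectors of loci i and j for that channel
#' (`sqrt(sum((x_i - x_j)^2) / L)`), in the loci's current orientations.
#'
#' @param sigs A `signature_set`.
#' @param channels Optional character vector restricting the channels.
#' @return A named list of symmetric, zero-diagonal N x N matrices.
#' @export
channel_distances <- function(sigs, channels = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  channels <- channels %||% sigs$channels$name
  out <- lapply(channels, function(ch) one_channel_distance(sigs, ch))
  setNames(out, channels)
}

one_channel_distance <- function(sigs, channel) {
  m <- match(channel, sigs$channels$name)
  if (is.na(m)) abort(paste0("unknown channel '", channel, "'"),
                      class = "chromsig_config_error")
  X <- t(sigs$data[m, , ]) # N x L
  L <- ncol(X)
  ss <- rowSums(X^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d <- sqrt(d2 / L)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Calibrate a channel's Gaussian-kernel bandwidth
#'
#' Sets the bandwidth to a low percentile (default the 10th) of the
#' channel's off-diagonal pairwise distance distribution (upper triangle,
#' linear-interpolation quantile).  With the Gaussian kernel this
#' guarantees that exactly `percentile`% of pairs get adjacency weights
#' above `exp(-1/2) = 0.606`, equalizing the influence of channels whose
#' raw signal magnitudes differ.
#'
#' @param dist Symmetric distance matrix (or a vector of off-diagonal
#'   distances).
#' @param percentile Percentile in (0, 100), default 10.
#' @return The bandwidth `sigma` (a positive number).
#' @export
calibrate_sigma <- function(dist, percentile = 10) {
  ut <- if (is.matrix(dist)) dist[upper.tri(dist)] else dist
  if (length(ut) < 1) abort("need at least one pair", class = "chromsig_data_error")
  sigma <- unname(quantile(ut, percentile / 100, type = 7, names = FALSE))
  if (!is.finite(sigma) || sigma <= 0) {
    abort("degenerate channel: calibrated sigma is not positive",
          class = "chromsig_data_error")
  }
  sigma
}

#' Gaussian kernel adjacency from a distance matrix
#'
#' `w[i, j] = exp(-dist[i, j]^2 / (2 sigma^2))`; the diagonal is 1 and a
#' pair at distance `sigma` gets weight `exp(-1/2)`.
#'
#' @param dist Distance matrix.
#' @param sigma Positive bandwidth.
#' @return A matrix of weights in (0, 1].
#' @export
gaussian_adjacency <- function(dist, sigma) {
  stopifnot(sigma > 0)
  exp(-dist^2 / (2 * sigma^2))
}

#' Sum per-channel adjacencies into one combined adjacency
#'
#' @param w_list List of equally sized weight matrices.
#' @return Their element-wise sum; the diagonal equals the channel count.
#' @export
combine_adjacency <- function(w_list) {
  stopifnot(length(w_list) >= 1)
  dims <- vapply(w_list, dim, integer(2))
  if (any(dims != dims[, 1])) {
    abort("adjacency matrices differ in shape", class = "chromsig_data_error")
  }
  Reduce(`+`, w_list)
}

#' Build the combined adjacency model for a signature set
#'
#' Streams one channel at a time (distance matrix, calibrated bandwidth,
#' kernel weights) and accumulates the combined adjacency, keeping memory
#' bounded at about two N x N matrices.
#'
#' @param sigs A `signature_set` with oriented loci.
#' @param percentile Bandwidth calibration percentile (default 10).
#' @param channels Optional channel subset.
#' @return An `adjacency_model`: combined matrix `W`, named `sigma` vector,
#'   `percentile`, `channels` and the locus count `n`.
#' @export
build_adjacency <- function(sigs, percentile = 10, channels = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  channels <- channels %||% sigs$channels$name
  W <- NULL
  sigma <- setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    d <- one_channel_distance(sigs, ch)
    sigma[[ch]] <- calibrate_sigma(d, percentile)
    w <- gaussian_adjacency(d, sigma[[ch]])
    W <- if (is.null(W)) w else W + w
  }
  structure(
    list(W = W, sigma = sigma, percentile = percentile,
         channels = channels, n = nrow(W)),
    class = "adjacency_model"
  )
}

#' @export
print.adjacency_model <- function(x, ...) {
  cat("<adjacency_model> ", x$n, " loci, ", length(x$channels),
      " channels, percentile ", x$percentile, "\n", sep = "")
  cat("  sigma: ", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}
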