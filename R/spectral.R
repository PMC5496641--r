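# Spectral clustering of oriented signatures: symmetric normalized
# Laplacian embedding (Ng-Jordan-Weiss), eigengap model selection, k-means.

# Eigendecomposition of L_sym = I - D^{-1/2} W D^{-1/2}; returns eigenvalues
# ascending with matching eigenvectors.
lsym_eigen <- function(W) {
  d <- rowSums(W)
  if (any(d <= 0)) {
    abort("zero-degree node in adjacency; graph must be connected",
          class = "chromsig_data_error")
  }
  isd <- 1 / sqrt(d)
  S <- W * tcrossprod(isd) # D^{-1/2} W D^{-1/2}
  Lsym <- diag(nrow(W)) - S
  e <- eigen(Lsym, symmetric = TRUE)
  n <- nrow(W)
  list(values = rev(e$values), vectors = e$vectors[, n:1, drop = FALSE])
}

#' Spectral embedding from a combined adjacency matrix
#'
#' Forms the symmetric normalized graph Laplacian
#' `L_sym = D^{-1/2} (D - W) D^{-1/2}`, takes the eigenvectors of its k
#' smallest eigenvalues, and rescales each row of the N x k eigenvector
#' matrix to unit L2 norm (projection to the k-sphere).
#'
#' @param W Symmetric adjacency matrix with positive degrees.
#' @param k Embedding dimension.
#' @return N x k matrix with unit-norm rows; the ascending eigenvalues are
#'   attached as `attr(, "eigenvalues")`.
#' @export
spectral_embed <- function(W, k) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), k >= 1, k <= nrow(W))
  e <- lsym_eigen(W)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm < .Machine$double.eps] <- 1
  U <- U / nrm
  attr(U, "eigenvalues") <- e$values
  U
}

#' Choose the number of clusters by the eigengap heuristic
#'
#' Scans the ascending Laplacian eigenvalues and picks the smallest
#' `k <= k_max` whose successive gap `lambda[k+1] - lambda[k]` exceeds
#' `gap_factor` times the mean successive gap over the first `k_max + 1`
#' eigenvalues; if no gap qualifies, falls back to the largest gap.
#'
#' @param eigenvalues Ascending eigenvalues (length at least `k_max + 1`).
#' @param k_max Largest k considered (default 10).
#' @param gap_factor Threshold multiplier on the mean gap (default 3).
#' @return The chosen k.
#' @export
choose_k_eigengap <- function(eigenvalues, k_max = 10, gap_factor = 3) {
  stopifnot(length(eigenvalues) >= k_max + 1)
  gaps <- diff(eigenvalues[seq_len(k_max + 1)])
  thr <- gap_factor * mean(gaps)
  k <- which(gaps > thr)[1]
  if (is.na(k)) k <- which.max(gaps)
  as.integer(k)
}

#' k-means on the spectral embedding
#'
#' Standard k-means with multiple random restarts, keeping the solution
#' with the smallest within-cluster sum of squares; deterministic given the
#' seed.  A failed restart (degenerate initial centres) is re-seeded.
#'
#' @param embedding N x k matrix of row-normalized eigenvectors.
#' @param k Number of clusters (>= 2).
#' @param n_restarts Random restarts (default 50).
#' @param seed Optional integer seed.
#' @return Integer cluster labels in `1..k`.
#' @export
cluster_embedding <- function(embedding, k, n_restarts = 50, seed = NULL) {
  if (k < 2) abort("k must be >= 2", class = "chromsig_config_error")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(10)) {
    fit <- tryCatch(
      withCallingHandlers(
        kmeans(embedding, centers = k, nstart = n_restarts, iter.max = 100),
        warning = function(w) {
          # Hartigan-Wong's Quick-TRANSfer can stall on near-duplicate
          # embedding rows; MacQueen is the standard fallback
          if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && !fit$ifault %in% c(2L, 4L)) {
      return(as.integer(fit$cluster))
    }
    if (!is.null(fit)) {
      fit2 <- tryCatch(
        kmeans(embedding, centers = k, nstart = n_restarts, iter.max = 300,
               algorithm = "MacQueen"),
        error = function(e) NULL
      )
      if (!is.null(fit2)) return(as.integer(fit2$cluster))
    }
  }
  abort("k-means failed after 10 re-seeded attempts",
        class = "chromsig_data_error")
}

#' Per-cluster mean signatures
#'
#' @param sigs A `signature_set` in its oriented frame.
#' @param labels Integer cluster labels covering all loci.
#' @return A list (one M x L matrix per cluster, named `"1"`, `"2"`, ...).
#' @export
cluster_means <- function(sigs, labels) {
  stopifnot(inherits(sigs, "signature_set"),
            length(labels) == dim(sigs$data)[3])
  lv <- sort(unique(labels))
  out <- lapply(lv, function(cl) {
    m <- rowMeans(sigs$data[, , labels == cl, drop = FALSE], dims = 2)
    rownames(m) <- sigs$channels$name
    m
  })
  setNames(out, as.character(lv))
}

#' Cluster oriented chromatin signatures
#'
#' Full spectral pipeline: per-channel RMSD distances, bandwidths
#' calibrated at `percentile`, Gaussian-kernel weights summed over channels
#' into one adjacency, symmetric normalized Laplacian embedding, eigengap
#' selection of k (unless `k` is given), and k-means on the row-normalized
#' embedding.  Cluster labels are relabelled in decreasing order of total
#' mean signal so that label 1 is the strongest signature and the last
#' label is typically the featureless class.
#'
#' @param sigs A `signature_set`, normally the `$signatures` of a
#'   [reorient()] fit.
#' @param percentile Bandwidth calibration percentile (default 10).
#' @param k Number of clusters; `NULL` (default) selects it by eigengap.
#' @param k_max,gap_factor Eigengap parameters (see [choose_k_eigengap()]).
#' @param n_restarts k-means restarts (default 50).
#' @param seed Integer seed for k-means.
#' @param channels Optional channel subset used for clustering.
#' @return A `cluster_fit` with `labels`, `k`, `eigenvalues`, `embedding`,
#'   `sigma`, `cluster_sizes`, per-cluster mean `cluster_signatures`, and
#'   the oriented input `signatures`.
#' @export
cluster_signatures <- function(sigs, percentile = 10, k = NULL, k_max = 10,
                               gap_factor = 3, n_restarts = 50, seed = NULL,
                               channels = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  adj <- build_adjacency(sigs, percentile = percentile, channels = channels)
  e <- lsym_eigen(adj$W)
  k_max_eff <- min(k_max, adj$n - 1L)
  if (is.null(k)) k <- choose_k_eigengap(e$values, k_max_eff, gap_factor)
  k <- max(2L, as.integer(k))
  U <- e$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm < .Machine$double.eps] <- 1
  U <- U / nrm
  labels <- cluster_embedding(U, k, n_restarts = n_restarts, seed = seed)
  # stable labelling: order clusters by decreasing total mean signal
  means <- cluster_means(sigs, labels)
  strength <- vapply(means, mean, numeric(1))
  remap <- match(seq_along(strength), order(strength, decreasing = TRUE))
  labels <- remap[labels]
  means <- cluster_means(sigs, labels)
  structure(
    list(
      labels = labels,
      k = k,
      eigenvalues = e$values[seq_len(min(adj$n, k_max_eff + 1L))],
      embedding = U,
      sigma = adj$sigma,
      percentile = percentile,
      cluster_sizes = as.integer(table(labels)),
      cluster_signatures = means,
      signatures = sigs,
      seed = seed
    ),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat("<cluster_fit> ", length(x$labels), " loci in ", x$k,
      " clusters (sizes: ", paste(x$cluster_sizes, collapse = ", "), ")\n",
      sep = "")
  cat("  leading eigenvalues: ",
      paste(sprintf("%.4f", head(x$eigenvalues, x$k + 1)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_signatures Per-locus tibble: locus coordinates,
#'   orientation and cluster label.
#' @param x,object A `cluster_fit`.
#' @param ... Unused.
#' @export
tidy.cluster_fit <- function(x, ...) {
  x$signatures$loci |>
    mutate(cluster = x$labels)
}

#' @describeIn cluster_signatures One-row summary: locus count, k, the
#'   eigengap at k, and the bandwidth percentile.
#' @export
glance.cluster_fit <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(
    n_loci = length(x$labels),
    k = x$k,
    eigengap = if (length(ev) > x$k) ev[x$k + 1] - ev[x$k] else NA_real_,
    percentile = x$percentile,
    min_cluster_size = min(x$cluster_sizes)
  )
}

#' @export
autoplot.cluster_fit <- function(object, ...) {
  sigs <- object$signatures
  df <- purrr::imap(object$cluster_signatures, function(m, cl) {
    signature_long(m, sigs$channels, sigs$bin_bp, sigs$window_bp) |>
      mutate(cluster = paste0("cluster ", cl))
  }) |>
    bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$position_bp, .data$value,
                                   colour = .data$timepoint)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(.data$modification),
                        ggplot2::vars(.data$cluster), scales = "free_y") +
    ggplot2::labs(x = "position relative to summit (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}
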