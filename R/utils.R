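# Internal numeric helpers shared across modules.

# Sliding dot product sum(x[s + j - 1] * t[j]) for every valid start s,
# computed by FFT with padding to a 5-smooth length (plain convolve() can hit
# catastrophically slow mixed-radix lengths on megabase tracks).
sliding_cross <- function(x, t) {
  nb <- length(x)
  L <- length(t)
  stopifnot(nb >= L)
  nfft <- stats::nextn(nb + L, c(2L, 3L, 5L))
  xp <- c(x, numeric(nfft - nb))
  tp <- c(t, numeric(nfft - L))
  cc <- Re(stats::fft(stats::fft(xp) * Conj(stats::fft(tp)), inverse = TRUE)) / nfft
  cc[seq_len(nb - L + 1L)]
}

# Running maximum over a centred window of `radius` positions each side,
# -Inf-padded so edge positions compare only against existing neighbours.
running_max <- function(x, radius) {
  if (radius <= 0L) return(x)
  padded <- c(rep(-Inf, radius), x, rep(-Inf, radius))
  zoo::rollmax(padded, k = 2L * radius + 1L, align = "center")
}

# Fraction of positions where two hard clusterings disagree, minimized over
# label permutations (exhaustive for small k, greedy by confusion-matrix
# weight otherwise).  Inputs are integer-like label vectors.
label_disagreement <- function(ref, other) {
  stopifnot(length(ref) == length(other))
  ref <- as.integer(factor(ref))
  other <- as.integer(factor(other))
  kr <- max(ref)
  ko <- max(other)
  conf <- table(factor(other, levels = seq_len(ko)),
                factor(ref, levels = seq_len(kr)))
  if (ko <= 7L) {
    perms <- all_permutations(ko)
    best <- 0L
    for (p in perms) {
      hit <- sum(vapply(seq_len(ko), function(i) {
        if (p[i] <= kr) conf[i, p[i]] else 0L
      }, numeric(1)))
      best <- max(best, hit)
    }
  } else {
    # greedy assignment on the confusion matrix
    cm <- as.matrix(conf)
    best <- 0L
    while (any(cm > -1) && nrow(cm) > 0 && ncol(cm) > 0) {
      idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      best <- best + cm[idx[1], idx[2]]
      cm <- cm[-idx[1], -idx[2], drop = FALSE]
      if (nrow(cm) == 0 || ncol(cm) == 0) break
    }
  }
  1 - best / length(ref)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Orientation disagreement up to a global sign flip.
orientation_disagreement <- function(ref, other) {
  stopifnot(length(ref) == length(other))
  d <- mean(ref != other)
  min(d, 1 - d)
}

# Per-locus assignment change between two runs: an orientation change
# (after aligning the unidentifiable global sign) or a cluster change
# (after optimal label matching).  Returns the per-locus indicator and the
# fraction changed.
assignment_change <- function(ref_orient, ref_labels, orient, labels) {
  if (mean(ref_orient != orient) > 0.5) {
    orient <- ifelse(orient == "+", "-", "+")
  }
  or_changed <- orient != ref_orient

  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k <= 7L) {
    best <- NULL
    best_score <- -1
    for (p in all_permutations(k)) {
      mapped <- p[labels]
      score <- mean(mapped == ref_labels)
      if (score > best_score) {
        best_score <- score
        best <- mapped
      }
    }
    cl_changed <- best != ref_labels
  } else {
    cl_changed <- rep(TRUE, length(labels))
  }
  changed <- or_changed | cl_changed
  list(per_locus = changed, fraction = mean(changed),
       orientation_fraction = mean(or_changed),
       cluster_fraction = mean(cl_changed))
}
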