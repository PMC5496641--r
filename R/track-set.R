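#' Construct a binned multichannel track set
#'
#' A `track_set` holds one binned, genome-wide, non-negative signal vector
#' per channel per chromosome.  A channel is one signal track, typically a
#' histone modification at one time point.  All channels share the bin size
#' and the chromosome set; bin values are arithmetic means of the underlying
#' base-pair signal, so changing the bin size rescales resolution, not
#' magnitude.
#'
#' @param signal Named list (one element per channel) of named lists (one
#'   numeric vector per chromosome) of binned values.
#' @param channels Data frame with columns `name`, `modification`,
#'   `timepoint` describing each channel, or a character vector of names.
#' @param bin_bp Bin width in base pairs.
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @return An object of class `track_set`.
#' @seealso [read_tracks()], [rebin_tracks()], [extract_signatures()]
#' @export
track_set <- function(signal, channels, bin_bp, chrom_sizes) {
  channels <- as_channel_table(channels)
  if (anyDuplicated(channels$name)) {
    abort("channel names must be unique", class = "chromsig_data_error")
  }
  if (!setequal(names(signal), channels$name)) {
    abort("`signal` names must match `channels$name`",
          class = "chromsig_data_error")
  }
  signal <- signal[channels$name]
  chroms <- names(chrom_sizes)
  n_bins <- ceiling(chrom_sizes / bin_bp)
  for (ch in channels$name) {
    if (!setequal(names(signal[[ch]]), chroms)) {
      bad <- c(setdiff(names(signal[[ch]]), chroms),
               setdiff(chroms, names(signal[[ch]])))
      abort(paste0("channel '", ch, "' chromosome mismatch: ",
                   paste(unique(bad), collapse = ", ")),
            class = "chromsig_data_error")
    }
    signal[[ch]] <- signal[[ch]][chroms]
    for (cr in chroms) {
      v <- signal[[ch]][[cr]]
      if (length(v) != n_bins[[cr]]) {
        abort(paste0("channel '", ch, "', chromosome '", cr, "': expected ",
                     n_bins[[cr]], " bins, got ", length(v)),
              class = "chromsig_data_error")
      }
      if (anyNA(v) || any(!is.finite(v))) {
        abort(paste0("non-finite signal in channel '", ch, "'"),
              class = "chromsig_data_error")
      }
      if (any(v < 0)) {
        abort(paste0("negative signal in channel '", ch, "'"),
              class = "chromsig_data_error")
      }
    }
  }
  structure(
    list(signal = signal, channels = channels, bin_bp = as.integer(bin_bp),
         chrom_sizes = chrom_sizes),
    class = "track_set"
  )
}

as_channel_table <- function(channels) {
  if (is.character(channels)) {
    parts <- strsplit(channels, "_", fixed = TRUE)
    channels <- tibble(
      name = channels,
      modification = vapply(parts, function(p) p[[1]], character(1)),
      timepoint = vapply(parts, function(p) {
        if (length(p) > 1) paste(p[-1], collapse = "_") else NA_character_
      }, character(1))
    )
  }
  channels <- as_tibble(channels)
  stopifnot(all(c("name", "modification", "timepoint") %in% names(channels)))
  channels
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set> ", nrow(x$channels), " channels, ",
      length(x$chrom_sizes), " chromosomes, bin ", x$bin_bp, " bp\n", sep = "")
  cat("  channels: ", paste(x$channels$name, collapse = ", "), "\n", sep = "")
  cat("  genome:   ", format(sum(as.numeric(x$chrom_sizes)), big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Read bedGraph signal tracks into a binned track set
#'
#' Each file is a 4-column bedGraph (0-based half-open intervals with a
#' value).  Signal is binned by the arithmetic mean of the per-base signal
#' within each bin; bases not covered by any interval contribute 0.
#'
#' @param paths Named character vector of file paths; names are channel
#'   names (used as `modification_timepoint` when `channels` is `NULL`).
#' @param channels Optional channel description data frame
#'   (`name`, `modification`, `timepoint`).
#' @param bin_bp Bin width in base pairs (default 10).
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   `NULL`, the largest end coordinate seen per chromosome across all
#'   channels is used.
#' @return A [track_set].
#' @export
read_tracks <- function(paths, channels = NULL, bin_bp = 10, chrom_sizes = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be a named vector (names = channel names)",
          class = "chromsig_config_error")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("track file(s) not found: ", paste(missing, collapse = ", ")),
          class = "chromsig_config_error")
  }
  channels <- as_channel_table(channels %||% names(paths))
  grs <- lapply(paths, rtracklayer::import, format = "bedGraph")
  for (ch in names(grs)) {
    if (any(GenomicRanges::score(grs[[ch]]) < 0)) {
      abort(paste0("negative values in track '", ch, "'"),
            class = "chromsig_data_error")
    }
  }
  chrom_seen <- lapply(grs, function(g) as.character(unique(GenomicRanges::seqnames(g))))
  all_chroms <- sort(unique(unlist(chrom_seen)))
  bad <- purrr::imap(chrom_seen, function(seen, ch) setdiff(all_chroms, seen))
  bad <- bad[lengths(bad) > 0]
  if (is.null(chrom_sizes) && length(bad)) {
    abort(paste0(
      "chromosome naming mismatch between channels; missing: ",
      paste(vapply(names(bad), function(ch) {
        paste0(ch, " lacks ", paste(bad[[ch]], collapse = "/"))
      }, character(1)), collapse = "; ")
    ), class = "chromsig_data_error")
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(all_chroms, function(cr) {
      max(vapply(grs, function(g) {
        hit <- GenomicRanges::seqnames(g) == cr
        if (!any(hit)) 0L else max(GenomicRanges::end(g[hit]))
      }, integer(1)))
    }, integer(1))
  }
  signal <- lapply(grs, bin_granges, chrom_sizes = chrom_sizes, bin_bp = bin_bp)
  track_set(signal, channels, bin_bp, chrom_sizes)
}

# Per-base coverage (Rle) -> per-bin means; uncovered bases are 0, and the
# final partial bin is zero-padded so every bin divides by bin_bp (mass
# conservation: sum(bins) * bin_bp == integral of the track).
bin_granges <- function(gr, chrom_sizes, bin_bp) {
  cov <- GenomicRanges::coverage(gr, weight = "score")
  out <- list()
  for (cr in names(chrom_sizes)) {
    n_bins <- ceiling(chrom_sizes[[cr]] / bin_bp)
    len <- n_bins * bin_bp
    r <- if (cr %in% names(cov)) cov[[cr]] else S4Vectors::Rle(0, len)
    if (length(r) < len) {
      r <- c(r, S4Vectors::Rle(0, len - length(r)))
    } else if (length(r) > len) {
      r <- r[seq_len(len)]
    }
    v <- IRanges::Views(r, start = seq(1L, len, by = bin_bp), width = bin_bp)
    out[[cr]] <- as.numeric(IRanges::viewMeans(v))
  }
  out
}

#' Re-bin a track set to a coarser resolution
#'
#' Groups of consecutive bins are averaged, so re-binning 10 bp data to
#' 20/50/100 bp equals binning the original base-pair signal directly at the
#' coarser size (for aligned bins).
#'
#' @param tracks A [track_set].
#' @param bin_bp New bin width; must be a multiple of the current one.
#' @return A [track_set] at the coarser resolution.
#' @export
rebin_tracks <- function(tracks, bin_bp) {
  stopifnot(inherits(tracks, "track_set"))
  f <- bin_bp / tracks$bin_bp
  if (f != as.integer(f) || f < 1) {
    abort("`bin_bp` must be a positive multiple of the current bin size",
          class = "chromsig_config_error")
  }
  f <- as.integer(f)
  if (f == 1L) return(tracks)
  signal <- lapply(tracks$signal, function(per_chrom) {
    lapply(per_chrom, function(v) {
      n_new <- ceiling(length(v) / f)
      pad <- n_new * f - length(v)
      if (pad > 0) v <- c(v, numeric(pad))
      colMeans(matrix(v, nrow = f))
    })
  })
  track_set(signal, tracks$channels, bin_bp, tracks$chrom_sizes)
}

#' Write a track set to bedGraph files
#'
#' One bedGraph per channel, with consecutive equal-valued bins merged into
#' runs.
#'
#' @param tracks A [track_set].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_tracks <- function(tracks, dir) {
  stopifnot(inherits(tracks, "track_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bin <- tracks$bin_bp
  paths <- setNames(
    file.path(dir, paste0(tracks$channels$name, ".bedGraph")),
    tracks$channels$name
  )
  for (ch in tracks$channels$name) {
    rows <- purrr::imap(tracks$signal[[ch]], function(v, cr) {
      r <- rle(v)
      ends <- cumsum(r$lengths) * bin
      starts <- ends - r$lengths * bin
      keep <- r$values != 0
      tibble(chrom = cr, start = starts[keep], end = pmin(ends[keep],
             tracks$chrom_sizes[[cr]]), value = r$values[keep])
    })
    readr::write_tsv(bind_rows(rows), paths[[ch]], col_names = FALSE,
                     progress = FALSE)
  }
  invisible(paths)
}

#' Write loci or scan hits as a BED6 file
#'
#' Output is 0-based half-open BED with the strand column carrying the
#' locus orientation and the score column carrying the score linearly
#' rescaled to `[0, 1000]` (browser convention).
#'
#' @param x A data frame with either `start`/`end` columns (scan hits) or a
#'   `summit` column plus `window_bp`; optional `orientation` and `score`.
#' @param path Output file path.
#' @param window_bp Window width used to expand `summit` rows.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, window_bp = NULL) {
  x <- as_tibble(x)
  if (!nrow(x)) {
    file.create(path)
    return(invisible(path))
  }
  if (!all(c("start", "end") %in% names(x))) {
    if (is.null(window_bp) || !"summit" %in% names(x)) {
      abort("need `start`/`end` columns, or a `summit` column plus `window_bp`",
            class = "chromsig_data_error")
    }
    x$start <- pmax(x$summit - window_bp / 2, 0)
    x$end <- x$summit + window_bp / 2
  }
  col_or <- function(col, default) {
    if (col %in% names(x)) x[[col]] else default
  }
  score <- col_or("score", rep(0, nrow(x)))
  score[is.na(score)] <- 0
  rng <- range(score)
  bed_score <- if (diff(rng) > 0) {
    round(1000 * (score - rng[1]) / diff(rng))
  } else {
    rep(0L, nrow(x))
  }
  bed <- tibble(
    chrom = x$chrom,
    start = as.integer(x$start),
    end = as.integer(x$end),
    name = col_or("name", paste0("locus_", seq_len(nrow(x)))),
    score = bed_score,
    strand = col_or("orientation", rep("+", nrow(x)))
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
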