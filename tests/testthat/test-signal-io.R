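# Reading, binning, window extraction, flipping and BED output.

test_that("bedGraph binning averages coverage and fills gaps with zero", {
  p1 <- write_bedgraph(data.frame("chrA", 0L, 20L, 4))
  tr <- read_tracks(c(k4 = p1), bin_bp = 10, chrom_sizes = c(chrA = 40L))
  expect_equal(tr$signal$k4$chrA, c(4, 4, 0, 0))

  p2 <- write_bedgraph(data.frame("chrA", c(0L, 10L), c(10L, 20L), c(2, 6)))
  tr2 <- read_tracks(c(k4 = p2), bin_bp = 20, chrom_sizes = c(chrA = 40L))
  expect_equal(tr2$signal$k4$chrA, c(4, 0))

  # intervals that straddle a bin boundary are averaged per base
  p3 <- write_bedgraph(data.frame("chrA", c(0L, 5L), c(5L, 20L), c(2, 10)))
  tr3 <- read_tracks(c(k4 = p3), bin_bp = 10, chrom_sizes = c(chrA = 20L))
  expect_equal(tr3$signal$k4$chrA, c((5 * 2 + 5 * 10) / 10, 10))
})

test_that("binning conserves mass for arbitrary synthetic tracks", {
  set.seed(7)
  iv <- data.frame(chrom = "chrA",
                   start = seq(0, 950, by = 50),
                   end = seq(50, 1000, by = 50),
                   value = round(runif(20, 0, 5), 3))
  path <- write_bedgraph(iv)
  integral <- sum((iv$end - iv$start) * iv$value)
  for (bb in c(10, 25, 100)) {
    tr <- read_tracks(c(x = path), bin_bp = bb, chrom_sizes = c(chrA = 1000L))
    expect_equal(sum(tr$signal$x$chrA) * bb, integral, tolerance = 1e-10)
  }
})

test_that("read_tracks rejects negative values and mismatched chromosomes", {
  bad <- write_bedgraph(data.frame("chrA", 0L, 10L, -1))
  expect_error(read_tracks(c(x = bad), bin_bp = 10), "negative",
               class = "chromsig_data_error")

  a <- write_bedgraph(data.frame("chrA", 0L, 10L, 1))
  b <- write_bedgraph(data.frame("chrB", 0L, 10L, 1))
  expect_error(read_tracks(c(x = a, y = b), bin_bp = 10),
               "chromosome naming mismatch.*chrB|chrA",
               class = "chromsig_data_error")
})

test_that("re-binning by averaging equals direct binning at the coarser size", {
  set.seed(11)
  iv <- data.frame(chrom = "chrA",
                   start = seq(0, 1980, by = 20),
                   end = seq(20, 2000, by = 20),
                   value = round(runif(100, 0, 8), 3))
  path <- write_bedgraph(iv)
  fine <- read_tracks(c(x = path), bin_bp = 10, chrom_sizes = c(chrA = 2000L))
  for (bb in c(20, 50, 100)) {
    direct <- read_tracks(c(x = path), bin_bp = bb,
                          chrom_sizes = c(chrA = 2000L))
    expect_equal(rebin_tracks(fine, bb)$signal$x$chrA,
                 direct$signal$x$chrA, tolerance = 1e-12)
  }
})

test_that("extraction yields the reference geometry: 10 Kb / 10 bp / M x 1000", {
  mods <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3", "H3K18ac")
  channels <- paste(rep(mods, 2), rep(c("c13", "c14"), each = 5), sep = "_")
  tr <- make_flat_tracks(channels, n_bins = 3000, value = 2.5)
  sigs <- extract_signatures(tr, data.frame(chrom = "chrT", summit = 15000),
                             window_bp = 10000)
  expect_equal(dim(sigs$data), c(10, 1000, 1))
  # constant track -> every entry equals the constant
  expect_true(all(sigs$data == 2.5))
})

test_that("windows overhanging a chromosome end are skipped with a warning", {
  tr <- make_flat_tracks(c("a_c14"), n_bins = 2000)
  loci <- data.frame(chrom = "chrT", summit = c(3000, 10000, 19000))
  expect_warning(sigs <- extract_signatures(tr, loci, window_bp = 10000),
                 "overhang")
  expect_equal(dim(sigs$data)[3], 1)
  expect_equal(sigs$loci$summit, 10000)
})

test_that("flip is an involution that reverses positions, not channels", {
  sim <- sim_three_class(n_per = 4, noise_sd = 0.05, seed = 2)
  sigs <- extract_signatures(sim$tracks, sim$peaks)
  flipped <- flip(sigs)
  expect_equal(flipped$data[, , 1], sigs$data[, ncol(sigs$data[, , 1]):1, 1])
  expect_equal(flip(flipped)$data, sigs$data)
  expect_equal(flip(flipped)$loci$orientation, sigs$loci$orientation)
  # matrix method: symmetric row unchanged, plain row reversed
  m <- rbind(sym = c(1, 2, 2, 1), asym = c(1, 2, 3, 4))
  expect_equal(flip(m)["sym", ], c(1, 2, 2, 1), ignore_attr = TRUE)
  expect_equal(flip(m)["asym", ], c(4, 3, 2, 1), ignore_attr = TRUE)
})

test_that("flipping a signature equals extracting from a mirrored genome", {
  sim <- sim_three_class(n_per = 3, noise_sd = 0.1, seed = 5)
  tr <- sim$tracks
  mirrored <- tr
  for (ch in names(tr$signal)) {
    mirrored$signal[[ch]] <- lapply(tr$signal[[ch]], rev)
  }
  loci <- sim$peaks[1, ]
  mir_loci <- data.frame(chrom = loci$chrom,
                         summit = tr$chrom_sizes[[loci$chrom]] - loci$summit)
  a <- flip(extract_signatures(tr, loci))
  b <- extract_signatures(mirrored, mir_loci)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("write_bed emits 0-based half-open BED6 with oriented strands", {
  loci <- tibble::tibble(chrom = "chr2L", summit = 5000,
                         orientation = "-", score = 3)
  path <- tempfile(fileext = ".bed")
  write_bed(loci, path, window_bp = 10000)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(unlist(bed[1, c(1, 2, 3, 6)], use.names = FALSE),
               c("chr2L", "0", "10000", "-"))

  # scores rescaled to [0, 1000]
  hits <- tibble::tibble(chrom = "chrA", start = c(0, 100), end = c(50, 150),
                         orientation = c("+", "-"), score = c(1, 5))
  write_bed(hits, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed[[5]], c(0, 1000))

  # empty input -> empty file, no error
  write_bed(tibble::tibble(), path)
  expect_equal(file.size(path), 0)
})

test_that("track sets round-trip through bedGraph files", {
  sim <- sim_three_class(n_per = 3, noise_sd = 0.1, seed = 9)
  dir <- tempfile()
  paths <- write_tracks(sim$tracks, dir)
  back <- read_tracks(paths, channels = sim$tracks$channels, bin_bp = 10,
                      chrom_sizes = sim$tracks$chrom_sizes)
  ch <- names(paths)[1]
  expect_equal(back$signal[[ch]], sim$tracks$signal[[ch]], tolerance = 1e-5)
})
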