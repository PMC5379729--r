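test_that("window arithmetic follows the w1..w5 decomposition", {
  sizes <- c(chr1 = 100000L)
  w <- make_windows(genome_regions("chr1", 1000, 2500), window_scheme(),
                    sizes)
  expect_equal(w$start, c(700L, 1000L, 1300L, 2200L, 2500L))
  expect_equal(w$end, c(1000L, 1300L, 2200L, 2500L, 2800L))
  expect_false(any(w$clipped))
  # upstream flank clipped at the chromosome start
  w2 <- make_windows(genome_regions("chr1", 100, 1600), window_scheme(),
                     sizes)
  expect_equal(w2$start[1], 0L)
  expect_equal(w2$end[1], 100L)
  expect_true(w2$clipped[1])
  # middle empty when the region is not longer than 2*edge
  w3 <- make_windows(genome_regions("chr1", 5000, 5600), window_scheme(),
                     sizes)
  expect_true(w3$empty[3])
})

test_that("w2..w4 tile each region exactly for any region over 600 bp", {
  sizes <- c(chr1 = 50000L)
  set.seed(17)
  for (rep in 1:100) {
    len <- sample(601:5000, 1)
    s <- sample.int(40000, 1)
    w <- make_windows(genome_regions("chr1", s, s + len), window_scheme(),
                      sizes)
    body <- w[2:4, ]
    expect_equal(body$start, c(s, s + 300L, s + len - 300L))
    expect_equal(body$end[1:2], body$start[2:3])     # contiguous, no overlap
    expect_equal(body$end[3], s + len)
    expect_equal(sum(body$end - body$start), len)
  }
})

test_that("GC profile reads known sequence composition", {
  # one chromosome built from blocks of known GC: region [300, 900),
  # flank/edge 300 -> each window is homogeneous
  seq <- paste0(strrep("A", 300),   # w1: GC 0
                strrep("G", 300),   # w2: GC 1
                strrep("AC", 150),  # w3: GC 0.5
                strrep("T", 300),   # w4: GC 0
                strrep("C", 300),   # w5: GC 1
                strrep("N", 100))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  reg <- genome_regions("chr1", 300, 1200)
  p <- gc_profile(reg, genome, window_scheme(flank = 300, edge = 300,
                                             middle_bins = 10))
  val <- tapply(p$bins$value, p$bins$segment, mean)
  expect_equal(as.numeric(val[c("w1", "w2", "w3", "w4", "w5")]),
               c(0, 1, 0.5, 0, 1))
  # all-N windows are recorded as missing, not zero
  regN <- genome_regions("chr1", 1500, 1590)
  pN <- suppressWarnings(gc_profile(regN, genome,
                                    window_scheme(flank = 10, edge = 10,
                                                  middle_bins = 5)))
  w2_bins <- pN$bins[pN$bins$segment == "w2", ]
  expect_true(all(is.na(w2_bins$value)))
  expect_true(all(w2_bins$n == 0))
})

test_that("coverage profiles localize annotation to the right window", {
  sizes <- c(chr1 = 10000L)
  reg <- genome_regions("chr1", 1000, 2500)
  # repeat covering exactly w2 = [1000, 1300)
  track <- annotation_track("chr1", 1000, 1300, "SINE", track = "repeat")
  p <- coverage_profile(reg, track, "SINE", sizes)
  by_seg <- tapply(p$bins$value, p$bins$segment, mean)
  expect_equal(as.numeric(by_seg["w2"]), 1)
  expect_equal(as.numeric(by_seg[c("w1", "w3", "w4", "w5")]), rep(0, 4))
  expect_error(coverage_profile(reg, track, "LINE", sizes), "LINE")
  # a label in the declared vocabulary but with no intervals: all zero
  p0 <- coverage_profile(reg, track, "LINE", sizes,
                         known_labels = c("SINE", "LINE"))
  expect_true(all(p0$bins$value == 0))
  # histone signal mode: mean value over bases, 0 where uncovered
  his <- annotation_track("chr1", c(1000, 1000), c(1300, 1300),
                          "H3K4Me1", value = c(2, 4), track = "histone")
  ph <- coverage_profile(reg, his, "H3K4Me1", sizes, signal = TRUE)
  seg <- tapply(ph$bins$value, ph$bins$segment, mean)
  expect_equal(as.numeric(seg["w2"]), 3)   # stacked intervals average
  expect_equal(as.numeric(seg["w3"]), 0)
})

test_that("coverage profile equals a per-base oracle on random fixtures", {
  set.seed(23)
  sizes <- c(chr1 = 8000L)
  for (rep in 1:25) {
    n <- sample(4:15, 1)
    st <- sample.int(7500, n)
    track <- annotation_track("chr1", st, st + sample.int(400, n), "SINE",
                              track = "repeat")
    m <- sample(2:5, 1)
    rs <- sample(800:5000, m)
    regions <- genome_regions("chr1", rs, rs + sample(700:2000, m))
    sch <- window_scheme(flank = 100, edge = 100, middle_bins = 7)
    got <- coverage_profile(regions, track, "SINE", sizes, sch)
    # oracle: explicit per-base 0/1 vector + naive per-region binning
    cov <- numeric(sizes[["chr1"]])
    for (i in seq_len(n)) {
      idx <- (track$start[i] + 1):min(8000, track$end[i])
      cov[idx] <- 1
    }
    per_region <- sapply(seq_len(m), function(i) {
      s <- regions$start[i]; e <- regions$end[i]
      grab <- function(a, b) {   # 0-based half-open, clipped
        a2 <- max(a, 0); b2 <- min(b, 8000)
        v <- if (b2 > a2) cov[(a2 + 1):b2] else numeric(0)
        c(rep(NA, a2 - a), v, rep(NA, b - b2))
      }
      binmean <- function(v, nb) {
        L <- length(v); br <- seq(0, L, length.out = nb + 1)
        vapply(seq_len(nb), function(b_) {
          w <- pmin(br[b_ + 1], seq_len(L)) - pmax(br[b_], seq_len(L) - 1)
          w[w < 0] <- 0
          ok <- !is.na(v) & w > 0
          if (!any(ok)) NA_real_ else sum(v[ok] * w[ok]) / sum(w[ok])
        }, 1)
      }
      c(binmean(grab(s - 100, s), 100), binmean(grab(s, s + 100), 100),
        binmean(grab(s + 100, e - 100), 7),
        binmean(grab(e - 100, e), 100), binmean(grab(e, e + 100), 100))
    })
    want <- rowMeans(per_region, na.rm = TRUE)
    expect_equal(got$bins$value, unname(want), tolerance = 1e-12)
  }
})

test_that("middle rescaling conserves covered bases and order invariance holds", {
  sizes <- c(chr1 = 20000L)
  set.seed(29)
  st <- sample.int(18000, 12)
  track <- annotation_track("chr1", st, st + sample.int(600, 12), "LINE",
                            track = "repeat")
  rs <- sample(1000:15000, 6)
  regions <- genome_regions("chr1", rs, rs + sample(800:2500, 6))
  sch <- window_scheme(flank = 150, edge = 150, middle_bins = 11)
  p1 <- coverage_profile(regions, track, "LINE", sizes, sch)
  p2 <- coverage_profile(regions[sample(6), ], track, "LINE", sizes, sch)
  expect_equal(p1$bins$value, p2$bins$value)
  # conservation: per-region weighted bin sum equals covered middle bases
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    L3 <- (r$end - 150) - (r$start + 150)
    pr <- coverage_profile(r, track, "LINE", sizes, sch)
    mid <- pr$bins$value[pr$bins$segment == "w3"]
    cov <- numeric(20000)
    for (k in seq_len(nrow(track)))
      cov[(track$start[k] + 1):track$end[k]] <- 1
    direct <- sum(cov[(r$start + 150 + 1):(r$end - 150)])
    expect_equal(sum(mid * L3 / 11), direct, tolerance = 1e-9)
  }
})

test_that("per-bin sums over exclusive repeat classes stay at most 1", {
  g <- simulate_genome(sim_config(seed = 41, n_chroms = 1,
                                  chrom_length = 60000))
  set.seed(42)
  rs <- sample(2000:50000, 30)
  regions <- genome_regions("chr1", rs, rs + sample(700:2000, 30))
  sch <- window_scheme(flank = 100, edge = 100, middle_bins = 20)
  labs <- unique(g$tracks$`repeat`$label)
  profs <- lapply(labs, function(l)
    coverage_profile(regions, g$tracks$`repeat`, l, g$sizes, sch)$bins$value)
  total <- Reduce(`+`, profs)
  expect_true(all(total <= 1 + 1e-9, na.rm = TRUE))
})
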