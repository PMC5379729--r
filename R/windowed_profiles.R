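#' Window scheme for region profiles
#'
#' Each called region plus flanks is decomposed into five windows: w1 (the
#' \code{flank} bp immediately upstream), w2 (the first \code{edge} bp of
#' the region), w3 (the variable-length middle), w4 (the last \code{edge}
#' bp) and w5 (the \code{flank} bp downstream). Flank and edge windows are
#' profiled at 1 bp per bin; the middle is rescaled to \code{middle_bins}
#' bins by proportional per-base assignment so profiles of unequal-length
#' regions can be averaged.
#'
#' @param flank upstream/downstream flank size, bp (default 300).
#' @param edge region edge window size, bp (default 300).
#' @param middle_bins number of bins the middle is rescaled to
#'   (default 300).
#' @param flank_bins,edge_bins number of bins the flank and edge windows
#'   are pooled into (default: one bin per bp, matching the published
#'   curves; coarser bins pool more bases per bin and tighten the sampling
#'   noise of each bin mean).
#' @return list of class \code{window_scheme}.
#' @export
window_scheme <- function(flank = 300L, edge = 300L, middle_bins = 300L,
                          flank_bins = flank, edge_bins = edge) {
  stopifnot(flank > 0, edge > 0, middle_bins > 0, flank_bins > 0,
            edge_bins > 0, flank_bins <= flank, edge_bins <= edge)
  structure(list(flank = as.integer(flank), edge = as.integer(edge),
                 middle_bins = as.integer(middle_bins),
                 flank_bins = as.integer(flank_bins),
                 edge_bins = as.integer(edge_bins)),
            class = "window_scheme")
}

#' The five windows of one region
#'
#' @param region one-row region data.frame.
#' @param scheme a [window_scheme()].
#' @param sizes named chromosome lengths (w1/w5 are clipped at chromosome
#'   boundaries).
#' @return data.frame with rows w1..w5 (chrom, start, end, clipped,
#'   empty). w3 is empty when the region is not longer than
#'   \code{2 * edge}.
#' @export
make_windows <- function(region, scheme = window_scheme(), sizes) {
  s <- region$start; e <- region$end; L <- sizes[[region$chrom]]
  f <- scheme$flank; g <- scheme$edge
  raw <- data.frame(
    window = c("w1", "w2", "w3", "w4", "w5"),
    start = c(s - f, s, s + g, e - g, e),
    end = c(s, s + g, e - g, e, e + f))
  out <- raw
  out$start <- pmax(0L, pmin(raw$start, L))
  out$end <- pmax(0L, pmin(raw$end, L))
  out$end <- pmax(out$start, out$end)   # empty, not negative
  out$chrom <- region$chrom
  out$clipped <- out$start != raw$start | out$end != raw$end
  out$clipped[3] <- FALSE               # an empty middle is not clipping
  out$empty <- out$end <= out$start
  out[, c("window", "chrom", "start", "end", "clipped", "empty")]
}

# per-base vector for one window of the profile matrix:
# fixed-width windows (w1/w2/w4/w5) are padded with NA where clipped, the
# pad sitting on the side away from the region body.
window_values <- function(w, width, value_fun, pad_side) {
  v <- if (w$end > w$start) value_fun(w$chrom, w$start, w$end) else numeric(0)
  pad <- rep(NA_real_, width - length(v))
  if (pad_side == "left") c(pad, v) else c(v, pad)
}

# rescale a per-base vector to m bins by proportional assignment; NA bases
# drop out of both numerator and weight
rescale_bins <- function(v, m) {
  L <- length(v)
  if (L == 0) return(rep(NA_real_, m))
  brk <- seq(0, L, length.out = m + 1)
  vapply(seq_len(m), function(b) {
    lo <- brk[b]; hi <- brk[b + 1]
    idx <- seq.int(floor(lo) + 1, ceiling(hi))
    idx <- idx[idx >= 1 & idx <= L]
    wts <- pmin(hi, idx) - pmax(lo, idx - 1)
    ok <- !is.na(v[idx]) & wts > 0
    if (!any(ok)) return(NA_real_)
    sum(v[idx][ok] * wts[ok]) / sum(wts[ok])
  }, numeric(1))
}

# shared profile engine: value_fun(chrom, start, end) -> per-base numeric
# vector (NA = missing base)
profile_regions <- function(regions, scheme, sizes, value_fun, feature,
                            background = NA_real_) {
  f <- scheme$flank; g <- scheme$edge; m <- scheme$middle_bins
  fb <- scheme$flank_bins; gb <- scheme$edge_bins
  n_bins <- 2L * fb + 2L * gb + m
  mat <- matrix(NA_real_, nrow(regions), n_bins)
  for (i in seq_len(nrow(regions))) {
    w <- make_windows(regions[i, ], scheme, sizes)
    mat[i, ] <- c(
      rescale_bins(window_values(w[1, ], f, value_fun, "left"), fb),
      rescale_bins(window_values(w[2, ], g, value_fun, "right"), gb),
      rescale_bins(if (w$empty[3]) rep(NA_real_, 1) else
        value_fun(w$chrom[3], w$start[3], w$end[3]), m),
      rescale_bins(window_values(w[4, ], g, value_fun, "left"), gb),
      rescale_bins(window_values(w[5, ], f, value_fun, "right"), fb))
  }
  seg <- rep(c("w1", "w2", "w3", "w4", "w5"), c(fb, gb, m, gb, fb))
  bins <- data.frame(segment = seg,
                     index = seq_len(n_bins),
                     value = colMeans(mat, na.rm = TRUE),
                     n = colSums(!is.na(mat)))
  bins$value[bins$n == 0] <- NA_real_
  structure(list(feature = feature, bins = bins, n_regions = nrow(regions),
                 background = background, scheme = scheme),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("window profile of", x$feature, "over", x$n_regions, "regions\n")
  agg <- tapply(x$bins$value, x$bins$segment, mean, na.rm = TRUE)
  print(round(agg[c("w1", "w2", "w3", "w4", "w5")], 4))
  if (!is.na(x$background))
    cat("genome-wide background:", round(x$background, 4), "\n")
  invisible(x)
}

#' GC-content profile across regions
#'
#' Per bin, the fraction of G/C bases (case-insensitive; N bases excluded
#' from the denominator and recorded as missing), averaged across regions.
#' The genome-wide GC fraction is attached as the flat background
#' reference.
#'
#' @param regions region data.frame.
#' @param genome named \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences.
#' @param scheme a [window_scheme()].
#' @return a \code{window_profile}.
#' @export
gc_profile <- function(regions, genome, scheme = window_scheme()) {
  genome <- Biostrings::DNAStringSet(genome)
  sizes <- setNames(Biostrings::width(genome), names(genome))
  chars <- lapply(as.character(genome), function(s)
    strsplit(toupper(s), "")[[1]])
  per_base <- lapply(chars, function(v) {
    out <- rep(NA_real_, length(v))
    out[v %in% c("G", "C")] <- 1
    out[v %in% c("A", "T")] <- 0
    out
  })
  value_fun <- function(chrom, start, end)
    per_base[[chrom]][(start + 1):end]
  bg <- mean(unlist(per_base), na.rm = TRUE)
  profile_regions(regions, scheme, sizes, value_fun, "GC", background = bg)
}

#' Annotation-coverage (or signal) profile across regions
#'
#' For presence/absence tracks (repeats): per bin, the fraction of bases
#' covered by annotations carrying the given label. For histone tracks
#' (\code{signal = TRUE}): per bin, the mean signal value over bases, with
#' 0 where uncovered and the mean of overlapping interval values where
#' intervals stack. The genome-wide mean is attached as background.
#'
#' @param regions region data.frame.
#' @param track annotation track.
#' @param label which annotation class to profile; must occur in the track.
#' @param sizes named chromosome lengths.
#' @param scheme a [window_scheme()].
#' @param signal use interval values (histone mode) instead of 0/1
#'   coverage.
#' @param known_labels label vocabulary of the track (default: the labels
#'   it contains). A label in the vocabulary but absent from the track
#'   yields an all-zero profile; a label outside it is an error.
#' @return a \code{window_profile}.
#' @export
coverage_profile <- function(regions, track, label, sizes,
                             scheme = window_scheme(), signal = FALSE,
                             known_labels = unique(track$label)) {
  if (!label %in% known_labels)
    stop("unknown label: ", label)
  ann <- track[track$label == label, , drop = FALSE]
  per_chrom <- lapply(names(sizes), function(ch) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    W <- sizes[[ch]]
    if (nrow(a) == 0) return(numeric(W))
    ir <- restrict(as_iranges0(a$start, a$end), 1L, W)
    if (signal) {
      num <- as.numeric(coverage(ir, weight = a$value, width = W))
      den <- as.numeric(coverage(ir, width = W))
      ifelse(den > 0, num / den, 0)
    } else {
      as.numeric(coverage(reduce(ir), width = W) > 0)
    }
  })
  names(per_chrom) <- names(sizes)
  value_fun <- function(chrom, start, end)
    per_chrom[[chrom]][(start + 1):end]
  bg <- mean(unlist(per_chrom))
  profile_regions(regions, scheme, sizes, value_fun,
                  feature = label, background = bg)
}

#' Flatten one or more window profiles into a table
#'
#' @param profiles a \code{window_profile} or list of them.
#' @return long data.frame: feature, segment, index, value, n.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "window_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p)
    cbind(feature = p$feature, p$bins,
          background = p$background, n_regions = p$n_regions)))
}
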