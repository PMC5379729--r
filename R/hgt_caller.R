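#' Parameters of the HGT caller
#'
#' Defaults follow the published pipeline: a focal-genome interval is a
#' non-mammal conserved region if at least \code{min_nonmammal_species}
#' distinct non-mammals align to it with identity no less than
#' \code{min_identity} and the interval is longer than \code{min_length}
#' (strict). Such a region is called HGT if at most
#' \code{max_mammal_support} mammals support it, a mammal supporting a
#' region iff its qualifying alignments (identity >=
#' \code{mammal_min_identity}) cover strictly more than
#' \code{mammal_min_coverage} of the region length.
#'
#' @param min_identity inclusive identity threshold for non-mammal blocks
#'   (default 0.40).
#' @param min_nonmammal_species minimum distinct non-mammal species per base
#'   (default 2).
#' @param min_length regions must be strictly longer than this, bp
#'   (default 1000).
#' @param max_mammal_support maximum number of supporting mammals for a
#'   region to be called (default 8).
#' @param mammal_min_coverage fraction of region length a mammal must
#'   exceed (strict) to count as support (default 0.40).
#' @param mammal_min_identity inclusive identity threshold for mammal
#'   support blocks (default 0.40).
#' @param merge_gap bridge sub-intervals separated by at most this many bp
#'   before applying the length filter (default 0: no bridging).
#' @param support_mode \code{"depth"} (default): the non-mammal species
#'   count is a per-base depth of distinct species. \code{"region"}: laxer
#'   reading where each species must independently cover at least
#'   \code{region_support_fraction} of a candidate interval (the union of
#'   qualifying non-mammal alignments).
#' @param region_support_fraction coverage fraction used by
#'   \code{support_mode = "region"} (default 0.4).
#' @return a list of class \code{call_params}.
#' @export
call_params <- function(min_identity = 0.40, min_nonmammal_species = 2L,
                        min_length = 1000L, max_mammal_support = 8L,
                        mammal_min_coverage = 0.40,
                        mammal_min_identity = 0.40, merge_gap = 0L,
                        support_mode = c("depth", "region"),
                        region_support_fraction = 0.4) {
  support_mode <- match.arg(support_mode)
  stopifnot(min_identity >= 0, min_identity <= 1,
            mammal_min_identity >= 0, mammal_min_identity <= 1,
            mammal_min_coverage >= 0, mammal_min_coverage <= 1,
            min_length > 0, max_mammal_support >= 0,
            min_nonmammal_species >= 1, merge_gap >= 0)
  structure(list(min_identity = min_identity,
                 min_nonmammal_species = as.integer(min_nonmammal_species),
                 min_length = as.integer(min_length),
                 max_mammal_support = as.integer(max_mammal_support),
                 mammal_min_coverage = mammal_min_coverage,
                 mammal_min_identity = mammal_min_identity,
                 merge_gap = as.integer(merge_gap),
                 support_mode = support_mode,
                 region_support_fraction = region_support_fraction),
            class = "call_params")
}

#' Filter blocks to one clade at an identity threshold
#'
#' @param blocks alignment block data.frame.
#' @param panel species panel.
#' @param clade \code{"mammal"} or \code{"non_mammal"}.
#' @param min_identity inclusive lower bound on identity.
#' @return the qualifying subset of \code{blocks}.
#' @export
qualifying_blocks <- function(blocks, panel, clade, min_identity) {
  keep <- panel$species[panel$clade == clade]
  blocks[blocks$species %in% keep & blocks$identity >= min_identity, ,
         drop = FALSE]
}

#' Non-mammal conserved regions
#'
#' Maximal focal-genome intervals where the per-base number of distinct
#' qualifying non-mammal species reaches
#' \code{params$min_nonmammal_species}, bridged across gaps of at most
#' \code{params$merge_gap} bp, and strictly longer than
#' \code{params$min_length}. Overlapping blocks of one species are unioned
#' before depth counting, so one species never counts twice at a base.
#'
#' @inheritParams qualifying_blocks
#' @param params a [call_params()] object.
#' @return region data.frame (chrom, start, end), sorted.
#' @export
nonmammal_conserved_regions <- function(blocks, panel, params = call_params()) {
  q <- qualifying_blocks(blocks, panel, "non_mammal", params$min_identity)
  out <- lapply(sort(unique(q$chrom)), function(chr) {
    b <- q[q$chrom == chr, , drop = FALSE]
    if (nrow(b) == 0) return(NULL)
    W <- max(b$end)
    if (params$support_mode == "depth") {
      per_sp <- lapply(split(seq_len(nrow(b)), b$species), function(i)
        reduce(as_iranges0(b$start[i], b$end[i])))
      depth <- Reduce(`+`, lapply(per_sp, coverage, width = W))
      hits <- slice(depth, lower = params$min_nonmammal_species,
                    rangesOnly = TRUE)
    } else {
      u <- reduce(as_iranges0(b$start, b$end))
      per_sp <- lapply(split(seq_len(nrow(b)), b$species), function(i)
        reduce(as_iranges0(b$start[i], b$end[i])))
      ok <- vapply(seq_along(u), function(k) {
        cand <- u[k]
        n_cov <- sum(vapply(per_sp, function(ir) {
          ov <- sum(IRanges::width(IRanges::intersect(ir, cand)))
          ov >= params$region_support_fraction * IRanges::width(cand)
        }, logical(1)))
        n_cov >= params$min_nonmammal_species
      }, logical(1))
      hits <- u[ok]
    }
    hits <- reduce(hits, min.gapwidth = params$merge_gap + 1L)
    hits <- hits[IRanges::width(hits) > params$min_length]
    from_iranges0(chr, hits)
  })
  out <- do.call(rbind, c(out, list(genome_regions("chr0", 0, 1)[0, ])))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Mammal support for one candidate region
#'
#' A mammal species supports the region iff the union of its alignment
#' blocks with identity at least \code{params$mammal_min_identity},
#' intersected with the region, covers strictly more than
#' \code{params$mammal_min_coverage} of the region length. Coverage is
#' measured against the final candidate region, not any single block.
#'
#' @param region one-row region data.frame (or list with chrom/start/end).
#' @inheritParams nonmammal_conserved_regions
#' @return list with \code{count} and sorted \code{supporters}.
#' @export
mammal_support <- function(region, blocks, panel, params = call_params()) {
  q <- qualifying_blocks(blocks, panel, "mammal", params$mammal_min_identity)
  q <- q[q$chrom == region$chrom, , drop = FALSE]
  reg <- as_iranges0(region$start, region$end)
  len <- region$end - region$start
  covered <- vapply(split(seq_len(nrow(q)), q$species), function(i) {
    ir <- IRanges::intersect(reduce(as_iranges0(q$start[i], q$end[i])), reg)
    sum(IRanges::width(ir))
  }, numeric(1))
  supp <- sort(names(covered)[covered > params$mammal_min_coverage * len])
  list(count = length(supp), supporters = supp)
}

#' Call predicted HGT regions
#'
#' Runs the full filter: non-mammal conserved regions (depth, length) whose
#' mammal support count is at most \code{params$max_mammal_support}. Each
#' call is annotated with its non-mammal supporters (species overlapping the
#' region with qualifying blocks, with per-species mean identity) and its
#' mammal supporters.
#'
#' @inheritParams nonmammal_conserved_regions
#' @return data.frame of class \code{hgt_calls}, sorted by (chrom, start),
#'   with list-columns \code{nonmammal_supporters} (data.frames of species +
#'   mean identity) and \code{mammal_supporters}.
#' @export
call_hgt <- function(blocks, panel, params = call_params()) {
  panel <- validate_panel(panel)
  if (sum(panel$clade == "non_mammal") < params$min_nonmammal_species)
    stop("panel has fewer non-mammal species than min_nonmammal_species")
  cand <- nonmammal_conserved_regions(blocks, panel, params)
  qn <- qualifying_blocks(blocks, panel, "non_mammal", params$min_identity)
  keep <- logical(nrow(cand))
  nm_sup <- vector("list", nrow(cand))
  m_cnt <- integer(nrow(cand)); m_sup <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    reg <- cand[k, ]
    ms <- mammal_support(reg, blocks, panel, params)
    keep[k] <- ms$count <= params$max_mammal_support
    m_cnt[k] <- ms$count; m_sup[[k]] <- ms$supporters
    b <- qn[qn$chrom == reg$chrom & qn$start < reg$end & qn$end > reg$start, ,
            drop = FALSE]
    mi <- vapply(split(b$identity, b$species), mean, numeric(1))
    nm_sup[[k]] <- data.frame(species = names(mi)[order(names(mi))],
                              mean_identity = unname(mi[order(names(mi))]),
                              stringsAsFactors = FALSE)
  }
  out <- cand
  out$length <- out$end - out$start
  out$n_nonmammal <- vapply(nm_sup, nrow, integer(1))
  out$mammal_support <- m_cnt
  out$nonmammal_supporters <- I(nm_sup)
  out$mammal_supporters <- I(m_sup)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hgt_calls", class(out))
  out
}

#' Validate called regions against the caller's own invariants
#'
#' Independent post-hoc check: every call must carry at least the minimum
#' number of non-mammal supporters, at most the maximum mammal support, and
#' be strictly longer than the length threshold.
#'
#' @param calls output of [call_hgt()].
#' @param params the parameters used.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_hgt_calls <- function(calls, params = call_params()) {
  stopifnot(all(calls$n_nonmammal >= params$min_nonmammal_species),
            all(calls$mammal_support <= params$max_mammal_support),
            all(calls$end - calls$start > params$min_length),
            !is.unsorted(order(calls$chrom, calls$start)))
  invisible(TRUE)
}

#' Threshold sensitivity grid
#'
#' Re-runs the caller over a grid of conservation identity thresholds
#' crossed with mammal coverage thresholds, reporting the number of called
#' regions and their total bases per cell. The mammal support filter keeps
#' its own identity threshold from \code{base_params} (the filter is
#' defined with a fixed 40% identity), so each grid axis moves exactly one
#' knob and the call set shrinks monotonically as identity rises.
#'
#' @inheritParams nonmammal_conserved_regions
#' @param identity_grid numeric vector of identity thresholds
#'   (published grid: 0.4, 0.5, 0.6).
#' @param coverage_grid numeric vector of mammal coverage thresholds
#'   (published grid: 0.4, 0.2, 0).
#' @param base_params parameters for everything not on the grid.
#' @return data.frame with columns \code{min_identity},
#'   \code{mammal_min_coverage}, \code{n_regions}, \code{total_bases}.
#' @export
threshold_grid <- function(blocks, panel, identity_grid = c(0.4, 0.5, 0.6),
                           coverage_grid = c(0.4, 0.2, 0),
                           base_params = call_params()) {
  stopifnot(length(identity_grid) > 0, length(coverage_grid) > 0)
  grid <- expand.grid(min_identity = identity_grid,
                      mammal_min_coverage = coverage_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base_params
    p$min_identity <- grid$min_identity[i]
    p$mammal_min_coverage <- grid$mammal_min_coverage[i]
    calls <- call_hgt(blocks, panel, p)
    data.frame(min_identity = p$min_identity,
               mammal_min_coverage = p$mammal_min_coverage,
               n_regions = nrow(calls),
               total_bases = sum(calls$end - calls$start))
  })
  do.call(rbind, res)
}
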