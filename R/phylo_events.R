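#' Pairwise p-distance between aligned sequences
#'
#' Proportion of differing sites among columns where both sequences carry a
#' non-gap, non-N character.
#'
#' @param seq_a,seq_b equal-length aligned sequence strings.
#' @return fraction in \[0, 1\].
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(ok)) stop("no comparable (both non-gap) columns")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' p-distance matrix of a homologous sequence set
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (one per species).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique species names")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- p_distance(seqs[[i]], seqs[[j]])
  d
}

#' Neighbor-joining tree of a distance matrix, rooted at an outgroup
#'
#' Standard Saitou-Nei neighbor joining (via \code{ape::nj}), with the
#' unrooted result rooted at a designated outgroup leaf so it can be
#' compared against a rooted species tree by SPR distance. NJ recovers the
#' true topology exactly whenever the matrix is additive.
#'
#' @param d symmetric distance matrix with species dimnames (n >= 3).
#' @param outgroup leaf to root at (default: first species
#'   lexicographically).
#' @return rooted binary \code{phylo} tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (is.null(outgroup)) outgroup <- sort(rownames(d))[1]
  if (!outgroup %in% rownames(d)) stop("outgroup not in distance matrix")
  tr <- ape::nj(as.dist(d))
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr
}

#' Lower-bound the number of transfer events for one region
#'
#' Prunes the region tree and the species tree to their common leaf set and
#' returns the exact rooted SPR distance between them. Each SPR move needed
#' to turn the species tree into the region (gene) tree corresponds to at
#' least one interspecies transfer event, so the distance is a lower bound
#' on the number of HGT events affecting the region.
#'
#' Rooted SPR distance is sensitive to root placement, so the two trees
#' must share a rooting convention: pass \code{outgroup} to re-root both
#' pruned trees on the same leaf (recommended whenever the region tree was
#' rooted independently of the species tree, as an NJ tree always is).
#'
#' @param region_tree rooted \code{phylo} built from the region's
#'   homologous sequences (e.g. [nj_tree()]).
#' @param species_tree rooted \code{phylo} reference species tree.
#' @param outgroup optional leaf label; when given, both trees are
#'   re-rooted at it after pruning to the common leaf set.
#' @param max_d,max_leaves passed to [spr_distance()].
#' @return integer lower bound, with attributes \code{leaves} (the common
#'   leaf set used) and \code{spr} (the full [spr_distance()] result). 0
#'   with a warning when fewer than 4 leaves are shared (no informative
#'   topology).
#' @export
count_hgt_events <- function(region_tree, species_tree, outgroup = NULL,
                             max_d = 6L, max_leaves = 12L) {
  common <- intersect(region_tree$tip.label, species_tree$tip.label)
  if (length(common) < 4) {
    warning("fewer than 4 shared leaves: topology uninformative, 0 returned")
    out <- 0L
    attr(out, "leaves") <- sort(common)
    return(out)
  }
  rt <- ape::keep.tip(region_tree, common)
  st <- ape::keep.tip(species_tree, common)
  if (!is.null(outgroup)) {
    if (!outgroup %in% common) stop("outgroup not in the common leaf set")
    reroot <- function(t)
      ape::root(ape::unroot(t), outgroup = outgroup, resolve.root = TRUE)
    rt <- reroot(rt); st <- reroot(st)
  }
  res <- spr_distance(rt, st, max_d = max_d, max_leaves = max_leaves)
  out <- res$distance
  attr(out, "leaves") <- sort(common)
  attr(out, "spr") <- res
  out
}
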