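#' Chromosome end-bias test for called regions
#'
#' Partitions each chromosome into two end zones (the terminal
#' \code{end_fraction} of its length on each side) and one middle zone,
#' assigns each region to a zone by its midpoint, and compares per-bp
#' region densities between end and middle zones with a paired one-sided
#' t-test across chromosomes (H1: end density exceeds middle density).
#' Densities rather than raw counts are compared so unequal zone sizes do
#' not bias the test.
#'
#' @param regions region data.frame (chrom, start, end).
#' @param sizes named chromosome lengths; all chromosomes in it enter the
#'   pairing, including those without regions.
#' @param end_fraction end-zone width per side as a fraction of chromosome
#'   length (default 0.10; must be in (0, 0.5)).
#' @return list with \code{t}, \code{p}, \code{df} and \code{per_chrom}
#'   (chromosome, counts and densities per zone, difference). When the
#'   paired differences have zero variance the test is degenerate: \code{t}
#'   and \code{p} are NA and a warning is raised.
#' @export
end_bias_test <- function(regions, sizes, end_fraction = 0.10) {
  stopifnot(end_fraction > 0, end_fraction < 0.5)
  if (length(sizes) < 2) stop("need at least 2 chromosomes to pair")
  if (nrow(regions) < 1) stop("need at least 1 region")
  mid <- (regions$start + regions$end) / 2
  per <- lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    zone_bp <- end_fraction * L
    m <- mid[regions$chrom == ch]
    n_end <- sum(m < zone_bp | m >= L - zone_bp)
    n_mid <- sum(m >= zone_bp & m < L - zone_bp)
    d_end <- n_end / (2 * zone_bp)
    d_mid <- n_mid / (L - 2 * zone_bp)
    data.frame(chrom = ch, n_end = n_end, n_mid = n_mid,
               density_end = d_end, density_mid = d_mid,
               diff = d_end - d_mid, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  d <- per$diff
  n <- length(d)
  if (sd(d) == 0) {
    warning("zero variance in paired differences; test degenerate")
    return(list(t = NA_real_, p = NA_real_, df = n - 1L, per_chrom = per))
  }
  t_stat <- mean(d) * sqrt(n) / sd(d)
  p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  list(t = t_stat, p = p, df = n - 1L, per_chrom = per)
}

# assign each base to the first label in `priority` whose (reduced)
# intervals cover it; returns per-label IRanges claims for one chromosome
claim_by_priority <- function(track_chr, priority, W) {
  claimed <- IRanges()
  claims <- list()
  for (lab in priority) {
    ir <- track_chr[track_chr$label == lab, , drop = FALSE]
    ir <- if (nrow(ir)) reduce(as_iranges0(ir$start, ir$end)) else IRanges()
    ir <- restrict(ir, 1L, W)
    take <- IRanges::setdiff(ir, claimed)
    claims[[lab]] <- take
    claimed <- reduce(c(claimed, take))
  }
  claims$..rest <- IRanges::setdiff(IRanges(1L, W), claimed)
  claims
}

#' Composition of called regions versus the genome background
#'
#' For each label, the fraction of region bases assigned to it, against the
#' same fraction over the whole genome. Overlaps between labels are
#' resolved by a priority list (first label wins per base); bases covered
#' by no annotation take \code{default_label}. Published analyses of this
#' form: gene-biotype composition (priority protein_coding > lincRNA >
#' antisense > other, remainder "non_gene") and chromatin-state composition
#' over the seven chromHMM-style states.
#'
#' @param regions region data.frame.
#' @param track annotation track data.frame (see [annotation_track()]).
#' @param sizes named chromosome lengths (defines the background).
#' @param priority character vector of labels, highest priority first. All
#'   labels present in the track must appear in it.
#' @param default_label label for unannotated bases (default: last element
#'   of \code{priority} if absent from the track, else \code{"none"}).
#' @return data.frame with columns \code{label},
#'   \code{foreground_fraction}, \code{background_fraction}; each column
#'   sums to 1.
#' @export
composition <- function(regions, track, sizes, priority,
                        default_label = NULL) {
  missing_lab <- setdiff(unique(track$label), priority)
  if (length(missing_lab))
    stop("track labels absent from priority list: ",
         paste(sort(missing_lab), collapse = ", "))
  if (is.null(default_label))
    default_label <- if (priority[length(priority)] %in% track$label)
      "none" else priority[length(priority)]
  labs <- unique(c(priority, default_label))
  fg <- bg <- setNames(numeric(length(labs)), labs)
  for (ch in names(sizes)) {
    W <- sizes[[ch]]
    claims <- claim_by_priority(track[track$chrom == ch, , drop = FALSE],
                                setdiff(labs, default_label), W)
    names(claims)[names(claims) == "..rest"] <- default_label
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    reg_ir <- reduce(as_iranges0(reg$start, reg$end))
    for (lab in names(claims)) {
      bg[lab] <- bg[lab] + sum(IRanges::width(claims[[lab]]))
      fg[lab] <- fg[lab] +
        sum(IRanges::width(IRanges::intersect(claims[[lab]], reg_ir)))
    }
  }
  total_fg <- sum(fg); total_bg <- sum(bg)
  if (total_fg == 0) stop("regions cover zero bases")
  data.frame(label = labs,
             foreground_fraction = unname(fg / total_fg),
             background_fraction = unname(bg / total_bg),
             stringsAsFactors = FALSE)
}

#' Genes overlapping called regions
#'
#' Any-overlap (at least 1 bp, half-open semantics) intersection between a
#' gene track and a region set. Each gene is reported once, with all its
#' overlapping regions.
#'
#' @param regions region data.frame.
#' @param gene_track gene annotation track with unique \code{id}s and
#'   biotype labels.
#' @return data.frame (one row per overlapped gene: id, biotype, chrom,
#'   start, end, n_regions) with a list-column \code{regions} of the
#'   overlapping region rows; attribute \code{n_genes} carries the distinct
#'   gene count.
#' @export
gene_overlap <- function(regions, gene_track) {
  if (anyNA(gene_track$id) || anyDuplicated(gene_track$id))
    stop("gene track must carry unique, non-missing gene ids")
  hits <- lapply(seq_len(nrow(gene_track)), function(g) {
    ov <- regions$chrom == gene_track$chrom[g] &
      regions$start < gene_track$end[g] &
      regions$end > gene_track$start[g]
    if (!any(ov)) return(NULL)
    df <- gene_track[g, c("id", "label", "chrom", "start", "end")]
    names(df)[2] <- "biotype"
    df$n_regions <- sum(ov)
    df$regions <- I(list(regions[ov, , drop = FALSE]))
    df
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(id = character(), biotype = character(),
                      chrom = character(), start = integer(),
                      end = integer(), n_regions = integer())
  rownames(out) <- NULL
  attr(out, "n_genes") <- nrow(out)
  out
}

#' Default label priorities for the shipped composition analyses
#'
#' Gene-biotype priority follows the published composition categories
#' (protein coding, lincRNA, antisense, other, remainder non-gene);
#' chromatin priority follows the seven-state ordering of the chromatin
#' composition table.
#'
#' @name composition_priorities
#' @export
gene_biotype_priority <- function()
  c("protein_coding", "lincRNA", "antisense", "other", "non_gene")

#' @rdname composition_priorities
#' @export
chromatin_state_priority <- function()
  c("Heterochrom", "Txn", "Enhancer", "Promoter", "Repressed", "Insulator",
    "Repetitive")
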