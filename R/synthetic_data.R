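#' Configuration of the synthetic study system
#'
#' The generator emulates the study design the caller was built for: a focal
#' genome aligned pairwise to a panel of 41 mammals and 12 non-mammal
#' vertebrates, with a handful of planted regions that are conserved across
#' a few non-mammals (identity well above the 0.40 calling threshold) while
#' being supported by few or no mammals, on top of a background in which
#' mammals align densely at high identity and non-mammals only sparsely at
#' low identity.
#'
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @param n_chroms,chrom_length focal genome shape (bp).
#' @param n_mammals,n_nonmammals panel sizes (defaults 41 and 12, the
#'   published panel split).
#' @param n_planted_hgt number of planted HGT regions.
#' @param planted_length length of each planted region, bp (default 1500,
#'   comfortably above the 1000 bp calling threshold).
#' @param hgt_nonmammal_identity identity of the supporting non-mammal
#'   blocks (default 0.6, a 0.2 margin over the threshold).
#' @param hgt_nonmammal_supporters how many non-mammals support each plant
#'   (>= 2).
#' @param hgt_mammal_supporters how many mammals support each plant
#'   (default 0; set to 9 for the "spoiler" negative control that must not
#'   be called under the at-most-8 rule).
#' @param background_mammal_identity mean identity of background mammal
#'   blocks (default 0.7).
#' @param background_nonmammal_identity mean identity of background
#'   non-mammal blocks (default 0.2; capped at 0.25, a 0.15 margin below
#'   the threshold).
#' @param background_block_rate background blocks per kb per species
#'   (default 0.05; 0 gives a clean margin-separated dataset).
#' @param substitution_rate_per_branch per-site substitution probability per
#'   tree branch for the sequence-set simulator.
#' @param end_bias_fraction fraction of planted regions forced into the
#'   terminal 10% zones of their chromosome (default 0: uniform placement).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 100000L,
                       n_mammals = 41L, n_nonmammals = 12L,
                       n_planted_hgt = 5L, planted_length = 1500L,
                       hgt_nonmammal_identity = 0.6,
                       hgt_nonmammal_supporters = 3L,
                       hgt_mammal_supporters = 0L,
                       background_mammal_identity = 0.7,
                       background_nonmammal_identity = 0.2,
                       background_block_rate = 0.05,
                       substitution_rate_per_branch = 0.02,
                       end_bias_fraction = 0) {
  stopifnot(hgt_nonmammal_supporters >= 2,
            hgt_nonmammal_identity >= 0, hgt_nonmammal_identity <= 1,
            background_mammal_identity >= 0, background_mammal_identity <= 1,
            background_block_rate >= 0, n_nonmammals >= 2, n_mammals >= 1,
            end_bias_fraction >= 0, end_bias_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @param cfg a \code{sim_config}.
#' @export
sim_panel <- function(cfg) {
  species_panel(
    c(sprintf("mammal_%02d", seq_len(cfg$n_mammals)),
      sprintf("nonmammal_%02d", seq_len(cfg$n_nonmammals))),
    rep(c("mammal", "non_mammal"), c(cfg$n_mammals, cfg$n_nonmammals)))
}

# draw from N(mu, sd) truncated into [lo, hi]
rnorm_trunc <- function(n, mu, sd, lo, hi)
  pmin(hi, pmax(lo, rnorm(n, mu, sd)))

#' Simulate the focal genome and its annotation tracks
#'
#' Uniform-random DNA plus simple annotation tracks: genes with Ensembl-style
#' biotypes, a chromatin segmentation over the seven chromHMM-style states
#' (Heterochrom, Txn, Enhancer, Promoter, Repressed, Insulator, Repetitive)
#' with genome-wide proportions close to published background values,
#' RepeatMasker-style repeat intervals, and histone-mark signal intervals.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genome} (a \code{DNAStringSet}), \code{sizes}
#'   (named lengths) and \code{tracks} (list of annotation data.frames:
#'   gene, chromatin, repeat, histone).
#' @export
simulate_genome <- function(cfg) {
  if (cfg$chrom_length < 4 * cfg$planted_length)
    stop("chrom_length too small to host planted regions")
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  sizes <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms), chroms)
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  gene_biotypes <- c(protein_coding = 0.5, lincRNA = 0.2, antisense = 0.12,
                     other = 0.18)
  chrom_states <- c(Heterochrom = 0.723, Txn = 0.202, Enhancer = 0.037,
                    Promoter = 0.016, Repressed = 0.013, Insulator = 0.007,
                    Repetitive = 0.002)
  repeat_classes <- c("SINE", "LINE", "LTR", "DNA", "Simple_repeat",
                      "Low_complexity")
  histone_marks <- c("H3K4Me1", "H2A.Z", "H3K4Me3", "H3K9Ac", "H3K27Ac",
                     "H3K27Me3")

  per_chrom <- function(fun) do.call(rbind, lapply(chroms, fun))

  genes <- per_chrom(function(ch) {
    n <- max(1L, rpois(1, cfg$chrom_length / 12000))
    len <- pmin(cfg$chrom_length %/% 4L,
                pmax(200L, as.integer(rlnorm(n, log(3000), 0.7))))
    start <- as.integer(floor(runif(n, 0, cfg$chrom_length - len)))
    data.frame(chrom = ch, start = start, end = start + len,
               label = sample(names(gene_biotypes), n, replace = TRUE,
                              prob = gene_biotypes),
               stringsAsFactors = FALSE)
  })
  genes <- genes[order(genes$chrom, genes$start), ]
  gene_track <- annotation_track(genes$chrom, genes$start, genes$end,
                                 genes$label,
                                 strand = sample(c("+", "-"), nrow(genes),
                                                 replace = TRUE),
                                 id = sprintf("gene_%04d", seq_len(nrow(genes))),
                                 track = "gene")

  chromatin <- per_chrom(function(ch) {
    brk <- 0L
    while (tail(brk, 1) < cfg$chrom_length)
      brk <- c(brk, tail(brk, 1) + max(200L, as.integer(rlnorm(1, log(2000), 0.8))))
    brk[length(brk)] <- cfg$chrom_length
    data.frame(chrom = ch, start = brk[-length(brk)], end = brk[-1],
               label = sample(names(chrom_states), length(brk) - 1,
                              replace = TRUE, prob = chrom_states),
               stringsAsFactors = FALSE)
  })
  chromatin_track <- annotation_track(chromatin$chrom, chromatin$start,
                                      chromatin$end, chromatin$label,
                                      track = "chromatin")

  repeats <- per_chrom(function(ch) {
    n <- max(1L, rpois(1, cfg$chrom_length / 2000))
    len <- pmax(50L, as.integer(rlnorm(n, log(300), 0.6)))
    start <- as.integer(floor(runif(n, 0, cfg$chrom_length - len)))
    df <- data.frame(chrom = ch, start = start, end = start + len,
                     label = sample(repeat_classes, n, replace = TRUE),
                     stringsAsFactors = FALSE)
    # RepeatMasker-style: one repeat call per base (greedy non-overlap)
    df <- df[order(df$start), ]
    keep <- rep(TRUE, nrow(df))
    last_end <- -1L
    for (i in seq_len(nrow(df))) {
      if (df$start[i] < last_end) keep[i] <- FALSE
      else last_end <- df$end[i]
    }
    df[keep, ]
  })
  repeat_track <- annotation_track(repeats$chrom, repeats$start, repeats$end,
                                   repeats$label, track = "repeat")

  histone <- per_chrom(function(ch) {
    n <- max(1L, rpois(1, cfg$chrom_length / 3000))
    len <- pmax(100L, as.integer(rlnorm(n, log(500), 0.5)))
    start <- as.integer(floor(runif(n, 0, cfg$chrom_length - len)))
    data.frame(chrom = ch, start = start, end = start + len,
               label = sample(histone_marks, n, replace = TRUE),
               value = rlnorm(n, log(2), 0.5), stringsAsFactors = FALSE)
  })
  histone_track <- annotation_track(histone$chrom, histone$start, histone$end,
                                    histone$label, value = histone$value,
                                    track = "histone")

  list(genome = genome, sizes = sizes,
       tracks = list(gene = gene_track, chromatin = chromatin_track,
                     "repeat" = repeat_track, histone = histone_track))
}

# non-overlapping placements of n regions of length len on one chromosome,
# each at least len from either boundary; end_biased placements instead land
# the region midpoint inside the terminal 10% zones.
place_regions <- function(n, len, L, n_end_biased = 0) {
  if (L < 4 * len) stop("chrom_length too small to host planted regions")
  placed <- integer(0)
  tries <- 0
  starts <- integer(0)
  while (length(starts) < n && tries < 2000 * n) {
    tries <- tries + 1
    biased <- length(starts) < n_end_biased
    if (biased) {
      zone_end <- floor(0.10 * L)
      left <- runif(1) < 0.5
      s <- if (left) floor(runif(1, 0, max(1, zone_end - len / 2)))
           else floor(runif(1, L - zone_end - len / 2, L - len))
      s <- max(0L, min(as.integer(s), L - len))
    } else {
      s <- as.integer(floor(runif(1, len, L - 2 * len)))
    }
    if (!any(abs(s - starts) < 2 * len)) starts <- c(starts, s)
  }
  if (length(starts) < n)
    stop("could not place planted regions without overlap; chromosome too crowded")
  sort(starts)
}

#' Plant HGT signals into a synthetic alignment-block table
#'
#' For each planted region, emits blocks from exactly
#' \code{hgt_nonmammal_supporters} non-mammals covering the whole region at
#' \code{hgt_nonmammal_identity}, and blocks from exactly
#' \code{hgt_mammal_supporters} mammals covering half the region at
#' identity 0.5 (qualifying support under the default thresholds).
#' Background blocks are Poisson counts per species per chromosome with
#' uniform starts and log-normal lengths; mammal background identity is high
#' (most mammals align well to most of a real genome), non-mammal background
#' identity is low (capped at 0.25 so it can never satisfy the 0.40
#' threshold).
#'
#' @param cfg a [sim_config()].
#' @param sizes named chromosome lengths.
#' @param panel optional panel (defaults to [sim_panel()] of \code{cfg}).
#' @return list with \code{blocks} (alignment block data.frame) and
#'   \code{truth} (regions + per-region supporter ids + mammal support
#'   count).
#' @export
plant_hgt_alignments <- function(cfg, sizes, panel = sim_panel(cfg)) {
  set.seed(cfg$seed + 1L)
  mams <- panel$species[panel$clade == "mammal"]
  nons <- panel$species[panel$clade == "non_mammal"]
  if (cfg$hgt_nonmammal_supporters > length(nons))
    stop("requested non-mammal supporters exceed panel size")
  if (cfg$hgt_mammal_supporters > length(mams))
    stop("requested mammal supporters exceed panel size")

  chroms <- names(sizes)
  n_per <- tabulate(sample.int(length(chroms), cfg$n_planted_hgt,
                               replace = TRUE), length(chroms))
  n_bias <- round(cfg$end_bias_fraction * n_per)
  truth_regions <- NULL
  blocks <- list()
  supporters <- list()
  for (ci in seq_along(chroms)) {
    if (n_per[ci] == 0) next
    starts <- place_regions(n_per[ci], cfg$planted_length, sizes[[ci]],
                            n_end_biased = n_bias[ci])
    for (s in starts) {
      e <- s + cfg$planted_length
      sup_n <- sample(nons, cfg$hgt_nonmammal_supporters)
      blocks[[length(blocks) + 1]] <- data.frame(
        species = sup_n, chrom = chroms[ci], start = s, end = e,
        identity = cfg$hgt_nonmammal_identity, stringsAsFactors = FALSE)
      if (cfg$hgt_mammal_supporters > 0) {
        sup_m <- sample(mams, cfg$hgt_mammal_supporters)
        half <- as.integer(cfg$planted_length / 2)
        blocks[[length(blocks) + 1]] <- data.frame(
          species = sup_m, chrom = chroms[ci],
          start = s + as.integer(cfg$planted_length / 4),
          end = s + as.integer(cfg$planted_length / 4) + half,
          identity = 0.5, stringsAsFactors = FALSE)
      }
      truth_regions <- rbind(truth_regions,
                             data.frame(chrom = chroms[ci], start = s, end = e,
                                        stringsAsFactors = FALSE))
      supporters[[length(supporters) + 1]] <- sort(sup_n)
    }
  }

  if (cfg$background_block_rate > 0) {
    for (sp in panel$species) {
      is_mam <- sp %in% mams
      for (ci in seq_along(chroms)) {
        L <- sizes[[ci]]
        n <- rpois(1, cfg$background_block_rate * L / 1000)
        if (n == 0) next
        len <- pmax(50L, as.integer(rlnorm(n, log(500), 0.6)))
        st <- as.integer(floor(runif(n, 0, L - len)))
        idy <- if (is_mam)
          rnorm_trunc(n, cfg$background_mammal_identity, 0.05, 0, 1)
        else
          rnorm_trunc(n, cfg$background_nonmammal_identity, 0.05, 0, 0.25)
        blocks[[length(blocks) + 1]] <- data.frame(
          species = sp, chrom = chroms[ci], start = st, end = st + len,
          identity = idy, stringsAsFactors = FALSE)
      }
    }
  }

  blocks <- do.call(rbind, blocks)
  blocks <- blocks[order(blocks$chrom, blocks$start, blocks$species), ]
  rownames(blocks) <- NULL
  truth <- list(regions = truth_regions,
                nonmammal_supporters = supporters,
                mammal_support = rep(cfg$hgt_mammal_supporters,
                                     NROW(truth_regions)))
  list(blocks = validate_blocks(blocks, panel, sizes), truth = truth)
}

#' Write planted truth as BED plus a JSON supporter sidecar
#'
#' @param truth truth component of [plant_hgt_alignments()].
#' @param bed_path,json_path output paths.
#' @export
write_planted_truth <- function(truth, bed_path, json_path) {
  write_regions_bed(truth$regions, bed_path)
  jsonlite::write_json(
    list(nonmammal_supporters = truth$nonmammal_supporters,
         mammal_support = truth$mammal_support),
    json_path, auto_unbox = FALSE)
  invisible(bed_path)
}

#' Deterministic species tree for a synthetic panel
#'
#' A rooted binary tree with the non-mammals as the basal clade (sister to
#' the mammal clade), random within-clade topology, unit branch lengths.
#' The most basal non-mammal leaf is the conventional outgroup.
#'
#' @param panel species panel.
#' @param seed RNG seed.
#' @return an \code{ape} \code{phylo} tree.
#' @export
make_species_tree <- function(panel, seed = 1L) {
  set.seed(seed)
  rand_clade <- function(labels) {
    # random sequential joins -> rooted binary newick fragment
    nodes <- as.list(sample(labels))
    while (length(nodes) > 1) {
      i <- sample.int(length(nodes), 2)
      nodes <- c(nodes[-i], list(paste0("(", nodes[[i[1]]], ":1,",
                                        nodes[[i[2]]], ":1):1")))
    }
    nodes[[1]]
  }
  mams <- panel$species[panel$clade == "mammal"]
  nons <- panel$species[panel$clade == "non_mammal"]
  frag <- function(labels) if (length(labels) == 1)
    paste0(labels, ":1") else rand_clade(labels)
  nwk <- paste0("(", frag(nons), ",", frag(mams), ");")
  ape::read.tree(text = nwk)
}

# mutate each site with probability p to a uniformly chosen different base
mutate_seq <- function(bases, p) {
  hit <- runif(length(bases)) < p
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(alt, b), 1), character(1))
  }
  bases
}

#' Simulate homologous sequences containing one planted transfer
#'
#' Evolves a root sequence down the species tree under a Jukes-Cantor-style
#' single-parameter process (each site substitutes with probability
#' \code{rate} per branch), then overwrites the recipient's sequence with a
#' near-copy of the donor's — the signature of a recent horizontal transfer.
#' The expected gene-tree topology is the species tree with the recipient
#' regrafted as sister to the donor, which sits exactly one rooted SPR move
#' away whenever donor and recipient were not sisters already.
#'
#' @param species_tree rooted binary \code{phylo} tree.
#' @param donor,recipient leaf labels; the recipient's lineage received the
#'   transferred copy.
#' @param length sequence length, bp.
#' @param rate per-site substitution probability per branch.
#' @param seed RNG seed.
#' @param transfer_divergence per-site divergence of the transferred copy
#'   from the donor (default 0.01).
#' @return list with \code{sequences} (named character vector) and
#'   \code{expected_topology} (\code{phylo}).
#' @export
simulate_transfer_sequences <- function(species_tree, donor, recipient,
                                        length = 2000L, rate = 0.02,
                                        seed = 1L, transfer_divergence = 0.01) {
  if (donor == recipient) stop("donor and recipient must differ")
  tips <- species_tree$tip.label
  if (!all(c(donor, recipient) %in% tips))
    stop("donor and recipient must be leaves of the species tree")
  set.seed(seed)
  phy <- ape::reorder.phylo(species_tree, "postorder")
  n_tip <- length(tips)
  root <- n_tip + 1L
  seqs <- vector("list", max(phy$edge))
  seqs[[root]] <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # preorder traversal: parents before children
  for (i in rev(seq_len(nrow(phy$edge)))) {
    par <- phy$edge[i, 1]; child <- phy$edge[i, 2]
    seqs[[child]] <- mutate_seq(seqs[[par]], rate)
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  names(out) <- tips
  donor_b <- strsplit(out[[donor]], "")[[1]]
  out[[recipient]] <- paste(mutate_seq(donor_b, transfer_divergence),
                            collapse = "")
  expected <- regraft_as_sister(species_tree, recipient, donor)
  list(sequences = out, expected_topology = expected)
}

# drop `tip` from the tree and re-attach it as the sister of `sister`
regraft_as_sister <- function(phy, tip, sister) {
  t <- clade_from_phylo(phy)
  t <- clade_drop_leaf(t, tip)
  t <- clade_attach_sister(t, sister, tip)
  ape::read.tree(text = paste0(clade_newick(t), ";"))
}
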