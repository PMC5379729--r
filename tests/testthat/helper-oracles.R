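# Brute-force oracles, kept deliberately independent of the package's
# interval-algebra / canonical-form implementations.

# per-base caller oracle: explicit species-set arrays over a toy chromosome
oracle_caller <- function(blocks, panel, params, chrom_lengths) {
  nonmam <- panel$species[panel$clade == "non_mammal"]
  out <- NULL
  for (ch in sort(names(chrom_lengths))) {
    L <- chrom_lengths[[ch]]
    depth <- matrix(FALSE, nrow = length(nonmam), ncol = L,
                    dimnames = list(nonmam, NULL))
    b <- blocks[blocks$chrom == ch & blocks$species %in% nonmam &
                  blocks$identity >= params$min_identity, , drop = FALSE]
    for (i in seq_len(nrow(b)))
      depth[b$species[i], (b$start[i] + 1):b$end[i]] <- TRUE
    deep <- colSums(depth) >= params$min_nonmammal_species
    # merge runs separated by <= merge_gap of shallow bases
    r <- rle(deep)
    if (params$merge_gap > 0) {
      idx <- which(!r$values & r$lengths <= params$merge_gap)
      idx <- idx[idx > 1 & idx < length(r$values)]
      r$values[idx] <- TRUE
      r <- rle(inverse.rle(r))
    }
    pos <- cumsum(c(0L, r$lengths))
    for (k in which(r$values)) {
      s <- as.integer(pos[k]); e <- as.integer(pos[k + 1])  # 0-based half-open
      if (e - s <= params$min_length) next
      sup <- oracle_mammal_support(ch, s, e, blocks, panel, params)
      if (length(sup) <= params$max_mammal_support)
        out <- rbind(out, data.frame(chrom = ch, start = s, end = e,
                                     n_mammal = length(sup),
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_mammal = integer())
  out[order(out$chrom, out$start), , drop = FALSE]
}

# per-base mammal support oracle for one region
oracle_mammal_support <- function(chrom, start, end, blocks, panel, params) {
  mams <- panel$species[panel$clade == "mammal"]
  b <- blocks[blocks$chrom == chrom & blocks$species %in% mams &
                blocks$identity >= params$mammal_min_identity, , drop = FALSE]
  len <- end - start
  sup <- character(0)
  for (sp in unique(b$species)) {
    covered <- logical(len)
    bb <- b[b$species == sp, , drop = FALSE]
    for (i in seq_len(nrow(bb))) {
      lo <- max(bb$start[i], start); hi <- min(bb$end[i], end)
      if (hi > lo) covered[(lo - start + 1):(hi - start)] <- TRUE
    }
    if (sum(covered) > params$mammal_min_coverage * len) sup <- c(sup, sp)
  }
  sort(sup)
}

# random block configuration on small chromosomes
random_block_config <- function(n_blocks, panel, chrom_lengths,
                                identity_range = c(0, 1)) {
  chroms <- names(chrom_lengths)
  ch <- sample(chroms, n_blocks, replace = TRUE)
  L <- unname(unlist(chrom_lengths[ch]))
  len <- pmax(50L, as.integer(rlnorm(n_blocks, log(800), 0.8)))
  len <- pmin(len, L - 1L)
  start <- as.integer(floor(runif(n_blocks, 0, L - len)))
  data.frame(species = sample(panel$species, n_blocks, replace = TRUE),
             chrom = ch, start = start, end = start + len,
             identity = runif(n_blocks, identity_range[1], identity_range[2]),
             stringsAsFactors = FALSE)
}

# ---- rooted SPR oracle: graph BFS over the full 5-leaf tree space -------
# Uses ape surgery (drop.tip / string assembly), a code path independent of
# the package's clade-list search.

canon_newick <- function(phy) {
  # canonical newick by recursive child sorting on an ape phylo
  n_tip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(node) {
    if (node <= n_tip) return(phy$tip.label[node])
    ch <- sort(vapply(kids[[as.character(node)]], build, ""))
    paste0("(", paste(ch, collapse = ","), ")")
  }
  build(n_tip + 1L)
}

# all rooted SPR neighbors of a rooted binary phylo, via prune + re-attach
# performed on newick strings
spr_neighbors_oracle <- function(phy) {
  n_tip <- length(phy$tip.label)
  nodes <- setdiff(seq_len(n_tip + phy$Nnode), n_tip + 1L)  # non-root
  out <- character(0)
  for (v in nodes) {
    sub_tips <- if (v <= n_tip) phy$tip.label[v] else
      ape::extract.clade(phy, v)$tip.label
    if (length(sub_tips) == n_tip - 1) next   # remainder must keep >= 1 leaf
    sub_nwk <- if (v <= n_tip) phy$tip.label[v] else
      sub("\\);$", ")", sub(";$", "", ape::write.tree(ape::extract.clade(phy, v))))
    sub_nwk <- sub(";$", "", sub_nwk)
    rest <- ape::drop.tip(phy, sub_tips)
    # attach above every node of rest (including its root)
    n_rest <- length(rest$tip.label)
    for (w in seq_len(n_rest + rest$Nnode)) {
      rest_nwk <- sub(";$", "", ape::write.tree(rest))
      w_nwk <- if (w <= n_rest) rest$tip.label[w] else
        sub(";$", "", ape::write.tree(ape::extract.clade(rest, w)))
      # replace the subtree string of w by (sub,w); fixed = TRUE to avoid
      # regex surprises in labels
      new_nwk <- sub(w_nwk, paste0("(", sub_nwk, ",", w_nwk, ")"),
                     rest_nwk, fixed = TRUE)
      out <- c(out, canon_newick(ape::read.tree(text = paste0(new_nwk, ";"))))
    }
  }
  setdiff(unique(out), canon_newick(phy))
}

# all rooted binary topologies on the given leaves (via phangorn), as
# canonical newick strings plus the phylo objects
all_rooted_topologies <- function(labels) {
  trees <- phangorn::allTrees(length(labels), rooted = TRUE,
                              tip.label = labels)
  keys <- vapply(trees, canon_newick, "")
  list(trees = trees, keys = keys)
}

# all-pairs SPR distances on the full topology graph, by BFS from each node
spr_distance_graph <- function(topo) {
  n <- length(topo$keys)
  adj <- lapply(seq_len(n), function(i)
    match(spr_neighbors_oracle(topo$trees[[i]]), topo$keys))
  stopifnot(!anyNA(unlist(adj)))
  dist <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n); d[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(d[nxt])]
      d[nxt] <- d[frontier[1]] + 1L
      frontier <- nxt
    }
    dist[s, ] <- d
  }
  dist
}

# random rooted binary tree on given labels (test-side generator)
random_rooted_tree <- function(labels) {
  nwk <- labels
  while (length(nwk) > 1) {
    i <- sample.int(length(nwk), 2)
    nwk <- c(nwk[-i], paste0("(", nwk[i[1]], ",", nwk[i[2]], ")"))
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# small fixed panel for caller tests
toy_panel <- function(n_mam = 10, n_non = 4)
  species_panel(c(sprintf("mam%02d", seq_len(n_mam)),
                  sprintf("non%02d", seq_len(n_non))),
                rep(c("mammal", "non_mammal"), c(n_mam, n_non)))

block_row <- function(species, chrom, start, end, identity)
  data.frame(species = species, chrom = chrom, start = as.integer(start),
             end = as.integer(end), identity = identity,
             stringsAsFactors = FALSE)
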