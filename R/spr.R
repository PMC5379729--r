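# Exact rooted SPR (subtree prune and regraft) distance.
#
# Trees are handled internally as recursive "clade lists": a leaf is its
# label (character scalar), an internal node is list(child, child). Rooted
# SPR here is the planted-tree variant: a pruned subtree may be regrafted
# onto any edge of the remainder, including the edge above the current root
# (creating a new root), which makes the move set symmetric and the distance
# a metric.

# ---- clade-list primitives ---------------------------------------------

is_leaf <- function(t) is.character(t)

clade_leaves <- function(t) {
  if (is_leaf(t)) return(t)
  c(clade_leaves(t[[1]]), clade_leaves(t[[2]]))
}

# canonical form: children ordered by canonical string; two rooted trees are
# isomorphic iff their canonical strings are equal
clade_canonical <- function(t) {
  if (is_leaf(t)) return(t)
  a <- clade_canonical(t[[1]]); b <- clade_canonical(t[[2]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

clade_newick <- function(t) {
  if (is_leaf(t)) return(t)
  paste0("(", clade_newick(t[[1]]), ",", clade_newick(t[[2]]), ")")
}

# rooted binary phylo -> clade list; multifurcations are resolved
# deterministically (children sorted by smallest leaf label, combined
# left-to-right) with a warning
clade_from_phylo <- function(phy) {
  n_tip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  multif <- any(lengths(kids) > 2)
  if (multif)
    warning("multifurcating tree resolved deterministically for rooted SPR")
  build <- function(node) {
    if (node <= n_tip) return(phy$tip.label[node])
    ch <- lapply(kids[[as.character(node)]], build)
    ch <- ch[order(vapply(ch, function(x) min(clade_leaves(x)), ""))]
    while (length(ch) > 2) ch <- c(list(list(ch[[1]], ch[[2]])), ch[-(1:2)])
    list(ch[[1]], ch[[2]])
  }
  build(n_tip + 1L)
}

clade_to_phylo <- function(t)
  ape::read.tree(text = paste0(clade_newick(t), ";"))

# drop one leaf, suppressing its parent
clade_drop_leaf <- function(t, label) {
  if (is_leaf(t)) {
    if (t == label) stop("cannot drop the whole tree")
    return(t)
  }
  for (i in 1:2) {
    if (is_leaf(t[[i]]) && t[[i]] == label) return(t[[3 - i]])
  }
  list(clade_drop_leaf(t[[1]], label), clade_drop_leaf(t[[2]], label))
}

# attach `new` (a clade or leaf label) as sister of the node whose leaf set
# is exactly `target` (a leaf label here)
clade_attach_sister <- function(t, target, new) {
  if (is_leaf(t)) {
    if (t == target) return(list(t, new))
    return(t)
  }
  list(clade_attach_sister(t[[1]], target, new),
       clade_attach_sister(t[[2]], target, new))
}

# ---- SPR neighborhood ---------------------------------------------------

# all (pruned subtree, remainder) pairs; pruning any non-root node
prune_options <- function(t) {
  out <- list()
  recurse <- function(node, rebuild) {
    if (!is_leaf(node)) {
      for (i in 1:2) {
        sib <- node[[3 - i]]
        # prune child i entirely: remainder replaces node by sibling
        out[[length(out) + 1]] <<- list(sub = node[[i]], rem = rebuild(sib))
        recurse(node[[i]], function(x) rebuild(list(x, sib)))
      }
    }
  }
  recurse(t, function(x) x)
  # rebuild closures above capture sib by position; fix child order is not
  # semantically relevant (canonicalised downstream)
  out
}

# all regraft placements of `sub` onto edges of `rem` (above every node,
# including above the root); returns list of list(tree, graft) where graft
# is the sorted leafset string of the node below the new edge
regraft_options <- function(rem, sub) {
  out <- list()
  recurse <- function(node, rebuild) {
    key <- paste(sort(clade_leaves(node)), collapse = ",")
    out[[length(out) + 1]] <<- list(tree = rebuild(list(sub, node)),
                                    graft = key)
    if (!is_leaf(node)) {
      for (i in 1:2) {
        sib <- node[[3 - i]]
        recurse(node[[i]], function(x) rebuild(list(x, sib)))
      }
    }
  }
  recurse(rem, function(x) x)
  out
}

# all SPR neighbors of t with move annotations:
# move = list(prune = leafset string, graft = leafset string)
spr_neighbors <- function(t) {
  out <- list()
  for (po in prune_options(t)) {
    pkey <- paste(sort(clade_leaves(po$sub)), collapse = ",")
    for (ro in regraft_options(po$rem, po$sub)) {
      out[[length(out) + 1]] <- list(tree = ro$tree,
                                     move = list(prune = pkey,
                                                 graft = ro$graft))
    }
  }
  out
}

# ---- common pendant subtree reduction ----------------------------------

# collect canonical strings of all internal clades (not the root, not leaves)
collect_clades <- function(t, acc = character(0), is_root = TRUE) {
  if (is_leaf(t)) return(acc)
  if (!is_root) acc <- c(acc, clade_canonical(t))
  acc <- collect_clades(t[[1]], acc, FALSE)
  collect_clades(t[[2]], acc, FALSE)
}

# replace maximal clades whose canonical form occurs in `common` by a
# single leaf named for the clade
collapse_by <- function(t, common, is_root = TRUE) {
  if (is_leaf(t)) return(t)
  key <- clade_canonical(t)
  if (!is_root && key %in% common) return(paste0("{", key, "}"))
  list(collapse_by(t[[1]], common, FALSE), collapse_by(t[[2]], common, FALSE))
}

collapse_common_pendants <- function(a, b) {
  common <- intersect(collect_clades(a), collect_clades(b))
  list(a = collapse_by(a, common), b = collapse_by(b, common))
}

# ---- move application and search ---------------------------------------

# apply one recorded move to a clade tree; clades are identified by their
# sorted-leafset key (leaf labels may themselves contain punctuation after
# pendant collapsing, so keys are compared whole, never re-split)
leafset_key <- function(t) paste(sort(clade_leaves(t)), collapse = ",")

apply_spr_move <- function(t, move) {
  found <- NULL
  detach <- function(node) {
    if (identical(leafset_key(node), move$prune)) {
      found <<- node
      return(NULL)
    }
    if (is_leaf(node)) return(node)
    a <- detach(node[[1]]); b <- detach(node[[2]])
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(a, b)
  }
  rem <- detach(t)
  if (is.null(found)) stop("witness prune clade not found in tree")
  done <- FALSE
  attach <- function(node) {
    if (!done && identical(leafset_key(node), move$graft)) {
      done <<- TRUE
      return(list(found, node))
    }
    if (is_leaf(node)) return(node)
    list(attach(node[[1]]), attach(node[[2]]))
  }
  res <- attach(rem)
  if (!done) stop("witness graft edge not found in tree")
  res
}

#' Exact rooted SPR distance between two trees
#'
#' Computes the minimum number of rooted subtree-prune-and-regraft moves
#' transforming tree \code{a} into tree \code{b}, by breadth-first search
#' over SPR neighborhoods with canonical-form deduplication, after first
#' collapsing maximal pendant subtrees common to both trees (a standard
#' distance-preserving kernelization). Returns one witness move sequence;
#' each move names the pruned clade (its leaf set) and the clade above whose
#' edge it was regrafted. The witness is replayed internally as a
#' correctness check before returning.
#'
#' Each SPR move needed to reconcile a gene tree with the species tree
#' lower-bounds one reticulation (here: horizontal transfer) event, which is
#' how [count_hgt_events()] uses this distance.
#'
#' @param a,b rooted binary \code{phylo} trees on the same leaf set
#'   (multifurcations are resolved deterministically with a warning).
#' @param max_d search cap; if the distance exceeds it the result is flagged
#'   \code{bounded} with \code{distance = NA} rather than failing.
#' @param max_leaves guard on exact-search problem size (default 12).
#' @return list of class \code{spr_result}: \code{distance}, \code{moves}
#'   (list of prune/graft leaf-set pairs, on the reduced trees),
#'   \code{bounded}, and \code{stats} (visited count, reduced leaf count).
#' @export
spr_distance <- function(a, b, max_d = 6L, max_leaves = 12L) {
  la <- sort(a$tip.label); lb <- sort(b$tip.label)
  if (!identical(la, lb)) stop("trees must share an identical leaf set")
  if (length(la) > max_leaves)
    stop("exact SPR search limited to ", max_leaves,
         " leaves; prune the trees or raise max_leaves")
  ta <- clade_from_phylo(a); tb <- clade_from_phylo(b)
  red <- collapse_common_pendants(ta, tb)
  ta <- red$a; tb <- red$b
  target <- clade_canonical(tb)
  start <- clade_canonical(ta)
  result <- function(d, moves, visited) {
    res <- structure(list(distance = d, moves = moves, bounded = FALSE,
                          stats = list(visited = visited,
                                       reduced_leaves = length(clade_leaves(ta)))),
                     class = "spr_result")
    # witness replay check
    t <- ta
    for (mv in moves) t <- apply_spr_move(t, mv)
    stopifnot(identical(clade_canonical(t), target))
    res
  }
  if (identical(start, target)) return(result(0L, list(), 1L))
  # BFS with parent pointers for witness reconstruction
  visited <- new.env(parent = emptyenv())
  assign(start, list(prev = NA, move = NULL, tree = ta), envir = visited)
  frontier <- list(ta)
  frontier_keys <- start
  for (depth in seq_len(max_d)) {
    nxt <- list(); nxt_keys <- character(0)
    for (fi in seq_along(frontier)) {
      for (nb in spr_neighbors(frontier[[fi]])) {
        key <- clade_canonical(nb$tree)
        if (exists(key, envir = visited, inherits = FALSE)) next
        assign(key, list(prev = frontier_keys[fi], move = nb$move,
                         tree = nb$tree), envir = visited)
        if (identical(key, target)) {
          moves <- list()
          k <- key
          repeat {
            rec <- get(k, envir = visited, inherits = FALSE)
            if (is.null(rec$move)) break
            moves <- c(list(rec$move), moves)
            k <- rec$prev
          }
          return(result(depth, moves,
                        length(ls(envir = visited))))
        }
        nxt[[length(nxt) + 1]] <- nb$tree
        nxt_keys <- c(nxt_keys, key)
      }
    }
    frontier <- nxt; frontier_keys <- nxt_keys
    if (length(frontier) == 0) break
  }
  structure(list(distance = NA_integer_, moves = list(), bounded = TRUE,
                 stats = list(visited = length(ls(envir = visited)),
                              reduced_leaves = length(clade_leaves(ta)))),
            class = "spr_result")
}

#' @export
print.spr_result <- function(x, ...) {
  if (x$bounded)
    cat("rooted SPR distance: > search cap (bounded result)\n")
  else
    cat("rooted SPR distance:", x$distance, "\n")
  cat("  visited", x$stats$visited, "topologies;",
      x$stats$reduced_leaves, "leaves after common-subtree reduction\n")
  invisible(x)
}

#' One uniformly random rooted SPR move applied to a tree
#'
#' Utility for perturbation experiments: draws one neighbor of \code{phy}
#' uniformly from its rooted SPR neighborhood, excluding neighbors
#' topologically identical to the input.
#'
#' @param phy rooted binary \code{phylo}.
#' @return a \code{phylo} one SPR move away.
#' @export
random_spr_move <- function(phy) {
  t <- clade_from_phylo(phy)
  key <- clade_canonical(t)
  nbs <- spr_neighbors(t)
  nbs <- Filter(function(nb) !identical(clade_canonical(nb$tree), key), nbs)
  clade_to_phylo(nbs[[sample.int(length(nbs), 1)]]$tree)
}
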