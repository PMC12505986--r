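# Tree-sample I/O and clade bookkeeping. Trees are ape "phylo" objects,
# required rooted and binary; the common taxon order is the sorted label set.

#' Read a posterior tree sample
#'
#' Reads Newick (one tree per line) or a NEXUS trees block (numeric translate
#' tables are resolved by \code{ape::read.nexus}), drops the first
#' \code{floor(burnin_fraction * N)} trees, and fixes the taxon order to the
#' sorted label set. All trees must be rooted, binary, and share one taxon
#' set.
#'
#' @param path tree file (Newick or NEXUS)
#' @param burnin_fraction proportion of initial trees to discard (default 0.1)
#' @return object of class \code{stator_treesample} with elements
#'   \code{trees} (multiPhylo), \code{taxa}, \code{burnin_fraction},
#'   \code{n_input}, \code{n_used}
#' @export
read_tree_sample <- function(path, burnin_fraction = 0.1) {
  first <- toupper(trimws(readLines(path, n = 1)))
  trees <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # single tree -> multiPhylo
  tree_sample(trees, burnin_fraction = burnin_fraction)
}

#' Build a tree sample object from a list of trees
#'
#' @param trees a multiPhylo or list of phylo objects
#' @param burnin_fraction proportion of initial trees to discard
#' @return a \code{stator_treesample}
#' @export
tree_sample <- function(trees, burnin_fraction = 0) {
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stopf("burnin_fraction must be in [0, 1)")
  if (!is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) stopf("empty tree sample")
  taxa <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!ape::is.rooted(tr))
      stopf("tree %d is unrooted; rooted trees are required", i)
    if (!ape::is.binary(tr))
      stopf("tree %d is not binary", i)
    if (!identical(sort(tr$tip.label), taxa))
      stopf("tree %d has a different taxon set than tree 1", i)
  }
  n_in <- length(trees)
  drop <- floor(burnin_fraction * n_in)
  if (drop >= n_in) stopf("burn-in removes all trees")
  kept <- trees[seq(drop + 1, n_in)]
  class(kept) <- "multiPhylo"
  structure(list(trees = kept, taxa = taxa,
                 burnin_fraction = burnin_fraction,
                 n_input = n_in, n_used = length(kept)),
            class = "stator_treesample")
}

#' @export
print.stator_treesample <- function(x, ...) {
  cat(sprintf("Tree sample: %d trees (%d read, burn-in %.0f%%), %d taxa\n",
              x$n_used, x$n_input, 100 * x$burnin_fraction,
              length(x$taxa)))
  invisible(x)
}

#' Write a tree sample as Newick
#'
#' @param sample a \code{stator_treesample}
#' @param path output path (one Newick string per line)
#' @export
write_tree_sample <- function(sample, path) {
  ape::write.tree(sample$trees, file = path)
  invisible(path)
}

# --- clade machinery -------------------------------------------------------
# A clade is the set of taxon indices (in the sample's sorted taxon order) of
# the leaves below a node. Keys are space-separated sorted indices; bitstrings
# ("0101...") give the deterministic tie-break order.

#' @keywords internal
#' @noRd
clade_key <- function(idx) paste(idx, collapse = " ")

#' @keywords internal
#' @noRd
key_size <- function(key) lengths(strsplit(key, " ", fixed = TRUE))

#' @keywords internal
#' @noRd
key_bitstring <- function(key, n_taxa) {
  idx <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
  b <- rep("0", n_taxa); b[idx] <- "1"
  paste(b, collapse = "")
}

# Per-tree clade sets and splits. Returns list(clades = character keys of all
# internal-node clades incl. root, splits = data.frame(parent,left,right)).
# Children are ordered so "left" contains the parent's smallest taxon index.
#' @keywords internal
#' @noRd
tree_splits <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tipidx <- match(tree$tip.label, taxa)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tipidx[i]
  e <- po$edge
  for (k in seq_len(nrow(e)))
    sets[[e[k, 1]]] <- c(sets[[e[k, 1]]], sets[[e[k, 2]]])
  internal <- seq(ntip + 1, ntip + nnode)
  keys <- character(ntip + nnode)
  for (v in seq_len(ntip + nnode)) keys[v] <- clade_key(sort(sets[[v]]))
  parent <- e[, 1]; child <- e[, 2]
  sp <- lapply(internal, function(v) {
    ch <- child[parent == v]
    k1 <- keys[ch[1]]; k2 <- keys[ch[2]]
    m1 <- min(sets[[ch[1]]]); m2 <- min(sets[[ch[2]]])
    if (m1 < m2) c(keys[v], k1, k2) else c(keys[v], k2, k1)
  })
  sp <- do.call(rbind, sp)
  list(clades = keys[internal],
       splits = data.frame(parent = sp[, 1], left = sp[, 2], right = sp[, 3],
                           stringsAsFactors = FALSE))
}

#' Count distinct clades in a tree sample
#'
#' The number of distinct clades of size >= 2 (root clade included, singleton
#' leaves excluded) observed across the retained trees. The counting
#' convention matters when comparing published clade counts, so it is part of
#' the contract; \code{include_root = FALSE} gives the alternative convention.
#'
#' @param sample a \code{stator_treesample}
#' @param include_root count the (always-present) root clade? default TRUE
#' @return integer count of distinct clades
#' @export
count_clades <- function(sample, include_root = TRUE) {
  all_keys <- unique(unlist(lapply(sample$trees, function(tr)
    tree_splits(tr, sample$taxa)$clades)))
  if (!include_root) {
    root_key <- clade_key(seq_along(sample$taxa))
    all_keys <- setdiff(all_keys, root_key)
  }
  length(all_keys)
}
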