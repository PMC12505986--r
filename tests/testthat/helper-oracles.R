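# Independent oracles used to check the package's implementations. These are
# deliberately naive (enumeration, double loops) and share no code with the
# implementation paths they verify.

# all rooted binary labeled topologies on a taxon set, as newick strings
all_rooted_topologies <- function(taxa) {
  if (length(taxa) == 1) return(taxa)
  rest <- taxa[-1]
  out <- character(0)
  for (m in 0:(2^length(rest) - 1)) {
    bits <- as.logical(intToBits(m)[seq_along(rest)])
    left <- c(taxa[1], rest[bits])
    right <- rest[!bits]
    if (length(right) == 0) next
    for (l in all_rooted_topologies(left))
      for (r in all_rooted_topologies(right))
        out <- c(out, sprintf("(%s,%s)", l, r))
  }
  out
}

# brute-force entropy: enumerate every topology in the CCD's support with its
# probability (product of conditional split probabilities), then -sum p ln p
oracle_ccd_entropy <- function(ccd) {
  splits <- ccd$splits
  rec <- function(key) {
    size <- length(strsplit(key, " ", fixed = TRUE)[[1]])
    if (size <= 2) return(1)
    sp <- splits[splits$parent == key, , drop = FALSE]
    out <- numeric(0)
    for (i in seq_len(nrow(sp)))
      out <- c(out, sp$prob[i] * as.vector(outer(rec(sp$left[i]),
                                                 rec(sp$right[i]))))
    out
  }
  root_key <- paste(seq_along(ccd$taxa), collapse = " ")
  p <- rec(root_key)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  -sum(p * log(p))
}

# brute-force distinct-clade count: set union of per-tree clades, computed
# from scratch with ape's prop.part-free traversal
oracle_count_clades <- function(sample) {
  taxa <- sample$taxa
  keys <- character(0)
  for (tr in sample$trees) {
    ntip <- length(tr$tip.label)
    for (v in seq(ntip + 1, ntip + tr$Nnode)) {
      tips <- ape::extract.clade(tr, v)$tip.label
      keys <- c(keys, paste(sort(match(tips, taxa)), collapse = " "))
    }
  }
  length(unique(keys))
}

# brute-force column likelihood: sum over all internal-state assignments
oracle_pruning <- function(tree, states_vec, model) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  k <- model$n_states
  tipidx <- match(states_vec[tree$tip.label], model$states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  p <- model$freqs[combos[, 1]]   # root is node ntip+1, first internal
  for (e in seq_len(nrow(tree$edge))) {
    P <- transition_matrix(model, tree$edge.length[e])
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sp <- combos[, par - ntip]
    if (ch <= ntip) {
      if (is.na(tipidx[ch])) next    # missing tip marginalizes to 1
      p <- p * P[cbind(sp, tipidx[ch])]
    } else {
      p <- p * P[cbind(sp, combos[, ch - ntip])]
    }
  }
  log(sum(p))
}

# brute-force marginal posterior at one internal node for one column
oracle_marginal <- function(tree, states_vec, model, node) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  k <- model$n_states
  tipidx <- match(states_vec[tree$tip.label], model$states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  p <- model$freqs[combos[, 1]]
  for (e in seq_len(nrow(tree$edge))) {
    P <- transition_matrix(model, tree$edge.length[e])
    sp <- combos[, tree$edge[e, 1] - ntip]
    ch <- tree$edge[e, 2]
    if (ch <= ntip) {
      if (is.na(tipidx[ch])) next
      p <- p * P[cbind(sp, tipidx[ch])]
    } else p <- p * P[cbind(sp, combos[, ch - ntip])]
  }
  post <- vapply(seq_len(k), function(s)
    sum(p[combos[, node - ntip] == s]), numeric(1))
  post / sum(post)
}

# naive mean pairwise identity via per-character loops
oracle_mpi <- function(rows) {
  ids <- numeric(0)
  n <- length(rows)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- strsplit(rows[[i]], "")[[1]]
    b <- strsplit(rows[[j]], "")[[1]]
    denom <- 0; same <- 0
    for (c in seq_along(a)) {
      if (a[c] != "-" && b[c] != "-") {
        denom <- denom + 1
        if (a[c] == b[c] && a[c] != "X") same <- same + 1
      }
    }
    ids <- c(ids, if (denom == 0) 0 else 100 * same / denom)
  }
  mean(ids)
}

# character-counting oracle for plug composition
oracle_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  gg <- 0L
  if (length(ch) >= 2)
    for (i in seq_len(length(ch) - 1)) if (ch[i] == "G" && ch[i + 1] == "G")
      gg <- gg + 1L
  list(length = length(ch), gly = sum(ch == "G"), pro = sum(ch == "P"),
       gg = gg)
}

random_tree_sample <- function(n_taxa, n_trees, seed, nni_rate = 3) {
  base <- gen_yule_tree(n_taxa, 1, seed = seed)
  gen_tree_sample(base, nni_rate, n_trees, seed = seed + 1)
}
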