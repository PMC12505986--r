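# Synthetic-data generators with planted ground truth. Every generator is
# driven by one integer seed and returns a manifest sufficient to score the
# downstream stage automatically. Posterior spread is emulated by random NNI
# perturbation of a base tree (the package tests entropy computation, not
# MCMC); the indel process is block-wise binary presence, matching the
# presence-absence gap reconstruction it feeds.

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_taxa number of leaves (>= 2)
#' @param birth_rate speciation rate (per lineage per unit time)
#' @param seed integer seed
#' @return rooted binary \code{phylo} with branch lengths, tips t1..tn
#' @export
gen_yule_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 2) stopf("n_taxa must be >= 2")
  with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
}

# one random rooted NNI move (swap a random child of an internal node with
# that node's sibling)
#' @keywords internal
#' @noRd
rooted_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  cand <- which(tree$edge[, 2] > ntip)   # edges whose child is internal
  if (length(cand) == 0) return(tree)
  e <- cand[sample.int(length(cand), 1)]
  u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
  vkids <- which(tree$edge[, 1] == v)
  sib <- which(tree$edge[, 1] == u & tree$edge[, 2] != v)
  k <- vkids[sample.int(2, 1)]
  tmp <- tree$edge[k, 2]
  tree$edge[k, 2] <- tree$edge[sib, 2]
  tree$edge[sib, 2] <- tmp
  ape::reorder.phylo(tree, "cladewise")
}

#' Emulate a tree posterior by NNI perturbation
#'
#' Each sampled tree is the base topology with Poisson(\code{nni_rate})
#' random nearest-neighbor-interchange moves applied; \code{nni_rate = 0}
#' gives a degenerate (topologically constant) sample. Larger rates emulate
#' posteriors with more topological spread.
#'
#' @param base rooted binary \code{phylo}
#' @param nni_rate expected NNI moves per sampled tree (>= 0)
#' @param n_trees number of trees
#' @param seed integer seed
#' @return a \code{stator_treesample}
#' @export
gen_tree_sample <- function(base, nni_rate, n_trees = 100, seed = 1) {
  if (nni_rate < 0) stopf("nni_rate must be >= 0")
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    tr <- base
    for (m in seq_len(stats::rpois(1, nni_rate))) tr <- rooted_nni(tr)
    tr
  }))
  class(trees) <- "multiPhylo"
  tree_sample(trees, burnin_fraction = 0)
}

# simulate discrete states down a tree; returns (ntip+nnode) x n_cols integer
# matrix of state indices
#' @keywords internal
#' @noRd
simulate_states <- function(tree, model, n_cols) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  k <- model$n_states
  states <- matrix(NA_integer_, nn, n_cols)
  root <- ntip + 1L
  states[root, ] <- sample.int(k, n_cols, replace = TRUE, prob = model$freqs)
  e <- ape::reorder.phylo(tree, "postorder")$edge
  el <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (i in rev(seq_len(nrow(e)))) {   # reverse postorder = preorder
    P <- transition_matrix(model, el[i])
    par <- states[e[i, 1], ]
    ch <- integer(n_cols)
    for (s in unique(par))
      ch[par == s] <- sample.int(k, sum(par == s), replace = TRUE,
                                 prob = P[s, ])
    states[e[i, 2], ] <- ch
  }
  states
}

#' Simulate an alignment with indel blocks on a known tree
#'
#' Residues evolve under the given substitution model. Columns are grouped
#' into blocks with geometric lengths (mean \code{mean_gap_len}); each
#' block's presence/absence evolves as a reversible binary character with
#' overall rate \code{indel_rate} (stationary presence probability 0.7).
#' The returned truth contains the full residue states and presence matrix
#' for every node, including internal ones.
#'
#' @param tree rooted binary \code{phylo} with branch lengths
#' @param model a \code{stator_ratemodel} (default LG)
#' @param n_cols alignment columns
#' @param indel_rate rate of the binary presence process (0 = no gaps)
#' @param mean_gap_len mean block length in columns
#' @param seed integer seed
#' @param presence_stationary stationary probability that a block is present
#' @return list: \code{aln} (a \code{stator_alignment} of the tips),
#'   \code{truth} with node_states (node x col state indices), presence
#'   (node x col logical), node_sequences (character, gaps applied),
#'   blocks, states, tree
#' @export
gen_alignment <- function(tree, model = rate_model("LG"), n_cols = 100,
                          indel_rate = 0.1, mean_gap_len = 6, seed = 1,
                          presence_stationary = 0.7) {
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    states <- simulate_states(tree, model, n_cols)
    presence <- matrix(TRUE, nn, n_cols)
    blocks <- NULL
    if (indel_rate > 0) {
      lens <- integer(0)
      while (sum(lens) < n_cols)
        lens <- c(lens, 1L + stats::rgeom(1, 1 / mean_gap_len))
      ends <- pmin(cumsum(lens), n_cols)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      keep <- starts <= n_cols
      blocks <- data.frame(start = starts[keep], end = ends[keep])
      gap_model <- rate_model("binary",
                              freqs = c(1 - presence_stationary,
                                        presence_stationary))
      tree_scaled <- tree
      tree_scaled$edge.length <- tree$edge.length * indel_rate
      bstates <- simulate_states(tree_scaled, gap_model, nrow(blocks))
      for (b in seq_len(nrow(blocks)))
        presence[, blocks$start[b]:blocks$end[b]] <- bstates[, b] == 2L
    }
    node_names <- c(tree$tip.label, as.character(seq(ntip + 1, nn)))
    seqs <- vapply(seq_len(nn), function(v) {
      ch <- model$states[states[v, ]]
      ch[!presence[v, ]] <- "-"
      paste(ch, collapse = "")
    }, character(1))
    names(seqs) <- node_names
    rownames(states) <- node_names
    rownames(presence) <- node_names
    list(aln = alignment(seqs[seq_len(ntip)]),
         truth = list(node_states = states, presence = presence,
                      node_sequences = seqs, blocks = blocks,
                      states = model$states, tree = tree),
         seed = seed)
  })
}

#' Plant a toy genome with A-B operons, decoys and duplicated-A loci
#'
#' Builds a single-contig annotated genome in which each planted operon has
#' an A gene with the B gene directly downstream on the same strand, plus
#' decoy genes (placed farther downstream than the true B, or in their own
#' windows) and duplicated-A loci (two A genes within 10 kb, each with a
#' downstream partner). Writes a GFF3 file, a hit TSV (planted A genes with
#' similarity >= 10, decoys below 10) and a JSON manifest with the planted
#' truth.
#'
#' @param n_operons number of planted A-B operons
#' @param n_decoys number of decoy genes
#' @param n_duplicated number of duplicated-A loci (2 A genes each)
#' @param gap_bp_range intergenic gap range (bp) for planted pairs
#' @param seed integer seed
#' @param dir output directory (created); files genome.gff3, hits.tsv,
#'   manifest.json
#' @return (invisibly) the manifest list
#' @export
gen_operon_genome <- function(n_operons = 30, n_decoys = 5, n_duplicated = 2,
                              gap_bp_range = c(5, 200), seed = 1,
                              dir = tempfile("operons")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    genes <- list()
    hits <- list()
    truth_pairs <- list()
    dup_ids <- character(0)
    decoy_ids <- character(0)
    window <- 20000L
    add_gene <- function(id, start, end, strand, product) {
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = id, start = start, end = end, strand = strand,
        product = product, stringsAsFactors = FALSE)
    }
    w <- 0L
    for (i in seq_len(n_operons)) {
      o <- w * window; w <- w + 1L
      strand <- sample(c("+", "-"), 1)
      gap <- sample(seq(gap_bp_range[1], gap_bp_range[2]), 1)
      aid <- sprintf("opA_%03d", i); bid <- sprintf("opB_%03d", i)
      if (strand == "+") {
        add_gene(aid, o + 1000L, o + 1900L, "+", "stator A subunit")
        add_gene(bid, o + 1900L + gap, o + 1900L + gap + 700L, "+",
                 "MotB-family stator B subunit")
      } else {
        add_gene(aid, o + 3000L, o + 3900L, "-", "stator A subunit")
        add_gene(bid, o + 3000L - gap - 700L, o + 3000L - gap, "-",
                 "MotB-family stator B subunit")
      }
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = aid, similarity_pct = round(stats::runif(1, 15, 95), 1),
        source = "iter1", stringsAsFactors = FALSE)
      truth_pairs[[length(truth_pairs) + 1L]] <-
        list(a_gene = aid, b_gene = bid, strand = strand, gap_bp = gap)
    }
    for (d in seq_len(n_duplicated)) {
      o <- w * window; w <- w + 1L
      for (rep in 1:2) {
        aid <- sprintf("dupA_%02d_%d", d, rep)
        base <- o + 1000L + (rep - 1L) * 3000L     # 3 kb apart: within 10 kb
        add_gene(aid, base, base + 900L, "+", "stator A subunit (duplicated)")
        add_gene(sprintf("dupB_%02d_%d", d, rep), base + 950L, base + 1650L,
                 "+", "stator B subunit")
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = aid, similarity_pct = round(stats::runif(1, 40, 95), 1),
          source = "iter1", stringsAsFactors = FALSE)
        dup_ids <- c(dup_ids, aid)
      }
    }
    for (k in seq_len(n_decoys)) {
      did <- sprintf("decoy_%02d", k)
      decoy_ids <- c(decoy_ids, did)
      if (k <= n_operons) {
        # farther downstream than the true B of operon k, same strand
        tp <- truth_pairs[[k]]
        o <- (k - 1L) * window
        if (tp$strand == "+")
          add_gene(did, o + 5000L, o + 5600L, "+", "hypothetical protein")
        else
          add_gene(did, o + 200L, o + 800L, "-", "hypothetical protein")
      } else {
        o <- w * window; w <- w + 1L
        add_gene(did, o + 1000L, o + 1600L, sample(c("+", "-"), 1),
                 "hypothetical protein")
      }
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = did, similarity_pct = round(stats::runif(1, 0, 9.8), 1),
        source = "iter1", stringsAsFactors = FALSE)
    }
    gdf <- do.call(rbind, genes)
    gr <- GenomicRanges::GRanges(
      seqnames = "contig1",
      ranges = IRanges::IRanges(start = gdf$start + 1L, end = gdf$end),
      strand = gdf$strand)
    gr$type <- "gene"
    gr$ID <- gdf$gene_id
    gr$product <- gdf$product
    gff <- file.path(dir, "genome.gff3")
    rtracklayer::export(gr, gff, format = "gff3")
    hdf <- do.call(rbind, hits)
    utils::write.table(hdf, file.path(dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(seed = seed,
                     parameters = list(n_operons = n_operons,
                                       n_decoys = n_decoys,
                                       n_duplicated = n_duplicated,
                                       gap_bp_range = gap_bp_range),
                     genome_id = "genome", contig = "contig1",
                     pairs = truth_pairs, duplicated_a = dup_ids,
                     decoys = decoy_ids,
                     files = list(gff = "genome.gff3", hits = "hits.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  })
}

#' Generate two plug+linker sequence groups with planted effects
#'
#' Emulates the flagellar (FIT) vs generic (GIT) comparison: FIT-like
#' sequences are longer and glycine/proline-richer. Lengths are Poisson with
#' the given means; residues are drawn i.i.d. with the given glycine and
#' proline probabilities (remaining mass spread over the other 18 residues).
#' Defaults reflect the study conditions: 102 flagellar vs 277 non-flagellar
#' sequences, a FIT reference plug+linker of 52 residues with 6/52 glycines
#' and 5/52 prolines, and a shorter, glycine-poorer GIT group.
#'
#' @param n_a,n_b group sizes (FIT-like, GIT-like)
#' @param len_means mean lengths c(FIT, GIT)
#' @param gly_probs glycine probabilities c(FIT, GIT)
#' @param pro_probs proline probabilities c(FIT, GIT)
#' @param seed integer seed
#' @return list with \code{fit}, \code{git} (named character vectors),
#'   \code{groups} (seq_id -> "TGI5"/"CCD2" map), \code{manifest}
#' @export
gen_plug_groups <- function(n_a = 102, n_b = 277,
                            len_means = c(52, 35),
                            gly_probs = c(0.115, 0.06),
                            pro_probs = c(0.096, 0.05),
                            seed = 1) {
  with_seed(seed, {
    draw <- function(n, len_mean, pg, pp, prefix) {
      others <- setdiff(AA20, c("G", "P"))
      probs <- c(pg, pp, rep((1 - pg - pp) / 18, 18))
      pool <- c("G", "P", others)
      seqs <- vapply(seq_len(n), function(i) {
        L <- stats::rpois(1, len_mean)
        if (L == 0) return("")
        paste(sample(pool, L, replace = TRUE, prob = probs), collapse = "")
      }, character(1))
      stats::setNames(seqs, sprintf("%s_%03d", prefix, seq_len(n)))
    }
    fit <- draw(n_a, len_means[1], gly_probs[1], pro_probs[1], "FIT")
    git <- draw(n_b, len_means[2], gly_probs[2], pro_probs[2], "GIT")
    groups <- c(stats::setNames(rep("TGI5", n_a), names(fit)),
                stats::setNames(rep("CCD2", n_b), names(git)))
    list(fit = fit, git = git, groups = groups,
         manifest = list(seed = seed, n_a = n_a, n_b = n_b,
                         len_means = len_means, gly_probs = gly_probs,
                         pro_probs = pro_probs))
  })
}
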