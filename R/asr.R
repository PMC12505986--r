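# Marginal ancestral state reconstruction on a fixed rooted tree via
# Felsenstein's pruning algorithm. Two model presets: a 2-state reversible
# chain for presence-absence (gap) characters, and LG+F for amino acids
# (LG exchangeabilities taken from phangorn's bundled model data,
# equilibrium frequencies supplied or estimated from the data). Q is
# normalized so branch lengths are expected substitutions per site.

#' Construct a reversible substitution rate model
#'
#' @param preset "binary" (2 states, equal exchange rate) or "LG"
#'   (20 amino-acid states, LG exchangeabilities). Use \code{exchangeabilities}
#'   and \code{freqs} for a custom model.
#' @param freqs equilibrium frequencies (sum to 1). Defaults: uniform for
#'   binary; LG's own frequencies for "LG" (override with observed
#'   frequencies for +F behavior).
#' @param exchangeabilities symmetric matrix of exchange rates (custom models)
#' @param states state labels; defaults \code{c("0","1")} or the 20 amino
#'   acids
#' @return object of class \code{stator_ratemodel} with the normalized
#'   generator and its symmetric eigendecomposition
#' @export
rate_model <- function(preset = c("binary", "LG", "custom"), freqs = NULL,
                       exchangeabilities = NULL, states = NULL) {
  preset <- match.arg(preset)
  if (preset == "binary") {
    k <- 2
    S <- matrix(1, 2, 2); diag(S) <- 0
    states <- states %||% c("0", "1")
    freqs <- freqs %||% rep(0.5, 2)
  } else if (preset == "LG") {
    lg <- get(".LG", envir = asNamespace("phangorn"))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- lg$Q
    S <- S + t(S)
    states <- states %||% AA20
    freqs <- freqs %||% unname(lg$bf)
  } else {
    if (is.null(exchangeabilities) || is.null(freqs))
      stopf("custom models need exchangeabilities and freqs")
    S <- exchangeabilities
    states <- states %||% as.character(seq_len(nrow(S)))
  }
  k <- length(freqs)
  if (abs(sum(freqs) - 1) > 1e-8) stopf("frequencies must sum to 1")
  if (!isTRUE(all.equal(S, t(S)))) stopf("exchangeabilities must be symmetric")
  Q <- S %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))          # expected rate under equilibrium
  Q <- Q / mu
  # reversible: D^{1/2} Q D^{-1/2} is symmetric; eigendecompose once
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(n_states = k, states = states, freqs = freqs, Q = Q,
                 eigvec = eig$vectors, eigval = eig$values, sqrt_f = d),
            class = "stator_ratemodel")
}

#' @export
print.stator_ratemodel <- function(x, ...) {
  cat(sprintf("Rate model: %d states (%s...)\n", x$n_states,
              paste(utils::head(x$states, 4), collapse = ",")))
  invisible(x)
}

#' Transition probability matrix exp(Q t)
#'
#' @param model a \code{stator_ratemodel}
#' @param t branch length (>= 0), expected substitutions per site
#' @return the n_states x n_states transition matrix
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stopf("negative branch length: %g", t)
  V <- model$eigvec
  P <- diag(1 / model$sqrt_f) %*% V %*% (exp(model$eigval * t) * t(V)) %*%
    diag(model$sqrt_f)
  P[P < 0] <- 0
  P / rowSums(P)
}

# --- internals -------------------------------------------------------------

# tip state matrix: integer matrix (n_tips x n_cols), NA = missing, in
# tree$tip.label row order
#' @keywords internal
#' @noRd
encode_tips <- function(tree, char_matrix, states) {
  if (!setequal(rownames(char_matrix), tree$tip.label))
    stopf("character matrix taxa must match tree tip labels exactly")
  m <- char_matrix[tree$tip.label, , drop = FALSE]
  enc <- matrix(match(m, states), nrow = nrow(m))
  rownames(enc) <- tree$tip.label
  enc
}

# post-order conditional likelihoods. Returns list(down = list over nodes of
# k x n_cols matrices, Pmats = per-edge transition matrices, order info).
#' @keywords internal
#' @noRd
prune_down <- function(tree, tips_enc, model) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ncol_ <- ncol(tips_enc)
  k <- model$n_states
  po <- ape::reorder.phylo(tree, "postorder")
  down <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    L <- matrix(0, k, ncol_)
    s <- tips_enc[i, ]
    miss <- is.na(s)
    if (any(miss)) L[, miss] <- 1
    if (any(!miss)) L[cbind(s[!miss], which(!miss))] <- 1
    down[[i]] <- L
  }
  Pmats <- vector("list", nrow(po$edge))
  for (v in unique(po$edge[, 1])) down[[v]] <- matrix(1, k, ncol_)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- transition_matrix(model, po$edge.length[e])
    Pmats[[e]] <- P
    down[[par]] <- down[[par]] * (P %*% down[[ch]])
  }
  list(down = down, po = po, Pmats = Pmats)
}

#' Log-likelihood of aligned columns by Felsenstein pruning
#'
#' Missing tip states (NA or characters outside the state alphabet, e.g. X)
#' contribute an all-ones partial. The root prior is the model's equilibrium
#' frequency vector.
#'
#' @param tree rooted binary \code{phylo} with branch lengths
#' @param char_matrix character matrix, rows named by tip label, one column
#'   per site (or a single named character vector for one column)
#' @param model a \code{stator_ratemodel}
#' @return total log-likelihood (sum over columns); per-column values in
#'   attribute \code{"by_column"}
#' @export
pruning_likelihood <- function(tree, char_matrix, model) {
  if (is.vector(char_matrix))
    char_matrix <- matrix(char_matrix, ncol = 1,
                          dimnames = list(names(char_matrix), NULL))
  enc <- encode_tips(tree, char_matrix, model$states)
  pr <- prune_down(tree, enc, model)
  root <- length(tree$tip.label) + 1L
  lik <- colSums(model$freqs * pr$down[[root]])
  if (any(!is.finite(log(lik)) & lik <= 0))
    stopf("non-finite likelihood encountered")
  ll <- log(lik)
  out <- sum(ll)
  attr(out, "by_column") <- ll
  out
}

#' Marginal ancestral state posteriors
#'
#' Per internal node and column, the posterior distribution over states given
#' all tip data, computed by combining post-order (downward) partials with
#' pre-order (outside) messages; the root uses the equilibrium prior.
#'
#' @inheritParams pruning_likelihood
#' @return object of class \code{stator_marginal}: list with \code{posterior}
#'   (list over internal node ids of n_states x n_cols matrices, columns
#'   summing to 1), \code{states}, \code{tree}
#' @export
marginal_ancestral <- function(tree, char_matrix, model) {
  if (is.vector(char_matrix))
    char_matrix <- matrix(char_matrix, ncol = 1,
                          dimnames = list(names(char_matrix), NULL))
  enc <- encode_tips(tree, char_matrix, model$states)
  pr <- prune_down(tree, enc, model)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ncol_ <- ncol(enc)
  k <- model$n_states
  po <- pr$po
  # outside message S[v]: prior-weighted likelihood of everything except the
  # subtree below v, as a function of v's state
  S <- vector("list", ntip + nnode)
  root <- ntip + 1L
  S[[root]] <- matrix(model$freqs, k, ncol_)
  # pre-order = reverse post-order edge traversal
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sib_edges <- which(po$edge[, 1] == par & po$edge[, 2] != ch)
    contrib <- S[[par]]
    for (se in sib_edges)
      contrib <- contrib * (pr$Pmats[[se]] %*% pr$down[[po$edge[se, 2]]])
    S[[ch]] <- t(pr$Pmats[[e]]) %*% contrib
  }
  posterior <- vector("list", nnode)
  for (v in seq(root, ntip + nnode)) {
    u <- S[[v]] * pr$down[[v]]
    posterior[[v - ntip]] <- sweep(u, 2, colSums(u), "/")
  }
  names(posterior) <- as.character(seq(root, ntip + nnode))
  structure(list(posterior = posterior, states = model$states, tree = tree,
                 n_columns = ncol_),
            class = "stator_marginal")
}

#' @export
print.stator_marginal <- function(x, ...) {
  cat(sprintf("Marginal ancestral posteriors: %d internal nodes x %d columns, %d states\n",
              length(x$posterior), x$n_columns, length(x$states)))
  invisible(x)
}

#' Gap mask from gap posteriors
#'
#' A position is reconstructed as a gap when its gap probability is greater
#' than *or equal to* the threshold (default 0.5; the boundary is inclusive).
#'
#' @param gap_posterior numeric vector/matrix of per-position gap
#'   probabilities, or a \code{stator_marginal} over a presence-absence model
#'   (state "0" = gap)
#' @param threshold inclusive gap-call threshold (default 0.5)
#' @return logical mask (TRUE = gap), same shape as the input; for a
#'   \code{stator_marginal}, a nodes x columns logical matrix
#' @export
reconstruct_gaps <- function(gap_posterior, threshold = 0.5) {
  if (inherits(gap_posterior, "stator_marginal")) {
    gi <- match("0", gap_posterior$states)
    if (is.na(gi)) stopf("marginal object has no '0' (gap/absence) state")
    m <- do.call(rbind, lapply(gap_posterior$posterior, function(p) p[gi, ]))
    rownames(m) <- names(gap_posterior$posterior)
    return(m >= threshold)
  }
  if (any(gap_posterior < -1e-9 | gap_posterior > 1 + 1e-9))
    stopf("gap posteriors must lie in [0,1]")
  gap_posterior >= threshold
}

#' Assemble an ancestral sequence from residue posteriors and a gap mask
#'
#' Non-gap positions get the maximum-posterior residue, with ties broken
#' alphabetically (tied positions are flagged low-confidence); masked
#' positions get '-'.
#'
#' @param aa_posterior n_states x n_cols matrix of residue posteriors with
#'   rownames = states, or a \code{stator_marginal} plus \code{node_id}
#' @param gap_mask logical vector, length = number of columns
#' @param node_id node label recorded in the result
#' @return list with node_id, sequence, max_posterior (numeric vector),
#'   low_confidence (logical vector)
#' @export
assemble_ancestor <- function(aa_posterior, gap_mask, node_id = "node") {
  if (inherits(aa_posterior, "stator_marginal")) {
    if (!node_id %in% names(aa_posterior$posterior))
      stopf("node '%s' not in marginal object", node_id)
    states <- aa_posterior$states
    aa_posterior <- aa_posterior$posterior[[node_id]]
    rownames(aa_posterior) <- states
  }
  if (ncol(aa_posterior) != length(gap_mask))
    stopf("posterior has %d columns but gap mask has %d positions",
          ncol(aa_posterior), length(gap_mask))
  states <- rownames(aa_posterior)
  ord <- order(states)   # alphabetical tie-break
  post_sorted <- aa_posterior[ord, , drop = FALSE]
  pick <- apply(post_sorted, 2, which.max)
  maxp <- post_sorted[cbind(pick, seq_along(pick))]
  ties <- vapply(seq_along(pick), function(j)
    sum(abs(post_sorted[, j] - maxp[j]) < 1e-12) > 1, logical(1))
  seq_chr <- states[ord][pick]
  seq_chr[gap_mask] <- "-"
  list(node_id = node_id,
       sequence = paste(seq_chr, collapse = ""),
       max_posterior = ifelse(gap_mask, NA_real_, maxp),
       low_confidence = !gap_mask & ties)
}

#' Optimize branch lengths by coordinate-wise likelihood maximization
#'
#' Cycles over branches, maximizing the total log-likelihood in each branch
#' length by bounded univariate search (branch length in [1e-8, 20]), until
#' the round-over-round improvement falls below \code{tol} or
#' \code{max_rounds} is reached. A proposal is accepted only if it improves
#' the likelihood, so the log-likelihood trace is non-decreasing.
#'
#' @inheritParams pruning_likelihood
#' @param tol convergence tolerance on the log-likelihood (default 1e-6)
#' @param max_rounds maximum optimization sweeps (default 20)
#' @return the tree with optimized \code{edge.length}; attribute
#'   \code{"loglik_trace"} holds the per-round log-likelihoods
#' @export
optimize_branch_lengths <- function(tree, char_matrix, model, tol = 1e-6,
                                    max_rounds = 20) {
  if (is.vector(char_matrix))
    char_matrix <- matrix(char_matrix, ncol = 1,
                          dimnames = list(names(char_matrix), NULL))
  ll <- as.numeric(pruning_likelihood(tree, char_matrix, model))
  if (!is.finite(ll)) stopf("non-finite initial likelihood")
  trace <- ll
  for (round in seq_len(max_rounds)) {
    ll_before <- ll
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tr2 <- tree
        tr2$edge.length[e] <- x
        as.numeric(pruning_likelihood(tr2, char_matrix, model))
      }
      opt <- stats::optimize(f, interval = c(1e-8, 20), maximum = TRUE)
      if (opt$objective > ll) {
        tree$edge.length[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    trace <- c(trace, ll)
    if (ll - ll_before < tol) break
  }
  attr(tree, "loglik_trace") <- trace
  tree
}

#' Full gap + residue ancestral reconstruction
#'
#' Convenience wrapper reproducing the two-track reconstruction workflow:
#' amino-acid marginal ASR under LG+F (frequencies estimated from the data
#' unless supplied) on one track, presence-absence gap ASR on a binary model
#' with the >= 0.5 rule on the other, assembled into per-node ancestral
#' sequences.
#'
#' @param tree rooted binary phylo with branch lengths
#' @param aln a \code{stator_alignment} whose sequence ids match the tips
#' @param gap_threshold inclusive gap-call threshold (default 0.5)
#' @param optimize_lengths optimize branch lengths under the amino-acid model
#'   first? (default FALSE)
#' @param aa_freqs optional amino-acid equilibrium frequencies (+F vector)
#' @return list with \code{ancestors} (list of assemble_ancestor results,
#'   named by node id), \code{gap_mask}, \code{aa_marginal},
#'   \code{gap_marginal}, \code{tree}
#' @export
reconstruct_ancestral_sequences <- function(tree, aln, gap_threshold = 0.5,
                                            optimize_lengths = FALSE,
                                            aa_freqs = NULL) {
  m <- aln_matrix(aln)
  if (!setequal(rownames(m), tree$tip.label))
    stopf("alignment ids must match tree tips")
  aa_m <- m
  aa_m[!(aa_m %in% AA20)] <- NA    # gaps and ambiguity codes -> missing
  if (is.null(aa_freqs)) {
    tab <- table(factor(aa_m[!is.na(aa_m)], levels = AA20))
    aa_freqs <- if (sum(tab) > 0) as.numeric(tab + 1) / (sum(tab) + 20)
                else NULL
  }
  aa_model <- rate_model("LG", freqs = aa_freqs)
  if (optimize_lengths)
    tree <- optimize_branch_lengths(tree, aa_m, aa_model)
  gap_m <- ifelse(m == "-", "0", "1")
  pres_freq <- min(0.99, max(0.01, mean(gap_m == "1")))
  gap_model <- rate_model("binary",
                          freqs = c(1 - pres_freq, pres_freq))
  aa_marg <- marginal_ancestral(tree, aa_m, aa_model)
  gap_marg <- marginal_ancestral(tree, gap_m, gap_model)
  mask <- reconstruct_gaps(gap_marg, gap_threshold)
  anc <- lapply(rownames(mask), function(nid)
    assemble_ancestor(aa_marg, mask[nid, ], node_id = nid))
  names(anc) <- rownames(mask)
  list(ancestors = anc, gap_mask = mask, aa_marginal = aa_marg,
       gap_marginal = gap_marg, tree = tree)
}

#' Write ancestral sequences to FASTA
#'
#' @param recon result of \code{\link{reconstruct_ancestral_sequences}}
#' @param path output FASTA path
#' @export
write_ancestors <- function(recon, path) {
  seqs <- vapply(recon$ancestors, `[[`, "", "sequence")
  write_alignment(alignment(seqs), path)
}
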