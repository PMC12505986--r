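# Conditional clade distributions (CCD): a factorized probability model over
# rooted topologies estimated from a tree sample. CCD1 estimates each split's
# conditional probability by its observed frequency among the parent clade's
# occurrences; CCD0 makes the split probability proportional to the product of
# the two child clades' marginal occurrence frequencies, renormalized over the
# parent's observed splits. Entropy of the induced tree distribution is
# computed in nats by a recursion over clades.

#' Build a conditional clade distribution from a tree sample
#'
#' @param sample a \code{stator_treesample}
#' @param estimator "CCD1" (observed conditional split frequencies, default)
#'   or "CCD0" (split probability proportional to the product of child-clade
#'   marginal frequencies)
#' @return object of class \code{stator_ccd}
#' @export
build_ccd <- function(sample, estimator = c("CCD1", "CCD0")) {
  estimator <- match.arg(estimator)
  n_trees <- length(sample$trees)
  clade_env <- new.env(hash = TRUE, parent = emptyenv())
  split_env <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(env, key) {
    assign(key, get0(key, envir = env, ifnotfound = 0L) + 1L, envir = env)
  }
  for (tr in sample$trees) {
    ts <- tree_splits(tr, sample$taxa)
    for (k in ts$clades) bump(clade_env, k)
    sp <- ts$splits
    for (i in seq_len(nrow(sp))) {
      skey <- paste(sp$parent[i], sp$left[i], sp$right[i], sep = "||")
      bump(split_env, skey)
    }
  }
  clade_counts <- unlist(as.list(clade_env))
  skeys <- ls(split_env)
  scounts <- unlist(mget(skeys, envir = split_env))
  parts <- strsplit(skeys, "||", fixed = TRUE)
  splits <- data.frame(parent = vapply(parts, `[`, "", 1),
                       left = vapply(parts, `[`, "", 2),
                       right = vapply(parts, `[`, "", 3),
                       count = as.integer(scounts),
                       stringsAsFactors = FALSE)
  # conditional probabilities per parent
  splits$prob <- NA_real_
  for (p in unique(splits$parent)) {
    idx <- which(splits$parent == p)
    if (estimator == "CCD1") {
      w <- splits$count[idx]
    } else {
      f <- function(k) {
        if (key_size(k) == 1) return(1)          # singletons always present
        unname(clade_counts[k]) / n_trees
      }
      w <- vapply(idx, function(i) f(splits$left[i]) * f(splits$right[i]),
                  numeric(1))
    }
    splits$prob[idx] <- w / sum(w)
  }
  structure(list(taxa = sample$taxa, n_trees = n_trees,
                 estimator = estimator,
                 clade_counts = clade_counts, splits = splits,
                 split_index = split(seq_len(nrow(splits)), splits$parent)),
            class = "stator_ccd")
}

#' @export
print.stator_ccd <- function(x, ...) {
  cat(sprintf("CCD (%s): %d trees, %d taxa, %d distinct clades, %d splits\n",
              x$estimator, x$n_trees, length(x$taxa),
              length(x$clade_counts), nrow(x$splits)))
  invisible(x)
}

# splits of one parent clade, as a data.frame
#' @keywords internal
#' @noRd
ccd_splits_of <- function(ccd, parent_key) {
  ccd$splits[ccd$split_index[[parent_key]], , drop = FALSE]
}

#' Entropy of a conditional clade distribution
#'
#' The Shannon entropy, in natural log units, of the distribution over rooted
#' topologies induced by the CCD, computed by the memoized recursion
#' \code{H(C) = sum_s p(s|C) * (-ln p(s|C) + H(C_left) + H(C_right))} with
#' \code{H} of singletons and cherries equal to 0. Zero if and only if the
#' sample is topologically constant.
#'
#' @param ccd a \code{stator_ccd}
#' @return entropy in nats (>= 0)
#' @export
ccd_entropy <- function(ccd) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(key) {
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    h <- 0
    if (key_size(key) > 2) {
      sp <- ccd_splits_of(ccd, key)
      h <- sum(sp$prob * (-log(sp$prob) +
                            vapply(sp$left, rec, numeric(1)) +
                            vapply(sp$right, rec, numeric(1))))
    }
    assign(key, h, envir = memo)
    h
  }
  root_key <- clade_key(seq_along(ccd$taxa))
  rec(root_key)
}

#' Entropy report for a tree sample
#'
#' @param sample a \code{stator_treesample}
#' @param estimator passed to \code{\link{build_ccd}}
#' @return list with n_distinct_clades, entropy_nats, estimator, n_trees_used
#' @export
entropy_report <- function(sample, estimator = "CCD1") {
  ccd <- build_ccd(sample, estimator)
  list(n_distinct_clades = length(ccd$clade_counts),
       entropy_nats = ccd_entropy(ccd),
       estimator = estimator,
       n_trees_used = ccd$n_trees)
}

#' Compare clade-support entropy across tree samples
#'
#' One row per named sample, enabling e.g. the comparison of an A-subunit
#' posterior, a B-subunit posterior and their concatenated analysis.
#'
#' @param samples non-empty named list of \code{stator_treesample} objects
#' @param estimator passed to \code{\link{build_ccd}}
#' @return data.frame with columns name, n_trees_used, n_distinct_clades,
#'   entropy_nats, estimator
#' @export
compare_entropy <- function(samples, estimator = "CCD1") {
  if (length(samples) == 0 || is.null(names(samples)) ||
      any(!nzchar(names(samples))))
    stopf("compare_entropy needs a non-empty *named* list of samples")
  rows <- lapply(names(samples), function(nm) {
    r <- entropy_report(samples[[nm]], estimator)
    data.frame(name = nm, n_trees_used = r$n_trees_used,
               n_distinct_clades = r$n_distinct_clades,
               entropy_nats = r$entropy_nats, estimator = r$estimator,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum a posteriori summary tree of a CCD
#'
#' The rooted topology maximizing the product of conditional split
#' probabilities, found by dynamic programming over observed clades in log
#' space. Ties are broken deterministically by the lexicographically smallest
#' child bitstring. Internal nodes of the returned tree are labeled with the
#' clade's marginal occurrence frequency in the sample.
#'
#' @param ccd a \code{stator_ccd}
#' @return an ape \code{phylo}; attribute \code{"log_score"} holds the log CCD
#'   score of the topology
#' @export
map_tree <- function(ccd) {
  n <- length(ccd$taxa)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  best <- function(key) {
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    idx <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
    res <- if (length(idx) == 1) {
      list(score = 0, nwk = ccd$taxa[idx])
    } else if (length(idx) == 2) {
      list(score = 0, nwk = sprintf("(%s,%s)", ccd$taxa[idx[1]],
                                    ccd$taxa[idx[2]]))
    } else {
      sp <- ccd_splits_of(ccd, key)
      sc <- numeric(nrow(sp))
      lb <- vector("list", nrow(sp)); rb <- vector("list", nrow(sp))
      for (i in seq_len(nrow(sp))) {
        lb[[i]] <- best(sp$left[i]); rb[[i]] <- best(sp$right[i])
        sc[i] <- log(sp$prob[i]) + lb[[i]]$score + rb[[i]]$score
      }
      cand <- which(sc >= max(sc) - 1e-12)
      if (length(cand) > 1) {
        bits <- vapply(cand, function(i)
          min(key_bitstring(sp$left[i], n), key_bitstring(sp$right[i], n)),
          character(1))
        cand <- cand[order(bits)][1]
      } else cand <- cand[1]
      list(score = sc[cand],
           nwk = sprintf("(%s,%s)", lb[[cand]]$nwk, rb[[cand]]$nwk))
    }
    assign(key, res, envir = memo)
    res
  }
  root <- best(clade_key(seq_len(n)))
  tr <- ape::read.tree(text = paste0(root$nwk, ";"))
  # label internal nodes with marginal clade frequencies
  ts <- tree_splits(tr, ccd$taxa)
  freq <- unname(ccd$clade_counts[ts$clades]) / ccd$n_trees
  tr$node.label <- formatC(freq, digits = 4, format = "f")
  attr(tr, "log_score") <- root$score
  tr
}

# log CCD score of an arbitrary topology under a CCD (0-probability splits
# give -Inf)
#' @keywords internal
#' @noRd
ccd_log_score <- function(ccd, tree) {
  ts <- tree_splits(tree, ccd$taxa)
  tot <- 0
  for (i in seq_len(nrow(ts$splits))) {
    s <- ts$splits[i, ]
    if (key_size(s$parent) <= 2) next
    sp <- ccd_splits_of(ccd, s$parent)
    hit <- which(sp$left == s$left & sp$right == s$right)
    if (length(hit) == 0) return(-Inf)
    tot <- tot + log(sp$prob[hit])
  }
  tot
}

#' Annotate a tree with clade posterior support
#'
#' Each internal node receives the fraction of retained sample trees that
#' contain its clade, plus a display category: \code{white} (P <= 0.5),
#' \code{gray} (0.5 < P <= 0.8), \code{dark_gray} (0.8 < P <= 0.95),
#' \code{black} (P > 0.95).
#'
#' @param tree a rooted binary \code{phylo} whose taxa are contained in the
#'   sample's taxon set
#' @param sample a \code{stator_treesample}
#' @return the tree with \code{node.label} set to the posterior fraction, and
#'   a data.frame attribute \code{"support"} with columns clade, posterior,
#'   support_bin
#' @export
annotate_support <- function(tree, sample) {
  if (!all(tree$tip.label %in% sample$taxa))
    stopf("tree contains taxa absent from the sample")
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in sample$trees) {
    for (k in tree_splits(tr, sample$taxa)$clades) {
      cur <- get0(k, envir = counts, ifnotfound = 0L)
      assign(k, cur + 1L, envir = counts)
    }
  }
  ts <- tree_splits(tree, sample$taxa)
  post <- vapply(ts$clades, function(k)
    get0(k, envir = counts, ifnotfound = 0L) / length(sample$trees),
    numeric(1))
  bin <- cut(post, breaks = c(-Inf, 0.5, 0.8, 0.95, Inf),
             labels = c("white", "gray", "dark_gray", "black"))
  tree$node.label <- formatC(post, digits = 4, format = "f")
  attr(tree, "support") <- data.frame(clade = ts$clades, posterior = post,
                                      support_bin = as.character(bin),
                                      stringsAsFactors = FALSE)
  tree
}

#' Support category for a posterior probability
#'
#' @param p posterior probability (vectorized)
#' @return character vector in c("white","gray","dark_gray","black")
#' @export
support_bin <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.5, 0.8, 0.95, Inf),
                   labels = c("white", "gray", "dark_gray", "black")))
}

#' Write an annotated tree as NEXUS with node comments
#'
#' Emits a NEXUS file whose tree carries \code{[&posterior=..,support_bin=..]}
#' comments on internal nodes (the figure-annotation convention of posterior
#' summary trees).
#'
#' @param tree a tree returned by \code{\link{annotate_support}}
#' @param path output path
#' @export
write_annotated_nexus <- function(tree, path) {
  supp <- attr(tree, "support")
  if (is.null(supp)) stopf("tree has no support annotation")
  taxa <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  # rebuild newick with comments, recursively from the edge matrix
  children <- split(tree$edge[, 2], tree$edge[, 1])
  lens <- if (!is.null(tree$edge.length))
    stats::setNames(tree$edge.length, tree$edge[, 2]) else NULL
  ts <- tree_splits(tree, taxa)
  node_comment <- stats::setNames(
    sprintf("[&posterior=%.4f,support_bin=%s]", supp$posterior,
            supp$support_bin),
    ts$clades)
  keys <- character(ntip + tree$Nnode)
  tipidx <- match(tree$tip.label, taxa)
  build <- function(v) {
    if (v <= ntip) {
      keys[v] <<- clade_key(tipidx[v])
      out <- tree$tip.label[v]
    } else {
      kids <- children[[as.character(v)]]
      parts <- vapply(kids, build, character(1))
      keyset <- sort(as.integer(unlist(strsplit(keys[kids], " "))))
      keys[v] <<- clade_key(keyset)
      out <- paste0("(", paste(parts, collapse = ","), ")",
                    node_comment[[keys[v]]] %||% "")
    }
    if (!is.null(lens) && !is.na(lens[as.character(v)]))
      out <- paste0(out, ":", format(lens[[as.character(v)]], digits = 10))
    out
  }
  root <- ntip + 1L
  nwk <- paste0(build(root), ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "begin trees;",
               paste0("tree SUMMARY = [&R] ", nwk), "end;"), con)
  invisible(path)
}
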