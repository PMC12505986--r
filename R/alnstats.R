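# Alignment-level statistics: pairwise identity, column conservation,
# plug+linker region extraction/composition, and the FIT-vs-GIT group test.

#' Mean pairwise identity of an alignment
#'
#' For every unordered pair of sequences, identity is the number of columns
#' where both rows carry the identical non-gap residue, divided by the number
#' of columns where both rows are non-gap, times 100. Pairs with zero
#' co-aligned columns contribute 0 and are reported via the
#' \code{"zero_overlap_pairs"} attribute. The denominator choice (mutually
#' non-gap columns, not alignment length) matters for sparse alignments and is
#' therefore part of the contract.
#'
#' @param aln a \code{stator_alignment} with at least two sequences
#' @return mean pairwise identity as a percentage (0..100)
#' @export
mean_pairwise_identity <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stopf("mean_pairwise_identity needs >= 2 sequences, got %d", n)
  nongap <- m != "-"
  ids <- numeric(0)
  zero_pairs <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- nongap[i, ] & nongap[j, ]
      denom <- sum(both)
      if (denom == 0) {
        ids <- c(ids, 0)
        zero_pairs <- c(zero_pairs,
                        paste(rownames(m)[i], rownames(m)[j], sep = "|"))
      } else {
        same <- sum(m[i, both] == m[j, both] & m[i, both] != "X")
        ids <- c(ids, 100 * same / denom)
      }
    }
  }
  out <- mean(ids)
  if (length(zero_pairs)) {
    warnf("%d sequence pair(s) share no co-aligned columns (counted as 0%%)",
          length(zero_pairs))
    attr(out, "zero_overlap_pairs") <- zero_pairs
  }
  out
}

#' Per-column conservation score
#'
#' Conservation of column c is \code{1 - H_c / ln(20)}, where \code{H_c} is
#' the Shannon entropy of the non-gap residue frequencies in that column.
#' All-gap columns score 0 by convention.
#'
#' @param aln a \code{stator_alignment}
#' @return numeric vector of per-column scores in [0, 1]
#' @export
column_conservation <- function(aln) {
  m <- aln_matrix(aln)
  if (ncol(m) == 0) return(numeric(0))
  apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    p <- table(col) / length(col)
    h <- -sum(p * log(p))
    max(0, 1 - h / log(20))
  })
}

#' Extract an alignment region as ungapped subsequences
#'
#' Slices columns \code{first_col..last_col} (1-based inclusive) from every
#' row and removes gap characters. The default region (columns 76-133) is the
#' plug+linker segment of the B-subunit alignment, i.e. the residues between
#' the catalytic TM domain and the peptidoglycan-binding (OmpA-like) domain.
#'
#' @param aln a \code{stator_alignment}
#' @param first_col,last_col 1-based inclusive alignment columns
#' @return named character vector, seq_id -> ungapped subsequence (possibly "")
#' @export
extract_region <- function(aln, first_col = 76, last_col = 133) {
  if (first_col < 1 || last_col > aln$length || first_col > last_col)
    stopf("region %d-%d out of bounds for alignment of %d columns",
          first_col, last_col, aln$length)
  sub <- substr(aln$rows, first_col, last_col)
  stats::setNames(gsub("-", "", sub, fixed = TRUE), names(aln$rows))
}

#' Composition statistics for plug+linker subsequences
#'
#' Per sequence: ungapped length, glycine count, proline count and the number
#' of overlapping "GG" dimers (so "GGG" counts 2). Unknown group labels are
#' assigned "other" with a warning.
#'
#' @param subseqs named character vector as returned by
#'   \code{\link{extract_region}}
#' @param groups optional named character vector mapping seq_id to a group
#'   label in \code{c("TGI4","TGI5","CCD2","CCD3","other")}
#' @return data.frame with columns seq_id, group, length_aa, gly, pro, gg
#'   and a logical empty_region flag
#' @export
plug_stats <- function(subseqs, groups = NULL) {
  known <- c("TGI4", "TGI5", "CCD2", "CCD3", "other")
  ids <- names(subseqs)
  grp <- rep("other", length(ids))
  if (!is.null(groups)) {
    g <- unname(groups[ids])
    bad <- !is.na(g) & !(g %in% known)
    if (any(bad)) {
      warnf("unknown group label(s) %s assigned 'other'",
            paste(unique(g[bad]), collapse = ", "))
      g[bad] <- "other"
    }
    grp <- ifelse(is.na(g), "other", g)
  }
  count_pat <- function(s, pat) {
    vapply(gregexpr(pat, s), function(m) sum(m > 0), integer(1))
  }
  gg <- vapply(subseqs, function(s) {
    if (nchar(s) < 2) return(0L)
    ch <- strsplit(s, "")[[1]]
    sum(ch[-length(ch)] == "G" & ch[-1] == "G")
  }, integer(1))
  data.frame(
    seq_id = ids,
    group = grp,
    length_aa = nchar(subseqs),
    gly = count_pat(subseqs, "G"),
    pro = count_pat(subseqs, "P"),
    gg = unname(gg),
    empty_region = nchar(subseqs) == 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided permutation test on the difference of group medians
#'
#' The observed statistic is \code{median(values_a) - median(values_b)}.
#' Group labels are permuted \code{n_permutations} times and the two-sided
#' p-value is \code{(1 + #(|permuted| >= |observed|)) / (n_permutations + 1)},
#' so its resolution is \code{1/(n_permutations+1)}. A difference of medians
#' is used because group summaries in this domain are reported as medians;
#' with integer-valued data (residue counts) ties make the p-value
#' conservative.
#'
#' @param values_a,values_b numeric vectors (both non-empty)
#' @param n_permutations number of label permutations (>= 1)
#' @param seed integer seed, recorded in the result
#' @return list with statistic_name, observed, p_value, n_permutations, seed
#' @export
group_permutation_test <- function(values_a, values_b,
                                   n_permutations = 10000, seed = 1) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stopf("both groups must be non-empty")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  na <- length(values_a)
  pool <- c(values_a, values_b)
  obs <- stats::median(values_a) - stats::median(values_b)
  exceed <- with_seed(seed, {
    perm <- vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(length(pool), na)
      stats::median(pool[idx]) - stats::median(pool[-idx])
    }, numeric(1))
    sum(abs(perm) >= abs(obs))
  })
  list(statistic_name = "median_difference",
       observed = obs,
       p_value = (1 + exceed) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations),
       seed = as.integer(seed))
}
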