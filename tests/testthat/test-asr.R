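# Ancestral reconstruction: rate models, pruning, marginal posteriors, gap
# rule, assembly and branch-length optimization.

test_that("rate models are valid generators with correct limits", {
  for (m in list(rate_model("binary"), rate_model("LG"))) {
    expect_lt(max(abs(rowSums(m$Q))), 1e-12)
    expect_equal(sum(m$freqs), 1, tolerance = 1e-9)
    expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-9)  # rate 1
    P0 <- transition_matrix(m, 0)
    expect_equal(P0, diag(m$n_states), tolerance = 1e-10)
    Pinf <- transition_matrix(m, 500)
    expect_equal(Pinf, matrix(m$freqs, m$n_states, m$n_states, byrow = TRUE),
                 tolerance = 1e-8)
  }
  expect_error(transition_matrix(rate_model("binary"), -0.1), "negative")
})

test_that("two-tip limits: t->0 approaches state certainty, t->inf independence", {
  m <- rate_model("binary", freqs = c(0.3, 0.7))
  tr <- ape::read.tree(text = "(A:0.0000005,B:0.0000005);")
  ll <- pruning_likelihood(tr, c(A = "1", B = "1"), m)
  expect_equal(as.numeric(ll), log(0.7), tolerance = 1e-4)
  trL <- ape::read.tree(text = "(A:300,B:300);")
  llL <- pruning_likelihood(trL, c(A = "1", B = "0"), m)
  expect_equal(as.numeric(llL), log(0.7) + log(0.3), tolerance = 1e-6)
})

test_that("pruning equals the state-enumeration oracle on all small topologies", {
  set.seed(42)
  for (n_tips in 3:5) {
    topos <- all_rooted_topologies(paste0("t", seq_len(n_tips)))
    models <- list(rate_model("binary", freqs = c(0.4, 0.6)),
                   rate_model("LG"))
    for (nwk in topos) {
      tr <- ape::read.tree(text = paste0(nwk, ";"))
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
      for (m in models) {
        states <- stats::setNames(sample(m$states, n_tips, replace = TRUE),
                                  tr$tip.label)
        ll <- as.numeric(pruning_likelihood(tr, states, m))
        expect_equal(ll, oracle_pruning(tr, states, m), tolerance = 1e-10)
      }
    }
  }
})

test_that("missing tip states marginalize correctly", {
  m <- rate_model("binary")
  tr <- ape::read.tree(text = "((A:0.3,B:0.2):0.1,C:0.4);")
  states <- c(A = "1", B = NA, C = "0")
  ll <- as.numeric(pruning_likelihood(tr, states, m))
  expect_equal(ll, oracle_pruning(tr, states, m), tolerance = 1e-12)
})

test_that("pruning log-likelihood matches phangorn on amino-acid data", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.4);")
  m <- rate_model("LG")
  seqs <- c(A = "M", B = "K", C = "M", D = "L")
  ll <- as.numeric(pruning_likelihood(tr, seqs, m))
  pd <- phangorn::phyDat(matrix(seqs, ncol = 1,
                                dimnames = list(names(seqs), NULL)),
                         type = "AA")
  fit <- phangorn::pml(tr, pd, model = "LG", bf = m$freqs)
  expect_equal(ll, fit$logLik, tolerance = 1e-8)
})

test_that("marginal posteriors sum to 1 and match the enumeration oracle", {
  set.seed(7)
  m2 <- rate_model("binary", freqs = c(0.45, 0.55))
  for (rep in 1:5) {
    tr <- gen_yule_tree(5, 1, seed = rep)
    states <- stats::setNames(sample(c("0", "1"), 5, replace = TRUE),
                              tr$tip.label)
    marg <- marginal_ancestral(tr, states, m2)
    for (nd in names(marg$posterior)) {
      post <- marg$posterior[[nd]][, 1]
      expect_equal(sum(post), 1, tolerance = 1e-9)
      expect_equal(post, oracle_marginal(tr, states, m2, as.integer(nd)),
                   tolerance = 1e-10)
    }
  }
})

test_that("marginal posteriors respect symmetry and consistency", {
  m <- rate_model("binary")
  # conflicting tips on a symmetric two-tip tree -> 50/50 at the root
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  marg <- marginal_ancestral(tr, c(A = "0", B = "1"), m)
  expect_equal(marg$posterior[["3"]][, 1], c(0.5, 0.5), tolerance = 1e-12)
  # unanimous tips on a short star-ish tree -> near-certain root
  tr2 <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  marg2 <- marginal_ancestral(tr2, c(A = "1", B = "1", C = "1", D = "1"), m)
  expect_gt(marg2$posterior[["5"]][2, 1], 0.99)
})

test_that("gap rule is boundary-inclusive at the 0.5 threshold", {
  expect_true(reconstruct_gaps(0.5))
  expect_false(reconstruct_gaps(0.499999))
  expect_equal(reconstruct_gaps(c(0, 0.5, 1)), c(FALSE, TRUE, TRUE))
  expect_error(reconstruct_gaps(1.5), "\\[0,1\\]")
})

test_that("all-gap tips reconstruct ancestral gaps everywhere", {
  tr <- gen_yule_tree(5, 1, seed = 3)
  aln <- alignment(stats::setNames(rep("---", 5), tr$tip.label))
  rec <- reconstruct_ancestral_sequences(tr, aln)
  expect_true(all(rec$gap_mask))
  expect_true(all(vapply(rec$ancestors, function(a)
    a$sequence == "---", logical(1))))
})

test_that("ancestor assembly uses alphabetical tie-breaks and flags ties", {
  post <- matrix(c(0.5, 0.5, 0.8, 0.2), 2, 2,
                 dimnames = list(c("T", "A"), NULL))
  a <- assemble_ancestor(post, c(FALSE, FALSE), "n1")
  expect_equal(a$sequence, "AT")                 # tie at col 1 -> 'A'
  expect_true(a$low_confidence[1])
  expect_false(a$low_confidence[2])
  am <- assemble_ancestor(post, c(TRUE, TRUE), "n1")
  expect_equal(am$sequence, "--")
  expect_error(assemble_ancestor(post, c(TRUE), "n1"), "mismatch|positions")
})

test_that("planted gaps are recovered at generator defaults", {
  tr <- gen_yule_tree(20, 2, seed = 14)
  sim <- gen_alignment(tr, rate_model("LG"), n_cols = 120, seed = 15)
  rec <- reconstruct_ancestral_sequences(tr, sim$aln)
  truth_pres <- sim$truth$presence[rownames(rec$gap_mask), , drop = FALSE]
  expect_gte(mean(rec$gap_mask == !truth_pres), 0.9)
})

test_that("residue recovery beats chance by a wide margin and degrades with branch length", {
  m <- rate_model("LG")
  acc_at <- function(scale) {
    tr <- gen_yule_tree(12, 2, seed = 8)
    tr$edge.length <- tr$edge.length * scale
    sim <- gen_alignment(tr, m, n_cols = 150, indel_rate = 0, seed = 9)
    rec <- reconstruct_ancestral_sequences(tr, sim$aln)
    mean(vapply(names(rec$ancestors), function(nid) {
      true_seq <- strsplit(sim$truth$node_sequences[[nid]], "")[[1]]
      got <- strsplit(rec$ancestors[[nid]]$sequence, "")[[1]]
      mean(got == true_seq)
    }, numeric(1)))
  }
  a_short <- acc_at(0.3)
  a_long <- acc_at(3)
  expect_gt(a_short, 0.05 + 0.5)   # chance + 50 points
  expect_gt(a_short, a_long)       # monotone degradation on average
})

test_that("branch-length optimization recovers a planted length and never decreases the likelihood", {
  m <- rate_model("LG")
  tr <- ape::read.tree(text = "(A:0.15,B:0.15);")
  sim <- gen_alignment(tr, m, n_cols = 800, indel_rate = 0, seed = 22)
  mat <- do.call(rbind, strsplit(sim$aln$rows, ""))
  rownames(mat) <- names(sim$aln$rows)
  start <- tr
  start$edge.length <- c(1, 1)
  opt <- optimize_branch_lengths(start, mat, m)
  trace <- attr(opt, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-9))
  expect_equal(sum(opt$edge.length), 0.3, tolerance = 0.2 * 0.3)
  # an already-optimal tree is a fixed point
  opt2 <- optimize_branch_lengths(opt, mat, m)
  expect_equal(sum(opt2$edge.length), sum(opt$edge.length), tolerance = 1e-3)
})
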