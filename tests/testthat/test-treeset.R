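# Tree-sample I/O, clade counting, CCD construction, entropy, MAP trees and
# support annotation.

three_taxon_topologies <- function() {
  c(ape::read.tree(text = "((a,b),c);"),
    ape::read.tree(text = "((a,c),b);"),
    ape::read.tree(text = "((b,c),a);"))
}

test_that("burn-in drops the leading fraction of trees", {
  trees <- rep(c(ape::read.tree(text = "((a,b),c);")), 100)
  class(trees) <- "multiPhylo"
  p <- tempfile()
  ape::write.tree(trees, p)
  s <- read_tree_sample(p, burnin_fraction = 0.1)
  expect_equal(s$n_input, 100)
  expect_equal(s$n_used, 90)
})

test_that("NEXUS translate tables resolve to the same topologies as Newick", {
  s0 <- random_tree_sample(8, 10, seed = 4)
  pn <- tempfile(fileext = ".nwk")
  px <- tempfile(fileext = ".nex")
  ape::write.tree(s0$trees, pn)
  ape::write.nexus(s0$trees, file = px, translate = TRUE)
  s1 <- read_tree_sample(pn, 0)
  s2 <- read_tree_sample(px, 0)
  key <- function(s) unname(lapply(s$trees, function(tr)
    sort(unlist(lapply(seq_len(tr$Nnode) + length(tr$tip.label), function(v)
      paste(sort(ape::extract.clade(tr, v)$tip.label), collapse = "|"))))))
  expect_equal(key(s1), key(s2))
})

test_that("round-trip write/read preserves every topology", {
  s0 <- random_tree_sample(9, 15, seed = 6)
  p <- tempfile()
  write_tree_sample(s0, p)
  s1 <- read_tree_sample(p, 0)
  expect_equal(count_clades(s0), count_clades(s1))
  expect_equal(ccd_entropy(build_ccd(s0)), ccd_entropy(build_ccd(s1)),
               tolerance = 1e-12)
})

test_that("unrooted or taxon-inconsistent inputs are rejected with the tree index", {
  unrooted <- ape::read.tree(text = "(a,b,c,d);")
  expect_error(tree_sample(c(unrooted)), "unrooted")
  t1 <- ape::read.tree(text = "((a,b),c);")
  t2 <- ape::read.tree(text = "((a,b),d);")
  expect_error(tree_sample(c(t1, t2)), "tree 2")
})

test_that("clade counting: constant sample has n-1 clades, 3-taxon support has 4", {
  tr <- gen_yule_tree(8, 1, seed = 2)
  s <- gen_tree_sample(tr, 0, 5, seed = 3)
  expect_equal(count_clades(s), 7)              # n - 1 for a binary rooted tree
  s3 <- tree_sample(three_taxon_topologies())
  expect_equal(count_clades(s3), 4)             # {abc} + three pairs
})

test_that("clade counting equals the brute-force union oracle on random samples", {
  for (seed in 1:3) {
    s <- random_tree_sample(8, 12, seed = seed)
    expect_equal(count_clades(s), oracle_count_clades(s))
  }
})

test_that("CCD conditional probabilities sum to 1 per parent; degenerate samples are certain", {
  s <- random_tree_sample(10, 20, seed = 8)
  for (est in c("CCD1", "CCD0")) {
    ccd <- build_ccd(s, est)
    sums <- tapply(ccd$splits$prob, ccd$splits$parent, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  sdeg <- gen_tree_sample(gen_yule_tree(6, 1, seed = 1), 0, 10, seed = 2)
  cdeg <- build_ccd(sdeg)
  expect_true(all(cdeg$splits$prob == 1))
})

test_that("3-taxon uniform sample: root splits at 1/3 under CCD1, entropy ln 3", {
  s3 <- tree_sample(three_taxon_topologies())
  ccd <- build_ccd(s3, "CCD1")
  root_key <- paste(1:3, collapse = " ")
  expect_equal(sort(ccd$splits$prob[ccd$splits$parent == root_key]),
               rep(1 / 3, 3))
  expect_equal(ccd_entropy(ccd), log(3), tolerance = 1e-12)
})

test_that("CCD0 and CCD1 agree when every parent has a single observed split", {
  sdeg <- gen_tree_sample(gen_yule_tree(7, 1, seed = 5), 0, 8, seed = 6)
  e0 <- ccd_entropy(build_ccd(sdeg, "CCD0"))
  e1 <- ccd_entropy(build_ccd(sdeg, "CCD1"))
  expect_equal(e0, 0)
  expect_equal(e1, 0)
  # also on a sample whose parents happen to have unique splits
  t1 <- ape::read.tree(text = "(((a,b),c),(d,e));")
  s <- tree_sample(c(t1, t1, t1))
  expect_equal(ccd_entropy(build_ccd(s, "CCD0")),
               ccd_entropy(build_ccd(s, "CCD1")))
})

test_that("entropy recursion equals brute-force enumeration over the CCD support", {
  for (seed in 1:10) {
    s <- random_tree_sample(6, 15, seed = 100 + seed, nni_rate = 4)
    for (est in c("CCD1", "CCD0")) {
      ccd <- build_ccd(s, est)
      expect_equal(ccd_entropy(ccd), oracle_ccd_entropy(ccd),
                   tolerance = 1e-9)
    }
  }
})

test_that("entropy is invariant to taxon relabeling and tree order", {
  s <- random_tree_sample(7, 12, seed = 31)
  e1 <- ccd_entropy(build_ccd(s))
  perm_trees <- rev(s$trees)
  class(perm_trees) <- "multiPhylo"
  expect_equal(ccd_entropy(build_ccd(tree_sample(perm_trees))), e1,
               tolerance = 1e-12)
  relab <- lapply(s$trees, function(tr) {
    tr$tip.label <- paste0("zz_", tr$tip.label)
    tr
  })
  class(relab) <- "multiPhylo"
  expect_equal(ccd_entropy(build_ccd(tree_sample(relab))), e1,
               tolerance = 1e-12)
})

test_that("MAP tree maximizes the CCD score over sampled topologies", {
  for (seed in 1:3) {
    s <- random_tree_sample(7, 25, seed = 50 + seed, nni_rate = 2)
    ccd <- build_ccd(s)
    mt <- map_tree(ccd)
    sc <- attr(mt, "log_score")
    sampled_scores <- vapply(s$trees, function(tr)
      statorevo:::ccd_log_score(ccd, tr), numeric(1))
    expect_gte(sc, max(sampled_scores) - 1e-9)
  }
  # majority rule on a simple 4-taxon mixture
  t1 <- ape::read.tree(text = "(((a,b),c),d);")
  t2 <- ape::read.tree(text = "(((a,c),b),d);")
  s <- tree_sample(c(rep(c(t1), 9), c(t2)))
  mt <- map_tree(build_ccd(s))
  expect_equal(sort(ape::extract.clade(
    mt, ape::getMRCA(mt, c("a", "b")))$tip.label), c("a", "b"))
})

test_that("degenerate sample's MAP tree is the unique sampled topology", {
  base <- gen_yule_tree(6, 1, seed = 9)
  s <- gen_tree_sample(base, 0, 5, seed = 10)
  mt <- map_tree(build_ccd(s))
  expect_equal(ape::dist.topo(ape::unroot(mt), ape::unroot(base)),
               0, ignore_attr = TRUE)
})

test_that("support annotation equals naive containment counts with the display bins", {
  s <- random_tree_sample(6, 20, seed = 77, nni_rate = 2)
  tr <- s$trees[[1]]
  ann <- annotate_support(tr, s)
  supp <- attr(ann, "support")
  # naive recount
  for (i in seq_len(nrow(supp))) {
    idx <- as.integer(strsplit(supp$clade[i], " ")[[1]])
    tips <- sort(s$taxa[idx])
    cnt <- sum(vapply(s$trees, function(t2) {
      any(vapply(seq_len(t2$Nnode) + length(t2$tip.label), function(v)
        identical(sort(ape::extract.clade(t2, v)$tip.label), tips),
        logical(1)))
    }, logical(1)))
    expect_equal(supp$posterior[i], cnt / length(s$trees))
  }
  expect_true(all(supp$support_bin %in%
                    c("white", "gray", "dark_gray", "black")))
})

test_that("support bins follow the display convention including the 0.95 boundary", {
  expect_equal(support_bin(c(0.3, 0.5, 0.7, 0.8, 0.9, 0.95, 0.96, 1)),
               c("white", "white", "gray", "gray", "dark_gray", "dark_gray",
                 "black", "black"))
})

test_that("annotated NEXUS output carries posterior node comments", {
  s <- random_tree_sample(5, 10, seed = 13)
  ann <- annotate_support(s$trees[[1]], s)
  p <- tempfile(fileext = ".nexus")
  write_annotated_nexus(ann, p)
  txt <- readLines(p)
  expect_true(any(grepl("&posterior=", txt)))
  expect_true(any(grepl("support_bin=", txt)))
  expect_equal(txt[1], "#NEXUS")
})

test_that("compare_entropy returns one deterministic row per named sample", {
  s <- random_tree_sample(6, 10, seed = 19)
  tab <- compare_entropy(list(one = s, two = s))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$entropy_nats[1], tab$entropy_nats[2])
  expect_error(compare_entropy(list()), "named")
  expect_error(compare_entropy(stats::setNames(list(s), "")), "named")
})
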