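# Alignment statistics: pairwise identity, conservation, region extraction,
# plug composition, permutation test.

test_that("mean pairwise identity matches hand-checkable cases", {
  expect_equal(mean_pairwise_identity(alignment(c(a = "ACDE", b = "ACDE"))),
               100)
  expect_equal(mean_pairwise_identity(alignment(c(a = "ACDE", b = "ACD-"))),
               100)   # denominator = mutually non-gap columns
  expect_equal(mean_pairwise_identity(alignment(c(a = "ACDE", b = "AGDE"))),
               75)
  expect_error(mean_pairwise_identity(alignment(c(a = "ACDE"))), ">= 2")
})

test_that("mean pairwise identity equals the naive double-loop oracle and is order-invariant", {
  set.seed(11)
  for (rep in 1:5) {
    rows <- vapply(1:10, function(i)
      paste(sample(c("A", "C", "D", "E", "G", "-"), 40, replace = TRUE),
            collapse = ""), character(1))
    names(rows) <- paste0("s", 1:10)
    aln <- alignment(rows)
    v1 <- suppressWarnings(as.numeric(mean_pairwise_identity(aln)))
    expect_equal(v1, suppressWarnings(oracle_mpi(rows)), tolerance = 1e-12)
    perm <- alignment(rows[sample(10)])
    expect_equal(suppressWarnings(as.numeric(mean_pairwise_identity(perm))),
                 v1, tolerance = 1e-12)
  }
})

test_that("pairs with zero co-aligned columns contribute 0 and are flagged", {
  aln <- alignment(c(a = "AC--", b = "--DE", c = "ACDE"))
  expect_warning(v <- mean_pairwise_identity(aln), "no co-aligned")
  expect_equal(attr(v, "zero_overlap_pairs"), "a|b")
  expect_equal(as.numeric(v), mean(c(0, 100, 100)))
})

test_that("column conservation is 1 for invariant, 0 for uniform, closed form between", {
  rows20 <- stats::setNames(paste0(AA20 <- c("A","R","N","D","C","Q","E","G",
                                             "H","I","L","K","M","F","P","S",
                                             "T","W","Y","V"), "G"),
                            paste0("s", 1:20))
  aln <- alignment(rows20)
  cc <- column_conservation(aln)
  expect_equal(cc[1], 0)                         # uniform over 20 residues
  expect_equal(cc[2], 1)                         # all G
  mixed <- alignment(c(a = "A", b = "A", c = "G", d = "G"))
  expect_equal(column_conservation(mixed), 1 - log(2) / log(20),
               ignore_attr = TRUE)
  allgap <- alignment(c(a = "-", b = "-"))
  expect_equal(column_conservation(allgap), 0, ignore_attr = TRUE)
})

test_that("region extraction slices columns and drops gaps", {
  aln <- alignment(c(r = "AB--CD"))
  expect_equal(unname(extract_region(aln, 2, 5)), "BC")
  expect_equal(unname(extract_region(alignment(c(r = "A----A")), 2, 5)), "")
  expect_error(extract_region(aln, 0, 5), "out of bounds")
  expect_error(extract_region(aln, 2, 9), "out of bounds")
})

test_that("a reference row over a 58-column region returns the printed 52-residue plug", {
  ref <- "SSPKELIQIAEYFRTPLATAVTGGDRISNSESPIPGGGDDYTQSQGEVNKQP"
  expect_equal(nchar(ref), 52)
  # plant the reference into columns 76-133 of a wider alignment with 6 gaps
  set.seed(21)
  padded <- strsplit(ref, "")[[1]]
  gaps_at <- sort(sample(58, 6))
  row <- character(58)
  row[gaps_at] <- "-"
  row[setdiff(1:58, gaps_at)] <- padded
  full <- paste0(paste(rep("M", 75), collapse = ""),
                 paste(row, collapse = ""),
                 paste(rep("M", 20), collapse = ""))
  aln <- alignment(c(ecoli_motb = full))
  got <- extract_region(aln, 76, 133)
  expect_equal(unname(got), ref)
})

test_that("plug composition matches the character-counting oracle on the reference", {
  ref <- c(ecoli_motb = "SSPKELIQIAEYFRTPLATAVTGGDRISNSESPIPGGGDDYTQSQGEVNKQP")
  st <- plug_stats(ref, c(ecoli_motb = "TGI5"))
  o <- oracle_counts(ref[[1]])
  expect_equal(st$length_aa, 52)
  expect_equal(st$gly, 6)
  expect_equal(st$pro, 5)
  expect_equal(st$gg, 3)
  expect_equal(st$length_aa, o$length)
  expect_equal(st$gly, o$gly)
  expect_equal(st$pro, o$pro)
  expect_equal(st$gg, o$gg)
  expect_equal(st$group, "TGI5")
})

test_that("GG counting is overlapping and empty sequences give zeros", {
  st <- plug_stats(c(x = "GGG", y = ""))
  expect_equal(st$gg[1], 2)
  expect_equal(unlist(st[2, c("length_aa", "gly", "pro", "gg")]),
               c(length_aa = 0, gly = 0, pro = 0, gg = 0))
  expect_true(st$empty_region[2])
})

test_that("plug composition is additive over concatenation of gap-free sequences", {
  set.seed(5)
  for (rep in 1:5) {
    s1 <- paste(sample(c("G", "P", "A", "L"), 30, replace = TRUE),
                collapse = "")
    s2 <- paste(sample(c("G", "P", "A", "L"), 25, replace = TRUE),
                collapse = "")
    a <- plug_stats(c(x = s1)); b <- plug_stats(c(x = s2))
    ab <- plug_stats(c(x = paste0(s1, s2)))
    expect_equal(ab$length_aa, a$length_aa + b$length_aa)
    expect_equal(ab$gly, a$gly + b$gly)
    expect_equal(ab$pro, a$pro + b$pro)
    # overlapping GG at the junction may add at most one extra dimer
    junction <- as.integer(substr(s1, 30, 30) == "G" &&
                             substr(s2, 1, 1) == "G")
    expect_equal(ab$gg, a$gg + b$gg + junction)
  }
})

test_that("unknown group labels fall back to 'other' with a warning", {
  expect_warning(st <- plug_stats(c(x = "AG"), c(x = "WEIRD")), "WEIRD")
  expect_equal(st$group, "other")
})

test_that("permutation test: identical groups give p near 1, shifted groups reject", {
  x <- rep(c(1, 2, 3, 4), 5)
  r <- group_permutation_test(x, x, n_permutations = 499, seed = 1)
  expect_gt(r$p_value, 0.9)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20) + 50
  r2 <- group_permutation_test(a, b, n_permutations = 999, seed = 3)
  expect_lte(r2$p_value, 0.01)
  expect_equal(r2$statistic_name, "median_difference")
  expect_equal(r2$seed, 3L)
  expect_error(group_permutation_test(a, numeric(0)), "non-empty")
  expect_error(group_permutation_test(a, b, n_permutations = 0), ">= 1")
})

test_that("permutation p-values are super-uniform under the integer-valued generator null", {
  # equal-parameter groups from the plug generator; ties make the test
  # conservative, so the rejection rate must not exceed the nominal level
  # (Monte Carlo slack included)
  n_sim <- 400
  rej <- 0
  for (i in seq_len(n_sim)) {
    g <- gen_plug_groups(n_a = 25, n_b = 25, len_means = c(40, 40),
                         gly_probs = c(0.08, 0.08), seed = 5000 + i)
    st <- plug_stats(c(g$fit, g$git))
    r <- group_permutation_test(st$length_aa[1:25], st$length_aa[26:50],
                                n_permutations = 199, seed = i)
    rej <- rej + (r$p_value <= 0.05)
  }
  expect_lte(rej / n_sim, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_sim))
})
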