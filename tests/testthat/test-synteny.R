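# Operon synteny: feature reading, hit filtering, downstream pairing.

write_gff3 <- function(rows, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

test_that("GFF3 coordinates convert to 0-based half-open and sort by contig/start", {
  p <- write_gff3(c(
    "ctg2\tsrc\tgene\t100\t800\t.\t+\t.\tID=g2;product=thing",
    "ctg1\tsrc\tgene\t50\t400\t.\t-\t.\tID=g1"))
  f <- read_features(p)
  expect_equal(f$gene_id, c("g1", "g2"))        # sorted by contig then start
  expect_equal(f$start[f$gene_id == "g2"], 99)  # 1-based inclusive -> 0-based
  expect_equal(f$end[f$gene_id == "g2"], 800)
  expect_equal(f$strand, c("-", "+"))
  expect_equal(f$product[f$gene_id == "g2"], "thing")
})

test_that("malformed GFF3 rows are reported with their line number", {
  p <- write_gff3(c(
    "ctg1\tsrc\tgene\t100\t800\t.\t+\t.\tID=g1",
    "ctg1\tsrc\tgene\t900"))
  expect_error(read_features(p), "line 3")
})

test_that("GenBank CDS features parse with strand and qualifiers", {
  gb <- c(
    "LOCUS       ctgA        9000 bp    DNA     linear",
    "FEATURES             Location/Qualifiers",
    "     CDS             101..700",
    "                     /locus_tag=\"aaa_001\"",
    "                     /product=\"stator A subunit\"",
    "     CDS             complement(801..1400)",
    "                     /locus_tag=\"aaa_002\"",
    "                     /product=\"hypothetical protein\"",
    "ORIGIN",
    "//")
  p <- tempfile(fileext = ".gbk")
  writeLines(gb, p)
  f <- read_features(p)
  expect_equal(nrow(f), 2)
  expect_equal(f$start, c(100, 800))
  expect_equal(f$end, c(700, 1400))
  expect_equal(f$strand, c("+", "-"))
  expect_equal(f$product[1], "stator A subunit")
})

test_that("hit filtering keeps the boundary value and preserves order; idempotent", {
  hits <- data.frame(gene_id = c("a", "b", "c"),
                     similarity_pct = c(9.9, 10.0, 57.2),
                     source = "it1")
  kept <- filter_hits(hits, 10)
  expect_equal(kept$gene_id, c("b", "c"))
  expect_equal(filter_hits(hits, 0), hits)
  expect_equal(filter_hits(kept, 10), kept)
  expect_equal(nrow(filter_hits(hits[0, ], 10)), 0)
})

test_that("downstream pairing respects strand orientation and the gap window", {
  genes <- data.frame(
    gene_id = c("A1", "B1", "A2", "X2", "A3", "F3"),
    genome_id = "g", contig_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    start = c(99L, 809L, 99L, 820L, 99L, 5000L),
    end = c(800L, 1500L, 800L, 1400L, 800L, 5600L),
    strand = c("+", "+", "+", "-", "+", "+"),
    product = NA_character_)
  hits <- data.frame(gene_id = c("A1", "A2", "A3"),
                     similarity_pct = 50, source = "it1")
  pr <- pair_downstream(genes, hits, max_gap_bp = 500)
  expect_equal(pr$status, c("paired", "unpaired", "unpaired"))
  expect_equal(pr$b_gene[1], "B1")
  expect_equal(pr$intergenic_gap_bp[1], 9L)     # 809 - 800
  # A2: nearest downstream gene is on the opposite strand -> unpaired
  expect_true(is.na(pr$b_gene[2]))
  # A3: nearest same-strand gene beyond the window -> unpaired
  expect_true(is.na(pr$b_gene[3]))
})

test_that("minus-strand downstream means decreasing coordinates, overlap gives negative gap", {
  genes <- data.frame(
    gene_id = c("A1", "B1"), genome_id = "g", contig_id = "c1",
    start = c(2000L, 1200L), end = c(2900L, 2050L),
    strand = c("-", "-"), product = NA_character_)
  hits <- data.frame(gene_id = "A1", similarity_pct = 80, source = "it1")
  pr <- pair_downstream(genes, hits)
  expect_equal(pr$status, "paired")
  expect_equal(pr$b_gene, "B1")
  expect_equal(pr$intergenic_gap_bp, -50L)      # a.start 2000 - b.end 2050
})

test_that("unresolvable hit ids raise an error naming them", {
  genes <- data.frame(gene_id = "A1", genome_id = "g", contig_id = "c1",
                      start = 0L, end = 10L, strand = "+",
                      product = NA_character_)
  hits <- data.frame(gene_id = c("A1", "ghost"), similarity_pct = 50,
                     source = "x")
  expect_error(pair_downstream(genes, hits), "ghost")
})

test_that("pairing is invariant to gene-row permutation", {
  man_dir <- tempfile()
  gen_operon_genome(10, 3, 1, c(5, 100), seed = 42, dir = man_dir)
  genes <- read_features(file.path(man_dir, "genome.gff3"))
  hits <- filter_hits(read_hits(file.path(man_dir, "hits.tsv")))
  p1 <- pair_downstream(genes, hits)
  set.seed(9)
  p2 <- pair_downstream(genes[sample(nrow(genes)), ], hits)
  expect_equal(p1, p2)
})

test_that("planted operons are recovered end to end with duplicates flagged", {
  man_dir <- tempfile()
  man <- gen_operon_genome(30, 5, 2, c(5, 200), seed = 7, dir = man_dir)
  genes <- read_features(file.path(man_dir, "genome.gff3"))
  hits <- read_hits(file.path(man_dir, "hits.tsv"))
  kept <- filter_hits(hits, 10)
  # decoys are planted below 10% similarity, true hits at or above
  expect_equal(sort(setdiff(hits$gene_id, kept$gene_id)), sort(man$decoys))
  pr <- pair_downstream(genes, kept)
  truth_b <- vapply(man$pairs, function(x) x$b_gene, "")
  names(truth_b) <- vapply(man$pairs, function(x) x$a_gene, "")
  got <- pr$b_gene[match(names(truth_b), pr$a_gene)]
  expect_equal(unname(got), unname(truth_b))     # 100% recall
  expect_true(all(pr$status[pr$a_gene %in% man$duplicated_a] ==
                    "excluded_duplicate"))
  expect_false(any(pr$b_gene %in% man$decoys, na.rm = TRUE))
})

test_that("generated genome round-trips through the GFF3 reader with planted coordinates", {
  man_dir <- tempfile()
  man <- gen_operon_genome(5, 0, 0, c(10, 10), seed = 3, dir = man_dir)
  genes <- read_features(file.path(man_dir, "genome.gff3"))
  # planted plus-strand pair geometry: gap equals manifest gap
  for (pp in man$pairs) {
    a <- genes[genes$gene_id == pp$a_gene, ]
    b <- genes[genes$gene_id == pp$b_gene, ]
    gap <- if (pp$strand == "+") b$start - a$end else a$start - b$end
    expect_equal(gap, pp$gap_bp)
  }
})

test_that("product keyword report flags paired B genes lacking stator annotations", {
  man_dir <- tempfile()
  gen_operon_genome(4, 0, 0, c(10, 50), seed = 5, dir = man_dir)
  genes <- read_features(file.path(man_dir, "genome.gff3"))
  hits <- filter_hits(read_hits(file.path(man_dir, "hits.tsv")))
  pr <- pair_downstream(genes, hits)
  rep <- product_keyword_report(pr, genes)
  expect_true(all(rep$keyword_match))   # planted B products mention MotB
})
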