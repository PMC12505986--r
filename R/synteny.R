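# Operon-synteny pairing of A-subunit hits with their downstream B genes.
# Internal coordinates are 0-based half-open; GFF3/GenBank use 1-based
# inclusive and are converted on input. On the minus strand "downstream"
# means decreasing coordinate.

#' Read gene features from GFF3 or GenBank
#'
#' Reads gene/CDS rows from a GFF3 file (via rtracklayer) or CDS features
#' from a GenBank flat file, converts coordinates to 0-based half-open, and
#' returns records sorted by contig then start. Gene ids are taken from the
#' ID, locus_tag or gene attribute, in that order.
#'
#' @param path annotation file; format guessed from content/extension unless
#'   given
#' @param format one of "auto", "gff3", "genbank"
#' @param genome_id genome identifier recorded in each row (defaults to the
#'   file name without extension)
#' @return data.frame with columns gene_id, genome_id, contig_id, start, end,
#'   strand, product
#' @export
read_features <- function(path, format = c("auto", "gff3", "genbank"),
                          genome_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^LOCUS", first)) "genbank" else "gff3"
  }
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  feats <- if (format == "gff3") read_gff3_features(path)
           else read_genbank_features(path)
  if (nrow(feats) == 0) {
    warnf("no gene/CDS features found in %s", path)
    feats$genome_id <- character(0)
    return(feats)
  }
  feats$genome_id <- genome_id
  feats <- feats[order(feats$contig_id, feats$start), , drop = FALSE]
  if (anyDuplicated(feats$gene_id))
    stopf("duplicate gene_id within genome: %s",
          paste(unique(feats$gene_id[duplicated(feats$gene_id)]),
                collapse = ", "))
  rownames(feats) <- NULL
  feats[, c("gene_id", "genome_id", "contig_id", "start", "end",
            "strand", "product")]
}

#' @keywords internal
#' @noRd
read_gff3_features <- function(path) {
  # light pre-scan so malformed rows are reported with their line number
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9))
    stopf("malformed GFF3 row at line %d of %s (%d fields, expected 9)",
          body[which(nf != 9)[1]], path, nf[nf != 9][1])
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  # prefer gene rows; fall back to CDS where no gene rows exist
  if (any(as.character(gr$type) == "gene"))
    gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0)
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  mc <- S4Vectors::mcols(gr)
  pick <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else
    rep(NA_character_, length(gr))
  gid <- pick("ID")
  gid <- ifelse(is.na(gid), pick("locus_tag"), gid)
  gid <- ifelse(is.na(gid), pick("gene"), gid)
  if (anyNA(gid)) stopf("GFF3 rows without ID/locus_tag/gene attribute in %s",
                        path)
  data.frame(
    gene_id = gid,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = pick("product"),
    stringsAsFactors = FALSE)
}

# Minimal GenBank flat-file CDS feature parser (coordinates + locus_tag/gene
# and product qualifiers; joins and fuzzy locations are out of scope).
#' @keywords internal
#' @noRd
read_genbank_features <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0) stopf("not a GenBank flat file: %s", path)
  contigs <- sub("^LOCUS\\s+(\\S+).*", "\\1", lines[locus])
  recs <- list()
  cur_contig <- NA_character_
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^LOCUS", ln))
      cur_contig <- sub("^LOCUS\\s+(\\S+).*", "\\1", ln)
    if (grepl("^\\s{5}CDS\\s", ln)) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", ln))
      m <- regmatches(loc, regexec("^(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?$", loc))[[1]]
      if (length(m) == 0)
        stopf("malformed CDS location at line %d of %s: '%s'", i, path, loc)
      strand <- if (nzchar(m[2])) "-" else "+"
      start1 <- as.integer(m[3]); end1 <- as.integer(m[4])
      gid <- NA_character_; prod <- NA_character_
      j <- i + 1L
      while (j <= n && grepl("^\\s{21}", lines[j])) {
        q <- trimws(lines[j])
        if (grepl("^/locus_tag=", q) && is.na(gid))
          gid <- gsub('"', "", sub("^/locus_tag=", "", q))
        if (grepl("^/gene=", q) && is.na(gid))
          gid <- gsub('"', "", sub("^/gene=", "", q))
        if (grepl("^/product=", q))
          prod <- gsub('"', "", sub("^/product=", "", q))
        j <- j + 1L
      }
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = gid, contig_id = cur_contig,
        start = start1 - 1L, end = end1, strand = strand,
        product = prod, stringsAsFactors = FALSE)
      i <- j
    } else i <- i + 1L
  }
  if (length(recs) == 0)
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  if (anyNA(out$gene_id))
    out$gene_id[is.na(out$gene_id)] <-
      sprintf("cds_%04d", which(is.na(out$gene_id)))
  out
}

#' Read a homology hit table
#'
#' TSV with header \code{gene_id  similarity_pct  source}.
#'
#' @param path TSV path
#' @return data.frame of hits
#' @export
read_hits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "similarity_pct")
  if (!all(need %in% names(h)))
    stopf("hit table must have columns %s", paste(need, collapse = ", "))
  if (!"source" %in% names(h)) h$source <- NA_character_
  if (any(h$similarity_pct < 0 | h$similarity_pct > 100))
    stopf("similarity_pct out of [0,100]")
  h
}

#' Filter homolog hits by similarity
#'
#' Retains exactly the hits with \code{similarity_pct >= min_similarity_pct}
#' (sequences *below* the threshold are excluded, so the boundary value is
#' kept), preserving input order. The default of 10 reproduces the curation
#' rule used to trim spurious remote hits.
#'
#' @param hits data.frame with a similarity_pct column
#' @param min_similarity_pct threshold in percent (default 10)
#' @return the retained rows
#' @export
filter_hits <- function(hits, min_similarity_pct = 10) {
  hits[hits$similarity_pct >= min_similarity_pct, , drop = FALSE]
}

#' Pair A-subunit hits with the gene directly downstream
#'
#' For each A hit, the next gene downstream on the same contig (in strand
#' orientation of the A gene) is examined. If it lies on the same strand and
#' its strand-oriented 5' start is within \code{max_gap_bp} of the A gene's 3'
#' end, the pair is reported with status \code{"paired"}; otherwise the hit is
#' \code{"unpaired"}. When two or more A hits occur on one contig within
#' \code{dup_window_bp} of each other, all are flagged \code{a_duplicated}
#' with status \code{"excluded_duplicate"} (duplicated loci break the
#' one-A-one-B operon assumption). Intergenic gaps may be negative for
#' overlapping genes.
#'
#' @param genes data.frame from \code{\link{read_features}}
#' @param a_hits data.frame with a gene_id column (e.g. filtered hits)
#' @param max_gap_bp maximum intergenic gap in bp (default 500)
#' @param dup_window_bp window for duplicated-A detection (default 10000)
#' @return data.frame with columns genome_id, a_gene, b_gene, strand,
#'   intergenic_gap_bp, a_duplicated, status
#' @export
pair_downstream <- function(genes, a_hits, max_gap_bp = 500,
                            dup_window_bp = 10000) {
  missing <- setdiff(a_hits$gene_id, genes$gene_id)
  if (length(missing))
    stopf("a_hit gene_id(s) not found in gene records: %s",
          paste(missing, collapse = ", "))
  a_ids <- a_hits$gene_id
  arec <- genes[match(a_ids, genes$gene_id), , drop = FALSE]

  # duplicated-A loci: >=2 hits on one contig within dup_window_bp
  dup <- rep(FALSE, length(a_ids))
  for (ct in unique(arec$contig_id)) {
    idx <- which(arec$contig_id == ct)
    if (length(idx) < 2) next
    pos <- (arec$start[idx] + arec$end[idx]) / 2
    for (k in seq_along(idx)) {
      if (any(abs(pos[-k] - pos[k]) <= dup_window_bp)) dup[idx[k]] <- TRUE
    }
  }

  out <- lapply(seq_along(a_ids), function(k) {
    a <- arec[k, ]
    cand <- genes[genes$contig_id == a$contig_id &
                    genes$gene_id != a$gene_id, , drop = FALSE]
    if (a$strand == "+") {
      cand <- cand[cand$start > a$start, , drop = FALSE]
      cand <- cand[order(cand$start), , drop = FALSE]
    } else {
      cand <- cand[cand$end < a$end, , drop = FALSE]
      cand <- cand[order(-cand$end), , drop = FALSE]
    }
    row <- data.frame(genome_id = a$genome_id, a_gene = a$gene_id,
                      b_gene = NA_character_, strand = a$strand,
                      intergenic_gap_bp = NA_integer_,
                      a_duplicated = dup[k], status = "unpaired",
                      stringsAsFactors = FALSE)
    if (nrow(cand) > 0) {
      b <- cand[1, ]   # the gene directly downstream, any strand
      gap <- if (a$strand == "+") b$start - a$end else a$start - b$end
      if (b$strand == a$strand && gap <= max_gap_bp) {
        row$b_gene <- b$gene_id
        row$intergenic_gap_bp <- as.integer(gap)
        row$status <- "paired"
      }
    }
    if (dup[k]) row$status <- "excluded_duplicate"
    row
  })
  do.call(rbind, out)
}

#' Write an operon-pair table
#'
#' @param pairs data.frame from \code{\link{pair_downstream}}
#' @param path output TSV path
#' @param seed,config_hash recorded in the header comment
#' @export
write_pairs <- function(pairs, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  utils::write.table(
    pairs[, c("genome_id", "a_gene", "b_gene", "strand",
              "intergenic_gap_bp", "status")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Product-name keyword report for paired B genes
#'
#' A non-blocking stand-in for manual curation of B-subunit identity: flags
#' paired B genes whose product annotation does not mention any of the
#' given keywords.
#'
#' @param pairs data.frame from \code{\link{pair_downstream}}
#' @param genes data.frame from \code{\link{read_features}}
#' @param keywords character vector of case-insensitive keywords
#' @return data.frame of paired rows with product and keyword_match columns
#' @export
product_keyword_report <- function(pairs, genes,
                                   keywords = c("MotB", "OmpA", "ExbD",
                                                "TolR", "stator")) {
  p <- pairs[pairs$status == "paired", , drop = FALSE]
  prod <- genes$product[match(p$b_gene, genes$gene_id)]
  pat <- paste(keywords, collapse = "|")
  p$product <- prod
  p$keyword_match <- !is.na(prod) & grepl(pat, prod, ignore.case = TRUE)
  p
}
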