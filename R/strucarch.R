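# Automated four-letter architecture classification of A-subunit monomer
# models from C-alpha geometry. Regions: N-terminal appendage | TM1 TM2 |
# torque-generating interface (TGI, the TM2-TM3 cytoplasmic loop) | TM3 TM4 |
# C-terminal domain. Letters: N size (S/L), TGI complexity (S/Z/L), TM3
# integrity (N/B), C-terminal size (S/L). The classification was originally
# done by expert inspection; every numeric threshold here is this package's
# own, chosen on idealized helix geometry and validated on generated
# structures, and all are configurable through `arch_config()`.

#' Classification thresholds
#'
#' @param tm_min_len minimum residues for a transmembrane helix candidate (15)
#' @param tm_min_kd minimum mean Kyte-Doolittle hydropathy of a TM candidate
#'   (1.0)
#' @param merge_gap_max maximum coil residues between two hydrophobic helix
#'   segments merged into one composite (broken) TM candidate (6)
#' @param kink_angle_deg TM3 is called broken above this inter-half axis angle
#'   even without a coil interruption (25)
#' @param n_appendage_large minimum N-appendage span, in residues, for letter
#'   L (20)
#' @param tgi_helix_min_len minimum helix length counted in the TGI region (6)
#' @param strand_min_len minimum strand length counted for the Z call (3)
#' @param c_helices_large minimum C-terminal helix count for letter L (2)
#' @return list of thresholds
#' @export
arch_config <- function(tm_min_len = 15, tm_min_kd = 1.0, merge_gap_max = 6,
                        kink_angle_deg = 25, n_appendage_large = 20,
                        tgi_helix_min_len = 6, strand_min_len = 3,
                        c_helices_large = 2) {
  list(tm_min_len = tm_min_len, tm_min_kd = tm_min_kd,
       merge_gap_max = merge_gap_max, kink_angle_deg = kink_angle_deg,
       n_appendage_large = n_appendage_large,
       tgi_helix_min_len = tgi_helix_min_len,
       strand_min_len = strand_min_len, c_helices_large = c_helices_large)
}

#' Parse a protein structure (PDB or mmCIF) to a C-alpha model
#'
#' Extracts the C-alpha trace of one chain (the first, unless named).
#' Multi-model files use the first model with a warning; insertion-coded
#' residues are renumbered sequentially.
#'
#' @param path PDB (.pdb) or mmCIF (.cif) file
#' @param chain chain id, or NULL for the first chain
#' @return object of class \code{stator_structure}: data.frame of residues
#'   (idx, resno, aa, x, y, z) plus chain and source attributes
#' @export
parse_structure <- function(path, chain = NULL) {
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  a <- pdb$atom
  ca <- a[a$elety == "CA" & a$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0) stopf("no C-alpha atoms in %s", path)
  chain <- chain %||% ca$chain[1]
  ca <- ca[ca$chain == chain, , drop = FALSE]
  if (nrow(ca) == 0) stopf("chain '%s' not found in %s", chain, path)
  ca <- ca[order(ca$resno), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]   # altloc duplicates
  res <- data.frame(
    idx = seq_len(nrow(ca)),
    resno = ca$resno,
    aa = unname(bio3d::aa321(ca$resid)),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(res[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in %s", path)
  structure(res, class = c("stator_structure", "data.frame"),
            chain = chain, source = basename(path))
}

#' @export
print.stator_structure <- function(x, ...) {
  cat(sprintf("Structure %s chain %s: %d residues (C-alpha)\n",
              attr(x, "source"), attr(x, "chain"), nrow(x)))
  invisible(x)
}

#' Assign secondary structure from C-alpha distances
#'
#' P-SEA-style criteria on short-range C-alpha distances: residue window i is
#' helical when d(i,i+2) in [5.1, 6.1], d(i,i+3) in [4.6, 6.0] and d(i,i+4)
#' in [5.5, 7.3] Angstrom (a passing window marks residues i..i+4); strand
#' when d(i,i+2) in [6.3, 7.2] and d(i,i+3) in [9.0, 11.0] (marks i..i+3).
#' Helix runs shorter than 5 and strand runs shorter than 3 revert to coil;
#' a single coil residue between two helix runs is merged into helix.
#'
#' @param struct a \code{stator_structure}
#' @return character vector of per-residue labels in c("H","E","C")
#' @export
assign_ss <- function(struct) {
  n <- nrow(struct)
  if (n < 5) return(rep("C", n))
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  dk <- function(k) {
    d <- sqrt(rowSums((xyz[seq_len(n - k) + k, , drop = FALSE] -
                         xyz[seq_len(n - k), , drop = FALSE])^2))
    c(d, rep(NA, k))
  }
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
  hwin <- !is.na(d4) & d2 >= 5.1 & d2 <= 6.1 & d3 >= 4.6 & d3 <= 6.0 &
    d4 >= 5.5 & d4 <= 7.3
  ewin <- !is.na(d3) & d2 >= 6.3 & d2 <= 7.2 & d3 >= 9.0 & d3 <= 11.0
  lab <- rep("C", n)
  for (i in which(ewin)) lab[i:min(n, i + 3)] <- "E"
  for (i in which(hwin)) lab[i:min(n, i + 4)] <- "H"   # helix wins conflicts
  revert_short <- function(lab, value, minlen) {
    r <- runs_of(lab, value)
    for (j in seq_len(nrow(r)))
      if (r$length[j] < minlen) lab[r$start[j]:r$end[j]] <- "C"
    lab
  }
  lab <- revert_short(lab, "H", 5)
  lab <- revert_short(lab, "E", 3)
  # single coil residue flanked by helix on both sides -> helix
  if (n >= 3) {
    singles <- which(lab == "C")
    singles <- singles[singles > 1 & singles < n]
    singles <- singles[lab[singles - 1] == "H" & lab[singles + 1] == "H"]
    lab[singles] <- "H"
  }
  lab
}

# principal axis of a residue range, oriented start -> end
#' @keywords internal
#' @noRd
segment_axis <- function(struct, start, end) {
  xyz <- as.matrix(struct[struct$idx >= start & struct$idx <= end,
                          c("x", "y", "z")])
  if (nrow(xyz) < 2) return(c(0, 0, 1))
  v <- svd(scale(xyz, scale = FALSE))$v[, 1]
  if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' @keywords internal
#' @noRd
segment_kd <- function(struct, start, end) {
  aa <- struct$aa[struct$idx >= start & struct$idx <= end]
  mean(KYTE_DOOLITTLE[aa], na.rm = TRUE)
}

#' Detect transmembrane helices and partition the chain into domains
#'
#' TM candidates are helix segments of length >= \code{tm_min_len} with mean
#' Kyte-Doolittle hydropathy >= \code{tm_min_kd}; two hydrophobic helix
#' segments separated by <= \code{merge_gap_max} coil residues are merged into
#' one composite candidate (a broken TM counts as one helix). The four
#' top-scoring candidates (by mean hydropathy), taken in sequence order,
#' become TM1-TM4; the chain before TM1, between TM2 and TM3, and after TM4
#' becomes the N appendage, the TGI (cytoplasmic) region and the C-terminal
#' domain. "Cytoplasmic" is defined topologically as the TM2-TM3 inter-helix
#' region, since monomer models carry no membrane frame.
#'
#' @param struct a \code{stator_structure}
#' @param ss labels from \code{\link{assign_ss}} (computed if NULL)
#' @param config thresholds from \code{\link{arch_config}}
#' @return list with status ("ok" or "unclassifiable" + reason), tm (list of
#'   segments with start, end, composite, sub_segments, kd), n_appendage,
#'   tgi_region, c_terminal (each c(start, end) or NULL), ss
#' @export
detect_tm_helices <- function(struct, ss = NULL, config = arch_config()) {
  ss <- ss %||% assign_ss(struct)
  hseg <- runs_of(ss, "H")
  # TM helices are hydrophobicity-defined: extend each helix segment over
  # contiguous residues with per-residue KD >= tm_min_kd (helix ends erode
  # under coordinate noise, but the hydrophobic span does not), then coalesce
  # segments that touch
  n_res <- nrow(struct)
  kd_res <- KYTE_DOOLITTLE[struct$aa] >= config$tm_min_kd
  kd_res[is.na(kd_res)] <- FALSE
  if (nrow(hseg) > 0) {
    for (j in seq_len(nrow(hseg))) {
      while (hseg$start[j] > 1 && kd_res[hseg$start[j] - 1])
        hseg$start[j] <- hseg$start[j] - 1L
      while (hseg$end[j] < n_res && kd_res[hseg$end[j] + 1])
        hseg$end[j] <- hseg$end[j] + 1L
    }
    # coalesce overlapping/adjacent spans (e.g. one helix fragmented by noise)
    keep <- list(hseg[1, ])
    for (j in seq_len(nrow(hseg))[-1]) {
      last <- keep[[length(keep)]]
      if (hseg$start[j] <= last$end + 1) {
        last$end <- max(last$end, hseg$end[j])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1]] <- hseg[j, ]
    }
    hseg <- do.call(rbind, keep)
    hseg$length <- hseg$end - hseg$start + 1L
  }
  # hydrophobic merge pass for broken TM helices
  cands <- list()
  i <- 1
  while (i <= nrow(hseg)) {
    seg <- list(start = hseg$start[i], end = hseg$end[i],
                composite = FALSE, sub_segments = list(c(hseg$start[i],
                                                         hseg$end[i])))
    while (i < nrow(hseg)) {
      gap_res <- hseg$start[i + 1] - hseg$end[i] - 1
      gap_is_coil <- gap_res >= 1 && gap_res <= config$merge_gap_max &&
        all(ss[(hseg$end[i] + 1):(hseg$start[i + 1] - 1)] == "C")
      both_hydro <- segment_kd(struct, seg$start, hseg$end[i]) >=
        config$tm_min_kd &&
        segment_kd(struct, hseg$start[i + 1], hseg$end[i + 1]) >=
        config$tm_min_kd
      # only fragments shorter than a full TM span are merge candidates;
      # two full-length hydrophobic helices are distinct TM helices
      both_fragments <- (hseg$end[i] - seg$start + 1) < config$tm_min_len &&
        hseg$length[i + 1] < config$tm_min_len
      if (gap_is_coil && both_hydro && both_fragments) {
        i <- i + 1
        seg$end <- hseg$end[i]
        seg$composite <- TRUE
        seg$sub_segments <- c(seg$sub_segments,
                              list(c(hseg$start[i], hseg$end[i])))
      } else break
    }
    cands[[length(cands) + 1]] <- seg
    i <- i + 1
  }
  for (j in seq_along(cands)) {
    cands[[j]]$length <- cands[[j]]$end - cands[[j]]$start + 1
    cands[[j]]$kd <- segment_kd(struct, cands[[j]]$start, cands[[j]]$end)
  }
  keep <- vapply(cands, function(s)
    s$length >= config$tm_min_len && s$kd >= config$tm_min_kd, logical(1))
  cands <- cands[keep]
  fail <- function(reason)
    list(status = "unclassifiable", reason = reason, tm = cands,
         n_appendage = NULL, tgi_region = NULL, c_terminal = NULL, ss = ss)
  if (length(cands) < 2)
    return(fail(sprintf("%d TM helix candidate(s); need at least 2",
                        length(cands))))
  if (length(cands) < 4)
    return(fail(sprintf("%d TM helix candidates; need 4 for the code",
                        length(cands))))
  if (length(cands) > 4) {
    ord <- order(vapply(cands, `[[`, 0, "kd"), decreasing = TRUE)
    cands <- cands[sort(ord[1:4])]
  }
  n <- nrow(struct)
  tm <- cands
  napp <- if (tm[[1]]$start > 1) c(1L, tm[[1]]$start - 1L) else NULL
  tgi <- if (tm[[3]]$start - tm[[2]]$end > 1)
    c(tm[[2]]$end + 1L, tm[[3]]$start - 1L) else NULL
  cterm <- if (tm[[4]]$end < n) c(tm[[4]]$end + 1L, n) else NULL
  list(status = "ok", reason = NA_character_, tm = tm,
       n_appendage = napp, tgi_region = tgi, c_terminal = cterm, ss = ss)
}

#' TM3 integrity letter
#'
#' \code{"B"} (broken) when TM3 is a composite candidate (helical
#' sub-segments separated by 1-6 coil residues; the coil rule takes
#' precedence, so a straight composite is still broken) or when the angle
#' between the axes of its two halves exceeds \code{kink_angle_deg};
#' otherwise \code{"N"}.
#'
#' @param struct a \code{stator_structure}
#' @param partition result of \code{\link{detect_tm_helices}}
#' @param config thresholds
#' @return "N" or "B"
#' @export
tm3_break <- function(struct, partition, config = arch_config()) {
  tm3 <- partition$tm[[3]]
  if (isTRUE(tm3$composite)) return("B")
  mid <- floor((tm3$start + tm3$end) / 2)
  a1 <- segment_axis(struct, tm3$start, mid)
  a2 <- segment_axis(struct, mid + 1, tm3$end)
  ang <- acos(min(1, max(-1, sum(a1 * a2)))) * 180 / pi
  if (ang > config$kink_angle_deg) "B" else "N"
}

#' TGI complexity letter and cytoplasmic helix count
#'
#' Counts helix segments of length >= \code{tgi_helix_min_len} lying within
#' the TGI (TM2-TM3) region: \code{"L"} for >= 3 helices, else \code{"Z"}
#' when >= 2 strand segments of length >= \code{strand_min_len} are present
#' (the beta-sheet cytoplasmic domain of Zorya-type proteins), else
#' \code{"S"}.
#'
#' @param partition result of \code{\link{detect_tm_helices}}
#' @param config thresholds
#' @return list(letter, cytoplasmic_helix_count)
#' @export
tgi_letter <- function(partition, config = arch_config()) {
  reg <- partition$tgi_region
  ss <- partition$ss
  if (is.null(reg)) return(list(letter = "S", cytoplasmic_helix_count = 0L))
  in_region <- function(seg) seg$start >= reg[1] & seg$end <= reg[2]
  hs <- runs_of(ss, "H")
  hs <- hs[hs$start >= reg[1] & hs$end <= reg[2] &
             hs$length >= config$tgi_helix_min_len, , drop = FALSE]
  es <- runs_of(ss, "E")
  es <- es[es$start >= reg[1] & es$end <= reg[2] &
             es$length >= config$strand_min_len, , drop = FALSE]
  nh <- nrow(hs)
  letter <- if (nh >= 3) "L" else if (nrow(es) >= 2) "Z" else "S"
  list(letter = letter, cytoplasmic_helix_count = as.integer(nh))
}

#' N-terminal and C-terminal size letters
#'
#' First letter: \code{"L"} when the N appendage (residues before TM1) spans
#' >= \code{n_appendage_large} residues, else \code{"S"}. Fourth letter:
#' \code{"L"} when >= \code{c_helices_large} helix segments lie in the
#' C-terminal region (one C-terminal helix is the minimal, "small"
#' configuration), else \code{"S"}.
#'
#' @param partition result of \code{\link{detect_tm_helices}}
#' @param config thresholds
#' @return list(first, fourth, n_appendage_len, c_helices)
#' @export
terminal_letters <- function(partition, config = arch_config()) {
  nlen <- if (is.null(partition$n_appendage)) 0L else
    partition$n_appendage[2] - partition$n_appendage[1] + 1L
  first <- if (nlen >= config$n_appendage_large) "L" else "S"
  ch <- 0L
  if (!is.null(partition$c_terminal)) {
    hs <- runs_of(partition$ss, "H")
    ch <- sum(hs$start >= partition$c_terminal[1] &
                hs$end <= partition$c_terminal[2] & hs$length >= 5)
  }
  fourth <- if (ch >= config$c_helices_large) "L" else "S"
  list(first = first, fourth = fourth, n_appendage_len = nlen,
       c_helices = as.integer(ch))
}

#' Four-letter architecture code of a structure
#'
#' Orchestrates secondary-structure assignment, TM detection and the letter
#' rules. The cytoplasmic class follows the cytoplasmic (TGI-region) helix
#' count: 2 -> CCD2, 3 -> CCD3, 4 -> TGI4, 5 -> TGI5, anything else ->
#' "other". Reference architectures: an E. coli MotA-like feature set gives
#' \code{"SLNL"}; an ExbB-like one gives \code{"LSBL"}.
#'
#' @param struct a \code{stator_structure} (or path to a PDB/mmCIF file)
#' @param config thresholds from \code{\link{arch_config}}
#' @return object of class \code{stator_arch}: list with code, letters,
#'   cytoplasmic_helix_count, cyto_class, tm3, n_appendage_len, c_helices,
#'   status, reason, model_id
#' @export
architecture_code <- function(struct, config = arch_config()) {
  if (is.character(struct)) struct <- parse_structure(struct)
  part <- detect_tm_helices(struct, config = config)
  mk <- function(code, letters, tgi, tm3, term, status, reason) {
    cls <- if (status != "ok") NA_character_ else
      switch(as.character(tgi$cytoplasmic_helix_count),
             "2" = "CCD2", "3" = "CCD3", "4" = "TGI4", "5" = "TGI5", "other")
    structure(list(code = code, letters = letters,
                   cytoplasmic_helix_count =
                     if (status == "ok") tgi$cytoplasmic_helix_count else NA,
                   cyto_class = cls, tm3 = tm3,
                   n_appendage_len = if (status == "ok") term$n_appendage_len
                                     else NA,
                   c_helices = if (status == "ok") term$c_helices else NA,
                   status = status, reason = reason,
                   model_id = attr(struct, "source") %||% "structure"),
              class = "stator_arch")
  }
  if (part$status != "ok")
    return(mk(NA_character_, NULL, NULL, NA_character_, NULL,
              "unclassifiable", part$reason))
  tgi <- tgi_letter(part, config)
  tm3 <- tm3_break(struct, part, config)
  term <- terminal_letters(part, config)
  letters <- c(term$first, tgi$letter, tm3, term$fourth)
  mk(paste(letters, collapse = ""), letters, tgi, tm3, term, "ok",
     NA_character_)
}

#' @export
print.stator_arch <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("%s: %s (cyto class %s, %d TGI helices, TM3 %s)\n",
                x$model_id, x$code, x$cyto_class,
                x$cytoplasmic_helix_count, x$tm3))
  else
    cat(sprintf("%s: unclassifiable (%s)\n", x$model_id, x$reason))
  invisible(x)
}

#' Size of the architecture code space
#'
#' Product of the per-position alphabet sizes; 16 for the default
#' {S,L} x {S,L} x {N,B} x {S,L}, 24 when Z is allowed at position 2.
#'
#' @param alphabets list of character vectors, one per code position
#' @return integer
#' @export
code_space <- function(alphabets = list(c("S", "L"), c("S", "L"),
                                        c("N", "B"), c("S", "L"))) {
  prod(lengths(alphabets))
}

#' Summarize architecture codes per group
#'
#' @param codes list of \code{stator_arch} objects (or character codes)
#' @param groups optional named map model_id -> group; single group otherwise
#' @param space code-space size for the coverage fraction
#' @return list with \code{by_group} (data.frame group, n, n_distinct,
#'   coverage) and \code{freq} (data.frame group, code, count)
#' @export
summarize_codes <- function(codes, groups = NULL, space = code_space()) {
  if (length(codes) && inherits(codes[[1]], "stator_arch")) {
    ids <- vapply(codes, `[[`, "", "model_id")
    cds <- vapply(codes, function(x) x$code %||% NA_character_, "")
  } else {
    cds <- as.character(unlist(codes))
    ids <- names(cds) %||% as.character(seq_along(cds))
  }
  grp <- if (is.null(groups)) rep("all", length(cds)) else {
    g <- unname(groups[ids]); ifelse(is.na(g), "other", g)
  }
  ok <- !is.na(cds)
  all_groups <- unique(grp)
  by_group <- do.call(rbind, lapply(all_groups, function(g) {
    cg <- cds[ok & grp == g]
    data.frame(group = g, n = sum(grp == g),
               n_distinct = length(unique(cg)),
               coverage = length(unique(cg)) / space,
               stringsAsFactors = FALSE)
  }))
  freq <- if (any(ok)) {
    f <- as.data.frame(table(group = grp[ok], code = cds[ok]),
                       stringsAsFactors = FALSE)
    names(f)[3] <- "count"
    f <- f[f$count > 0, , drop = FALSE]
    rownames(f) <- NULL
    f
  } else data.frame(group = character(0), code = character(0),
                    count = integer(0))
  list(by_group = by_group, freq = freq)
}

#' Write an architecture classification table
#'
#' @param archs list of \code{stator_arch}
#' @param path output TSV
#' @param seed,config_hash recorded in the header
#' @export
write_codes <- function(archs, path, seed = NULL, config_hash = NULL) {
  df <- do.call(rbind, lapply(archs, function(a) data.frame(
    model_id = a$model_id, code = a$code %||% NA,
    cyto_class = a$cyto_class %||% NA,
    tgi_helices = a$cytoplasmic_helix_count %||% NA,
    tm3 = a$tm3 %||% NA, n_appendage_len = a$n_appendage_len %||% NA,
    c_helices = a$c_helices %||% NA, status = a$status,
    stringsAsFactors = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
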