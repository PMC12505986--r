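# Pipeline orchestration: one config (list or YAML file) drives every stage.
# Machine outputs go to files under config$out_dir; log messages go to
# standard error. All randomness derives from config$seed, and nothing
# time-dependent is written, so re-running with one seed reproduces every
# output byte for byte.

#' Build and validate a run configuration
#'
#' Unknown keys are rejected; missing keys take defaults. The effective
#' configuration is echoed into the output directory by \code{\link{run_all}}.
#'
#' @param config a named list, a YAML file path, or NULL for all defaults
#' @param ... individual overrides (e.g. \code{seed = 7})
#' @return validated config list of class \code{stator_config}
#' @export
run_config <- function(config = NULL, ...) {
  defaults <- list(
    seed = 1L,
    out_dir = "statorevo_out",
    synteny = list(min_similarity_pct = 10, max_gap_bp = 500,
                   dup_window_bp = 10000),
    alnstats = list(region_first = 76, region_last = 133,
                    n_permutations = 999),
    treeset = list(burnin_fraction = 0, estimator = "CCD1"),
    asr = list(gap_threshold = 0.5, optimize_lengths = FALSE),
    strucarch = arch_config(),
    simulate = list(n_taxa = 20, birth_rate = 2, n_trees = 100,
                    nni_rate_b_like = 8, nni_rate_a_like = 2,
                    nni_rate_joint = 0.5,
                    n_cols = 120, indel_rate = 0.1, mean_gap_len = 6,
                    n_operons = 30, n_decoys = 5, n_duplicated = 2,
                    gap_bp_range = c(5, 200),
                    reps_per_code = 1, noise_sigma = 0.1,
                    plug_n_fit = 102, plug_n_git = 277,
                    plug_len_means = c(52, 35),
                    plug_gly_probs = c(0.115, 0.06),
                    plug_pro_probs = c(0.096, 0.05)))
  user <- if (is.character(config)) yaml::read_yaml(config)
          else config %||% list()
  over <- list(...)
  merge_checked <- function(def, usr, path = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stopf("unknown config key(s): %s",
            paste0(path, unknown, collapse = ", "))
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && is.list(usr[[nm]]))
        def[[nm]] <- merge_checked(def[[nm]], usr[[nm]],
                                   paste0(path, nm, "."))
      else def[[nm]] <- usr[[nm]]
    }
    def
  }
  cfg <- merge_checked(defaults, user)
  cfg <- merge_checked(cfg, over)
  # the hash fingerprints the scientific parameters, not the output location
  cfg$config_hash <- fnv1a32(yaml::as.yaml(cfg[setdiff(names(cfg),
                                                       c("config_hash",
                                                         "out_dir"))]))
  structure(cfg, class = c("stator_config", "list"))
}

#' @keywords internal
#' @noRd
log_msg <- function(...) message("[statorevo] ", ...)

#' @keywords internal
#' @noRd
stage_paths <- function(config) {
  d <- config$out_dir
  list(sim = file.path(d, "sim"),
       pairs = file.path(d, "pairs.tsv"),
       plug_stats = file.path(d, "plug_stats.tsv"),
       plug_test = file.path(d, "plug_test.json"),
       entropy_json = file.path(d, "entropy.json"),
       entropy_tsv = file.path(d, "entropy.tsv"),
       map_nexus = file.path(d, "map_tree_annotated.nexus"),
       ancestors = file.path(d, "ancestors.fasta"),
       asr_posteriors = file.path(d, "asr_max_posteriors.tsv"),
       codes = file.path(d, "codes.tsv"),
       code_summary = file.path(d, "code_summary.tsv"),
       config_echo = file.path(d, "effective_config.yaml"))
}

#' Simulate all pipeline inputs
#'
#' Writes synthetic genomes, alignments, tree samples and structures (with
#' manifests) under \code{out_dir/sim}.
#'
#' @param config a \code{stator_config}
#' @return (invisibly) list of generated input descriptions
#' @export
run_simulate <- function(config = run_config()) {
  p <- stage_paths(config)
  s <- config$simulate
  dir.create(p$sim, showWarnings = FALSE, recursive = TRUE)
  log_msg("simulating inputs under ", p$sim)
  seed <- config$seed
  genome <- gen_operon_genome(s$n_operons, s$n_decoys, s$n_duplicated,
                              s$gap_bp_range, seed = derive_seed(seed, 1),
                              dir = file.path(p$sim, "genome"))
  base <- gen_yule_tree(s$n_taxa, s$birth_rate, seed = derive_seed(seed, 2))
  samples <- list(b_like = gen_tree_sample(base, s$nni_rate_b_like,
                                           s$n_trees, derive_seed(seed, 3)),
                  a_like = gen_tree_sample(base, s$nni_rate_a_like,
                                           s$n_trees, derive_seed(seed, 4)),
                  joint = gen_tree_sample(base, s$nni_rate_joint,
                                          s$n_trees, derive_seed(seed, 5)))
  for (nm in names(samples))
    write_tree_sample(samples[[nm]], file.path(p$sim,
                                               paste0(nm, ".trees.nwk")))
  ape::write.tree(base, file.path(p$sim, "base_tree.nwk"))
  sim_aln <- gen_alignment(base, rate_model("LG"), s$n_cols, s$indel_rate,
                           s$mean_gap_len, seed = derive_seed(seed, 6))
  write_alignment(sim_aln$aln, file.path(p$sim, "alignment.fasta"))
  codes <- apply(expand.grid(c("S", "L"), c("S", "L"), c("N", "B"),
                             c("S", "L"), stringsAsFactors = FALSE), 1,
                 paste, collapse = "")
  struct_dir <- file.path(p$sim, "structures")
  dir.create(struct_dir, showWarnings = FALSE)
  structs <- list()
  for (i in seq_along(codes)) {
    for (r in seq_len(s$reps_per_code)) {
      f <- file.path(struct_dir, sprintf("%s_%02d.pdb", codes[i], r))
      gs <- gen_structure(codes[i], seed = derive_seed(seed, 100 + 10 * i + r),
                          noise_sigma = s$noise_sigma, file = f)
      structs[[length(structs) + 1L]] <- list(path = f, code = codes[i])
    }
  }
  plug <- gen_plug_groups(s$plug_n_fit, s$plug_n_git, s$plug_len_means,
                          s$plug_gly_probs, s$plug_pro_probs,
                          seed = derive_seed(seed, 7))
  invisible(list(genome = genome, base_tree = base, samples = samples,
                 alignment = sim_aln, structures = structs, plug = plug))
}

#' Run the synteny pairing stage
#'
#' @param config a \code{stator_config}
#' @param sim simulated inputs from \code{\link{run_simulate}} (regenerated
#'   if NULL)
#' @return (invisibly) the pair table
#' @export
run_pair <- function(config = run_config(), sim = NULL) {
  p <- stage_paths(config)
  sim <- sim %||% run_simulate(config)
  log_msg("pairing A hits with downstream B genes")
  genes <- read_features(file.path(p$sim, "genome", "genome.gff3"))
  hits <- read_hits(file.path(p$sim, "genome", "hits.tsv"))
  hits <- filter_hits(hits, config$synteny$min_similarity_pct)
  pairs <- pair_downstream(genes, hits, config$synteny$max_gap_bp,
                           config$synteny$dup_window_bp)
  write_pairs(pairs, p$pairs, config$seed, config$config_hash)
  log_msg(sprintf("  %d paired, %d unpaired, %d excluded_duplicate",
                  sum(pairs$status == "paired"),
                  sum(pairs$status == "unpaired"),
                  sum(pairs$status == "excluded_duplicate")))
  invisible(pairs)
}

#' Run the alignment/plug statistics stage
#'
#' @inheritParams run_pair
#' @return (invisibly) list(stats, test)
#' @export
run_alnstats <- function(config = run_config(), sim = NULL) {
  p <- stage_paths(config)
  sim <- sim %||% run_simulate(config)
  log_msg("plug+linker statistics and FIT vs GIT test")
  plug <- sim$plug
  subseqs <- c(plug$fit, plug$git)
  st <- plug_stats(subseqs, plug$groups)
  con <- file(p$plug_stats, "w")
  writeLines(output_header(config$seed, config$config_hash), con)
  utils::write.table(st[, c("seq_id", "group", "length_aa", "gly", "pro",
                            "gg")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  fit_rows <- st$group %in% c("TGI4", "TGI5")
  tests <- list(
    length = group_permutation_test(st$length_aa[fit_rows],
                                    st$length_aa[!fit_rows],
                                    config$alnstats$n_permutations,
                                    derive_seed(config$seed, 20)),
    glycine = group_permutation_test(st$gly[fit_rows], st$gly[!fit_rows],
                                     config$alnstats$n_permutations,
                                     derive_seed(config$seed, 21)))
  jsonlite::write_json(list(version = as.character(
    utils::packageVersion("statorevo")),
    seed = config$seed, config = config$config_hash, tests = tests),
    p$plug_test, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg(sprintf("  length p=%.4g glycine p=%.4g",
                  tests$length$p_value, tests$glycine$p_value))
  invisible(list(stats = st, tests = tests))
}

#' Run the tree-entropy comparison stage
#'
#' @inheritParams run_pair
#' @return (invisibly) the entropy comparison table
#' @export
run_entropy <- function(config = run_config(), sim = NULL) {
  p <- stage_paths(config)
  sim <- sim %||% run_simulate(config)
  log_msg("CCD entropy comparison across tree samples")
  tab <- compare_entropy(sim$samples, config$treeset$estimator)
  jsonlite::write_json(list(version = as.character(
    utils::packageVersion("statorevo")),
    seed = config$seed, config = config$config_hash, entropy = tab),
    p$entropy_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  con <- file(p$entropy_tsv, "w")
  writeLines(output_header(config$seed, config$config_hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ccd <- build_ccd(sim$samples$joint, config$treeset$estimator)
  mt <- map_tree(ccd)
  mt <- annotate_support(mt, sim$samples$joint)
  write_annotated_nexus(mt, p$map_nexus)
  log_msg(paste(capture_tab(tab), collapse = "; "))
  invisible(tab)
}

#' @keywords internal
#' @noRd
capture_tab <- function(tab) {
  sprintf("%s: %.2f nats (%d clades)", tab$name, tab$entropy_nats,
          tab$n_distinct_clades)
}

#' Run the ancestral reconstruction stage
#'
#' @inheritParams run_pair
#' @return (invisibly) the reconstruction result
#' @export
run_asr <- function(config = run_config(), sim = NULL) {
  p <- stage_paths(config)
  sim <- sim %||% run_simulate(config)
  log_msg("marginal ancestral reconstruction with gap calls")
  recon <- reconstruct_ancestral_sequences(
    sim$alignment$truth$tree, sim$alignment$aln,
    gap_threshold = config$asr$gap_threshold,
    optimize_lengths = config$asr$optimize_lengths)
  write_ancestors(recon, p$ancestors)
  maxp <- do.call(rbind, lapply(recon$ancestors, function(a)
    data.frame(node_id = a$node_id,
               column = seq_along(a$max_posterior),
               max_posterior = round(a$max_posterior, 6),
               stringsAsFactors = FALSE)))
  con <- file(p$asr_posteriors, "w")
  writeLines(output_header(config$seed, config$config_hash), con)
  utils::write.table(maxp, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(recon)
}

#' Run the structural classification stage
#'
#' @inheritParams run_pair
#' @return (invisibly) list(archs, summary)
#' @export
run_classify <- function(config = run_config(), sim = NULL) {
  p <- stage_paths(config)
  sim <- sim %||% run_simulate(config)
  log_msg("architecture classification of structure models")
  cfg <- do.call(arch_config, config$strucarch)
  archs <- lapply(sim$structures, function(s)
    architecture_code(parse_structure(s$path), cfg))
  write_codes(archs, p$codes, config$seed, config$config_hash)
  truth <- vapply(sim$structures, `[[`, "", "code")
  got <- vapply(archs, function(a) a$code %||% NA_character_, "")
  acc <- mean(!is.na(got) & got == truth)
  summ <- summarize_codes(archs)
  con <- file(p$code_summary, "w")
  writeLines(c(output_header(config$seed, config$config_hash),
               sprintf("# planted-code recovery: %.3f", acc)), con)
  utils::write.table(summ$freq, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  log_msg(sprintf("  recovered %.0f%% of planted codes", 100 * acc))
  invisible(list(archs = archs, summary = summ, recovery = acc))
}

#' Run the whole pipeline on synthetic inputs
#'
#' Simulates every input, then runs pairing, plug statistics, entropy
#' comparison, ancestral reconstruction and structural classification,
#' writing all outputs (with version/seed/config-hash headers) under
#' \code{config$out_dir}. Re-running with the same seed reproduces every
#' output byte for byte.
#'
#' @param config a \code{stator_config}, config list, or YAML path
#' @return (invisibly) named list of stage results
#' @export
run_all <- function(config = run_config()) {
  if (!inherits(config, "stator_config")) config <- run_config(config)
  p <- stage_paths(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- unclass(config)
  echo$out_dir <- NULL   # location is not part of the reproducible state
  yaml::write_yaml(echo, p$config_echo)
  t0 <- Sys.time()
  run_stage <- function(name, fun) {
    ts <- Sys.time()
    res <- tryCatch(fun, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log_msg(sprintf("stage %s done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }
  sim <- run_stage("simulate", run_simulate(config))
  out <- list(
    pairs = run_stage("pair", run_pair(config, sim)),
    alnstats = run_stage("aln-stats", run_alnstats(config, sim)),
    entropy = run_stage("entropy", run_entropy(config, sim)),
    asr = run_stage("asr", run_asr(config, sim)),
    classify = run_stage("classify", run_classify(config, sim)))
  log_msg(sprintf("pipeline complete in %.1fs -> %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$out_dir))
  invisible(out)
}
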