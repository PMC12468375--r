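#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' tunable parameter at its default. Values can be overridden by the
#' `...` arguments or by loading a YAML file with [load_config()].
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "consensusDR_run",
    stages = c("simulate", "de", "signature", "aggregate", "enrich",
               "structsim", "synergy", "report"),
    # synthetic study conditions
    n_genes = 1000L, n_planted_up = 100L, n_planted_down = 100L,
    effect_size = 2, noise_sd = 0.5, n_cases = 20L, n_controls = 20L,
    n_datasets = 4L, n_tools = 3L, n_drugs = 300L, n_true_reversers = 25L,
    rank_advantage = 0.9,
    disease_stages = c("MGUS", "sMM", "MM"),
    # consensus
    w1 = 0.7, w2 = 0.3, top_k = 50L, threshold = 0.75,
    absent_policy = "ignore",
    # de / signatures / enrichment
    alpha = 0.05, n_signature = 150L,
    n_gene_sets = 50L,
    # structural similarity
    n_bits = 1024L, fp_clusters = 3L, within_tanimoto = 0.95,
    sim_threshold = 0.80, soergel_cut = 0.15, linkage = "complete",
    # synergy
    synergy_thresholds = c(5, 10), synergy_delta = 10,
    synergy_noise_sd = 0, n_surfaces = 8L,
    dose_grid = c(0, 0.1, 0.3, 1, 3, 10, 30, 100)
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (abs(cfg$w1 + cfg$w2 - 1) > 1e-8)
    warning("w1 + w2 != 1 in configuration")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [default_config()].
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  do.call(default_config, overrides)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on synthetic data
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' inputs: simulate all input types; differential expression and
#' signature extraction per dataset and stage; two-level weighted
#' consensus aggregation of the tool outputs with shortlist retention;
#' pathway over-representation with the same cross-dataset aggregation;
#' fingerprint clustering and cross-set screening; synergy scoring of
#' planted dose-response surfaces; and a summary report. Every stage
#' writes plain-text outputs (with truth sidecars for synthetic inputs)
#' under `cfg$out_dir`, and a JSON run manifest records the configuration
#' and per-output MD5 hashes, so identical configurations reproduce
#' identical hashes.
#'
#' @param cfg A `pipeline_config` from [default_config()] or
#'   [load_config()].
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`). The in-memory results of each stage are attached
#'   as attribute `results`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  hash <- config_hash(cfg)
  res <- list()
  t0 <- Sys.time()
  stage_on <- function(s) s %in% cfg$stages

  if (stage_on("simulate")) {
    cdr_log("stage simulate")
    genes_up <- sprintf("UP%03d", seq_len(cfg$n_planted_up))
    genes_down <- sprintf("DN%03d", seq_len(cfg$n_planted_down))
    ex_truth <- planted_expression_truth(genes_up, genes_down,
                                         cfg$effect_size, cfg$noise_sd)
    res$datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
      gen_expression(cfg$n_genes, cfg$n_cases, cfg$n_controls, ex_truth,
                     seed = sub_seed(seed, d), dataset_id = sprintf("DS%d", d),
                     stage = cfg$disease_stages[1])
    })
    names(res$datasets) <- sprintf("DS%d", seq_len(cfg$n_datasets))
    ep <- file.path(cfg$out_dir, "expression_DS1.tsv")
    write_expression(res$datasets[[1]], ep,
                     file.path(cfg$out_dir, "samples_DS1.tsv"), seed = seed)
    write_truth_sidecar(ex_truth, ep)

    drug_universe <- sprintf("drug%03d", seq_len(cfg$n_drugs))
    tool_truth <- planted_tool_truth(
      true_reversers = utils::head(drug_universe, cfg$n_true_reversers),
      n_tools = cfg$n_tools, n_datasets = cfg$n_datasets,
      top_k = cfg$top_k, rank_advantage = cfg$rank_advantage)
    res$tool_outputs <- lapply(cfg$disease_stages, function(st) {
      gen_tool_outputs(drug_universe, tool_truth,
                       seed = sub_seed(seed, 1000L + match(st, cfg$disease_stages)),
                       stage = st)
    })
    names(res$tool_outputs) <- cfg$disease_stages
    tp <- file.path(cfg$out_dir, "tool_outputs.csv")
    write_tool_outputs(res$tool_outputs[[1]], tp, seed = seed)
    write_truth_sidecar(tool_truth, tp)

    res$fp_lib <- gen_fingerprints(cfg$n_drugs %/% 10, cfg$n_bits,
                                   cfg$fp_clusters, cfg$within_tanimoto,
                                   seed = sub_seed(seed, 7L))
    fpp <- file.path(cfg$out_dir, "fingerprints.tsv")
    write_fingerprints(res$fp_lib, fpp, seed = seed)
    write_truth_sidecar(list(assignment = attr(res$fp_lib, "truth")), fpp)

    models <- c("bliss", "hsa", "loewe", "zip")
    res$surfaces <- lapply(seq_len(cfg$n_surfaces), function(k) {
      truth <- planted_synergy_truth(
        model = models[(k - 1) %% 4 + 1],
        delta = if (k <= 4) cfg$synergy_delta else 0,
        hill_a = c(y_min = 0, y_max = 90, ec50 = 1, slope = 1.5),
        hill_b = c(y_min = 0, y_max = 80, ec50 = 3, slope = 1))
      gen_dose_response(truth, cfg$dose_grid, cfg$dose_grid,
                        noise_sd = cfg$synergy_noise_sd,
                        seed = sub_seed(seed, 9000L + k),
                        drug_row = sprintf("fda%02d", k),
                        drug_col = sprintf("cand%02d", k))
    })
    names(res$surfaces) <- sprintf("block%02d", seq_len(cfg$n_surfaces))
    dp <- file.path(cfg$out_dir, "dose_response.csv")
    write_dose_response(res$surfaces, dp, seed = seed)
  }

  if (stage_on("de")) {
    cdr_log("stage de")
    if (is.null(res$datasets)) stop("missing dependency: no expression datasets (run 'simulate' or provide data)")
    res$de <- lapply(res$datasets, function(ds) {
      ds$matrix <- quantile_normalize(log2_if_needed(ds$matrix))
      moderated_t(ds)
    })
    for (d in names(res$de))
      write_with_header(res$de[[d]], file.path(cfg$out_dir, sprintf("de_%s.csv", d)),
                        seed = seed, config_hash = hash)
  }

  if (stage_on("signature")) {
    cdr_log("stage signature")
    if (is.null(res$de)) stop("missing dependency: run 'de' first")
    res$signatures <- lapply(names(res$de), function(d) {
      extract_signature(res$de[[d]], n_each = cfg$n_signature, alpha = cfg$alpha,
                        stage = cfg$disease_stages[1], dataset_id = d)
    })
    names(res$signatures) <- names(res$de)
    for (d in names(res$signatures)) {
      sg <- res$signatures[[d]]
      df <- data.frame(gene = c(sg$up, sg$down),
                       direction = rep(c("up", "down"), c(length(sg$up), length(sg$down))))
      write_with_header(df, file.path(cfg$out_dir, sprintf("signature_%s.tsv", d)),
                        seed = seed, config_hash = hash, sep = "\t")
    }
  }

  if (stage_on("aggregate")) {
    cdr_log("stage aggregate")
    if (is.null(res$tool_outputs)) stop("missing dependency: tool outputs not available (tool_outputs.csv)")
    res$consensus <- lapply(names(res$tool_outputs), function(st) {
      per_ds <- lapply(res$tool_outputs[[st]], function(tool_lists) {
        lists <- lapply(tool_lists, truncate_top_k, k = cfg$top_k)
        aggregate_within_dataset(lists, w1 = cfg$w1, w2 = cfg$w2,
                                 absent_policy = cfg$absent_policy)
      })
      aggregate_across_datasets(per_ds, stage = st, w1 = cfg$w1, w2 = cfg$w2,
                                absent_policy = cfg$absent_policy)
    })
    names(res$consensus) <- names(res$tool_outputs)
    res$shortlists <- lapply(res$consensus, retain_threshold, threshold = cfg$threshold)
    for (st in names(res$consensus)) {
      write_with_header(res$consensus[[st]],
                        file.path(cfg$out_dir, sprintf("consensus_%s.csv", st)),
                        seed = seed, config_hash = hash)
      write_with_header(as.data.frame(res$shortlists[[st]]),
                        file.path(cfg$out_dir, sprintf("shortlist_%s.csv", st)),
                        seed = seed, config_hash = hash)
    }
  }

  if (stage_on("enrich")) {
    cdr_log("stage enrich")
    if (is.null(res$de) || is.null(res$signatures)) stop("missing dependency: run 'de' and 'signature' first")
    universe <- res$datasets[[1]]$gene_ids
    planted_term <- list(PLANTED_DE = utils::head(
      c(sprintf("UP%03d", 1:20), sprintf("DN%03d", 1:20)), 40))
    coll <- gen_gene_sets(universe, n_sets = cfg$n_gene_sets,
                          planted = planted_term, seed = sub_seed(seed, 77L))
    write_gmt(coll, file.path(cfg$out_dir, "gene_sets.gmt"))
    res$enrichment <- lapply(names(res$signatures), function(d) {
      sg <- res$signatures[[d]]
      hypergeom_ora(c(sg$up, sg$down), coll)
    })
    names(res$enrichment) <- names(res$signatures)
    res$pathway_consensus <- rank_pathways(res$enrichment,
                                           stage = cfg$disease_stages[1],
                                           w1 = cfg$w1, w2 = cfg$w2)
    write_with_header(res$pathway_consensus,
                      file.path(cfg$out_dir, "pathway_consensus.csv"),
                      seed = seed, config_hash = hash)
  }

  if (stage_on("structsim")) {
    cdr_log("stage structsim")
    if (is.null(res$fp_lib)) stop("missing dependency: fingerprint library (fingerprints.tsv)")
    res$clusters <- cluster_drugs(res$fp_lib, cut = cfg$soergel_cut,
                                  method = cfg$linkage)
    write_with_header(as.data.frame(res$clusters),
                      file.path(cfg$out_dir, "clusters.csv"),
                      seed = seed, config_hash = hash)
    half <- seq_len(length(res$fp_lib$ids) %/% 2)
    lib_a <- fp_library(res$fp_lib$bits[half, , drop = FALSE], origin = "synthetic")
    lib_b <- fp_library(res$fp_lib$bits[-half, , drop = FALSE], origin = "synthetic")
    res$screen <- cross_set_screen(lib_a, lib_b, threshold = cfg$sim_threshold,
                                   reduce_max = TRUE)
    write_with_header(res$screen$flagged,
                      file.path(cfg$out_dir, "similarity_flags.csv"),
                      seed = seed, config_hash = hash)
  }

  if (stage_on("synergy")) {
    cdr_log("stage synergy")
    if (is.null(res$surfaces)) stop("missing dependency: dose-response surfaces (dose_response.csv)")
    res$synergy <- do.call(rbind, lapply(res$surfaces, synergy_summary,
                                         thresholds = cfg$synergy_thresholds))
    rownames(res$synergy) <- NULL
    res$synergy_ranked <- classify_and_rank(res$synergy,
                                            thresholds = cfg$synergy_thresholds)
    write_with_header(res$synergy, file.path(cfg$out_dir, "synergy_summary.csv"),
                      seed = seed, config_hash = hash)
  }

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("consensusDR")),
    config = unclass(cfg),
    config_hash = hash,
    output_hashes = as.list(tools::md5sum(outputs)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (stage_on("report")) pipeline_report(res, cfg)
  attr(manifest, "results") <- res
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Prints per-stage tables: shortlist sizes per stage, enriched-term
#' counts, cluster counts, synergy classifications, and — when truth is
#' available — recovery metrics against the planted ground truth.
#'
#' @param res The `results` attribute of a [run_pipeline()] manifest.
#' @param cfg The configuration used.
#' @return Invisibly, a list of summary data frames.
#' @export
pipeline_report <- function(res, cfg = default_config()) {
  out <- list()
  cat("== consensusDR run summary ==\n")
  if (!is.null(res$shortlists)) {
    sizes <- vapply(res$shortlists, nrow, 1L)
    out$shortlist_sizes <- data.frame(stage = names(sizes), n_retained = sizes,
                                      row.names = NULL)
    cat("Shortlisted drugs per stage (score >= ", cfg$threshold, "):\n", sep = "")
    print(out$shortlist_sizes)
    truth <- attr(res$tool_outputs[[1]], "truth")
    if (!is.null(truth)) {
      rec <- vapply(names(res$shortlists), function(st) {
        sl <- res$shortlists[[st]]
        if (nrow(sl) == 0) return(NA_real_)
        mean(sl$item_id %in% truth$true_reversers)
      }, 1)
      out$reverser_precision <- data.frame(stage = names(rec),
                                           planted_fraction = rec, row.names = NULL)
      cat("Fraction of shortlist that is planted reversers:\n")
      print(out$reverser_precision)
    }
  }
  if (!is.null(res$enrichment)) {
    n_sig <- vapply(res$enrichment, function(e) nrow(significant_terms(e)), 1L)
    out$enriched_counts <- data.frame(dataset = names(n_sig), n_significant = n_sig,
                                      row.names = NULL)
    cat("Significant enriched terms per dataset (adj_p < 0.05):\n")
    print(out$enriched_counts)
  }
  if (!is.null(res$clusters)) {
    out$n_clusters <- length(unique(res$clusters$cluster))
    cat("Structural clusters at Soergel <=", cfg$soergel_cut, ":",
        out$n_clusters, "\n")
  }
  if (!is.null(res$synergy)) {
    cat("Synergy classifications:\n")
    cls <- res$synergy[, c("pair_id", "zip_class", "loewe_class",
                           "hsa_class", "bliss_class")]
    print(cls)
    out$synergy_classes <- cls
    cat("Pairs synergistic under all four models:",
        length(res$synergy_ranked$intersection), "\n")
  }
  invisible(out)
}
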