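#' Planted truth for a synthetic expression dataset
#'
#' @param de_genes_up,de_genes_down Disjoint character vectors of planted
#'   differentially expressed genes (shifted up / down in cases).
#' @param effect_size Log2 fold-change magnitude, > 0 (0 allowed for the
#'   null generator).
#' @param noise_sd Per-gene Gaussian standard deviation, > 0.
#' @return List of class `planted_expression_truth`.
#' @export
planted_expression_truth <- function(de_genes_up, de_genes_down,
                                     effect_size = 2, noise_sd = 0.5) {
  de_genes_up <- unique(as.character(de_genes_up))
  de_genes_down <- unique(as.character(de_genes_down))
  if (length(intersect(de_genes_up, de_genes_down)) > 0)
    stop("up and down planted gene sets must be disjoint")
  stopifnot(effect_size >= 0, noise_sd > 0)
  structure(list(de_genes_up = de_genes_up, de_genes_down = de_genes_down,
                 effect_size = effect_size, noise_sd = noise_sd),
            class = "planted_expression_truth")
}

#' Generate a synthetic expression dataset with planted DE genes
#'
#' Controls are drawn from `N(baseline, noise_sd^2)` per gene and sample;
#' cases are additionally shifted by `+effect_size` on the planted up
#' genes and `-effect_size` on the planted down genes. The baseline is
#' 8.0, a typical log2-scale microarray intensity. Deterministic given the
#' seed.
#'
#' @param n_genes Total genes (>= number of planted genes).
#' @param n_cases,n_controls Samples per group, each >= 2.
#' @param truth A [planted_expression_truth()].
#' @param seed Integer seed.
#' @param baseline Baseline log2 expression, default 8.
#' @param stage,dataset_id Metadata labels.
#' @return An [expression_dataset()] with the truth in attribute `truth`.
#' @export
gen_expression <- function(n_genes, n_cases, n_controls, truth, seed,
                           baseline = 8, stage = "MM", dataset_id = "SYN1") {
  stopifnot(inherits(truth, "planted_expression_truth"))
  n_planted <- length(truth$de_genes_up) + length(truth$de_genes_down)
  if (n_genes < n_planted) stop("planted gene sets exceed n_genes")
  if (n_cases < 2 || n_controls < 2) stop("need at least 2 samples per group")
  set.seed(sub_seed(seed, 101L))
  genes <- sprintf("G%05d", seq_len(n_genes))
  # planted genes occupy the first slots unless ids were given explicitly
  up_idx <- seq_along(truth$de_genes_up)
  down_idx <- length(truth$de_genes_up) + seq_along(truth$de_genes_down)
  if (all(truth$de_genes_up %in% genes) && all(truth$de_genes_down %in% genes)) {
    up_idx <- match(truth$de_genes_up, genes)
    down_idx <- match(truth$de_genes_down, genes)
  } else {
    genes[up_idx] <- truth$de_genes_up
    genes[down_idx] <- truth$de_genes_down
  }
  n <- n_cases + n_controls
  m <- matrix(stats::rnorm(n_genes * n, mean = baseline, sd = truth$noise_sd),
              nrow = n_genes, ncol = n)
  groups <- c(rep("case", n_cases), rep("control", n_controls))
  m[up_idx, groups == "case"] <- m[up_idx, groups == "case"] + truth$effect_size
  m[down_idx, groups == "case"] <- m[down_idx, groups == "case"] - truth$effect_size
  rownames(m) <- genes
  colnames(m) <- sprintf("S%03d_%s", seq_len(n), ifelse(groups == "case", "case", "ctrl"))
  ds <- expression_dataset(m, groups, stage = stage, dataset_id = dataset_id)
  attr(ds, "truth") <- truth
  ds
}

#' Planted truth for synthetic repurposing-tool outputs
#'
#' @param true_reversers Character vector of drug ids planted as true
#'   signature reversers.
#' @param n_tools,n_datasets Number of tools and datasets to emulate.
#' @param top_k List length per tool output (default 50).
#' @param rank_advantage Probability that a true reverser outranks a decoy
#'   in any pairwise contest; in (0.5, 1\].
#' @return List of class `planted_tool_truth`.
#' @export
planted_tool_truth <- function(true_reversers, n_tools = 3, n_datasets = 4,
                               top_k = 50, rank_advantage = 0.9) {
  stopifnot(rank_advantage > 0.5 - 1e-12, rank_advantage <= 1, top_k >= 1,
            n_tools >= 1, n_datasets >= 1)
  structure(list(true_reversers = unique(as.character(true_reversers)),
                 n_tools = n_tools, n_datasets = n_datasets,
                 top_k = top_k, rank_advantage = rank_advantage),
            class = "planted_tool_truth")
}

#' Generate synthetic repurposing-tool outputs with planted reversers
#'
#' For each dataset and tool, every drug draws a latent reverser strength;
#' planted true reversers draw from a normal distribution shifted so that
#' they beat any decoy in a pairwise rank contest with probability
#' `rank_advantage` (advantage 0.5 would be a coin flip; advantage 1 is a
#' guaranteed win). Drugs are sorted by decreasing strength, truncated to
#' `top_k`, and assigned strictly decreasing negative inhibition scores on
#' \[-100, 0) — the convention in which a strongly negative score marks a
#' drug that reverses the disease signature. Only the rank order carries
#' information downstream.
#'
#' @param drug_universe Character vector of all candidate drug ids;
#'   must contain the planted reversers and have at least `top_k` drugs.
#' @param truth A [planted_tool_truth()].
#' @param seed Integer seed.
#' @param stage Stage label stamped on every list.
#' @return Nested list: `out[[dataset_id]][[tool_id]]` is a
#'   reverser-first `data.frame` with `item_id`, `inhibition_score`,
#'   `tool_id`, `dataset_id`, `stage`. The truth is in attribute `truth`.
#' @export
gen_tool_outputs <- function(drug_universe, truth, seed, stage = "MM") {
  stopifnot(inherits(truth, "planted_tool_truth"))
  drug_universe <- unique(as.character(drug_universe))
  if (length(drug_universe) == 0) stop("empty drug universe")
  if (truth$top_k > length(drug_universe)) stop("top_k exceeds the drug universe")
  if (!all(truth$true_reversers %in% drug_universe))
    stop("true reversers must be in the drug universe")
  set.seed(sub_seed(seed, 202L))
  is_true <- drug_universe %in% truth$true_reversers
  # pairwise win probability p = P(N(mu,1) > N(0,1)) = pnorm(mu/sqrt(2))
  mu <- if (truth$rank_advantage >= 1) Inf
        else sqrt(2) * stats::qnorm(truth$rank_advantage)
  out <- list()
  for (d in seq_len(truth$n_datasets)) {
    ds_id <- sprintf("DS%d", d)
    out[[ds_id]] <- list()
    for (t in seq_len(truth$n_tools)) {
      tool_id <- sprintf("tool%d", t)
      latent <- stats::rnorm(length(drug_universe))
      latent[is_true] <- latent[is_true] + if (is.finite(mu)) mu else 1e6
      ord <- order(-latent, drug_universe)
      keep <- utils::head(ord, truth$top_k)
      k <- length(keep)
      # strictly decreasing reverser strength: most negative score first
      score <- -100 + 99.9 * (seq_len(k) - 1) / max(k - 1, 1)
      out[[ds_id]][[tool_id]] <- data.frame(
        item_id = drug_universe[keep], inhibition_score = score,
        tool_id = tool_id, dataset_id = ds_id, stage = stage,
        stringsAsFactors = FALSE
      )
    }
  }
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic fingerprint library with planted clusters
#'
#' Builds `n_clusters` random cluster centres (each with half the bits
#' set, so unrelated centres have expected Tanimoto near 1/3) and derives
#' members by swapping a fixed number of set bits to unset positions. The
#' swap count is chosen so that the worst-case within-cluster pairwise
#' Tanimoto stays at or above `within_cluster_tanimoto`; an infeasible
#' target (no swap count achieves it, or the bit budget is too small)
#' raises an error rather than silently clipping.
#'
#' @param n_drugs Total fingerprints, split as evenly as possible across
#'   clusters.
#' @param n_bits Fingerprint length, >= 64.
#' @param n_clusters Number of planted clusters.
#' @param within_cluster_tanimoto Minimum expected pairwise Tanimoto
#'   within a cluster, in (0, 1\].
#' @param seed Integer seed.
#' @return [fp_library()] (`origin = "synthetic"`) with attribute `truth`:
#'   integer cluster assignment named by drug id.
#' @export
gen_fingerprints <- function(n_drugs, n_bits, n_clusters,
                             within_cluster_tanimoto, seed) {
  stopifnot(n_bits >= 64, within_cluster_tanimoto > 0,
            within_cluster_tanimoto <= 1, n_clusters >= 1,
            n_drugs >= n_clusters)
  set.seed(sub_seed(seed, 303L))
  m <- floor(n_bits / 2)          # set bits per fingerprint
  t <- within_cluster_tanimoto
  # two members with disjoint j-bit swaps from the centre have Tanimoto
  # (m - 2j) / (m + 2j) >= t  =>  j <= m (1 - t) / (2 (1 + t))
  j <- floor(m * (1 - t) / (2 * (1 + t)))
  if (t < 1 && j < 1)
    stop("infeasible within-cluster similarity target: ", t,
         " requires more bits (no positive swap count achieves it)")
  if (m + j > n_bits)
    stop("infeasible: not enough unset bits to swap into")
  sizes <- rep(floor(n_drugs / n_clusters), n_clusters)
  sizes[seq_len(n_drugs - sum(sizes))] <- sizes[seq_len(max(n_drugs - sum(sizes), 0))] + 1
  bits <- matrix(FALSE, nrow = n_drugs, ncol = n_bits)
  assignment <- integer(n_drugs)
  row <- 1L
  for (c in seq_len(n_clusters)) {
    centre <- sample.int(n_bits, m)
    for (k in seq_len(sizes[c])) {
      member <- centre
      if (t < 1 && j > 0) {
        drop_pos <- sample(seq_len(m), j)
        add_pos <- sample(setdiff(seq_len(n_bits), centre), j)
        member <- c(centre[-drop_pos], add_pos)
      }
      bits[row, member] <- TRUE
      assignment[row] <- c
      row <- row + 1L
    }
  }
  ids <- sprintf("drug%03d", seq_len(n_drugs))
  rownames(bits) <- ids
  lib <- fp_library(bits, origin = "synthetic")
  attr(lib, "truth") <- stats::setNames(assignment, ids)
  lib
}

#' Planted truth for a synthetic dose-response surface
#'
#' @param model Synergy null model the surface is generated under: one of
#'   `"zip"`, `"loewe"`, `"hsa"`, `"bliss"`.
#' @param delta Planted mean deviation from the model's null expectation,
#'   in % response units (any sign; 0 gives a pure null surface).
#' @param hill_a,hill_b Monotherapy Hill parameters per drug:
#'   named numeric vectors `c(y_min, y_max, ec50, slope)` with
#'   `ec50 > 0` and `y_min <= y_max`.
#' @return List of class `planted_synergy_truth`.
#' @export
planted_synergy_truth <- function(model = c("bliss", "hsa", "loewe", "zip"),
                                  delta = 0,
                                  hill_a = c(y_min = 0, y_max = 100, ec50 = 1, slope = 1),
                                  hill_b = c(y_min = 0, y_max = 100, ec50 = 1, slope = 1)) {
  model <- match.arg(model)
  for (h in list(hill_a, hill_b)) {
    stopifnot(all(c("y_min", "y_max", "ec50", "slope") %in% names(h)),
              h[["ec50"]] > 0, h[["y_min"]] <= h[["y_max"]])
  }
  structure(list(model = model, delta = delta, hill_a = hill_a, hill_b = hill_b),
            class = "planted_synergy_truth")
}

#' Generate a synthetic dose-response surface under a synergy null
#'
#' Monotherapy rows follow the stated Hill curves exactly (plus noise);
#' each positive-dose combination cell equals the chosen model's null
#' expectation at the true Hill parameters, plus the planted `delta`,
#' plus Gaussian noise. With `delta = 0` and `noise_sd = 0` the matching
#' downstream model scores the surface at exactly zero (up to fitting
#' tolerance for Loewe/ZIP).
#'
#' @param truth A [planted_synergy_truth()].
#' @param dose_grid_a,dose_grid_b Strictly increasing dose vectors
#'   starting at 0.
#' @param noise_sd Gaussian noise SD (>= 0) added to every treated cell.
#' @param seed Integer seed.
#' @param drug_row,drug_col Drug identifiers.
#' @return A [dose_response_surface()] with the truth in attribute
#'   `truth`.
#' @export
gen_dose_response <- function(truth, dose_grid_a, dose_grid_b, noise_sd = 0,
                              seed = 1, drug_row = "drugA", drug_col = "drugB") {
  stopifnot(inherits(truth, "planted_synergy_truth"), noise_sd >= 0)
  if (any(dose_grid_a < 0) || any(dose_grid_b < 0)) stop("negative doses")
  if (length(dose_grid_a) == 0 || length(dose_grid_b) == 0) stop("empty dose grid")
  set.seed(sub_seed(seed, 404L))
  ha <- truth$hill_a; hb <- truth$hill_b
  ya <- hill_response(dose_grid_a, ha[["y_min"]], ha[["y_max"]], ha[["ec50"]], ha[["slope"]])
  yb <- hill_response(dose_grid_b, hb[["y_min"]], hb[["y_max"]], hb[["ec50"]], hb[["slope"]])
  nr <- length(dose_grid_a); nc <- length(dose_grid_b)
  resp <- matrix(0, nr, nc)
  resp[, 1] <- ya
  resp[1, ] <- yb
  fit_a <- structure(list(y_min = ha[["y_min"]], y_max = ha[["y_max"]],
                          ec50 = ha[["ec50"]], slope = ha[["slope"]],
                          converged = TRUE), class = "hill_fit")
  fit_b <- structure(list(y_min = hb[["y_min"]], y_max = hb[["y_max"]],
                          ec50 = hb[["ec50"]], slope = hb[["slope"]],
                          converged = TRUE), class = "hill_fit")
  for (i in 2:nr) for (j in 2:nc) {
    null_y <- switch(truth$model,
      bliss = ,
      zip = ya[i] + yb[j] - ya[i] * yb[j] / 100,
      hsa = max(ya[i], yb[j]),
      loewe = loewe_expected_cell(dose_grid_a[i], dose_grid_b[j], fit_a, fit_b)
    )
    if (is.na(null_y)) null_y <- max(ya[i], yb[j])
    resp[i, j] <- null_y + truth$delta
  }
  if (noise_sd > 0) {
    noise <- matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    noise[1, 1] <- 0
    resp <- resp + noise
  }
  s <- dose_response_surface(resp, dose_grid_a, dose_grid_b,
                             drug_row = drug_row, drug_col = drug_col,
                             clip = FALSE)
  attr(s, "truth") <- truth
  s
}

#' Generate a synthetic gene-set collection with planted enriched terms
#'
#' Builds random gene sets over a universe plus optional planted terms
#' composed of given genes, for exercising over-representation analysis.
#'
#' @param universe Character vector of background genes.
#' @param n_sets Number of random sets.
#' @param set_size_range Integer range of set sizes.
#' @param planted Optional named list of gene vectors to include verbatim.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] with attribute `truth` naming the
#'   planted terms.
#' @export
gen_gene_sets <- function(universe, n_sets = 50, set_size_range = c(10, 50),
                          planted = NULL, seed = 1) {
  set.seed(sub_seed(seed, 505L))
  sets <- lapply(seq_len(n_sets), function(i) {
    sz <- sample(set_size_range[1]:set_size_range[2], 1)
    sample(universe, sz)
  })
  names(sets) <- sprintf("TERM%04d", seq_len(n_sets))
  if (!is.null(planted)) sets <- c(planted, sets)
  coll <- gene_set_collection(sets, universe)
  attr(coll, "truth") <- names(planted)
  coll
}
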