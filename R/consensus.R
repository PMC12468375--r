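#' Truncate a ranked drug list to its top k entries
#'
#' Harmonises list lengths across tools: when one tool caps its output at
#' k entries (50 for common signature-reversal services), the same cutoff
#' is applied to every other list so that rank normalisation is comparable.
#'
#' @param x `data.frame` ordered reverser-first, with at least `item_id`.
#' @param k Maximum entries to keep (default 50).
#' @return The first `min(k, nrow(x))` rows.
#' @export
truncate_top_k <- function(x, k = 50) {
  stopifnot(is.data.frame(x), k >= 0)
  utils::head(x, k)
}

# Shared worker behind both aggregation levels. Takes one rank table per
# source: data.frame(item_id, rank, K) where rank may be fractional
# (average ranks for ties) and K is the source list length. An item at
# rank r in a K-item list contributes the normalised rank value
# (K - r + 1) / K, i.e. rank 1 -> 1 (best), rank K -> 1/K.
consensus_worker <- function(rank_tables, w1, w2, absent_policy) {
  stopifnot(length(rank_tables) >= 1)
  if (abs(w1 + w2 - 1) > 1e-8)
    warning("weights w1 + w2 = ", w1 + w2, " do not sum to 1")
  n_sources <- length(rank_tables)
  per_source <- lapply(rank_tables, function(tab) {
    stopifnot(all(c("item_id", "rank", "K") %in% names(tab)))
    if (anyDuplicated(tab$item_id)) stop("duplicate item within one source list")
    data.frame(item_id = as.character(tab$item_id),
               value = (tab$K - tab$rank + 1) / tab$K,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, per_source)
  if (nrow(long) == 0) stop("empty union of items across sources")
  appearances <- table(long$item_id)
  sums <- tapply(long$value, long$item_id, sum)
  items <- sort(names(appearances))
  n_app <- as.vector(appearances[items])
  if (absent_policy == "ignore") {
    R <- as.vector(sums[items]) / n_app
  } else { # "penalize": absence counts as rank K + 1, value 0
    R <- as.vector(sums[items]) / n_sources
  }
  A <- n_app / n_sources
  score <- w1 * R + w2 * A
  out <- data.frame(item_id = items, R = R, A = A, score = score,
                    n_sources = n_app, stringsAsFactors = FALSE)
  # descending score, lexicographic item_id tie-break
  out <- out[order(-out$score, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-dataset consensus across repurposing tools
#'
#' Combines the ranked drug lists produced by several repurposing tools
#' for the same dataset and stage into one consensus list. Each drug's
#' consensus score is the weighted sum `w1 * R + w2 * A`, where `R` is the
#' mean normalised rank value over the tools that report the drug (rank r
#' in a K-item list maps to `(K - r + 1) / K`) and `A` is the fraction of
#' tools reporting it.
#'
#' @param lists List of reverser-first ordered `data.frame`s (one per
#'   tool) each containing `item_id`; typically already truncated with
#'   [truncate_top_k()].
#' @param w1,w2 Weights of the rank and appearance components
#'   (defaults 0.7 and 0.3).
#' @param absent_policy `"ignore"` (default) averages `R` only over the
#'   tools that report the drug; `"penalize"` treats absence as rank
#'   K + 1 (normalised value 0).
#' @return `data.frame` with `item_id`, `R`, `A`, `score`, `n_sources`,
#'   sorted by descending score (ties lexicographic), with attribute
#'   `level = "within_dataset"`.
#' @export
aggregate_within_dataset <- function(lists, w1 = 0.7, w2 = 0.3,
                                     absent_policy = c("ignore", "penalize")) {
  absent_policy <- match.arg(absent_policy)
  rank_tables <- lapply(lists, function(l) {
    stopifnot(is.data.frame(l), "item_id" %in% names(l))
    data.frame(item_id = l$item_id, rank = seq_len(nrow(l)), K = nrow(l))
  })
  out <- consensus_worker(rank_tables, w1, w2, absent_policy)
  attr(out, "level") <- "within_dataset"
  out
}

#' Cross-dataset consensus per stage
#'
#' Re-ranks the per-dataset consensus lists of one stage into a single
#' stage-level list with the same weighted formula: an item at position r
#' of an M-item dataset list gets normalised rank value `(M - r + 1) / M`;
#' `R` averages these over the datasets where the item appears and `A` is
#' the fraction of datasets reporting it. Tied scores within a dataset
#' list receive average (fractional) ranks.
#'
#' @param per_dataset List of `data.frame`s (one per dataset), each with
#'   `item_id` and `score`, as returned by [aggregate_within_dataset()].
#' @param stage Stage label attached to the result.
#' @inheritParams aggregate_within_dataset
#' @return `data.frame` as in [aggregate_within_dataset()], attribute
#'   `level = "cross_dataset"` and `stage`.
#' @export
aggregate_across_datasets <- function(per_dataset, stage = NULL, w1 = 0.7, w2 = 0.3,
                                      absent_policy = c("ignore", "penalize")) {
  absent_policy <- match.arg(absent_policy)
  stopifnot(length(per_dataset) >= 1)
  rank_tables <- lapply(per_dataset, function(l) {
    stopifnot(is.data.frame(l), "item_id" %in% names(l))
    r <- if ("score" %in% names(l)) rank(-l$score, ties.method = "average")
         else seq_len(nrow(l))
    data.frame(item_id = l$item_id, rank = r, K = nrow(l))
  })
  out <- consensus_worker(rank_tables, w1, w2, absent_policy)
  attr(out, "level") <- "cross_dataset"
  attr(out, "stage") <- stage
  out
}

#' Retain high-consensus items
#'
#' Applies the shortlist rule: keep items whose cross-dataset consensus
#' score is `threshold` or higher (inclusive).
#'
#' @param scores Consensus `data.frame` (cross-dataset level).
#' @param threshold Retention cutoff, default 0.75.
#' @return Object of class `stage_shortlist`: the retained rows sorted by
#'   descending score, with `stage` and `threshold` attributes.
#' @export
retain_threshold <- function(scores, threshold = 0.75) {
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  keep <- scores[scores$score >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$item_id), , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(keep) == 0) warning("no items reach the retention threshold ", threshold)
  structure(keep, class = c("stage_shortlist", "data.frame"),
            stage = attr(scores, "stage"), threshold = threshold)
}

#' Stage-level pathway consensus from per-dataset enrichment tables
#'
#' Ranks pathways within each dataset by adjusted p-value (ascending, rank
#' 1 = most significant; ties get average ranks) and then applies the
#' cross-dataset weighted consensus verbatim with pathways as items.
#'
#' @param tables List of per-dataset enrichment `data.frame`s with
#'   `term_id` (or `item_id`) and `adj_p` columns.
#' @param stage Stage label.
#' @inheritParams aggregate_within_dataset
#' @return Cross-dataset consensus `data.frame` over pathways.
#' @export
rank_pathways <- function(tables, stage = NULL, w1 = 0.7, w2 = 0.3,
                          absent_policy = c("ignore", "penalize")) {
  absent_policy <- match.arg(absent_policy)
  rank_tables <- lapply(tables, function(tab) {
    stopifnot(is.data.frame(tab))
    id_col <- if ("term_id" %in% names(tab)) "term_id" else "item_id"
    if (!"adj_p" %in% names(tab)) stop("enrichment table lacks an adj_p column")
    data.frame(item_id = tab[[id_col]],
               rank = rank(tab$adj_p, ties.method = "average"),
               K = nrow(tab))
  })
  out <- consensus_worker(rank_tables, w1, w2, absent_policy)
  attr(out, "level") <- "cross_dataset"
  attr(out, "stage") <- stage
  out
}

#' Harmonise drug names across tools and datasets
#'
#' Case-folds, trims and collapses internal whitespace so the same drug
#' reported with different capitalisation matches across sources. An
#' optional synonym map (named character vector, `names` = alias,
#' `values` = canonical id) is applied after normalisation.
#'
#' @param ids Character vector of drug names.
#' @param synonyms Optional named character vector of alias -> canonical.
#' @return Normalised character vector.
#' @export
harmonize_drug_ids <- function(ids, synonyms = NULL) {
  out <- tolower(trimws(gsub("\\s+", " ", as.character(ids))))
  if (!is.null(synonyms)) {
    names(synonyms) <- tolower(trimws(gsub("\\s+", " ", names(synonyms))))
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}
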