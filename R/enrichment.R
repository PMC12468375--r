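#' Build a gene-set collection against a background universe
#'
#' Intersects every set with the universe and drops sets left empty, so
#' that the hypergeometric test's sampling frame is consistent. The
#' universe defaults to the genes measured on the platform, the
#' conservative standard background for over-representation analysis.
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param universe Character vector of background gene identifiers.
#' @param descriptions Optional named character vector of term descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  sets <- sets[vapply(sets, length, 1L) > 0]
  if (length(sets) == 0) stop("no gene set overlaps the universe")
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the overlap between the query gene set and
#' the term's members is larger than expected under uniform sampling from
#' the universe: the upper-tail hypergeometric probability of observing at
#' least the observed overlap. Terms with zero overlap are excluded before
#' testing; p-values are BH-adjusted across all tested terms. Query genes
#' outside the universe are dropped and counted.
#'
#' @param query Character vector of query gene identifiers.
#' @param collection A [gene_set_collection()].
#' @return `data.frame` with `term_id`, `description`, `overlap_count`,
#'   `set_size`, `query_size`, `universe_size`, `p_value`, `adj_p`, sorted
#'   by ascending p-value; attribute `n_dropped` counts query genes
#'   outside the universe.
#' @export
hypergeom_ora <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  in_univ <- query %in% collection$universe
  n_dropped <- sum(!in_univ)
  if (n_dropped > 0)
    cdr_log("dropping %d query genes outside the universe", n_dropped)
  query <- query[in_univ]
  if (length(query) == 0) stop("empty query after intersecting with the universe")
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    set <- collection$sets[[term]]
    k <- length(intersect(set, query))
    if (k == 0) return(NULL)
    K <- length(set)
    # P(X >= k), X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               description = collection$descriptions[term] %||% term,
               overlap_count = k, set_size = K, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(structure(data.frame(term_id = character(), description = character(),
                                overlap_count = integer(), set_size = integer(),
                                query_size = integer(), universe_size = integer(),
                                p_value = numeric(), adj_p = numeric()),
                     n_dropped = n_dropped))
  }
  rows$description <- unname(rows$description)
  rows$adj_p <- bh_adjust(rows$p_value)
  rows <- rows[order(rows$p_value, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "n_dropped") <- n_dropped
  rows
}

#' Union of drug-target genes for a shortlist
#'
#' Looks up every shortlisted drug in a drug-to-target map and returns the
#' union of their target genes (set semantics: shared targets appear
#' once). Drugs with no mapping are counted and reported.
#'
#' @param shortlist A [retain_threshold()] result, or any `data.frame`
#'   with an `item_id` column, or a character vector of drug ids.
#' @param target_map `data.frame` with columns `drug` and `target`
#'   (gene symbols), e.g. read from a Drug Repurposing Hub style CSV.
#' @return Character vector of target genes (uppercased), with attribute
#'   `n_unmapped` counting shortlisted drugs without targets.
#' @export
targets_to_query <- function(shortlist, target_map) {
  drugs <- if (is.character(shortlist)) shortlist else shortlist$item_id
  stopifnot(is.data.frame(target_map), all(c("drug", "target") %in% names(target_map)))
  drugs <- harmonize_drug_ids(drugs)
  map_drug <- harmonize_drug_ids(target_map$drug)
  hit <- map_drug %in% drugs
  mapped_drugs <- unique(map_drug[hit])
  n_unmapped <- length(setdiff(drugs, mapped_drugs))
  if (n_unmapped > 0)
    cdr_log("%d of %d shortlisted drugs have no target mapping", n_unmapped, length(drugs))
  genes <- sort(unique(toupper(as.character(target_map$target[hit]))))
  if (length(genes) == 0) warning("empty target union for the shortlist")
  attr(genes, "n_unmapped") <- n_unmapped
  genes
}

#' Filter enrichment results to significant terms
#'
#' Strict adjusted-p filter (`adj_p < alpha`), sorted ascending.
#'
#' @param rows Enrichment `data.frame` from [hypergeom_ora()].
#' @param alpha Significance cutoff, default 0.05 (strict inequality).
#' @return Filtered, sorted `data.frame`.
#' @export
significant_terms <- function(rows, alpha = 0.05) {
  stopifnot(is.data.frame(rows), "adj_p" %in% names(rows))
  out <- rows[rows$adj_p < alpha, , drop = FALSE]
  out <- out[order(out$adj_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
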