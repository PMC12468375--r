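#' Construct a fingerprint library
#'
#' A fingerprint library holds one fixed-length binary fingerprint per
#' drug. All-zero fingerprints are rejected (they make Tanimoto
#' undefined).
#'
#' @param bits Logical or 0/1 matrix, drugs in rows, bits in columns;
#'   rownames are drug identifiers.
#' @param origin `"from_structure"` or `"synthetic"`.
#' @return Object of class `fp_library`.
#' @export
fp_library <- function(bits, origin = c("from_structure", "synthetic")) {
  origin <- match.arg(origin)
  bits <- as.matrix(bits)
  if (is.null(rownames(bits))) stop("bits matrix must have drug ids as rownames")
  storage.mode(bits) <- "logical"
  if (any(rowSums(bits) == 0)) stop("all-zero fingerprints are not allowed")
  structure(list(ids = rownames(bits), bits = bits, n_bits = ncol(bits),
                 origin = origin),
            class = "fp_library")
}

#' @export
print.fp_library <- function(x, ...) {
  cat(sprintf("<fp_library> %d drugs x %d bits (%s)\n",
              length(x$ids), x$n_bits, x$origin))
  invisible(x)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, in \[0, 1\].
#'
#' @param a,b Logical/0-1 vectors of equal length, not both all-zero.
#' @return Similarity scalar.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0) stop("both fingerprints are all-zero")
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param lib_a Query [fp_library()].
#' @param lib_b Reference library; defaults to `lib_a` (self-comparison,
#'   symmetric with unit diagonal).
#' @return Numeric matrix, rows = `lib_a` drugs, columns = `lib_b` drugs.
#' @export
tanimoto_matrix <- function(lib_a, lib_b = lib_a) {
  stopifnot(inherits(lib_a, "fp_library"), inherits(lib_b, "fp_library"))
  if (lib_a$n_bits != lib_b$n_bits) stop("libraries have different bit lengths")
  A <- lib_a$bits * 1; B <- lib_b$bits * 1
  inter <- tcrossprod(A, B)
  ca <- rowSums(A); cb <- rowSums(B)
  uni <- outer(ca, cb, "+") - inter
  sim <- inter / uni
  dimnames(sim) <- list(lib_a$ids, lib_b$ids)
  sim
}

#' Soergel distance matrix of a fingerprint library
#'
#' For binary fingerprints the Soergel distance is the complement of the
#' Tanimoto similarity, `d = 1 - T`; it is a metric on bit sets and is the
#' distance used for hierarchical clustering.
#'
#' @param lib A [fp_library()].
#' @return Symmetric distance matrix.
#' @export
soergel_matrix <- function(lib) 1 - tanimoto_matrix(lib)

#' Convert between Soergel distance and Tanimoto similarity
#'
#' Threshold translation uses the reciprocal convention
#' `T = 1 / (1 + d)` (and its inverse `d = (1 - T) / T`), so a Soergel
#' cut of 0.15 corresponds to a Tanimoto similarity of about 87%.
#'
#' @param d Soergel distance, `d >= 0`.
#' @param s Tanimoto similarity, `0 < s <= 1`.
#' @return The converted value.
#' @export
soergel_to_tanimoto <- function(d) {
  stopifnot(all(d >= 0))
  1 / (1 + d)
}

#' @rdname soergel_to_tanimoto
#' @export
tanimoto_to_soergel <- function(s) {
  if (any(s <= 0)) stop("similarity must be positive to invert")
  stopifnot(all(s <= 1))
  (1 - s) / s
}

#' Cross-set structural similarity screen
#'
#' Computes the full A-by-B Tanimoto matrix between two fingerprint
#' libraries (e.g. shortlisted repurposed drugs vs. clinical-trial drugs)
#' and flags pairs at or above the similarity threshold (default 80%).
#'
#' @param lib_a,lib_b Fingerprint libraries.
#' @param threshold Tanimoto flag threshold, default 0.80.
#' @param reduce_max If `TRUE`, additionally report, for each drug in
#'   `lib_a`, its maximum similarity over `lib_b` (the compact view used
#'   when the reference set is large).
#' @return List with `similarity` (matrix), `flagged`
#'   (`data.frame`: drug_a, drug_b, tanimoto for pairs >= threshold,
#'   sorted by descending similarity) and, when requested, `max_per_a`.
#' @export
cross_set_screen <- function(lib_a, lib_b, threshold = 0.80, reduce_max = FALSE) {
  if (length(lib_a$ids) == 0 || length(lib_b$ids) == 0) stop("empty fingerprint set")
  sim <- tanimoto_matrix(lib_a, lib_b)
  hit <- which(sim >= threshold, arr.ind = TRUE)
  flagged <- data.frame(
    drug_a = rownames(sim)[hit[, 1]],
    drug_b = colnames(sim)[hit[, 2]],
    tanimoto = sim[hit],
    stringsAsFactors = FALSE
  )
  flagged <- flagged[order(-flagged$tanimoto, flagged$drug_a, flagged$drug_b), , drop = FALSE]
  rownames(flagged) <- NULL
  out <- list(similarity = sim, flagged = flagged, threshold = threshold)
  if (reduce_max) {
    out$max_per_a <- data.frame(
      drug_a = rownames(sim),
      best_match = colnames(sim)[max.col(sim, ties.method = "first")],
      tanimoto = apply(sim, 1, max),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out
}

#' Hierarchical clustering of drugs by structural similarity
#'
#' Agglomerative clustering on the Soergel distance matrix (complete
#' linkage by default, so every within-cluster pairwise distance is at
#' most the cut height) with flat clusters obtained by cutting at
#' `cut` (default 0.15, i.e. within-cluster Tanimoto >= 0.85). Singletons
#' are allowed. Cluster labels are contiguous from 1, numbered in order of
#' first appearance over the input drugs.
#'
#' @param lib A [fp_library()] with at least 2 drugs.
#' @param cut Soergel distance cut height, default 0.15.
#' @param method Linkage passed to [stats::hclust()], default
#'   `"complete"`.
#' @return Object of class `cluster_assignment`: `data.frame` with
#'   `drug_id` and `cluster`, attributes `cut`, `method` and the
#'   `hclust` tree.
#' @export
cluster_drugs <- function(lib, cut = 0.15, method = "complete") {
  stopifnot(inherits(lib, "fp_library"))
  if (length(lib$ids) < 2) stop("need at least 2 drugs to cluster")
  d <- stats::as.dist(soergel_matrix(lib))
  tree <- stats::hclust(d, method = method)
  raw <- stats::cutree(tree, h = cut)
  # relabel contiguous in order of first appearance for determinism
  labels <- match(raw, unique(raw))
  out <- data.frame(drug_id = lib$ids, cluster = labels, stringsAsFactors = FALSE)
  structure(out, class = c("cluster_assignment", "data.frame"),
            cut = cut, method = method, tree = tree)
}

#' Fingerprints from chemical structures
#'
#' Parses SMILES records, canonicalises them (parsing itself normalises
#' the molecular graph), strips salts by keeping the largest fragment, and
#' computes hashed topological path fingerprints via OpenBabel
#' (ChemmineR/ChemmineOB, fingerprint `"FP2"`, 1024 bits). Records that
#' fail to parse are skipped with their identifiers logged and returned.
#'
#' @param smiles Named character vector of SMILES strings (names are drug
#'   identifiers), or a path to a `.smi` file (whitespace-delimited
#'   `SMILES id` per line).
#' @param fp_name OpenBabel fingerprint name, default `"FP2"`.
#' @return [fp_library()] with `origin = "from_structure"` and attribute
#'   `skipped` (character vector of unparsable ids).
#' @export
fingerprint_from_structure <- function(smiles, fp_name = "FP2") {
  if (length(smiles) == 1 && is.character(smiles) && file.exists(smiles)) {
    smiles <- read_smi(smiles)
  }
  stopifnot(is.character(smiles), !is.null(names(smiles)))
  # salt stripping: keep the largest dot-separated fragment
  stripped <- vapply(smiles, function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    # largest fragment by element-symbol count (brackets/charges excluded)
    frags[which.max(nchar(gsub("[^A-Za-z]", "", frags)))]
  }, character(1))
  # validate each record alone so one bad SMILES cannot poison the batch
  valid <- vapply(names(stripped), function(id) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(stripped[[id]], id))),
      error = function(e) NULL
    )
    !is.null(sdf) && length(sdf) > 0 && any(ChemmineR::validSDF(sdf))
  }, logical(1))
  skipped <- names(stripped)[!valid]
  if (length(skipped) > 0)
    cdr_log("skipped %d unparsable structures: %s", length(skipped),
            paste(skipped, collapse = ", "))
  if (!any(valid)) stop("no valid structures to fingerprint")
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(stripped[valid]))
  ChemmineR::cid(sdfset) <- names(stripped)[valid]
  fpset <- ChemmineR::fingerprintOB(sdfset, fp_name)
  bits <- fpset@fpma
  storage.mode(bits) <- "logical"
  rownames(bits) <- names(stripped)[valid]
  lib <- fp_library(bits, origin = "from_structure")
  attr(lib, "skipped") <- skipped
  lib
}
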