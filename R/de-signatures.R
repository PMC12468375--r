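#' Construct an expression dataset
#'
#' Bundles a genes-by-samples log2-scale expression matrix with per-sample
#' case/control labels and stage metadata. This is the raw material for
#' signature extraction.
#'
#' @param matrix Numeric matrix, genes in rows, samples in columns.
#' @param groups Character vector, one of `"case"`/`"control"` per sample.
#' @param stage Disease stage label (e.g. `"MGUS"`, `"sMM"`, `"MM"`).
#' @param dataset_id Dataset identifier string.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, groups, stage = "MM", dataset_id = "DS1") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix))) stop("matrix must have gene identifiers as rownames")
  if (is.null(colnames(matrix))) stop("matrix must have sample identifiers as colnames")
  if (anyDuplicated(colnames(matrix))) stop("duplicate sample identifiers")
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix)) stop("one group label per sample required")
  if (!all(groups %in% c("case", "control"))) stop("groups must be 'case' or 'control'")
  if (min(table(factor(groups, c("case", "control")))) < 2)
    stop("at least 2 samples per group required")
  structure(
    list(matrix = matrix, gene_ids = rownames(matrix), groups = groups,
         stage = stage, dataset_id = dataset_id),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s / %s: %d genes x %d samples (%d case, %d control)\n",
              x$dataset_id, x$stage, nrow(x$matrix), ncol(x$matrix),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Quantile normalisation
#'
#' Forces every column (sample) of an expression matrix onto a common
#' reference distribution: the mean of the column order statistics. After
#' normalisation all columns share the same sorted value multiset (exactly
#' so when ranks are untied; tied values receive the interpolated reference
#' value at their average rank).
#'
#' @param m Numeric matrix (genes x samples), all entries finite.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (!all(is.finite(m))) stop("non-finite entries; impute or drop before normalising")
  n <- nrow(m)
  if (n == 1L) {
    m[] <- mean(m)
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    stats::approx(seq_len(n), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform an expression matrix when it looks unlogged
#'
#' Applies `log2(x + 1)` if the matrix maximum exceeds `threshold`
#' (raw-intensity scale); otherwise returns the matrix unchanged. The
#' decision is logged either way.
#'
#' @param m Numeric matrix.
#' @param threshold Maximum value above which the data are treated as
#'   unlogged intensities. Default 50.
#' @return Matrix on log2 scale.
#' @export
log2_if_needed <- function(m, threshold = 50) {
  if (max(m, na.rm = TRUE) > threshold) {
    cdr_log("matrix maximum %.1f > %g: applying log2(x + 1)", max(m, na.rm = TRUE), threshold)
    log2(m + 1)
  } else {
    cdr_log("matrix maximum %.1f <= %g: already log-scale, left unchanged",
            max(m, na.rm = TRUE), threshold)
    m
  }
}

#' Moderated t-statistic differential expression
#'
#' Two-group differential expression with empirical-Bayes variance
#' shrinkage. Per-gene pooled variances are shrunk toward a prior variance
#' estimated by fitting a scaled inverse-chi-square distribution across all
#' genes (method of moments on the log residual variances); the moderated
#' t-statistic divides the log2 fold-change by the shrunken standard error
#' and is referred to a t-distribution with augmented degrees of freedom.
#' P-values are BH-adjusted across all genes.
#'
#' @param dataset An [expression_dataset()].
#' @param prior_df Optional fixed prior degrees of freedom. `NULL`
#'   (default) estimates it from the data; `0` disables shrinkage, giving
#'   the ordinary two-sample pooled t-test per gene.
#' @return A `data.frame` with one row per gene: `gene`, `log2fc`
#'   (case minus control), `t_stat`, `p_value`, `adj_p`. Attributes
#'   `df_prior` and `s2_prior` record the fitted shrinkage parameters.
#' @export
moderated_t <- function(dataset, prior_df = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- dataset$matrix
  is_case <- dataset$groups == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  df_resid <- n1 + n2 - 2L

  mu1 <- rowMeans(m[, is_case, drop = FALSE])
  mu2 <- rowMeans(m[, !is_case, drop = FALSE])
  log2fc <- mu1 - mu2
  ss1 <- rowSums((m[, is_case, drop = FALSE] - mu1)^2)
  ss2 <- rowSums((m[, !is_case, drop = FALSE] - mu2)^2)
  s2 <- (ss1 + ss2) / df_resid
  if (all(s2 == 0)) stop("zero residual variance for every gene: degenerate input")

  if (!is.null(prior_df) && prior_df == 0) {
    df_prior <- 0
    s2_prior <- NA_real_
    s2_post <- s2
  } else {
    # Method of moments on z = log(s2): for s2 ~ s2_g * chi^2_d / d with a
    # scaled inverse-chi-square prior (d0, s0^2) on s2_g,
    #   E[z] = log(s0^2) + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
    #   Var[z] = trigamma(d/2) + trigamma(d0/2).
    pos <- s2 > 0
    z <- log(s2[pos])
    e <- z - digamma(df_resid / 2) + log(df_resid / 2)
    excess <- stats::var(e) - trigamma(df_resid / 2)
    if (!is.null(prior_df)) {
      df_prior <- prior_df
    } else if (is.finite(excess) && excess > 0) {
      df_prior <- 2 * trigamma_inverse(excess)
    } else {
      df_prior <- Inf
    }
    if (is.finite(df_prior)) {
      s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
      s2_post <- (df_prior * s2_prior + df_resid * s2) / (df_prior + df_resid)
    } else {
      s2_prior <- exp(mean(e))
      s2_post <- rep(s2_prior, length(s2))
    }
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- log2fc / se
  df_total <- if (is.finite(df_prior)) df_resid + df_prior else Inf
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  res <- data.frame(
    gene = dataset$gene_ids, log2fc = log2fc, t_stat = t_stat,
    p_value = p, adj_p = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "df_prior") <- df_prior
  attr(res, "s2_prior") <- s2_prior
  res
}

#' Collapse probe-level results to gene symbols
#'
#' When several probes map to the same gene symbol, the most differentially
#' expressed probe (largest absolute log2 fold-change) represents the gene.
#' Ties on |log2fc| break by smaller adjusted p-value, then lexicographic
#' probe identifier, so the result is deterministic. Probes without a
#' mapping are dropped and counted.
#'
#' @param de Differential-expression `data.frame` keyed by probe in its
#'   `gene` column (as returned by [moderated_t()] on probe-level data).
#' @param probe_map `data.frame` with columns `probe` and `gene`.
#' @return DE `data.frame` keyed by gene symbol, one row per symbol, with
#'   attribute `n_unmapped` giving the dropped probe count.
#' @export
collapse_probes <- function(de, probe_map) {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "adj_p") %in% names(de)))
  stopifnot(is.data.frame(probe_map), all(c("probe", "gene") %in% names(probe_map)))
  if (nrow(probe_map) == 0) stop("empty probe-to-gene map")
  idx <- match(de$gene, probe_map$probe)
  n_unmapped <- sum(is.na(idx))
  if (n_unmapped > 0)
    cdr_log("dropping %d probes without a gene mapping", n_unmapped)
  keep <- !is.na(idx)
  probes <- de$gene[keep]
  out <- de[keep, , drop = FALSE]
  symbol <- probe_map$gene[idx[keep]]
  # deterministic winner per symbol: max |log2fc|, then min adj_p, then probe id
  ord <- order(symbol, -abs(out$log2fc), out$adj_p, probes)
  out <- out[ord, , drop = FALSE]
  symbol <- symbol[ord]
  first <- !duplicated(symbol)
  res <- out[first, , drop = FALSE]
  res$probe <- probes[ord][first]
  res$gene <- symbol[first]
  rownames(res) <- NULL
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Extract an up/down perturbation signature
#'
#' Filters to genes with adjusted p-value strictly below `alpha`, then
#' takes up to `n_each` most over-expressed (largest positive log2fc) and
#' `n_each` most under-expressed (most negative log2fc) genes. A side with
#' fewer than `n_each` qualifying genes returns all of them with a warning.
#'
#' @param de DE `data.frame` with `gene`, `log2fc`, `adj_p`.
#' @param n_each Maximum genes per direction (default 150, the input limit
#'   of common signature-reversal tools).
#' @param alpha Adjusted-p cutoff, strict inequality. Default 0.05.
#' @param rank_first If `TRUE`, rank all genes by log2fc first and then
#'   apply the significance filter within the top/bottom `n_each`;
#'   the default (`FALSE`) filters for significance first, then ranks.
#' @param stage,dataset_id Metadata carried into the signature.
#' @return An object of class `signature`: list with ordered character
#'   vectors `up` (most over-expressed first) and `down` (most
#'   under-expressed first), plus `stage` and `dataset_id`.
#' @export
extract_signature <- function(de, n_each = 150, alpha = 0.05, rank_first = FALSE,
                              stage = NULL, dataset_id = NULL) {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "adj_p") %in% names(de)))
  pick <- function(d, direction) {
    d <- d[if (direction == "up") d$log2fc > 0 else d$log2fc < 0, , drop = FALSE]
    ord <- order(if (direction == "up") -d$log2fc else d$log2fc, d$adj_p, d$gene)
    utils::head(d$gene[ord], n_each)
  }
  if (rank_first) {
    up_pool <- de[order(-de$log2fc, de$adj_p, de$gene), , drop = FALSE]
    up_pool <- utils::head(up_pool[up_pool$log2fc > 0, , drop = FALSE], n_each)
    up <- up_pool$gene[up_pool$adj_p < alpha]
    dn_pool <- de[order(de$log2fc, de$adj_p, de$gene), , drop = FALSE]
    dn_pool <- utils::head(dn_pool[dn_pool$log2fc < 0, , drop = FALSE], n_each)
    down <- dn_pool$gene[dn_pool$adj_p < alpha]
  } else {
    sig <- de[de$adj_p < alpha, , drop = FALSE]
    up <- pick(sig, "up")
    down <- pick(sig, "down")
  }
  if (length(up) == 0 && length(down) == 0)
    warning("no genes pass adj_p < ", alpha, ": empty signature")
  else if (length(up) < n_each || length(down) < n_each)
    cdr_log("signature undersized: %d up, %d down (requested %d each)",
            length(up), length(down), n_each)
  structure(
    list(up = up, down = down, stage = stage, dataset_id = dataset_id),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %s / %s: %d up, %d down\n",
              x$dataset_id %||% "?", x$stage %||% "?", length(x$up), length(x$down)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
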