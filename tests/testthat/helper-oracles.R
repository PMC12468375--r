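options(consensusDR.quiet = TRUE)

# Naive, loop-based recomputation of the weighted consensus score for one
# level: independent of the package's vectorised implementation.
oracle_consensus <- function(lists, w1 = 0.7, w2 = 0.3) {
  items <- sort(unique(unlist(lapply(lists, function(l) l$item_id))))
  out <- data.frame(item_id = character(), R = numeric(), A = numeric(),
                    score = numeric(), stringsAsFactors = FALSE)
  for (it in items) {
    vals <- c()
    for (l in lists) {
      K <- nrow(l)
      pos <- which(l$item_id == it)
      if (length(pos) == 1) vals <- c(vals, (K - pos + 1) / K)
    }
    R <- mean(vals)
    A <- length(vals) / length(lists)
    out <- rbind(out, data.frame(item_id = it, R = R, A = A,
                                 score = w1 * R + w2 * A))
  }
  out
}

# Naive two-level oracle: within-dataset consensus per dataset, then the
# cross-dataset re-ranking with average fractional ranks for tied scores.
oracle_two_level <- function(per_dataset_lists, w1 = 0.7, w2 = 0.3) {
  within <- lapply(per_dataset_lists, oracle_consensus, w1 = w1, w2 = w2)
  items <- sort(unique(unlist(lapply(within, function(l) l$item_id))))
  out <- data.frame()
  for (it in items) {
    vals <- c()
    for (l in within) {
      pos <- which(l$item_id == it)
      if (length(pos) == 1) {
        M <- nrow(l)
        s <- l$score[pos]
        # average fractional rank among tied scores, rank 1 = best
        r <- sum(l$score > s) + (sum(l$score == s) + 1) / 2
        vals <- c(vals, (M - r + 1) / M)
      }
    }
    out <- rbind(out, data.frame(item_id = it, R = mean(vals),
                                 A = length(vals) / length(within),
                                 score = w1 * mean(vals) + w2 * length(vals) / length(within)))
  }
  out
}

# Random ordered item lists for oracle comparisons.
random_lists <- function(n_items, n_lists, item_pool = letters) {
  items <- item_pool[seq_len(n_items)]
  lapply(seq_len(n_lists), function(i) {
    k <- sample(seq_len(n_items), 1)
    data.frame(item_id = sample(items, k), stringsAsFactors = FALSE)
  })
}

# Brute-force BH adjustment on a small vector.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    j_range <- which(rank(p, ties.method = "first") >= rank(p, ties.method = "first")[i])
    # classic definition: adj_i = min over j >= rank(i) of p_(j) * n / j
    r <- rank(p, ties.method = "first")[i]
    cand <- sapply(r:n, function(j) p[ord[j]] * n / j)
    adj[i] <- min(1, min(cand))
  }
  adj
}

# Tiny deterministic fingerprint library from a 0/1 matrix.
lib_from_rows <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  fp_library(m == 1, origin = "synthetic")
}
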