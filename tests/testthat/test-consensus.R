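test_that("within-dataset consensus reproduces hand-computed scores", {
  ids <- sprintf("d%02d", 1:50)
  # item d01 at rank 1 in all three 50-item lists -> score 1
  l <- data.frame(item_id = ids)
  cs <- aggregate_within_dataset(list(l, l, l))
  expect_equal(cs$score[cs$item_id == "d01"], 1.0)
  expect_equal(cs$R[cs$item_id == "d01"], 1.0)
  expect_equal(cs$A[cs$item_id == "d01"], 1.0)

  # item at ranks 1, 2, 3 across tools: R = (1 + 0.98 + 0.96)/3 = 0.98
  l1 <- data.frame(item_id = ids)
  l2 <- data.frame(item_id = ids[c(2, 1, 3:50)])
  l3 <- data.frame(item_id = ids[c(2, 3, 1, 4:50)])
  cs2 <- aggregate_within_dataset(list(l1, l2, l3))
  expect_equal(cs2$R[cs2$item_id == "d01"], 0.98)
  expect_equal(cs2$score[cs2$item_id == "d01"], 0.7 * 0.98 + 0.3 * 1)

  # item at rank 50 in exactly 1 of 3 lists: R = 0.02, A = 1/3, score 0.114
  only <- data.frame(item_id = c(ids[2:50], "unique"))
  cs3 <- aggregate_within_dataset(list(l1, l1, only))
  row <- cs3[cs3$item_id == "unique", ]
  expect_equal(row$R, 0.02)
  expect_equal(row$A, 1 / 3)
  expect_equal(row$score, 0.7 * 0.02 + 0.3 / 3)
})

test_that("scores satisfy the weighted-sum identity and bounds", {
  set.seed(8)
  lists <- random_lists(10, 3, item_pool = sprintf("i%02d", 1:10))
  cs <- aggregate_within_dataset(lists)
  expect_true(all(cs$score >= 0 & cs$score <= 1))
  expect_equal(cs$score, 0.7 * cs$R + 0.3 * cs$A, tolerance = 1e-12)
  expect_equal(cs$A, cs$n_sources / 3, tolerance = 1e-12)
})

test_that("implementation matches the naive oracle over all small configurations", {
  set.seed(99)
  for (n_items in 1:6) {
    for (n_tools in 1:3) {
      for (rep in 1:3) {
        lists <- random_lists(n_items, n_tools, item_pool = sprintf("x%02d", 1:6))
        got <- aggregate_within_dataset(lists)
        want <- oracle_consensus(lists)
        got <- got[order(got$item_id), ]
        expect_equal(got$score, want$score[match(got$item_id, want$item_id)],
                     tolerance = 1e-12)
        expect_equal(got$R, want$R[match(got$item_id, want$item_id)],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("two-level aggregation matches the naive two-level oracle", {
  set.seed(123)
  for (n_datasets in 1:3) {
    for (rep in 1:5) {
      per_ds_lists <- lapply(seq_len(n_datasets), function(d)
        random_lists(sample(2:6, 1), sample(1:3, 1), item_pool = sprintf("x%02d", 1:6)))
      within <- lapply(per_ds_lists, aggregate_within_dataset)
      got <- aggregate_across_datasets(within, stage = "MM")
      want <- oracle_two_level(per_ds_lists)
      got <- got[order(got$item_id), ]
      want <- want[order(want$item_id), ]
      expect_equal(got$item_id, want$item_id)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("single-dataset cross aggregation preserves order with top score 1", {
  ids <- sprintf("d%02d", 1:20)
  within <- aggregate_within_dataset(list(data.frame(item_id = ids)))
  cross <- aggregate_across_datasets(list(within), stage = "MGUS")
  expect_equal(cross$item_id, within$item_id)
  expect_equal(cross$score[1], 1.0)
  expect_equal(attr(cross, "stage"), "MGUS")
})

test_that("an item top-ranked in 2 of 4 datasets scores 0.7 + 0.3 * 0.5", {
  ids <- sprintf("p%03d", 1:100)
  top <- data.frame(item_id = ids, score = seq(1, 0.01, length.out = 100))
  other <- data.frame(item_id = sprintf("q%03d", 1:100), score = seq(1, 0.01, length.out = 100))
  cross <- aggregate_across_datasets(list(top, top, other, other), stage = "MM")
  row <- cross[cross$item_id == "p001", ]
  expect_equal(row$R, 1)
  expect_equal(row$A, 0.5)
  expect_equal(row$score, 0.85)
})

test_that("ranking aggregation is invariant to source order and monotone", {
  set.seed(21)
  lists <- random_lists(6, 3, item_pool = sprintf("m%02d", 1:6))
  a <- aggregate_within_dataset(lists)
  b <- aggregate_within_dataset(rev(lists))
  expect_equal(a, b)

  # improving an item's rank never lowers its score
  ids <- sprintf("d%02d", 1:10)
  l_base <- data.frame(item_id = ids)
  l_swap <- data.frame(item_id = ids[c(2, 1, 3:10)])  # d01 moves 1 -> 2
  s_before <- aggregate_within_dataset(list(l_base, l_base))
  s_after <- aggregate_within_dataset(list(l_base, l_swap))
  expect_lte(s_after$score[s_after$item_id == "d01"],
             s_before$score[s_before$item_id == "d01"])
})

test_that("retention threshold is inclusive at the boundary", {
  scores <- data.frame(item_id = c("a", "b", "c"),
                       score = c(0.75, 0.7499, 0.9))
  sl <- retain_threshold(scores)
  expect_setequal(sl$item_id, c("a", "c"))
  expect_equal(sl$item_id[1], "c")  # sorted descending
  expect_warning(retain_threshold(data.frame(item_id = "x", score = 0.1)), "threshold")
})

test_that("truncation mirrors the shortest tool list", {
  l <- data.frame(item_id = sprintf("d%03d", 1:120))
  expect_equal(nrow(truncate_top_k(l)), 50)
  expect_equal(nrow(truncate_top_k(l[1:30, , drop = FALSE])), 30)
  expect_equal(nrow(truncate_top_k(l, 0)), 0)
})

test_that("pathway ranking uses adjusted p-values with average ranks for ties", {
  t1 <- data.frame(term_id = c("A", "B", "C"), adj_p = c(0.01, 0.02, 0.03))
  cs <- rank_pathways(list(t1, t1, t1), stage = "MM")
  expect_equal(cs$score[cs$item_id == "A"], 1.0)

  # identical adj_p -> same average rank -> same score
  t2 <- data.frame(term_id = c("A", "B", "C"), adj_p = c(0.01, 0.01, 0.03))
  cs2 <- rank_pathways(list(t2), stage = "MM")
  expect_equal(cs2$score[cs2$item_id == "A"], cs2$score[cs2$item_id == "B"])
  expect_error(rank_pathways(list(data.frame(term_id = "A"))), "adj_p")
})

test_that("a pathway shared across datasets scores near 1 when always top-ranked", {
  set.seed(4)
  tables <- lapply(1:3, function(d) {
    others <- data.frame(term_id = sprintf("T%02d_%d", 1:40, d),
                         adj_p = runif(40, 0.001, 1))
    rbind(data.frame(term_id = "SHARED", adj_p = 1e-10), others)
  })
  cs <- rank_pathways(tables, stage = "sMM")
  expect_equal(cs$item_id[1], "SHARED")
  expect_gte(cs$score[1], 0.99)
})

test_that("drug name harmonisation folds case, whitespace and synonyms", {
  ids <- c(" Bortezomib ", "bortezomib", "VELCADE", "dexa  methasone")
  out <- harmonize_drug_ids(ids, synonyms = c(velcade = "bortezomib"))
  expect_equal(out, c("bortezomib", "bortezomib", "bortezomib", "dexa methasone"))
})

test_that("duplicate items within one source list are rejected", {
  bad <- data.frame(item_id = c("a", "a", "b"))
  expect_error(aggregate_within_dataset(list(bad)), "duplicate")
})
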