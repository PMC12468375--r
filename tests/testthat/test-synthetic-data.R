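test_that("expression generator is deterministic and respects the planted structure", {
  truth <- planted_expression_truth(c("UP001", "UP002"), c("DN001",  "DN002"),
                                    effect_size = 2, noise_sd = 0.5)
  a <- gen_expression(100, 5, 5, truth, seed = 42)
  b <- gen_expression(100, 5, 5, truth, seed = 42)
  expect_identical(a$matrix, b$matrix)
  c <- gen_expression(100, 5, 5, truth, seed = 43)
  expect_false(identical(a$matrix, c$matrix))

  # effect_size 0 -> no expected case/control difference anywhere
  null_truth <- planted_expression_truth("UP001", "DN001", effect_size = 0, noise_sd = 0.5)
  set.seed(1)
  diffs <- replicate(50, {
    d <- gen_expression(20, 10, 10, null_truth, seed = sample.int(1e6, 1))
    mean(d$matrix["UP001", d$groups == "case"]) - mean(d$matrix["UP001", d$groups == "control"])
  })
  expect_lt(abs(mean(diffs)), 0.15)

  # planted shift has the right sign and size
  big <- gen_expression(500, 50, 50, truth, seed = 9)
  up_diff <- mean(big$matrix["UP001", big$groups == "case"]) -
    mean(big$matrix["UP001", big$groups == "control"])
  expect_equal(up_diff, 2, tolerance = 0.5)
  expect_error(gen_expression(3, 5, 5, truth, seed = 1), "exceed")
  expect_error(gen_expression(100, 1, 5, truth, seed = 1), "at least 2")
})

test_that("type-I error of the moderated t is calibrated on null data", {
  null_truth <- planted_expression_truth(character(0), character(0),
                                         effect_size = 0, noise_sd = 0.5)
  rates <- vapply(1:100, function(s) {
    ds <- gen_expression(200, 10, 10, null_truth, seed = s)
    mean(moderated_t(ds)$p_value < 0.05)
  }, 1)
  expect_gte(mean(rates), 0.04)
  expect_lte(mean(rates), 0.06)
})

test_that("tool-output generator honours the rank-advantage contract", {
  universe <- sprintf("drug%03d", 1:100)
  # advantage 1 with |true| = top_k: every list is exactly the true set
  truth <- planted_tool_truth(universe[1:10], n_tools = 2, n_datasets = 2,
                              top_k = 10, rank_advantage = 1)
  outs <- gen_tool_outputs(universe, truth, seed = 1)
  for (ds in outs) for (l in ds) {
    expect_setequal(l$item_id, universe[1:10])
    expect_true(all(diff(l$inhibition_score) > 0))  # strictly decreasing strength
    expect_true(all(l$inhibition_score < 0))        # reversers are negative
  }

  # determinism
  outs2 <- gen_tool_outputs(universe, truth, seed = 1)
  expect_identical(outs, outs2)

  expect_error(gen_tool_outputs(character(0), truth, seed = 1), "empty")
  expect_error(gen_tool_outputs(universe[1:5], truth, seed = 1), "top_k")
})

test_that("null rank advantage gives true and decoy drugs indistinguishable scores", {
  universe <- sprintf("drug%03d", 1:60)
  truth <- planted_tool_truth(universe[1:10], n_tools = 2, n_datasets = 2,
                              top_k = 20, rank_advantage = 0.5 + 1e-12)
  diffs <- vapply(1:200, function(s) {
    outs <- gen_tool_outputs(universe, truth, seed = s)
    per_ds <- lapply(outs, function(tools) aggregate_within_dataset(
      lapply(tools, truncate_top_k, k = 20)))
    final <- aggregate_across_datasets(per_ds, stage = "MM")
    is_true <- final$item_id %in% truth$true_reversers
    mean(final$score[is_true]) - mean(final$score[!is_true])
  }, 1)
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("strong rank advantage concentrates planted drugs in the consensus top 20", {
  universe <- sprintf("drug%03d", 1:300)
  truth <- planted_tool_truth(universe[1:25], n_tools = 3, n_datasets = 4,
                              top_k = 50, rank_advantage = 0.9)
  fracs <- vapply(1:20, function(s) {
    outs <- gen_tool_outputs(universe, truth, seed = s)
    per_ds <- lapply(outs, function(tools) aggregate_within_dataset(
      lapply(tools, truncate_top_k)))
    final <- aggregate_across_datasets(per_ds, stage = "MM")
    mean(head(final$item_id, 20) %in% truth$true_reversers)
  }, 1)
  expect_gte(mean(fracs), 0.8)
})

test_that("fingerprint generator plants clusters at the requested similarity", {
  lib <- gen_fingerprints(30, 1024, 3, 0.95, seed = 1)
  truth <- attr(lib, "truth")
  expect_length(truth, 30)
  tm <- tanimoto_matrix(lib)
  for (k in 1:3) {
    idx <- which(truth == k)
    expect_gte(min(tm[idx, idx]), 0.95)
  }
  between <- tm[truth == 1, truth == 2]
  expect_lt(max(between), 0.6)

  # within = 1 -> all cluster members identical
  lib1 <- gen_fingerprints(8, 128, 1, 1, seed = 2)
  expect_true(all(tanimoto_matrix(lib1) == 1))

  # determinism
  expect_identical(gen_fingerprints(10, 256, 2, 0.9, seed = 5)$bits,
                   gen_fingerprints(10, 256, 2, 0.9, seed = 5)$bits)

  # infeasible target flagged, not clipped
  expect_error(gen_fingerprints(10, 64, 2, 0.999, seed = 1), "infeasible")
})

test_that("dose-response generator produces exact Hill margins and planted deltas", {
  grid <- c(0, 0.3, 1, 3, 10, 30)
  ha <- c(y_min = 0, y_max = 90, ec50 = 1, slope = 1.5)
  hb <- c(y_min = 0, y_max = 80, ec50 = 3, slope = 1)
  truth <- planted_synergy_truth("bliss", delta = 0, hill_a = ha, hill_b = hb)
  s <- gen_dose_response(truth, grid, grid, noise_sd = 0, seed = 1)
  # monotherapy margins follow the stated curves
  expect_equal(s$response[, 1], 90 / (1 + (1 / grid)^1.5) * (grid > 0), tolerance = 1e-12)
  expect_equal(s$response[1, ], 80 / (1 + (3 / grid)^1) * (grid > 0), tolerance = 1e-12)
  expect_equal(s$response[1, 1], 0)

  # determinism with noise
  s1 <- gen_dose_response(truth, grid, grid, noise_sd = 2, seed = 7)
  s2 <- gen_dose_response(truth, grid, grid, noise_sd = 2, seed = 7)
  expect_identical(s1$response, s2$response)
  expect_error(gen_dose_response(truth, c(-1, 0, 1), grid, 0, 1), "negative")
  expect_error(gen_dose_response(truth, numeric(0), grid, 0, 1), "empty")
})

test_that("planted deltas survive noise within a unit over repeated draws", {
  grid <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100)
  ha <- c(y_min = 0, y_max = 90, ec50 = 1, slope = 1.5)
  hb <- c(y_min = 0, y_max = 80, ec50 = 3, slope = 1)
  for (model in c("bliss", "hsa")) {
    truth <- planted_synergy_truth(model, delta = 10, hill_a = ha, hill_b = hb)
    scores <- vapply(1:100, function(s) {
      surf <- gen_dose_response(truth, grid, grid, noise_sd = 2, seed = s)
      if (model == "bliss") bliss_score(surf) else hsa_score(surf)
    }, 1)
    expect_lt(abs(mean(scores) - 10), 1)
  }
})

test_that("truth sidecars round-trip the planted parameters", {
  tmp <- withr::local_tempdir()
  truth <- planted_expression_truth("UP001", "DN001", 2, 0.5)
  p <- file.path(tmp, "expr.tsv")
  writeLines("x", p)
  write_truth_sidecar(truth, p)
  back <- read_truth_sidecar(p)
  expect_equal(back$effect_size, 2)
  expect_equal(back$de_genes_up, "UP001")
  expect_true(file.exists(file.path(tmp, "expr.truth.json")))
})
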