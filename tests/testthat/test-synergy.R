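# shared Hill parameter sets used across blocks
HILL_A <- c(y_min = 0, y_max = 90, ec50 = 1, slope = 1.5)
HILL_B <- c(y_min = 0, y_max = 80, ec50 = 3, slope = 1)
GRID <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100)

test_that("Hill fitting recovers exact generating parameters and handles degenerate input", {
  doses <- GRID
  y <- 5 + (85 - 5) / (1 + (2 / doses)^1.3)
  y[doses == 0] <- 5
  fit <- fit_hill(doses, y)
  expect_true(fit$converged)
  expect_equal(fit$y_min, 5, tolerance = 1e-6)
  expect_equal(fit$y_max, 85, tolerance = 1e-6)
  expect_equal(fit$ec50, 2, tolerance = 1e-6)
  expect_equal(fit$slope, 1.3, tolerance = 1e-6)

  flat <- fit_hill(doses, rep(0, length(doses)))
  expect_false(flat$converged)
  expect_equal(predict(flat, c(0.5, 5)), c(0, 0))
})

test_that("Hill EC50 is recovered within 15% under noise", {
  set.seed(77)
  rel_err <- replicate(100, {
    y <- hsa_truth <- 0 + (90 - 0) / (1 + (2 / GRID)^1.5)
    y[GRID == 0] <- 0
    fit <- fit_hill(GRID, y + rnorm(length(GRID), 0, 2))
    abs(fit$ec50 - 2) / 2
  })
  expect_lt(median(rel_err), 0.15)
})

test_that("each model scores zero on its own noise-free null surface", {
  for (model in c("bliss", "hsa", "loewe", "zip")) {
    truth <- planted_synergy_truth(model, delta = 0, hill_a = HILL_A, hill_b = HILL_B)
    s <- gen_dose_response(truth, GRID, GRID, noise_sd = 0, seed = 1)
    score <- switch(model, bliss = bliss_score(s), hsa = hsa_score(s),
                    loewe = as.numeric(loewe_score(s)), zip = as.numeric(zip_score(s)))
    tol <- if (model %in% c("bliss", "hsa")) 1e-9 else 1e-3
    expect_lt(abs(score), tol)
  }
})

test_that("planted deviations are recovered by the matching model", {
  for (model in c("bliss", "hsa", "loewe", "zip")) {
    truth <- planted_synergy_truth(model, delta = 10, hill_a = HILL_A, hill_b = HILL_B)
    s <- gen_dose_response(truth, GRID, GRID, noise_sd = 0, seed = 2)
    score <- switch(model, bliss = bliss_score(s), hsa = hsa_score(s),
                    loewe = as.numeric(loewe_score(s)), zip = as.numeric(zip_score(s)))
    expect_equal(as.numeric(score), 10, tolerance = 0.05 * 10)
  }
})

test_that("cell-level deviations match hand computations", {
  # Bliss: y_a = y_b = 50, observed 85 -> deviation 85 - 75 = +10
  resp <- matrix(c(0, 50, 50, 85), 2, 2)
  s <- dose_response_surface(resp, c(0, 1), c(0, 1))
  expect_equal(bliss_score(s), 10)
  # HSA: y_a = 60, y_b = 40, observed 72 -> deviation +12
  resp2 <- matrix(c(0, 60, 40, 72), 2, 2)
  s2 <- dose_response_surface(resp2, c(0, 1), c(0, 1))
  expect_equal(hsa_score(s2), 12)
  expect_equal(classify_synergy(hsa_score(s2)), "strong")
  # observed below both margins -> negative (antagonism)
  resp3 <- matrix(c(0, 60, 40, 30), 2, 2)
  expect_lt(hsa_score(dose_response_surface(resp3, c(0, 1), c(0, 1))), 0)
})

test_that("a sham combination of a drug with itself scores zero under Loewe", {
  f <- function(x) ifelse(x == 0, 0, 95 / (1 + (2 / x)^1.3))
  resp <- outer(GRID, GRID, function(a, b) f(a + b))
  s <- dose_response_surface(resp, GRID, GRID, clip = FALSE)
  expect_lt(abs(as.numeric(loewe_score(s))), 1e-6)
})

test_that("equal-potency drugs observed at Hill(x_a + x_b) are Loewe-additive", {
  f <- function(x) ifelse(x == 0, 0, 90 / (1 + (5 / x)^2))
  resp <- outer(GRID, GRID, function(a, b) f(a + b))
  s <- dose_response_surface(resp, GRID, GRID, clip = FALSE)
  expect_lt(abs(as.numeric(loewe_score(s))), 1e-6)
})

test_that("Loewe is the most conservative model for mechanistically distinct pairs", {
  # Loewe's dose-equivalence expectation exceeds the independence and
  # best-single-agent nulls for steep, full-efficacy curves of different
  # potency, so its synergy score is the lowest of the four in that regime
  steep_a <- c(y_min = 0, y_max = 100, ec50 = 1, slope = 2)
  steep_b <- c(y_min = 0, y_max = 100, ec50 = 5, slope = 2.5)
  truth <- planted_synergy_truth("bliss", delta = 8, hill_a = steep_a, hill_b = steep_b)
  s <- gen_dose_response(truth, GRID, GRID, noise_sd = 0, seed = 3)
  scores <- c(zip = as.numeric(zip_score(s)), bliss = bliss_score(s),
              hsa = hsa_score(s), loewe = as.numeric(loewe_score(s)))
  expect_lte(scores[["loewe"]], min(scores[c("zip", "bliss", "hsa")]) + 1e-6)
})

test_that("all four scores are invariant to swapping the two drugs", {
  truth <- planted_synergy_truth("bliss", delta = 6, hill_a = HILL_A, hill_b = HILL_B)
  s <- gen_dose_response(truth, GRID, c(0, 0.3, 1, 3, 10, 30), noise_sd = 1, seed = 4)
  st <- transpose_surface(s)
  expect_equal(bliss_score(s), bliss_score(st), tolerance = 1e-12)
  expect_equal(hsa_score(s), hsa_score(st), tolerance = 1e-12)
  expect_equal(as.numeric(loewe_score(s)), as.numeric(loewe_score(st)), tolerance = 1e-6)
  expect_equal(as.numeric(zip_score(s)), as.numeric(zip_score(st)), tolerance = 1e-3)
})

test_that("adding a constant to all combination cells shifts every score by that constant", {
  truth <- planted_synergy_truth("bliss", delta = 0, hill_a = HILL_A, hill_b = HILL_B)
  s0 <- gen_dose_response(truth, GRID, GRID, noise_sd = 0, seed = 5)
  s1 <- s0
  s1$response[2:length(GRID), 2:length(GRID)] <-
    s1$response[2:length(GRID), 2:length(GRID)] + 7
  expect_equal(bliss_score(s1) - bliss_score(s0), 7, tolerance = 1e-9)
  expect_equal(hsa_score(s1) - hsa_score(s0), 7, tolerance = 1e-9)
  expect_equal(as.numeric(loewe_score(s1)) - as.numeric(loewe_score(s0)), 7, tolerance = 1e-3)
  expect_equal(as.numeric(zip_score(s1)) - as.numeric(zip_score(s0)), 7, tolerance = 0.5)
})

test_that("classification respects the strict +5/+10 boundaries", {
  expect_equal(classify_synergy(5), "none")
  expect_equal(classify_synergy(5.01), "moderate")
  expect_equal(classify_synergy(10), "moderate")
  expect_equal(classify_synergy(10.01), "strong")
  expect_equal(classify_synergy(-3), "none")
  # planted +7 classifies as moderate end to end
  truth <- planted_synergy_truth("hsa", delta = 7, hill_a = HILL_A, hill_b = HILL_B)
  s <- gen_dose_response(truth, GRID, GRID, noise_sd = 0, seed = 6)
  expect_equal(classify_synergy(hsa_score(s)), "moderate")
})

test_that("per-model ranking and cross-model intersection behave as documented", {
  summaries <- data.frame(
    pair_id = c("p1", "p2", "p3"),
    zip_score = c(12, 8, 1), loewe_score = c(11, 2, 0),
    hsa_score = c(13, 9, 2), bliss_score = c(14, 7, 3),
    stringsAsFactors = FALSE
  )
  out <- classify_and_rank(summaries)
  # p2 synergistic under zip/hsa/bliss but not loewe: union yes, intersection no
  expect_true("p2" %in% out$union$pair_id)
  expect_false("p2" %in% out$intersection)
  expect_equal(out$intersection, "p1")
  expect_equal(out$per_model$zip$pair_id, c("p1", "p2"))
  # score exactly 5 is not synergistic
  summaries$zip_score[3] <- 5
  out2 <- classify_and_rank(summaries)
  expect_false("p3" %in% out2$per_model$zip$pair_id)
  # empty input gives empty outputs
  out3 <- classify_and_rank(summaries[0, ])
  expect_length(out3$intersection, 0)
  expect_equal(nrow(out3$union), 0)
})

test_that("surface construction validates grids and clips wild responses", {
  expect_error(dose_response_surface(matrix(0, 2, 2), c(0, -1), c(0, 1)), "negative")
  expect_error(dose_response_surface(matrix(0, 2, 2), c(1, 2), c(0, 1)), "start at 0")
  expect_error(dose_response_surface(matrix(0, 2, 2), c(0, 0), c(0, 1)), "increasing")
  expect_error(dose_response_surface(matrix(0, 3, 2), c(0, 1), c(0, 1)), "dimensions")
  expect_warning(s <- dose_response_surface(matrix(c(0, 150, 20, 30), 2, 2), c(0, 1), c(0, 1)),
                 "clipped")
  expect_equal(max(s$response), 100)
})
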