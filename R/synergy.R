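#' Construct a dose-response surface
#'
#' Holds monotherapy and combination responses of a drug pair on a dose
#' grid. Responses are percent inhibition on the 0-100 scale (0 = no
#' effect, 100 = full effect); the (0, 0) cell is the untreated control.
#'
#' @param response Numeric matrix, `length(conc_r)` x `length(conc_c)`;
#'   rows follow the row drug's doses, columns the column drug's doses.
#' @param conc_r,conc_c Strictly increasing dose vectors starting at 0
#'   (concentration units are the caller's; only the grid matters).
#' @param drug_row,drug_col Drug identifiers.
#' @param clip Clip responses into \[0, 100\]? Values outside
#'   \[-10, 110\] trigger a warning first. Default `TRUE`.
#' @return Object of class `dr_surface`.
#' @export
dose_response_surface <- function(response, conc_r, conc_c,
                                  drug_row = "drugA", drug_col = "drugB",
                                  clip = TRUE) {
  response <- as.matrix(response)
  stopifnot(is.numeric(response), is.numeric(conc_r), is.numeric(conc_c))
  if (any(conc_r < 0) || any(conc_c < 0)) stop("negative doses")
  if (length(conc_r) == 0 || length(conc_c) == 0) stop("empty dose grid")
  if (conc_r[1] != 0 || conc_c[1] != 0) stop("dose grids must start at 0 (untreated margin)")
  if (any(diff(conc_r) <= 0) || any(diff(conc_c) <= 0)) stop("dose grids must be strictly increasing")
  if (!all(dim(response) == c(length(conc_r), length(conc_c))))
    stop("response matrix dimensions do not match the dose grids")
  if (clip) {
    if (any(response < -10 | response > 110))
      warning("responses outside [-10, 110] clipped to [0, 100]")
    response <- pmin(pmax(response, 0), 100)
  }
  structure(list(response = response, conc_r = conc_r, conc_c = conc_c,
                 drug_row = drug_row, drug_col = drug_col),
            class = "dr_surface")
}

#' @export
print.dr_surface <- function(x, ...) {
  cat(sprintf("<dr_surface> %s x %s: %d x %d dose grid\n",
              x$drug_row, x$drug_col, length(x$conc_r), length(x$conc_c)))
  invisible(x)
}

#' Transpose a dose-response surface (swap the two drugs)
#' @param s A `dr_surface`.
#' @return The transposed surface.
#' @export
transpose_surface <- function(s) {
  dose_response_surface(t(s$response), s$conc_c, s$conc_r,
                        drug_row = s$drug_col, drug_col = s$drug_row, clip = FALSE)
}

# Four-parameter log-logistic (Hill) response:
#   y(x) = y_min + (y_max - y_min) / (1 + (ec50 / x)^slope),  y(0) = y_min.
hill_response <- function(x, y_min, y_max, ec50, slope) {
  y <- y_min + (y_max - y_min) / (1 + (ec50 / x)^slope)
  y[x == 0] <- y_min
  y
}

#' Fit a Hill (four-parameter log-logistic) curve
#'
#' Least-squares fit of `y = y_min + (y_max - y_min) / (1 + (ec50/x)^slope)`
#' by Levenberg-Marquardt with multiple slope starts (0.5, 1, 2, 4). When
#' no start converges the fit falls back to monotone linear interpolation
#' of the observed points (`converged = FALSE`); degenerate flat data
#' return a flat fit.
#'
#' @param doses Numeric vector including 0, at least 4 points.
#' @param responses Numeric vector of the same length (% inhibition).
#' @return Object of class `hill_fit` with fields `y_min`, `y_max`,
#'   `ec50`, `slope`, `converged`, `rmse` and the data for the
#'   interpolation fallback.
#' @export
fit_hill <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), length(doses) >= 4, 0 %in% doses)
  ord <- order(doses)
  doses <- doses[ord]; responses <- responses[ord]
  flat <- function() {
    structure(list(y_min = mean(responses), y_max = mean(responses),
                   ec50 = max(doses[doses > 0], 1), slope = 1,
                   converged = FALSE, rmse = stats::sd(responses) %||% 0,
                   doses = doses, responses = responses),
              class = "hill_fit")
  }
  if (stats::sd(responses) < 1e-12) return(flat())
  pos <- doses > 0
  ec50_start <- exp(mean(log(doses[pos])))
  best <- NULL
  for (slope0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ hill_response(doses, y_min, y_max, ec50, slope),
        start = list(y_min = min(responses), y_max = max(responses),
                     ec50 = ec50_start, slope = slope0),
        lower = c(y_min = -50, y_max = -50, ec50 = 1e-12, slope = 0.05),
        upper = c(y_min = 150, y_max = 150, ec50 = 1e12, slope = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    f <- flat()
    # monotone interpolation fallback keeps downstream models usable
    f$responses <- responses
    return(f)
  }
  cf <- stats::coef(best$fit)
  if (cf[["y_min"]] > cf[["y_max"]]) {
    # re-express a decreasing fit as increasing in the other direction:
    # keep parameters but note y_min <= y_max by swapping is not valid for
    # the same curve, so treat as non-converged and interpolate.
    f <- flat()
    return(f)
  }
  structure(list(y_min = unname(cf[["y_min"]]), y_max = unname(cf[["y_max"]]),
                 ec50 = unname(cf[["ec50"]]), slope = unname(cf[["slope"]]),
                 converged = TRUE,
                 rmse = sqrt(best$rss / length(doses)),
                 doses = doses, responses = responses),
            class = "hill_fit")
}

#' Predicted response from a Hill fit
#' @param object A `hill_fit`.
#' @param x Doses at which to predict.
#' @param ... Unused.
#' @return Predicted % inhibition.
#' @export
predict.hill_fit <- function(object, x, ...) {
  if (!object$converged) {
    # monotone linear interpolation of the observed points, constant tails
    return(stats::approx(object$doses, object$responses, xout = x, rule = 2)$y)
  }
  hill_response(x, object$y_min, object$y_max, object$ec50, object$slope)
}

# Dose producing effect y under a Hill fit (inverse function); NA outside
# the achievable open interval (y_min, y_max).
invert_hill <- function(fit, y) {
  if (!fit$converged || fit$y_max - fit$y_min < 1e-9) return(rep(NA_real_, length(y)))
  out <- rep(NA_real_, length(y))
  ok <- y > fit$y_min & y < fit$y_max
  out[ok] <- fit$ec50 * ((y[ok] - fit$y_min) / (fit$y_max - y[ok]))^(1 / fit$slope)
  out
}

# Margins of a surface: observed monotherapy responses along row/col 0.
surface_margins <- function(s) {
  list(ya = s$response[, 1], yb = s$response[1, ])  # ya over conc_r, yb over conc_c
}

#' Bliss independence synergy score
#'
#' For each positive-dose cell the null expectation assumes probabilistic
#' independence of the two drugs' effects,
#' `E = y_a + y_b - y_a * y_b / 100` (responses in % inhibition), with
#' monotherapy values taken from the measured margins. The score is the
#' mean of observed minus expected over the positive-dose grid; positive
#' values indicate synergy.
#'
#' @param s A [dose_response_surface()].
#' @return Scalar synergy score (% response units).
#' @export
bliss_score <- function(s) {
  stopifnot(inherits(s, "dr_surface"))
  m <- surface_margins(s)
  nr <- length(s$conc_r); nc <- length(s$conc_c)
  dev <- outer(2:nr, 2:nc, Vectorize(function(i, j) {
    ya <- m$ya[i]; yb <- m$yb[j]
    s$response[i, j] - (ya + yb - ya * yb / 100)
  }))
  mean(dev)
}

#' Highest single agent (HSA) synergy score
#'
#' Null expectation per cell is the better of the two monotherapy effects
#' at the component doses, `E = max(y_a, y_b)`; the score is the mean
#' observed-minus-expected deviation over positive-dose cells.
#'
#' @inheritParams bliss_score
#' @return Scalar synergy score.
#' @export
hsa_score <- function(s) {
  stopifnot(inherits(s, "dr_surface"))
  m <- surface_margins(s)
  nr <- length(s$conc_r); nc <- length(s$conc_c)
  dev <- outer(2:nr, 2:nc, Vectorize(function(i, j) {
    s$response[i, j] - max(m$ya[i], m$yb[j])
  }))
  mean(dev)
}

# Loewe additive expectation for one dose pair under two Hill fits: the
# effect level y solving the isobole equation x_a / D_a(y) + x_b / D_b(y) = 1.
loewe_expected_cell <- function(xa, xb, fit_a, fit_b, tol = 1e-9) {
  lo <- max(fit_a$y_min, fit_b$y_min)
  hi <- min(fit_a$y_max, fit_b$y_max)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-9) return(NA_real_)
  f <- function(y) {
    da <- invert_hill(fit_a, y); db <- invert_hill(fit_b, y)
    xa / da + xb / db - 1
  }
  eps <- (hi - lo) * 1e-9
  # f decreases in y from +Inf (y -> lo) ; no root means the combined dose
  # saturates both curves: score against the asymptotic expectation hi.
  if (f(hi - eps) > 0) return(hi)
  lower <- lo + eps; upper <- hi - eps
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Loewe additivity synergy score
#'
#' Fits Hill curves to both monotherapy margins and, for each
#' positive-dose cell, solves the dose-equivalence (isobole) equation
#' `x_a / D_a(y) + x_b / D_b(y) = 1` for the expected additive effect `y`
#' by bisection, where `D(y)` inverts the fitted Hill curve. Cells whose
#' expectation is unattainable within both curves' common effect range are
#' scored against the asymptotic expectation and flagged; the score is the
#' mean observed-minus-expected deviation.
#'
#' @inheritParams bliss_score
#' @return Scalar synergy score, with attribute `n_asymptotic` counting
#'   cells scored against the asymptote and `n_skipped` counting cells
#'   with no computable expectation.
#' @export
loewe_score <- function(s) {
  stopifnot(inherits(s, "dr_surface"))
  fit_a <- fit_hill(s$conc_r, s$response[, 1])
  fit_b <- fit_hill(s$conc_c, s$response[1, ])
  if (!fit_a$converged || !fit_b$converged)
    cdr_log("loewe: monotherapy Hill fit did not converge; using interpolation where possible")
  nr <- length(s$conc_r); nc <- length(s$conc_c)
  dev <- c(); n_asym <- 0L; n_skip <- 0L
  hi <- min(fit_a$y_max, fit_b$y_max)
  for (i in 2:nr) for (j in 2:nc) {
    exp_y <- loewe_expected_cell(s$conc_r[i], s$conc_c[j], fit_a, fit_b)
    if (is.na(exp_y)) { n_skip <- n_skip + 1L; next }
    if (isTRUE(all.equal(exp_y, hi))) n_asym <- n_asym + 1L
    dev <- c(dev, s$response[i, j] - exp_y)
  }
  if (length(dev) == 0) stop("no Loewe expectation computable on this surface (flat margins?)")
  structure(mean(dev), n_asymptotic = n_asym, n_skipped = n_skip)
}

#' Zero interaction potency (ZIP) synergy score
#'
#' The ZIP delta compares a smoothed response surface against the
#' zero-interaction expectation built from fitted monotherapy curves.
#' Hill curves are fitted to each row (varying the row drug at fixed
#' column dose) and each column of the combination matrix; the fitted
#' combination response at a cell is the average of its row-fit and
#' column-fit predictions. The zero-interaction expectation is the
#' probabilistic-independence surface of the fitted (not raw) monotherapy
#' margins, and the score is the mean difference over positive-dose
#' cells. Rows/columns with fewer than 4 points or failed fits fall back
#' to the raw observations (flagged `degraded`).
#'
#' @inheritParams bliss_score
#' @return Scalar synergy score with attribute `degraded` (logical).
#' @export
zip_score <- function(s) {
  stopifnot(inherits(s, "dr_surface"))
  fit_a <- fit_hill(s$conc_r, s$response[, 1])
  fit_b <- fit_hill(s$conc_c, s$response[1, ])
  nr <- length(s$conc_r); nc <- length(s$conc_c)
  degraded <- FALSE
  smooth_line <- function(doses, resp) {
    if (length(doses) < 4) { degraded <<- TRUE; return(resp) }
    f <- fit_hill(doses, resp)
    if (!f$converged) { degraded <<- TRUE; return(resp) }
    predict(f, doses)
  }
  row_pred <- s$response
  for (j in 2:nc) row_pred[, j] <- smooth_line(s$conc_r, s$response[, j])
  col_pred <- s$response
  for (i in 2:nr) col_pred[i, ] <- smooth_line(s$conc_c, s$response[i, ])
  ya_hat <- predict(fit_a, s$conc_r)
  yb_hat <- predict(fit_b, s$conc_c)
  dev <- outer(2:nr, 2:nc, Vectorize(function(i, j) {
    fitted_y <- (row_pred[i, j] + col_pred[i, j]) / 2
    ya <- ya_hat[i]; yb <- yb_hat[j]
    fitted_y - (ya + yb - ya * yb / 100)
  }))
  structure(mean(dev), degraded = degraded)
}

#' Score one surface under all four synergy reference models
#'
#' @inheritParams bliss_score
#' @param thresholds Moderate/strong synergy thresholds, default
#'   `c(5, 10)`; classification is strict (`> 5`, `> 10`).
#' @return One-row `data.frame` with `pair_id`, the four scores
#'   (`zip_score`, `loewe_score`, `hsa_score`, `bliss_score`) and a
#'   classification column per model.
#' @export
synergy_summary <- function(s, thresholds = c(5, 10)) {
  scores <- c(zip = as.numeric(zip_score(s)),
              loewe = as.numeric(loewe_score(s)),
              hsa = hsa_score(s),
              bliss = bliss_score(s))
  cls <- vapply(scores, classify_synergy, character(1), thresholds = thresholds)
  out <- data.frame(pair_id = paste(s$drug_row, s$drug_col, sep = " + "),
                    drug_row = s$drug_row, drug_col = s$drug_col,
                    zip_score = scores[["zip"]], loewe_score = scores[["loewe"]],
                    hsa_score = scores[["hsa"]], bliss_score = scores[["bliss"]],
                    zip_class = cls[["zip"]], loewe_class = cls[["loewe"]],
                    hsa_class = cls[["hsa"]], bliss_class = cls[["bliss"]],
                    stringsAsFactors = FALSE)
  out
}

#' Classify a synergy score
#'
#' Strictly greater than +10 is `"strong"`, strictly greater than +5 (and
#' not strong) is `"moderate"`, anything else (including exactly +5 or
#' +10 at the boundary of its band) is `"none"`.
#'
#' @param score Synergy score.
#' @param thresholds `c(moderate, strong)` cutoffs, default `c(5, 10)`.
#' @return `"strong"`, `"moderate"` or `"none"`.
#' @export
classify_synergy <- function(score, thresholds = c(5, 10)) {
  if (score > thresholds[2]) "strong"
  else if (score > thresholds[1]) "moderate"
  else "none"
}

#' Per-model top lists and the cross-model intersection
#'
#' From a table of per-pair synergy summaries, extracts for each model the
#' pairs that are synergistic (score strictly above the moderate
#' threshold) sorted by descending score, the top-`top_n` view of each,
#' the pairs synergistic under all four models simultaneously, and the
#' union of pairs synergistic under at least one model annotated with
#' which models fired.
#'
#' @param summaries `data.frame` of stacked [synergy_summary()] rows.
#' @param thresholds Moderate/strong thresholds, default `c(5, 10)`.
#' @param top_n Rows in each per-model top view, default 20.
#' @return List with `per_model` (named list of `data.frame`s), `top`
#'   (named list, head `top_n` of each), `intersection` (pair ids
#'   synergistic under all models) and `union` (`data.frame`: pair_id,
#'   models, n_models).
#' @export
classify_and_rank <- function(summaries, thresholds = c(5, 10), top_n = 20) {
  stopifnot(is.data.frame(summaries))
  models <- c("zip", "loewe", "hsa", "bliss")
  if (nrow(summaries) == 0) {
    empty <- stats::setNames(lapply(models, function(m) summaries), models)
    return(list(per_model = empty, top = empty, intersection = character(),
                union = data.frame(pair_id = character(), models = character(),
                                   n_models = integer())))
  }
  per_model <- lapply(models, function(m) {
    col <- paste0(m, "_score")
    hit <- summaries[summaries[[col]] > thresholds[1], , drop = FALSE]
    hit <- hit[order(-hit[[col]], hit$pair_id), , drop = FALSE]
    rownames(hit) <- NULL
    hit
  })
  names(per_model) <- models
  fired <- sapply(models, function(m) summaries[[paste0(m, "_score")]] > thresholds[1])
  fired <- matrix(fired, nrow = nrow(summaries), dimnames = list(NULL, models))
  inter <- summaries$pair_id[rowSums(fired) == length(models)]
  any_hit <- rowSums(fired) > 0
  union_df <- data.frame(
    pair_id = summaries$pair_id[any_hit],
    models = apply(fired[any_hit, , drop = FALSE], 1,
                   function(r) paste(models[r], collapse = ",")),
    n_models = rowSums(fired)[any_hit],
    stringsAsFactors = FALSE
  )
  union_df <- union_df[order(-union_df$n_models, union_df$pair_id), , drop = FALSE]
  rownames(union_df) <- NULL
  list(per_model = per_model,
       top = lapply(per_model, utils::head, top_n),
       intersection = sort(inter),
       union = union_df)
}
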