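# Calibration and validation: rejection approximate Bayesian computation
# over (h, c, M_e), and presence/absence distribution skill via a
# threshold-optimised sensitivity/specificity.

#' Rejection-ABC calibration
#'
#' Draws parameter vectors from independent uniform priors, runs the
#' simulator for each draw, scores every run against the target series with
#' a normalised sum of squared deviations, and accepts the best
#' `accept_frac` of draws as the posterior sample.
#'
#' The cost for each dataset is the sum of squared deviations divided by
#' the variance of that dataset's observations, which makes the total cost
#' invariant to rescaling any single dataset (the datasets differ in
#' units). A simulator failure is recorded as infinite cost.
#'
#' @param simulator `function(params)` taking a named list/vector of the
#'   calibrated parameters and returning a named list of numeric vectors,
#'   one per target dataset (e.g. an SSB series and a weight-at-age
#'   series).
#' @param priors data.frame with columns `name`, `min`, `max` (uniform
#'   bounds).
#' @param targets Named list of numeric vectors matching the simulator's
#'   outputs.
#' @param n_sims Number of prior draws (must be at least `1/accept_frac`).
#' @param accept_frac Fraction of draws accepted (default 0.01).
#' @param seed RNG seed.
#' @param lhs Use a Latin-hypercube design instead of independent uniform
#'   draws (useful at small `n_sims`).
#' @return An object of class `abc_result`: the draw table with costs and
#'   acceptance flags, posterior summaries (mean and 2.5/50/97.5 percent
#'   quantiles per parameter), and pointwise 95 percent credible bands of
#'   the accepted runs' outputs.
#' @export
abc_calibrate <- function(simulator, priors, targets, n_sims,
                          accept_frac = 0.01, seed = 1, lhs = FALSE) {
  stopifnot(all(c("name", "min", "max") %in% names(priors)))
  if (n_sims < 1 / accept_frac) {
    stop("n_sims (", n_sims, ") must be at least 1/accept_frac (",
         ceiling(1 / accept_frac), ")")
  }
  k <- nrow(priors)
  set.seed(seed)
  if (lhs) {
    u <- sapply(seq_len(k), function(j) {
      (sample.int(n_sims) - stats::runif(n_sims)) / n_sims
    })
  } else {
    u <- matrix(stats::runif(n_sims * k), n_sims, k)
  }
  draws <- sweep(sweep(u, 2, priors$max - priors$min, `*`), 2, priors$min, `+`)
  colnames(draws) <- priors$name

  norm <- vapply(targets, function(v) {
    s <- stats::var(v)
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))

  costs <- numeric(n_sims)
  outputs <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim <- tryCatch(simulator(as.list(draws[i, ])), error = function(e) NULL)
    if (is.null(sim)) {
      costs[i] <- Inf
      next
    }
    outputs[[i]] <- sim
    costs[i] <- sum(vapply(names(targets), function(nm) {
      d <- sim[[nm]] - targets[[nm]]
      sum(d^2) / norm[nm]
    }, numeric(1)))
  }

  n_acc <- ceiling(accept_frac * n_sims)
  ord <- order(costs)
  accepted <- logical(n_sims)
  accepted[ord[seq_len(n_acc)]] <- TRUE

  post <- draws[accepted, , drop = FALSE]
  summaries <- data.frame(
    name = priors$name,
    mean = colMeans(post),
    q2.5 = apply(post, 2, stats::quantile, 0.025),
    q50 = apply(post, 2, stats::quantile, 0.5),
    q97.5 = apply(post, 2, stats::quantile, 0.975),
    row.names = NULL
  )

  bands <- lapply(names(targets), function(nm) {
    mat <- do.call(rbind, lapply(which(accepted), function(i) outputs[[i]][[nm]]))
    if (is.null(mat)) return(NULL)
    data.frame(
      index = seq_len(ncol(mat)),
      lower = apply(mat, 2, stats::quantile, 0.025),
      median = apply(mat, 2, stats::quantile, 0.5),
      upper = apply(mat, 2, stats::quantile, 0.975)
    )
  })
  names(bands) <- names(targets)

  structure(list(
    priors = priors,
    draws = data.frame(draws, cost = costs, accepted = accepted),
    accept_frac = accept_frac, n_accepted = n_acc,
    posterior = summaries, credible_bands = bands
  ), class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result> ", nrow(x$draws), " draws, ", x$n_accepted,
      " accepted (", 100 * x$accept_frac, "%)\n", sep = "")
  print(x$posterior, ...)
  invisible(x)
}

#' Persist ABC draws and summaries
#'
#' Writes the draw table as CSV and the posterior summary as JSON.
#' @param x An `abc_result`.
#' @param dir Output directory.
#' @export
write_abc_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$draws, file.path(dir, "abc_draws.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x$posterior, file.path(dir, "abc_posterior.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Threshold-optimised presence/absence skill
#'
#' Scans every candidate density threshold (the finite set of observed
#' predicted densities) and returns the one maximising the objective,
#' together with the resulting sensitivity (proportion of presences
#' correctly classified) and specificity (proportion of absences correctly
#' classified). A cell is classed as a presence when its predicted density
#' is at or above the threshold. Predictions and observations are pooled
#' over cells (and survey years) before scanning.
#'
#' @param predicted Numeric vector of predicted densities per pooled cell.
#' @param observed Logical (or 0/1) vector of observed presences.
#' @param objective `"youden"` (sensitivity + specificity - 1, default) or
#'   `"accuracy"`.
#' @return An object of class `skill_result`: `threshold`, `sensitivity`,
#'   `specificity`, `objective`, and the pooled confusion counts.
#' @export
optimise_threshold <- function(predicted, observed,
                               objective = c("youden", "accuracy")) {
  objective <- match.arg(objective)
  observed <- as.logical(observed)
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must be pooled on matching cells")
  }
  if (all(observed) || !any(observed)) {
    stop("observations contain a single class; sensitivity or specificity ",
         "is undefined")
  }
  cands <- sort(unique(predicted))
  cands <- c(cands, max(cands) + 1)  # the all-absent classification
  best <- NULL
  for (t in cands) {
    s <- classify_skill(predicted, observed, t)
    score <- switch(objective,
      youden = s$sensitivity + s$specificity - 1,
      accuracy = (s$tp + s$tn) / length(observed))
    if (is.null(best) || score > best$score) {
      best <- c(s, list(score = score, threshold = t))
    }
  }
  structure(list(
    threshold = best$threshold,
    sensitivity = best$sensitivity, specificity = best$specificity,
    objective = objective, score = best$score,
    counts = c(tp = best$tp, fp = best$fp, tn = best$tn, fn = best$fn)
  ), class = "skill_result")
}

#' Sensitivity and specificity at a fixed threshold
#'
#' @param predicted Predicted densities.
#' @param observed Observed presence logical vector.
#' @param threshold Density at or above which a cell is classed a presence.
#' @return List with confusion counts, sensitivity and specificity.
#' @export
classify_skill <- function(predicted, observed, threshold) {
  pred <- predicted >= threshold
  tp <- sum(pred & observed); fn <- sum(!pred & observed)
  tn <- sum(!pred & !observed); fp <- sum(pred & !observed)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' @export
print.skill_result <- function(x, ...) {
  cat("<skill_result> threshold = ", format(x$threshold, digits = 4),
      "; sensitivity = ", round(x$sensitivity, 3),
      ", specificity = ", round(x$specificity, 3),
      " (", x$objective, ")\n", sep = "")
  invisible(x)
}
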