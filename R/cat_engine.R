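#' Configuration of a post-hoc CAT simulation
#'
#' Defaults mirror standard PROMIS practice: stop when the standard error
#' reaches 3 on the T-score metric (`SE_theta <= 0.3`, reliability
#' `1 - 0.3^2 = 0.91`, i.e. slightly above 0.90) or after 12 items; no
#' minimum number of items; maximum-likelihood trait estimation bounded to
#' \code{[-4, 4]}; item selection by maximum Fisher information at the
#' current estimate starting from `theta = 0`.
#'
#' @param se_stop SE stopping rule on the T metric (theta SE times 10).
#' @param max_items maximum items administered.
#' @param min_items minimum items before the SE rule may stop.
#' @param fixed_length if set, administer exactly this many items
#'   (overrides the SE rule).
#' @param estimator interim/final estimator: `"ML"`, `"EAP"` or `"MAP"`.
#' @param theta_bounds trait bounds for ML estimation and clamping.
#' @param start_theta trait value at which the first item is selected.
#' @return list of class `cat_config`.
#' @export
cat_config <- function(se_stop = 3, max_items = 12L, min_items = 0L,
                       fixed_length = NULL, estimator = "ML",
                       theta_bounds = c(-4, 4), start_theta = 0) {
  stopifnot(se_stop > 0, min_items >= 0, min_items <= max_items)
  if (!is.null(fixed_length)) stopifnot(fixed_length >= 1)
  structure(
    list(se_stop = se_stop, max_items = as.integer(max_items),
         min_items = as.integer(min_items),
         fixed_length = if (is.null(fixed_length)) NULL else as.integer(fixed_length),
         estimator = match.arg(estimator, c("ML", "EAP", "MAP")),
         theta_bounds = theta_bounds, start_theta = start_theta),
    class = "cat_config"
  )
}

#' Select the starting item of a CAT
#'
#' The item with the highest Fisher information at `start_theta` (the
#' population average by default); ties break toward the lowest item
#' index.
#'
#' @param bank an `item_bank`.
#' @param start_theta trait value, default 0.
#' @return integer index into the bank.
#' @export
select_start_item <- function(bank, start_theta = 0) {
  stopifnot(inherits(bank, "item_bank"), n_items(bank) >= 1)
  info <- vapply(seq_len(n_items(bank)), function(i) {
    item_information(bank$slope[i], bank$thresholds[[i]], start_theta)
  }, numeric(1))
  which.max(info)                           # which.max takes the first tie
}

#' Replay one person's responses through a simulated CAT
#'
#' Post-hoc simulation: the person's full recorded response vector is
#' replayed, items being selected by maximum information at the current
#' trait estimate. After each response the trait is re-estimated; while
#' the administered pattern is all-extreme the ML estimate is pinned at
#' the relevant bound so information-based selection can proceed. Stopping
#' is checked after each response: SE on the T metric at or below
#' `se_stop` (once `min_items` is reached), `max_items` administered,
#' `fixed_length` reached, or the bank exhausted.
#'
#' @param responses integer category vector, one response per bank item
#'   (replay requires completeness).
#' @param bank an `item_bank`.
#' @param config a `cat_config`.
#' @return list of class `cat_trace`: `administered` (item indices in
#'   order), `interim_theta`, `interim_se`, `theta`, `se`, `clamped`,
#'   `n_items`, `stop_reason` (one of `se_met`, `max_items`,
#'   `fixed_length`, `bank_exhausted`).
#' @export
run_cat <- function(responses, bank, config = cat_config()) {
  stopifnot(inherits(bank, "item_bank"), inherits(config, "cat_config"))
  p <- n_items(bank)
  if (length(responses) != p || anyNA(responses)) {
    stop("post-hoc replay requires a complete response to every bank item")
  }
  target_len <- if (!is.null(config$fixed_length)) {
    min(config$fixed_length, p)
  } else {
    min(config$max_items, p)
  }
  administered <- integer(0)
  interim_theta <- numeric(0)
  interim_se <- numeric(0)
  theta <- config$start_theta
  repeat {
    remaining <- setdiff(seq_len(p), administered)
    info <- vapply(remaining, function(i) {
      item_information(bank$slope[i], bank$thresholds[[i]], theta)
    }, numeric(1))
    nxt <- remaining[which.max(info)]
    administered <- c(administered, nxt)

    pattern <- rep(NA_integer_, p)
    pattern[administered] <- responses[administered]
    est <- score_theta(pattern, bank, estimator = config$estimator,
                       bounds = config$theta_bounds)
    theta <- est$theta
    interim_theta <- c(interim_theta, est$theta)
    interim_se <- c(interim_se, est$se)

    n_adm <- length(administered)
    stop_reason <- NULL
    if (!is.null(config$fixed_length)) {
      if (n_adm >= target_len) {
        stop_reason <- if (target_len < config$fixed_length) {
          "bank_exhausted"
        } else "fixed_length"
      }
    } else if (!est$clamped && est$se * 10 <= config$se_stop &&
               n_adm >= config$min_items) {
      stop_reason <- "se_met"
    } else if (n_adm >= config$max_items) {
      stop_reason <- "max_items"
    } else if (n_adm >= p) {
      stop_reason <- "bank_exhausted"
    }
    if (!is.null(stop_reason)) break
  }
  structure(
    list(administered = administered, interim_theta = interim_theta,
         interim_se = interim_se, theta = est$theta, se = est$se,
         clamped = est$clamped, n_items = length(administered),
         stop_reason = stop_reason),
    class = "cat_trace"
  )
}

#' @export
print.cat_trace <- function(x, ...) {
  cat(sprintf("<cat_trace> %d items, theta %.3f (SE %.3f), stop: %s\n",
              x$n_items, x$theta, x$se, x$stop_reason))
  invisible(x)
}

#' Simulate a CAT for every person in a cohort
#'
#' Replays [run_cat()] over the rows of a complete response matrix and
#' summarizes the cohort: the fraction of persons reaching final
#' reliability of at least 0.90, mean / range of items used, the
#' distribution of administered lengths, and the count of persons with
#' clamped (all-extreme) trait estimates, reported separately.
#'
#' @param rm a complete `response_matrix` covering all bank items.
#' @param bank an `item_bank`.
#' @param config a `cat_config`.
#' @return list of class `cat_cohort` with `traces`, `results` (per-person
#'   data.frame: theta, se, t_score, reliability, n_items, clamped,
#'   stop_reason) and `summary`.
#' @export
simulate_cat_cohort <- function(rm, bank, config = cat_config()) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "simulate_cat_cohort")
  idx <- match(rm$item_ids, bank$item_id)
  if (anyNA(idx)) stop("response matrix contains items not in the bank")
  bank <- bank[idx]
  n <- nrow(rm$responses)
  traces <- vector("list", n)
  for (j in seq_len(n)) {
    traces[[j]] <- run_cat(rm$responses[j, ], bank, config)
  }
  results <- data.frame(
    person_id = rm$person_ids,
    theta = vapply(traces, `[[`, numeric(1), "theta"),
    se = vapply(traces, `[[`, numeric(1), "se"),
    n_items = vapply(traces, `[[`, integer(1), "n_items"),
    clamped = vapply(traces, `[[`, logical(1), "clamped"),
    stop_reason = vapply(traces, `[[`, character(1), "stop_reason"),
    stringsAsFactors = FALSE
  )
  results$t_score <- t_score(results$theta)
  results$reliability <- reliability_from_se(results$se)
  ok <- !results$clamped
  summary <- list(
    n_persons = n,
    n_clamped = sum(results$clamped),
    pct_clamped = 100 * mean(results$clamped),
    pct_reliable_0.90 = 100 * mean(results$reliability[ok] >= 0.90),
    mean_items = mean(results$n_items),
    min_items = min(results$n_items),
    max_items = max(results$n_items),
    item_length_distribution = as.list(table(results$n_items))
  )
  structure(list(traces = traces, results = results, summary = summary),
            class = "cat_cohort")
}

#' @export
print.cat_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cat_cohort> %d persons: mean %.1f items (range %d-%d), %.1f%% with reliability >= 0.90 (%d clamped excluded)\n",
    s$n_persons, s$mean_items, s$min_items, s$max_items,
    s$pct_reliable_0.90, s$n_clamped
  ))
  invisible(x)
}

#' Evaluate a fixed short form non-adaptively
#'
#' Scores every person on a fixed item subset (a short form) with the
#' given estimator and reports the same reliability summary as the CAT
#' simulation, for side-by-side comparison.
#'
#' @param rm a complete `response_matrix`.
#' @param bank an `item_bank`.
#' @param items item ids or indices forming the short form.
#' @param estimator passed to [score_theta()].
#' @return list with `results` (per-person data.frame) and `summary`.
#' @export
evaluate_short_form <- function(rm, bank, items, estimator = "ML") {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "evaluate_short_form")
  if (is.character(items)) items <- match(items, rm$item_ids)
  if (anyNA(items)) stop("unknown short-form item")
  sub <- rm
  sub$responses <- rm$responses[, items, drop = FALSE]
  sub$item_ids <- rm$item_ids[items]
  sub$n_categories <- rm$n_categories[items]
  res <- score_cohort(sub, bank, estimator = estimator)
  ok <- !res$clamped
  list(
    results = res,
    summary = list(
      n_items = length(items),
      n_clamped = sum(res$clamped),
      pct_reliable_0.90 = 100 * mean(res$reliability[ok] >= 0.90)
    )
  )
}
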