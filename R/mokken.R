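#' Loevinger scalability coefficients for polytomous items
#'
#' `H_ij` is the ratio of the observed inter-item covariance to its maximum
#' attainable value given the two observed marginals — the covariance of
#' the comonotonic coupling, obtained by pairing the two sorted response
#' vectors. Item and scale coefficients pool numerators and denominators:
#' `H_i = sum_j cov_ij / sum_j covmax_ij`,
#' `H = sum_{i<j} cov_ij / sum_{i<j} covmax_ij`.
#' Conventional benchmarks: every `H_i >= 0.30` and `H >= 0.50` for a
#' strong Mokken scale supporting monotone item response functions.
#'
#' @param rm a `response_matrix` with complete cases and >= 2 items.
#' @return list of class `scalability_result` with `H_pairs` (matrix, `NA`
#'   diagonal), `H_items`, `H_scale`.
#' @export
scalability <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "scalability")
  X <- rm$responses
  p <- ncol(X)
  if (p < 2) stop("scalability needs >= 2 items")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance item(s): ",
         paste(rm$item_ids[v == 0], collapse = ", "))
  }
  covs <- stats::cov(X)
  Xs <- apply(X, 2, sort)                   # comonotonic coupling
  covmax <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      covmax[i, j] <- covmax[j, i] <- stats::cov(Xs[, i], Xs[, j])
    }
  }
  H_pairs <- covs / covmax
  diag(H_pairs) <- NA_real_
  dimnames(H_pairs) <- list(rm$item_ids, rm$item_ids)
  num_i <- rowSums(covs) - diag(covs)
  den_i <- rowSums(covmax, na.rm = TRUE)
  H_items <- stats::setNames(num_i / den_i, rm$item_ids)
  off <- upper.tri(covs)
  H_scale <- sum(covs[off]) / sum(covmax[off])
  structure(
    list(H_pairs = H_pairs, H_items = H_items, H_scale = H_scale),
    class = "scalability_result"
  )
}

#' @export
print.scalability_result <- function(x, ...) {
  cat(sprintf("<scalability_result> H = %.3f, item H in [%.3f, %.3f]\n",
              x$H_scale, min(x$H_items), max(x$H_items)))
  invisible(x)
}

# group persons by rest score into ordered groups of >= minsize, with
# boundaries only at distinct rest-score values (equal rest scores share a
# group); a too-small trailing group is merged into its predecessor.
restscore_groups <- function(rest, minsize) {
  vals <- sort(unique(rest))
  counts <- as.integer(table(factor(rest, levels = vals)))
  group_of_val <- integer(length(vals))
  g <- 1L
  acc <- 0L
  for (k in seq_along(vals)) {
    group_of_val[k] <- g
    acc <- acc + counts[k]
    if (acc >= minsize && k < length(vals)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  if (acc > 0L && acc < minsize && g > 1L) {
    group_of_val[group_of_val == g] <- g - 1L
  }
  group_of_val[match(rest, vals)]
}

#' Monotonicity check of item-step response functions
#'
#' Persons are grouped by rest score (total score minus the item) into
#' ordered groups of at least `minsize`; per item step `k` the probability
#' `P(X_i >= k | group)` is estimated within each group. Under a monotone
#' item response function these step probabilities are non-decreasing in
#' the rest score; a decrease between adjacent groups larger than
#' `tolerance` counts as a violation.
#'
#' @param rm a `response_matrix` with complete cases.
#' @param minsize minimum rest-score group size; default
#'   `max(floor(n/10), 50)`.
#' @param tolerance size a decrease must exceed to count, default 0.03
#'   (guards against small-sample noise).
#' @return list of class `monotonicity_result` with `violations`
#'   (data.frame: item_id, n_violations, max_violation), `curves` (long
#'   data.frame of step probabilities per rest-score group, exportable for
#'   visual inspection), `minsize`, `tolerance`.
#' @export
monotonicity_check <- function(rm, minsize = NULL, tolerance = 0.03) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "monotonicity_check")
  X <- rm$responses
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(minsize)) minsize <- max(floor(n / 10), 50L)
  if (n < 2 * minsize) {
    stop(sprintf(
      "only %d persons for minsize %d (need >= 2 groups); use a smaller minsize",
      n, minsize
    ))
  }
  total <- rowSums(X)
  viol <- data.frame(item_id = rm$item_ids,
                     n_violations = 0L,
                     max_violation = 0,
                     stringsAsFactors = FALSE)
  curves <- list()
  for (i in seq_len(p)) {
    rest <- total - X[, i]
    grp <- restscore_groups(rest, minsize)
    ng <- max(grp)
    m <- rm$n_categories[i]
    for (k in 2:m) {
      step <- as.numeric(X[, i] >= k)
      pk <- tapply(step, grp, mean)
      rest_mean <- tapply(rest, grp, mean)
      nk <- tapply(step, grp, length)
      curves[[length(curves) + 1L]] <- data.frame(
        item_id = rm$item_ids[i], step = k,
        group = seq_len(ng), n = as.integer(nk),
        mean_rest = as.numeric(rest_mean),
        prob = as.numeric(pk),
        stringsAsFactors = FALSE
      )
      if (ng > 1) {
        dec <- -diff(as.numeric(pk))
        bad <- dec > tolerance
        viol$n_violations[i] <- viol$n_violations[i] + sum(bad)
        if (any(bad)) {
          viol$max_violation[i] <- max(viol$max_violation[i], max(dec[bad]))
        }
      }
    }
  }
  structure(
    list(violations = viol, curves = do.call(rbind, curves),
         minsize = minsize, tolerance = tolerance),
    class = "monotonicity_result"
  )
}
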