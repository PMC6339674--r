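#' Summed-score distribution of a set of graded items
#'
#' Generalized Lord-Wingersky recursion: at a given trait value the
#' per-item category-score distributions (category `k` contributes
#' `k - 1` score points) are convolved into the distribution of the summed
#' score. Probabilities are conserved to machine precision.
#'
#' @param bank an `item_bank` (or subset).
#' @param theta numeric vector of trait values.
#' @return matrix `length(theta) x (max_score + 1)`; column `s + 1` holds
#'   `P(S = s | theta)` for summed score `s` in `0..sum(m_i - 1)`. For a
#'   single `theta` value, a plain named vector.
#' @export
summed_score_distribution <- function(bank, theta) {
  stopifnot(inherits(bank, "item_bank"), n_items(bank) >= 1)
  Q <- length(theta)
  L <- matrix(1, Q, 1)
  for (i in seq_len(n_items(bank))) {
    p <- prob_categories(bank$slope[i], bank$thresholds[[i]], theta)
    m <- ncol(p)
    S_old <- ncol(L)
    L_new <- matrix(0, Q, S_old + m - 1L)
    for (k in seq_len(m)) {
      cols <- seq_len(S_old) + (k - 1L)
      L_new[, cols] <- L_new[, cols] + L * p[, k]
    }
    L <- L_new
  }
  colnames(L) <- as.character(seq_len(ncol(L)) - 1L)
  if (Q == 1L) L[1, ] else L
}

# collapse adjacent category cells within one row (toward the nearer
# category tail, ties toward the lower category) until all cells reach the
# floor or only one cell remains; returns the cell values and group sizes
collapse_cells <- function(o, e, floor) {
  repeat {
    k <- length(e)
    if (k <= 1L || all(e >= floor)) break
    bad <- which(e < floor)
    dist_tail <- pmin(bad - 1L, k - bad)
    r <- bad[order(dist_tail, bad)][1]
    into <- if (r == 1L) 2L
            else if (r == k) k - 1L
            else if (r - 1L <= k - r) r - 1L else r + 1L
    o[into] <- o[into] + o[r]
    e[into] <- e[into] + e[r]
    o <- o[-r]
    e <- e[-r]
  }
  list(o = o, e = e)
}

# two-level collapsing of the (rest score x category) tables: adjacent
# score rows are merged (toward the nearer distribution tail, ties toward
# lower scores) while a row's total expected count is below m * floor;
# then, within each surviving row, adjacent category cells below the floor
# are merged. A row irreducible to >= 2 valid cells merges into its
# neighbour. Returns per-row collapsed cells and the independent-cell
# count sum(K_s - 1).
collapse_table <- function(O, E, floor = 1) {
  repeat {
    n_rows <- nrow(E)
    if (n_rows <= 1L) break
    tot <- rowSums(E)
    bad <- which(tot < ncol(E) * floor)
    if (!length(bad)) break
    dist_tail <- pmin(bad - 1L, n_rows - bad)
    r <- bad[order(dist_tail, bad)][1]
    into <- if (r == 1L) 2L
            else if (r == n_rows) n_rows - 1L
            else if (r - 1L <= n_rows - r) r - 1L else r + 1L
    O[into, ] <- O[into, ] + O[r, ]
    E[into, ] <- E[into, ] + E[r, ]
    O <- O[-r, , drop = FALSE]
    E <- E[-r, , drop = FALSE]
  }
  repeat {
    rows <- lapply(seq_len(nrow(E)), function(r) {
      collapse_cells(O[r, ], E[r, ], floor)
    })
    short <- which(vapply(rows, function(x) length(x$e) < 2L ||
                            any(x$e < floor), TRUE))
    if (!length(short) || nrow(E) <= 1L) break
    r <- short[1]
    n_rows <- nrow(E)
    into <- if (r == 1L) 2L
            else if (r == n_rows) n_rows - 1L
            else if (r - 1L <= n_rows - r) r - 1L else r + 1L
    O[into, ] <- O[into, ] + O[r, ]
    E[into, ] <- E[into, ] + E[r, ]
    O <- O[-r, , drop = FALSE]
    E <- E[-r, , drop = FALSE]
  }
  ok <- vapply(rows, function(x) length(x$e) >= 2L && all(x$e >= floor), TRUE)
  rows <- rows[ok]
  list(rows = rows,
       n_cells = sum(vapply(rows, function(x) length(x$e) - 1L, integer(1))),
       n_rows = length(rows))
}

#' Orlando-Thissen S-X2 item fit for polytomous items
#'
#' For each item, persons are cross-classified by rest score (summed score
#' over all other items) and response category; observed counts are
#' compared with the counts expected under the fitted graded response
#' model, `E_sk = N_s * E[P_ik(theta) | S_minus_i = s]`, the conditional
#' expectation taken over the standard-normal trait via quadrature and the
#' Lord-Wingersky rest-score distribution. Sparse cells are collapsed in
#' two passes, merging always toward the nearer distribution tail with
#' ties toward lower scores/categories: adjacent rest-score rows first,
#' then adjacent category cells within a row, until every remaining cell's
#' expected count is at least `min_expected`. The statistic
#' `X2 = sum (O - E)^2 / E` is referred to a chi-square distribution with
#' `df = sum_s (K_s - 1) - m`, the independent cells after collapsing
#' minus the item's free parameters (one slope and `m - 1` thresholds) —
#' the subtraction presumes the bank was estimated from this same sample.
#'
#' @param rm the `response_matrix` the model was fitted to (complete cases).
#' @param fitted a `grm_fit` or an `item_bank` taken as the fitted model.
#' @param alpha flagging level on the p-value, default 0.001.
#' @param min_expected cell-collapsing floor, default 1.
#' @param n_quad,quad_range quadrature grid.
#' @return data.frame of class `itemfit_result`: `item_id`, `s_x2`, `df`,
#'   `p_value`, `n_collapsed_cells`, `flagged` (p < alpha), `testable`
#'   (`FALSE` when collapsing leaves df <= 0; such items are never flagged).
#' @export
s_x2 <- function(rm, fitted, alpha = 0.001, min_expected = 1,
                 n_quad = 49L, quad_range = c(-6, 6)) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "s_x2")
  bank <- if (inherits(fitted, "grm_fit")) fitted$bank else fitted
  stopifnot(inherits(bank, "item_bank"))
  idx <- match(rm$item_ids, bank$item_id)
  if (anyNA(idx)) stop("response matrix contains items not in the fitted bank")
  bank <- bank[idx]
  X <- rm$responses
  n <- nrow(X)
  p <- ncol(X)
  if (p < 2) stop("S-X2 needs >= 2 items")
  quad <- grm_quadrature(n_quad, quad_range)

  out <- data.frame(
    item_id = rm$item_ids, s_x2 = NA_real_, df = NA_integer_,
    p_value = NA_real_, n_collapsed_cells = NA_integer_,
    flagged = FALSE, testable = TRUE, stringsAsFactors = FALSE
  )
  score0 <- sweep(X, 2, 1L)                 # 0-based category scores
  total0 <- rowSums(score0)
  for (i in seq_len(p)) {
    m <- bank$n_categories[i]
    rest <- total0 - score0[, i]
    max_rest <- sum(bank$n_categories[-i] - 1L)
    scores <- 0:max_rest

    R <- summed_score_distribution(bank[-i], quad$nodes)   # Q x (max_rest+1)
    P_i <- prob_categories(bank$slope[i], bank$thresholds[[i]], quad$nodes)
    wR <- quad$weights * R                  # recycles by column
    den <- colSums(wR)                      # P(S_-i = s) under the prior
    num <- t(wR) %*% P_i                    # (max_rest+1) x m
    cond <- num / pmax(den, 1e-300)         # E[P_ik | S_-i = s]

    N_s <- tabulate(rest + 1L, nbins = max_rest + 1L)
    O <- matrix(0, max_rest + 1L, m)
    for (k in seq_len(m)) {
      O[, k] <- tabulate(rest[X[, i] == k] + 1L, nbins = max_rest + 1L)
    }
    E <- cond * N_s

    n_cells_before <- length(E)
    cl <- collapse_table(O, E, floor = min_expected)
    n_cells_after <- sum(vapply(cl$rows, function(x) length(x$e), integer(1)))
    out$n_collapsed_cells[i] <- n_cells_before - n_cells_after
    stat <- sum(vapply(cl$rows, function(x) sum((x$o - x$e)^2 / x$e),
                       numeric(1)))
    df <- cl$n_cells - m
    out$s_x2[i] <- stat
    out$df[i] <- df
    if (df >= 1L) {
      out$p_value[i] <- stats::pchisq(stat, df, lower.tail = FALSE)
      out$flagged[i] <- out$p_value[i] < alpha
    } else {
      out$testable[i] <- FALSE
    }
  }
  attr(out, "alpha") <- alpha
  attr(out, "min_expected") <- min_expected
  class(out) <- c("itemfit_result", "data.frame")
  out
}
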