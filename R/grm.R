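#' Category probabilities of the logistic graded response model
#'
#' For an item with slope `a` and thresholds `b_1 < ... < b_{m-1}` the
#' cumulative probability of responding in category `k` or above is
#' `P*_k(theta) = 1 / (1 + exp(-a (theta - b_k)))`, with `P*_0 = 1` and
#' `P*_m = 0`; the probability of category `k` (coded 1..m) is
#' `P_k = P*_{k-1} - P*_k`. The logistic metric carries no `D = 1.7`
#' scaling constant, so slopes are directly comparable to those reported by
#' mainstream GRM software.
#'
#' @param slope positive slope `a`.
#' @param thresholds strictly increasing numeric vector `b` of length `m-1`.
#' @param theta numeric vector of latent-trait values.
#' @return `prob_categories`: a `length(theta) x m` matrix of category
#'   probabilities (rows sum to 1). `item_information`: numeric vector of
#'   Fisher information values, one per `theta`.
#' @examples
#' p <- prob_categories(2, c(-1, 0, 1, 2), theta = 0)
#' rowSums(p) # 1
#' item_information(2, c(-1, 0, 1, 2), theta = c(-2, 0, 2))
#' @export
prob_categories <- function(slope, thresholds, theta) {
  cum <- grm_cumulative(slope, thresholds, theta)
  m <- length(thresholds) + 1L
  full <- cbind(1, cum, 0)
  p <- full[, seq_len(m), drop = FALSE] - full[, seq_len(m) + 1L, drop = FALSE]
  # guard against exact zeros from floating underflow in extreme tails
  pmax(p, 0)
}

grm_cumulative <- function(slope, thresholds, theta) {
  # length(theta) x (m-1) matrix of P*_k(theta)
  eta <- slope * outer(theta, thresholds, "-")
  stats::plogis(eta)
}

#' @rdname prob_categories
#' @export
item_information <- function(slope, thresholds, theta) {
  cum <- grm_cumulative(slope, thresholds, theta)
  w <- cum * (1 - cum)                      # P*(1-P*) per boundary
  wfull <- cbind(0, w, 0)
  m <- length(thresholds) + 1L
  dP <- slope * (wfull[, seq_len(m), drop = FALSE] -
                   wfull[, seq_len(m) + 1L, drop = FALSE])
  p <- prob_categories(slope, thresholds, theta)
  rowSums(dP^2 / pmax(p, 1e-300))
}

#' Test information and standard error of an item bank
#'
#' Fisher information is additive over items; the standard error of the
#' trait estimate is `SE(theta) = 1 / sqrt(I(theta))` and the IRT
#' reliability at that trait level is `1 - SE^2` (population SD 1).
#'
#' @param bank an `item_bank`.
#' @param theta numeric vector of trait values.
#' @param items optional integer/character subset of items to include.
#' @return numeric vector of test information values, one per `theta`.
#' @export
test_information <- function(bank, theta, items = NULL) {
  if (!is.null(items)) bank <- bank[items]
  info <- numeric(length(theta))
  for (i in seq_len(n_items(bank))) {
    info <- info + item_information(bank$slope[i], bank$thresholds[[i]], theta)
  }
  info
}

#' Gauss-type quadrature grid for the standard-normal prior
#'
#' A fixed rectangular grid: `n` equally spaced nodes on `range`, with
#' weights proportional to the standard-normal density, normalized to sum
#' to one. Deterministic and adequate for slopes up to about 5.
#'
#' @param n number of nodes (default 49).
#' @param range interval covered (default `c(-6, 6)`).
#' @param mean,sd prior mean and SD (default standard normal).
#' @return list with `nodes` and `weights`.
#' @export
grm_quadrature <- function(n = 49L, range = c(-6, 6), mean = 0, sd = 1) {
  nodes <- seq(range[1], range[2], length.out = n)
  w <- stats::dnorm(nodes, mean, sd)
  list(nodes = nodes, weights = w / sum(w))
}

# log P(x_ij | theta_q) accumulated over items: n_persons x n_nodes matrix
pattern_loglik_matrix <- function(responses, bank, nodes) {
  n <- nrow(responses)
  ll <- matrix(0, n, length(nodes))
  for (i in seq_len(ncol(responses))) {
    p <- prob_categories(bank$slope[i], bank$thresholds[[i]], nodes)
    logp <- log(pmax(p, 1e-300))           # nodes x m
    ll <- ll + t(logp[, responses[, i], drop = FALSE])
  }
  ll
}

#' Fit a graded response model by marginal maximum likelihood (EM)
#'
#' Item parameters are estimated by an EM algorithm: the E-step computes
#' posterior weights for each person over a fixed quadrature grid under a
#' standard-normal prior; the M-step maximizes the expected complete-data
#' log-likelihood per item over `(log a, b_1, log-increments of b)` — an
#' unconstrained parameterization that enforces positive slopes and
#' strictly ordered thresholds. The marginal log-likelihood is
#' non-decreasing across cycles (asserted internally).
#'
#' @param rm a `response_matrix` with complete cases. Every category of
#'   every item must be observed at least once (unobserved categories are
#'   collapsed into their lower neighbour with a warning; the fitted item
#'   then has fewer categories).
#' @param n_quad,quad_range quadrature grid (default 49 nodes on
#'   \code{[-6, 6]}).
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change per cycle (natural metric), default `1e-4`.
#' @param max_cycles EM cycle cap, default 500.
#' @param verbose print the marginal log-likelihood each cycle.
#' @return An object of class `grm_fit`: list with `bank` (fitted
#'   `item_bank`), `log_likelihood` (marginal, at the solution),
#'   `ll_trace`, `n_cycles`, `converged`, `collapsed` (per-item list of
#'   collapsed category maps, if any), and `quad`.
#' @export
fit_grm <- function(rm, n_quad = 49L, quad_range = c(-6, 6), tol = 1e-4,
                    max_cycles = 500L, verbose = FALSE) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "fit_grm")
  X <- rm$responses
  n <- nrow(X)
  p <- ncol(X)
  if (p < 1 || n < 2) stop("need >= 2 persons and >= 1 item")

  # collapse unobserved categories so every modelled category has data
  collapsed <- vector("list", p)
  m_eff <- integer(p)
  for (i in seq_len(p)) {
    m <- rm$n_categories[i]
    seen <- sort(unique(X[, i]))
    if (length(seen) < 2L) {
      stop(sprintf("item '%s' has a single observed category", rm$item_ids[i]))
    }
    if (length(seen) < m) {
      warning(sprintf(
        "item '%s': categories %s unobserved; collapsed before fitting",
        rm$item_ids[i],
        paste(setdiff(seq_len(m), seen), collapse = ", ")
      ))
      map <- match(X[, i], seen)          # recode to 1..length(seen)
      X[, i] <- map
      collapsed[[i]] <- seen
    }
    m_eff[i] <- length(unique(X[, i]))
  }

  quad <- grm_quadrature(n_quad, quad_range)
  nodes <- quad$nodes
  logw <- log(quad$weights)

  # starting values: slope 1.5, thresholds at inverse-normal marginals
  slopes <- rep(1.5, p)
  thresholds <- vector("list", p)
  for (i in seq_len(p)) {
    m <- m_eff[i]
    cum <- cumsum(tabulate(X[, i], m))[-m] / n
    cum <- pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n))
    b <- stats::qnorm(cum)
    thresholds[[i]] <- enforce_gap(b, 0.01)
  }

  ll_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    bank_now <- item_bank(rm$item_ids, slopes, thresholds)
    ll_mat <- pattern_loglik_matrix(X, bank_now, nodes)
    lj <- sweep(ll_mat, 2, logw, "+")
    mrow <- apply(lj, 1, max)
    lik <- exp(lj - mrow)
    marg <- rowSums(lik)
    ll <- sum(log(marg) + mrow)
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("cycle %3d  logLik %.6f", cycle, ll))
    if (ll < prev_ll - 1e-6) {
      stop(sprintf("EM log-likelihood decreased at cycle %d (%.8f -> %.8f)",
                   cycle, prev_ll, ll))
    }
    post <- lik / marg                     # n x Q posterior weights

    max_delta <- 0
    for (i in seq_len(p)) {
      m <- m_eff[i]
      # expected counts r[q, k]
      r <- matrix(0, length(nodes), m)
      for (k in seq_len(m)) {
        idx <- X[, i] == k
        if (any(idx)) r[, k] <- colSums(post[idx, , drop = FALSE])
      }
      new_par <- mstep_item(slopes[i], thresholds[[i]], r, nodes)
      max_delta <- max(max_delta,
                       abs(new_par$slope - slopes[i]),
                       max(abs(new_par$thresholds - thresholds[[i]])))
      slopes[i] <- new_par$slope
      thresholds[[i]] <- new_par$thresholds
    }
    prev_ll <- ll
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
  }

  # marginal log-likelihood at the final (post-M-step) parameters
  bank_fin <- item_bank(rm$item_ids, slopes, thresholds, rm$reverse_coded)
  lj <- sweep(pattern_loglik_matrix(X, bank_fin, nodes), 2, logw, "+")
  mrow <- apply(lj, 1, max)
  ll_final <- sum(log(rowSums(exp(lj - mrow))) + mrow)
  ll_trace <- c(ll_trace, ll_final)

  structure(
    list(
      bank = bank_fin,
      log_likelihood = ll_final,
      ll_trace = ll_trace,
      n_cycles = cycles,
      converged = converged,
      collapsed = collapsed,
      quad = quad
    ),
    class = "grm_fit"
  )
}

#' Recode a response matrix onto a fitted bank's collapsed categories
#'
#' When [fit_grm()] collapses categories that were never observed, the
#' fitted bank has fewer categories than the raw coding. This helper maps
#' the raw codes onto the fitted bank's contiguous `1..m_eff` coding so
#' the data can be scored and tested against that bank.
#'
#' @param rm the `response_matrix` the model was fitted to.
#' @param fit the `grm_fit`.
#' @return a `response_matrix` aligned with `fit$bank`.
#' @export
collapse_categories <- function(rm, fit) {
  stopifnot(inherits(rm, "response_matrix"), inherits(fit, "grm_fit"))
  out <- rm
  for (i in seq_along(fit$collapsed)) {
    seen <- fit$collapsed[[i]]
    if (is.null(seen)) next
    j <- match(fit$bank$item_id[i], rm$item_ids)
    rec <- match(rm$responses[, j], seen)
    if (anyNA(rec)) stop("responses contain categories the fit never saw")
    out$responses[, j] <- rec
    out$n_categories[j] <- length(seen)
  }
  out
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf(
    "<grm_fit> %d items, logLik %.3f, %d EM cycles, %s\n",
    n_items(x$bank), x$log_likelihood, x$n_cycles,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

enforce_gap <- function(b, gap) {
  for (k in seq_along(b)[-1]) {
    if (b[k] < b[k - 1] + gap) b[k] <- b[k - 1] + gap
  }
  b
}

# one item's M-step: maximize sum_q sum_k r[q,k] log P_k(theta_q)
# over par = (log a, b1, log diff(b)); gradient is analytic.
mstep_item <- function(slope, thresholds, r, nodes) {
  m <- ncol(r)
  par0 <- c(log(slope), thresholds[1],
            if (m > 2) log(diff(thresholds)) else NULL)

  unpack <- function(par) {
    a <- exp(par[1])
    b <- cumsum(c(par[2], if (m > 2) exp(par[-(1:2)]) else NULL))
    list(a = a, b = b)
  }

  negll <- function(par) {
    th <- unpack(par)
    p <- prob_categories(th$a, th$b, nodes)
    -sum(r * log(pmax(p, 1e-300)))
  }

  neggr <- function(par) {
    th <- unpack(par)
    a <- th$a
    b <- th$b
    cum <- grm_cumulative(a, b, nodes)      # Q x (m-1)
    w <- cum * (1 - cum)
    p <- pmax(prob_categories(a, b, nodes), 1e-10)
    s <- r / p                              # Q x m
    # d logLik / d P*_k contribution: P_k = P*_{k-1} - P*_k
    # => dL/dP*_k = s[, k+1] - s[, k]
    dL_dcum <- s[, -1, drop = FALSE] - s[, -m, drop = FALSE]  # Q x (m-1)
    # dP*_k/da = (theta - b_k) w_k ; dP*_k/db_k = -a w_k
    ga <- sum(dL_dcum * w * outer(nodes, b, "-"))
    gb <- -a * colSums(dL_dcum * w)         # length m-1, wrt each b_k
    # chain rule to (log a, b1, log diffs)
    g <- numeric(length(par))
    g[1] <- ga * a
    g[2] <- sum(gb)
    if (m > 2) {
      for (j in 3:length(par)) {
        # par[j] = log(b_{j-1} - b_{j-2}); affects b_k for k >= j-1
        g[j] <- sum(gb[(j - 1):(m - 1)]) * exp(par[j])
      }
    }
    -g
  }

  fit <- tryCatch(
    stats::optim(par0, negll, neggr, method = "BFGS",
                 control = list(maxit = 50, reltol = 1e-10)),
    error = function(e) NULL
  )
  # on optimizer failure, or a worse point, keep the current parameters
  # (the EM step is then a no-op for this item; the likelihood cannot drop)
  if (is.null(fit) || !all(is.finite(fit$par)) ||
      fit$value > negll(par0) + 1e-10) {
    return(list(slope = slope, thresholds = thresholds))
  }
  th <- unpack(fit$par)
  list(slope = th$a, thresholds = th$b)
}

#' Score a person's latent trait from an item bank
#'
#' Estimators: `"ML"` maximizes the response-pattern log-likelihood on the
#' bounded trait range (default \code{[-4, 4]}); an all-lowest or
#' all-highest response pattern has no interior ML maximum and is clamped
#' to the lower/upper bound with `clamped = TRUE`. `"EAP"` is the posterior
#' mean over the quadrature grid under a standard-normal prior (SE =
#' posterior SD); `"MAP"` the posterior mode. ML/MAP standard errors are
#' `1/sqrt(I(theta_hat))` from the test information of the answered items.
#'
#' @param responses integer vector of category codes (1..m), one per bank
#'   item; `NA` entries are skipped (the item is not used).
#' @param bank an `item_bank`.
#' @param estimator one of `"ML"`, `"EAP"`, `"MAP"`.
#' @param bounds trait bounds for ML/MAP, default `c(-4, 4)`.
#' @param prior_mean,prior_sd prior for EAP/MAP.
#' @return list of class `theta_estimate` with fields `theta`, `se`,
#'   `estimator`, `clamped`, `n_items_used`.
#' @export
score_theta <- function(responses, bank, estimator = c("ML", "EAP", "MAP"),
                        bounds = c(-4, 4), prior_mean = 0, prior_sd = 1) {
  estimator <- match.arg(estimator)
  use <- which(!is.na(responses))
  if (!length(use)) stop("cannot score a person with no answered items")
  sub <- bank[use]
  x <- responses[use]
  m <- sub$n_categories
  if (any(x < 1L | x > m)) stop("response code out of category range")

  loglik <- function(theta) {
    out <- numeric(length(theta))
    for (i in seq_along(x)) {
      p <- prob_categories(sub$slope[i], sub$thresholds[[i]], theta)[, x[i]]
      out <- out + log(pmax(p, 1e-300))
    }
    out
  }

  clamped <- FALSE
  if (estimator == "ML") {
    if (all(x == 1L)) {
      theta <- bounds[1]; clamped <- TRUE
    } else if (all(x == m)) {
      theta <- bounds[2]; clamped <- TRUE
    } else {
      opt <- stats::optimize(loglik, interval = bounds, maximum = TRUE,
                             tol = 1e-6)
      theta <- opt$maximum
      # monotone likelihoods push the optimum to a boundary
      if (min(theta - bounds[1], bounds[2] - theta) < 1e-4) {
        edge <- if (loglik(bounds[1]) >= loglik(bounds[2])) bounds[1] else bounds[2]
        if (loglik(edge) >= opt$objective) {
          theta <- edge
          clamped <- TRUE
        }
      }
    }
    info <- test_information(sub, theta)
    se <- 1 / sqrt(max(info, 1e-12))
  } else {
    quad <- grm_quadrature(mean = prior_mean, sd = prior_sd)
    lp <- loglik(quad$nodes) + log(quad$weights)
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    if (estimator == "EAP") {
      theta <- sum(w * quad$nodes)
      se <- sqrt(sum(w * (quad$nodes - theta)^2))
    } else {
      logpost <- function(th) {
        loglik(th) + stats::dnorm(th, prior_mean, prior_sd, log = TRUE)
      }
      opt <- stats::optimize(logpost, interval = bounds, maximum = TRUE,
                             tol = 1e-6)
      theta <- opt$maximum
      info <- test_information(sub, theta) + 1 / prior_sd^2
      se <- 1 / sqrt(info)
    }
  }
  structure(
    list(theta = theta, se = se, estimator = estimator,
         clamped = clamped, n_items_used = length(use)),
    class = "theta_estimate"
  )
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("<theta_estimate> %s theta = %.3f (SE %.3f)%s, %d items\n",
              x$estimator, x$theta, x$se,
              if (x$clamped) " [clamped]" else "", x$n_items_used))
  invisible(x)
}

#' Score every person in a response matrix
#'
#' @param rm a `response_matrix` (complete cases).
#' @param bank an `item_bank` covering the matrix's items.
#' @param estimator passed to [score_theta()].
#' @param ... passed to [score_theta()].
#' @return data.frame with columns `person_id`, `theta`, `se`, `clamped`,
#'   `t_score`, `reliability`.
#' @export
score_cohort <- function(rm, bank, estimator = "ML", ...) {
  stopifnot(inherits(rm, "response_matrix"))
  idx <- match(rm$item_ids, bank$item_id)
  if (anyNA(idx)) stop("response matrix contains items not in the bank")
  bank <- bank[idx]
  n <- nrow(rm$responses)
  theta <- se <- numeric(n)
  clamped <- logical(n)
  for (j in seq_len(n)) {
    est <- score_theta(rm$responses[j, ], bank, estimator = estimator, ...)
    theta[j] <- est$theta
    se[j] <- est$se
    clamped[j] <- est$clamped
  }
  data.frame(
    person_id = rm$person_ids,
    theta = theta,
    se = se,
    clamped = clamped,
    t_score = t_score(theta),
    reliability = reliability_from_se(se),
    stringsAsFactors = FALSE
  )
}
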