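#' Proportional-odds (cumulative logit) model fit
#'
#' Thin wrapper used by the DIF screen: fits `y ~ X` as an ordinal
#' logistic regression (proportional odds) via [MASS::polr()] and returns
#' the maximized log-likelihood plus McFadden's pseudo-R2 against the
#' intercept-only null (whose log-likelihood is the closed-form multinomial
#' `sum n_k log(n_k / n)`). When `polr` fails to converge (e.g. complete
#' separation) a ridge-stabilized direct maximization is used instead, with
#' a warning.
#'
#' @param y integer or factor ordinal response with >= 2 observed levels.
#' @param X numeric matrix / data.frame of predictors, or `NULL` for the
#'   intercept-only model.
#' @param start optional start values `c(beta, zeta)` (a nested model's
#'   solution, padded with zeros, guarantees monotone nesting of
#'   log-likelihoods).
#' @return list with `log_lik`, `null_log_lik`, `mcfadden_r2`,
#'   `coefficients`, `zeta` (ordered intercepts), `method`.
#' @export
cumulative_logit_fit <- function(y, X = NULL, start = NULL) {
  yf <- factor(y)
  if (nlevels(yf) < 2) stop("y must have >= 2 observed categories")
  n <- length(yf)
  counts <- table(yf)
  ll_null <- sum(counts * log(counts / n))
  if (is.null(X) || NCOL(X) == 0) {
    return(list(log_lik = ll_null, null_log_lik = ll_null, mcfadden_r2 = 0,
                coefficients = numeric(0),
                zeta = stats::qlogis(cumsum(counts / n)[-nlevels(yf)]),
                method = "closed_form"))
  }
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("predictors must be finite")
  K <- nlevels(yf)
  zeta0 <- stats::qlogis(pmin(pmax(cumsum(counts / n)[-K], 1e-4), 1 - 1e-4))
  if (is.null(start)) start <- c(rep(0, ncol(X)), zeta0)
  df <- data.frame(.y = yf, X)
  fit <- tryCatch(
    MASS::polr(.y ~ ., data = df, method = "logistic", start = start,
               control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit)) {
    ll <- as.numeric(stats::logLik(fit))
    res <- list(log_lik = ll, coefficients = stats::coef(fit),
                zeta = fit$zeta, method = "polr")
  } else {
    warning("polr failed; using ridge-stabilized direct maximization")
    res <- po_direct_fit(yf, X, start, ridge = 1e-4)
  }
  res$null_log_lik <- ll_null
  res$mcfadden_r2 <- 1 - res$log_lik / ll_null
  res
}

# direct proportional-odds likelihood maximization with ordered intercepts
# (first intercept + log increments) and an L2 ridge on the slopes
po_direct_fit <- function(yf, X, start, ridge = 1e-4) {
  K <- nlevels(yf)
  yi <- as.integer(yf)
  nb <- ncol(X)
  to_par <- function(beta, zeta) {
    c(beta, zeta[1], if (K > 2) log(pmax(diff(zeta), 1e-6)) else NULL)
  }
  from_par <- function(par) {
    beta <- par[seq_len(nb)]
    zeta <- cumsum(c(par[nb + 1],
                     if (K > 2) exp(par[-(seq_len(nb + 1))]) else NULL))
    list(beta = beta, zeta = zeta)
  }
  negll <- function(par) {
    th <- from_par(par)
    eta <- drop(X %*% th$beta)
    cum <- cbind(0, stats::plogis(outer(-eta, th$zeta, "+")), 1)
    p <- cum[cbind(seq_along(yi), yi + 1L)] - cum[cbind(seq_along(yi), yi)]
    -sum(log(pmax(p, 1e-300))) + ridge * sum(th$beta^2)
  }
  par0 <- to_par(start[seq_len(nb)], start[-seq_len(nb)])
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- from_par(opt$par)
  eta <- drop(X %*% th$beta)
  cum <- cbind(0, stats::plogis(outer(-eta, th$zeta, "+")), 1)
  p <- cum[cbind(seq_along(yi), yi + 1L)] - cum[cbind(seq_along(yi), yi)]
  list(log_lik = sum(log(pmax(p, 1e-300))), coefficients = th$beta,
       zeta = th$zeta, method = "ridge_direct")
}

# encode a grouping for the regression: ordinal groupings become one
# numeric column, nominal ones a reference-vs-level dummy block
group_design <- function(g, ordinal = FALSE) {
  gf <- factor(g)
  if (ordinal || nlevels(gf) == 2) {
    matrix(as.numeric(as.integer(gf)), ncol = 1,
           dimnames = list(NULL, "group"))
  } else {
    mm <- stats::model.matrix(~ gf)[, -1, drop = FALSE]
    colnames(mm) <- paste0("group_", levels(gf)[-1])
    mm
  }
}

#' Screen an item bank for differential item functioning
#'
#' Per item, three nested proportional-odds models are fitted:
#' M1 `y ~ theta`, M2 `y ~ theta + group`, M3
#' `y ~ theta + group + theta:group`. The effect-size criterion is
#' McFadden's pseudo-R2 change: an item is flagged when
#' `R2(M3) - R2(M1) >= threshold` (default 0.02); the flag is classified
#' uniform (the group main effect carries the change), non-uniform (the
#' interaction does), or mixed. No multiple-testing correction is applied —
#' the R2 change is an effect size, not a test. With `purify = TRUE` the
#' trait is re-scored (EAP) from the currently unflagged items and the
#' screen repeats until the flag set is stable (at most `max_iter` times).
#'
#' @param rm a `response_matrix` with complete cases.
#' @param group grouping: the name of a covariate column, or a vector with
#'   one level per person. Needs >= 2 levels with at least
#'   `min_group_size` persons each.
#' @param thetas numeric trait scores per person; default EAP scores from
#'   `bank` (stable for all-extreme response patterns).
#' @param bank `item_bank`; required when `thetas` is missing or
#'   `purify = TRUE`.
#' @param ordinal treat a multi-level grouping as ordinal (single numeric
#'   code, e.g. education low/middle/high) instead of a dummy block.
#' @param threshold flagging threshold on the total R2 change, default 0.02.
#' @param purify iteratively re-score the trait from unflagged items.
#' @param min_group_size per-level floor, default 50.
#' @param max_iter purification cap, default 10.
#' @return data.frame of class `dif_result` with per-item columns `r2_m1`,
#'   `r2_m2`, `r2_m3`, `delta_total`, `delta_uniform`, `delta_nonuniform`,
#'   `flagged`, `classification`; attribute `purification_iterations`.
#' @export
dif_screen <- function(rm, group, thetas = NULL, bank = NULL,
                       ordinal = FALSE, threshold = 0.02, purify = FALSE,
                       min_group_size = 50L, max_iter = 10L) {
  stopifnot(inherits(rm, "response_matrix"))
  require_complete(rm, "dif_screen")
  if (is.character(group) && length(group) == 1) {
    if (is.null(rm$covariates) || !group %in% names(rm$covariates)) {
      stop("no covariate column named '", group, "'")
    }
    if (identical(group, "education")) ordinal <- TRUE
    g <- rm$covariates[[group]]
    if (identical(group, "education")) {
      lv <- intersect(c("low", "middle", "high"), unique(g))
      if (length(lv) == length(unique(g))) g <- factor(g, levels = lv)
    }
  } else {
    g <- group
  }
  g <- factor(g)
  if (nlevels(g) < 2) stop("grouping must have >= 2 levels")
  sizes <- table(g)
  if (any(sizes < min_group_size)) {
    stop("group level(s) below the size floor (", min_group_size, "): ",
         paste(names(sizes)[sizes < min_group_size], collapse = ", "))
  }
  if (is.null(thetas)) {
    if (is.null(bank)) stop("supply thetas or a bank to score them from")
    thetas <- score_cohort(rm, bank, estimator = "EAP")$theta
  }
  if (purify && is.null(bank)) stop("purify = TRUE requires a bank")

  G <- group_design(g, ordinal = ordinal)
  p <- ncol(rm$responses)
  flagged_prev <- rep(FALSE, p)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    res <- dif_pass(rm, thetas, G, threshold)
    if (!purify || identical(res$flagged, flagged_prev) ||
        iterations >= max_iter) break
    flagged_prev <- res$flagged
    keep <- which(!res$flagged)
    if (!length(keep)) break
    sub <- rm
    sub$responses <- rm$responses[, keep, drop = FALSE]
    sub$item_ids <- rm$item_ids[keep]
    sub$n_categories <- rm$n_categories[keep]
    thetas <- score_cohort(sub, bank, estimator = "EAP")$theta
  }
  attr(res, "purification_iterations") <- iterations
  attr(res, "threshold") <- threshold
  class(res) <- c("dif_result", "data.frame")
  res
}

dif_pass <- function(rm, thetas, G, threshold) {
  p <- ncol(rm$responses)
  out <- data.frame(
    item_id = rm$item_ids,
    r2_m1 = NA_real_, r2_m2 = NA_real_, r2_m3 = NA_real_,
    delta_total = NA_real_, delta_uniform = NA_real_,
    delta_nonuniform = NA_real_,
    flagged = FALSE, classification = "none",
    stringsAsFactors = FALSE
  )
  inter <- G * thetas
  colnames(inter) <- paste0(colnames(G), "_x_theta")
  for (i in seq_len(p)) {
    y <- rm$responses[, i]
    X1 <- cbind(theta = thetas)
    m1 <- cumulative_logit_fit(y, X1)
    X2 <- cbind(X1, G)
    m2 <- cumulative_logit_fit(y, X2,
                               start = c(m1$coefficients, rep(0, ncol(G)),
                                         m1$zeta))
    X3 <- cbind(X2, inter)
    m3 <- cumulative_logit_fit(y, X3,
                               start = c(m2$coefficients, rep(0, ncol(inter)),
                                         m2$zeta))
    out$r2_m1[i] <- m1$mcfadden_r2
    out$r2_m2[i] <- m2$mcfadden_r2
    out$r2_m3[i] <- m3$mcfadden_r2
    out$delta_total[i] <- m3$mcfadden_r2 - m1$mcfadden_r2
    out$delta_uniform[i] <- m2$mcfadden_r2 - m1$mcfadden_r2
    out$delta_nonuniform[i] <- m3$mcfadden_r2 - m2$mcfadden_r2
    if (out$delta_total[i] >= threshold) {
      out$flagged[i] <- TRUE
      u <- out$delta_uniform[i] >= threshold
      nu <- out$delta_nonuniform[i] >= threshold
      out$classification[i] <-
        if (u && nu) "mixed" else if (nu) "non-uniform" else "uniform"
    }
  }
  out
}

#' Median split of age into two groups
#'
#' The split rule is `<= median` versus `> median`, the median computed on
#' the analysis sample itself.
#'
#' @param age numeric ages in years.
#' @return factor with levels `le_median`, `gt_median`; the split value is
#'   stored in `attr(, "median")`.
#' @export
age_median_split <- function(age) {
  if (!length(age) || any(is.na(age))) stop("ages must be present for all persons")
  med <- stats::median(age)
  out <- factor(ifelse(age <= med, "le_median", "gt_median"),
                levels = c("le_median", "gt_median"))
  attr(out, "median") <- med
  out
}
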