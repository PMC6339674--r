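#' Specify a synthetic cohort simulation
#'
#' The generator emulates a general-population Likert survey: latent traits
#' `theta ~ Normal(theta_mean, theta_sd^2)`, graded responses drawn from a
#' logistic GRM, demographic labels drawn to fixed population proportions,
#' an optional target fraction of all-extreme response patterns (ceiling /
#' floor effects), and optional injected DIF. The defaults mirror a
#' high-discrimination participation item bank: 35 five-category items,
#' slopes uniform in \code{[2.4, 4.8]}, thresholds in \code{[-2.5, 0.6]}.
#'
#' @param n_persons cohort size.
#' @param n_items,n_categories bank dimensions (used when no explicit bank
#'   is supplied to [simulate_responses()]).
#' @param slope_range length-2 positive range for uniform slope draws.
#' @param threshold_range length-2 range for threshold draws; per item the
#'   `m - 1` draws are sorted and separated by a minimum gap of 0.05 so no
#'   category is near-degenerate.
#' @param theta_mean,theta_sd latent-trait distribution (default standard
#'   normal, the reference-population scaling).
#' @param dif_spec optional list of DIF injections, each a list with fields
#'   `item` (id or index), `group_variable`, `focal_level`,
#'   `uniform_shift` (theta units, added to all thresholds for the focal
#'   group) and `slope_multiplier` (non-uniform DIF).
#' @param extreme_target optional fraction in `[0, 1)`: the generating
#'   theta mean is shifted (by bisection on the model-implied expectation)
#'   until the expected fraction of all-extreme patterns matches this
#'   target within 0.005.
#' @param seed integer seed; all draws are reproducible under it.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n_persons = 1000L, n_items = 35L,
                              n_categories = 5L,
                              slope_range = c(2.4, 4.8),
                              threshold_range = c(-2.5, 0.6),
                              theta_mean = 0, theta_sd = 1,
                              dif_spec = NULL, extreme_target = NULL,
                              seed = 1L) {
  stopifnot(n_persons >= 1, n_items >= 1, n_categories >= 2)
  if (length(slope_range) != 2 || any(slope_range <= 0) ||
      slope_range[1] > slope_range[2]) {
    stop("slope_range must be an ordered positive interval")
  }
  if (length(threshold_range) != 2 || threshold_range[1] > threshold_range[2]) {
    stop("threshold_range must be ordered")
  }
  if (!is.null(extreme_target) &&
      (extreme_target < 0 || extreme_target >= 1)) {
    stop("extreme_target must be in [0, 1)")
  }
  structure(
    list(n_persons = as.integer(n_persons), n_items = as.integer(n_items),
         n_categories = as.integer(n_categories),
         slope_range = slope_range, threshold_range = threshold_range,
         theta_mean = theta_mean, theta_sd = theta_sd,
         dif_spec = dif_spec, extreme_target = extreme_target,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Draw a random item bank from a simulation design
#'
#' Slopes are uniform in `slope_range`; per item, `m - 1` thresholds are
#' drawn uniformly in `threshold_range`, sorted, and pushed apart to a
#' minimum gap of 0.05.
#'
#' @param design a `simulation_design` with range-based bank spec.
#' @return an `item_bank` with `design$n_items` items named `item01..`.
#' @export
sample_bank <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  withr_seed(design$seed, {
    p <- design$n_items
    m <- design$n_categories
    slopes <- stats::runif(p, design$slope_range[1], design$slope_range[2])
    thresholds <- lapply(seq_len(p), function(i) {
      b <- sort(stats::runif(m - 1, design$threshold_range[1],
                             design$threshold_range[2]))
      enforce_gap(b, 0.05)
    })
    item_bank(sprintf("item%02d", seq_len(p)), slopes, thresholds)
  })
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Expected fraction of all-extreme response patterns
#'
#' Integrates, over a normal trait distribution, the probability that a
#' respondent answers the lowest category on every item plus the
#' probability of the highest category on every item.
#'
#' @param bank an `item_bank`.
#' @param theta_mean,theta_sd trait distribution.
#' @return scalar expected fraction.
#' @export
expected_extreme_fraction <- function(bank, theta_mean = 0, theta_sd = 1) {
  quad <- grm_quadrature(n = 201, range = theta_mean + c(-8, 8) * theta_sd,
                         mean = theta_mean, sd = theta_sd)
  p_lo <- rep(1, length(quad$nodes))
  p_hi <- rep(1, length(quad$nodes))
  for (i in seq_len(n_items(bank))) {
    pr <- prob_categories(bank$slope[i], bank$thresholds[[i]], quad$nodes)
    p_lo <- p_lo * pr[, 1]
    p_hi <- p_hi * pr[, ncol(pr)]
  }
  sum(quad$weights * (p_lo + p_hi))
}

calibrate_theta_mean <- function(bank, target, theta_sd, tol = 0.005) {
  g <- function(mu) expected_extreme_fraction(bank, mu, theta_sd)
  # g(mu) -> 1 at both extremes (all-floor on the left, all-ceiling on the
  # right) with a minimum in between; emulate ceiling effects by solving on
  # the increasing right branch.
  opt <- stats::optimize(g, interval = c(-6, 6))
  if (g(opt$minimum) > target + tol) {
    warning(sprintf(
      "extreme_target %.3f unreachable; minimum expected fraction is %.3f",
      target, g(opt$minimum)
    ))
    return(opt$minimum)
  }
  lo <- opt$minimum
  hi <- 8
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    fm <- g(mid) - target
    if (abs(fm) <= tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate graded responses for a cohort
#'
#' Latent traits are drawn from the design's normal distribution (shifted
#' first, if `extreme_target` is set, so the expected all-extreme fraction
#' matches the target); responses are drawn from the GRM category
#' probabilities of [prob_categories()] — the single source of truth for
#' the model. Demographic covariates (age, gender, education, region,
#' ethnicity, language) are drawn to fixed Dutch general-population
#' proportions as labels only; they carry no response effect unless
#' `dif_spec` says so.
#'
#' @param bank an `item_bank` (e.g. from [sample_bank()]).
#' @param design a `simulation_design`.
#' @param covariates generate demographic covariate columns (default TRUE).
#' @return list with `rm` (a `response_matrix`), `theta` (true traits),
#'   `theta_mean_used` (after any extreme-target calibration), and `group`
#'   (focal-group indicator used for DIF injection, or `NULL`).
#' @export
simulate_responses <- function(bank, design, covariates = TRUE) {
  stopifnot(inherits(bank, "item_bank"), inherits(design, "simulation_design"))
  mu <- design$theta_mean
  if (!is.null(design$extreme_target)) {
    mu <- calibrate_theta_mean(bank, design$extreme_target, design$theta_sd)
  }
  withr_seed(design$seed + 1L, {
    n <- design$n_persons
    theta <- stats::rnorm(n, mu, design$theta_sd)
    covs <- if (covariates) simulate_covariates(n) else NULL

    banks <- list(reference = bank)
    group <- NULL
    if (!is.null(design$dif_spec)) {
      banks <- inject_dif(bank, design$dif_spec)
      gv <- unique(vapply(design$dif_spec, `[[`, "", "group_variable"))
      if (length(gv) != 1) stop("dif_spec entries must share one group_variable")
      if (!is.null(covs) && gv %in% names(covs)) {
        focal_level <- vapply(design$dif_spec, `[[`, "", "focal_level")[1]
        group <- covs[[gv]] == focal_level
      } else {
        group <- stats::runif(n) < 0.5      # balanced two-group design
        if (is.null(covs)) covs <- data.frame(row.names = seq_len(n))
        covs[[gv]] <- ifelse(group, "focal", "reference")
      }
    }

    X <- matrix(0L, n, n_items(bank))
    for (i in seq_len(n_items(bank))) {
      pr_ref <- prob_categories(banks$reference$slope[i],
                                banks$reference$thresholds[[i]], theta)
      pr <- pr_ref
      if (!is.null(group) && any(group)) {
        pr_foc <- prob_categories(banks$focal$slope[i],
                                  banks$focal$thresholds[[i]], theta)
        pr[group, ] <- pr_foc[group, ]
      }
      u <- stats::runif(n)
      X[, i] <- 1L + rowSums(u > t(apply(pr, 1, cumsum)))
    }
    X <- pmin(X, matrix(bank$n_categories, n, n_items(bank), byrow = TRUE))

    rm <- response_matrix(X, item_ids = bank$item_id,
                          person_ids = sprintf("p%05d", seq_len(n)),
                          covariates = covs,
                          n_categories = bank$n_categories)
    list(rm = rm, theta = theta, theta_mean_used = mu, group = group)
  })
}

# label-only demographics at Dutch general-population proportions
simulate_covariates <- function(n) {
  age <- pmin(pmax(round(stats::rnorm(n, 51, 17)), 18), 95)
  data.frame(
    age = age,
    gender = sample(c("male", "female"), n, TRUE, prob = c(0.476, 0.524)),
    education = sample(c("low", "middle", "high"), n, TRUE,
                       prob = c(0.293, 0.426, 0.280)),
    region = sample(c("north", "east", "south", "west"), n, TRUE,
                    prob = c(0.102, 0.199, 0.201, 0.496)),
    ethnicity = sample(c("native", "western_immigrant", "nonwestern_immigrant"),
                       n, TRUE, prob = c(0.772, 0.126, 0.101)),
    language = rep("dutch", n),
    stringsAsFactors = FALSE
  )
}

#' Build group-specific banks with injected DIF
#'
#' Uniform DIF shifts all thresholds of the named item for the focal group;
#' non-uniform DIF multiplies its slope. The reference bank is returned
#' unchanged.
#'
#' @param bank the reference `item_bank`.
#' @param dif_spec list of injections (see [simulation_design()]).
#' @return list with `reference` and `focal` banks.
#' @export
inject_dif <- function(bank, dif_spec) {
  focal <- bank
  for (spec in dif_spec) {
    i <- spec$item
    if (is.character(i)) {
      i <- match(i, bank$item_id)
      if (is.na(i)) stop("unknown item in dif_spec: ", spec$item)
    }
    if (i < 1 || i > n_items(bank)) stop("dif_spec item index out of range")
    shift <- spec$uniform_shift %||% 0
    mult <- spec$slope_multiplier %||% 1
    if (mult <= 0) stop("slope_multiplier must be positive")
    focal$thresholds[[i]] <- focal$thresholds[[i]] + shift
    focal$slope[i] <- focal$slope[i] * mult
  }
  list(reference = bank, focal = focal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
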