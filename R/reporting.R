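#' T-score and reliability transforms
#'
#' `t_score` maps the latent trait to the reporting metric,
#' `T = 10 theta + 50`: 50 is the reference-population mean (SD 10), and
#' the effective trait range \code{[-4, 4]} maps to T-scores 10 to 90.
#' `theta_from_t` is the exact inverse. `reliability_from_se` converts a
#' standard error on the theta metric (population SD 1) to the IRT
#' marginal reliability `1 - SE^2`, clamped below at 0; an SE of 0.316
#' corresponds to reliability 0.90 and an SE of 0.548 to 0.70.
#'
#' @param theta,t,se_theta numeric vectors.
#' @return numeric vector.
#' @export
t_score <- function(theta) 10 * theta + 50

#' @rdname t_score
#' @export
theta_from_t <- function(t) (t - 50) / 10

#' @rdname t_score
#' @export
reliability_from_se <- function(se_theta) {
  stopifnot(all(se_theta > 0))
  pmax(1 - se_theta^2, 0)
}

#' Default analysis thresholds for the validation pipeline
#'
#' One versioned set of conventional criteria: CFI/TLI above 0.95, RMSEA
#' below 0.06, SRMR below 0.08, first-to-second eigenvalue ratio above 4
#' with the first factor at least 20% of the variance, residual
#' correlations at most 0.20, item scalability at least 0.30 and scale
#' scalability at least 0.50, S-X2 flagging at p below 0.001, DIF flagging
#' at a McFadden pseudo-R2 change of at least 0.02, and CAT stopping at an
#' SE of 3 on the T metric or 12 items. Every element can be overridden
#' per run.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cfi_min = 0.95, tli_min = 0.95, rmsea_max = 0.06, srmr_max = 0.08,
    eigen_ratio_min = 4, pct_first_min = 0.20,
    residual_threshold = 0.20,
    h_item_min = 0.30, h_scale_min = 0.50,
    monotonicity_tolerance = 0.03,
    sx2_alpha = 0.001,
    dif_threshold = 0.02, dif_min_group = 50L,
    se_stop = 3, max_items = 12L, fixed_length = 8L,
    dif_groupings = c("age", "gender", "education", "region", "ethnicity",
                      "language"),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a validation report
#'
#' JSON stores the full report and round-trips to an equal object
#' (`read_report(write_report(x)) == x` up to floating-point printing,
#' which is written at full precision). CSV writes one table per report
#' section into a directory.
#'
#' @param report a `validation_report` (see [run_pipeline()]).
#' @param path output file (JSON) or directory (CSV).
#' @param format `"json"` or `"csv"`.
#' @return `write_report` invisibly returns `path`; `read_report` returns
#'   the reconstructed `validation_report`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         dataframe = "columns")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (section in names(report)) {
      x <- report[[section]]
      df <- if (is.data.frame(x)) x else flatten_to_df(x)
      if (!is.null(df)) {
        utils::write.csv(df, file.path(path, paste0(section, ".csv")),
                         row.names = FALSE, na = "")
      }
    }
  }
  invisible(path)
}

flatten_to_df <- function(x) {
  if (is.null(x)) return(NULL)
  flat <- tryCatch(unlist(x, use.names = TRUE), error = function(e) NULL)
  if (is.null(flat) || !length(flat)) return(NULL)
  data.frame(field = names(flat), value = as.character(flat),
             stringsAsFactors = FALSE)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE)
  class(x) <- "validation_report"
  x
}

#' Run the full item-bank validation pipeline
#'
#' Executes, in order: polychoric correlations, one-factor fit and
#' eigenvalue ratio (unidimensionality), residual-correlation screening
#' (local dependence), Mokken scalability and monotonicity, graded
#' response model estimation (unless a calibrated bank is supplied), S-X2
#' item fit, DIF screening per grouping, full-bank scoring, and the CAT
#' simulations (standard stopping rules plus a fixed-length CAT). Every
#' threshold comes from one `pipeline_config`; all stages are
#' deterministic given the data, so the same input and config reproduce
#' the report byte for byte. A stage failure is recorded in the `errors`
#' section and the remaining stages still run.
#'
#' @param rm a complete `response_matrix`.
#' @param bank optional calibrated `item_bank`; when `NULL` the bank is
#'   estimated from the data by [fit_grm()].
#' @param config a `pipeline_config`.
#' @param short_form optional item ids/indices of a fixed short form to
#'   evaluate alongside the CATs.
#' @return list of class `validation_report`.
#' @export
run_pipeline <- function(rm, bank = NULL, config = pipeline_config(),
                         short_form = NULL) {
  stopifnot(inherits(rm, "response_matrix"), inherits(config, "pipeline_config"))
  require_complete(rm, "run_pipeline")
  report <- list(
    meta = list(
      package = "irtvalid",
      n_persons = nrow(rm$responses),
      n_items = ncol(rm$responses),
      bank_estimated = is.null(bank),
      thresholds = config[!vapply(config, is.null, TRUE)]
    ),
    errors = list()
  )
  note_error <- function(stage, e) {
    report$errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  p <- ncol(rm$responses)
  n <- nrow(rm$responses)

  # dimensionality + local dependence
  if (p >= 3) {
    dim_res <- tryCatch({
      pc <- polychoric_matrix(rm)
      fit <- one_factor_fit(pc, n)
      efa <- efa_eigen_ratio(pc)
      ld <- local_dependence(fit, config$residual_threshold)
      list(pc = pc, fit = fit, efa = efa, ld = ld)
    }, error = function(e) note_error("dimensionality", e))
    if (!is.null(dim_res)) {
      f <- dim_res$fit$fit_indices
      report$fit_indices <- list(
        chi_square = f$chi_square, df = f$df, cfi = f$cfi, tli = f$tli,
        rmsea = f$rmsea, srmr = f$srmr,
        cfi_pass = f$cfi > config$cfi_min,
        tli_pass = f$tli > config$tli_min,
        rmsea_pass = f$rmsea < config$rmsea_max,
        srmr_pass = f$srmr < config$srmr_max,
        estimator = "ULS (unscaled)"
      )
      report$efa <- list(
        eigenvalue_1 = dim_res$efa$eigenvalues[1],
        eigenvalue_2 = dim_res$efa$eigenvalues[2],
        ratio = dim_res$efa$ratio,
        pct_first = dim_res$efa$pct_first,
        ratio_pass = dim_res$efa$ratio > config$eigen_ratio_min,
        pct_first_pass = dim_res$efa$pct_first >= config$pct_first_min
      )
      report$local_dependence <- list(
        threshold = config$residual_threshold,
        n_flagged_pairs = nrow(dim_res$ld$flagged_pairs),
        flagged_pairs = dim_res$ld$flagged_pairs
      )
    }
  } else {
    report$errors$dimensionality <-
      sprintf("skipped: %d item(s), need >= 3 for a one-factor model", p)
  }

  # Mokken scaling
  mk <- tryCatch({
    sc <- scalability(rm)
    mono <- monotonicity_check(rm, tolerance = config$monotonicity_tolerance)
    list(sc = sc, mono = mono)
  }, error = function(e) note_error("mokken", e))
  if (!is.null(mk)) {
    report$scalability <- list(
      H_scale = mk$sc$H_scale,
      H_item_min = min(mk$sc$H_items),
      H_item_max = max(mk$sc$H_items),
      scale_pass = mk$sc$H_scale >= config$h_scale_min,
      items_pass = all(mk$sc$H_items >= config$h_item_min),
      H_items = data.frame(item_id = names(mk$sc$H_items),
                           H = unname(mk$sc$H_items),
                           stringsAsFactors = FALSE)
    )
    report$monotonicity <- list(
      tolerance = mk$mono$tolerance,
      minsize = mk$mono$minsize,
      total_violations = sum(mk$mono$violations$n_violations),
      violations = mk$mono$violations
    )
  }

  # GRM calibration
  fit <- NULL
  if (is.null(bank)) {
    fit <- tryCatch(fit_grm(rm), error = function(e) note_error("grm", e))
    if (!is.null(fit)) {
      bank <- fit$bank
      rm <- collapse_categories(rm, fit)   # align data with the fitted coding
      report$grm <- list(
        log_likelihood = fit$log_likelihood,
        n_cycles = fit$n_cycles,
        converged = fit$converged,
        slope_min = min(bank$slope), slope_max = max(bank$slope),
        slope_mean = mean(bank$slope),
        threshold_min = min(unlist(bank$thresholds)),
        threshold_max = max(unlist(bank$thresholds))
      )
    }
  }

  if (!is.null(bank)) {
    # item fit
    itf <- tryCatch(s_x2(rm, bank, alpha = config$sx2_alpha),
                    error = function(e) note_error("itemfit", e))
    if (!is.null(itf)) {
      report$item_fit <- list(
        alpha = config$sx2_alpha,
        n_flagged = sum(itf$flagged),
        flagged_items = itf$item_id[itf$flagged],
        table = as.data.frame(itf)
      )
    }

    # DIF per available grouping
    thetas_eap <- tryCatch(score_cohort(rm, bank, estimator = "EAP")$theta,
                           error = function(e) note_error("dif_scoring", e))
    if (!is.null(thetas_eap) && !is.null(rm$covariates)) {
      report$dif <- list(threshold = config$dif_threshold)
      for (gv in intersect(config$dif_groupings, names(rm$covariates))) {
        g <- rm$covariates[[gv]]
        if (gv == "age") g <- age_median_split(g)
        if (gv == "education") {
          g <- factor(g, levels = intersect(c("low", "middle", "high"),
                                            unique(g)))
        }
        if (length(unique(g)) < 2) next
        dres <- tryCatch(
          dif_screen(rm, g, thetas = thetas_eap,
                     ordinal = identical(gv, "education"),
                     threshold = config$dif_threshold,
                     min_group_size = config$dif_min_group),
          error = function(e) note_error(paste0("dif_", gv), e)
        )
        if (!is.null(dres)) {
          report$dif[[gv]] <- list(
            n_flagged = sum(dres$flagged),
            flagged_items = dres$item_id[dres$flagged],
            table = as.data.frame(dres)
          )
        }
      }
    }

    # full-bank scoring and T-score distribution
    full <- tryCatch(score_cohort(rm, bank, estimator = "ML"),
                     error = function(e) note_error("scoring", e))
    if (!is.null(full)) {
      ok <- !full$clamped
      report$full_bank <- list(
        pct_clamped = 100 * mean(full$clamped),
        pct_reliable_0.90 = 100 * mean(full$reliability[ok] >= 0.90),
        t_score_distribution = list(
          mean = mean(full$t_score), sd = stats::sd(full$t_score),
          min = min(full$t_score), max = max(full$t_score)
        )
      )
    }

    # CAT simulations
    cats <- tryCatch({
      std <- simulate_cat_cohort(
        rm, bank, cat_config(se_stop = config$se_stop,
                             max_items = config$max_items))
      fx <- simulate_cat_cohort(
        rm, bank, cat_config(fixed_length = config$fixed_length))
      list(standard = std$summary, fixed_length = fx$summary)
    }, error = function(e) note_error("cat", e))
    if (!is.null(cats)) report$cat_summaries <- cats

    if (!is.null(short_form)) {
      sf <- tryCatch(evaluate_short_form(rm, bank, short_form),
                     error = function(e) note_error("short_form", e))
      if (!is.null(sf)) report$short_form <- sf$summary
    }
  }

  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (!is.null(x$fit_indices)) {
    cat(sprintf("  one-factor fit: CFI %.3f, TLI %.3f, RMSEA %.3f, SRMR %.3f\n",
                x$fit_indices$cfi, x$fit_indices$tli, x$fit_indices$rmsea,
                x$fit_indices$srmr))
  }
  if (!is.null(x$efa)) {
    cat(sprintf("  eigenvalue ratio: %.1f (first factor %.1f%% of variance)\n",
                x$efa$ratio, 100 * x$efa$pct_first))
  }
  if (!is.null(x$scalability)) {
    cat(sprintf("  scalability: H = %.2f (items %.2f-%.2f)\n",
                x$scalability$H_scale, x$scalability$H_item_min,
                x$scalability$H_item_max))
  }
  if (!is.null(x$item_fit)) {
    cat(sprintf("  item fit: %d item(s) flagged at p < %g\n",
                x$item_fit$n_flagged, x$item_fit$alpha))
  }
  if (!is.null(x$dif)) {
    for (gv in setdiff(names(x$dif), "threshold")) {
      cat(sprintf("  DIF (%s): %d item(s) flagged\n", gv,
                  x$dif[[gv]]$n_flagged))
    }
  }
  if (!is.null(x$cat_summaries)) {
    s <- x$cat_summaries$standard
    cat(sprintf("  standard CAT: mean %.1f items, %.0f%% reliability >= 0.90\n",
                s$mean_items, s$pct_reliable_0.90))
  }
  if (length(x$errors)) {
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
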