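#' Construct a respondent-by-item response matrix
#'
#' Responses are integer categories coded `1..m` per item (`NA` is the
#' missing sentinel accepted at the I/O boundary; every statistical stage
#' requires complete cases, see [complete_cases]). Optional per-person
#' demographic covariates (e.g. `age`, `gender`, `education`, `region`,
#' `ethnicity`, `language`) travel with the matrix and are used by the DIF
#' screen.
#'
#' @param responses integer matrix, persons in rows, items in columns.
#' @param item_ids character vector of unique item labels (defaults to the
#'   matrix column names, or `item1..itemP`).
#' @param person_ids character vector of unique person labels (defaults to
#'   `p1..pN`).
#' @param covariates data.frame of per-person fields, `n_persons` rows, or
#'   `NULL`.
#' @param n_categories integer scalar or vector: number of response
#'   categories per item (default 5). Responses outside `[1, m]` are an
#'   error.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, item_ids = NULL, person_ids = NULL,
                            covariates = NULL, n_categories = 5L) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  p <- ncol(responses)
  if (n < 1 || p < 1) stop("need at least one person and one item")
  if (is.null(item_ids)) {
    item_ids <- colnames(responses)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(p))
  }
  if (is.null(person_ids)) {
    person_ids <- rownames(responses)
    if (is.null(person_ids)) person_ids <- paste0("p", seq_len(n))
  }
  item_ids <- as.character(item_ids)
  person_ids <- as.character(person_ids)
  if (length(item_ids) != p) stop("item_ids length must match ncol(responses)")
  if (length(person_ids) != n) stop("person_ids length must match nrow(responses)")
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (anyDuplicated(person_ids)) stop("person_ids must be unique")
  n_categories <- as.integer(n_categories)
  if (length(n_categories) == 1L) n_categories <- rep(n_categories, p)
  if (length(n_categories) != p || any(n_categories < 2L)) {
    stop("n_categories must be a scalar or per-item vector of integers >= 2")
  }
  storage.mode(responses) <- "integer"
  check_response_range(responses, n_categories, item_ids)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n) stop("covariates must have one row per person")
  }
  dimnames(responses) <- list(person_ids, item_ids)
  structure(
    list(
      responses = responses,
      item_ids = item_ids,
      person_ids = person_ids,
      covariates = covariates,
      n_categories = n_categories,
      reverse_coding_applied = FALSE
    ),
    class = "response_matrix"
  )
}

check_response_range <- function(responses, n_categories, item_ids) {
  raw <- responses
  for (j in seq_len(ncol(raw))) {
    x <- raw[, j]
    bad <- which(!is.na(x) & (x < 1L | x > n_categories[j]))
    if (length(bad)) {
      stop(sprintf(
        "item '%s': response code %d out of range [1, %d] for person(s) %s",
        item_ids[j], x[bad[1]], n_categories[j],
        paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }
  invisible(TRUE)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> %d persons x %d items%s%s\n",
    nrow(x$responses), ncol(x$responses),
    if (!is.null(x$covariates)) {
      sprintf(", covariates: %s", paste(names(x$covariates), collapse = ", "))
    } else "",
    if (x$reverse_coding_applied) " (reverse-coded)" else ""
  ))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Drop persons with any missing response
#'
#' Explicit listwise deletion. Every statistical stage in the pipeline
#' requires complete cases and errors on missing values, so that the
#' analysis sample is always chosen deliberately rather than silently.
#'
#' @param rm a `response_matrix`.
#' @return a `response_matrix` containing only the complete rows.
#' @export
complete_cases <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  keep <- stats::complete.cases(rm$responses)
  if (all(keep)) return(rm)
  out <- rm
  out$responses <- rm$responses[keep, , drop = FALSE]
  out$person_ids <- rm$person_ids[keep]
  if (!is.null(rm$covariates)) {
    out$covariates <- rm$covariates[keep, , drop = FALSE]
  }
  out
}

require_complete <- function(rm, what) {
  if (anyNA(rm$responses)) {
    stop(what, " requires complete cases; use complete_cases() first")
  }
  invisible(TRUE)
}

#' Apply reverse coding to flagged items
#'
#' For every item flagged `reverse_coded` in the bank, category `c` is
#' mapped to `m + 1 - c` so that higher categories mean more of the trait.
#' The operation records that coding was applied and refuses a second
#' application (the value-level map is an involution, so applying it twice
#' would silently undo it).
#'
#' @param rm a `response_matrix`.
#' @param bank an `item_bank` whose `reverse_coded` flags name the items to
#'   recode; all flagged items must be present in `rm`.
#' @return the recoded `response_matrix` with `reverse_coding_applied = TRUE`.
#' @export
apply_reverse_coding <- function(rm, bank) {
  stopifnot(inherits(rm, "response_matrix"), inherits(bank, "item_bank"))
  if (rm$reverse_coding_applied) {
    stop("reverse coding has already been applied to this response matrix")
  }
  flagged <- bank$item_id[bank$reverse_coded]
  missing_items <- setdiff(flagged, rm$item_ids)
  if (length(missing_items)) {
    stop("reverse-coded items not in response matrix: ",
         paste(missing_items, collapse = ", "))
  }
  out <- rm
  for (id in flagged) {
    j <- match(id, rm$item_ids)
    m <- rm$n_categories[j]
    out$responses[, j] <- m + 1L - rm$responses[, j]
  }
  out$reverse_coding_applied <- TRUE
  out
}

#' Read / write response matrices as CSV
#'
#' The CSV layout is one row per person: an id column, one column per item,
#' and optional covariate columns. `schema` maps the file's columns onto
#' these roles; by default the first column is the person id and every other
#' column is an item.
#'
#' @param path file path to a delimited text file with a header row.
#' @param schema optional list with fields `person_id` (column name),
#'   `items` (character vector of item column names) and `covariates`
#'   (character vector of covariate column names).
#' @param n_categories per-item category count passed to
#'   [response_matrix()].
#' @return `read_responses` returns a validated `response_matrix`;
#'   `write_responses` invisibly returns `path`.
#' @export
read_responses <- function(path, schema = NULL, n_categories = 5L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("response file needs an id column and >= 1 item column")
  if (is.null(schema)) {
    schema <- list(person_id = names(df)[1],
                   items = names(df)[-1],
                   covariates = character(0))
  }
  need <- c(schema$person_id, schema$items, schema$covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("columns missing from file: ", paste(miss, collapse = ", "))
  resp <- df[, schema$items, drop = FALSE]
  for (cn in names(resp)) {
    x <- resp[[cn]]
    non_int <- !is.na(x) & (is.na(suppressWarnings(as.numeric(x))) |
                              as.numeric(x) != round(as.numeric(x)))
    if (any(non_int)) {
      stop(sprintf("item '%s': non-integer response in row(s) %s",
                   cn, paste(utils::head(which(non_int), 5), collapse = ", ")))
    }
    resp[[cn]] <- as.integer(x)
  }
  covs <- if (length(schema$covariates)) {
    df[, schema$covariates, drop = FALSE]
  } else NULL
  response_matrix(
    as.matrix(resp),
    item_ids = schema$items,
    person_ids = as.character(df[[schema$person_id]]),
    covariates = covs,
    n_categories = n_categories
  )
}

#' @rdname read_responses
#' @param rm a `response_matrix`.
#' @export
write_responses <- function(rm, path) {
  stopifnot(inherits(rm, "response_matrix"))
  df <- data.frame(person_id = rm$person_ids, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(rm$responses, stringsAsFactors = FALSE))
  if (!is.null(rm$covariates)) df <- cbind(df, rm$covariates)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
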