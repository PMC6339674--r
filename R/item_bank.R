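#' Construct an item bank of graded-response-model parameters
#'
#' An item bank holds, for each item, a positive slope (discrimination) on
#' the logistic metric (no 1.7 scaling constant) and a strictly increasing
#' vector of thresholds in theta units; an item with `m` ordered response
#' categories has `m - 1` thresholds. Categories are coded `1..m`.
#'
#' @param item_id character vector of unique item labels.
#' @param slope numeric vector of positive slopes, one per item.
#' @param thresholds list of numeric vectors; `thresholds[[i]]` is the
#'   strictly increasing threshold vector of item `i`.
#' @param reverse_coded logical vector; items whose raw responses must be
#'   reverse-coded (category `c` mapped to `m + 1 - c`) before analysis.
#'   Defaults to `FALSE` for all items.
#' @return An object of class `item_bank`: a list with fields `item_id`,
#'   `slope`, `thresholds`, `n_categories`, `reverse_coded`.
#' @examples
#' bank <- item_bank(
#'   item_id = c("it1", "it2"),
#'   slope = c(2.5, 3.1),
#'   thresholds = list(c(-1, 0, 1, 2), c(-2, -1, 0, 1))
#' )
#' n_items(bank)
#' @export
item_bank <- function(item_id, slope, thresholds, reverse_coded = NULL) {
  item_id <- as.character(item_id)
  slope <- as.numeric(slope)
  if (!is.list(thresholds)) thresholds <- list(as.numeric(thresholds))
  thresholds <- lapply(thresholds, as.numeric)
  p <- length(item_id)
  if (length(slope) != p || length(thresholds) != p) {
    stop("item_id, slope and thresholds must have one entry per item")
  }
  if (anyDuplicated(item_id)) stop("item_id values must be unique")
  if (any(!is.finite(slope)) || any(slope <= 0)) {
    stop("all slopes must be finite and > 0")
  }
  for (i in seq_len(p)) {
    b <- thresholds[[i]]
    if (length(b) < 1 || any(!is.finite(b))) {
      stop(sprintf("item '%s': thresholds must be finite and non-empty", item_id[i]))
    }
    if (length(b) > 1 && any(diff(b) <= 0)) {
      stop(sprintf("item '%s': thresholds must be strictly increasing", item_id[i]))
    }
  }
  if (is.null(reverse_coded)) reverse_coded <- rep(FALSE, p)
  reverse_coded <- as.logical(reverse_coded)
  if (length(reverse_coded) == 1L) reverse_coded <- rep(reverse_coded, p)
  structure(
    list(
      item_id = item_id,
      slope = slope,
      thresholds = thresholds,
      n_categories = vapply(thresholds, length, integer(1)) + 1L,
      reverse_coded = reverse_coded
    ),
    class = "item_bank"
  )
}

#' Number of items in an item bank
#' @param bank an `item_bank`.
#' @return integer count of items.
#' @export
n_items <- function(bank) length(bank$item_id)

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf(
    "<item_bank> %d items, %s categories, slopes in [%.2f, %.2f]\n",
    n_items(x),
    paste(unique(range(x$n_categories)), collapse = "-"),
    min(x$slope), max(x$slope)
  ))
  invisible(x)
}

#' Subset an item bank
#' @param x an `item_bank`.
#' @param i integer, logical, or character (item_id) index.
#' @param ... ignored.
#' @return an `item_bank` containing the selected items, in the given order.
#' @export
`[.item_bank` <- function(x, i, ...) {
  if (is.character(i)) {
    idx <- match(i, x$item_id)
    if (anyNA(idx)) stop("unknown item_id: ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  item_bank(x$item_id[i], x$slope[i], x$thresholds[i], x$reverse_coded[i])
}

bank_as_data_frame <- function(bank) {
  max_b <- max(lengths(bank$thresholds))
  bmat <- t(vapply(bank$thresholds, function(b) {
    c(b, rep(NA_real_, max_b - length(b)))
  }, numeric(max_b)))
  colnames(bmat) <- paste0("b", seq_len(max_b))
  data.frame(
    item_id = bank$item_id,
    slope = bank$slope,
    bmat,
    n_categories = bank$n_categories,
    reverse_coded = bank$reverse_coded,
    stringsAsFactors = FALSE
  )
}

bank_from_data_frame <- function(df) {
  req <- c("item_id", "slope", "n_categories")
  if (!all(req %in% names(df))) {
    stop("item bank table must have columns: ", paste(req, collapse = ", "))
  }
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  thresholds <- lapply(seq_len(nrow(df)), function(i) {
    b <- as.numeric(df[i, bcols])
    b <- b[!is.na(b)]
    nb <- as.integer(df$n_categories[i]) - 1L
    if (length(b) != nb) {
      stop(sprintf(
        "item '%s': expected %d thresholds, found %d",
        df$item_id[i], nb, length(b)
      ))
    }
    b
  })
  rev_flag <- if ("reverse_coded" %in% names(df)) df$reverse_coded else FALSE
  item_bank(df$item_id, df$slope, thresholds, as.logical(rev_flag))
}

#' Read / write item banks as CSV or JSON
#'
#' The CSV dialect has columns `item_id, slope, b1..bK, n_categories,
#' reverse_coded` (K = max categories minus one; items with fewer categories
#' leave trailing threshold cells empty). The JSON mirror stores the same
#' fields per item. `write_item_bank` then `read_item_bank` round-trips to
#' an equal bank.
#'
#' @param path file path; format inferred from the `.csv` / `.json` extension
#'   unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `read_item_bank` returns an `item_bank`; `write_item_bank`
#'   invisibly returns `path`.
#' @examples
#' bank <- read_item_bank(
#'   system.file("extdata", "example_bank.csv", package = "irtvalid"))
#' bank
#' @export
read_item_bank <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    bank_from_data_frame(df)
  } else {
    df <- jsonlite::fromJSON(path)
    bank_from_data_frame(as.data.frame(df, stringsAsFactors = FALSE))
  }
}

#' @rdname read_item_bank
#' @param bank an `item_bank`.
#' @export
write_item_bank <- function(bank, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(bank, "item_bank"))
  format <- resolve_format(match.arg(format), path)
  df <- bank_as_data_frame(bank)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else stop("cannot infer format from path: ", path)
}
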