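#' Construct a categorical survey dataset
#'
#' Bundles an N x D matrix of integer-coded categorical responses with the
#' number of response options per dimension and an optional categorical
#' outcome label per row (the outcome is never seen by the sampler; it is
#' used only when profiling clusters). Codes in dimension `d` must lie in
#' `1..V_d` with no missing values: states such as "not applicable" are
#' their own response category, not missing data.
#'
#' @param responses N x D matrix or data frame of integer codes (1-based).
#' @param category_counts integer vector `V_d >= 2` of options per
#'   dimension; defaults to the per-column maximum observed code.
#' @param item_labels length-D character vector of item names; defaults to
#'   column names.
#' @param outcome optional length-N vector of categorical outcome labels.
#' @return an object of class `categorical_dataset` with elements
#'   `responses`, `category_counts`, `item_labels`, `outcome`, `n`, `d`.
#' @export
categorical_dataset <- function(responses, category_counts = NULL,
                                item_labels = NULL, outcome = NULL) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses) || !is.numeric(responses)) {
    stop("`responses` must be a numeric matrix or data frame")
  }
  if (anyNA(responses)) {
    stop("`responses` must not contain missing values; ",
         "code not-applicable states as their own category")
  }
  if (any(responses != round(responses))) stop("`responses` must be integer codes")
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  d <- ncol(responses)
  if (n < 1L || d < 1L) stop("`responses` needs at least one row and one column")
  if (is.null(item_labels)) {
    item_labels <- colnames(responses)
    if (is.null(item_labels)) item_labels <- paste0("item_", seq_len(d))
  }
  if (length(item_labels) != d) stop("`item_labels` must have one entry per column")
  if (is.null(category_counts)) {
    category_counts <- apply(responses, 2L, max)
  }
  category_counts <- as.integer(category_counts)
  if (length(category_counts) != d) {
    stop("`category_counts` must have one entry per column")
  }
  if (any(category_counts < 2L)) stop("every dimension needs at least 2 categories")
  if (any(responses < 1L) ||
      any(responses > matrix(category_counts, n, d, byrow = TRUE))) {
    stop("response codes must lie in 1..V_d for every dimension d")
  }
  if (!is.null(outcome)) {
    if (length(outcome) != n) stop("`outcome` must have one entry per row")
    if (anyNA(outcome)) stop("`outcome` must not contain missing values")
    outcome <- as.factor(outcome)
  }
  colnames(responses) <- item_labels
  structure(
    list(responses = responses, category_counts = category_counts,
         item_labels = item_labels, outcome = outcome, n = n, d = d),
    class = "categorical_dataset"
  )
}

#' @export
print.categorical_dataset <- function(x, ...) {
  cat("Categorical dataset:", x$n, "respondents x", x$d, "items\n")
  cat("Options per item:", paste(x$category_counts, collapse = " "), "\n")
  if (!is.null(x$outcome)) {
    cat("Outcome: ", nlevels(x$outcome), " categories (",
        paste(utils::head(levels(x$outcome), 4L), collapse = ", "),
        if (nlevels(x$outcome) > 4L) ", ..." else "", ")\n", sep = "")
  }
  invisible(x)
}

#' Read or write a categorical dataset
#'
#' The dataset is stored as a CSV with a header row of item labels and one
#' integer-coded row per respondent (plus the outcome column, if present),
#' alongside a JSON schema sidecar listing the number of options per item
#' and the name of the outcome column.
#'
#' @param data a [categorical_dataset()].
#' @param csv_path path of the data CSV.
#' @param schema_path path of the JSON schema sidecar; defaults to
#'   `csv_path` with extension `.schema.json`.
#' @return `read_dataset()` returns a `categorical_dataset`;
#'   `write_dataset()` returns `csv_path` invisibly.
#' @export
write_dataset <- function(data, csv_path, schema_path = NULL) {
  stopifnot(inherits(data, "categorical_dataset"))
  if (is.null(schema_path)) schema_path <- sub("\\.csv$", ".schema.json", csv_path)
  df <- as.data.frame(data$responses)
  schema <- list(items = data.frame(label = data$item_labels,
                                    levels = data$category_counts))
  if (!is.null(data$outcome)) {
    df$outcome <- as.character(data$outcome)
    schema$outcome <- list(column = "outcome", categories = levels(data$outcome))
  }
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(csv_path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(csv_path, schema_path = NULL) {
  if (is.null(schema_path)) schema_path <- sub("\\.csv$", ".schema.json", csv_path)
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path, check.names = FALSE)
  outcome <- NULL
  if (!is.null(schema$outcome)) {
    outcome <- factor(df[[schema$outcome$column]],
                      levels = schema$outcome$categories)
    df[[schema$outcome$column]] <- NULL
  }
  categorical_dataset(as.matrix(df[, schema$items$label, drop = FALSE]),
                      category_counts = schema$items$levels,
                      item_labels = schema$items$label,
                      outcome = outcome)
}
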