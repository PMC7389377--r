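# Labelled-matrix CSV dialect shared by probability and rate matrices:
# first row and first column carry the state labels; absorbing states are
# declared in a reserved `#absorbing:` header comment (comma-separated),
# or passed explicitly by the caller.

.read_labelled_matrix <- function(path) {
  lines <- readLines(path)
  absorbing <- NULL
  hdr <- grep("^#absorbing:", lines, value = TRUE)
  if (length(hdr)) {
    absorbing <- trimws(strsplit(sub("^#absorbing:", "", hdr[1]), ",")[[1]])
    absorbing <- absorbing[nzchar(absorbing)]
  }
  body <- lines[!startsWith(lines, "#")]
  df <- read.csv(text = paste(body, collapse = "\n"), row.names = 1,
                 check.names = FALSE)
  list(values = as.matrix(df), absorbing = absorbing)
}

#' Read a transition-probability matrix from labelled CSV
#'
#' Expects the labelled-matrix dialect: state labels in the first row and
#' column, cell (i, j) = p_ij, and the absorbing states declared either in
#' a leading `#absorbing: name1, name2` comment line or via the
#' `absorbing` argument (which takes precedence).
#'
#' @param path CSV file path.
#' @param absorbing optional character vector overriding the header
#'   declaration.
#' @return A validated [markov_chain()].
#' @export
read_chain_csv <- function(path, absorbing = NULL) {
  x <- .read_labelled_matrix(path)
  if (is.null(absorbing)) absorbing <- x$absorbing
  if (is.null(absorbing) || !length(absorbing)) {
    stop("absorbing states not declared: add a '#absorbing:' header or pass `absorbing`")
  }
  markov_chain(x$values, absorbing = absorbing)
}

#' Read a transition-rate matrix from labelled CSV
#'
#' Same dialect as [read_chain_csv()]; cells hold per-step rates
#' (off-diagonal occurrence-exposure rates, diagonal zero or generator
#' convention).
#'
#' @inheritParams read_chain_csv
#' @param units time unit of the rates.
#' @return A [rate_matrix()].
#' @export
read_rates_csv <- function(path, absorbing = NULL, units = "step") {
  x <- .read_labelled_matrix(path)
  if (is.null(absorbing)) absorbing <- x$absorbing
  if (is.null(absorbing) || !length(absorbing)) {
    stop("absorbing states not declared: add a '#absorbing:' header or pass `absorbing`")
  }
  rate_matrix(x$values, absorbing = absorbing, units = units)
}

#' Write a chain or rate matrix to labelled CSV
#'
#' Writes the labelled-matrix dialect with a `#absorbing:` header comment,
#' so the file round-trips through [read_chain_csv()] /
#' [read_rates_csv()].
#'
#' @param x a [markov_chain()] or [rate_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(x, path) {
  if (inherits(x, "markov_chain")) {
    M <- x$P
  } else if (inherits(x, "rate_matrix")) {
    M <- x$Q
  } else {
    stop("`x` must be a markov_chain or rate_matrix")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#absorbing: ",
                    paste(absorbing_states(x$states), collapse = ", ")), con)
  write.csv(as.data.frame(M), con, row.names = TRUE)
  invisible(path)
}
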