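#' Item response matrices
#'
#' An `item_data` object holds an n x k table of item scores (rows =
#' respondents, columns = items) with missing cells stored as `NA`. It is the
#' raw input of every analysis in the package.
#'
#' @param values numeric matrix (or data frame) of item scores; `NA` marks a
#'   missing response.
#' @param item_names optional character vector of k unique item labels;
#'   defaults to the column names, or `item1 ... itemk`.
#'
#' @return An object of class `item_data` with elements `values` (numeric
#'   matrix with `NA`s), `mask` (logical matrix, `TRUE` = observed),
#'   `item_names`, `n`, `k`.
#' @examples
#' x <- item_data(matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 2))
#' x$n
#' @export
item_data <- function(values, item_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  k <- ncol(values)
  if (k < 2L) stop("item_data needs at least 2 items (columns), got ", k)
  if (n < 2L) stop("item_data needs at least 2 respondents (rows), got ", n)
  if (is.null(item_names)) {
    item_names <- colnames(values)
    if (is.null(item_names)) item_names <- paste0("item", seq_len(k))
  }
  if (length(item_names) != k) stop("item_names must have length k = ", k)
  if (anyDuplicated(item_names)) stop("item_names must be unique")
  mask <- !is.na(values)
  obs_per_col <- colSums(mask)
  if (any(obs_per_col < 2L)) {
    stop("every item needs at least 2 observed values; item(s) ",
         paste(item_names[obs_per_col < 2L], collapse = ", "), " have fewer")
  }
  colnames(values) <- item_names
  structure(
    list(values = values, mask = mask, item_names = item_names, n = n, k = k),
    class = "item_data"
  )
}

#' @export
print.item_data <- function(x, ...) {
  n_miss <- sum(!x$mask)
  cat(sprintf("item_data: %d respondents x %d items (%s)\n", x$n, x$k,
              if (n_miss == 0L) "complete"
              else sprintf("%d missing cells", n_miss)))
  cat("items:", paste(x$item_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read item-response data from a CSV file
#'
#' Reads a comma-separated table with a mandatory header row into an
#' [item_data] object. Cells matching one of `missing_codes` (or empty cells)
#' are marked missing; any other non-numeric cell is a parse error that names
#' the offending row and column.
#'
#' @param path path to a CSV file.
#' @param missing_codes character vector of cell values treated as missing;
#'   default: the empty string and `"NA"`.
#' @return An [item_data] object; column order of the file is preserved.
#' @export
read_item_data <- function(path, missing_codes = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         strip.white = TRUE)
  if (ncol(raw) < 2L) {
    stop("need at least 2 item columns, file has ", ncol(raw))
  }
  vals <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- raw[[j]]
    is_missing <- cell %in% missing_codes
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s in row %d, column %s",
                   dQuote(cell[bad[1L]]), bad[1L], dQuote(names(raw)[j])))
    }
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }
  colnames(vals) <- names(raw)
  item_data(vals)
}

#' Rows of an item_data object with no missing cells
#'
#' @param data an [item_data] object.
#' @return numeric matrix of the listwise-complete rows.
#' @export
complete_rows <- function(data) {
  stopifnot(inherits(data, "item_data"))
  data$values[rowSums(!data$mask) == 0L, , drop = FALSE]
}
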