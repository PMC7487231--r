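# Reading and writing the pipeline's tabular formats.
# All inputs are UTF-8 CSV with a header row, comma delimiter, "." decimal.

fecal_columns <- c("sample_id", "species", "taxon", "category",
                   "count", "volume")
isotope_columns <- c("individual_id", "group", "d13c", "d15n")

check_numeric_column <- function(x, col, file) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) | !is.finite(out))
  if (length(bad)) {
    stop(sprintf(
      "%s: column '%s' is not finite numeric at data row(s) %s (value(s): %s)",
      file, col, paste(bad, collapse = ", "),
      paste(raw[bad], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a fecal-content table
#'
#' Reads a long-format CSV with one row per food item per fecal sample and
#' validates it against the data model: columns `sample_id`, `species`,
#' `taxon`, `category`, `count` (non-negative integer number of items) and
#' `volume` (non-negative reconstituted volume in mm^3).  A row with both
#' `count = 0` and `volume = 0` carries no information and is rejected.
#'
#' @param path Path to a CSV file.
#' @param categories Optional character vector of admissible resource
#'   categories; when supplied, any unknown category is an error.
#' @return A `data.frame` with the six validated columns.
#' @seealso [tabulate_diet()], [simulate_feces()]
#' @export
read_fecal_table <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(fecal_columns, names(df))
  if (length(missing)) stop_bad_column(missing, path)
  df <- df[fecal_columns]
  df$count <- check_numeric_column(df$count, "count", path)
  df$volume <- check_numeric_column(df$volume, "volume", path)
  bad <- which(df$count < 0 | df$volume < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative count/volume at data row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  empty <- which(df$count == 0 & df$volume == 0)
  if (length(empty)) {
    stop(sprintf(
      "%s: row(s) %s have count = 0 and volume = 0 (empty records)",
      path, paste(empty, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(categories)) {
    unknown <- setdiff(unique(df$category), categories)
    if (length(unknown)) {
      stop(sprintf("%s: unknown resource category(ies): %s",
                   path, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Read a consumer/source isotope table
#'
#' Reads a CSV with columns `individual_id`, `group` (consumer species or
#' source label), `d13c` and `d15n` (delta values in permil vs. VPDB and
#' atmospheric air respectively).  Delta values must parse as finite
#' numbers; a `group` must be non-empty.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with the four validated columns.  An empty data
#'   section yields a zero-row data frame with a warning.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(isotope_columns, names(df))
  if (length(missing)) stop_bad_column(missing, path)
  df <- df[isotope_columns]
  if (nrow(df) == 0L) {
    warning(path, ": isotope table has no data rows", call. = FALSE)
    return(df)
  }
  df$d13c <- check_numeric_column(df$d13c, "d13c", path)
  df$d15n <- check_numeric_column(df$d15n, "d15n", path)
  blank <- which(is.na(df$group) | !nzchar(trimws(df$group)))
  if (length(blank)) {
    stop(sprintf("%s: empty group label at data row(s) %s",
                 path, paste(blank, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a results table to CSV
#'
#' Writes a data frame with a deterministic column order (as given) and
#' numeric columns rounded to a configurable number of significant digits,
#' so that two identical inputs produce byte-identical files.
#'
#' @param x A data frame (any stage output).
#' @param path Output file path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return Invisibly, the path written.
#' @export
write_results <- function(x, path, digits = 6) {
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.numeric, logical(1L))
  x[num] <- lapply(x[num], signif, digits = digits)
  ok <- tryCatch({
    utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop("cannot write results to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Published 95% credible intervals for three thrush species
#'
#' Returns the 95% credible intervals of dietary-source contributions to
#' whole-blood synthesis for three sympatric \emph{Turdus} thrushes
#' (\emph{T. amaurochalinus}, \emph{T. albicollis}, \emph{T. rufiventris})
#' over seven resource groups, as printed in a published field study from
#' southern Brazil.  These are the reference data behind the worked
#' isotope-network example: the matrix of interval midpoints is the
#' isotope-based interaction matrix.
#'
#' @return A `data.frame` with columns `species`, `source`, `lower`,
#'   `upper` (fractions of the assimilated diet).
#' @seealso [build_isotope_matrix()]
#' @examples
#' ci <- thrush_isotope_ci()
#' head(ci)
#' @export
thrush_isotope_ci <- function() {
  path <- system.file("extdata", "thrush_isotope_ci.csv",
                      package = "trophicniche", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
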