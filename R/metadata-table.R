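#' Sample-metadata tables
#'
#' A metadata table is a samples-by-features table of free-text cells, carried
#' as a character tibble with a `dataset_id` attribute (and, when read from
#' disk, a `source_path`). Duplicate column headers are legal at load time —
#' they are exactly what the duplicate-resolution curation stage exists to
#' fix — so the tibble is built with minimal name repair. Cells are kept
#' verbatim: no trimming, no NA conversion at load.
#'
#' @name metadata_table
NULL

#' Construct a metadata table from a data frame
#'
#' @param df Data frame or tibble; all columns are coerced to character.
#' @param dataset_id Non-empty dataset identifier.
#' @param source_path Optional path the table came from.
#' @param headers Optional character vector of headers overriding `names(df)`
#'   (needed to carry duplicate or punctuated headers a data frame cannot).
#' @return A `tgx_table`: a character tibble with attributes `dataset_id` and
#'   `source_path`.
#' @export
metadata_table <- function(df, dataset_id, source_path = NA_character_,
                           headers = NULL) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L,
            nzchar(dataset_id))
  hdr <- as.character(headers %||% names(df))
  if (length(hdr) != ncol(df)) {
    stop("header count does not match column count", call. = FALSE)
  }
  if (any(is.na(hdr) | !nzchar(trimws(hdr)))) {
    stop("blank column headers are not allowed", call. = FALSE)
  }
  out <- tibble::as_tibble(lapply(df, as.character), .name_repair = "minimal")
  names(out) <- hdr
  attr(out, "dataset_id") <- dataset_id
  attr(out, "source_path") <- source_path
  class(out) <- c("tgx_table", class(out))
  out
}

#' @export
print.tgx_table <- function(x, ...) {
  cat(sprintf("<tgx_table> dataset '%s': %d sample(s) x %d column(s)\n",
              dataset_id(x), nrow(x), ncol(x)))
  NextMethod()
}

#' @rdname metadata_table
#' @param t A `tgx_table`.
#' @export
dataset_id <- function(t) attr(t, "dataset_id", exact = TRUE)

# structural equality of tables: headers, cells, dataset id
tables_identical <- function(a, b) {
  identical(names(a), names(b)) &&
    identical(dataset_id(a), dataset_id(b)) &&
    nrow(a) == nrow(b) &&
    identical(unname(lapply(a, as.character)), unname(lapply(b, as.character)))
}

#' Read a delimited sample-metadata table
#'
#' Reads an RFC-4180 CSV or TSV file with a header row into a [metadata_table].
#' The file must be rectangular; ragged rows are an error naming the first bad
#' data row. Duplicate header texts load fine (flagged later by
#' [detect_duplicate_columns()]); blank headers are a load error. Every cell
#' is kept verbatim as text.
#'
#' @param path File path (UTF-8).
#' @param delimiter `"comma"` or `"tab"`; the default guesses from the file
#'   extension (`.tsv`/`.tab` means tab).
#' @param dataset_id Dataset identifier; defaults to the file stem.
#' @return A `tgx_table`.
#' @export
load_table <- function(path, delimiter = c("auto", "comma", "tab"),
                       dataset_id = NULL) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (delimiter == "auto") {
    delimiter <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE))
      "tab" else "comma"
  }
  delim <- if (delimiter == "tab") "\t" else ","
  df <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(0), trim_ws = FALSE, name_repair = "minimal",
    progress = FALSE, show_col_types = FALSE))
  prob <- readr::problems(df)
  ragged <- prob[grepl("columns", prob$expected), , drop = FALSE]
  if (nrow(ragged) > 0L) {
    stop(sprintf("ragged table '%s': row %d has %s but %s were expected",
                 path, ragged$row[[1]], ragged$actual[[1]], ragged$expected[[1]]),
         call. = FALSE)
  }
  df[is.na(df)] <- ""
  id <- dataset_id %||% sub("\\.[^.]*$", "", basename(path))
  metadata_table(df, dataset_id = id, source_path = path)
}

#' Write a metadata table to delimited text
#'
#' Writes RFC-4180 CSV/TSV with minimal quoting and the current column order.
#' `load_table(write_table(t))` round-trips to a structurally identical table.
#'
#' @param t A `tgx_table`.
#' @param path Output path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(t, path, delimiter = c("auto", "comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (delimiter == "auto") {
    delimiter <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE))
      "tab" else "comma"
  }
  delim <- if (delimiter == "tab") "\t" else ","
  tmp <- paste0(path, ".tmp", Sys.getpid())
  # built by hand so duplicate headers survive (data.frame() would repair them)
  df <- structure(lapply(seq_along(names(t)), function(i) as.character(t[[i]])),
                  names = names(t), class = "data.frame",
                  row.names = seq_len(nrow(t)))
  readr::write_delim(df, tmp, delim = delim, quote = "needed", na = "")
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
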