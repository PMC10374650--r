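#' Read and write datasets as SQLite databases
#'
#' The relational form of the data scheme is a single-file SQLite database
#' with seven tables named `intermolecular`, `bond`, `angle`, `torsion`,
#' `improper`, `1n_potential` and `special` (the last-but-one starts with a
#' digit and is always addressed with quoted identifiers).  Rigid entries
#' store the literal string `none` in the id column (matched
#' case-insensitively on read, written lowercase); wildcard bond orders
#' store `X`.  `write_database()` refuses datasets with validation errors
#' and writes rows in a deterministic order (sorted by tag tuple), so that
#' `read_database()` inverts it record-for-record.
#'
#' @param path file path of the SQLite database.
#' @param name dataset name for the returned object (default: file stem).
#' @param units unit-profile marker recorded on the returned dataset.
#' @return `read_database()` returns an [ff_dataset()].
#' @examples
#' db <- tempfile(fileext = ".sqlite")
#' write_database(load_bundled(), db)
#' read_database(db)
#' @export
read_database <- function(path, name = NULL, units = "K-A-e") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "ffdat_format_error")
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  have <- DBI::dbListTables(con)
  sections <- purrr::imap(.ff_sections, function(spec, sec) {
    tbl <- db_table_name(sec)
    if (!tbl %in% have) {
      rlang::abort(sprintf("database is missing table '%s'", tbl),
                   class = "ffdat_format_error")
    }
    raw <- DBI::dbGetQuery(con, sprintf('SELECT * FROM "%s"', tbl))
    storage_to_section(raw, sec, context = sprintf("table '%s'", tbl))
  })
  do.call(ff_dataset, c(
    list(name = name %||% sub("\\.[^.]*$", "", basename(path)), units = units),
    sections))
}

#' @rdname read_database
#' @param dataset an [ff_dataset()]; must validate without errors.
#' @return `write_database()` returns `path` invisibly.
#' @export
write_database <- function(dataset, path) {
  stopifnot(is_ff_dataset(dataset))
  stop_if_invalid(dataset)
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (sec in names(.ff_sections)) {
    df <- section_to_storage(sort_section(dataset[[sec]], sec), sec)
    DBI::dbWriteTable(con, db_table_name(sec), as.data.frame(df))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
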