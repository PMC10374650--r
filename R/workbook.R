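#' Read and write datasets as spreadsheet workbooks
#'
#' The spreadsheet form of the data scheme is a workbook with one sheet per
#' section (`intermolecular`, `bond`, `angle`, `torsion`, `improper`,
#' `1n_potential`, `special`), row 1 carrying the relational column names.
#' Numeric cells stored as text are coerced leniently on read.  Writing
#' produces an XLSX file; reading accepts XLSX as well as legacy XLS (via
#' readxl).  Workbook, database and in-memory forms round-trip without loss
#' at the record level.
#'
#' @param path workbook file path (`.xlsx`; `.xls` accepted on read).
#' @param name,units as in [read_database()].
#' @return `read_workbook()` returns an [ff_dataset()];
#'   `write_workbook()` returns `path` invisibly.
#' @examples
#' wb <- tempfile(fileext = ".xlsx")
#' write_workbook(load_bundled(), wb)
#' read_workbook(wb)
#' @export
read_workbook <- function(path, name = NULL, units = "K-A-e") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "ffdat_format_error")
  }
  have <- readxl::excel_sheets(path)
  sections <- purrr::imap(.ff_sections, function(spec, sec) {
    sheet <- db_table_name(sec)
    if (!sheet %in% have) {
      rlang::abort(sprintf("workbook is missing sheet '%s'", sheet),
                   class = "ffdat_format_error")
    }
    raw <- readxl::read_excel(path, sheet = sheet, col_types = "text")
    storage_to_section(raw, sec, context = sprintf("sheet '%s'", sheet))
  })
  do.call(ff_dataset, c(
    list(name = name %||% sub("\\.[^.]*$", "", basename(path)), units = units),
    sections))
}

#' @rdname read_workbook
#' @param dataset an [ff_dataset()]; must validate without errors.
#' @export
write_workbook <- function(dataset, path) {
  stopifnot(is_ff_dataset(dataset))
  stop_if_invalid(dataset)
  sheets <- purrr::imap(.ff_sections, function(spec, sec) {
    section_to_storage(sort_section(dataset[[sec]], sec), sec)
  })
  names(sheets) <- vapply(names(.ff_sections), db_table_name, character(1))
  xlsx_write(sheets, path)
  invisible(path)
}
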