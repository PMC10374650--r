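# Section layouts: column names and parameter-column counts.  The parameter
# width of each section is fixed at the maximum arity in the registry so the
# relational schema stays static; entries beyond a function's arity are NA.
.ff_sections <- list(
  intermolecular = list(tags = "tag", orders = character(), id = "id1", np = 4L),
  bond     = list(tags = c("tag1", "tag2"), orders = "order", id = "id2", np = 4L),
  angle    = list(tags = paste0("tag", 1:3), orders = paste0("order", 1:2), id = "id3", np = 9L),
  torsion  = list(tags = paste0("tag", 1:4), orders = paste0("order", 1:3), id = "id4", np = 12L),
  improper = list(tags = paste0("tag", 0:3), orders = paste0("order", 1:3), id = "id5", np = 2L),
  one_n    = list(tags = character(), orders = character(), id = NULL, np = 0L),
  special  = list(tags = c("tag1", "tag2"), orders = character(), id = "id7", np = 2L)
)

# canonical column order of a section tibble (tags and orders interleaved
# as in the relational layout)
section_columns <- function(section) {
  s <- .ff_sections[[section]]
  if (section == "one_n") return(c("n", "scaling1", "scaling2", "ref"))
  head_cols <- switch(section,
    intermolecular = "tag",
    bond     = c("tag1", "order", "tag2"),
    angle    = c("tag1", "order1", "tag2", "order2", "tag3"),
    torsion  = c("tag1", "order1", "tag2", "order2", "tag3", "order3", "tag4"),
    improper = c("tag0", "order1", "tag1", "order2", "tag2", "order3", "tag3"),
    special  = c("tag1", "dist", "tag2")
  )
  c(head_cols, s$id, if (s$np > 0L) paste0("p", seq_len(s$np)), "ref")
}

#' Empty dataset section
#'
#' @param section one of `"intermolecular"`, `"bond"`, `"angle"`,
#'   `"torsion"`, `"improper"`, `"one_n"`, `"special"`.
#' @return a zero-row tibble with the section's canonical columns: tag
#'   columns are character (wildcard `"X"` allowed), order/`dist`/`n`
#'   columns integer (`NA` = wildcard order), the id column integer with
#'   `NA` meaning a rigid (`"none"`) entry, parameter columns double,
#'   `ref` character (a DOI).
#' @examples
#' ff_section("bond")
#' @export
ff_section <- function(section = names(.ff_sections)) {
  section <- match.arg(section)
  cols <- section_columns(section)
  out <- purrr::map(cols, function(col) {
    if (startsWith(col, "tag") || col == "ref") character()
    else if (startsWith(col, "p") || startsWith(col, "scaling")) double()
    else integer()
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

as_section <- function(df, section) {
  cols <- section_columns(section)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("section '%s' is missing column(s): %s",
                         section, paste(missing, collapse = ", ")),
                 class = "ffdat_format_error")
  }
  df <- tibble::as_tibble(df)[cols]
  proto <- ff_section(section)
  for (col in cols) {
    target <- proto[[col]]
    v <- df[[col]]
    df[[col]] <- if (is.character(target)) as.character(v)
                 else if (is.double(target)) as.double(v)
                 else as.integer(v)
  }
  df
}

#' Transferable force-field datasets
#'
#' A dataset is the in-memory form of the seven-section relational data
#' format: one tibble per section (`intermolecular`, `bond`, `angle`,
#' `torsion`, `improper`, `one_n`, `special`) plus a name and the unit
#' profile its energies are on.  Tag columns hold tag strings (wildcards
#' allowed), order columns integers (`NA` = wildcard), id columns the
#' potential-function identifier (`NA` = rigid `"none"` entry, in which
#' case `p1` is the fixed length/angle), and `ref` the DOI of the source
#' publication.
#'
#' @param name dataset name.
#' @param units unit-profile name, `"K-A-e"` or `"eV-A-e"`.
#' @param intermolecular,bond,angle,torsion,improper,one_n,special data
#'   frames with the section's canonical columns (see [ff_section()]);
#'   missing sections default to empty.
#' @return an object of class `ff_dataset`.
#' @seealso [validate_dataset()], [read_database()], [load_bundled()]
#' @export
ff_dataset <- function(name = "unnamed", units = "K-A-e",
                       intermolecular = NULL, bond = NULL, angle = NULL,
                       torsion = NULL, improper = NULL, one_n = NULL,
                       special = NULL) {
  sections <- list(intermolecular = intermolecular, bond = bond,
                   angle = angle, torsion = torsion, improper = improper,
                   one_n = one_n, special = special)
  sections <- purrr::imap(sections, function(df, sec) {
    if (is.null(df)) ff_section(sec) else as_section(df, sec)
  })
  structure(c(list(name = name, units = units), sections),
            class = "ff_dataset")
}

#' @export
print.ff_dataset <- function(x, ...) {
  cat(sprintf("<ff_dataset> %s [%s]\n", x$name, x$units))
  for (sec in names(.ff_sections)) {
    cat(sprintf("  %-15s %d record(s)\n", sec, nrow(x[[sec]])))
  }
  invisible(x)
}

#' @rdname ff_dataset
#' @param x object to test.
#' @export
is_ff_dataset <- function(x) inherits(x, "ff_dataset")

#' Pretty-print a dataset as delimited text
#'
#' Writes every section as a tab-separated block (rigid ids as `none`,
#' wildcard orders as `X`), suitable for diffing two datasets.
#'
#' @param dataset an [ff_dataset()].
#' @param path output file; the default writes to the console.
#' @return `path`, invisibly.
#' @export
write_dataset_text <- function(dataset, path = stdout()) {
  stopifnot(is_ff_dataset(dataset))
  lines <- c(sprintf("# %s [%s]", dataset$name, dataset$units))
  for (sec in names(.ff_sections)) {
    df <- section_to_storage(dataset[[sec]], sec)
    lines <- c(lines, sprintf("## %s", db_table_name(sec)),
               paste(names(df), collapse = "\t"),
               if (nrow(df) > 0L)
                 do.call(paste, c(purrr::map(df, format_cell), sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

format_cell <- function(v) {
  out <- vapply(v, function(x) {
    if (is.na(x)) "" else if (is.numeric(x)) format(x, digits = 17) else as.character(x)
  }, character(1))
  out
}

db_table_name <- function(section) {
  if (section == "one_n") "1n_potential" else section
}
section_for_table <- function(table) {
  if (table == "1n_potential") "one_n" else table
}

# --- storage form ----------------------------------------------------------
# The relational/spreadsheet layer stores rigid ids as the literal "none"
# and wildcard orders as "X"; in memory both are NA in typed columns.

section_to_storage <- function(df, section) {
  s <- .ff_sections[[section]]
  out <- df
  if (!is.null(s$id)) {
    out[[s$id]] <- ifelse(is.na(df[[s$id]]), "none", as.character(df[[s$id]]))
  }
  for (col in s$orders) {
    out[[col]] <- ifelse(is.na(df[[col]]), "X", as.character(df[[col]]))
  }
  out
}

storage_to_section <- function(df, section, context = section) {
  s <- .ff_sections[[section]]
  df <- tibble::as_tibble(df)
  cols <- section_columns(section)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("%s: missing column(s): %s",
                         context, paste(missing, collapse = ", ")),
                 class = "ffdat_format_error")
  }
  df <- df[cols]
  coerce_int <- function(v, col, allow = NULL) {
    v_chr <- stringr::str_trim(as.character(v))
    out <- rep(NA_integer_, length(v_chr))
    special <- !is.na(v_chr) & tolower(v_chr) %in% allow
    numeric_ok <- !is.na(v_chr) & !special &
      stringr::str_detect(v_chr, "^-?[0-9]+(\\.0*)?$")
    bad <- !is.na(v_chr) & !special & !numeric_ok
    if (any(bad)) {
      rlang::abort(sprintf("%s, row %d: cannot parse '%s' in column '%s'",
                           context, which(bad)[1L], v_chr[bad][1L], col),
                   class = "ffdat_format_error")
    }
    out[numeric_ok] <- as.integer(as.numeric(v_chr[numeric_ok]))
    out
  }
  if (!is.null(s$id)) {
    df[[s$id]] <- coerce_int(df[[s$id]], s$id, allow = "none")
  }
  for (col in s$orders) {
    df[[col]] <- coerce_int(df[[col]], col, allow = "x")
  }
  for (col in names(df)) {
    if (startsWith(col, "p") || startsWith(col, "scaling") || col %in% c("n", "dist")) {
      v <- df[[col]]
      if (is.character(v)) {
        v <- stringr::str_trim(v)
        v[!nzchar(v)] <- NA_character_
        num <- suppressWarnings(as.numeric(v))
        bad <- !is.na(v) & is.na(num)
        if (any(bad)) {
          rlang::abort(sprintf("%s, row %d: cannot parse '%s' in column '%s'",
                               context, which(bad)[1L], v[bad][1L], col),
                       class = "ffdat_format_error")
        }
        df[[col]] <- num
      }
    }
  }
  # tag syntax is checked here so a broken cell is reported with its row
  for (col in s$tags) {
    v <- df[[col]]
    for (i in seq_along(v)) {
      tryCatch(parse_tag(v[[i]]), error = function(e) {
        rlang::abort(sprintf("%s, row %d, column '%s': %s",
                             context, i, col, conditionMessage(e)),
                     class = "ffdat_format_error")
      })
    }
  }
  as_section(df, section)
}

# deterministic row order: sort by the tag tuple text, then remaining keys
sort_section <- function(df, section) {
  if (nrow(df) == 0L) return(df)
  s <- .ff_sections[[section]]
  keys <- c(s$tags, s$orders,
            intersect(c("n", "dist"), names(df)))
  df[do.call(order, unname(as.list(df[keys]))), ]
}
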