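# Canonical key of a record for duplicate detection.  Reversing a bond,
# angle or torsion tuple describes the same chemistry, so tuples are
# normalized before comparison: bonds sorted lexicographically, angles
# reversed iff tag3 < tag1, torsions reversed iff the reversed text tuple
# sorts lower, improper neighbors treated as a multiset around the center.
record_key <- function(df, section) {
  n <- nrow(df)
  if (n == 0L) return(character())
  ord_chr <- function(v) ifelse(is.na(v), "X", as.character(v))
  switch(section,
    intermolecular = df$tag,
    bond = vapply(seq_len(n), function(i) {
      a <- c(df$tag1[i], df$tag2[i])
      o <- ord_chr(df$order[i])
      paste(c(sort(a), o), collapse = "|")
    }, character(1)),
    angle = vapply(seq_len(n), function(i) {
      fwd <- c(df$tag1[i], ord_chr(df$order1[i]), df$tag2[i],
               ord_chr(df$order2[i]), df$tag3[i])
      rev_ <- fwd[5:1]
      paste(if (paste(rev_, collapse = "|") < paste(fwd, collapse = "|")) rev_ else fwd,
            collapse = "|")
    }, character(1)),
    torsion = vapply(seq_len(n), function(i) {
      fwd <- c(df$tag1[i], ord_chr(df$order1[i]), df$tag2[i], ord_chr(df$order2[i]),
               df$tag3[i], ord_chr(df$order3[i]), df$tag4[i])
      rev_ <- fwd[7:1]
      paste(if (paste(rev_, collapse = "|") < paste(fwd, collapse = "|")) rev_ else fwd,
            collapse = "|")
    }, character(1)),
    improper = vapply(seq_len(n), function(i) {
      nb <- sort(paste(c(df$tag1[i], df$tag2[i], df$tag3[i]),
                       ord_chr(c(df$order1[i], df$order2[i], df$order3[i])), sep = "@"))
      paste(c(df$tag0[i], nb), collapse = "|")
    }, character(1)),
    one_n = as.character(df$n),
    special = vapply(seq_len(n), function(i) {
      paste(c(sort(c(df$tag1[i], df$tag2[i])), df$dist[i]), collapse = "|")
    }, character(1))
  )
}

#' Validate a dataset
#'
#' Checks every record of every section against the scheme's constraints
#' and returns the issues found; it never throws.  `ERROR` issues are
#' structural (bad tag syntax, unknown function id, parameter count not
#' matching the function's arity, duplicate records after symmetry
#' normalization, out-of-range orders/distances); `WARNING` issues are
#' advisory (a `ref` that is not DOI-formatted, a group abbreviation not in
#' the registry).
#'
#' @param dataset an [ff_dataset()].
#' @param groups group registry used for the unknown-group warning.
#' @param registry potential registry used for id/arity checks.
#' @return a tibble with columns `severity`, `section`, `row`, `message`
#'   (zero rows when the dataset is clean).
#' @examples
#' validate_dataset(load_bundled())
#' @export
validate_dataset <- function(dataset, groups = ff_groups(),
                             registry = ff_potentials()) {
  stopifnot(is_ff_dataset(dataset))
  issues <- list()
  add <- function(severity, section, row, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      severity = severity, section = section, row = as.integer(row),
      message = message)
  }
  reg_section <- function(sec) if (sec == "special") "special" else sec

  for (sec in names(.ff_sections)) {
    s <- .ff_sections[[sec]]
    df <- dataset[[sec]]
    if (nrow(df) == 0L) next
    for (i in seq_len(nrow(df))) {
      # tags parse and carry known groups
      for (col in s$tags) {
        t <- tryCatch(parse_tag(df[[col]][i]), error = function(e) e)
        if (inherits(t, "error")) {
          add("ERROR", sec, i, sprintf("column '%s': %s", col, conditionMessage(t)))
        } else if (!is.na(t$group) && !known_group(t$group, groups)) {
          add("WARNING", sec, i,
              sprintf("column '%s': unknown group abbreviation '%s'", col, t$group))
        }
      }
      for (col in s$orders) {
        o <- df[[col]][i]
        if (!is.na(o) && o < 1L) add("ERROR", sec, i, sprintf("%s must be >= 1", col))
      }
      if (sec == "one_n" && (is.na(df$n[i]) || df$n[i] <= 1L)) {
        add("ERROR", sec, i, "n must be > 1")
      }
      if (sec == "special" && (is.na(df$dist[i]) || df$dist[i] < 2L)) {
        add("ERROR", sec, i, "dist must be >= 2")
      }
      # function id and arity
      if (!is.null(s$id)) {
        id <- df[[s$id]][i]
        np_given <- {
          pv <- unlist(df[i, paste0("p", seq_len(s$np))])
          if (all(is.na(pv))) 0L else max(which(!is.na(pv)))
        }
        if (is.na(id)) {           # rigid "none": p1 is the fixed value
          if (sec == "intermolecular") {
            add("ERROR", sec, i, "intermolecular entries cannot be rigid ('none')")
          } else if (np_given != 1L) {
            add("ERROR", sec, i,
                sprintf("rigid entry must carry exactly p1 (the fixed value), got %d", np_given))
          }
        } else if (!known_potential(reg_section(sec), id, registry)) {
          add("ERROR", sec, i, sprintf("unknown %s id %d", s$id, id))
        } else {
          arity <- potential_arity(reg_section(sec), id, registry)
          if (np_given != arity) {
            add("ERROR", sec, i,
                sprintf("%s=%d expects %d parameter(s), got %d", s$id, id, arity, np_given))
          }
        }
      }
      ref <- df$ref[i]
      if (is.na(ref) || !startsWith(ref, "10.")) {
        add("WARNING", sec, i, "ref is not a DOI (expected prefix '10.')")
      }
    }
    keys <- record_key(df, sec)
    dup <- duplicated(keys)
    for (i in which(dup)) {
      add("ERROR", sec, i,
          sprintf("duplicate record (same key as row %d after symmetry normalization)",
                  match(keys[i], keys)))
    }
  }
  if (length(issues) == 0L) {
    tibble::tibble(severity = character(), section = character(),
                   row = integer(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

stop_if_invalid <- function(dataset, ...) {
  issues <- validate_dataset(dataset, ...)
  errs <- issues[issues$severity == "ERROR", ]
  if (nrow(errs) > 0L) {
    rlang::abort(
      c("dataset fails validation:",
        sprintf("%s row %d: %s", errs$section, errs$row, errs$message)),
      class = "ffdat_validation_error"
    )
  }
  invisible(issues)
}
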